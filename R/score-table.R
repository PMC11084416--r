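#' Load a declarative score table
#'
#' A score table fully specifies one scoring algorithm: an ordered list of
#' items, each mapping clinical levels to integer points; a strict
#' positivity threshold (`related` iff net score `> threshold`); contiguous
#' category bands covering every reachable score; and a category-to-binary
#' map recording the conventional related/unrelated reading of the bands.
#'
#' Band coverage is validated against the analytic minimum and maximum of
#' the item points: a gap, an overlap, or a reachable score outside all
#' bands is a configuration error.
#'
#' @param path Path to a YAML score-table config.
#' @return A validated `score_table` object.
#' @seealso [default_score_table()], [classify()]
#' @export
load_score_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("score table config not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  tab <- .validate_score_table(cfg, path)
  tab$source <- normalizePath(path)
  tab
}

#' Shipped default score tables
#'
#' Returns one of the score tables installed with the package:
#' `"aldress"` (DRESS-specific causality score, positive when net score
#' exceeds 7), `"sefv"` (Spanish Pharmacovigilance System seven-factor
#' score, positive above 6), or `"regiscar"` (RegiSCAR DRESS validation
#' score with excluded/possible/probable/definite bands).
#'
#' The ALDRESS point allocation shipped here is this package's documented
#' convention, constrained by the published positivity rule (score > 7) and
#' the requirement that a textbook single-drug presentation scores as
#' related; it is fully overridable via [load_score_table()].
#'
#' @param name `"aldress"`, `"sefv"`, or `"regiscar"`.
#' @return A `score_table` object.
#' @export
default_score_table <- function(name = c("aldress", "sefv", "regiscar")) {
  name <- match.arg(name)
  cached <- .table_cache[[name]]
  if (!is.null(cached)) return(cached)
  tab <- load_score_table(system.file("extdata", paste0(name, ".yaml"),
                                      package = "aldress", mustWork = TRUE))
  .table_cache[[name]] <- tab
  tab
}

.table_cache <- new.env(parent = emptyenv())

.validate_score_table <- function(cfg, where = "config") {
  for (f in c("algorithm", "items", "positivity_threshold", "bands",
              "binary_map")) {
    if (is.null(cfg[[f]])) {
      stop(sprintf("score table '%s' lacks required field '%s'", where, f),
           call. = FALSE)
    }
  }
  thr <- cfg$positivity_threshold
  if (length(thr) != 1L || is.na(thr) || thr != as.integer(thr)) {
    stop(sprintf("positivity_threshold must be a single integer in '%s'",
                 where), call. = FALSE)
  }
  items <- cfg$items
  ids <- vapply(items, function(it) it$id %||% "", character(1))
  if (any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop(sprintf("score table '%s' has missing or duplicated item ids", where),
         call. = FALSE)
  }
  for (it in items) {
    pts <- unlist(it$levels)
    if (length(pts) == 0L || any(is.na(pts)) ||
        any(pts != as.integer(pts))) {
      stop(sprintf("item '%s' must map each level to one integer (in '%s')",
                   it$id, where), call. = FALSE)
    }
  }
  min_sum <- sum(vapply(items, function(it) min(unlist(it$levels)), numeric(1)))
  max_sum <- sum(vapply(items, function(it) max(unlist(it$levels)), numeric(1)))
  bands <- cfg$bands
  bmin <- vapply(bands, function(b) as.numeric(b$min), numeric(1))
  bmax <- vapply(bands, function(b) as.numeric(b$max), numeric(1))
  bname <- vapply(bands, function(b) as.character(b$name), character(1))
  ord <- order(bmin)
  bmin <- bmin[ord]; bmax <- bmax[ord]; bname <- bname[ord]
  if (any(bmax < bmin)) {
    stop(sprintf("score table '%s' has a band with max < min", where),
         call. = FALSE)
  }
  if (length(bmin) > 1L && any(bmin[-1] != bmax[-length(bmax)] + 1)) {
    stop(sprintf("category bands of '%s' have a gap or overlap", where),
         call. = FALSE)
  }
  if (bmin[1] > min_sum || bmax[length(bmax)] < max_sum) {
    stop(sprintf(
      "category bands of '%s' do not cover reachable scores [%d, %d]",
      where, min_sum, max_sum), call. = FALSE)
  }
  bm <- cfg$binary_map
  if (!setequal(names(bm), bname) ||
      !all(unlist(bm) %in% c("related", "unrelated"))) {
    stop(sprintf(
      "binary_map of '%s' must map every band to related/unrelated", where),
      call. = FALSE)
  }
  structure(list(
    algorithm = as.character(cfg$algorithm),
    description = cfg$description %||% "",
    items = items,
    positivity_threshold = as.integer(thr),
    bands = data.frame(name = bname, min = bmin, max = bmax,
                       stringsAsFactors = FALSE),
    binary_map = bm,
    min_score = min_sum,
    max_score = max_sum
  ), class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table %s> %d items, scores in [%d, %d], positive > %d\n",
              x$algorithm, length(x$items), x$min_score, x$max_score,
              x$positivity_threshold))
  invisible(x)
}

# Sum item points for a named list of levels; error on a level the table
# does not cover (configuration error, per contract).
.score_items <- function(levels, table) {
  pts <- integer(length(table$items))
  names(pts) <- vapply(table$items, function(it) it$id, character(1))
  for (it in table$items) {
    lev <- levels[[it$id]]
    if (is.null(lev)) {
      stop(sprintf("no level supplied for item '%s' of algorithm '%s'",
                   it$id, table$algorithm), call. = FALSE)
    }
    p <- it$levels[[lev]]
    if (is.null(p)) {
      stop(sprintf(
        "level '%s' of item '%s' is absent from the '%s' score table",
        lev, it$id, table$algorithm), call. = FALSE)
    }
    pts[[it$id]] <- as.integer(p)
  }
  pts
}

#' Classify a net score under a score table
#'
#' Looks up the category band containing `score` and applies the strict
#' positivity rule: `related` is `TRUE` iff `score > positivity_threshold`.
#' A score equal to the threshold is therefore unrelated.
#'
#' @param score Integer net score.
#' @param table A `score_table`.
#' @param binary `"threshold"` (default; the validated positivity rule) or
#'   `"category"` (the conventional related = possible/probable/definite
#'   reading via the table's `binary_map`).
#' @return List with `category` (band name) and `related` (logical).
#' @export
classify <- function(score, table, binary = c("threshold", "category")) {
  binary <- match.arg(binary)
  stopifnot(inherits(table, "score_table"), length(score) == 1L, !is.na(score))
  b <- table$bands
  hit <- which(score >= b$min & score <= b$max)
  if (length(hit) != 1L) {
    stop(sprintf("score %d is outside the bands of the '%s' table",
                 score, table$algorithm), call. = FALSE)
  }
  category <- b$name[hit]
  related <- if (binary == "threshold") {
    score > table$positivity_threshold
  } else {
    identical(table$binary_map[[category]], "related")
  }
  list(category = category, related = related)
}
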