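#' Exact agreement between two score vectors
#'
#' Fraction of positions where two raters (or two algorithms) produced an
#' identical value — e.g. matching net scores.
#'
#' @param scores_a,scores_b Vectors of equal, nonzero length.
#' @return Proportion of exact matches in `[0, 1]`.
#' @examples
#' percent_agreement(c(1, 2, 3), c(1, 2, 4)) # 2/3
#' @export
percent_agreement <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must have the same length", call. = FALSE)
  }
  if (length(scores_a) == 0L) {
    stop("score vectors must be nonempty", call. = FALSE)
  }
  mean(scores_a == scores_b)
}

.kappa_weights <- function(k, weighting) {
  d <- abs(outer(seq_len(k), seq_len(k), `-`))
  if (k == 1L) return(matrix(1, 1, 1))
  switch(weighting,
         unweighted = (d == 0) * 1,
         linear = 1 - d / (k - 1),
         quadratic = 1 - (d / (k - 1))^2)
}

#' Cohen's kappa with asymptotic inference
#'
#' Chance-corrected agreement between two raters over a shared ordered
#' category set: `kappa = (p_o - p_e) / (1 - p_e)` with agreement weights
#' `w_ij` applied to both the observed and the chance-expected proportions.
#' Weights are identity (unweighted), linear `1 - |i-j|/(k-1)`, or
#' quadratic `1 - ((i-j)/(k-1))^2`. The standard error is the large-sample
#' value under the alternative (Fleiss-Cohen-Everitt), used for both the z
#' statistic (`z = kappa/ase`) and the confidence interval
#' (`kappa +/- z_{alpha/2} * ase`), with a two-sided normal p-value.
#'
#' With two categories every weighting collapses to the same single
#' off-diagonal weight level, so weighted and unweighted kappa coincide on
#' binary ratings.
#'
#' @param ratings_a,ratings_b Vectors of equal length (at least 2) holding
#'   categories from a shared set.
#' @param weighting `"unweighted"`, `"linear"`, or `"quadratic"`.
#' @param categories Ordered category levels; defaults to the sorted union
#'   of the observed values. Order matters for weighted kappa.
#' @param alpha Significance level for the interval, default 0.05.
#' @return A `kappa_result` with `kappa`, `ase`, `z`, `p_value`, `ci_low`,
#'   `ci_high`, `weighting`, `interpretation` (Landis-Koch band), `n`, and
#'   the contingency `table`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b,
                        weighting = c("unweighted", "linear", "quadratic"),
                        categories = NULL, alpha = 0.05) {
  weighting <- match.arg(weighting)
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have the same length", call. = FALSE)
  }
  if (length(ratings_a) < 2L) {
    stop("need at least two rated subjects", call. = FALSE)
  }
  if (anyNA(ratings_a) || anyNA(ratings_b)) {
    stop("ratings must not contain missing values", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- sort(unique(c(ratings_a, ratings_b)))
  }
  if (!all(c(ratings_a, ratings_b) %in% categories)) {
    stop("ratings contain values outside the category set", call. = FALSE)
  }
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  tab <- table(fa, fb)
  n <- length(ratings_a)
  k <- length(categories)
  p <- tab / n
  r <- rowSums(p); cc <- colSums(p)
  w <- .kappa_weights(k, weighting)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cc))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop(paste("kappa is undefined: expected agreement is 1",
               "(both raters confined to a single category)"), call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance under the alternative.
  wr <- as.vector(w %*% cc)   # row-wise weighted column margins
  wc <- as.vector(t(w) %*% r) # column-wise weighted row margins
  term <- (w - outer(wr, wc, `+`) * (1 - kappa))^2
  v <- (sum(p * term) - (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  ase <- sqrt(max(v, 0))
  z <- if (ase > 0) kappa / ase else NA_real_
  crit <- stats::qnorm(1 - alpha / 2)
  structure(list(
    kappa = kappa, ase = ase, z = z,
    p_value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
    ci_low = kappa - crit * ase, ci_high = kappa + crit * ase,
    weighting = weighting, alpha = alpha,
    interpretation = interpret_kappa(kappa),
    n = n, table = tab
  ), class = "kappa_result")
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bands: below 0.10 no agreement, 0.10-0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81 and above near perfect.
#'
#' @param kappa A value in `[-1, 1]`.
#' @return One of `"none"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"near_perfect"`.
#' @examples
#' interpret_kappa(0.576) # moderate
#' interpret_kappa(0.88)  # near_perfect
#' @export
interpret_kappa <- function(kappa) {
  if (length(kappa) != 1L || is.na(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must be a single value in [-1, 1]", call. = FALSE)
  }
  if (kappa < 0.10) "none"
  else if (kappa < 0.21) "slight"
  else if (kappa < 0.41) "fair"
  else if (kappa < 0.61) "moderate"
  else if (kappa < 0.81) "substantial"
  else "near_perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s, n = %d)\n", x$weighting, x$n))
  cat(sprintf("  Value %.4f   ASE %.4f   Z %.3f   Pr(<|z|) %.3g   %.0f%% CI %.3f-%.3f\n",
              x$kappa, x$ase, x$z, x$p_value, 100 * (1 - x$alpha),
              x$ci_low, x$ci_high))
  cat(sprintf("  Landis-Koch: %s agreement\n",
              gsub("_", " ", x$interpretation)))
  invisible(x)
}
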