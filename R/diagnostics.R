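#' Cross-tabulate binary calls against reference labels
#'
#' @param truth,predicted Logical vectors of equal, nonzero length without
#'   missing values.
#' @return A `confusion_matrix` list with counts `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length", call. = FALSE)
  }
  if (length(truth) == 0L) {
    stop("cannot cross-tabulate empty vectors", call. = FALSE)
  }
  if (anyNA(truth) || anyNA(predicted)) {
    stop("truth and predicted must not contain missing values", call. = FALSE)
  }
  confusion_matrix(tp = sum(truth & predicted),
                   fn = sum(truth & !predicted),
                   fp = sum(!truth & predicted),
                   tn = sum(!truth & !predicted))
}

#' Construct a 2x2 confusion matrix from counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts (total at least 1).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != as.integer(counts))) {
    stop("confusion matrix counts must be non-negative integers",
         call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion matrix must hold at least one subject",
                            call. = FALSE)
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Inverts the exact binomial tail probabilities: the lower bound solves
#' the upper tail at `alpha/2` (0 when `x = 0`), the upper bound the lower
#' tail at `alpha/2` (1 when `x = n`), computed through the beta-quantile
#' form of the binomial tail sums.
#'
#' @param x Number of successes (0 to `n`).
#' @param n Number of trials (at least 1).
#' @param alpha Two-sided significance level, default 0.05.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' exact_binomial_ci(6, 7)   # 0.4213 to 0.9964
#' exact_binomial_ci(28, 30) # 0.7793 to 0.9918
#' @export
exact_binomial_ci <- function(x, n, alpha = 0.05) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != as.integer(x) || n != as.integer(n)) {
    stop("require integers 0 <= x <= n with n >= 1", call. = FALSE)
  }
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

.metric_with_ci <- function(x, n, alpha) {
  if (n == 0) {
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                x = x, n = n, alpha = alpha, undefined = TRUE))
  }
  ci <- exact_binomial_ci(x, n, alpha)
  list(estimate = x / n, ci_low = unname(ci["low"]),
       ci_high = unname(ci["high"]), x = x, n = n, alpha = alpha,
       undefined = FALSE)
}

#' Diagnostic accuracy report for a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy, each with a Clopper-Pearson exact confidence interval, plus
#' the positive likelihood ratio computed from the unrounded sensitivity
#' and specificity. A metric whose denominator is zero is flagged
#' `undefined` (estimate `NA`), never silently reported as 0; the
#' likelihood ratio is undefined when specificity is 1.
#'
#' @param cm A `confusion_matrix`.
#' @param alpha Significance level for the intervals, default 0.05.
#' @return A `diagnostic_report` object.
#' @examples
#' diagnostic_report(confusion_matrix(tp = 6, fn = 1, fp = 2, tn = 28))
#' @export
diagnostic_report <- function(cm, alpha = 0.05) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  sens <- .metric_with_ci(cm$tp, cm$tp + cm$fn, alpha)
  spec <- .metric_with_ci(cm$tn, cm$tn + cm$fp, alpha)
  lr <- if (sens$undefined || spec$undefined || spec$estimate == 1) NA_real_
        else sens$estimate / (1 - spec$estimate)
  structure(list(
    cm = cm, n = n, alpha = alpha,
    sensitivity = sens,
    specificity = spec,
    ppv = .metric_with_ci(cm$tp, cm$tp + cm$fp, alpha),
    npv = .metric_with_ci(cm$tn, cm$tn + cm$fn, alpha),
    accuracy = .metric_with_ci(cm$tp + cm$tn, n, alpha),
    lr_positive = lr
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy (n = %d; %.0f%% CI, Clopper-Pearson)\n",
              x$n, 100 * (1 - x$alpha)))
  fmt <- function(name, m) {
    if (m$undefined) {
      cat(sprintf("  %-28s undefined (denominator 0)\n", name))
    } else {
      cat(sprintf("  %-28s %.4f   %.4f to %.4f\n", name, m$estimate,
                  m$ci_low, m$ci_high))
    }
  }
  fmt("Sensitivity", x$sensitivity)
  fmt("Specificity", x$specificity)
  fmt("Positive Predictive Value", x$ppv)
  fmt("Negative Predictive Value", x$npv)
  fmt("Accuracy", x$accuracy)
  cat(sprintf("  %-28s %s\n", "Likelihood Ratio (+)",
              if (is.na(x$lr_positive)) "undefined"
              else sprintf("%.2f", x$lr_positive)))
  invisible(x)
}

#' Flatten a diagnostic report to a data frame
#'
#' @param x A `diagnostic_report`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return Data frame with columns `metric`, `estimate`, `ci_low`, `ci_high`.
#' @export
as.data.frame.diagnostic_report <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  metrics <- list(sensitivity = x$sensitivity, specificity = x$specificity,
                  ppv = x$ppv, npv = x$npv, accuracy = x$accuracy)
  df <- data.frame(
    metric = c(names(metrics), "lr_positive"),
    estimate = c(vapply(metrics, `[[`, numeric(1), "estimate"), x$lr_positive),
    ci_low = c(vapply(metrics, `[[`, numeric(1), "ci_low"), NA_real_),
    ci_high = c(vapply(metrics, `[[`, numeric(1), "ci_high"), NA_real_),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Fisher's exact test for a 2x2 confusion matrix
#'
#' Two-sided p-value obtained by summing, at fixed margins, the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (the conventional two-sided rule; no mid-p correction).
#'
#' @param cm A `confusion_matrix`.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}
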