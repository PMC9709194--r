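# Validation statistics: paired t, Pearson correlation, one-sample t of
# paired differences, per-class accuracy. All tests are two-sided.
# Zero-variance inputs yield an explicitly flagged degenerate result
# instead of infinite statistics.

check_paired <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  invisible(TRUE)
}

#' One-sample t-test with degenerate handling
#'
#' Two-sided Student t-test of `differences` against `mu0`. When the
#' differences have zero variance the result is flagged `degenerate`: the
#' statistic is 0 with p = 1 if the mean equals `mu0` (no evidence either
#' way from constant data), otherwise NA.
#'
#' @param differences Numeric vector, length >= 3.
#' @param mu0 Null mean.
#' @return List with `mean`, `sd`, `t`, `p`, `df`, `n`, `degenerate`.
#' @examples
#' one_sample_t(c(1, 2, 3, 4, 5))  # t = 4.243
#' @export
one_sample_t <- function(differences, mu0 = 0) {
  stopifnot(is.numeric(differences), all(is.finite(differences)))
  n <- length(differences)
  if (n < 3L) stop("need at least 3 observations")
  m <- mean(differences); s <- sd(differences)
  if (s == 0) {
    return(list(mean = m, sd = 0, t = if (m == mu0) 0 else NA_real_,
                p = if (m == mu0) 1 else NA_real_, df = n - 1L, n = n,
                degenerate = TRUE))
  }
  ht <- t.test(differences, mu = mu0)
  list(mean = m, sd = s, t = unname(ht$statistic), p = ht$p.value,
       df = n - 1L, n = n, degenerate = FALSE)
}

#' Paired t-test
#'
#' Two-sided paired Student t on the differences `x - y` (df = n - 1);
#' identical to [one_sample_t()] of the differences against 0.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return List with `t`, `p`, `df`, `mean_diff`, `sd_diff`, `n`,
#'   `degenerate`.
#' @examples
#' paired_t(c(1, 2, 3, 4), c(2, 3, 5, 6))  # t = -5.196
#' @export
paired_t <- function(x, y) {
  check_paired(x, y)
  r <- one_sample_t(x - y, mu0 = 0)
  list(t = r$t, p = r$p, df = r$df, mean_diff = r$mean, sd_diff = r$sd,
       n = r$n, degenerate = r$degenerate)
}

#' Pearson correlation
#'
#' Product-moment correlation with its square reported alongside.
#'
#' @param x,y Equal-length numeric vectors with nonzero variance.
#' @return List with `r` and `r_squared`.
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4))  # r = 0.9820
#' @export
pearson <- function(x, y) {
  check_paired(x, y)
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  r <- cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Per-class recognition accuracy
#'
#' Percent of correct predictions per class and overall, formatted to two
#' decimals in the `accuracy_pct` column (exact values kept in
#' `accuracy`).
#'
#' @param labels_true True class labels.
#' @param labels_pred Predicted labels, same length.
#' @param classes Optional class ordering; defaults to the classes present
#'   in `labels_true`.
#' @return Data frame with columns `class`, `n`, `correct`, `accuracy`,
#'   `accuracy_pct`; the final row is the overall total.
#' @export
class_accuracy <- function(labels_true, labels_pred, classes = NULL) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length")
  }
  labels_true <- as.character(labels_true)
  labels_pred <- as.character(labels_pred)
  if (is.null(classes)) classes <- unique(labels_true)
  if (!all(labels_true %in% classes)) stop("labels outside the class set")
  rows <- lapply(classes, function(cl) {
    sel <- labels_true == cl
    if (!any(sel)) stop("empty class: ", cl)
    data.frame(class = cl, n = sum(sel),
               correct = sum(labels_pred[sel] == cl))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(class = "overall", n = length(labels_true),
                               correct = sum(labels_true == labels_pred)))
  out$accuracy <- 100 * out$correct / out$n
  out$accuracy_pct <- sprintf("%.2f%%", out$accuracy)
  out
}

#' Validation report for estimated vs measured values
#'
#' Runs the full validation battery on paired estimates and measurements:
#' paired t-test, Pearson correlation, and the one-sample t-test of the
#' differences (estimated - measured) against zero, reporting mean and sd
#' of the differences.
#'
#' @param estimated,measured Equal-length numeric vectors, length >= 3.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(estimated, measured) {
  check_paired(estimated, measured)
  d <- estimated - measured
  pt <- paired_t(estimated, measured)
  pr <- if (var(estimated) > 0 && var(measured) > 0) {
    pearson(estimated, measured)
  } else {
    list(r = NA_real_, r_squared = NA_real_)
  }
  ot <- one_sample_t(d, mu0 = 0)
  structure(list(n = length(d), mean_diff = mean(d), sd_diff = sd(d),
                 paired_t = pt, pearson_r = pr$r, r_squared = pr$r_squared,
                 one_sample_t = ot),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  n = %d pairs\n", x$n))
  cat(sprintf("  difference (estimated - measured): %.3f +/- %.3f\n",
              x$mean_diff, x$sd_diff))
  cat(sprintf("  paired t = %s, p = %s\n", format(x$paired_t$t, digits = 4),
              format(x$paired_t$p, digits = 4)))
  cat(sprintf("  Pearson r = %.4f (R^2 = %.4f)\n", x$pearson_r, x$r_squared))
  cat(sprintf("  one-sample t of differences: t = %s, p = %s\n",
              format(x$one_sample_t$t, digits = 4),
              format(x$one_sample_t$p, digits = 4)))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A [validation_report()].
#' @param path Output path (omit to get the JSON string).
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
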