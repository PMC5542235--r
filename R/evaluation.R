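#' Confusion counts from per-case predictions
#'
#' The positive class is IDH-mutant (label 1) throughout: `tp` counts
#' mutants predicted mutant, `tn` wild-types predicted wild-type.
#'
#' @param preds a `case_predictions` data frame (see [loocv()]) or any
#'   data frame with `predicted` and `truth` columns in 0/1.
#' @return Object of class `confusion_counts`: named integer vector
#'   `c(tp, fn, fp, tn)`.
#' @export
confusion <- function(preds) {
  stopifnot(is.data.frame(preds), nrow(preds) > 0,
            all(c("predicted", "truth") %in% names(preds)))
  pr <- preds$predicted
  tr <- preds$truth
  stopifnot(all(pr %in% c(0, 1)), all(tr %in% c(0, 1)))
  out <- c(tp = sum(pr == 1 & tr == 1), fn = sum(pr == 0 & tr == 1),
           fp = sum(pr == 1 & tr == 0), tn = sum(pr == 0 & tr == 0))
  structure(as.integer(out), names = names(out), class = "confusion_counts")
}

#' Build confusion counts directly
#'
#' @param tp,fn,fp,tn non-negative counts (positive class = IDH-mutant).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(v >= 0), all(v == round(v)))
  structure(as.integer(v), names = names(v), class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity
#'
#' `accuracy = (tp + tn) / n`, `sensitivity = tp / (tp + fn)` (over the
#' true mutants), `specificity = tn / (tn + fp)` (over the true
#' wild-types).
#'
#' @param c a [confusion_counts()] object.
#' @return Named vector `c(accuracy, sensitivity, specificity)`.
#' @export
performance <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- sum(c)
  if (n == 0) stop("undefined metric: empty confusion table", call. = FALSE)
  pos <- c["tp"] + c["fn"]
  neg <- c["tn"] + c["fp"]
  if (pos == 0)
    stop("undefined metric: sensitivity needs at least one true mutant",
         call. = FALSE)
  if (neg == 0)
    stop("undefined metric: specificity needs at least one true wild-type",
         call. = FALSE)
  c(accuracy = unname((c["tp"] + c["tn"]) / n),
    sensitivity = unname(c["tp"] / pos),
    specificity = unname(c["tn"] / neg))
}

#' Cohen's kappa with agreement band
#'
#' Chance-corrected agreement between predicted and true status:
#' `kappa = (Po - Pe) / (1 - Pe)` with observed agreement
#' `Po = (tp + tn)/n` and expected agreement `Pe` from the row/column
#' marginals. Bands (intervals closed on the right): slight up to 0.20,
#' fair to 0.40, moderate to 0.60, substantial to 0.80, almost perfect
#' above.
#'
#' @param c a [confusion_counts()] object.
#' @return List with `kappa` and `band`.
#' @export
cohens_kappa <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- sum(c)
  if (n == 0) stop("undefined kappa: empty confusion table", call. = FALSE)
  tp <- c[["tp"]]; fn <- c[["fn"]]; fp <- c[["fp"]]; tn <- c[["tn"]]
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe == 1)
    stop("undefined kappa: degenerate marginals (expected agreement 1)",
         call. = FALSE)
  k <- (po - pe) / (1 - pe)
  list(kappa = k, band = kappa_band(k))
}

kappa_band <- function(k) {
  if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' Chi-squared comparison of two correct-classification proportions
#'
#' Pearson chi-squared test (1 degree of freedom, no continuity
#' correction) on the 2x2 table of correct/incorrect counts of two models,
#' as used to compare accuracy, sensitivity or specificity between feature
#' sets.
#'
#' @param correct_a,n_a correct count and total for model A.
#' @param correct_b,n_b correct count and total for model B.
#' @return List with `chi2` and two-sided `p`.
#' @export
compare_chi_squared <- function(correct_a, n_a, correct_b, n_b) {
  stopifnot(n_a > 0, n_b > 0, correct_a <= n_a, correct_b <= n_b,
            correct_a >= 0, correct_b >= 0)
  tab <- rbind(c(correct_a, n_a - correct_a),
               c(correct_b, n_b - correct_b))
  if (any(colSums(tab) == 0))
    stop("undefined test: zero-margin contingency table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Full performance report for one set of predictions
#'
#' @param preds a `case_predictions` data frame.
#' @return Object of class `performance_report`: `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `kappa`, `kappa_band`, `n`.
#' @export
performance_report <- function(preds) {
  cc <- confusion(preds)
  perf <- performance(cc)
  kap <- cohens_kappa(cc)
  structure(list(confusion = cc, accuracy = perf[["accuracy"]],
                 sensitivity = perf[["sensitivity"]],
                 specificity = perf[["specificity"]],
                 kappa = kap$kappa, kappa_band = kap$band, n = sum(cc)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cc <- x$confusion
  cat(sprintf("accuracy    %2.0f%% (%d/%d)\n", 100 * x$accuracy,
              cc[["tp"]] + cc[["tn"]], x$n))
  cat(sprintf("sensitivity %2.0f%% (%d/%d)\n", 100 * x$sensitivity,
              cc[["tp"]], cc[["tp"]] + cc[["fn"]]))
  cat(sprintf("specificity %2.0f%% (%d/%d)\n", 100 * x$specificity,
              cc[["tn"]], cc[["tn"]] + cc[["fp"]]))
  cat(sprintf("kappa       %.3f (%s)\n", x$kappa, x$kappa_band))
  invisible(x)
}
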