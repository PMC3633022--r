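#' Classification performance metrics
#'
#' Computes the confusion counts and derived metrics for scored two-class
#' predictions at a decision threshold: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), positive predictive value ppv = TP/(TP+FP),
#' F1 = 2 * sensitivity * ppv / (sensitivity + ppv), and AUC. Allergens are
#' the positive class.
#'
#' AUC is the Mann-Whitney rank statistic: the probability that a random
#' allergen scores above a random non-allergen, with ties counted half.
#' This form is used because nearest-neighbour scores are coarse (multiples
#' of 1/k), so tie handling matters.
#'
#' A single-class input leaves the undefined metrics as `NA` with a
#' warning — never silently zero.
#'
#' @param labels True class labels (`"allergen"` / `"non-allergen"`).
#' @param scores Predicted allergen scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5); a score at or above
#'   it predicts allergen.
#' @return A `metrics_report` list: `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `f1`, `auc`, `threshold`, `n_evaluated`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (!length(labels) || length(labels) != length(scores)) {
    stop("'labels' and 'scores' must be non-empty and equal length",
         call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("scores must be in [0, 1]", call. = FALSE)
  }
  pos <- labels == "allergen"
  pred <- scores >= threshold
  tp <- sum(pos & pred); fn <- sum(pos & !pred)
  tn <- sum(!pos & !pred); fp <- sum(!pos & pred)

  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (denominator 0); reported as NA", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  ppv <- safe_div(tp, tp + fp, "ppv")
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_ else {
    2 * sens * ppv / (sens + ppv)
  }
  auc <- if (any(pos) && any(!pos)) auc_rank(scores, pos) else {
    warning("AUC undefined for single-class input; reported as NA",
            call. = FALSE)
    NA_real_
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec, ppv = ppv,
                 f1 = f1, auc = auc, threshold = threshold,
                 n_evaluated = length(labels)),
            class = "metrics_report")
}

# Mann-Whitney AUC with half-credit for ties, via mid-ranks
auc_rank <- function(scores, pos) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Performance at threshold %.2f (n = %d)\n", x$threshold, x$n_evaluated))
  cat(sprintf("  TP=%d FN=%d TN=%d FP=%d\n", x$tp, x$fn, x$tn, x$fp))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("  sensitivity=%s specificity=%s ppv=%s F1=%s AUC=%s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$f1), fmt(x$auc)))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
             sensitivity = x$sensitivity, specificity = x$specificity,
             ppv = x$ppv, f1 = x$f1, auc = x$auc,
             threshold = x$threshold, n_evaluated = x$n_evaluated)
}
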