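# Tracer-agreement chi-square tests and ROC derivation of CL cutoffs for
# regional positivity.

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' Statistic = sum (O - E)^2 / E over the four cells; p from the upper tail
#' of chi-square with 1 df. No Yates correction is applied: the
#' uncorrected statistic is the one that matches published tracer-agreement
#' tables. A table with a zero row or column sum is degenerate: the statistic
#' is defined as 0 with `degenerate = TRUE` and p = 1.
#'
#' @param counts 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   counts; rows = the two tracers, columns = negative/positive calls.
#' @return A tibble with `statistic`, `p_value`, `df`, `degenerate`.
#' @export
chi_square_2x2 <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  stopifnot(all(dim(m) == c(2, 2)))
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) < 1) stop("empty table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble::tibble(statistic = 0, p_value = 1, df = 1L,
                          degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value), df = 1L, degenerate = FALSE)
}

#' ROC analysis of the global CL scale against regional positivity
#'
#' Sweeps the decision threshold over midpoints of sorted unique scores plus
#' +/- infinity (score >= threshold is called positive), reports the
#' trapezoidal AUC (equal to the Mann-Whitney rank statistic), and selects
#' the operating cutoff maximizing accuracy (TP + TN)/N -- the "most accurate
#' detection" rule -- with ties broken toward the lowest cutoff. Youden's J
#' is available as an alternative rule.
#'
#' @param scores Numeric vector (e.g. CL values).
#' @param labels Logical, or factor/character/0-1 vector; `TRUE`/"positive"/1
#'   marks the positive class. Both classes must be present.
#' @param rule Cutoff selection rule, `"accuracy"` (default) or `"youden"`.
#' @return An `aq_roc` list: `auc`, `cutoff`, `sensitivity`, `specificity`,
#'   `accuracy` (percent, at the cutoff), `curve` (tibble of threshold, tpr,
#'   fpr, accuracy), `n_pos`, `n_neg`. Has [tidy()]/[glance()]/[autoplot()]
#'   methods.
#' @export
roc_analysis <- function(scores, labels, rule = c("accuracy", "youden")) {
  rule <- match.arg(rule)
  lab <- normalize_labels(labels)
  stopifnot(length(scores) == length(lab))
  ok <- is.finite(scores)
  scores <- scores[ok]; lab <- lab[ok]
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & lab) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !lab) / n_neg, 0)
  acc <- vapply(thr, function(t) (sum(scores >= t & lab) +
                                    sum(scores < t & !lab)) / length(lab), 0)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(ord)]) / 2)
  crit <- if (rule == "accuracy") acc else tpr - fpr
  best <- which(crit == max(crit))
  pick <- best[which.min(thr[best])]   # ties toward the lowest cutoff
  structure(list(
    auc = auc, cutoff = thr[pick],
    sensitivity = 100 * tpr[pick],
    specificity = 100 * (1 - fpr[pick]),
    accuracy = 100 * acc[pick],
    rule = rule,
    curve = tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr,
                           accuracy = acc),
    n_pos = n_pos, n_neg = n_neg
  ), class = "aq_roc")
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  lx <- tolower(as.character(labels))
  stopifnot(all(lx %in% c("positive", "negative", "pos", "neg", "true", "false")))
  lx %in% c("positive", "pos", "true")
}

#' @export
print.aq_roc <- function(x, ...) {
  cat(sprintf("<aq_roc> AUC %.4f; cutoff %.4g (%s rule): sens %.1f%%, spec %.1f%%, acc %.1f%% (n+ %d, n- %d)\n",
              x$auc, x$cutoff, x$rule, x$sensitivity, x$specificity,
              x$accuracy, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy aq_roc
#' @export
tidy.aq_roc <- function(x, ...) x$curve

#' @method glance aq_roc
#' @export
glance.aq_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method autoplot aq_roc
#' @export
autoplot.aq_roc <- function(object, ...) {
  pick <- which.min(abs(object$curve$threshold - object$cutoff))
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(data = object$curve[pick, ], colour = "firebrick", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC %.3f; cutoff %.3g (sens %.1f%%, spec %.1f%%)",
                                  object$auc, object$cutoff,
                                  object$sensitivity, object$specificity)) +
    ggplot2::theme_minimal()
}
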