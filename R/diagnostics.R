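# ROC curve construction and AUC for any scalar marker.

#' ROC curve with trapezoidal AUC
#'
#' Sweeps thresholds over the unique marker values (ties grouped at a single
#' threshold), accumulating true- and false-positive rates from (0,0) to
#' (1,1), and integrates the curve by the trapezoidal rule. The marker
#' orientation must be declared: `"higher-in-positive"` scores positives
#' high, `"lower-in-positive"` scores them low (e.g. a silenced tumor
#' suppressor whose low expression marks tumors). `"auto"` picks the
#' orientation with AUC >= 0.5 and records the choice.
#'
#' @param scores numeric marker values, one per sample.
#' @param labels `"positive"`/`"negative"` per sample (or a logical vector,
#'   `TRUE` = positive).
#' @param direction `"higher-in-positive"`, `"lower-in-positive"`, or
#'   `"auto"`.
#' @return object of class `roc_curve`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   `direction`, `n_pos`, `n_neg`.
#' @seealso [auc_mannwhitney()] for the rank-statistic AUC.
#' @export
roc <- function(scores, labels,
                direction = c("higher-in-positive", "lower-in-positive",
                              "auto")) {
  direction <- match.arg(direction)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  labels <- as.character(labels)
  assert_that(length(scores) == length(labels) && all(is.finite(scores)),
              "scores and labels must be finite and matched")
  assert_that(all(labels %in% c("positive", "negative")),
              "labels must be 'positive' or 'negative'")
  pos <- labels == "positive"
  assert_that(any(pos) && any(!pos), "both classes must be non-empty")

  build <- function(s) {
    thr <- sort(unique(s), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(s[pos] >= t), numeric(1))
    fp <- vapply(thr, function(t) sum(s[!pos] >= t), numeric(1))
    list(thresholds = thr,
         tpr = c(0, tp / sum(pos)),
         fpr = c(0, fp / sum(!pos)))
  }
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

  if (direction == "auto") {
    hi <- build(scores)
    auc_hi <- trapz(hi$fpr, hi$tpr)
    direction <- if (auc_hi >= 0.5) "higher-in-positive" else
      "lower-in-positive"
  }
  s <- if (direction == "lower-in-positive") -scores else scores
  cv <- build(s)
  structure(list(thresholds = if (direction == "lower-in-positive")
                   -cv$thresholds else cv$thresholds,
                 fpr = cv$fpr, tpr = cv$tpr,
                 auc = trapz(cv$fpr, cv$tpr),
                 direction = direction,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%s; %d positive, %d negative)\n",
              x$auc, x$direction, x$n_pos, x$n_neg))
  invisible(x)
}

#' Tie-corrected Mann-Whitney AUC
#'
#' AUC as the probability that a random positive outranks a random
#' negative, counting ties as one half:
#' `AUC = (U + ties/2) / (n_pos * n_neg)`, computed from the rank-sum
#' statistic on the pooled sample (average ranks). Equals the trapezoidal
#' AUC of [roc()] exactly.
#'
#' @inheritParams roc
#' @param direction as in [roc()], but `"auto"` is not available here.
#' @return scalar AUC in \[0,1\].
#' @export
auc_mannwhitney <- function(scores, labels,
                            direction = c("higher-in-positive",
                                          "lower-in-positive")) {
  direction <- match.arg(direction)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  labels <- as.character(labels)
  pos <- labels == "positive"
  assert_that(any(pos) && any(!pos), "both classes must be non-empty")
  s <- if (direction == "lower-in-positive") -scores else scores
  r <- rank(s)
  np <- sum(pos); nn <- sum(!pos)
  u <- sum(r[pos]) - np * (np + 1) / 2
  u / (np * nn)
}
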