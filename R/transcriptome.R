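# Count normalization and differential expression calling.

#' Normalize a count matrix to TPM, FPKM, or log2(FPKM + 1e-4)
#'
#' FPKM = count * 1e9 / (length * column_total);
#' TPM  = rate / sum(rates) * 1e6 with rate = count / length;
#' logFPKM = log2(FPKM + 1e-4). TPM columns each sum to 1e6 by construction.
#'
#' @param counts non-negative gene x sample count matrix with gene ids as
#'   rownames.
#' @param lengths per-gene transcript lengths in bp (named or in row order).
#' @param method one of `"TPM"`, `"FPKM"`, `"logFPKM"`.
#' @return numeric matrix with attribute `unit` set to `method`.
#' @export
normalize_counts <- function(counts, lengths,
                             method = c("TPM", "FPKM", "logFPKM")) {
  method <- match.arg(method)
  assert_that(is.matrix(counts) && all(counts >= 0),
              "`counts` must be a non-negative matrix")
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  assert_that(length(lengths) == nrow(counts) && all(lengths > 0),
              "one positive length per gene required")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    stop(sprintf("sample(s) with zero total counts: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  rate <- counts / lengths
  out <- switch(method,
    FPKM = sweep(counts * 1e9 / lengths, 2, tot, "/"),
    TPM = sweep(rate, 2, colSums(rate), "/") * 1e6,
    logFPKM = log2(sweep(counts * 1e9 / lengths, 2, tot, "/") + 1e-4)
  )
  attr(out, "unit") <- method
  out
}

#' Differential expression testing on normalized values
#'
#' Per gene, the effect is `log2((mean_tumor + c) / (mean_normal + c))` with
#' pseudocount `c = 1e-4` (the same constant used in the log-FPKM
#' transform), and the p-value is the two-sided Wilcoxon-Mann-Whitney
#' rank-sum test comparing tumor and normal samples (exact/no-tie rules as
#' in [dm_test()]). The rank test is invariant to monotone per-gene
#' rescaling, so any of the normalization units gives identical p-values.
#'
#' @param norm normalized gene x sample matrix (e.g. TPM from
#'   [normalize_counts()]).
#' @param groups per-sample labels, `"tumor"`/`"normal"`.
#' @param pseudocount offset for the fold-change means (default `1e-4`).
#' @return data.frame of class `de_records`: `gene`, `mean_tumor`,
#'   `mean_normal`, `effect`, `p`, `q`.
#' @export
de_test <- function(norm, groups, pseudocount = 1e-4) {
  assert_that(is.matrix(norm), "`norm` must be a matrix")
  groups <- as.character(groups)
  tum <- groups == "tumor"
  assert_that(length(groups) == ncol(norm), "one group label per sample")
  assert_that(sum(tum) >= 2 && sum(!tum) >= 2,
              "need at least 2 samples per group")
  mt <- rowMeans(norm[, tum, drop = FALSE])
  mn <- rowMeans(norm[, !tum, drop = FALSE])
  p <- vapply(seq_len(nrow(norm)),
              function(i) rank_sum_test(norm[i, tum], norm[i, !tum]),
              numeric(1))
  out <- data.frame(gene = rownames(norm), mean_tumor = mt,
                    mean_normal = mn,
                    effect = log2((mt + pseudocount) / (mn + pseudocount)),
                    p = p, q = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_records", "data.frame")
  out
}

#' Call significant differential expression
#'
#' Inclusive thresholds `p <= 0.05` and `|log2FC| >= 1`, partitioned into
#' up- and down-regulated genes.
#'
#' @param records output of [de_test()].
#' @param p_max,lfc_min threshold overrides.
#' @return subset of `records` with added `direction` (`"up"`/`"down"`).
#' @export
call_de <- function(records, p_max = 0.05, lfc_min = 1) {
  assert_that(p_max > 0 && lfc_min > 0, "thresholds must be positive")
  hit <- records$p <= p_max & abs(records$effect) >= lfc_min
  out <- records[hit, , drop = FALSE]
  out$direction <- ifelse(out$effect > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_i = min over j with p_(j) >= p_(i) of
#' m * p_(j) / rank_j`, capped at 1 (delegated to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0,1\]; `NA`/`NaN` are rejected.
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && !anyNA(p), "p-values must be numeric, no NA")
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}
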