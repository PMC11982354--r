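# Beta/M-value handling, gene- and region-level aggregation, and
# differential methylation calling.

REGION_CLASSES <- c("island", "shore_N", "shore_S", "shelf_N", "shelf_S",
                    "open_sea")

#' Construct a probe-level methylation matrix with annotation
#'
#' Bundles an Infinium-style beta-value matrix (probes x samples, values in
#' \[0,1\]) with its probe annotation and per-sample group labels. This is the
#' methylation-side input of the integrative screen.
#'
#' @param values numeric matrix of beta values in \[0,1\]; rownames are probe
#'   ids, colnames are sample ids. Probe ids must be unique.
#' @param annotation data.frame with one row per probe and columns
#'   `probe_id`, `gene` (symbol, `NA` when unannotated), `chr`, `pos`, and
#'   `region` (one of island, shore_N, shore_S, shelf_N, shelf_S, open_sea,
#'   mirroring the 450k manifest's relation-to-CpG-island classes).
#' @param groups character/factor of length `ncol(values)` with levels
#'   `"tumor"` and `"normal"`.
#' @param patient optional per-sample patient id for paired designs.
#' @return an object of class `beta_matrix` (a list with the validated
#'   components).
#' @export
beta_matrix <- function(values, annotation, groups, patient = NULL) {
  assert_that(is.matrix(values) && is.numeric(values),
              "`values` must be a numeric matrix")
  assert_that(all(is.finite(values) | is.na(values)),
              "beta values must be finite or NA")
  rng <- range(values, na.rm = TRUE)
  assert_that(rng[1] >= 0 && rng[2] <= 1, "beta values must lie in [0,1]")
  assert_that(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
              "probe ids (rownames) must be present and unique")
  assert_that(is.data.frame(annotation) &&
                all(c("probe_id", "gene", "region") %in% names(annotation)),
              "annotation needs columns probe_id, gene, region")
  assert_that(all(rownames(values) %in% annotation$probe_id),
              "every probe must be annotated")
  groups <- as.character(groups)
  assert_that(length(groups) == ncol(values),
              "one group label per sample required")
  assert_that(all(groups %in% c("tumor", "normal")),
              "groups must be 'tumor' or 'normal'")
  ann <- annotation[match(rownames(values), annotation$probe_id), ,
                    drop = FALSE]
  rownames(ann) <- NULL
  structure(list(values = values, annotation = ann, groups = groups,
                 patient = patient),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "tumor"), sum(x$groups == "normal")))
  cat(sprintf("annotated genes: %d\n",
              length(unique(stats::na.omit(x$annotation$gene)))))
  invisible(x)
}

#' Convert beta values to M-values
#'
#' The M-value is the base-2 logit of the beta value,
#' M = log2(beta / (1 - beta)) = log2(methylated / unmethylated), the
#' variance-stabilized scale used for differential methylation testing.
#' Betas are clipped to \[eps, 1 - eps\] first so boundary values map to
#' finite M.
#'
#' @param beta numeric vector/matrix of beta values in \[0,1\].
#' @param eps clipping constant (default `1e-6`).
#' @return M-values with the shape of the input. `NA`s propagate.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @seealso [m_to_beta()] for the inverse.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  ok <- is.na(beta) | (beta >= 0 & beta <= 1)
  assert_that(all(ok), "beta values must lie in [0,1]")
  b <- clip(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()] on the clipped interval:
#' beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector/matrix of finite M-values.
#' @return beta values in (0,1).
#' @export
m_to_beta <- function(m) {
  assert_that(all(is.finite(m) | is.na(m)), "M-values must be finite or NA")
  # computed via plogis-style stable form to avoid overflow for large |m|
  1 / (1 + 2^(-m))
}

#' Gene-level mean methylation
#'
#' Collapses a probe-level beta matrix to one row per gene: the arithmetic
#' mean beta across the gene's probes, per sample. Probes without a gene
#' symbol are excluded; genes end up in the output only if they retain at
#' least one probe.
#'
#' @param x a [beta_matrix()].
#' @return an object of class `gene_methylation`: list with `values`
#'   (gene x sample mean-beta matrix), `n_probes` (named integer), and
#'   `groups`.
#' @export
aggregate_gene <- function(x) {
  stopifnot(inherits(x, "beta_matrix"))
  gene <- x$annotation$gene
  keep <- !is.na(gene) & gene != ""
  assert_that(any(keep), "annotation maps no probe to a gene symbol")
  v <- x$values[keep, , drop = FALSE]
  g <- factor(gene[keep])
  vals <- rowsum(v, g, na.rm = TRUE) / as.vector(table(g))
  n_probes <- as.integer(table(g))
  names(n_probes) <- levels(g)
  structure(list(values = as.matrix(vals), n_probes = n_probes,
                 groups = x$groups),
            class = "gene_methylation")
}

#' @export
print.gene_methylation <- function(x, ...) {
  cat(sprintf("gene_methylation: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Region-class methylation profile of one gene
#'
#' Group-wise mean beta of a gene's probes stratified by the manifest's
#' relation-to-CpG-island class (island, N/S shores, N/S shelves, open sea).
#' Classes without probes for this gene are reported with `n_probes = 0` and
#' `NA` means.
#'
#' @param x a [beta_matrix()].
#' @param gene gene symbol present in the annotation.
#' @return data.frame with columns `region`, `n_probes`, `mean_normal`,
#'   `mean_tumor`.
#' @export
region_methylation <- function(x, gene) {
  stopifnot(inherits(x, "beta_matrix"))
  idx <- which(!is.na(x$annotation$gene) & x$annotation$gene == gene)
  assert_that(length(idx) > 0, "gene '%s' not found in annotation", gene)
  out <- data.frame(region = REGION_CLASSES, n_probes = 0L,
                    mean_normal = NA_real_, mean_tumor = NA_real_,
                    stringsAsFactors = FALSE)
  tum <- x$groups == "tumor"
  for (i in seq_along(REGION_CLASSES)) {
    p <- idx[x$annotation$region[idx] == REGION_CLASSES[i]]
    if (length(p) == 0) next
    out$n_probes[i] <- length(p)
    out$mean_normal[i] <- mean(x$values[p, !tum], na.rm = TRUE)
    out$mean_tumor[i] <- mean(x$values[p, tum], na.rm = TRUE)
  }
  out
}

# Two-sided Wilcoxon-Mann-Whitney rank-sum p-value.
#
# Exact null distribution (via the Wilcoxon distribution function) when the
# smaller group has <= `exact_max` observations and the pooled sample is
# tie-free; otherwise the normal approximation with tie correction and a
# 0.5 continuity correction. Degenerate pooled samples (zero rank variance)
# return p = 1.
rank_sum_test <- function(x, y, exact_max = 8L) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && min(nx, ny) <= exact_max) {
    p <- if (u > nx * ny / 2) {
      stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    } else {
      stats::pwilcox(u, nx, ny)
    }
    return(min(1, 2 * p))
  }
  mu <- nx * ny / 2
  n <- nx + ny
  sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Differential methylation testing
#'
#' Tests each unit (probe, or gene after [aggregate_gene()]) for a
#' tumor-versus-normal shift on the M-value scale. The effect is the mean
#' M-value difference (tumor - normal), reported as `effect` and
#' interpretable as a log2 fold change of the methylated/unmethylated ratio.
#' P-values come from a two-sided Wilcoxon-Mann-Whitney rank-sum test (exact
#' when the smaller group has at most 8 samples and there are no ties,
#' normal approximation with tie and continuity correction otherwise);
#' multiplicity is controlled by Benjamini-Hochberg.
#'
#' Units with any missing value are dropped before testing rather than
#' imputed.
#'
#' @param x a [beta_matrix()] (probe level) or a `gene_methylation` object
#'   (gene level).
#' @return data.frame of class `dm_records` with columns `id`,
#'   `mean_m_tumor`, `mean_m_normal`, `effect`, `p`, `q` and attribute
#'   `level` (`"probe"` or `"gene"`).
#' @export
dm_test <- function(x) {
  if (inherits(x, "beta_matrix")) {
    values <- x$values; groups <- x$groups; level <- "probe"
  } else if (inherits(x, "gene_methylation")) {
    values <- x$values; groups <- x$groups; level <- "gene"
  } else {
    stop("`x` must be a beta_matrix or gene_methylation object")
  }
  tum <- groups == "tumor"
  assert_that(sum(tum) >= 2 && sum(!tum) >= 2,
              "need at least 2 samples per group")
  keep <- stats::complete.cases(values)
  values <- values[keep, , drop = FALSE]
  m <- beta_to_m(values)
  mt <- rowMeans(m[, tum, drop = FALSE])
  mn <- rowMeans(m[, !tum, drop = FALSE])
  p <- vapply(seq_len(nrow(m)),
              function(i) rank_sum_test(m[i, tum], m[i, !tum]),
              numeric(1))
  out <- data.frame(id = rownames(values), mean_m_tumor = mt,
                    mean_m_normal = mn, effect = mt - mn, p = p,
                    q = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "level") <- level
  class(out) <- c("dm_records", "data.frame")
  out
}

#' Call significant differential methylation
#'
#' Applies the study's inclusive dual thresholds: at gene level
#' `p <= 0.05` and `|effect| >= 0.5`; at probe/island level `p <= 0.05` and
#' `|effect| >= log2(1.45)`, reading the island-level "fold change >= 1.45"
#' as a fold change of the methylated/unmethylated ratio, i.e. a threshold
#' of log2(1.45) on the M-value difference.
#'
#' @param records output of [dm_test()].
#' @param level `"gene"` or `"probe"`; defaults to the records' own level.
#' @param p_max,lfc_min threshold overrides.
#' @return subset of `records` with an added `direction` column
#'   (`"hyper"`/`"hypo"`).
#' @export
call_dm <- function(records, level = attr(records, "level"),
                    p_max = 0.05, lfc_min = NULL) {
  level <- match.arg(level, c("gene", "probe"))
  if (is.null(lfc_min)) lfc_min <- if (level == "gene") 0.5 else log2(1.45)
  assert_that(p_max > 0 && lfc_min > 0, "thresholds must be positive")
  hit <- records$p <= p_max & abs(records$effect) >= lfc_min
  out <- records[hit, , drop = FALSE]
  out$direction <- ifelse(out$effect > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}
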