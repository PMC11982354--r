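# Orchestration and summary tables: DE/DM tallies with printed-style
# percentages, the end-to-end screen pipeline, and report output.

#' Tally differential expression calls
#'
#' Counts tested/significant/up/down genes and reports the up/down shares
#' of the significant set as percentages rounded half-away-from-zero to
#' one decimal (the convention of printed summary tables, e.g.
#' 3073/4941 -> 62.2). With no significant genes the percentages are
#' `NA` (undefined), never 0.
#'
#' @param records output of [de_test()].
#' @param calls output of [call_de()] on those records.
#' @return list: `n_tested`, `n_significant`, `n_up`, `n_down`, `pct_up`,
#'   `pct_down`.
#' @export
summarize_de <- function(records, calls) {
  n_up <- sum(calls$direction == "up")
  n_down <- sum(calls$direction == "down")
  list(n_tested = nrow(records), n_significant = nrow(calls),
       n_up = n_up, n_down = n_down,
       pct_up = percent_of(n_up, nrow(calls)),
       pct_down = percent_of(n_down, nrow(calls)))
}

#' Tally differential methylation calls
#'
#' As [summarize_de()], partitioning significant units into
#' hyper-/hypomethylated.
#'
#' @param records output of [dm_test()].
#' @param calls output of [call_dm()] on those records.
#' @return list: `n_tested`, `n_significant`, `n_hyper`, `n_hypo`,
#'   `pct_hyper`, `pct_hypo`.
#' @export
summarize_dm <- function(records, calls) {
  n_hyper <- sum(calls$direction == "hyper")
  n_hypo <- sum(calls$direction == "hypo")
  list(n_tested = nrow(records), n_significant = nrow(calls),
       n_hyper = n_hyper, n_hypo = n_hypo,
       pct_hyper = percent_of(n_hyper, nrow(calls)),
       pct_hypo = percent_of(n_hypo, nrow(calls)))
}

#' Configuration for an end-to-end screen run
#'
#' Validates thresholds before any computation starts.
#'
#' @param counts gene x sample count matrix.
#' @param lengths per-gene transcript lengths (bp).
#' @param beta a [beta_matrix()] on the same samples.
#' @param groups per-sample `"tumor"`/`"normal"` labels.
#' @param de_p,de_lfc,dm_p,dm_lfc significance thresholds (all > 0).
#' @param focus_gene gene for the correlation/ROC follow-up; defaults to
#'   the screen hit with the smallest combined p.
#' @param roc_direction marker orientation for the focus-gene ROC.
#' @param survival optional data.frame (`time`, `event`, `marker`) for a
#'   best-cutoff scan.
#' @param out_dir optional directory for stage TSVs and the report JSON.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, lengths, beta, groups,
                            de_p = 0.05, de_lfc = 1, dm_p = 0.05,
                            dm_lfc = 0.5, focus_gene = NULL,
                            roc_direction = "lower-in-positive",
                            survival = NULL, out_dir = NULL) {
  assert_that(de_p > 0 && de_lfc > 0 && dm_p > 0 && dm_lfc > 0,
              "all thresholds must be positive")
  assert_that(inherits(beta, "beta_matrix"), "`beta` must be a beta_matrix")
  assert_that(is.matrix(counts) && ncol(counts) == ncol(beta$values),
              "counts and beta must cover the same samples")
  if (!is.null(survival)) {
    assert_that(all(c("time", "event", "marker") %in% names(survival)),
                "survival needs columns time, event, marker")
  }
  structure(list(counts = counts, lengths = lengths, beta = beta,
                 groups = as.character(groups), de_p = de_p,
                 de_lfc = de_lfc, dm_p = dm_p, dm_lfc = dm_lfc,
                 focus_gene = focus_gene, roc_direction = roc_direction,
                 survival = survival, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the integrative screen pipeline end to end
#'
#' Normalization (TPM) -> differential expression -> gene-level
#' differential methylation -> dual-threshold screen -> focus-gene
#' methylation/expression correlation and diagnostic ROC -> optional
#' best-cutoff survival scan. Deterministic: the same configuration
#' always yields an identical report. When `out_dir` is set, stage tables
#' (TSV) and a machine-readable `report.json` are written.
#'
#' @param config a [pipeline_config()].
#' @return list of class `summary_report`: `thresholds`, `de`
#'   (records/calls/tally), `dm`, `screen` (calls + hit list),
#'   `correlation` (pearson + spearman for the focus gene), `roc`,
#'   `survival` (cutoff scan or NULL), `focus_gene`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tpm <- normalize_counts(config$counts, config$lengths, "TPM")
  de <- de_test(tpm, config$groups)
  de_calls <- call_de(de, p_max = config$de_p, lfc_min = config$de_lfc)
  gm <- aggregate_gene(config$beta)
  dm <- dm_test(gm)
  dm_calls <- call_dm(dm, level = "gene", p_max = config$dm_p,
                      lfc_min = config$dm_lfc)
  screen <- screen_cohort(de, dm, p_max = min(config$de_p, config$dm_p),
                          de_lfc_min = config$de_lfc,
                          dm_lfc_min = config$dm_lfc)
  hits <- screen$gene[screen$is_hit]

  focus <- config$focus_gene
  if (is.null(focus) && length(hits) > 0) {
    sub <- screen[screen$is_hit, ]
    focus <- sub$gene[which.min(sub$de_p * sub$dm_p)]
  }
  correlation <- roc_res <- NULL
  if (!is.null(focus) && focus %in% rownames(tpm) &&
      focus %in% rownames(gm$values)) {
    expr <- tpm[focus, ]
    meth <- gm$values[focus, ]
    correlation <- list(pearson = correlate(meth, expr, "pearson"),
                        spearman = correlate(meth, expr, "spearman"))
    roc_res <- roc(expr, config$groups == "tumor",
                   direction = config$roc_direction)
  }
  surv_res <- if (!is.null(config$survival)) {
    best_cutoff_scan(config$survival$time, config$survival$event,
                     config$survival$marker)
  } else NULL

  report <- structure(list(
    thresholds = list(de_p = config$de_p, de_lfc = config$de_lfc,
                      dm_p = config$dm_p, dm_lfc = config$dm_lfc),
    de = list(records = de, calls = de_calls,
              tally = summarize_de(de, de_calls)),
    dm = list(records = dm, calls = dm_calls,
              tally = summarize_dm(dm, dm_calls)),
    screen = list(calls = screen, hits = hits),
    correlation = correlation, roc = roc_res, survival = surv_res,
    focus_gene = focus), class = "summary_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat("summary_report\n")
  with(x$de$tally, cat(sprintf(
    "  DE: %d tested, %d significant (%d up = %.1f%%, %d down = %.1f%%)\n",
    n_tested, n_significant, n_up, pct_up, n_down, pct_down)))
  with(x$dm$tally, cat(sprintf(
    paste0("  DM: %d tested, %d significant (%d hyper = %.1f%%, ",
           "%d hypo = %.1f%%)\n"),
    n_tested, n_significant, n_hyper, pct_hyper, n_hypo, pct_hypo)))
  cat(sprintf("  screen hits (hyper-down): %d\n",
              length(x$screen$hits)))
  if (!is.null(x$focus_gene)) {
    cat(sprintf("  focus gene: %s", x$focus_gene))
    if (!is.null(x$roc)) cat(sprintf(" (AUC = %.3f)", x$roc$auc))
    cat("\n")
  }
  if (!is.null(x$survival)) {
    cat(sprintf("  best cutoff: %.4g (log-rank p = %.3g)\n",
                x$survival$best_cutoff, x$survival$best_p))
  }
  invisible(x)
}

# write stage TSVs and a machine-readable JSON report
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(report$de$records, "de_records.tsv")
  wtsv(report$de$calls, "de_calls.tsv")
  wtsv(report$dm$records, "dm_records.tsv")
  wtsv(report$dm$calls, "dm_calls.tsv")
  wtsv(report$screen$calls, "screen_calls.tsv")
  js <- list(thresholds = report$thresholds,
             de_tally = report$de$tally, dm_tally = report$dm$tally,
             n_hits = length(report$screen$hits),
             hits = report$screen$hits, focus_gene = report$focus_gene)
  if (!is.null(report$roc)) js$auc <- report$roc$auc
  if (!is.null(report$correlation)) {
    js$correlation <- list(
      pearson_r = report$correlation$pearson$estimate,
      pearson_p = report$correlation$pearson$p,
      spearman_rho = report$correlation$spearman$estimate,
      spearman_p = report$correlation$spearman$p)
  }
  if (!is.null(report$survival)) {
    js$survival <- list(best_cutoff = report$survival$best_cutoff,
                        best_p = report$survival$best_p,
                        best_hr = report$survival$best_hr,
                        multiplicity_biased = TRUE)
  }
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
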