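# Plain-text input/output for the standard pipeline formats: counts TSV,
# beta TSV, probe-annotation TSV (Infinium-manifest-style column names),
# sample-sheet CSV, survival CSV, and truth JSON.

#' Write a synthetic cohort to a directory of standard pipeline inputs
#'
#' Writes `counts.tsv` (genes x samples, plus a `length` column),
#' `beta.tsv` (probes x samples), `annotation.tsv` with manifest-style
#' columns (IlmnID, UCSC_RefGene_Name, CHR, MAPINFO,
#' Relation_to_UCSC_CpG_Island), `samples.csv`, and `truth.json`.
#'
#' @param cohort output of [gen_cohort()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cdf <- data.frame(gene = rownames(cohort$counts),
                    length = unname(cohort$lengths), cohort$counts,
                    check.names = FALSE)
  utils::write.table(cdf, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bdf <- data.frame(probe_id = rownames(cohort$beta$values),
                    cohort$beta$values, check.names = FALSE)
  utils::write.table(bdf, file.path(dir, "beta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- cohort$annotation
  adf <- data.frame(IlmnID = ann$probe_id, UCSC_RefGene_Name = ann$gene,
                    CHR = ann$chr, MAPINFO = ann$pos,
                    Relation_to_UCSC_CpG_Island = ann$region)
  utils::write.table(adf, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read pipeline inputs written by [write_cohort()]
#'
#' @param dir directory containing `counts.tsv`, `beta.tsv`,
#'   `annotation.tsv` and `samples.csv`.
#' @return list with `counts`, `lengths`, `beta` (a [beta_matrix()]) and
#'   `samples`.
#' @export
read_cohort <- function(dir) {
  cdf <- utils::read.delim(file.path(dir, "counts.tsv"),
                           check.names = FALSE)
  counts <- as.matrix(cdf[, -(1:2), drop = FALSE])
  rownames(counts) <- cdf$gene
  lengths <- stats::setNames(cdf$length, cdf$gene)
  samples <- utils::read.delim(file.path(dir, "samples.csv"), sep = ",")
  bdf <- utils::read.delim(file.path(dir, "beta.tsv"), check.names = FALSE)
  bvals <- as.matrix(bdf[, -1, drop = FALSE])
  rownames(bvals) <- bdf$probe_id
  adf <- utils::read.delim(file.path(dir, "annotation.tsv"))
  ann <- data.frame(probe_id = adf$IlmnID, gene = adf$UCSC_RefGene_Name,
                    chr = adf$CHR, pos = adf$MAPINFO,
                    region = adf$Relation_to_UCSC_CpG_Island,
                    stringsAsFactors = FALSE)
  grp <- samples$group[match(colnames(bvals), samples$sample)]
  list(counts = counts, lengths = lengths,
       beta = beta_matrix(bvals, ann, grp), samples = samples)
}
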