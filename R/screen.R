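# The integrative screen: intersect hypermethylated with down-expressed
# genes within and across cohorts, methylation-expression correlation, and
# generic over-representation analysis against user-supplied gene sets.

#' Screen one cohort for hypermethylated, down-expressed genes
#'
#' Joins differential expression and differential methylation records by
#' gene and assigns each gene a quadrant from the effect signs, provided
#' both sides are significant (`de_p <= p_max`, `|de_effect| >= de_lfc_min`,
#' `dm_p <= p_max`, `|dm_effect| >= dm_lfc_min`); otherwise
#' `"non-significant"`. A gene is a screen hit when it falls in the
#' hyper-down quadrant: significantly hypermethylated
#' (`dm_effect >= dm_lfc_min`) and significantly down-expressed
#' (`de_effect <= -de_lfc_min`). Raw p-values are thresholded (mirroring the
#' printed cut-offs); BH q-values remain available in the input records.
#'
#' Genes present on only one side are excluded; their count is kept in the
#' `n_dropped` attribute.
#'
#' @param de_records output of [de_test()].
#' @param dm_records output of [dm_test()] at gene level.
#' @param p_max significance threshold on both raw p-values (default 0.05).
#' @param de_lfc_min,dm_lfc_min absolute effect thresholds (defaults 1 and
#'   0.5).
#' @return data.frame of class `screen_calls`: `gene`, `de_effect`, `de_p`,
#'   `dm_effect`, `dm_p`, `quadrant`, `is_hit`.
#' @export
screen_cohort <- function(de_records, dm_records, p_max = 0.05,
                          de_lfc_min = 1, dm_lfc_min = 0.5) {
  assert_that(p_max > 0 && de_lfc_min > 0 && dm_lfc_min > 0,
              "thresholds must be positive")
  common <- intersect(de_records$gene, dm_records$id)
  assert_that(length(common) > 0,
              "no genes shared between DE and DM records")
  de <- de_records[match(common, de_records$gene), ]
  dm <- dm_records[match(common, dm_records$id), ]
  sig <- de$p <= p_max & abs(de$effect) >= de_lfc_min &
    dm$p <= p_max & abs(dm$effect) >= dm_lfc_min
  quadrant <- rep("non-significant", length(common))
  quadrant[sig] <- paste0(ifelse(dm$effect[sig] > 0, "hyper", "hypo"), "-",
                          ifelse(de$effect[sig] > 0, "up", "down"))
  is_hit <- de$p <= p_max & de$effect <= -de_lfc_min &
    dm$p <= p_max & dm$effect >= dm_lfc_min
  out <- data.frame(gene = common, de_effect = de$effect, de_p = de$p,
                    dm_effect = dm$effect, dm_p = dm$p, quadrant = quadrant,
                    is_hit = is_hit, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- length(union(de_records$gene, dm_records$id)) -
    length(common)
  class(out) <- c("screen_calls", "data.frame")
  out
}

#' Intersect screen hits across two cohorts
#'
#' The two-cohort Venn: hit sets per cohort, their intersection (the
#' candidate tumor-suppressor list), and the Venn counts.
#'
#' @param calls_a,calls_b `screen_calls` from [screen_cohort()].
#' @param names_ab labels for the two cohorts.
#' @return object of class `overlap_result`: list with `sets` (named list of
#'   hit gene vectors), `intersection`, and `counts` (only_a, only_b, both).
#' @export
intersect_cohorts <- function(calls_a, calls_b,
                              names_ab = c("cohort_A", "cohort_B")) {
  ha <- sort(calls_a$gene[calls_a$is_hit])
  hb <- sort(calls_b$gene[calls_b$is_hit])
  both <- intersect(ha, hb)
  out <- list(
    sets = stats::setNames(list(ha, hb), names_ab),
    intersection = both,
    counts = c(only_a = length(setdiff(ha, hb)),
               only_b = length(setdiff(hb, ha)),
               both = length(both))
  )
  class(out) <- "overlap_result"
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: |A| = %d, |B| = %d, shared = %d\n",
              length(x$sets[[1]]), length(x$sets[[2]]),
              length(x$intersection)))
  if (length(x$intersection)) {
    cat("shared genes:", paste(x$intersection, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Correlate two variables (Pearson or Spearman)
#'
#' Pearson's R by the product-moment formula with the t-distribution
#' p-value on n - 2 degrees of freedom; Spearman's rho as Pearson applied
#' to average ranks, with the same p-value machinery.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `correlation_result`: `method`, `estimate`, `p`,
#'   `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3")
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "x and y must be finite")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in x or y")
  r <- stats::cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(method = method, estimate = r, p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  lab <- if (x$method == "pearson") "R" else "rho"
  cat(sprintf("%s correlation: %s = %.4f, p = %.3g, n = %d\n",
              x$method, lab, x$estimate, x$p, x$n))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0, "empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(parts) >= 3),
              "each GMT line needs name, description and >= 1 gene")
  stats::setNames(lapply(parts, function(f) unique(f[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Over-representation analysis (hypergeometric)
#'
#' For each gene set, the one-sided hypergeometric upper-tail probability of
#' observing at least the realized overlap between the hit list and the set
#' (both intersected with the universe), BH-adjusted across sets. A set is
#' flagged significant at raw `p < 0.05`.
#'
#' @param hits character vector of hit gene ids (must be a subset of
#'   `universe`).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of all testable gene ids.
#' @return data.frame of class `enrichment_records`: `set`, `k` (overlap),
#'   `K` (set size in universe), `n` (hit-list size), `N` (universe size),
#'   `p`, `q`, `significant`.
#' @export
ora <- function(hits, gene_sets, universe) {
  universe <- unique(universe)
  assert_that(length(universe) > 0, "empty universe")
  hits <- unique(hits)
  assert_that(all(hits %in% universe), "hits must be a subset of universe")
  n <- length(hits)
  N <- length(universe)
  rec <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(hits, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < 0.05
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_records", "data.frame")
  out
}
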