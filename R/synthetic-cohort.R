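# Synthetic discovery-cohort generator: paired tumor/normal expression and
# methylation matrices with planted hypermethylated/down-expressed genes,
# and exponential proportional-hazards survival records. All generators are
# deterministic for a fixed spec and restore the caller's RNG state.

#' Specification of a synthetic tumor/normal cohort
#'
#' Defaults emulate the discovery design of a paired breast cohort:
#' 31 tumor versus 12 normal samples, negative-binomial RNA-seq counts with
#' gene-specific log-means, and Beta-distributed methylation beta values
#' with a bimodal baseline (unmethylated/methylated modes). Planted genes
#' are simultaneously hypermethylated (beta-scale shift
#' `planted_meth_delta` in tumors) and down-expressed
#' (`planted_expr_lfc` log2 fold change in tumors); all other genes have
#' identical group distributions.
#'
#' @param n_genes number of genes.
#' @param probes_per_gene integer range (length 2) of CpG probes per gene.
#' @param n_tumor,n_normal group sizes.
#' @param n_planted number of planted hyper/down genes (`<= n_genes`).
#' @param planted_meth_delta beta-scale mean shift in \[0, 0.9\]; baselines
#'   of planted probes are drawn low enough that the shifted mean stays
#'   below 0.95, so the realized mean difference equals the nominal delta.
#' @param planted_expr_lfc log2 fold change applied to tumor count means
#'   (negative for a silenced suppressor).
#' @param nb_dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param baseline_log_mean_range natural-log interval for gene mean counts.
#' @param baseline_beta_mode bimodal baseline: list with `low`, `high`
#'   (mode centers), `weight_high` (mixture weight of the methylated mode),
#'   `sd` (spread of probe means around a mode).
#' @param beta_precision concentration of the per-sample Beta noise
#'   (`shape1 = m * phi`, `shape2 = (1 - m) * phi`).
#' @param planted_genes optional gene ids (`"GENE0001"` style) to plant
#'   instead of a random draw — used to give two cohorts the same
#'   underlying biology; overrides `n_planted`.
#' @param seed master RNG seed; substreams for layout, counts and betas are
#'   derived by fixed offsets.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 2000, probes_per_gene = c(3, 8),
                        n_tumor = 31, n_normal = 12, n_planted = 50,
                        planted_meth_delta = 0.25, planted_expr_lfc = -2,
                        nb_dispersion = 0.4,
                        baseline_log_mean_range = log(c(20, 2000)),
                        baseline_beta_mode = list(low = 0.2, high = 0.75,
                                                  weight_high = 0.5,
                                                  sd = 0.05),
                        beta_precision = 30, planted_genes = NULL,
                        seed = 1) {
  assert_that(n_genes >= 1 && n_tumor >= 2 && n_normal >= 2,
              "need n_genes >= 1 and >= 2 samples per group")
  assert_that(n_planted >= 0 && n_planted <= n_genes,
              "n_planted must lie in [0, n_genes]")
  assert_that(length(probes_per_gene) == 2 && probes_per_gene[1] >= 1 &&
                probes_per_gene[1] <= probes_per_gene[2],
              "probes_per_gene must be an increasing range >= 1")
  assert_that(is_scalar_in(planted_meth_delta, 0, 1 - 1e-9),
              "planted_meth_delta must lie in [0, 1)")
  assert_that(planted_meth_delta + 0.05 <= 0.95,
              paste("infeasible spec: planted_meth_delta = %.3g would push",
                    "beta means above 0.95 before clipping"),
              planted_meth_delta)
  assert_that(nb_dispersion > 0, "nb_dispersion must be > 0")
  assert_that(beta_precision > 0, "beta_precision must be > 0")
  assert_that(length(baseline_log_mean_range) == 2 &&
                diff(baseline_log_mean_range) > 0,
              "baseline_log_mean_range must be an increasing interval")
  if (!is.null(planted_genes)) {
    idx <- match(planted_genes, sprintf("GENE%04d", seq_len(n_genes)))
    assert_that(!anyNA(idx), "planted_genes must exist in the gene set")
    n_planted <- length(idx)
  }
  structure(list(n_genes = n_genes, probes_per_gene = probes_per_gene,
                 n_tumor = n_tumor, n_normal = n_normal,
                 n_planted = n_planted, planted_genes = planted_genes,
                 planted_meth_delta = planted_meth_delta,
                 planted_expr_lfc = planted_expr_lfc,
                 nb_dispersion = nb_dispersion,
                 baseline_log_mean_range = baseline_log_mean_range,
                 baseline_beta_mode = baseline_beta_mode,
                 beta_precision = beta_precision, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic tumor/normal cohort with known ground truth
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cohort`:
#'   `counts` (gene x sample integer matrix), `lengths` (per-gene bp),
#'   `beta` (a [beta_matrix()]), `annotation` (probe annotation),
#'   `samples` (sample sheet: sample, group, patient), and `truth`
#'   (data.frame of planted genes with their true `meth_delta` and
#'   `expr_lfc`).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_s <- spec$n_tumor + spec$n_normal
  genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
  samples <- data.frame(
    sample = sprintf("S%02d", seq_len(n_s)),
    group = rep(c("tumor", "normal"), c(spec$n_tumor, spec$n_normal)),
    patient = c(sprintf("P%02d", seq_len(spec$n_tumor)),
                sprintf("P%02d", seq_len(spec$n_normal))),
    stringsAsFactors = FALSE)
  tum <- samples$group == "tumor"

  # layout substream: planted set, probe counts, baselines, lengths
  layout <- with_seed(spec$seed + 101L, {
    planted <- if (!is.null(spec$planted_genes)) {
      sort(match(spec$planted_genes, genes))
    } else {
      sort(sample(spec$n_genes, spec$n_planted))
    }
    npb <- sample(seq(spec$probes_per_gene[1], spec$probes_per_gene[2]),
                  spec$n_genes, replace = TRUE)
    lengths <- round(runif(spec$n_genes, 500, 5000))
    mu <- exp(runif(spec$n_genes, spec$baseline_log_mean_range[1],
                    spec$baseline_log_mean_range[2]))
    bm <- spec$baseline_beta_mode
    gene_of_probe <- rep(seq_len(spec$n_genes), npb)
    n_probes <- length(gene_of_probe)
    is_planted_probe <- gene_of_probe %in% planted
    mode <- ifelse(runif(n_probes) < bm$weight_high, bm$high, bm$low)
    pm <- clip(rnorm(n_probes, mode, bm$sd), 0.01, 0.99)
    # planted probes start low so the full delta is realized after shift
    lo <- 0.05
    hi <- min(0.6, 0.95 - spec$planted_meth_delta)
    pm[is_planted_probe] <- runif(sum(is_planted_probe), lo, hi)
    list(planted = planted, npb = npb, lengths = lengths, mu = mu,
         gene_of_probe = gene_of_probe, probe_mean = pm)
  })

  counts <- with_seed(spec$seed + 202L, {
    mu_mat <- matrix(layout$mu, spec$n_genes, n_s)
    mu_mat[layout$planted, tum] <- mu_mat[layout$planted, tum] *
      2^spec$planted_expr_lfc
    m <- matrix(rnbinom(spec$n_genes * n_s, mu = as.vector(mu_mat),
                        size = 1 / spec$nb_dispersion),
                spec$n_genes, n_s)
    dimnames(m) <- list(genes, samples$sample)
    m
  })

  n_probes <- length(layout$gene_of_probe)
  probe_ids <- sprintf("cg%07d", seq_len(n_probes))
  beta_vals <- with_seed(spec$seed + 303L, {
    mean_mat <- matrix(layout$probe_mean, n_probes, n_s)
    planted_probe <- layout$gene_of_probe %in% layout$planted
    mean_mat[planted_probe, tum] <- mean_mat[planted_probe, tum] +
      spec$planted_meth_delta
    phi <- spec$beta_precision
    b <- matrix(rbeta(n_probes * n_s, as.vector(mean_mat) * phi,
                      (1 - as.vector(mean_mat)) * phi),
                n_probes, n_s)
    dimnames(b) <- list(probe_ids, samples$sample)
    b
  })

  annotation <- with_seed(spec$seed + 404L, data.frame(
    probe_id = probe_ids,
    gene = genes[layout$gene_of_probe],
    chr = sample(paste0("chr", 1:22), n_probes, replace = TRUE),
    pos = sample.int(2e8, n_probes, replace = TRUE),
    region = sample(REGION_CLASSES, n_probes, replace = TRUE),
    stringsAsFactors = FALSE))

  truth <- data.frame(
    gene = genes[layout$planted],
    meth_delta = rep(spec$planted_meth_delta, spec$n_planted),
    expr_lfc = rep(spec$planted_expr_lfc, spec$n_planted),
    stringsAsFactors = FALSE)

  names(layout$lengths) <- genes
  structure(list(counts = counts, lengths = layout$lengths,
                 beta = beta_matrix(beta_vals, annotation, samples$group,
                                    samples$patient),
                 annotation = annotation, samples = samples, truth = truth,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic cohort: %d genes x %d samples ",
                     "(%d tumor / %d normal), %d probes, %d planted\n"),
              nrow(x$counts), ncol(x$counts), x$spec$n_tumor,
              x$spec$n_normal, nrow(x$beta$values), nrow(x$truth)))
  invisible(x)
}

#' Specification of a synthetic survival cohort
#'
#' Event times follow the exponential proportional-hazards model
#' `h(t | x) = baseline_hazard * exp(log_hr_per_unit * x)` for a scalar
#' marker `x`. Censoring is independent exponential, with its rate chosen
#' so the expected censored fraction matches `censoring_rate` under the
#' marginal marker distribution; `censoring_rate = 0` disables censoring.
#'
#' @param n_patients number of patients.
#' @param marker_distribution list: `dist` (`"normal"`, `"uniform"` or
#'   `"bernoulli"`) plus `mean`/`sd`, `min`/`max` or `p`; a bernoulli
#'   marker encodes a two-arm design whose between-arm hazard ratio is
#'   `exp(log_hr_per_unit)`.
#' @param log_hr_per_unit log hazard ratio per marker unit.
#' @param baseline_hazard events per time unit at marker 0 (> 0).
#' @param censoring_rate expected censored fraction in \[0, 1).
#' @param seed RNG seed.
#' @return validated list of class `survival_spec`.
#' @export
survival_spec <- function(n_patients = 200,
                          marker_distribution = list(dist = "normal",
                                                     mean = 0, sd = 1),
                          log_hr_per_unit = 1, baseline_hazard = 0.05,
                          censoring_rate = 0.2, seed = 1) {
  assert_that(n_patients >= 1, "n_patients must be >= 1")
  assert_that(baseline_hazard > 0, "baseline_hazard must be > 0")
  assert_that(is_scalar_in(censoring_rate, 0, 1 - 1e-9),
              "censoring_rate must lie in [0, 1)")
  assert_that(marker_distribution$dist %in%
                c("normal", "uniform", "bernoulli"),
              "marker_distribution$dist must be normal/uniform/bernoulli")
  structure(list(n_patients = n_patients,
                 marker_distribution = marker_distribution,
                 log_hr_per_unit = log_hr_per_unit,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate, seed = seed),
            class = "survival_spec")
}

#' Generate synthetic survival records
#'
#' @param spec a [survival_spec()].
#' @return data.frame with columns `time`, `event` (1 = event,
#'   0 = censored), `marker`.
#' @export
gen_survival <- function(spec) {
  stopifnot(inherits(spec, "survival_spec"))
  with_seed(spec$seed + 505L, {
    md <- spec$marker_distribution
    x <- switch(md$dist,
                normal = rnorm(spec$n_patients, md$mean, md$sd),
                uniform = runif(spec$n_patients, md$min, md$max),
                bernoulli = as.numeric(runif(spec$n_patients) < md$p))
    haz <- spec$baseline_hazard * exp(spec$log_hr_per_unit * x)
    t_event <- rexp(spec$n_patients, rate = haz)
    if (spec$censoring_rate > 0) {
      # marginal average hazard sets the censoring rate so that the
      # expected censored fraction ~ censoring_rate
      avg_haz <- mean(haz)
      rate_c <- avg_haz * spec$censoring_rate / (1 - spec$censoring_rate)
      t_cens <- rexp(spec$n_patients, rate = rate_c)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, spec$n_patients)
      time <- t_event
    }
    data.frame(time = time, event = event, marker = x)
  })
}
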