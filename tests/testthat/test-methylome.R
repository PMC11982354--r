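# beta/M conversions, gene and region aggregation, and differential
# methylation calling

make_beta <- function(values, genes = NULL, regions = "island",
                      groups = NULL) {
  probes <- rownames(values)
  if (is.null(genes)) genes <- rep("G1", nrow(values))
  ann <- data.frame(probe_id = probes, gene = genes,
                    chr = "chr1", pos = seq_len(nrow(values)),
                    region = rep(regions, length.out = nrow(values)))
  if (is.null(groups)) {
    groups <- rep(c("tumor", "normal"), length.out = ncol(values))
  }
  beta_matrix(values, ann, groups)
}

test_that("beta_to_m matches the logit2 formula and rejects bad input", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  expect_error(beta_to_m(1.2), "\\[0,1\\]")
  expect_error(beta_to_m(-0.1), "\\[0,1\\]")
  # boundary betas stay finite through the epsilon clip
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
})

test_that("beta_to_m is strictly increasing and inverts to 1e-12", {
  x <- seq(1e-3, 1 - 1e-3, length.out = 501)
  m <- beta_to_m(x)
  expect_true(all(diff(m) > 0))
  expect_equal(m_to_beta(m), x, tolerance = 1e-12)
  expect_equal(m_to_beta(0), 0.5)
  expect_equal(m_to_beta(2), 0.8)
})

test_that("aggregate_gene averages probes per gene", {
  v <- matrix(c(0.2, 0.4, 0.9, 0.1,
                0.3, 0.5, 0.8, 0.2), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
  gm <- aggregate_gene(make_beta(v, genes = c("A", "A")))
  expect_equal(unname(gm$values["A", ]), c(0.25, 0.45, 0.85, 0.15))
  # one-probe gene is the identity
  gm2 <- aggregate_gene(make_beta(v, genes = c("A", "B")))
  expect_equal(unname(gm2$values["B", ]), unname(v["p2", ]))
  expect_equal(unname(gm2$n_probes["A"]), 1L)
})

test_that("aggregate_gene matches a brute-force per-gene mean", {
  set.seed(42)
  v <- matrix(runif(20 * 5), 20, 5,
              dimnames = list(sprintf("p%02d", 1:20), paste0("s", 1:5)))
  genes <- sample(paste0("G", 1:5), 20, replace = TRUE)
  gm <- aggregate_gene(make_beta(v, genes = genes))
  for (g in unique(genes)) {
    expect_equal(unname(gm$values[g, ]),
                 unname(colMeans(v[genes == g, , drop = FALSE])))
  }
  # probes without a gene symbol are excluded
  genes_na <- genes
  genes_na[1:3] <- NA
  gm2 <- aggregate_gene(make_beta(v, genes = genes_na))
  expect_equal(sum(gm2$n_probes), 17L)
})

test_that("region_methylation stratifies by CpG-region class", {
  v <- matrix(c(0.1, 0.1, 0.5, 0.5, 0.7, 0.7), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  bm <- make_beta(v, genes = rep("A", 3),
                  regions = c("island", "shore_N", "shore_N"),
                  groups = c("tumor", "normal"))
  rm_ <- region_methylation(bm, "A")
  expect_equal(rm_$mean_tumor[rm_$region == "island"], 0.1)
  expect_equal(rm_$mean_tumor[rm_$region == "shore_N"], 0.6)
  expect_equal(rm_$n_probes[rm_$region == "open_sea"], 0L)
  expect_true(is.na(rm_$mean_tumor[rm_$region == "open_sea"]))
  expect_error(region_methylation(bm, "NOPE"), "not found")
})

test_that("dm_test reproduces the exact rank-sum p for {1,2,3} vs {4,5,6}", {
  # build betas whose M-values are exactly 1..6
  b <- matrix(m_to_beta(c(4, 5, 6, 1, 2, 3)), nrow = 1,
              dimnames = list("p1", paste0("s", 1:6)))
  bm <- make_beta(b, groups = rep(c("tumor", "normal"), each = 3))
  rec <- dm_test(bm)
  expect_equal(rec$p, 0.1)
  expect_equal(rec$effect, 5 - 2)
})

test_that("dm_test returns p = 1 and effect 0 for identical groups", {
  b <- matrix(rep(c(0.2, 0.4, 0.6), 2), nrow = 1,
              dimnames = list("p1", paste0("s", 1:6)))
  bm <- make_beta(b, groups = rep(c("tumor", "normal"), each = 3))
  rec <- dm_test(bm)
  expect_equal(rec$p, 1)
  expect_equal(rec$effect, 0)
  # degenerate constant probe
  b2 <- matrix(0.5, 1, 6, dimnames = list("p1", paste0("s", 1:6)))
  rec2 <- dm_test(make_beta(b2, groups = rep(c("tumor", "normal"), 3)))
  expect_equal(rec2$p, 1)
})

test_that("exact rank-sum p equals full permutation enumeration", {
  set.seed(7)
  for (sizes in list(c(2, 2), c(3, 3), c(4, 4), c(3, 4), c(2, 4))) {
    for (rep in 1:5) {
      x <- rnorm(sizes[1]); y <- rnorm(sizes[2])
      expect_equal(methscreen:::rank_sum_test(x, y),
                   perm_wilcox_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("dm_test ranks planted genes ahead of the background", {
  co <- gen_cohort(cohort_spec(n_genes = 150, n_planted = 10,
                               planted_meth_delta = 0.3, seed = 11))
  rec <- dm_test(aggregate_gene(co$beta))
  top <- rec$id[order(rec$p)][1:10]
  expect_gte(length(intersect(top, co$truth$gene)), 9)
})

test_that("call_dm applies inclusive thresholds at both levels", {
  rec <- data.frame(id = c("a", "b", "c", "d"),
                    mean_m_tumor = 0, mean_m_normal = 0,
                    effect = c(0.8, 0.3, 0.5, -0.6),
                    p = c(0.001, 0.001, 0.05, 0.2),
                    q = c(0.004, 0.004, 0.1, 0.2))
  out <- call_dm(rec, level = "gene")
  expect_setequal(out$id, c("a", "c"))  # boundary (0.5, 0.05) is called
  expect_equal(out$direction, c("hyper", "hyper"))
  # probe level uses the stricter log2(1.45) ~ 0.536 threshold, so the
  # 0.5-effect gene drops out while the exact boundary value stays in
  outp <- call_dm(rec, level = "probe")
  expect_setequal(outp$id, "a")
  rec2 <- rec
  rec2$effect[2] <- log2(1.45)
  expect_true("b" %in% call_dm(rec2, level = "probe")$id)
  rec2$effect[2] <- 0.52  # gene-called, below the island threshold
  expect_true("b" %in% call_dm(rec2, level = "gene")$id)
  expect_false("b" %in% call_dm(rec2, level = "probe")$id)
})

test_that("call_dm equals a brute-force filter on random records", {
  set.seed(13)
  rec <- data.frame(id = paste0("g", 1:200),
                    mean_m_tumor = 0, mean_m_normal = 0,
                    effect = rnorm(200, sd = 0.8),
                    p = runif(200))
  rec$q <- bh_adjust(rec$p)
  out <- call_dm(rec, level = "gene")
  manual <- rec$id[rec$p <= 0.05 & abs(rec$effect) >= 0.5]
  expect_setequal(out$id, manual)
})

test_that("dm_test drops probes with missing values and small groups fail", {
  v <- matrix(runif(12), 3, 4,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  v[2, 1] <- NA
  bm <- make_beta(v, groups = c("tumor", "tumor", "normal", "normal"))
  expect_equal(nrow(dm_test(bm)), 2)
  bm1 <- make_beta(v[, 1:3], groups = c("tumor", "tumor", "normal"))
  expect_error(dm_test(bm1), "2 samples per group")
})
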