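# integrative screen: quadrant calls, two-cohort intersection,
# correlation, and over-representation analysis

fake_de <- function(genes, effect, p) {
  data.frame(gene = genes, mean_tumor = 0, mean_normal = 0,
             effect = effect, p = p, q = bh_adjust(p))
}
fake_dm <- function(genes, effect, p) {
  data.frame(id = genes, mean_m_tumor = 0, mean_m_normal = 0,
             effect = effect, p = p, q = bh_adjust(p))
}

test_that("screen_cohort assigns quadrants and hits by the dual rule", {
  de <- fake_de(c("a", "b", "c"), c(-2, -2, -2), c(0.01, 0.01, 0.5))
  dm <- fake_dm(c("a", "b", "c"), c(0.8, -0.8, 0.8), c(0.001, 0.001, 0.6))
  sc <- screen_cohort(de, dm)
  expect_equal(sc$quadrant, c("hyper-down", "hypo-down", "non-significant"))
  expect_equal(sc$is_hit, c(TRUE, FALSE, FALSE))
})

test_that("screen_cohort equals a brute-force filter on random tables", {
  set.seed(31)
  genes <- paste0("g", 1:60)
  de <- fake_de(genes, rnorm(60, sd = 1.5), runif(60))
  dm <- fake_dm(genes, rnorm(60, sd = 0.7), runif(60))
  sc <- screen_cohort(de, dm)
  manual <- genes[de$p <= 0.05 & de$effect <= -1 &
                    dm$p <= 0.05 & dm$effect >= 0.5]
  expect_setequal(sc$gene[sc$is_hit], manual)
})

test_that("genes missing on one side are dropped with a count", {
  de <- fake_de(c("a", "b"), c(-2, -2), c(0.01, 0.01))
  dm <- fake_dm(c("b", "c"), c(0.8, 0.8), c(0.01, 0.01))
  sc <- screen_cohort(de, dm)
  expect_equal(sc$gene, "b")
  expect_equal(attr(sc, "n_dropped"), 2L)
  expect_error(screen_cohort(de, fake_dm("z", 1, 0.01)), "shared")
})

test_that("intersect_cohorts computes the Venn of hit sets", {
  a <- fake_de(c("a", "b"), c(-2, -2), c(0.01, 0.01))
  ma <- fake_dm(c("a", "b"), c(0.8, 0.8), c(0.01, 0.01))
  b2 <- fake_de(c("b", "c"), c(-2, -2), c(0.01, 0.01))
  mb <- fake_dm(c("b", "c"), c(0.8, 0.8), c(0.01, 0.01))
  ov <- intersect_cohorts(screen_cohort(a, ma), screen_cohort(b2, mb))
  expect_equal(ov$intersection, "b")
  expect_equal(unname(ov$counts), c(1, 1, 1))
  # identical hit sets intersect to themselves; disjoint sets to nothing
  ov2 <- intersect_cohorts(screen_cohort(a, ma), screen_cohort(a, ma))
  expect_equal(ov2$intersection, c("a", "b"))
  mb0 <- fake_dm(c("b", "c"), c(-0.8, 0.8), c(0.01, 0.01))
  ov3 <- intersect_cohorts(screen_cohort(a, ma), screen_cohort(b2, mb0))
  expect_equal(length(intersect(ov3$sets[[1]], ov3$sets[[2]])),
               unname(ov3$counts["both"]))
})

test_that("two synthetic cohorts recover the planted intersection", {
  run_one <- function(seed, planted = NULL) {
    co <- gen_cohort(cohort_spec(n_genes = 250, n_planted = 15,
                                 planted_genes = planted, seed = seed))
    tpm <- normalize_counts(co$counts, co$lengths, "TPM")
    de <- de_test(tpm, co$samples$group)
    dm <- dm_test(aggregate_gene(co$beta))
    list(calls = screen_cohort(de, dm), truth = co$truth$gene)
  }
  a <- run_one(101)
  b <- run_one(202, planted = a$truth)  # same biology, new cohort
  ov <- intersect_cohorts(a$calls, b$calls)
  hits <- ov$intersection
  recall <- length(intersect(hits, a$truth)) / length(a$truth)
  precision <- length(intersect(hits, a$truth)) / max(1, length(hits))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("correlate matches the closed-form Pearson and handles signs", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate(x, x)$estimate, 1)
  expect_equal(correlate(x, x)$p, 0)
  expect_equal(correlate(x, -x)$estimate, -1)
  # hand-evaluated product-moment formula on (0,0),(1,1),(2,0),(3,1)
  px <- c(0, 1, 2, 3); py <- c(0, 1, 0, 1)
  num <- sum((px - mean(px)) * (py - mean(py)))
  den <- sqrt(sum((px - mean(px))^2) * sum((py - mean(py))^2))
  expect_equal(correlate(px, py)$estimate, num / den)
  expect_error(correlate(px, rep(1, 4)), "variance")
  expect_error(correlate(1:2, 1:2), "length")
})

test_that("spearman is invariant to strictly monotone transforms", {
  set.seed(17)
  x <- rnorm(25); y <- x + rnorm(25)
  base <- correlate(x, y, "spearman")
  tr <- correlate(exp(x), y^3 + 5 * y, "spearman")
  expect_equal(base$estimate, tr$estimate, tolerance = 1e-12)
  expect_equal(base$p, tr$p, tolerance = 1e-12)
})

test_that("ora reproduces exact hypergeometric tail probabilities", {
  universe <- paste0("g", 1:20)
  sets <- list(all_hits = paste0("g", 1:5),
               none = paste0("g", 6:10),
               whole = universe)
  hits <- paste0("g", 1:5)
  res <- ora(hits, sets, universe)
  expect_equal(res$p[res$set == "all_hits"], 1 / choose(20, 5))
  expect_equal(res$p[res$set == "none"], 1,
               tolerance = 1e-12)  # upper tail includes k = 0
  expect_equal(res$p[res$set == "whole"], 1)
  expect_error(ora(hits, sets, character(0)), "universe")
  expect_error(ora("zzz", sets, universe), "subset")
})

test_that("ora p-values match pmf enumeration for small universes", {
  set.seed(23)
  universe <- paste0("g", 1:30)
  hits <- sample(universe, 8)
  sets <- list(s1 = sample(universe, 10), s2 = sample(universe, 4))
  res <- ora(hits, sets, universe)
  for (nm in names(sets)) {
    K <- length(sets[[nm]]); k <- length(intersect(hits, sets[[nm]]))
    pm <- sum(vapply(k:min(K, 8), function(j) {
      choose(K, j) * choose(30 - K, 8 - j) / choose(30, 8)
    }, numeric(1)))
    expect_equal(res$p[res$set == nm], pm, tolerance = 1e-12)
  }
})

test_that("read_gmt parses name, description and members", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\turl\tg2\tg4"), f)
  gs <- read_gmt(f)
  expect_equal(names(gs), c("setA", "setB"))
  expect_equal(gs$setA, c("g1", "g2", "g3"))
  expect_equal(gs$setB, c("g2", "g4"))
})
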