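# toy per-sample count matrix: 100 cells, population "T" of size 10
toy_counts <- function() {
  set.seed(42)
  labels <- c(rep("T", 10), rep("rest", 90))
  counts <- matrix(rpois(5 * 100, lambda = 2), nrow = 5,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:100)))
  counts["g1", labels == "T"] <- 0          # fails the 5% in-cluster rule
  counts["g2", ] <- rep(c(0, 1, 2, 3, 4), 20)  # identical in and out
  counts["g3", labels == "T"] <- rpois(10, lambda = 20)  # strong marker
  list(counts = counts, labels = labels)
}

test_that("per_sample_de applies the 5% expression filter and null behaviour", {
  toy <- toy_counts()
  res <- per_sample_de(toy$counts, toy$labels, "T")
  expect_false("g1" %in% res$gene)   # 0 of 10 cluster cells expressed
  expect_true("g3" %in% res$gene)
  expect_lt(res$p[res$gene == "g3"], 0.01)
  expect_gt(res$log2fc[res$gene == "g3"], 1)
  expect_error(per_sample_de(toy$counts, toy$labels, "absent_pop"),
               "absent")
  # wilcoxon fallback agrees on the strong marker
  resw <- per_sample_de(toy$counts, toy$labels, "T", method = "wilcox")
  expect_lt(resw$p[resw$gene == "g3"], 0.01)
})

test_that("a gene with identical count distribution in and out is null", {
  labels <- c(rep("T", 50), rep("rest", 50))
  counts <- matrix(rep(c(0, 1, 2, 3, 4), 40), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gnull", "gnull2"), NULL))
  colnames(counts) <- paste0("c", 1:100)
  res <- per_sample_de(counts, labels, "T")
  expect_true(all(res$p > 0.5))
  expect_true(all(abs(res$log2fc) < 0.05))
})

test_that("planted population markers are recovered per sample", {
  sim <- simulate_sc_cohort(small_config(seed = 13))
  res <- per_sample_de(sim$counts[[1]], sim$labels[[1]], "pop1")
  markers <- intersect(sim$truth$population_markers$pop1, res$gene)
  expect_gte(mean(res$p[res$gene %in% markers] < 0.01), 0.9)
})

test_that("sample inclusion follows the population-fraction threshold", {
  labels <- list(
    s1 = rep(c("T", "rest"), c(29, 971)),    # 2.9% -> excluded at 3%
    s2 = rep(c("T", "rest"), c(50, 950)),    # 5%
    s3 = rep(c("T", "rest"), c(100, 900)),   # 10%
    s4 = rep("T", 50))                       # 100%
  expect_identical(sample_inclusion(labels, "T", 0.03),
                   c("s2", "s3", "s4"))
  labels2 <- list(a = rep(c("T", "rest"), c(2, 98)),
                  b = rep(c("T", "rest"), c(5, 95)),
                  c = rep(c("T", "rest"), c(10, 90)))
  expect_identical(sample_inclusion(labels2, "T", 0.03), c("b", "c"))
})

test_that("Fisher combination matches the chi-square closed forms", {
  # k = 1: identity
  for (p in c(0.001, 0.05, 0.5, 1)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  }
  # p = 1 contributes nothing
  expect_equal(fisher_combine(c(1, 1, 1)), 1, tolerance = 1e-12)
  # closed-form chi-square survival oracles, k = 2 and 3:
  # S(X; 4)  = exp(-X/2) (1 + X/2)
  # S(X; 6)  = exp(-X/2) (1 + X/2 + X^2/8)
  set.seed(31)
  for (i in 1:50) {
    p2 <- runif(2)
    x <- -2 * sum(log(p2))
    expect_equal(fisher_combine(p2), exp(-x / 2) * (1 + x / 2),
                 tolerance = 1e-10)
    p3 <- runif(3)
    x <- -2 * sum(log(p3))
    expect_equal(fisher_combine(p3),
                 exp(-x / 2) * (1 + x / 2 + x^2 / 8), tolerance = 1e-10)
  }
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.0174792, tolerance = 1e-4)
  expect_error(fisher_combine(c(0.5, 0)), "floor")
  expect_error(fisher_combine(numeric(0)), "no p-values")
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  # step-up by hand: q_i = min over j with p_(j) >= p_(i) of m p_(j) / j
  p <- c(0.005, 0.04, 0.03, 0.8)
  ps <- sort(p)
  q_manual <- vapply(p, function(pi) {
    j <- which(ps >= pi)
    min(pmin(length(p) * ps[j] / j, 1))
  }, numeric(1))
  expect_equal(bh_fdr(p), q_manual)
})

test_that("combination respects the two-sample rule and flags singletons", {
  per_sample <- list(
    s1 = data.frame(gene = c("g1", "g2"), p = c(0.05, 0.01),
                    log2fc = c(1, 2)),
    s2 = data.frame(gene = c("g1"), p = c(0.05), log2fc = c(1.2)),
    s3 = data.frame(gene = c("g3"), p = c(0.2), log2fc = c(0.5)))
  res <- combine_across_samples(per_sample, c("s1", "s2", "s3"))
  g1 <- res[res$feature == "g1", ]
  expect_true(g1$combined)
  expect_equal(g1$combined_p, 0.0174792, tolerance = 1e-4)
  # tested in one included sample only: reported, flagged uncombined
  g2 <- res[res$feature == "g2", ]
  expect_false(g2$combined)
  expect_equal(g2$combined_p, 0.01)
  # tested in no sample: absent
  expect_false("g4" %in% res$feature)
  # excluded samples do not contribute
  res2 <- combine_across_samples(per_sample, c("s1", "s3"))
  expect_false(res2[res2$feature == "g1", "combined"])
  expect_warning(out <- combine_across_samples(per_sample, character(0)),
                 "no included samples")
  expect_equal(nrow(out), 0)
})

test_that("gene filter and sample inclusion commute", {
  sim <- simulate_sc_cohort(small_config(seed = 17, n_samples_per_group = 4L))
  cfg <- de_config()
  # pipeline A: inclusion first (the multisample_de path)
  a <- multisample_de(sim$counts, sim$labels, "pop2", cfg)
  # pipeline B: per-sample DE everywhere, subset to included afterwards
  per_sample <- lapply(names(sim$counts), function(s) {
    per_sample_de(sim$counts[[s]], sim$labels[[s]], "pop2", cfg)
  })
  names(per_sample) <- names(sim$counts)
  included <- sample_inclusion(sim$labels, "pop2",
                               cfg$min_cluster_sample_frac)
  b <- combine_across_samples(per_sample, included, cfg)
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
})
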