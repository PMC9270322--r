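test_that("per-sample Fisher exact DA matches hypergeometric enumeration", {
  # 8/10 accessible in population vs 2/10 outside
  labels <- rep(c("T", "rest"), each = 10)
  mat <- matrix(0, nrow = 2, ncol = 20,
                dimnames = list(c("pk_da", "pk_flat"), paste0("c", 1:20)))
  mat["pk_da", c(1:8, 11:12)] <- 1
  mat["pk_flat", c(1:5, 11:15)] <- 1
  res <- per_sample_da(mat, labels, "T")
  expect_equal(res$p[res$peak == "pk_da"], 4252 / 184756, tolerance = 1e-10)
  expect_equal(res$p[res$peak == "pk_da"], oracle_fisher2(8, 2, 2, 8),
               tolerance = 1e-12)
  # identical proportions: p = 1
  expect_equal(res$p[res$peak == "pk_flat"], 1)
  expect_gt(res$log_odds[res$peak == "pk_da"], 0)
})

test_that("Fisher exact p agrees with full enumeration for all tables N <= 40", {
  set.seed(77)
  for (i in 1:200) {
    N <- sample(4:40, 1)
    a <- sample(0:N, 1)
    b <- sample(0:(N - a), 1)
    c_ <- sample(0:(N - a - b), 1)
    d <- N - a - b - c_
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    expect_equal(min(1, fisher.test(matrix(c(a, b, c_, d), 2))$p.value),
                 min(1, oracle_fisher2(a, b, c_, d)), tolerance = 1e-9)
  }
})

test_that("30% accessibility filter removes weakly accessible peaks pre-test", {
  labels <- rep(c("T", "rest"), each = 10)
  mat <- matrix(0, nrow = 1, ncol = 20,
                dimnames = list("pk_low", paste0("c", 1:20)))
  mat["pk_low", c(1, 2, 11:18)] <- 1  # 2 of 10 population cells (20%)
  res <- per_sample_da(mat, labels, "T")
  expect_false("pk_low" %in% res$peak)
  expect_error(per_sample_da(mat, labels, "missing"), "absent")
})

test_that("multi-sample DA applies the 4% rule and calls direction", {
  sim <- simulate_accessibility(small_config(seed = 19,
                                             n_samples_per_group = 4L))
  res <- differential_accessibility(sim$matrices, sim$labels, "pop1")
  planted <- intersect(sim$truth$da_peaks$pop1, res$feature)
  expect_gt(length(planted), 10)
  hit <- res[res$feature %in% planted, ]
  expect_gte(mean(hit$combined_p < 0.01), 0.9)
  expect_true(all(hit$direction[hit$combined_p < 0.01] == "up"))
  # the 4% rule: excluded samples never appear in the bookkeeping
  frac <- vapply(sim$labels, function(l) mean(l == "pop1"), numeric(1))
  excluded <- names(frac)[frac < 0.04]
  if (length(excluded)) {
    listed <- unlist(strsplit(res$included_samples, ","))
    expect_false(any(excluded %in% listed))
  }
  expect_error(
    differential_accessibility(sim$matrices,
                               lapply(sim$labels, function(l) rep("x", length(l))),
                               "pop1"),
    "absent from all samples")
})

test_that("enhancer concordance tests DA-enhancer targets against DEGs", {
  universe <- paste0("g", 1:20)
  # enhancers for g1..g10 at disjoint intervals; DA peaks overlap all ten
  enh <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                    end = seq(0, 900, 100) + 50, gene = paste0("g", 1:10))
  da <- data.frame(chrom = "chr1", start = seq(0, 900, 100) + 10,
                   end = seq(0, 900, 100) + 20)
  degs <- paste0("g", c(1:8, 15, 16))  # overlap 8 of 10
  res <- enhancer_concordance(da, enh, degs, universe)
  expect_equal(unname(res$counts["overlap"]), 8)
  expect_equal(res$p, oracle_fisher2(8, 2, 2, 8), tolerance = 1e-9)
  expect_equal(res$p, 4252 / 184756, tolerance = 1e-4)
  # overlap at expectation is not significant
  u2 <- paste0("g", 1:100)
  enh2 <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                     end = seq(0, 900, 100) + 50, gene = paste0("g", 1:10))
  res2 <- enhancer_concordance(da, enh2, paste0("g", 10:19), u2)
  expect_gt(res2$p, 0.5)
  # empty DA set
  res3 <- enhancer_concordance(da[0, ], enh, degs, universe)
  expect_equal(unname(res3$counts["overlap"]), 0)
  expect_equal(res3$p, 1)
  expect_error(enhancer_concordance(da, enh, degs, character(0)), "universe")
})

test_that("motif deviation test combines rank-sum p with the delta-z filter", {
  set.seed(3)
  n_pop <- 50
  n_rest <- 200
  labels <- list(s1 = rep(c("M", "rest"), c(n_pop, n_rest)))
  dev <- matrix(rnorm(3 * 250), nrow = 3,
                dimnames = list(c("TF_up", "TF_null", "TF_small"), NULL))
  dev["TF_up", 1:n_pop] <- dev["TF_up", 1:n_pop] + 2       # +2 SD shift
  dev["TF_null", ] <- 0.5                                  # identical in/out
  dev["TF_small", 1:n_pop] <- dev["TF_small", 1:n_pop] + 0.8
  res <- motif_deviation_test(list(s1 = dev), labels, "M",
                              motif_config(fdr_threshold = 0.05))
  up <- res[res$tf == "TF_up", ]
  expect_lt(up$combined_p, 1e-6)
  expect_gt(up$delta_z, 1)
  expect_true(up$flagged)
  null <- res[res$tf == "TF_null", ]
  expect_gt(null$combined_p, 0.5)
  expect_lt(abs(null$delta_z), 0.3)
  # significant but small shift: the delta-z >= 1 display rule blocks it
  small <- res[res$tf == "TF_small", ]
  expect_lt(small$fdr, 0.05)
  expect_lt(small$delta_z, 1)
  expect_false(small$flagged)
  expect_error(motif_deviation_test(list(s1 = dev), labels, "absent"),
               "absent")
})

test_that("joint screen requires both correlation and motif significance", {
  set.seed(5)
  ab <- c(s1 = 0.1, s2 = 0.2, s3 = 0.35, s4 = 0.5, s5 = 0.7, s6 = 0.9)
  expr <- rbind(TF_pos = ab * 10,            # perfectly monotone
                TF_neg = rev(ab) * 3,        # perfectly anti-monotone
                TF_null = c(0.4, 0.1, 0.5, 0.2, 0.45, 0.3))
  colnames(expr) <- names(ab)
  motif <- data.frame(tf = c("TF_pos", "TF_neg", "TF_null"),
                      fdr = c(0.01, 0.2, 0.01))
  res <- joint_emt_screen(expr, ab, motif)
  expect_equal(res$rho[res$tf == "TF_pos"], 1)
  expect_equal(res$rho[res$tf == "TF_neg"], -1)
  expect_true(res$selected[res$tf == "TF_pos"])
  # significant correlation but motif FDR above 0.05: rejected by the AND rule
  expect_false(res$selected[res$tf == "TF_neg"])
  expect_identical(res$direction[res$tf == "TF_neg"], "anti-correlated")
  expect_error(joint_emt_screen(expr[, 1:3], ab[1:3], motif), ">= 4")
})
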