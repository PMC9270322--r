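test_that("rank_genes sorts by decreasing value with lexicographic ties", {
  expect_identical(rank_genes(c(A = 3, B = 1, C = 2))$genes, c("A", "C", "B"))
  expect_identical(rank_genes(c(C = 1, A = 1, B = 1))$genes, c("A", "B", "C"))
  # rank-only dependence: any strictly increasing transform gives same order
  v <- c(a = 0.2, b = 5, c = 1.7, d = 0.01)
  expect_identical(rank_genes(v)$genes, rank_genes(exp(v))$genes)
  expect_identical(rank_genes(v)$genes, rank_genes(rank(v))$genes)
  expect_error(rank_genes(c(A = 1, A = 2)), "duplicate")
  expect_error(rank_genes(numeric(0)), "empty")
})

test_that("running sum walks the documented six-step example", {
  prof <- profile_with_ranks(6)
  sig <- names(sort(prof, decreasing = TRUE))[c(2, 5)]
  res <- running_sum_es(rank_genes(prof), sig)
  expect_equal(res$curve, c(-0.25, 0.25, 0.0, -0.25, 0.25, 0.0))
  expect_equal(res$es, 0.25)
  # signature occupying the top n ranks scores exactly 1
  prof10 <- profile_with_ranks(10)
  top2 <- names(sort(prof10, decreasing = TRUE))[1:2]
  expect_equal(running_sum_es(rank_genes(prof10), top2)$es, 1.0)
})

test_that("running-sum curve telescopes to zero and matches the brute-force oracle", {
  # exhaustive check over all C(m, n) placements, m <= 12, n <= 3
  for (m in 3:12) {
    prof <- profile_with_ranks(m)
    ranked <- rank_genes(prof)
    for (n in 1:min(3, m - 1)) {
      placements <- utils::combn(m, n)
      for (k in seq_len(ncol(placements))) {
        pos <- placements[, k]
        res <- running_sum_es(ranked, ranked$genes[pos])
        expected <- oracle_curve(pos, m)
        expect_equal(res$curve, expected, tolerance = 1e-12)
        expect_equal(res$es, max(expected), tolerance = 1e-12)
        expect_equal(res$curve[m], 0, tolerance = 1e-12)
      }
    }
  }
})

test_that("position-based enrichment score equals the full cumulative sum", {
  set.seed(5)
  for (i in 1:200) {
    m <- sample(20:200, 1)
    n <- sample(seq_len(min(15, m - 1)), 1)
    pos <- sort(sample.int(m, n))
    ranked <- rank_genes(profile_with_ranks(m))
    full <- running_sum_es(ranked, ranked$genes[pos])$es
    fast <- pfomics:::es_from_positions(pos, m, n)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("running_sum_es rejects invalid signatures", {
  ranked <- rank_genes(profile_with_ranks(6))
  expect_error(running_sum_es(ranked, c("absent1", "absent2")), "absent")
  expect_error(running_sum_es(ranked, ranked$genes), "smaller")
  expect_error(running_sum_es(ranked, character(0)), "empty")
})

test_that("permutation p-values are deterministic, bounded and monotone in es", {
  prof <- profile_with_ranks(100)
  ranked <- rank_genes(prof)
  top <- ranked$genes[1:5]
  r1 <- permutation_p(ranked, top, n_perm = 200, seed = 3)
  r2 <- permutation_p(ranked, top, n_perm = 200, seed = 3)
  expect_identical(r1$p, r2$p)
  # a perfectly enriched signature attains the add-one minimum
  expect_equal(r1$es, 1.0)
  expect_equal(r1$p, 1 / 201)
  # monotone non-increasing in the observed score at fixed seed and n
  placements <- list(1:5, c(1:4, 50), c(1:3, 50, 60), c(10, 30, 50, 70, 90),
                     96:100)
  res <- lapply(placements, function(pos) {
    permutation_p(ranked, ranked$genes[pos], n_perm = 200, seed = 3)
  })
  es <- vapply(res, `[[`, numeric(1), "es")
  p <- vapply(res, `[[`, numeric(1), "p")
  expect_true(all(diff(es) < 0))
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("normalized enrichment scores behave as enrichment ratios", {
  ranked <- rank_genes(profile_with_ranks(100))
  expect_gt(normalized_es(ranked, ranked$genes[1:5], n_perm = 200, seed = 2), 1)
  # NES of random signatures concentrates near 1
  set.seed(9)
  nes <- replicate(200, {
    sig <- sample(ranked$genes, 5)
    normalized_es(ranked, sig, n_perm = 100, seed = sample.int(1e6, 1))
  })
  expect_lt(abs(stats::median(nes) - 1), 0.25)
})

test_that("decision rules: unassignment, carve-out precedence and tie-breaks", {
  cfg <- classifier_config(pfb_group = "PFB")
  p_all_high <- c(A = 1, B = 1, PFB = 1)
  es <- c(A = 0.2, B = 0.2, PFB = 0.2)
  expect_identical(pfomics:::decide_group(p_all_high, es, cfg), "UNASSIGNED")
  expect_identical(
    pfomics:::decide_group(c(A = 0.5, B = 0.5, PFB = 0.33), es, cfg), "PFB")
  # carve-out wins even when another group has smaller p
  expect_identical(
    pfomics:::decide_group(c(A = 0.01, B = 0.5, PFB = 0.33), es, cfg), "PFB")
  # without the carve-out, argmin-p wins at p <= 0.35
  cfg0 <- classifier_config()
  expect_identical(
    pfomics:::decide_group(c(A = 0.35, B = 0.5, PFB = 0.4), es, cfg0), "A")
  expect_identical(
    pfomics:::decide_group(c(A = 0.36, B = 0.5, PFB = 0.4), es, cfg0),
    "UNASSIGNED")
  # ties: larger es, then lexicographic
  expect_identical(
    pfomics:::decide_group(c(B = 0.1, A = 0.1), c(B = 0.5, A = 0.3), cfg0),
    "B")
  expect_identical(
    pfomics:::decide_group(c(B = 0.1, A = 0.1), c(B = 0.5, A = 0.5), cfg0),
    "A")
})

test_that("classify_profile applies the carve-out and unassignment end to end", {
  m <- 500
  prof <- profile_with_ranks(m)
  ranked_names <- names(sort(prof, decreasing = TRUE))
  sigs <- list(A = ranked_names[1:20],
               PFB = ranked_names[seq(5, 245, by = 12)],
               C = ranked_names[(m - 19):m])
  cfg <- classifier_config(pfb_group = "PFB", n_perm = 400, seed = 11)
  res <- classify_profile(prof, sigs, cfg)
  ps <- res$per_signature
  expect_lt(ps$p[ps$group == "PFB"], 0.34)
  expect_lte(ps$p[ps$group == "A"], ps$p[ps$group == "PFB"])
  expect_identical(res$assigned_group, "PFB")
  # without the carve-out the same profile goes to the minimum-p group
  res2 <- classify_profile(prof, sigs, classifier_config(n_perm = 400,
                                                         seed = 11))
  expect_identical(res2$assigned_group, "A")
  # a profile enriched for no signature stays unassigned
  sigs_bottom <- list(A = ranked_names[(m - 19):m],
                      B = ranked_names[(m - 39):(m - 20)])
  res3 <- classify_profile(prof, sigs_bottom,
                           classifier_config(n_perm = 400, seed = 11))
  expect_identical(res3$assigned_group, "UNASSIGNED")
  # signature genes absent from the profile are dropped with a warning
  expect_warning(
    classify_profile(prof, list(A = c(ranked_names[1:10], "missing_gene")),
                     classifier_config(n_perm = 50, seed = 1)),
    "dropped")
  expect_error(classify_profile(prof, list(), cfg), "empty")
})

test_that("evaluate_classifier counts UNASSIGNED as misclassification", {
  truth <- c("A", "B", "A")
  expect_equal(evaluate_classifier(truth, truth)$error_rate, 0)
  expect_equal(evaluate_classifier(rep("UNASSIGNED", 3), truth)$error_rate, 1)
  ev <- evaluate_classifier(c("A", "UNASSIGNED", "B"), truth)
  expect_equal(ev$error_rate, 2 / 3)
  expect_equal(unname(ev$confusion["A", "A"]), 1)
  expect_error(evaluate_classifier("A", truth), "equal length")
})
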