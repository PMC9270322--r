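# Per-sample population-versus-rest differential testing, inclusion
# filters, Fisher's-method combination across samples and BH FDR.

#' Differential-expression configuration
#'
#' @param min_cluster_expr_frac A gene is tested only when it is expressed
#'   (count > 0) in at least this fraction of the cells of the target
#'   population (default 0.05).
#' @param min_cluster_sample_frac A sample enters the combination only when
#'   at least this fraction of its cells belongs to the target population
#'   (default 0.03 for expression; accessibility and motif analyses use
#'   0.04).
#' @param min_samples_for_combination Minimum number of included samples in
#'   which a feature must be tested for its p-values to be combined
#'   (default 2); features tested in exactly one sample are reported
#'   uncombined and flagged.
#' @param fdr_threshold Reporting threshold on the BH-adjusted combined
#'   p-value (default 0.1).
#' @return A `de_config` list.
#' @export
de_config <- function(min_cluster_expr_frac = 0.05,
                      min_cluster_sample_frac = 0.03,
                      min_samples_for_combination = 2L,
                      fdr_threshold = 0.1) {
  assert_fraction(min_cluster_expr_frac, "min_cluster_expr_frac")
  assert_fraction(min_cluster_sample_frac, "min_cluster_sample_frac")
  assert_count(min_samples_for_combination, "min_samples_for_combination")
  assert_fraction(fdr_threshold, "fdr_threshold")
  structure(list(min_cluster_expr_frac = min_cluster_expr_frac,
                 min_cluster_sample_frac = min_cluster_sample_frac,
                 min_samples_for_combination =
                   as.integer(min_samples_for_combination),
                 fdr_threshold = fdr_threshold),
            class = "de_config")
}

# Negative-binomial likelihood-ratio test for one gene: group-specific means
# versus a common mean, with the dispersion profiled under the alternative
# and held fixed for the null fit. Degenerate genes (no counts, or both
# group means equal) return p = 1.
nb_lrt_gene <- function(y, in_pop) {
  y1 <- y[in_pop]
  y0 <- y[!in_pop]
  mu1 <- mean(y1)
  mu0 <- mean(y0)
  mu <- mean(y)
  if (mu == 0 || mu1 == mu0) return(1)
  ll_alt <- function(log_theta) {
    th <- exp(log_theta)
    sum(stats::dnbinom(y1, mu = max(mu1, 1e-10), size = th, log = TRUE)) +
      sum(stats::dnbinom(y0, mu = max(mu0, 1e-10), size = th, log = TRUE))
  }
  opt <- stats::optimize(ll_alt, interval = c(-7, 9), maximum = TRUE,
                         tol = 1e-3)
  theta <- exp(opt$maximum)
  ll1 <- opt$objective
  ll0 <- sum(stats::dnbinom(y, mu = mu, size = theta, log = TRUE))
  lrt <- max(0, 2 * (ll1 - ll0))
  stats::pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' Per-sample differential expression, one population versus the rest
#'
#' Tests each gene for differential expression between the cells of
#' `population` and all other cells of the sample. Genes expressed (count
#' > 0) in fewer than `min_cluster_expr_frac` of the population's cells are
#' excluded from the output. The reference test is a negative-binomial
#' likelihood-ratio test (overdispersed counts, two-sided); a Wilcoxon
#' rank-sum fallback is available. Log2 fold changes are computed on
#' depth-normalized per-group mean counts with a +1 pseudocount.
#'
#' @param counts Genes x cells count matrix (dense or sparse).
#' @param cell_labels Population label per cell.
#' @param population Target population; an error (distinct from filter
#'   exclusion) is raised when absent from the sample.
#' @param config A [de_config()].
#' @param method `"nb_lrt"` (default) or `"wilcox"`.
#' @return `data.frame` with columns `gene`, `log2fc`, `p` for the genes
#'   passing the expression filter.
#' @export
per_sample_de <- function(counts, cell_labels, population,
                          config = de_config(),
                          method = c("nb_lrt", "wilcox")) {
  method <- match.arg(method)
  if (length(cell_labels) != ncol(counts)) {
    stop("cell_labels must have one entry per cell")
  }
  in_pop <- cell_labels == population
  if (!any(in_pop)) {
    stop("population '", population, "' absent from the sample")
  }
  expr_frac <- Matrix::rowMeans(counts[, in_pop, drop = FALSE] > 0)
  keep <- which(expr_frac >= config$min_cluster_expr_frac)
  if (!length(keep)) {
    return(data.frame(gene = character(), log2fc = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  sub <- as.matrix(counts[keep, , drop = FALSE])

  depth <- Matrix::colSums(counts)
  sf <- depth / mean(depth)
  sf[sf == 0] <- 1
  norm <- sweep(sub, 2, sf, `/`)
  m1 <- rowMeans(norm[, in_pop, drop = FALSE])
  m0 <- rowMeans(norm[, !in_pop, drop = FALSE])
  lfc <- log2((m1 + 1) / (m0 + 1))

  p <- if (method == "nb_lrt") {
    apply(sub, 1L, nb_lrt_gene, in_pop = in_pop)
  } else {
    apply(sub, 1L, function(y) {
      stats::wilcox.test(y[in_pop], y[!in_pop], exact = FALSE)$p.value
    })
  }
  p[is.na(p)] <- 1
  data.frame(gene = rownames(counts)[keep], log2fc = lfc, p = pmin(p, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Samples eligible for p-value combination
#'
#' A sample is included when at least `threshold` of its cells belongs to
#' the population of interest (3% for expression, 4% for accessibility and
#' motif analyses).
#'
#' @param labels_per_sample Named list of per-cell population label vectors.
#' @param population Target population.
#' @param threshold Minimum population fraction.
#' @return Character vector of included sample names.
#' @export
sample_inclusion <- function(labels_per_sample, population,
                             threshold = 0.03) {
  stopifnot(length(labels_per_sample) > 0)
  frac <- vapply(labels_per_sample, function(l) {
    if (!length(l)) stop("empty label vector")
    mean(l == population)
  }, numeric(1))
  names(frac)[frac >= threshold]
}

#' Combine p-values with Fisher's method
#'
#' Computes `X = -2 * sum(log(p))` and refers it to a chi-square
#' distribution with `2k` degrees of freedom (upper tail). With a single
#' p-value the input is returned unchanged.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("no p-values to combine")
  if (any(p_values <= 0)) {
    stop("p-values must be > 0; floor them (e.g. at 1e-300) before combining")
  }
  if (any(p_values > 1)) stop("p-values must be <= 1")
  x <- -2 * sum(log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p_values Numeric vector of p-values.
#' @return Vector of BH step-up adjusted values (q-values), same order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Combine per-sample test results across samples
#'
#' Features with per-sample p-values in at least
#' `min_samples_for_combination` included samples are Fisher-combined
#' (p-values floored at 1e-300 before taking logs); features tested in
#' exactly one included sample are reported uncombined and flagged. BH FDR
#' is computed over the reported p-values (combined where available,
#' otherwise the single-sample p).
#'
#' @param per_sample_results Named list (one element per sample) of data
#'   frames with columns `gene` (or `feature`/`peak`), `p` and optionally
#'   `log2fc`, as returned by [per_sample_de()].
#' @param included_samples Character vector of sample names to combine
#'   (see [sample_inclusion()]).
#' @param config A [de_config()].
#' @return `data.frame` with columns `feature`, `n_samples`, `combined`
#'   (logical), `combined_p`, `fdr`, `mean_log2fc` and `included_samples`;
#'   per-sample p and log2fc matrices are attached as attributes
#'   `per_sample_p` and `per_sample_log2fc`.
#' @export
combine_across_samples <- function(per_sample_results, included_samples,
                                   config = de_config()) {
  included_samples <- intersect(names(per_sample_results), included_samples)
  if (!length(included_samples)) {
    warning("no included samples; returning empty result")
    return(data.frame(feature = character(), n_samples = integer(),
                      combined = logical(), combined_p = numeric(),
                      fdr = numeric(), mean_log2fc = numeric(),
                      included_samples = character(),
                      stringsAsFactors = FALSE))
  }
  res <- per_sample_results[included_samples]
  res <- lapply(res, function(d) {
    key <- intersect(c("gene", "feature", "peak"), names(d))[1]
    if (is.na(key)) stop("per-sample results need a gene/feature/peak column")
    data.frame(feature = d[[key]], p = d$p,
               log2fc = if ("log2fc" %in% names(d)) d$log2fc else NA_real_,
               stringsAsFactors = FALSE)
  })
  features <- sort(unique(unlist(lapply(res, `[[`, "feature"))))
  pm <- matrix(NA_real_, nrow = length(features), ncol = length(res),
               dimnames = list(features, included_samples))
  lm <- pm
  for (s in included_samples) {
    i <- match(res[[s]]$feature, features)
    pm[i, s] <- res[[s]]$p
    lm[i, s] <- res[[s]]$log2fc
  }
  n_samples <- rowSums(!is.na(pm))
  combined <- n_samples >= config$min_samples_for_combination
  combined_p <- vapply(seq_along(features), function(i) {
    ps <- pm[i, !is.na(pm[i, ])]
    if (combined[i]) fisher_combine(pmax(ps, 1e-300)) else unname(ps[1])
  }, numeric(1))
  out <- data.frame(
    feature = features,
    n_samples = as.integer(n_samples),
    combined = combined,
    combined_p = combined_p,
    fdr = bh_fdr(combined_p),
    mean_log2fc = rowMeans(lm, na.rm = TRUE),
    included_samples = vapply(seq_along(features), function(i) {
      paste(colnames(pm)[!is.na(pm[i, ])], collapse = ",")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_sample_p") <- pm
  attr(out, "per_sample_log2fc") <- lm
  out
}

#' Multi-sample differential expression for one population
#'
#' Convenience wrapper: applies the 3% sample-inclusion rule, runs
#' [per_sample_de()] in every included sample that contains the population,
#' and combines the per-gene p-values with [combine_across_samples()].
#'
#' @param counts_per_sample Named list of gene x cell count matrices.
#' @param labels_per_sample Named list of per-cell population labels.
#' @param population Target population.
#' @param config A [de_config()].
#' @param method Per-sample test, see [per_sample_de()].
#' @return See [combine_across_samples()].
#' @export
multisample_de <- function(counts_per_sample, labels_per_sample, population,
                           config = de_config(),
                           method = c("nb_lrt", "wilcox")) {
  method <- match.arg(method)
  included <- sample_inclusion(labels_per_sample, population,
                               config$min_cluster_sample_frac)
  if (!length(included)) {
    warning("population '", population, "' below the sample-inclusion ",
            "threshold in every sample")
    return(combine_across_samples(list(), character(0), config))
  }
  per_sample <- lapply(included, function(s) {
    per_sample_de(counts_per_sample[[s]], labels_per_sample[[s]],
                  population, config, method)
  })
  names(per_sample) <- included
  combine_across_samples(per_sample, included, config)
}
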