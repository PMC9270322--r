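# Differential accessibility, enhancer concordance, motif-deviation testing
# and the joint expression-correlation / motif-accessibility screen.

#' Differential-accessibility configuration
#'
#' @param min_cluster_access_frac Peaks accessible (nonzero) in fewer than
#'   this fraction of the population's cells are removed before testing
#'   (default 0.30).
#' @param min_cluster_sample_frac Samples with fewer than this fraction of
#'   cells in the population are excluded from the combination
#'   (default 0.04).
#' @param min_samples_for_combination Minimum samples for Fisher combination
#'   (default 2).
#' @param fdr_threshold Reporting FDR threshold (default 0.05).
#' @return A `da_config` list.
#' @export
da_config <- function(min_cluster_access_frac = 0.30,
                      min_cluster_sample_frac = 0.04,
                      min_samples_for_combination = 2L,
                      fdr_threshold = 0.05) {
  assert_fraction(min_cluster_access_frac, "min_cluster_access_frac")
  assert_fraction(min_cluster_sample_frac, "min_cluster_sample_frac")
  assert_count(min_samples_for_combination, "min_samples_for_combination")
  assert_fraction(fdr_threshold, "fdr_threshold")
  structure(list(min_cluster_access_frac = min_cluster_access_frac,
                 min_cluster_sample_frac = min_cluster_sample_frac,
                 min_samples_for_combination =
                   as.integer(min_samples_for_combination),
                 fdr_threshold = fdr_threshold),
            class = "da_config")
}

# Two-sided Fisher exact p-value and odds-ratio sign for one peak's 2x2
# table: accessible yes/no x in-population yes/no.
fisher_peak <- function(a, b, c, d) {
  # fisher.test can exceed 1 by a few ulps when summing table probabilities
  min(1, stats::fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value)
}

#' Per-sample differential accessibility, one population versus the rest
#'
#' For every peak, tests the 2x2 table (accessible yes/no x in-population
#' yes/no) with a two-sided Fisher exact test. Peaks accessible in fewer
#' than `min_cluster_access_frac` of the population's cells are removed
#' before testing.
#'
#' @param mat Peak x cell matrix (binary or counts; "accessible" means a
#'   nonzero entry).
#' @param cell_labels Population label per cell.
#' @param population Target population.
#' @param config A [da_config()].
#' @return `data.frame` with columns `peak`, `log_odds`, `p`.
#' @export
per_sample_da <- function(mat, cell_labels, population,
                          config = da_config()) {
  if (length(cell_labels) != ncol(mat)) {
    stop("cell_labels must have one entry per cell")
  }
  in_pop <- cell_labels == population
  if (!any(in_pop)) {
    stop("population '", population, "' absent from the sample")
  }
  acc <- mat > 0
  n1 <- sum(in_pop)
  n0 <- sum(!in_pop)
  a <- Matrix::rowSums(acc[, in_pop, drop = FALSE])
  c_ <- Matrix::rowSums(acc[, !in_pop, drop = FALSE])
  keep <- which(a / n1 >= config$min_cluster_access_frac)
  p <- vapply(keep, function(i) {
    fisher_peak(a[i], n1 - a[i], c_[i], n0 - c_[i])
  }, numeric(1))
  # log odds with Haldane correction, for the direction call only
  lo <- log(((a[keep] + 0.5) / (n1 - a[keep] + 0.5)) /
              ((c_[keep] + 0.5) / (n0 - c_[keep] + 0.5)))
  data.frame(peak = rownames(mat)[keep], log_odds = lo, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-sample differential accessibility
#'
#' Runs [per_sample_da()] in every sample where the population makes up at
#' least `min_cluster_sample_frac` of the cells (4% rule), combines per-peak
#' p-values across samples with Fisher's method (requiring at least
#' `min_samples_for_combination` samples; single-sample peaks are reported
#' uncombined), and calls a direction per peak from the majority sign of the
#' per-sample log odds (ties give `"ambiguous"`).
#'
#' @param mats_per_sample Named list of peak x cell matrices sharing a union
#'   peak set (common rownames).
#' @param labels_per_sample Named list of per-cell population labels.
#' @param population Target population; an error is raised when absent from
#'   every sample.
#' @param config A [da_config()].
#' @return `data.frame` as [combine_across_samples()], plus a `direction`
#'   column (`"up"`, `"down"` or `"ambiguous"`).
#' @export
differential_accessibility <- function(mats_per_sample, labels_per_sample,
                                       population, config = da_config()) {
  present <- vapply(labels_per_sample, function(l) any(l == population),
                    logical(1))
  if (!any(present)) {
    stop("population '", population, "' absent from all samples")
  }
  included <- sample_inclusion(labels_per_sample, population,
                               config$min_cluster_sample_frac)
  if (!length(included)) {
    warning("population '", population, "' below the 4% rule in every sample")
    return(combine_across_samples(list(), character(0), as_de_config(config)))
  }
  per_sample <- lapply(included, function(s) {
    per_sample_da(mats_per_sample[[s]], labels_per_sample[[s]], population,
                  config)
  })
  names(per_sample) <- included
  out <- combine_across_samples(per_sample, included, as_de_config(config))
  lo <- matrix(NA_real_, nrow = nrow(out), ncol = length(included),
               dimnames = list(out$feature, included))
  for (s in included) {
    i <- match(per_sample[[s]]$peak, out$feature)
    lo[i, s] <- per_sample[[s]]$log_odds
  }
  n_up <- rowSums(lo > 0, na.rm = TRUE)
  n_dn <- rowSums(lo < 0, na.rm = TRUE)
  out$direction <- ifelse(n_up > n_dn, "up",
                          ifelse(n_dn > n_up, "down", "ambiguous"))
  out
}

as_de_config <- function(config) {
  de_config(min_cluster_expr_frac = config$min_cluster_access_frac,
            min_cluster_sample_frac = config$min_cluster_sample_frac,
            min_samples_for_combination = config$min_samples_for_combination,
            fdr_threshold = config$fdr_threshold)
}

#' Concordance between DA enhancers and differentially expressed genes
#'
#' Intersects differentially accessible peaks with a GeneHancer-style
#' enhancer-to-gene map to obtain the genes targeted by DA enhancers, then
#' tests the overlap between that gene set and the differentially expressed
#' genes over a gene universe with a two-sided Fisher exact test.
#'
#' @param da_peaks `data.frame` of DA peak intervals (`chrom`, `start`,
#'   `end`).
#' @param enhancer_map `data.frame` with columns `chrom`, `start`, `end`,
#'   `gene`.
#' @param deg_genes Character vector of differentially expressed genes.
#' @param gene_universe Character vector defining the universe.
#' @return List with `counts` (named: `overlap`, `da_only`, `deg_only`,
#'   `neither`), `p` and `da_enhancer_genes`.
#' @export
enhancer_concordance <- function(da_peaks, enhancer_map, deg_genes,
                                 gene_universe) {
  if (!length(gene_universe)) stop("empty gene universe")
  validate_intervals(enhancer_map, what = "enhancer")
  da_genes <- character(0)
  if (nrow(da_peaks)) {
    validate_intervals(da_peaks, what = "peak")
    hits <- GenomicRanges::findOverlaps(bed_to_granges(da_peaks),
                                        bed_to_granges(enhancer_map))
    da_genes <- unique(enhancer_map$gene[S4Vectors::subjectHits(hits)])
  }
  u <- unique(gene_universe)
  da_in <- u %in% da_genes
  deg_in <- u %in% deg_genes
  a <- sum(da_in & deg_in)
  b <- sum(da_in & !deg_in)
  c_ <- sum(!da_in & deg_in)
  d <- sum(!da_in & !deg_in)
  p <- if (a + b == 0L) 1 else fisher_peak(a, b, c_, d)
  list(counts = c(overlap = a, da_only = b, deg_only = c_, neither = d),
       p = p, da_enhancer_genes = intersect(u, da_genes))
}

#' Motif-deviation test configuration
#'
#' @param delta_z_min Minimum difference in mean deviation score between the
#'   population and the rest for a TF to be flagged (default 1).
#' @param fdr_threshold FDR threshold for flagging (default 0.05; figures in
#'   this field often display the stricter 0.01).
#' @param sample_min_frac Sample-inclusion fraction (default 0.04).
#' @param alternative `"greater"` (one-sided upregulation, default) or
#'   `"two.sided"`.
#' @return A `motif_config` list.
#' @export
motif_config <- function(delta_z_min = 1, fdr_threshold = 0.05,
                         sample_min_frac = 0.04,
                         alternative = c("greater", "two.sided")) {
  assert_number(delta_z_min, "delta_z_min", min = 0)
  assert_fraction(fdr_threshold, "fdr_threshold")
  assert_fraction(sample_min_frac, "sample_min_frac")
  structure(list(delta_z_min = delta_z_min, fdr_threshold = fdr_threshold,
                 sample_min_frac = sample_min_frac,
                 alternative = match.arg(alternative)),
            class = "motif_config")
}

#' Test TF motif deviation scores for population-specific upregulation
#'
#' Per sample, compares each transcription factor's per-cell deviation
#' scores in the population against the rest with a Wilcoxon rank-sum test
#' (one-sided, upregulation); combines p-values across samples with
#' Fisher's method under the 4% sample-inclusion rule; adjusts with BH. The
#' z-score fold change `delta_z` is the difference in mean deviation score
#' (population minus rest) pooled over the included samples, and a TF is
#' flagged when `fdr < fdr_threshold` and `delta_z >= delta_z_min`.
#'
#' @param dev_per_sample Named list of TF x cell deviation-score matrices
#'   (real-valued, may be negative).
#' @param labels_per_sample Named list of per-cell population labels.
#' @param population Target population.
#' @param config A [motif_config()].
#' @return `data.frame` with columns `tf`, `n_samples`, `combined`,
#'   `combined_p`, `fdr`, `delta_z`, `flagged`.
#' @export
motif_deviation_test <- function(dev_per_sample, labels_per_sample,
                                 population, config = motif_config()) {
  present <- vapply(labels_per_sample, function(l) any(l == population),
                    logical(1))
  if (!any(present)) {
    stop("population '", population, "' absent from all samples")
  }
  included <- sample_inclusion(labels_per_sample, population,
                               config$sample_min_frac)
  if (!length(included)) {
    stop("population '", population, "' below the sample-inclusion rule ",
         "in every sample")
  }
  per_sample <- lapply(included, function(s) {
    dev <- dev_per_sample[[s]]
    in_pop <- labels_per_sample[[s]] == population
    p <- apply(dev, 1L, function(z) {
      stats::wilcox.test(z[in_pop], z[!in_pop],
                         alternative = config$alternative,
                         exact = FALSE)$p.value
    })
    p[is.na(p)] <- 1  # fully tied scores carry no evidence
    data.frame(feature = rownames(dev), p = pmin(pmax(p, 0), 1),
               stringsAsFactors = FALSE)
  })
  names(per_sample) <- included
  comb <- combine_across_samples(
    per_sample, included,
    de_config(min_cluster_sample_frac = config$sample_min_frac))

  pop_scores <- do.call(cbind, lapply(included, function(s) {
    dev_per_sample[[s]][, labels_per_sample[[s]] == population, drop = FALSE]
  }))
  rest_scores <- do.call(cbind, lapply(included, function(s) {
    dev_per_sample[[s]][, labels_per_sample[[s]] != population, drop = FALSE]
  }))
  dz <- rowMeans(pop_scores) - rowMeans(rest_scores)
  data.frame(tf = comb$feature,
             n_samples = comb$n_samples,
             combined = comb$combined,
             combined_p = comb$combined_p,
             fdr = comb$fdr,
             delta_z = dz[comb$feature],
             flagged = comb$fdr < config$fdr_threshold &
               dz[comb$feature] >= config$delta_z_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Joint expression-correlation and motif-accessibility screen
#'
#' Selects transcription factors whose bulk expression correlates
#' (Spearman) with the abundance of a cell population of interest at
#' p < `cor_p_threshold` and whose binding-motif accessibility is
#' differentially accessible at `motif_fdr < motif_fdr_threshold`. The sign
#' of the correlation is reported, not interpreted.
#'
#' @param tf_expression TF x sample numeric matrix of bulk expression.
#' @param abundance Named numeric vector of per-sample population abundances
#'   (e.g. deconvolved mesenchymal-like cell fractions); names must match
#'   the expression columns.
#' @param motif_results `data.frame` with columns `tf` and `fdr`, e.g. from
#'   [motif_deviation_test()].
#' @param cor_p_threshold Spearman p-value threshold (default 0.05).
#' @param motif_fdr_threshold Motif FDR threshold (default 0.05).
#' @return `data.frame` with columns `tf`, `rho`, `cor_p`, `motif_fdr`,
#'   `direction` (`"correlated"`/`"anti-correlated"`), `selected`.
#' @export
joint_emt_screen <- function(tf_expression, abundance, motif_results,
                             cor_p_threshold = 0.05,
                             motif_fdr_threshold = 0.05) {
  shared <- intersect(colnames(tf_expression), names(abundance))
  if (length(shared) < 4L) {
    stop("joint screen requires >= 4 paired samples")
  }
  expr <- tf_expression[, shared, drop = FALSE]
  ab <- abundance[shared]
  ct <- lapply(seq_len(nrow(expr)), function(i) {
    suppressWarnings(stats::cor.test(expr[i, ], ab, method = "spearman"))
  })
  rho <- vapply(ct, function(x) unname(x$estimate), numeric(1))
  cp <- vapply(ct, function(x) x$p.value, numeric(1))
  mf <- motif_results$fdr[match(rownames(expr), motif_results$tf)]
  data.frame(tf = rownames(expr),
             rho = rho,
             cor_p = cp,
             motif_fdr = mf,
             direction = ifelse(rho >= 0, "correlated", "anti-correlated"),
             selected = !is.na(mf) & cp < cor_p_threshold &
               mf < motif_fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
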