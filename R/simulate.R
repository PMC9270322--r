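# Synthetic multi-omic cohort simulators with planted ground truth.
#
# Every simulator is fully deterministic given `config$seed`; each draws from
# its own derived sub-stream so the modalities can be generated independently
# yet stay mutually consistent (binding sites coincide with planted
# differentially accessible peaks, enhancers target planted population
# markers).

#' Simulation configuration
#'
#' Collects the knobs of the synthetic cohort generators. The defaults
#' describe the reference study conditions used throughout the package's
#' tests: an eight-group bulk cohort with ten samples per group and strong
#' planted markers (3 log2 units), and small single-nucleus cohorts whose
#' population proportions deliberately straddle the 3% and 4% inclusion
#' thresholds of the multi-sample statistics.
#'
#' @param seed Integer seed; fully determines every simulator's output.
#' @param n_groups Number of bulk molecular groups.
#' @param n_genes Number of genes in all expression modalities.
#' @param n_samples_per_group Bulk samples per group; also the number of
#'   samples in the single-cell and accessibility cohorts.
#' @param n_planted_markers_per_group Planted marker genes per group (bulk)
#'   and per population (single-cell); also the number of planted
#'   differentially accessible peaks per population.
#' @param marker_log2fc Planted marker effect size, log2 units.
#' @param baseline_dispersion Noise scale: sd of log2 multiplicative noise
#'   for bulk expression; negative-binomial dispersion (1/size) for counts.
#' @param n_cells_per_sample Cells per single-cell sample.
#' @param n_populations Number of cell populations.
#' @param n_peaks Number of background accessibility peaks.
#' @param genome_length Simulated genome length in bp (one chromosome).
#' @param n_tfs Number of transcription factors with loci and binding sites.
#' @param da_margin Accessibility-probability margin added to planted
#'   differentially accessible peaks in their target population.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_groups = 8L,
                              n_genes = 2000L,
                              n_samples_per_group = 10L,
                              n_planted_markers_per_group = 60L,
                              marker_log2fc = 3,
                              baseline_dispersion = 0.5,
                              n_cells_per_sample = 300L,
                              n_populations = 4L,
                              n_peaks = 400L,
                              genome_length = 2e6,
                              n_tfs = 12L,
                              da_margin = 0.3) {
  assert_count(seed, "seed", min = 0L)
  assert_count(n_groups, "n_groups")
  assert_count(n_genes, "n_genes")
  assert_count(n_samples_per_group, "n_samples_per_group")
  assert_count(n_planted_markers_per_group, "n_planted_markers_per_group")
  assert_number(marker_log2fc, "marker_log2fc")
  assert_number(baseline_dispersion, "baseline_dispersion", min = 0)
  assert_count(n_cells_per_sample, "n_cells_per_sample")
  assert_count(n_populations, "n_populations")
  assert_count(n_peaks, "n_peaks", min = 2L)
  assert_count(genome_length, "genome_length", min = 1000L)
  assert_count(n_tfs, "n_tfs", min = 2L)
  assert_number(da_margin, "da_margin", min = 0)
  if (n_planted_markers_per_group * n_groups > n_genes) {
    stop("n_planted_markers_per_group * n_groups exceeds n_genes")
  }
  structure(list(
    seed = as.integer(seed),
    n_groups = as.integer(n_groups),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    n_planted_markers_per_group = as.integer(n_planted_markers_per_group),
    marker_log2fc = as.numeric(marker_log2fc),
    baseline_dispersion = as.numeric(baseline_dispersion),
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_populations = as.integer(n_populations),
    n_peaks = as.integer(n_peaks),
    genome_length = as.numeric(genome_length),
    n_tfs = as.integer(n_tfs),
    da_margin = as.numeric(da_margin)
  ), class = "simulation_config")
}

gene_ids <- function(n) sprintf("gene%05d", seq_len(n))

#' Simulate a labeled bulk expression cohort
#'
#' Per-gene baselines are log-normal (heavy-tailed, positive); each group's
#' planted marker genes are shifted by `marker_log2fc` on the log2 scale in
#' that group's samples only; multiplicative log-normal noise is applied to
#' every matrix cell.
#'
#' @param config A [simulation_config()].
#' @return List with `expression` (genes x samples matrix), `labels` (named
#'   character vector of group labels per sample) and `truth` (list with
#'   `group_markers`, a named list of planted marker genes per group).
#' @export
simulate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(sub_seed(config$seed, "bulk"), {
    genes <- gene_ids(config$n_genes)
    groups <- sprintf("group%d", seq_len(config$n_groups))
    labels <- rep(groups, each = config$n_samples_per_group)
    samples <- sprintf("%s_s%02d", labels,
                       sequence(rep(config$n_samples_per_group,
                                    config$n_groups)))
    names(labels) <- samples

    nm <- config$n_planted_markers_per_group
    marker_idx <- sample.int(config$n_genes, nm * config$n_groups)
    group_markers <- split(genes[marker_idx],
                           rep(groups, each = nm))[groups]

    base_log2 <- log2(stats::rlnorm(config$n_genes,
                                    meanlog = log(50), sdlog = 1.2))
    log2expr <- matrix(base_log2, nrow = config$n_genes,
                       ncol = length(samples))
    for (g in seq_along(groups)) {
      rows <- match(group_markers[[g]], genes)
      cols <- which(labels == groups[g])
      log2expr[rows, cols] <- log2expr[rows, cols] + config$marker_log2fc
    }
    noise <- matrix(stats::rnorm(length(log2expr),
                                 sd = config$baseline_dispersion),
                    nrow = nrow(log2expr))
    expr <- 2^(log2expr + noise)
    dimnames(expr) <- list(genes, samples)

    list(expression = expr, labels = labels,
         truth = list(group_markers = group_markers))
  })
}

# Deterministic per-sample population compositions. The last population is
# rare with per-sample fractions cycling below 3%, between 3% and 4%, and
# above 4%, so both inclusion thresholds are exercised; the remaining mass
# is split among the other populations by a Dirichlet draw.
population_fractions <- function(n_samples, n_populations) {
  rare <- rep_len(c(0.02, 0.035, 0.05, 0.08, 0.12), n_samples)
  frac <- matrix(0, nrow = n_populations, ncol = n_samples)
  for (s in seq_len(n_samples)) {
    w <- stats::rgamma(n_populations - 1L, shape = 4)
    frac[, s] <- c(w / sum(w) * (1 - rare[s]), rare[s])
  }
  frac
}

population_labels <- function(frac, n_cells, populations) {
  counts <- floor(frac * n_cells)
  counts[which.max(counts)] <- counts[which.max(counts)] +
    (n_cells - sum(counts))
  sample(rep(populations, counts))
}

#' Simulate a multi-sample single-cell expression cohort
#'
#' Counts follow a gamma-Poisson (negative binomial) model. Each
#' population's planted marker genes have their expected expression raised
#' by `marker_log2fc` log2 units in that population. Population proportions
#' vary across samples so that the rare population falls below 3% in some
#' samples and above 4% in others.
#'
#' @param config A [simulation_config()] with `n_populations >= 2`.
#' @return List with `counts` (named list of gene x cell sparse matrices,
#'   one per sample), `labels` (named list of per-cell population labels)
#'   and `truth` (list with `population_markers`).
#' @export
simulate_sc_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_populations < 2L) {
    stop("simulate_sc_cohort requires n_populations >= 2")
  }
  plan <- plan_genome(config)
  with_seed(sub_seed(config$seed, "sc"), {
    genes <- gene_ids(config$n_genes)
    populations <- sprintf("pop%d", seq_len(config$n_populations))
    n_samples <- config$n_samples_per_group
    sample_ids <- sprintf("sample%02d", seq_len(n_samples))

    mu0 <- stats::rlnorm(config$n_genes, meanlog = log(0.3), sdlog = 1)
    size <- 1 / max(config$baseline_dispersion, 1e-8)
    frac <- population_fractions(n_samples, config$n_populations)

    marker_rows <- lapply(plan$population_markers,
                          function(g) match(g, genes))

    counts <- list()
    labels <- list()
    for (s in seq_len(n_samples)) {
      lab <- population_labels(frac[, s], config$n_cells_per_sample,
                               populations)
      mu <- matrix(mu0, nrow = config$n_genes,
                   ncol = config$n_cells_per_sample)
      for (p in seq_along(populations)) {
        cells <- which(lab == populations[p])
        if (length(cells)) {
          mu[marker_rows[[p]], cells] <-
            mu[marker_rows[[p]], cells] * 2^config$marker_log2fc
        }
      }
      depth <- stats::rlnorm(config$n_cells_per_sample, sdlog = 0.2)
      mu <- sweep(mu, 2, depth, `*`)
      y <- stats::rnbinom(length(mu), mu = mu, size = size)
      m <- Matrix::Matrix(matrix(y, nrow = config$n_genes), sparse = TRUE)
      dimnames(m) <- list(genes, sprintf("%s_cell%04d", sample_ids[s],
                                         seq_len(ncol(m))))
      counts[[sample_ids[s]]] <- m
      names(lab) <- colnames(m)
      labels[[sample_ids[s]]] <- lab
    }
    list(counts = counts, labels = labels,
         truth = list(population_markers = plan$population_markers))
  })
}

#' Simulate a multi-sample single-cell accessibility cohort
#'
#' Generates binary peak-by-cell matrices per sample over a shared peak set,
#' with per-sample jittered peak coordinates (so that peak-set union/merge is
#' exercised) and planted differentially accessible peaks whose
#' accessibility probability is raised by `da_margin` in their target
#' population.
#'
#' @param config A [simulation_config()].
#' @return List with `matrices` (named list of peak x cell sparse binary
#'   matrices), `peak_beds` (named list of per-sample peak data frames with
#'   0-based half-open coordinates), `labels` (named list of per-cell
#'   population labels) and `truth` (list with `da_peaks`, a named list of
#'   planted peak identifiers per population).
#' @export
simulate_accessibility <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  plan <- plan_genome(config)
  peaks <- plan$peaks
  with_seed(sub_seed(config$seed, "atac"), {
    populations <- sprintf("pop%d", seq_len(config$n_populations))
    n_samples <- config$n_samples_per_group
    sample_ids <- sprintf("sample%02d", seq_len(n_samples))
    n_peaks <- nrow(peaks)

    # Baseline accessible-cell fractions straddle the 30% in-cluster filter
    # so that both filtered-out and tested peaks occur in every cohort.
    p0 <- stats::runif(n_peaks, 0.2, 0.6)
    frac <- population_fractions(n_samples, config$n_populations)

    da_rows <- lapply(plan$da_peaks, function(p) match(p, peaks$name))

    matrices <- list()
    peak_beds <- list()
    labels <- list()
    for (s in seq_len(n_samples)) {
      lab <- population_labels(frac[, s], config$n_cells_per_sample,
                               populations)
      prob <- matrix(p0, nrow = n_peaks, ncol = config$n_cells_per_sample)
      for (p in seq_along(populations)) {
        cells <- which(lab == populations[p])
        if (length(cells)) {
          prob[da_rows[[p]], cells] <-
            pmin(prob[da_rows[[p]], cells] + config$da_margin, 0.95)
        }
      }
      y <- stats::rbinom(length(prob), size = 1L, prob = prob)
      m <- Matrix::Matrix(matrix(y, nrow = n_peaks), sparse = TRUE)
      dimnames(m) <- list(peaks$name, sprintf("%s_cell%04d", sample_ids[s],
                                              seq_len(ncol(m))))
      matrices[[sample_ids[s]]] <- m
      names(lab) <- colnames(m)
      labels[[sample_ids[s]]] <- lab

      jitter <- sample(-25:25, n_peaks, replace = TRUE)
      bed <- peaks
      bed$start <- pmax(0, peaks$start + jitter)
      bed$end <- pmin(config$genome_length, peaks$end + jitter)
      bed <- bed[bed$start < bed$end, , drop = FALSE]
      peak_beds[[sample_ids[s]]] <- bed
    }
    list(matrices = matrices, peak_beds = peak_beds, labels = labels,
         truth = list(da_peaks = plan$da_peaks))
  })
}

#' Simulate genome annotation with planted TF regulatory edges
#'
#' Places transcription-factor gene loci, gene loci for enhancer targets, a
#' GeneHancer-style enhancer-to-gene map, and TF binding sites. For every
#' planted regulatory edge A -> B, at least one binding site of A lies
#' within +/- 10 kbp of B's gene locus and coincides with a peak planted as
#' differentially accessible in population 1 (so the full accessibility
#' pipeline recovers the edge); decoy binding sites are placed outside all
#' +/- 10 kbp locus windows.
#'
#' @param config A [simulation_config()].
#' @return List with `tf_loci`, `gene_loci` (data frames with `gene`,
#'   `chrom`, `start`, `end`, `strand`, `tss`), `enhancer_map` (`chrom`,
#'   `start`, `end`, `gene`), `tf_sites` (`tf`, `chrom`, `start`, `end`,
#'   `site_id`), `peaks`, and `truth` (list with `planted_edges` data frame
#'   and `supporting_sites`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  plan <- plan_genome(config)
  list(tf_loci = plan$tf_loci,
       gene_loci = plan$gene_loci,
       enhancer_map = plan$enhancer_map,
       tf_sites = plan$tf_sites,
       peaks = plan$peaks,
       truth = list(planted_edges = plan$planted_edges,
                    supporting_sites = plan$supporting_sites,
                    da_peaks = plan$da_peaks,
                    population_markers = plan$population_markers))
}

# Shared coordinate and identity layout. Both the accessibility and the
# annotation simulators derive from this single deterministic plan so that
# binding sites coincide with planted DA peaks and enhancers target planted
# population markers.
plan_genome <- function(config) {
  with_seed(sub_seed(config$seed, "genome"), {
    G <- config$genome_length
    K <- config$n_populations
    genes <- gene_ids(config$n_genes)
    populations <- sprintf("pop%d", seq_len(K))
    tfs <- sprintf("TF%02d", seq_len(config$n_tfs))

    if (K * config$n_planted_markers_per_group > config$n_genes) {
      stop("population markers exceed the gene universe")
    }
    nm <- config$n_planted_markers_per_group
    marker_idx <- sample.int(config$n_genes, nm * K)
    population_markers <- split(genes[marker_idx],
                                rep(populations, each = nm))[populations]

    # TF loci: fixed 4 kb bodies on a 40 kb stride so that the +/- 10 kb
    # windows of distinct loci can never overlap (24 kb window vs 40 kb
    # stride) and decoys fit in the inter-window gaps.
    locus_w <- 4000
    stride <- 40000
    if (2000 + config$n_tfs * stride > G / 2) {
      stop("genome_length too small for n_tfs TF loci on a 40 kb stride")
    }
    tf_start <- 2000 + (seq_len(config$n_tfs) - 1L) * stride
    tf_loci <- data.frame(gene = tfs, chrom = "chr1", start = tf_start,
                          end = tf_start + locus_w, strand = "+",
                          tss = tf_start, stringsAsFactors = FALSE)

    # Annotated (non-TF) gene loci in the second half of the genome.
    n_anno <- min(config$n_genes, 100L)
    gl_w <- 3000
    gl_stride <- max(gl_w + 1000, floor((G / 2 - 2000) / n_anno))
    gl_start <- floor(G / 2) + (seq_len(n_anno) - 1L) * gl_stride
    gl_strand <- rep_len(c("+", "-"), n_anno)
    gene_loci <- data.frame(
      gene = genes[seq_len(n_anno)], chrom = "chr1", start = gl_start,
      end = gl_start + gl_w, strand = gl_strand,
      tss = ifelse(gl_strand == "+", gl_start, gl_start + gl_w),
      stringsAsFactors = FALSE)

    # Planted directed edges; the first one is supported by a site placed
    # exactly at the half-open window edge (locus start - 10000).
    n_edges <- config$n_tfs
    src <- sample(tfs, n_edges, replace = TRUE)
    tgt <- sample(tfs, n_edges, replace = TRUE)
    keep <- !duplicated(paste(src, tgt)) & src != tgt
    planted_edges <- data.frame(source = src[keep], target = tgt[keep],
                                stringsAsFactors = FALSE)

    site_w <- 200
    window <- 10000
    site_rows <- lapply(seq_len(nrow(planted_edges)), function(i) {
      b <- tf_loci[tf_loci$gene == planted_edges$target[i], ]
      lo <- max(0, b$start - window)
      hi <- b$end + window - site_w
      start <- if (i == 1L) lo else sample(seq(lo, hi), 1L)
      data.frame(tf = planted_edges$source[i], chrom = "chr1",
                 start = start, end = start + site_w,
                 site_id = sprintf("site%03d", i), stringsAsFactors = FALSE)
    })
    supporting <- do.call(rbind, site_rows)

    # Decoys: mid-gap between consecutive TF windows, never inside any
    # +/- 10 kb locus window.
    n_decoys <- config$n_tfs
    gap_anchor <- tf_start + locus_w + window + 2000
    decoys <- data.frame(
      tf = sample(tfs, n_decoys, replace = TRUE), chrom = "chr1",
      start = rep_len(gap_anchor, n_decoys),
      end = rep_len(gap_anchor, n_decoys) + site_w,
      site_id = sprintf("decoy%03d", seq_len(n_decoys)),
      stringsAsFactors = FALSE)
    tf_sites <- rbind(supporting, decoys)
    rownames(tf_sites) <- NULL

    # Background peaks plus one peak per binding site (supporting sites
    # coincide with planted DA peaks of population 1; decoy-site peaks are
    # not DA). A few oversized peaks exercise the width filter.
    widths <- round(stats::rlnorm(config$n_peaks, meanlog = log(350),
                                  sdlog = 0.3))
    widths[seq_len(min(3L, config$n_peaks))] <- 8000
    starts <- sort(sample.int(G - 10000L, config$n_peaks))
    bg <- data.frame(chrom = "chr1", start = starts,
                     end = pmin(starts + widths, G),
                     name = sprintf("peak%05d", seq_len(config$n_peaks)),
                     stringsAsFactors = FALSE)
    site_peaks <- data.frame(chrom = "chr1", start = tf_sites$start,
                             end = tf_sites$end,
                             name = paste0("pk_", tf_sites$site_id),
                             stringsAsFactors = FALSE)
    peaks <- rbind(bg, site_peaks)
    rownames(peaks) <- NULL

    n_da <- max(5L, config$n_peaks %/% (4L * K))
    da_pool <- sample(bg$name)
    da_peaks <- split(da_pool[seq_len(n_da * K)],
                      rep(populations, each = n_da))[populations]
    da_peaks[["pop1"]] <- c(da_peaks[["pop1"]],
                            paste0("pk_", supporting$site_id))

    # Enhancer map: planted DA peaks of each population target that
    # population's planted marker genes; background enhancers target
    # non-marker genes.
    enh <- list()
    for (p in seq_along(populations)) {
      pk <- peaks[match(utils::head(da_peaks[[p]], 10L), peaks$name), ]
      enh[[p]] <- data.frame(chrom = pk$chrom, start = pk$start,
                             end = pk$end,
                             gene = utils::head(population_markers[[p]],
                                                nrow(pk)),
                             stringsAsFactors = FALSE)
    }
    nonmarkers <- setdiff(genes, unlist(population_markers))
    bg_pk <- peaks[match(utils::head(setdiff(bg$name, unlist(da_peaks)),
                                     20L), peaks$name), ]
    enh_bg <- data.frame(chrom = bg_pk$chrom, start = bg_pk$start,
                         end = bg_pk$end,
                         gene = sample(nonmarkers, nrow(bg_pk)),
                         stringsAsFactors = FALSE)
    enhancer_map <- do.call(rbind, c(enh, list(enh_bg)))
    rownames(enhancer_map) <- NULL

    list(population_markers = population_markers, tf_loci = tf_loci,
         gene_loci = gene_loci, planted_edges = planted_edges,
         supporting_sites = supporting$site_id, tf_sites = tf_sites,
         peaks = peaks, da_peaks = da_peaks, enhancer_map = enhancer_map)
  })
}
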