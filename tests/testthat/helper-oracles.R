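# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately use naive, explicit computations so they stay
# independent of the implementation paths they check.

# Running-sum curve by explicit stepwise accumulation over a ranked list of
# length m with signature genes at positions `pos`.
oracle_curve <- function(pos, m) {
  n <- length(pos)
  cur <- numeric(m)
  acc <- 0
  for (j in seq_len(m)) {
    acc <- acc + if (j %in% pos) 1 / n else -1 / (m - n)
    cur[j] <- acc
  }
  cur
}

# Two-sided Fisher exact p-value by full hypergeometric enumeration of all
# tables with the observed margins; tables at least as improbable as the
# observed one are summed (R's tolerance convention).
oracle_fisher2 <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  lo <- max(0L, r1 + c1 - N)
  hi <- min(r1, c1)
  aa <- lo:hi
  probs <- exp(lchoose(c1, aa) + lchoose(N - c1, r1 - aa) - lchoose(N, r1))
  sum(probs[probs <= probs[aa == a] * (1 + 1e-7)])
}

# Union of half-open intervals by naive fixed-point pairwise merging: any
# two intervals with a nonzero per-bp intersection (strict overlap; abutting
# intervals do not intersect) are replaced by their union until no pair
# overlaps.
oracle_interval_union <- function(starts, ends) {
  s <- starts
  e <- ends
  repeat {
    merged <- FALSE
    for (i in seq_along(s)) {
      for (j in seq_along(s)) {
        if (i < j && s[i] < e[j] && s[j] < e[i]) {
          s[i] <- min(s[i], s[j])
          e[i] <- max(e[i], e[j])
          s <- s[-j]
          e <- e[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  o <- order(s)
  data.frame(start = s[o], end = e[o])
}

# A small, fast simulation configuration used by most recovery tests.
small_config <- function(seed = 7L, ...) {
  defaults <- list(seed = seed, n_groups = 3L, n_genes = 400L,
                   n_samples_per_group = 6L,
                   n_planted_markers_per_group = 30L, marker_log2fc = 3,
                   n_cells_per_sample = 200L, n_populations = 3L,
                   n_peaks = 120L, genome_length = 1e6, n_tfs = 6L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Expression profile whose ranked order places `sig_ranks` at given
# positions among m genes (all values distinct).
profile_with_ranks <- function(m) {
  v <- seq(m, 1)
  names(v) <- sprintf("g%03d", seq_len(m))
  v
}
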