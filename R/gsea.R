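# Running-sum enrichment statistic, gene-randomization permutation test and
# molecular-group decision rules.

#' Rank the genes of an expression profile
#'
#' Orders genes by decreasing expression; ties are broken lexicographically
#' by gene identifier so the ranking is deterministic across platforms.
#'
#' @param profile Named numeric vector of expression values (unique gene
#'   names).
#' @return A `ranked_genes` object: list with `genes` (ordered identifiers)
#'   and `m` (total gene count).
#' @export
rank_genes <- function(profile) {
  if (!length(profile)) stop("profile is empty")
  if (is.null(names(profile)) || anyNA(names(profile))) {
    stop("profile must be a named numeric vector")
  }
  if (anyDuplicated(names(profile))) {
    stop("duplicate gene identifiers in profile")
  }
  ord <- order(-profile, names(profile), method = "radix")
  structure(list(genes = names(profile)[ord], m = length(profile)),
            class = "ranked_genes")
}

#' Running-sum enrichment score
#'
#' Walks down the ranked gene list; at every gene in the signature the
#' statistic increases by 1/n, at every other gene it decreases by
#' 1/(m - n), where n is the signature size and m the total number of genes.
#' The enrichment score is the maximum of the running sum; the curve always
#' terminates at 0 (telescoping identity).
#'
#' @param ranked A [rank_genes()] result (or a character vector of ordered
#'   gene identifiers).
#' @param signature A `GeneSignature` or character vector of signature
#'   genes; must be a strict, non-empty subset of the ranked genes.
#' @param keep_curve Return the full running-sum curve.
#' @return List with `es` and, when requested, `curve` (length m).
#' @export
running_sum_es <- function(ranked, signature, keep_curve = TRUE) {
  genes <- if (inherits(ranked, "ranked_genes")) ranked$genes else ranked
  sig <- if (inherits(signature, "GeneSignature")) signature$genes
         else signature
  m <- length(genes)
  n <- length(sig)
  if (n == 0L) stop("empty signature")
  if (n >= m) stop("signature size must be smaller than the ranked list")
  hit <- genes %in% sig
  if (sum(hit) != n) {
    stop("signature genes absent from the ranked list; intersect first")
  }
  steps <- ifelse(hit, 1 / n, -1 / (m - n))
  curve <- cumsum(steps)
  out <- list(es = max(curve))
  if (keep_curve) out$curve <- curve
  out
}

# Enrichment score from the sorted ranks of the signature genes. The running
# sum decreases between hits, so its global maximum is attained either at a
# hit position or at position 1 (value -1/(m-n) when rank 1 is a miss).
es_from_positions <- function(pos, m, n) {
  k <- seq_len(n)
  max(max(k / n - (pos - k) / (m - n)), -1 / (m - n))
}

# Null enrichment scores for B uniform random n-subsets of an m-gene list.
# Randomizing the genes of the signature makes the hit positions a uniform
# random n-subset of 1..m, so the null depends on (m, n) only.
null_es <- function(m, n, n_perm) {
  vapply(seq_len(n_perm), function(b) {
    es_from_positions(sort.int(sample.int(m, n)), m, n)
  }, numeric(1))
}

#' Permutation p-value for a running-sum enrichment score
#'
#' Estimates significance by randomizing the genes of the signature:
#' `n_perm` uniform random n-subsets of the ranked list are scored and the
#' add-one estimator `p = (1 + #\{es_b >= es_obs\}) / (n_perm + 1)` is
#' returned.
#'
#' @inheritParams running_sum_es
#' @param n_perm Number of random signatures.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return List with `es`, `p`, `n_perm` and `curve`.
#' @export
permutation_p <- function(ranked, signature, n_perm = 1000L, seed = 1L) {
  assert_count(n_perm, "n_perm")
  obs <- running_sum_es(ranked, signature, keep_curve = TRUE)
  genes <- if (inherits(ranked, "ranked_genes")) ranked$genes else ranked
  sig <- if (inherits(signature, "GeneSignature")) signature$genes
         else signature
  m <- length(genes)
  n <- length(sig)
  null <- with_seed(seed, null_es(m, n, n_perm))
  p <- (1 + sum(null >= obs$es)) / (n_perm + 1)
  list(es = obs$es, p = p, n_perm = as.integer(n_perm), curve = obs$curve)
}

#' Normalized enrichment score
#'
#' Divides the observed enrichment score by the mean of the positive
#' permuted scores; values above 1 indicate enrichment, below 1 depletion.
#'
#' @inheritParams permutation_p
#' @return Single numeric NES.
#' @export
normalized_es <- function(ranked, signature, n_perm = 1000L, seed = 1L) {
  if (n_perm < 10L) stop("normalized_es requires n_perm >= 10")
  obs <- running_sum_es(ranked, signature, keep_curve = FALSE)
  genes <- if (inherits(ranked, "ranked_genes")) ranked$genes else ranked
  sig <- if (inherits(signature, "GeneSignature")) signature$genes
         else signature
  null <- with_seed(seed, null_es(length(genes), length(sig), n_perm))
  pos <- null[null > 0]
  if (!length(pos)) stop("no positive permuted enrichment scores")
  obs$es / mean(pos)
}

#' Classifier configuration
#'
#' @param unassigned_threshold When every signature's permutation p-value
#'   exceeds this value, no group is assigned (default 0.35).
#' @param pfb_threshold Carve-out threshold for the low-power group: when
#'   `pfb_group` is set and its p-value falls strictly below this value the
#'   profile is assigned to `pfb_group` (default 0.34).
#' @param pfb_group Optional label of the carve-out group (e.g. `"PFB"`);
#'   `NULL` disables the carve-out.
#' @param n_perm Permutations per signature (default 1000, resolving the
#'   0.34/0.35 boundary with a Monte-Carlo standard error of about 0.015).
#' @param seed Integer seed for the permutation null.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(unassigned_threshold = 0.35,
                              pfb_threshold = 0.34,
                              pfb_group = NULL,
                              n_perm = 1000L,
                              seed = 1L) {
  assert_fraction(unassigned_threshold, "unassigned_threshold")
  assert_fraction(pfb_threshold, "pfb_threshold")
  assert_count(n_perm, "n_perm")
  structure(list(unassigned_threshold = unassigned_threshold,
                 pfb_threshold = pfb_threshold,
                 pfb_group = pfb_group,
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# Decision rules given per-signature p-values and enrichment scores:
# (1) carve-out group wins when its p falls below pfb_threshold;
# (2) otherwise the minimum-p group is assigned when its p does not exceed
#     unassigned_threshold (ties by larger es, then lexicographic);
# (3) otherwise UNASSIGNED.
decide_group <- function(p, es, config) {
  stopifnot(length(p) == length(es), !is.null(names(p)))
  if (!is.null(config$pfb_group) && config$pfb_group %in% names(p) &&
      p[[config$pfb_group]] < config$pfb_threshold) {
    return(config$pfb_group)
  }
  if (min(p) <= config$unassigned_threshold) {
    cand <- names(p)[p == min(p)]
    if (length(cand) > 1L) {
      cand <- cand[es[cand] == max(es[cand])]
      cand <- sort(cand)
    }
    return(cand[1L])
  }
  "UNASSIGNED"
}

#' Classify an expression profile into a molecular group
#'
#' Ranks the profile's genes by decreasing expression, scores every
#' signature with the running-sum statistic, estimates per-signature
#' permutation p-values, and applies the decision rules: a carve-out group
#' (when configured) is assigned if its p-value is below `pfb_threshold`;
#' otherwise the smallest-p signature is assigned provided its p-value does
#' not exceed `unassigned_threshold`; otherwise the profile is left
#' `UNASSIGNED`.
#'
#' Signature genes absent from the profile are dropped (with a warning); the
#' step sizes use the post-intersection signature size. Since randomizing
#' the genes of a signature makes its null depend only on the signature
#' size, one permutation null per distinct size is shared across signatures.
#'
#' @param profile Named numeric expression vector.
#' @param signatures Named list of `GeneSignature` objects (or character
#'   vectors).
#' @param config A [classifier_config()].
#' @return List with `assigned_group` and `per_signature` (data frame of
#'   `group`, `es`, `p`, `n_used`).
#' @export
classify_profile <- function(profile, signatures, config = classifier_config()) {
  if (!length(signatures)) stop("empty signature list")
  if (is.null(names(signatures))) {
    nm <- vapply(signatures, function(s) {
      if (inherits(s, "GeneSignature")) s$group else NA_character_
    }, character(1))
    if (anyNA(nm)) stop("signatures must be named")
    names(signatures) <- nm
  }
  ranked <- rank_genes(profile)
  sig_genes <- lapply(signatures, function(s) {
    g <- if (inherits(s, "GeneSignature")) s$genes else s
    kept <- intersect(g, ranked$genes)
    if (length(kept) < length(g)) {
      warning(sprintf("%d signature gene(s) absent from the profile dropped",
                      length(g) - length(kept)))
    }
    if (!length(kept)) stop("signature has no genes in common with profile")
    kept
  })
  pos <- lapply(sig_genes, function(g) sort.int(match(g, ranked$genes)))
  sizes <- vapply(sig_genes, length, integer(1))
  es <- mapply(function(pp, n) es_from_positions(pp, ranked$m, n), pos, sizes)

  nulls <- lapply(unique(sizes), function(n) {
    with_seed(sub_seed(config$seed, paste0("null", n)),
              null_es(ranked$m, n, config$n_perm))
  })
  names(nulls) <- as.character(unique(sizes))
  p <- vapply(seq_along(sig_genes), function(i) {
    null <- nulls[[as.character(sizes[i])]]
    (1 + sum(null >= es[i])) / (config$n_perm + 1)
  }, numeric(1))
  names(p) <- names(sig_genes)
  names(es) <- names(sig_genes)

  list(assigned_group = decide_group(p, es, config),
       per_signature = data.frame(group = names(p), es = unname(es),
                                  p = unname(p), n_used = unname(sizes),
                                  row.names = NULL,
                                  stringsAsFactors = FALSE))
}

#' Classify every sample of an expression matrix
#'
#' @param expression Genes x samples matrix.
#' @param signatures Named list of signatures.
#' @param config A [classifier_config()].
#' @return `data.frame` with one row per sample: `sample`, `assigned_group`
#'   and per-signature `es_*` / `p_*` columns.
#' @export
classify_cohort <- function(expression, signatures,
                            config = classifier_config()) {
  res <- lapply(colnames(expression), function(s) {
    r <- classify_profile(expression[, s], signatures, config)
    ps <- r$per_signature
    row <- data.frame(sample = s, assigned_group = r$assigned_group,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ps))) {
      row[[paste0("es_", ps$group[i])]] <- ps$es[i]
      row[[paste0("p_", ps$group[i])]] <- ps$p[i]
    }
    row
  })
  do.call(rbind, res)
}

#' Evaluate classifier predictions against true labels
#'
#' @param predictions Character vector of assigned groups (may contain
#'   `"UNASSIGNED"`, which always counts as an error).
#' @param truth Character vector of true group labels, same length.
#' @return List with `error_rate` and `confusion` (table over
#'   groups + UNASSIGNED).
#' @export
evaluate_classifier <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth must have equal length")
  }
  lev <- sort(unique(c(predictions, truth, "UNASSIGNED")))
  confusion <- table(truth = factor(truth, lev),
                     predicted = factor(predictions, lev))
  list(error_rate = mean(predictions != truth), confusion = confusion)
}
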