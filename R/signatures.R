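# Construction of group-exclusive upregulated gene signatures from a
# labeled reference expression cohort.

#' Per-gene two-group differential expression
#'
#' Computes, for every gene, a two-sided unequal-variance (Welch) t-test on
#' log2(x + 1) expression between the samples of `group` and all other
#' samples, together with the log2 fold change (mean log2 expression in the
#' group minus mean outside).
#'
#' @param reference Genes x samples numeric expression matrix (non-negative;
#'   a +1 pseudocount is applied before log2).
#' @param labels Character vector of group labels, one per column.
#' @param group Group to contrast against the rest.
#' @return `data.frame` with columns `gene`, `log2fc`, `p`. Genes with zero
#'   variance in both groups get `p = 1` when the means agree.
#' @export
per_group_de <- function(reference, labels, group) {
  stopifnot(is.matrix(reference), length(labels) == ncol(reference))
  in_grp <- labels == group
  n1 <- sum(in_grp)
  n0 <- sum(!in_grp)
  if (n1 < 2L || n0 < 2L) {
    stop("per_group_de requires >= 2 samples inside and outside the group")
  }
  x <- log2(reference + 1)
  x1 <- x[, in_grp, drop = FALSE]
  x0 <- x[, !in_grp, drop = FALSE]
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1L)
  se2 <- v1 / n1 + v0 / n0
  lfc <- m1 - m0
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate genes: zero variance in both groups
  degen <- se2 == 0
  p[degen & lfc == 0] <- 1
  p[degen & lfc != 0] <- 1e-300
  data.frame(gene = rownames(reference), log2fc = lfc, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a group-exclusive upregulated gene signature
#'
#' A gene belongs to the signature of `group` when it passes the
#' differential-expression thresholds (`p < p_threshold` and
#' `log2fc > log2fc_threshold`) in that group and in no other group
#' (exclusivity at the threshold level). Qualifying genes are ranked by
#' ascending p-value and truncated to the top `n`; when fewer than `n`
#' qualify, all qualifying genes are returned and the shortfall is flagged.
#'
#' @param reference Genes x samples expression matrix.
#' @param labels Group label per column.
#' @param group Group whose signature to build.
#' @param n Signature size (top differentially expressed genes kept).
#' @param p_threshold P-value cut for inclusion (and for exclusivity
#'   disqualification in other groups).
#' @param log2fc_threshold Log2 fold-change cut.
#' @param de_tables Optional precomputed named list of [per_group_de()]
#'   tables (one per group), to avoid recomputation when building all
#'   signatures.
#' @return A `GeneSignature`: list with `group`, `genes` (ordered by
#'   ascending p), `n` (actual size) and `shortfall` (logical).
#' @export
build_signature <- function(reference, labels, group, n = 50L,
                            p_threshold = 0.01, log2fc_threshold = 2,
                            de_tables = NULL) {
  assert_count(n, "n")
  assert_fraction(p_threshold, "p_threshold")
  assert_number(log2fc_threshold, "log2fc_threshold", min = 0)
  groups <- unique(labels)
  if (!group %in% groups) stop("unknown group: ", group)
  if (is.null(de_tables)) {
    de_tables <- lapply(groups, function(g) per_group_de(reference, labels, g))
    names(de_tables) <- groups
  }
  passes <- vapply(de_tables, function(d) {
    d$p < p_threshold & d$log2fc > log2fc_threshold
  }, logical(nrow(de_tables[[1]])))
  own <- de_tables[[group]]
  other <- rowSums(passes[, setdiff(groups, group), drop = FALSE]) > 0
  qualify <- passes[, group] & !other
  if (!any(qualify)) {
    stop("no genes qualify for the signature of group '", group, "'")
  }
  hits <- own[qualify, , drop = FALSE]
  hits <- hits[order(hits$p, hits$gene), , drop = FALSE]
  genes <- utils::head(hits$gene, n)
  shortfall <- length(genes) < n
  if (shortfall) {
    warning(sprintf("signature for '%s' has only %d of the requested %d genes",
                    group, length(genes), n))
  }
  structure(list(group = group, genes = genes, n = length(genes),
                 shortfall = shortfall),
            class = "GeneSignature")
}

#' Build signatures for every group in a reference cohort
#'
#' @inheritParams build_signature
#' @return Named list of `GeneSignature` objects, one per group.
#' @export
build_signatures <- function(reference, labels, n = 50L, p_threshold = 0.01,
                             log2fc_threshold = 2) {
  groups <- unique(labels)
  de_tables <- lapply(groups, function(g) per_group_de(reference, labels, g))
  names(de_tables) <- groups
  sigs <- lapply(groups, function(g) {
    build_signature(reference, labels, g, n = n, p_threshold = p_threshold,
                    log2fc_threshold = log2fc_threshold,
                    de_tables = de_tables)
  })
  names(sigs) <- groups
  sigs
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d genes%s\n", x$group, x$n,
              if (isTRUE(x$shortfall)) " (shortfall)" else ""))
  cat(" ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (x$n > 8) "..." else "", "\n")
  invisible(x)
}
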