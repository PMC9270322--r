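# Directed TF -> TF regulatory network from differentially accessible
# binding sites near gene loci.

#' Assign differential-accessibility p-values to binding sites
#'
#' Gives every binding site the smallest combined p-value among the tested
#' peaks it overlaps (half-open intervals); sites overlapping no tested peak
#' get p = 1.
#'
#' @param sites `data.frame` with columns `tf`, `chrom`, `start`, `end`.
#' @param da_results `data.frame` of differential-accessibility results with
#'   a `feature` (peak name) and `combined_p` column, e.g. from
#'   [differential_accessibility()].
#' @param peaks Peak coordinate `data.frame` (`chrom`, `start`, `end`,
#'   `name`) mapping peak names to intervals.
#' @return `sites` with an added `p` column.
#' @export
annotate_sites_with_da <- function(sites, da_results, peaks) {
  validate_intervals(sites, what = "binding site")
  validate_intervals(peaks, what = "peak")
  pk <- peaks[match(da_results$feature, peaks$name), , drop = FALSE]
  keep <- !is.na(pk$start)
  pk <- pk[keep, , drop = FALSE]
  pv <- da_results$combined_p[keep]
  sites$p <- 1
  if (nrow(pk)) {
    hits <- GenomicRanges::findOverlaps(bed_to_granges(sites),
                                        bed_to_granges(pk))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    best <- tapply(pv[s], q, min)
    sites$p[as.integer(names(best))] <- as.numeric(best)
  }
  sites
}

#' Build a directed TF regulatory network from significant binding sites
#'
#' Adds a directed edge from transcription factor A to transcription factor
#' B when at least one significant (p < `p_threshold`) differentially
#' accessible binding site of A lies within the gene locus of B extended by
#' `window` bp upstream and downstream. The extended locus is half-open and
#' clipped at 0: a site starting exactly at `locus_start - window` supports
#' the edge, one bp further upstream does not. Self-loops are permitted.
#'
#' @param sites `data.frame` with columns `tf`, `chrom`, `start`, `end`,
#'   `p` (per-site differential-accessibility p-value; see
#'   [annotate_sites_with_da()]).
#' @param tf_loci `data.frame` with columns `gene` (TF name), `chrom`,
#'   `start`, `end`.
#' @param window Locus extension in bp (default 10000).
#' @param p_threshold Per-site significance cut (default 0.05, raw p-values
#'   as in the construction rule).
#' @param use_fdr Apply a BH adjustment to the site p-values and threshold
#'   the adjusted values instead (default `FALSE`).
#' @return A `tf_network`: list with `nodes` (all TFs appearing in `sites`
#'   or `tf_loci`), `edges` (`data.frame` of `source`, `target`, `n_sites`,
#'   `min_p`) and `edge_sites` (list of supporting site tables).
#' @export
build_tf_network <- function(sites, tf_loci, window = 10000,
                             p_threshold = 0.05, use_fdr = FALSE) {
  if (window < 0) stop("window must be >= 0")
  validate_intervals(sites, what = "binding site")
  validate_intervals(tf_loci, what = "TF locus")
  if (!"p" %in% names(sites)) stop("sites need a 'p' column")
  pv <- if (use_fdr) bh_fdr(sites$p) else sites$p
  sig <- sites[pv < p_threshold, , drop = FALSE]
  nodes <- sort(unique(c(sites$tf, tf_loci$gene)))
  empty <- data.frame(source = character(), target = character(),
                      n_sites = integer(), min_p = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) {
    return(structure(list(nodes = nodes, edges = empty,
                          edge_sites = list()), class = "tf_network"))
  }
  win <- data.frame(chrom = tf_loci$chrom,
                    start = pmax(0, tf_loci$start - window),
                    end = tf_loci$end + window,
                    stringsAsFactors = FALSE)
  hits <- GenomicRanges::findOverlaps(bed_to_granges(sig),
                                      bed_to_granges(win))
  if (!length(hits)) {
    return(structure(list(nodes = nodes, edges = empty,
                          edge_sites = list()), class = "tf_network"))
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  pair <- data.frame(source = sig$tf[q], target = tf_loci$gene[s],
                     p = sig$p[q], site_row = q,
                     stringsAsFactors = FALSE)
  key <- paste(pair$source, pair$target, sep = "\r")
  groups <- split(pair, key)
  edges <- do.call(rbind, lapply(groups, function(d) {
    data.frame(source = d$source[1], target = d$target[1],
               n_sites = nrow(d), min_p = min(d$p),
               stringsAsFactors = FALSE)
  }))
  edge_sites <- lapply(groups, function(d) sig[d$site_row, , drop = FALSE])
  ord <- order(edges$source, edges$target)
  edges <- edges[ord, , drop = FALSE]
  edge_sites <- edge_sites[ord]
  rownames(edges) <- NULL
  names(edge_sites) <- paste(edges$source, edges$target, sep = "->")
  structure(list(nodes = nodes, edges = edges, edge_sites = edge_sites),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("tf_network: %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}

#' Convert a TF network to an igraph graph
#'
#' @param network A `tf_network` from [build_tf_network()].
#' @return An `igraph` directed graph with `n_sites` and `min_p` edge
#'   attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "tf_network"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for as_igraph()")
  }
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}
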