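# Interval utilities: peak-set union, peak-width filtering and gene
# activity scores. All coordinates are 0-based half-open (BED convention);
# abutting intervals do not overlap.

validate_intervals <- function(df, what = "interval") {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(df))) {
    stop(what, " table must have columns chrom, start, end")
  }
  bad <- which(!(df$start >= 0 & df$start < df$end) |
                 is.na(df$start) | is.na(df$end))
  if (length(bad)) {
    stop(sprintf("malformed %s at record %d: start=%s end=%s", what, bad[1],
                 format(df$start[bad[1]]), format(df$end[bad[1]])))
  }
  invisible(df)
}

# BED (0-based half-open) <-> GRanges (1-based closed)
bed_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge per-sample peak sets into a union peak set
#'
#' Merges intersecting peaks across samples into maximal unions of
#' overlapping intervals. Intervals are half-open, so peaks that merely abut
#' (`end == start`) are not merged. Output is disjoint and sorted by
#' (chrom, start).
#'
#' @param peak_sets A single peak `data.frame` (`chrom`, `start`, `end`) or
#'   a list of them (one per sample).
#' @return `data.frame` of merged peaks with columns `chrom`, `start`,
#'   `end`, `name`.
#' @export
merge_peak_sets <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  for (i in seq_along(peak_sets)) {
    validate_intervals(peak_sets[[i]], what = paste0("peak (sample ", i, ")"))
  }
  all_peaks <- do.call(rbind, lapply(peak_sets, function(d) {
    d[, c("chrom", "start", "end")]
  }))
  gr <- GenomicRanges::reduce(bed_to_granges(all_peaks), min.gapwidth = 0L)
  gr <- GenomicRanges::sort(gr)
  out <- granges_to_bed(gr)
  out$name <- sprintf("union_peak%05d", seq_len(nrow(out)))
  out
}

#' Remove abnormally wide peaks
#'
#' Drops peaks whose width exceeds the mean peak width by more than three
#' standard deviations (mean and SD computed on the input widths). Order is
#' preserved.
#'
#' @param peaks Peak `data.frame` (`chrom`, `start`, `end`, ...), at least
#'   two rows.
#' @return The filtered `data.frame`.
#' @export
filter_peak_widths <- function(peaks) {
  validate_intervals(peaks, what = "peak")
  if (nrow(peaks) < 2L) stop("filter_peak_widths requires >= 2 peaks")
  w <- peaks$end - peaks$start
  cutoff <- mean(w) + 3 * stats::sd(w)
  peaks[w <= cutoff, , drop = FALSE]
}

#' Gene activity scores from fragments
#'
#' Counts, per gene and cell, the fragments overlapping the union of the
#' gene body and its promoter, defined as the 2 kb region upstream of the
#' TSS (strand-aware; clipped at position 0). Overlap is half-open with
#' nonzero intersection length; a fragment inside both body and promoter is
#' counted once.
#'
#' @param fragments `data.frame` with columns `chrom`, `start`, `end`,
#'   `cell` (0-based half-open coordinates).
#' @param gene_loci `data.frame` with columns `gene`, `chrom`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`; missing or other values are an error).
#' @param promoter_width Upstream promoter extent in bp (default 2000).
#' @return Sparse gene x cell matrix of fragment counts.
#' @export
gene_activity <- function(fragments, gene_loci, promoter_width = 2000) {
  validate_intervals(fragments, what = "fragment")
  validate_intervals(gene_loci, what = "gene locus")
  if (!"cell" %in% names(fragments)) stop("fragments need a 'cell' column")
  if (!all(c("gene", "strand") %in% names(gene_loci))) {
    stop("gene_loci need 'gene' and 'strand' columns")
  }
  if (anyNA(gene_loci$strand) || !all(gene_loci$strand %in% c("+", "-"))) {
    stop("every gene locus must have strand '+' or '-'")
  }
  reg_start <- ifelse(gene_loci$strand == "+",
                      pmax(0, gene_loci$start - promoter_width),
                      gene_loci$start)
  reg_end <- ifelse(gene_loci$strand == "+",
                    gene_loci$end,
                    gene_loci$end + promoter_width)
  regions <- GenomicRanges::GRanges(
    gene_loci$chrom, IRanges::IRanges(start = reg_start + 1, end = reg_end))
  frags <- bed_to_granges(fragments)
  hits <- GenomicRanges::findOverlaps(frags, regions)
  cells <- sort(unique(fragments$cell))
  i <- S4Vectors::subjectHits(hits)
  j <- match(fragments$cell[S4Vectors::queryHits(hits)], cells)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(nrow(gene_loci), length(cells)),
                       dimnames = list(gene_loci$gene, cells))
}
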