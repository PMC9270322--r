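# Readers and writers for the plain-text formats the package consumes and
# produces: expression TSV, GMT gene sets, BED intervals, MatrixMarket count
# bundles, enhancer maps and ground-truth JSON.

#' Read a genes-by-samples expression table
#'
#' @param path Path to a TSV with gene identifiers in the first column and
#'   one column per sample (header row).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a genes-by-samples expression table
#'
#' @param expr Numeric matrix with gene rownames.
#' @param path Output TSV path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then the member genes, all
#' tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors, or a list of
#'   [GeneSignature][build_signature] objects.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "pfomics") {
  if (length(sets) && inherits(sets[[1]], "GeneSignature")) {
    nm <- vapply(sets, function(s) s$group, character(1))
    sets <- lapply(sets, function(s) s$genes)
    names(sets) <- nm
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named")
  }
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read BED intervals
#'
#' Reads the first three (or, when present, six) columns of a BED file into
#' a data frame with 0-based half-open coordinates.
#'
#' @param path Path to a BED file (no header).
#' @return `data.frame` with columns `chrom`, `start`, `end` and, when the
#'   file has them, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  df
}

#' Write intervals as BED
#'
#' @param intervals `data.frame` with at least `chrom`, `start`, `end`;
#'   `name`, `score`, `strand` are written when present.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a sparse count matrix as a MatrixMarket bundle
#'
#' Writes `matrix.mtx`, `features.tsv` (row identifiers) and `barcodes.tsv`
#' (column identifiers) under `dir`, the layout emitted by the common
#' single-cell quantification pipelines.
#'
#' @param counts Matrix (dense or `Matrix` sparse) with dimnames.
#' @param dir Output directory, created if needed.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket count bundle
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return Sparse `dgCMatrix` with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

#' Write simulation ground truth as JSON
#'
#' @param truth Ground-truth list as returned by the simulators.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read simulation ground truth from JSON
#'
#' @param path Path written by [write_ground_truth()].
#' @return List.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a TF network edge list as TSV
#'
#' @param network `tf_network` object from [build_tf_network()].
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "tf_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
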