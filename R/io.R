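# coerce any matrix-like input to a general CsparseMatrix
as_sparse <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(m, "CsparseMatrix")
  if (!methods::is(m, "dMatrix")) m <- m * 1   # pattern/logical -> numeric
  methods::as(m, "generalMatrix")
}

#' Annotated count matrix constructor
#'
#' Thin container pairing a sparse non-negative integer feature x cell matrix
#' with per-cell metadata. Feature and cell ids must be unique and metadata
#' rows align 1:1 with matrix columns.
#'
#' @param counts sparse (or dense) matrix, features in rows, cells in columns,
#'   with dimnames set.
#' @param metadata data.frame with one row per cell; a `cell` column is
#'   added/validated against colnames(counts).
#' @return object of class `annotated_counts` (list: counts, metadata).
#' @export
annotated_counts <- function(counts, metadata = NULL) {
  counts <- as_sparse(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature and cell ids as dimnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (any(counts@x < 0)) stop("negative counts")
  if (is.null(metadata))
    metadata <- data.frame(cell = colnames(counts), stringsAsFactors = FALSE)
  if (is.null(metadata$cell)) metadata$cell <- colnames(counts)
  if (nrow(metadata) != ncol(counts) || !all(metadata$cell == colnames(counts)))
    stop("metadata rows must align 1:1 with cells")
  structure(list(counts = counts, metadata = metadata),
            class = "annotated_counts")
}

#' Write an MTX bundle (matrix.mtx + features.tsv + barcodes.tsv + metadata.tsv)
#'
#' MatrixMarket indices are 1-based at the file boundary. Writing is
#' deterministic: entries are emitted in column-major order.
#'
#' @param x `annotated_counts`.
#' @param dir output directory (created if missing).
#' @export
write_mtx_bundle <- function(x, dir) {
  stopifnot(inherits(x, "annotated_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an MTX bundle written by [write_mtx_bundle()] (or cellranger-style)
#'
#' @param dir directory containing matrix.mtx, features.tsv, barcodes.tsv and
#'   optionally metadata.tsv.
#' @return `annotated_counts`; round-trips with [write_mtx_bundle()] exactly.
#' @export
read_mtx_bundle <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  bcs <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feats, bcs))
    if (!file.exists(f)) stop("missing file: ", f)
  # Pre-validate indices so a malformed 0 index is reported with its line.
  lines <- readLines(mtx)
  body_at <- which(!startsWith(lines, "%"))[1]  # header size line
  if (length(lines) > body_at) {
    entries <- lines[(body_at + 1L):length(lines)]
    ij <- vapply(strsplit(entries, "[ \t]+"),
                 function(p) as.numeric(p[1:2]), numeric(2))
    bad <- which(ij[1, ] < 1 | ij[2, ] < 1)
    if (length(bad))
      stop("matrix.mtx: 1-based index < 1 at line ", body_at + bad[1],
           ": '", entries[bad[1]], "'")
  }
  m <- as_sparse(Matrix::readMM(mtx))
  feat_ids <- readLines(feats)
  cell_ids <- readLines(bcs)
  if (nrow(m) != length(feat_ids))
    stop("dimension mismatch: matrix.mtx has ", nrow(m), " rows but ",
         feats, " lists ", length(feat_ids), " features")
  if (ncol(m) != length(cell_ids))
    stop("dimension mismatch: matrix.mtx has ", ncol(m), " cols but ",
         bcs, " lists ", length(cell_ids), " barcodes")
  dimnames(m) <- list(feat_ids, cell_ids)
  meta_file <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_file))
    utils::read.table(meta_file, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, colClasses = "character")
  else NULL
  annotated_counts(m, meta)
}

#' Genomic interval set (BED 0-based half-open)
#'
#' @param chrom,start,end,id,strand,score interval columns; `start` 0-based,
#'   `end` exclusive, strand in +/-/. .
#' @return data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL, strand = ".",
                              score = NULL) {
  n <- length(start)
  if (is.null(id)) id <- sprintf("iv%d", seq_len(n))
  df <- data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
                   end = as.integer(end), id = id,
                   score = if (is.null(score)) 0 else score,
                   strand = rep_len(strand, n), stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$start >= df$end)) stop("start >= end (intervals are half-open, need start < end)")
  if (anyDuplicated(df$id)) stop("duplicate interval ids")
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Read a BED file (BED4/BED6) as 0-based half-open intervals
#' @param path BED file path.
#' @return `genomic_intervals`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  genomic_intervals(chrom = df$chrom, start = df$start, end = df$end,
                    id = if (ncol(df) >= 4) df[[4]] else NULL,
                    score = if (ncol(df) >= 5) df[[5]] else NULL,
                    strand = if (ncol(df) >= 6) df[[6]] else ".")
}

#' Write a BED6 file, preserving 0-based half-open coordinates exactly
#' @param x `genomic_intervals`. @param path output path.
#' @param sort sort by (chrom, start, end) before writing (stable).
#' @export
write_bed <- function(x, path, sort = FALSE) {
  stopifnot(inherits(x, "genomic_intervals"))
  if (sort) x <- x[order(x$chrom, x$start, x$end), ]
  utils::write.table(x[, c("chrom", "start", "end", "id", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Promoter windows around TSS anchors
#'
#' Builds symmetric windows of `flank` bp on each side of 1-bp TSS anchors
#' (clipped at 0). The flank is symmetric, so strand only matters upstream of
#' this function, in the choice of the anchor coordinate.
#'
#' @param tss `genomic_intervals` of 1-bp anchors.
#' @param flank half-window in bp (default 200).
#' @return `genomic_intervals` of promoters, ids prefixed `prom_`.
#' @export
make_promoters <- function(tss, flank = 200L) {
  stopifnot(inherits(tss, "genomic_intervals"))
  if (any(tss$end - tss$start != 1L)) stop("tss must be 1-bp anchors")
  genomic_intervals(chrom = tss$chrom,
                    start = pmax(0L, tss$start - as.integer(flank)),
                    end = tss$start + as.integer(flank),
                    id = paste0("prom_", tss$id),
                    strand = tss$strand)
}
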