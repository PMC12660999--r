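#' Aggregate single-cell counts into pseudobulk groups
#'
#' Sums counts of every feature over the cells of each group. Groups are the
#' interaction of the annotation columns in `keys` (e.g. `"cluster"`, or
#' `c("cluster","condition","replicate")` for a supermatrix of
#' pseudo-samples). Empty groups are dropped with a warning; total count mass
#' is conserved.
#'
#' @param counts features x cells matrix (sparse ok).
#' @param annotation data.frame with one row per cell.
#' @param keys character vector of annotation column names.
#' @return list: `counts` (features x groups dense matrix), `groups`
#'   (data.frame of group key values and cell counts `n_cells`).
#' @export
pb_aggregate <- function(counts, annotation, keys = "cluster") {
  stopifnot(ncol(counts) == nrow(annotation), all(keys %in% names(annotation)))
  for (k in keys) if (anyNA(annotation[[k]]))
    stop("annotation column '", k, "' has missing values")
  key_vals <- do.call(paste, c(annotation[keys], sep = "."))
  f <- factor(key_vals, levels = unique(key_vals[order(key_vals)]))
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  agg <- as.matrix(counts %*% ind)
  colnames(agg) <- levels(f)
  n_cells <- as.integer(table(f))
  groups <- unique(data.frame(annotation[keys], stringsAsFactors = FALSE))
  groups <- groups[match(levels(f), do.call(paste, c(groups, sep = "."))), , drop = FALSE]
  groups$group <- levels(f)
  groups$n_cells <- n_cells
  rownames(groups) <- NULL
  list(counts = agg, groups = groups)
}

#' Expressing-cell fractions inside and outside each group
#'
#' For feature i and group j, `a[i,j]` is the fraction of cells of group j
#' with count >= `min_counts_per_cell`, and `b[i,j]` the same fraction over
#' all cells NOT in group j. Needs at least two groups (b is undefined
#' otherwise).
#'
#' @inheritParams pb_aggregate
#' @param min_counts_per_cell detection threshold per cell (default 1).
#' @return list of matrices `a` and `b` (features x groups, in [0,1]).
#' @export
expressing_fractions <- function(counts, annotation, keys = "cluster",
                                 min_counts_per_cell = 1) {
  stopifnot(min_counts_per_cell >= 1)
  key_vals <- do.call(paste, c(annotation[keys], sep = "."))
  f <- factor(key_vals, levels = unique(key_vals[order(key_vals)]))
  if (nlevels(f) < 2) stop("expressing_fractions needs >= 2 groups (b undefined)")
  detected <- counts >= min_counts_per_cell
  detected <- methods::as(detected, "dMatrix") * 1
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  n_in <- as.integer(table(f))
  expr_in <- as.matrix(detected %*% ind)
  colnames(expr_in) <- levels(f)
  total_expr <- Matrix::rowSums(detected)
  a <- sweep(expr_in, 2, n_in, "/")
  b <- sweep(-expr_in + total_expr, 2, length(f) - n_in, "/")
  list(a = a, b = b)
}

#' Cell-weight matrix from expressing fractions
#'
#' The expression-constraint weight \eqn{w_{ij} = 1 - \exp(-a_{ij}/b_{ij})}
#' down-weights features whose counts are scattered thinly across a large
#' group relative to the rest of the dataset. Limit conventions: `a = 0`
#' gives `w = 0`; `a > 0, b = 0` gives `w = 1` (the continuous completion).
#'
#' @param a,b matrices in [0,1] from [expressing_fractions()].
#' @return weight matrix `w` in [0,1], same shape.
#' @export
cell_weights <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)), all(a >= 0 & a <= 1), all(b >= 0 & b <= 1))
  w <- 1 - exp(-a / b)
  w[a == 0] <- 0
  w[a > 0 & b == 0] <- 1
  w
}

#' Filter a pseudobulk by total counts and expressing-cell support
#'
#' Removes features with fewer than `min_counts` summed counts over the whole
#' dataset, and zeroes entries (i, j) supported by fewer than `min_cells`
#' expressing cells of group j (entry zeroing, not feature removal: the
#' per-group support rule retrieves expression information per group).
#'
#' @param pb result of [pb_aggregate()].
#' @param expr_cells features x groups matrix of expressing-cell counts
#'   (a * group size), or NULL to skip the per-entry rule.
#' @param min_counts minimum dataset-total counts per feature (default 30).
#' @param min_cells minimum expressing cells per retained entry (default 3).
#' @return `pb` with filtered `counts` and a `support_mask` matrix.
#' @export
pb_filter <- function(pb, expr_cells = NULL, min_counts = 30, min_cells = 3) {
  keep <- rowSums(pb$counts) >= min_counts
  if (!any(keep)) stop("all features removed by min_counts filter")
  counts <- pb$counts[keep, , drop = FALSE]
  mask <- NULL
  if (!is.null(expr_cells)) {
    mask <- expr_cells[keep, , drop = FALSE] >= min_cells
  }
  out <- pb
  out$counts <- counts
  out$support_mask <- mask
  out
}

#' Median-of-ratios size factors
#'
#' Per-column median of count ratios to the geometric-mean reference, over
#' features positive in every column (the standard median-of-ratios
#' convention). If no feature is positive everywhere, falls back to
#' column-sum scaling (normalised to geometric mean 1) with a message.
#'
#' @param counts features x groups matrix.
#' @return positive numeric vector of size factors, one per column.
#' @export
size_factors_median_ratio <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    message("no feature positive in all columns; falling back to column-sum scaling")
    cs <- colSums(counts)
    return(cs / exp(mean(log(cs))))
  }
  logs <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logs)
  sf <- apply(logs, 2, function(col) exp(stats::median(col - ref)))
  unname(sf)
}

#' Normalise by size factors, then apply cell weights
#'
#' Order is fixed: counts are divided by their column's size factor first and
#' the result is multiplied elementwise by the weight matrix; entries failing
#' the support mask (if given) are zeroed.
#'
#' @param counts features x groups matrix.
#' @param size_factors positive per-column factors.
#' @param w weight matrix in [0,1], same shape as counts.
#' @param support_mask optional logical matrix; FALSE entries are zeroed.
#' @return normalised weighted matrix.
#' @export
normalize_and_weight <- function(counts, size_factors, w, support_mask = NULL) {
  stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0),
            all(dim(w) == dim(counts)))
  out <- sweep(as.matrix(counts), 2, size_factors, "/") * w
  if (!is.null(support_mask)) out <- out * support_mask
  out
}

#' Weighted, normalised pseudobulk
#'
#' End-to-end constructor: aggregate, expressing fractions, cell weights,
#' filters, median-of-ratios size factors, then normalise and weight (in that
#' order: counts are divided by their group's size factor first, then
#' multiplied elementwise by w; entries failing the min_cells support rule
#' are zeroed).
#'
#' @inheritParams pb_aggregate
#' @param min_counts,min_cells filter thresholds (defaults 30 and 3).
#' @param min_counts_per_cell per-cell detection threshold for a/b.
#' @return object of class `weighted_pseudobulk`: list with `counts`, `a`,
#'   `b`, `w`, `size_factors`, `normalized`, `normalized_weighted`, `groups`.
#' @export
weighted_pseudobulk <- function(counts, annotation, keys = "cluster",
                                min_counts = 30, min_cells = 3,
                                min_counts_per_cell = 1) {
  pb <- pb_aggregate(counts, annotation, keys)
  fr <- expressing_fractions(counts, annotation, keys, min_counts_per_cell)
  expr_cells <- sweep(fr$a, 2, pb$groups$n_cells, "*")
  keep <- rowSums(pb$counts) >= min_counts
  if (!any(keep)) stop("all features removed by min_counts filter")
  cts <- pb$counts[keep, , drop = FALSE]
  a <- fr$a[keep, , drop = FALSE]
  b <- fr$b[keep, , drop = FALSE]
  w <- cell_weights(a, b)
  support <- expr_cells[keep, , drop = FALSE] >= min_cells
  sf <- size_factors_median_ratio(cts)
  normalized <- sweep(cts, 2, sf, "/")
  nw <- normalized * w * support
  structure(list(counts = cts, a = a, b = b, w = w, size_factors = sf,
                 normalized = normalized, normalized_weighted = nw,
                 groups = pb$groups),
            class = "weighted_pseudobulk")
}

#' @exportS3Method base::print
print.weighted_pseudobulk <- function(x, ...) {
  cat("weighted_pseudobulk:", nrow(x$counts), "features x",
      ncol(x$counts), "groups\n")
  cat("groups:", paste(utils::head(colnames(x$counts), 8), collapse = ", "),
      if (ncol(x$counts) > 8) "..." else "", "\n")
  invisible(x)
}
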