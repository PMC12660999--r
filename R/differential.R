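# Moment estimator of NB dispersion from normalised counts, shrunk toward a
# gamma-family mean-dispersion trend (disp ~ a0 + a1/mean), as a lightweight
# stand-in for full maximum-likelihood dispersion machinery.
estimate_dispersions <- function(norm_counts, shrink_weight = 0.75,
                                 min_disp = 1e-8) {
  mu <- rowMeans(norm_counts)
  v <- apply(norm_counts, 1, stats::var)
  raw <- pmax((v - mu) / mu^2, min_disp)
  usable <- mu > 0 & is.finite(raw)
  trend <- rep(stats::median(raw[usable]), length(raw))
  if (sum(usable) >= 10) {
    df <- data.frame(d = raw[usable], im = 1 / mu[usable])
    fit <- try(suppressWarnings(
      stats::glm(d ~ im, data = df,
                 family = stats::Gamma(link = "identity"),
                 start = c(stats::median(df$d), 1))), silent = TRUE)
    if (!inherits(fit, "try-error") && all(is.finite(stats::coef(fit)))) {
      co <- stats::coef(fit)
      tr <- co[1] + co[2] / mu
      tr <- pmax(tr, min_disp)
      trend[is.finite(tr)] <- tr[is.finite(tr)]
    }
  }
  disp <- (1 - shrink_weight) * raw + shrink_weight * trend
  pmax(disp, min_disp)
}

# One-gene NB log-link GLM by IRLS with fixed dispersion and offsets.
# Returns coefficients, their covariance, and convergence flag.
nb_irls <- function(y, X, offset, dispersion, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y / exp(offset)) + 1e-8)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    Wd <- mu / (1 + dispersion * mu)        # NB2 working weights, log link
    z <- eta - offset + (y - mu) / mu
    XtW <- t(X * Wd)
    H <- XtW %*% X
    Hc <- try(chol(H + diag(1e-10, ncol(X))), silent = TRUE)
    if (inherits(Hc, "try-error")) return(NULL)
    beta_new <- drop(backsolve(Hc, forwardsolve(t(Hc), XtW %*% z)))
    if (any(!is.finite(beta_new))) return(NULL)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      conv <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + offset
  mu <- exp(pmin(pmax(eta, -30), 30))
  Wd <- mu / (1 + dispersion * mu)
  H <- t(X * Wd) %*% X
  cov <- try(solve(H + diag(1e-10, ncol(X))), silent = TRUE)
  if (inherits(cov, "try-error")) return(NULL)
  list(beta = beta, cov = cov, converged = conv)
}

#' Pseudobulk negative-binomial Wald differential test
#'
#' Simplified NB differential pipeline for replicated pseudobulk columns:
#' genes with fewer than `min_detected` non-zero samples are removed;
#' median-of-ratios size factors; per-gene moment dispersions shrunk toward
#' a fitted mean-dispersion trend (weighted average, weight configurable);
#' NB log-link GLM by IRLS; Wald z test on the condition coefficient (log2
#' fold change of `level_test` over `level_reference`); BH adjustment.
#' Null calibration of the default shrinkage weight is shown in the methods
#' vignette.
#'
#' @param counts genes x samples integer matrix (pseudobulk supermatrix
#'   columns for one contrast).
#' @param condition factor/character per sample.
#' @param level_test,level_reference condition levels to contrast.
#' @param min_detected minimum samples with >= 1 count to keep a gene
#'   (default 2).
#' @param shrink_weight dispersion shrinkage weight toward the trend
#'   (default 0.75).
#' @param alpha DEG padj threshold (default 0.05).
#' @return data.frame of class `dge_result`: gene, baseMean, log2FC, SE,
#'   stat, p, padj, deg.
#' @export
nb_wald_test <- function(counts, condition, level_test, level_reference,
                         min_detected = 2, shrink_weight = 0.75, alpha = 0.05) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(counts))
  use <- condition %in% c(level_test, level_reference)
  counts <- counts[, use, drop = FALSE]
  condition <- condition[use]
  if (sum(condition == level_test) < 2 || sum(condition == level_reference) < 2)
    stop("need >= 2 replicate columns per level")
  keep <- rowSums(counts >= 1) >= min_detected
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) stop("no genes pass the detection filter")

  sf <- size_factors_median_ratio(counts)
  norm <- sweep(counts, 2, sf, "/")
  disp <- estimate_dispersions(norm, shrink_weight)
  X <- cbind(1, as.numeric(condition == level_test))
  offset <- log(sf)

  fit_one <- function(i) {
    f <- nb_irls(counts[i, ], X, offset, disp[i])
    if (is.null(f) || !f$converged)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    se <- sqrt(f$cov[2, 2])
    stat <- f$beta[2] / se
    p <- 2 * stats::pnorm(-abs(stat))
    c(f$beta[2] / log(2), se / log(2), stat, p)
  }
  res <- t(vapply(seq_len(nrow(counts)), fit_one, numeric(4)))
  n_fail <- sum(is.na(res[, 4]))
  if (n_fail) message(n_fail, " genes did not converge; statistics set NA")
  out <- data.frame(gene = rownames(counts), baseMean = rowMeans(norm),
                    log2FC = res[, 1], SE = res[, 2], stat = res[, 3],
                    p = res[, 4],
                    padj = stats::p.adjust(res[, 4], method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$deg <- !is.na(out$padj) & out$padj < alpha
  class(out) <- c("dge_result", "data.frame")
  out
}

#' Contrast columns for one cell type versus the stem-cell origin
#'
#' Selects from a pseudobulk supermatrix the pseudo-sample columns of
#' `type_x` and of `origin`, using the replicate key as replicates.
#'
#' @param groups data.frame of pseudo-sample metadata (from
#'   [pb_aggregate()]; needs `cluster` and a replicate column).
#' @param type_x cell type to test. @param origin reference type.
#' @param replicate_col replicate column name (default "replicate").
#' @return list of class `contrast_spec`: `columns` (indices), `condition`
#'   (per selected column), `level_test`, `level_reference`.
#' @export
build_one_vs_neoblast <- function(groups, type_x, origin,
                                  replicate_col = "replicate") {
  stopifnot(replicate_col %in% names(groups))
  if (!type_x %in% groups$cluster) stop("cell type not present: ", type_x)
  if (!origin %in% groups$cluster) stop("origin type not present: ", origin)
  if (type_x == origin) stop("empty contrast: test level equals reference")
  sel <- which(groups$cluster %in% c(type_x, origin))
  cond <- groups$cluster[sel]
  if (sum(cond == type_x) < 2 || sum(cond == origin) < 2)
    stop("need >= 2 replicate columns per level")
  structure(list(columns = sel, condition = cond, level_test = type_x,
                 level_reference = origin), class = "contrast_spec")
}

#' One-vs-rest contrast by aggregating all other cells as "else"
#'
#' Re-aggregates the count matrix labelling every cell not of `type_x` as
#' "else", keeping the replicate structure, and returns the contrast.
#'
#' @param counts features x cells matrix.
#' @param annotation cell metadata with `cluster` and `replicate` columns.
#' @param type_x cell type of interest.
#' @return list: `counts` (features x pseudo-samples), `condition`,
#'   `level_test` = type_x, `level_reference` = "else".
#' @export
build_one_vs_rest <- function(counts, annotation, type_x) {
  if (!type_x %in% annotation$cluster) stop("cell type not present: ", type_x)
  ann <- annotation
  ann$side <- ifelse(ann$cluster == type_x, type_x, "else")
  keys <- intersect(c("side", "replicate"), names(ann))
  pb <- pb_aggregate(counts, ann, keys)
  structure(list(counts = pb$counts, condition = pb$groups$side,
                 level_test = type_x, level_reference = "else",
                 groups = pb$groups), class = "contrast_spec")
}

#' Random half-split of cells into two pseudoreplicates per group
#'
#' @param annotation cell metadata with a `cluster` column.
#' @param seed RNG seed.
#' @return character vector ("pr1"/"pr2") aligned with annotation rows;
#'   within each cluster the two halves differ in size by at most one cell.
#' @export
pseudoreplicate_split <- function(annotation, seed = 1L) {
  set.seed(seed)
  out <- character(nrow(annotation))
  for (cl in unique(annotation$cluster)) {
    idx <- which(annotation$cluster == cl)
    n <- length(idx)
    half <- sample(idx, n %/% 2)
    out[idx] <- "pr1"
    out[half] <- "pr2"
  }
  out
}
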