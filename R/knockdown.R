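#' Per-cell gene-set score
#'
#' For each cell: mean normalised expression over the gene set minus the
#' mean over a random subsample of `subsample_frac` of all genes; the
#' resulting per-cell values are z-normalised across cells (configurable).
#' Normalised expression defaults to log1p of counts-per-10k.
#'
#' @param counts genes x cells matrix.
#' @param gene_set character vector of gene ids.
#' @param subsample_frac fraction of genes in the random reference set
#'   (default 0.05).
#' @param seed RNG seed for the subsample.
#' @param normalise "z" (default) or "none" for the across-cell step.
#' @param expr optional pre-normalised genes x cells matrix; if NULL,
#'   log1p(10^4 * count / colsum) is used.
#' @return numeric vector of per-cell scores (named by cell).
#' @export
gene_score <- function(counts, gene_set, subsample_frac = 0.05, seed = 1L,
                       normalise = c("z", "none"), expr = NULL) {
  normalise <- match.arg(normalise)
  if (is.null(expr)) {
    cs <- Matrix::colSums(counts)
    cs[cs == 0] <- 1
    expr <- log1p(Matrix::t(Matrix::t(counts) / cs) * 1e4)
  }
  gene_set <- intersect(gene_set, rownames(expr))
  if (!length(gene_set)) stop("gene_set has no genes in the matrix")
  set.seed(seed)
  n_ref <- max(1L, ceiling(subsample_frac * nrow(expr)))
  ref <- sample(rownames(expr), n_ref)
  score <- Matrix::colMeans(expr[gene_set, , drop = FALSE]) -
    Matrix::colMeans(expr[ref, , drop = FALSE])
  score <- as.numeric(score)
  names(score) <- colnames(expr)
  if (normalise == "z" && stats::sd(score) > 0)
    score <- (score - mean(score)) / stats::sd(score)
  score
}

#' Chi-squared abundance test with adjusted standardized residuals
#'
#' Omnibus Pearson chi-squared on a cluster x condition cell-count table,
#' plus per-cell adjusted standardized residuals
#' r_ij = (O - E) / sqrt(E (1 - row_i/N) (1 - col_j/N)), approximately
#' standard normal under independence. Stars: |r| > 1.96 "*" (p < 0.05),
#' |r| > 2.58 "**" (p < 0.01).
#'
#' @param tab cluster x condition matrix/table of cell counts.
#' @return list of class `abundance_chisq`: `statistic`, `df`, `p`,
#'   `observed`, `expected`, `residuals`, `stars`.
#' @export
abundance_chisq <- function(tab) {
  O <- as.matrix(tab)
  N <- sum(O)
  rs <- rowSums(O); cs <- colSums(O)
  E <- outer(rs, cs) / N
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  denom <- sqrt(E * outer(1 - rs / N, 1 - cs / N))
  r <- (O - E) / denom
  stars <- matrix("", nrow(O), ncol(O), dimnames = dimnames(O))
  stars[abs(r) > 1.96] <- "*"
  stars[abs(r) > 2.58] <- "**"
  structure(list(statistic = stat, df = df, p = p, observed = O,
                 expected = E, residuals = r, stars = stars),
            class = "abundance_chisq")
}

#' Overlap partition of two DEG sets with union percentages
#'
#' Partitions two sets into exclusive and shared parts and reports each
#' part's percentage of the union, rounded to the nearest integer.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param names_ab labels for the two sets.
#' @return data.frame: part, n, percent.
#' @export
deg_overlap <- function(set_a, set_b, names_ab = c("A", "B")) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  only_a <- setdiff(set_a, set_b)
  only_b <- setdiff(set_b, set_a)
  un <- length(union(set_a, set_b))
  n <- c(length(only_a), length(only_b), length(shared))
  data.frame(part = c(paste0(names_ab[1], "_only"),
                      paste0(names_ab[2], "_only"), "shared"),
             n = n,
             percent = if (un > 0) round(100 * n / un) else rep(0, 3),
             stringsAsFactors = FALSE)
}

#' Interaction scores of a TF's edges grouped by DEG status
#'
#' Extracts the TF's edges from an interaction network, groups the targets
#' by their DEG label, and tests (one-sided rank-sum, alternative "greater")
#' whether labelled targets have higher interaction scores than the rest.
#'
#' @param net `interaction_network`.
#' @param tf TF id.
#' @param deg_sets named list of character vectors (e.g. downregulated per
#'   set); targets in none of the sets form the reference group.
#' @return list: `table` (target, score, group), `summaries` (per-group
#'   median/mean/n), `p` (named vector, one per set; NA if a set is empty
#'   on the network).
#' @export
score_vs_deg <- function(net, tf, deg_sets) {
  edges <- net[net$tf == tf, , drop = FALSE]
  grp <- rep("none", nrow(edges))
  for (nm in names(deg_sets)) grp[edges$target %in% deg_sets[[nm]]] <- nm
  tab <- data.frame(target = edges$target, score = edges$score, group = grp,
                    stringsAsFactors = FALSE)
  summaries <- do.call(rbind, lapply(split(tab$score, tab$group), function(x)
    data.frame(n = length(x), median = stats::median(x), mean = mean(x))))
  summaries$group <- rownames(summaries)
  p <- vapply(names(deg_sets), function(nm) {
    x <- tab$score[tab$group == nm]
    y <- tab$score[tab$group == "none"]
    if (!length(x) || !length(y)) return(NA_real_)
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  }, 0)
  list(table = tab, summaries = summaries, p = p)
}

#' Logistic regression of DEG detection on interaction score
#'
#' Fits deg_flag ~ score with a binomial logit GLM (IRLS) and reports the
#' slope, its SE and Wald p. Complete or quasi-complete separation is
#' detected (fitted probabilities collapsing to 0/1) and flagged.
#'
#' @param deg_flag logical vector.
#' @param score numeric vector, same length.
#' @return list: `coefficient`, `SE`, `z`, `p`, `separation` (logical).
#' @export
detection_logistic <- function(deg_flag, score) {
  stopifnot(length(deg_flag) == length(score))
  fit <- suppressWarnings(stats::glm(deg_flag ~ score, family = stats::binomial()))
  co <- summary(fit)$coefficients
  eps <- 1e-8
  separation <- any(fit$fitted.values > 1 - eps) && any(fit$fitted.values < eps) &&
    all(fit$fitted.values[deg_flag] > 1 - eps | fit$fitted.values[deg_flag] < eps)
  separation <- separation || !fit$converged || abs(co["score", 1]) > 20
  list(coefficient = co["score", 1], SE = co["score", 2],
       z = co["score", 3], p = co["score", 4], separation = separation)
}

#' Exclusive intersection partition of several sets (up-set table)
#'
#' Counts, for every non-empty membership pattern over the named sets, the
#' elements belonging to exactly that pattern. The per-set sums of exclusive
#' parts recover the set sizes.
#'
#' @param deg_sets named list of character vectors.
#' @return data.frame: one column per set (logical), `n` (exclusive count),
#'   sorted by n descending.
#' @export
upset_partition <- function(deg_sets) {
  stopifnot(length(deg_sets) >= 1, !is.null(names(deg_sets)))
  universe <- unique(unlist(deg_sets))
  memb <- vapply(deg_sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(deg_sets)))
  pat <- apply(memb, 1, paste, collapse = "")
  tab <- table(pat)
  pats <- names(tab)
  flags <- t(vapply(pats, function(p) as.logical(memb[match(p, pat), ]),
                    logical(length(deg_sets))))
  out <- data.frame(flags)
  names(out) <- names(deg_sets)
  out$n <- as.integer(tab)
  out <- out[order(-out$n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
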