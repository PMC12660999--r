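#' Filter features by coefficient of variation
#'
#' Keeps rows whose sd/mean exceeds `cv_min` (rows with non-positive mean are
#' dropped: CV is undefined there).
#'
#' @param mat features x groups matrix.
#' @param cv_min CV threshold (default 1.25).
#' @return row-subset of `mat`.
#' @export
filter_by_cv <- function(mat, cv_min = 1.25) {
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  keep <- m > 0 & (s / m) > cv_min
  mat[keep, , drop = FALSE]
}

#' Scale-free topology fit scan over soft powers
#'
#' For each power beta, the adjacency is |cor|^beta and the connectivity of
#' feature i is the row sum minus 1 (the self term). The scale-free fit is
#' the R^2 of the regression of log10 frequency on log10 mean connectivity
#' over connectivity bins. The chosen power is the smallest beta whose R^2
#' reaches `r2_target`, otherwise the argmax of R^2.
#'
#' @param cor_abs absolute correlation matrix (features x features).
#' @param powers integer powers to scan (default 1:20).
#' @param r2_target target fit (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return list: `table` (data.frame power, r2, mean_k), `beta` chosen power.
#' @export
soft_power_scan <- function(cor_abs, powers = 1:20, r2_target = 0.8,
                            n_bins = 10) {
  stopifnot(isSymmetric(unname(cor_abs)))
  res <- lapply(powers, function(p) {
    adj <- cor_abs^p
    k <- rowSums(adj) - 1
    r2 <- scale_free_fit(k, n_bins)
    data.frame(power = p, r2 = r2, mean_k = mean(k))
  })
  tab <- do.call(rbind, res)
  hit <- which(!is.na(tab$r2) & tab$r2 >= r2_target)
  beta <- if (length(hit)) tab$power[hit[1]]
  else if (all(is.na(tab$r2))) NA_integer_
  else tab$power[which.max(tab$r2)]
  list(table = tab, beta = beta)
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & !is.na(pk) & dk > 0 & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij = sum_{u != i,j} a_iu a_uj and unit diagonal. The adjacency diagonal
#' is ignored (treated as 0 for L and k).
#'
#' @param adjacency symmetric matrix in [0,1].
#' @return symmetric TOM matrix in [0,1], unit diagonal.
#' @export
tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a))) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must be in [0,1]")
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tm <- (L + a) / denom
  diag(tm) <- 1
  dimnames(tm) <- dimnames(adjacency)
  tm
}

#' Detect modules by hierarchical clustering of 1 - TOM
#'
#' Average (or Ward) linkage tree on the TOM dissimilarity, cut by a
#' simplified dynamic branch acceptance: starting at the root, a branch is
#' split while both of its children hold at least `min_module_size` leaves;
#' when only one child is large enough, the small side's leaves become
#' unassigned and descent continues into the large child; a branch whose
#' children are both too small is accepted as a module. Deterministic and
#' invariant to feature order.
#'
#' After branch acceptance, leftover features are reattached to the accepted
#' module with the highest mean TOM to its members, provided that mean
#' reaches `reattach_frac` of the module's internal mean TOM (a medoid-style
#' rescue of near-module leaves; disable with `reattach = FALSE`).
#'
#' @param tom_mat TOM matrix.
#' @param min_module_size minimum module size (default 50).
#' @param linkage "average" or "ward.D2".
#' @param reattach rescue unassigned features into their nearest module.
#' @param reattach_frac fraction of a module's internal mean TOM a leftover
#'   must reach to join it (default 0.5).
#' @return list of class `module_assignment`: `module` (named character;
#'   NA = unassigned), `tree` (hclust), `sizes`.
#' @export
detect_modules <- function(tom_mat, min_module_size = 50,
                           linkage = c("average", "ward.D2"),
                           reattach = TRUE, reattach_frac = 0.5) {
  linkage <- match.arg(linkage)
  n <- nrow(tom_mat)
  ids <- rownames(tom_mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- stats::as.dist(1 - tom_mat)
  tree <- stats::hclust(d, method = linkage)
  tree$labels <- ids

  # leaves under each merge node
  leaves_of <- vector("list", nrow(tree$merge))
  node_leaves <- function(node) {
    if (node < 0) return(-node)
    leaves_of[[node]]
  }
  for (i in seq_len(nrow(tree$merge))) {
    leaves_of[[i]] <- c(node_leaves(tree$merge[i, 1]),
                        node_leaves(tree$merge[i, 2]))
  }
  module <- rep(NA_character_, n)
  counter <- 0L
  accept <- function(node_idx) {
    counter <<- counter + 1L
    module[leaves_of[[node_idx]]] <<- sprintf("module_%02d", counter)
  }
  descend <- function(node_idx) {
    ch <- tree$merge[node_idx, ]
    sizes <- vapply(ch, function(x) if (x < 0) 1L else length(leaves_of[[x]]), 0L)
    big <- sizes >= min_module_size
    if (all(big)) {
      descend(ch[1]); descend(ch[2])
    } else if (any(big)) {
      descend(ch[which(big)])       # small side stays unassigned
    } else {
      if (sum(sizes) >= min_module_size) accept(node_idx)
      # else: leaves stay unassigned
    }
  }
  if (n >= min_module_size) {
    root <- nrow(tree$merge)
    ch <- tree$merge[root, ]
    sizes <- vapply(ch, function(x) if (x < 0) 1L else length(leaves_of[[x]]), 0L)
    if (all(sizes >= min_module_size)) {
      descend(root)
    } else if (any(sizes >= min_module_size)) {
      descend(ch[which(sizes >= min_module_size)])
    } else {
      accept(root)
    }
  } else {
    warning("no module of min size possible: n < min_module_size")
  }
  names(module) <- ids
  if (all(is.na(module)))
    warning("no module of minimum size found at any height; all unassigned")
  if (reattach && any(is.na(module)) && !all(is.na(module))) {
    mods <- sort(unique(module[!is.na(module)]))
    tm <- as.matrix(tom_mat)
    internal <- vapply(mods, function(m) {
      idx <- which(module == m)
      s <- tm[idx, idx, drop = FALSE]
      mean(s[upper.tri(s)])
    }, 0)
    for (i in which(is.na(module))) {
      fit <- vapply(mods, function(m)
        mean(tm[i, which(module == m)]), 0)
      best <- which.max(fit)
      if (fit[best] >= reattach_frac * internal[best])
        module[i] <- mods[best]
    }
  }
  structure(list(module = module, tree = tree,
                 sizes = table(module, useNA = "no")),
            class = "module_assignment")
}

#' Average and relative per-group profiles of modules
#'
#' The average profile of a module is the mean over its member features of
#' the supplied matrix; the relative profile divides each group's value by
#' the sum over groups (rows sum to 1 when the total is positive).
#'
#' @param assignment `module_assignment` (or named character vector).
#' @param mat features x groups matrix (e.g. normalised weighted pseudobulk).
#' @return list: `average` and `relative` (modules x groups matrices).
#' @export
module_profiles <- function(assignment, mat) {
  mod <- if (inherits(assignment, "module_assignment")) assignment$module else assignment
  mod <- mod[!is.na(mod)]
  mod <- mod[names(mod) %in% rownames(mat)]
  mods <- sort(unique(mod))
  avg <- t(vapply(mods, function(m) {
    colMeans(mat[names(mod)[mod == m], , drop = FALSE])
  }, numeric(ncol(mat))))
  rownames(avg) <- mods
  tot <- rowSums(avg)
  rel <- avg / ifelse(tot > 0, tot, 1)
  list(average = avg, relative = rel)
}

#' Tau specificity index
#'
#' \eqn{\tau = \sum_i (1 - x_i / \max_j x_j) / (n - 1)} over a non-negative
#' profile with positive maximum: 0 for a uniform profile, 1 for a one-hot
#' profile.
#'
#' @param profile non-negative numeric vector (or a features x groups matrix,
#'   applied row-wise).
#' @return tau in [0,1] (vector for matrix input).
#' @export
tau <- function(profile) {
  tau1 <- function(x) {
    if (any(x < 0)) stop("tau requires a non-negative profile")
    mx <- max(x)
    if (mx <= 0) return(NA_real_)
    sum(1 - x / mx) / (length(x) - 1)
  }
  if (is.matrix(profile)) apply(profile, 1, tau1) else tau1(profile)
}

#' Classify modules as specific ("s") or mixed ("m") and order them
#'
#' For each module, the per-group distribution of its member features' upper
#' quartiles (type-7 interpolation) is computed; groups exceeding
#' mean + 1.5 sd of that distribution are outlier (peak) groups. Exactly one
#' outlier gives class "s"; zero or two-plus give "m" (the "s" label requires
#' positive evidence of a single peak). Modules are renamed
#' `<class><prefix><##>` ordered by the position of their peak group in the
#' group ordering, ties broken by module size (larger first).
#'
#' @param assignment `module_assignment`.
#' @param mat features x groups matrix used for classification.
#' @param prefix one-letter data prefix for display ids ("E" expression,
#'   "O" open-chromatin).
#' @return data.frame: module (original id), class, peak_group, n_features,
#'   display_id; plus `renamed` named vector feature -> display module id.
#' @export
classify_modules <- function(assignment, mat, prefix = "E") {
  mod <- assignment$module
  mod <- mod[!is.na(mod)]
  mods <- sort(unique(mod))
  groups <- colnames(mat)
  rows <- lapply(mods, function(m) {
    members <- names(mod)[mod == m]
    if (length(members) < 4)
      message("module ", m, " has <4 members; quartiles use interpolation")
    uq <- apply(mat[members, , drop = FALSE], 2, stats::quantile,
                probs = 0.75, type = 7)
    thr <- mean(uq) + 1.5 * stats::sd(uq)
    outliers <- which(uq > thr)
    avg <- colMeans(mat[members, , drop = FALSE])
    data.frame(module = m,
               class = if (length(outliers) == 1) "s" else "m",
               peak_group = groups[which.max(avg)],
               peak_index = which.max(avg),
               n_features = length(members),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$peak_index, -tab$n_features)
  tab <- tab[ord, ]
  # number within each class by peak-group order
  tab$display_id <- NA_character_
  for (cl in c("s", "m")) {
    sel <- tab$class == cl
    tab$display_id[sel] <- sprintf("%s%s%02d", cl, prefix, seq_len(sum(sel)))
  }
  rownames(tab) <- NULL
  renamed <- setNames(tab$display_id[match(mod, tab$module)], names(mod))
  attr(tab, "renamed") <- renamed
  tab
}

#' TF-to-module connectivity
#'
#' Pearson correlation of each TF's per-group profile with each module's
#' average profile (kME-style connectivity at the module level). Constant
#' profiles give NA.
#'
#' @param tf_mat TFs x groups matrix.
#' @param module_avg modules x groups matrix (from [module_profiles()]).
#' @return TFs x modules correlation matrix in [-1,1].
#' @export
tf_connectivity <- function(tf_mat, module_avg) {
  stopifnot(ncol(tf_mat) == ncol(module_avg))
  out <- suppressWarnings(stats::cor(t(tf_mat), t(module_avg)))
  dimnames(out) <- list(rownames(tf_mat), rownames(module_avg))
  out
}
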