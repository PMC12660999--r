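gini <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2 || sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Prune a TOM into a gene graph at the most even-component threshold
#'
#' For each candidate threshold t, edges with TOM >= t are kept and the graph
#' is scored by count x (1 - Gini) over the sizes of its connected components
#' with at least 2 nodes, favouring many evenly-sized components. The
#' highest-scoring threshold wins (ties to the larger t). Isolated nodes are
#' dropped from the returned graph.
#'
#' @param tom_mat TOM matrix.
#' @param thresholds candidate thresholds (default seq(0.05, 0.95, 0.05)).
#' @return list: `threshold`, `graph` (igraph), `scores` (data.frame).
#' @export
prune_tom_graph <- function(tom_mat, thresholds = seq(0.05, 0.95, by = 0.05)) {
  m <- as.matrix(tom_mat)
  diag(m) <- 0
  score_one <- function(t) {
    adj <- m >= t
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$csize >= 2]
    if (!length(sizes)) return(c(n_comp = 0, score = 0))
    c(n_comp = length(sizes), score = length(sizes) * (1 - gini(sizes)))
  }
  sc <- t(vapply(thresholds, score_one, c(n_comp = 0, score = 0)))
  scores <- data.frame(threshold = thresholds, n_components = sc[, 1],
                       score = sc[, 2])
  if (all(scores$score == 0))
    warning("no threshold yields >= 2 non-trivial components")
  best <- max(scores$score)
  t_star <- max(scores$threshold[scores$score == best])   # ties -> larger t
  g <- igraph::graph_from_adjacency_matrix(m * (m >= t_star),
                                           mode = "undirected", weighted = TRUE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  list(threshold = t_star, graph = g, scores = scores)
}

#' Size-normalised cross-connections between modules
#'
#' For every gene x of module M, its direct neighbours are counted per
#' module and divided by |M| (the size of x's own module), then summed over
#' the genes of M. The resulting module x module matrix is read as an
#' upper-triangle weighted graph (entry [i, j], i < j in module order).
#'
#' @param graph igraph gene graph (vertex names = feature ids).
#' @param assignment named character vector feature -> module (NA ignored).
#' @return list: `matrix` (module x module), `graph` (igraph, upper-mode).
#' @export
cross_connections <- function(graph, assignment) {
  mod <- assignment[!is.na(assignment)]
  mods <- sort(unique(mod))
  sizes <- table(factor(mod, mods))
  vs <- intersect(igraph::V(graph)$name, names(mod))
  cc <- matrix(0, length(mods), length(mods), dimnames = list(mods, mods))
  for (v in vs) {
    m_v <- mod[[v]]
    nb <- igraph::neighbors(graph, v)$name
    nb <- nb[nb %in% names(mod)]
    if (!length(nb)) next
    tab <- table(factor(mod[nb], mods)) / sizes[[m_v]]
    cc[m_v, ] <- cc[m_v, ] + as.numeric(tab)
  }
  diag(cc) <- 0
  g <- igraph::graph_from_adjacency_matrix(cc, mode = "upper", weighted = TRUE,
                                           diag = FALSE)
  list(matrix = cc, graph = g)
}

#' Module-module adjacency from profile correlation
#'
#' Pearson correlation between module profile vectors (rows of
#' `profile_matrix`); edges kept where r >= `threshold`.
#'
#' @param profile_matrix modules x variables matrix (motif enrichment,
#'   functional enrichment or TF connectivity profiles).
#' @param threshold minimum correlation for an edge (default 0.5).
#' @return list: `cor` (module x module), `graph` (igraph).
#' @export
correlation_layer <- function(profile_matrix, threshold = 0.5) {
  cc <- suppressWarnings(stats::cor(t(profile_matrix)))
  cc[is.na(cc)] <- 0
  adj <- (cc >= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(cor = cc, graph = g)
}

#' Consensus merge of module-wise similarity layers
#'
#' Keeps the module-module edges present in at least `min_support` of the
#' given layers; the retained edge weight is its support count and per-layer
#' presence flags are kept as edge attributes.
#'
#' @param layers named list of igraph graphs over the same module ids.
#' @param min_support minimum number of layers (default 2).
#' @return igraph graph with `weight` (support) and one logical attribute
#'   per layer.
#' @export
consensus_merge <- function(layers, min_support = 2) {
  if (is.null(names(layers)))
    names(layers) <- paste0("layer", seq_along(layers))
  all_nodes <- sort(unique(unlist(lapply(layers, function(g) igraph::V(g)$name))))
  edge_key <- function(g) {
    if (igraph::ecount(g) == 0) return(character())
    e <- igraph::as_edgelist(g)
    apply(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])), 1, paste,
          collapse = "\r")
  }
  keys <- lapply(layers, edge_key)
  all_keys <- sort(unique(unlist(keys)))
  support <- sapply(all_keys, function(k)
    sum(vapply(keys, function(x) k %in% x, FALSE)))
  keep <- all_keys[support >= min_support]
  el <- do.call(rbind, strsplit(keep, "\r", fixed = TRUE))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (length(keep)) {
    g <- igraph::add_edges(g, t(matrix(match(el, all_nodes), ncol = 2)))
    igraph::E(g)$weight <- unname(support[keep])
    for (ln in names(layers))
      g <- igraph::set_edge_attr(g, ln, value = keep %in% keys[[ln]])
  }
  g
}

#' Weighted label-propagation communities (seeded, deterministic)
#'
#' @param graph igraph graph with edge `weight` (e.g. consensus support).
#' @param seed RNG seed fixing the label-propagation order.
#' @return named integer vector of community labels.
#' @export
communities_label_propagation <- function(graph, seed = 1L) {
  set.seed(seed)
  w <- igraph::E(graph)$weight
  cl <- igraph::cluster_label_prop(graph, weights = w)
  stats::setNames(igraph::membership(cl), igraph::V(graph)$name)
}

#' Ensemble co-occurrence tree of groups
#'
#' Repeatedly subsamples features, clusters the groups by average linkage on
#' Pearson-correlation distance, cuts the tree at each of the given heights,
#' and counts how often each pair of groups lands in the same cluster. The
#' co-clustering frequency matrix (in [0,1], unit diagonal) is turned into a
#' consensus dendrogram by average linkage on 1 - frequency.
#'
#' @param mat features x groups matrix.
#' @param heights dendrogram cut heights (default c(0.75, 0.9)).
#' @param n iterations (default 1000).
#' @param subsample_frac fraction of features per iteration (default 0.05).
#' @param seed RNG seed.
#' @return list of class `cooccurrence_tree`: `frequency` (group x group),
#'   `tree` (hclust), `newick` (character).
#' @export
ensemble_cooccurrence_tree <- function(mat, heights = c(0.75, 0.9), n = 1000,
                                       subsample_frac = 0.05, seed = 1L) {
  n_feat <- nrow(mat)
  k <- ceiling(subsample_frac * n_feat)
  if (k < 3) stop("subsample would hold < 3 features; raise subsample_frac")
  groups <- colnames(mat)
  G <- length(groups)
  set.seed(seed)
  freq <- matrix(0, G, G, dimnames = list(groups, groups))
  n_cuts <- 0L
  for (it in seq_len(n)) {
    rows <- sample.int(n_feat, k)
    cc <- suppressWarnings(stats::cor(mat[rows, , drop = FALSE]))
    cc[is.na(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    for (h in heights) {
      lab <- stats::cutree(hc, h = h)
      same <- outer(lab, lab, "==") * 1
      freq <- freq + same
      n_cuts <- n_cuts + 1L
    }
  }
  freq <- freq / n_cuts
  diag(freq) <- 1
  tree <- stats::hclust(stats::as.dist(1 - freq), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(tree))
  structure(list(frequency = freq, tree = tree, newick = nwk),
            class = "cooccurrence_tree")
}
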