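#' Distance-decayed TF binding scores from motif-bearing OCRs
#'
#' For TF t and gene g, sums the accessibility (in a chosen cell type) of
#' every OCR carrying one of t's motifs within `window` bp of g's TSS,
#' decayed exponentially with distance:
#' B_tg = sum_o acc(o) * exp(-|d(o, g)| / lambda). B is 0 when no
#' motif-bearing OCR is within range. TFs without motif annotation get a
#' zero row (logged via message).
#'
#' @param motif_hits data.frame (region_id, motif_id); OCR hits only are
#'   used.
#' @param ocr_accessibility named numeric vector: per-OCR accessibility in
#'   the cell type of interest (e.g. a normalised pseudobulk column).
#' @param ocr_gene_map data.frame (ocr, gene, distance) from
#'   [nearest_tss()].
#' @param tf2motif named character vector TF -> motif id.
#' @param genes gene universe for columns (default: genes in the map).
#' @param window max |distance| in bp (default 1e5).
#' @param lambda decay length in bp (default 2.5e4).
#' @return TFs x genes matrix of non-negative binding scores.
#' @export
weighted_binding <- function(motif_hits, ocr_accessibility, ocr_gene_map,
                             tf2motif, genes = NULL,
                             window = 1e5, lambda = 2.5e4) {
  if (is.null(genes)) genes <- sort(unique(ocr_gene_map$gene))
  tfs <- names(tf2motif)
  B <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  map <- ocr_gene_map[abs(ocr_gene_map$distance) <= window &
                        ocr_gene_map$gene %in% genes, , drop = FALSE]
  map$acc <- ocr_accessibility[map$ocr]
  map$decay <- exp(-abs(map$distance) / lambda)
  for (t in tfs) {
    motif <- tf2motif[[t]]
    if (is.na(motif) || !motif %in% motif_hits$motif_id) {
      message("TF ", t, " has no motif annotation or hits; zero binding row")
      next
    }
    hit_ocrs <- unique(motif_hits$region_id[motif_hits$motif_id == motif])
    sub <- map[map$ocr %in% hit_ocrs & !is.na(map$acc), , drop = FALSE]
    if (!nrow(sub)) next
    contrib <- tapply(sub$acc * sub$decay, factor(sub$gene, genes), sum,
                      default = 0)
    B[t, ] <- as.numeric(contrib)
  }
  B
}

scale01 <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Additive TF-target interaction scores
#'
#' Every TF-gene pair is scored as the mean of four min-max-scaled rank
#' components over the whole network: rank of the TF's expression, rank of
#' the target's expression, rank of the binding score B_tg, and rank of the
#' TF's activity (its mean binding over all genes). Scores lie in [0,1];
#' self-edges are allowed but flagged.
#'
#' @param binding TFs x genes matrix from [weighted_binding()].
#' @param expr named numeric vector of gene expression in the cell type
#'   (must cover TFs' gene ids via `tf_gene`).
#' @param tf_gene named character vector TF -> its own gene id (for TF
#'   expression lookup and self-edge flagging).
#' @return data.frame of class `interaction_network`: tf, target, score,
#'   and the four scaled components.
#' @export
interaction_scores <- function(binding, expr, tf_gene) {
  tfs <- rownames(binding); genes <- colnames(binding)
  stopifnot(all(tfs %in% names(tf_gene)), all(genes %in% names(expr)))
  tf_expr <- expr[tf_gene[tfs]]
  activity <- rowMeans(binding)
  # components constant per TF or per gene, expanded over the pair grid
  s_tf_expr <- scale01(rank(tf_expr))
  s_tg_expr <- scale01(rank(expr[genes]))
  s_activity <- scale01(rank(activity))
  s_binding_m <- matrix(scale01(rank(binding)), nrow(binding))
  net <- data.frame(
    tf = rep(tfs, times = length(genes)),
    target = rep(genes, each = length(tfs)),
    score = NA_real_,
    tf_expr = rep(unname(s_tf_expr), times = length(genes)),
    target_expr = rep(unname(s_tg_expr), each = length(tfs)),
    binding = as.numeric(s_binding_m),
    tf_activity = rep(unname(s_activity), times = length(genes)),
    stringsAsFactors = FALSE)
  net$score <- (net$tf_expr + net$target_expr + net$binding + net$tf_activity) / 4
  net$self_edge <- unname(tf_gene[net$tf]) == net$target
  class(net) <- c("interaction_network", "data.frame")
  net
}

#' Prune an interaction network to its high-scoring edges
#'
#' Keeps edges with score strictly above `min_score` and removes genes left
#' without neighbours (isolates never enter the graph).
#'
#' @param net `interaction_network`.
#' @param min_score threshold (default 0.8; strict ">").
#' @return directed igraph with edge attribute `score`.
#' @export
prune_network <- function(net, min_score = 0.8) {
  keep <- net[net$score > min_score, , drop = FALSE]
  if (!nrow(keep)) {
    warning("no interaction above score ", min_score, "; empty graph")
    return(igraph::make_empty_graph(directed = TRUE))
  }
  igraph::graph_from_data_frame(keep[, c("tf", "target", "score")],
                                directed = TRUE)
}

#' Degree and centrality metrics of a pruned network
#'
#' In/out degrees by edge counting; relative outdegree defaults to
#' outdegree / (indegree + outdegree) with the literal variant
#' indegree / (indegree + outdegree) behind `variant = "literal"`;
#' centrality is PageRank on edge scores, out-centrality the same on the
#' reversed graph; `active_tfs` counts genes with outdegree > 0.
#'
#' @param graph igraph from [prune_network()].
#' @param variant "outdegree" (default) or "literal".
#' @return list: `table` (data.frame gene, indegree, outdegree,
#'   relative_outdegree, centrality, out_centrality), `active_tfs`.
#' @export
network_metrics <- function(graph, variant = c("outdegree", "literal")) {
  variant <- match.arg(variant)
  if (igraph::vcount(graph) == 0)
    return(list(table = data.frame(gene = character(), indegree = integer(),
                                   outdegree = integer(),
                                   relative_outdegree = numeric(),
                                   centrality = numeric(),
                                   out_centrality = numeric()),
                active_tfs = 0L))
  indeg <- igraph::degree(graph, mode = "in")
  outdeg <- igraph::degree(graph, mode = "out")
  tot <- indeg + outdeg
  rel <- ifelse(tot > 0,
                if (variant == "outdegree") outdeg / tot else indeg / tot, 0)
  w <- igraph::E(graph)$score
  centr <- igraph::page_rank(graph, weights = w)$vector
  out_centr <- igraph::page_rank(igraph::reverse_edges(graph), weights = w)$vector
  tab <- data.frame(gene = igraph::V(graph)$name, indegree = indeg,
                    outdegree = outdeg, relative_outdegree = rel,
                    centrality = centr, out_centrality = out_centr,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, active_tfs = sum(outdeg > 0))
}

#' Correlation and Ward tree of per-fate TF centrality profiles
#'
#' @param centrality_by_fate TFs x fates matrix of centrality values.
#' @return list: `cor` (fate x fate Pearson), `tree` (hclust, ward.D2 on
#'   1 - cor).
#' @export
centrality_similarity <- function(centrality_by_fate) {
  cc <- suppressWarnings(stats::cor(centrality_by_fate))
  cc[is.na(cc)] <- 0
  tree <- stats::hclust(stats::as.dist(1 - cc), method = "ward.D2")
  list(cor = cc, tree = tree)
}

#' Influence of TFs on an origin-to-fate transition
#'
#' Restricts the fate network to its `top_edges` highest-scoring edges whose
#' targets are significantly upregulated in fate vs origin (padj below
#' `p_threshold`, log2FC > 0), accumulates per TF
#' G_t = sum over those targets of score * log2FC, and mixes it 50/50 with
#' the TF's own expression change:
#' influence = 0.5 * scale01(max(0, log2FC_tf)) + 0.5 * scale01(G_t).
#'
#' @param net_fate `interaction_network` of the fate.
#' @param dge data.frame from [nb_wald_test()] (gene, log2FC, padj).
#' @param tf_gene named character vector TF -> gene id (for the TF's own
#'   log2FC lookup).
#' @param top_edges edge budget (default 250000).
#' @param p_threshold DEG padj threshold (default 0.05).
#' @return data.frame: tf, expr_change, target_support, influence (in
#'   [0,1]), sorted by influence.
#' @export
influence_scores <- function(net_fate, dge, tf_gene, top_edges = 250000,
                             p_threshold = 0.05) {
  up <- dge$gene[!is.na(dge$padj) & dge$padj < p_threshold & dge$log2FC > 0]
  tfs <- sort(unique(net_fate$tf))
  if (!length(up)) {
    warning("no upregulated DEGs; influence all zero")
    return(data.frame(tf = tfs, expr_change = 0, target_support = 0,
                      influence = 0))
  }
  ord <- order(net_fate$score, decreasing = TRUE)
  budget <- ord[seq_len(min(top_edges, length(ord)))]
  sub <- net_fate[budget, , drop = FALSE]
  sub <- sub[sub$target %in% up, , drop = FALSE]
  lfc <- stats::setNames(dge$log2FC, dge$gene)
  G <- vapply(tfs, function(t) {
    rows <- sub$tf == t
    if (!any(rows)) return(0)
    sum(sub$score[rows] * lfc[sub$target[rows]])
  }, 0)
  dE <- vapply(tfs, function(t) {
    g <- tf_gene[[t]]
    v <- lfc[g]
    if (is.na(v)) 0 else max(0, v)
  }, 0)
  out <- data.frame(tf = tfs, expr_change = unname(dE),
                    target_support = unname(G),
                    influence = 0.5 * scale01(dE) + 0.5 * scale01(G),
                    stringsAsFactors = FALSE)
  out[order(-out$influence), ]
}

#' Clusters of co-influential TFs across fates
#'
#' Ward tree on 1 - Pearson correlation of TF influence profiles, cut at
#' height `cut`. Within each cluster, TFs are ranked by correlation to the
#' cluster's mean profile and the top `top_n` reported.
#'
#' @param influence_mat TFs x fates influence matrix.
#' @param cut tree cut height (default 0.7).
#' @param top_n TFs reported per cluster (default 5).
#' @return list: `clusters` (named integer vector), `top` (list of character
#'   vectors per cluster).
#' @export
coinfluence_clusters <- function(influence_mat, cut = 0.7, top_n = 5) {
  if (nrow(influence_mat) == 1) {
    cl <- stats::setNames(1L, rownames(influence_mat))
    return(list(clusters = cl, top = list(`1` = rownames(influence_mat))))
  }
  cc <- suppressWarnings(stats::cor(t(influence_mat)))
  cc[is.na(cc)] <- 0
  tree <- stats::hclust(stats::as.dist(1 - cc), method = "ward.D2")
  cl <- stats::cutree(tree, h = cut)
  top <- lapply(sort(unique(cl)), function(k) {
    members <- names(cl)[cl == k]
    if (length(members) == 1) return(members)
    centre <- colMeans(influence_mat[members, , drop = FALSE])
    r <- apply(influence_mat[members, , drop = FALSE], 1, function(x)
      suppressWarnings(stats::cor(x, centre)))
    r[is.na(r)] <- -Inf
    utils::head(members[order(-r)], top_n)
  })
  names(top) <- as.character(sort(unique(cl)))
  list(clusters = cl, top = top)
}

#' Top targets of a TF (upper score quantile, ties kept)
#'
#' @param net `interaction_network`.
#' @param tf TF id.
#' @param quantile score quantile cutoff (default 0.95, i.e. top 5%).
#' @return data.frame of the TF's edges at or above the cutoff, sorted by
#'   score.
#' @export
top_targets <- function(net, tf, quantile = 0.95) {
  edges <- net[net$tf == tf, , drop = FALSE]
  if (!nrow(edges)) return(edges)
  cut <- stats::quantile(edges$score, quantile, type = 7)
  out <- edges[edges$score >= cut, , drop = FALSE]
  out[order(-out$score), ]
}
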