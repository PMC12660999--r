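#' Upper-tail hypergeometric enrichment of terms in a foreground set
#'
#' For each term, tests whether the foreground regions/genes carry more hits
#' than expected from the pooled universe (foreground + background;
#' foreground and background must be disjoint, as when the background is
#' "everything not in the queried set"). p = P[X >= fg_hits] with
#' X ~ Hypergeom(N = fg_total + bg_total, K = total hits of the term,
#' n = fg_total). q is Benjamini-Hochberg over terms within the call.
#'
#' @param fg_ids foreground ids. @param bg_ids background ids (disjoint).
#' @param hit_table data.frame with columns `region_id` (or `gene_id`) and
#'   `motif_id` (or `term`); one row per (unit, term) hit.
#' @param id_col,term_col column names in `hit_table`.
#' @param q_threshold significance threshold on q (default 0.1).
#' @return data.frame: term, fg_hits, fg_total, bg_hits, bg_total, fold, p,
#'   q, significant.
#' @export
hypergeometric_enrichment <- function(fg_ids, bg_ids, hit_table,
                                      id_col = "region_id",
                                      term_col = "motif_id",
                                      q_threshold = 0.1) {
  if (length(intersect(fg_ids, bg_ids)))
    stop("foreground and background must be disjoint")
  terms <- sort(unique(hit_table[[term_col]]))
  fg_total <- length(fg_ids)
  bg_total <- length(bg_ids)
  rows <- lapply(terms, function(tm) {
    hit_ids <- unique(hit_table[[id_col]][hit_table[[term_col]] == tm])
    fg_hits <- sum(fg_ids %in% hit_ids)
    bg_hits <- sum(bg_ids %in% hit_ids)
    K <- fg_hits + bg_hits
    p <- if (K == 0) 1 else
      stats::phyper(fg_hits - 1, K, fg_total + bg_total - K, fg_total,
                    lower.tail = FALSE)
    fg_rate <- fg_hits / fg_total
    bg_rate <- bg_hits / bg_total
    data.frame(term = tm, fg_hits = fg_hits, fg_total = fg_total,
               bg_hits = bg_hits, bg_total = bg_total,
               fold = if (bg_rate > 0) fg_rate / bg_rate else Inf,
               p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < q_threshold
  tab[order(tab$p), ]
}

#' One-sided Fisher functional-category enrichment
#'
#' Fisher's exact test (alternative "greater") of each annotation term in a
#' gene set against a gene universe. Terms with fewer than `min_term_size`
#' annotated genes in the universe are discarded.
#'
#' @param set_ids genes of interest (subset of universe).
#' @param universe all considered genes.
#' @param gene2term data.frame with columns `gene` and `term`.
#' @param min_term_size minimum annotated genes per term (default 5).
#' @param q_threshold BH significance threshold (default 0.05).
#' @return data.frame: term, fg_hits, fg_total, bg_hits, bg_total, fold, p,
#'   q, significant.
#' @export
functional_enrichment <- function(set_ids, universe, gene2term,
                                  min_term_size = 5, q_threshold = 0.05) {
  set_ids <- intersect(set_ids, universe)
  gene2term <- gene2term[gene2term$gene %in% universe, , drop = FALSE]
  sizes <- table(gene2term$term)
  terms <- names(sizes)[sizes >= min_term_size]
  if (!length(terms))
    return(data.frame(term = character(), fg_hits = integer(),
                      fg_total = integer(), bg_hits = integer(),
                      bg_total = integer(), fold = numeric(), p = numeric(),
                      q = numeric(), significant = logical()))
  n_set <- length(set_ids)
  n_bg <- length(universe) - n_set
  rows <- lapply(terms, function(tm) {
    ann <- unique(gene2term$gene[gene2term$term == tm])
    fg_hits <- sum(set_ids %in% ann)
    bg_hits <- length(ann) - fg_hits
    m <- matrix(c(fg_hits, n_set - fg_hits, bg_hits, n_bg - bg_hits), 2)
    p <- stats::fisher.test(m, alternative = "greater")$p.value
    data.frame(term = tm, fg_hits = fg_hits, fg_total = n_set,
               bg_hits = bg_hits, bg_total = n_bg,
               fold = if (bg_hits > 0) (fg_hits / n_set) / (bg_hits / n_bg) else Inf,
               p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < q_threshold
  tab[order(tab$p), ]
}

#' Assign each OCR to its single nearest TSS with a signed distance
#'
#' Distance convention (reference-signed, strand-agnostic): 0 if the TSS
#' falls inside the OCR; `tss - end` (positive) when the TSS lies right of
#' the OCR; `tss - start` (negative) when it lies left. The nearest TSS
#' minimises |distance|; ties go to the TSS with the smaller coordinate.
#' Assignment is per chromosome.
#'
#' @param ocrs,tss `genomic_intervals`; `tss` must be 1-bp anchors.
#' @return data.frame: ocr, gene, distance.
#' @export
nearest_tss <- function(ocrs, tss) {
  stopifnot(inherits(ocrs, "genomic_intervals"), inherits(tss, "genomic_intervals"))
  if (any(tss$end - tss$start != 1L)) stop("tss must be 1-bp anchors")
  out <- lapply(seq_len(nrow(ocrs)), function(i) {
    cand <- tss[tss$chrom == ocrs$chrom[i], , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    t <- cand$start
    d <- ifelse(t >= ocrs$start[i] & t < ocrs$end[i], 0,
                ifelse(t >= ocrs$end[i], t - ocrs$end[i], t - ocrs$start[i]))
    best <- which(abs(d) == min(abs(d)))
    best <- best[which.min(t[best])]          # tie: lower coordinate wins
    data.frame(ocr = ocrs$id[i], gene = cand$id[best], distance = d[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Enrichment of OCR/gene pairs across module pairs
#'
#' For every (gene module G, OCR module O) cell, counts the mapped OCR/gene
#' pairs with the OCR in O and its gene in G, and tests the count against an
#' upper-tail hypergeometric null over all mapped pairs. BH adjustment is
#' across all cells.
#'
#' @param gene_modules named character vector gene -> module.
#' @param ocr_modules named character vector ocr -> module.
#' @param map data.frame from [nearest_tss()] (columns ocr, gene).
#' @return list of matrices: `observed`, `expected`, `p`, `q`
#'   (gene modules x OCR modules).
#' @export
ocr_gene_pair_enrichment <- function(gene_modules, ocr_modules, map) {
  map <- map[map$ocr %in% names(ocr_modules) & map$gene %in% names(gene_modules), ]
  map$gm <- unname(gene_modules[map$gene])
  map$om <- unname(ocr_modules[map$ocr])
  map <- map[!is.na(map$gm) & !is.na(map$om), ]
  gms <- sort(unique(map$gm)); oms <- sort(unique(map$om))
  N <- nrow(map)
  obs <- table(factor(map$gm, gms), factor(map$om, oms))
  obs <- matrix(obs, nrow = length(gms), dimnames = list(gms, oms))
  rowK <- rowSums(obs); coln <- colSums(obs)
  expected <- outer(rowK, coln) / N
  p <- matrix(1, length(gms), length(oms), dimnames = list(gms, oms))
  for (i in seq_along(gms)) for (j in seq_along(oms)) {
    p[i, j] <- stats::phyper(obs[i, j] - 1, rowK[i], N - rowK[i], coln[j],
                             lower.tail = FALSE)
  }
  q <- matrix(stats::p.adjust(p, "BH"), nrow(p), dimnames = dimnames(p))
  list(observed = obs, expected = expected, p = p, q = q)
}

#' Correlate motif enrichment profiles with TF connectivity profiles
#'
#' For every (TF, motif) pair, the Pearson correlation between the motif's
#' per-module enrichment profile (fraction of the module's regions carrying
#' the motif) and the TF's per-module connectivity. High r for a TF and its
#' own motif indicates agreement between co-expression and motif evidence.
#'
#' @param connectivity TFs x modules matrix (from [tf_connectivity()]).
#' @param motif_profiles motifs x modules matrix of per-module enrichment
#'   (e.g. fraction of regions with the motif).
#' @return TFs x motifs correlation matrix (NA where a profile is constant).
#' @export
connectivity_motif_agreement <- function(connectivity, motif_profiles) {
  stopifnot(ncol(connectivity) == ncol(motif_profiles))
  common <- intersect(colnames(connectivity), colnames(motif_profiles))
  if (length(common)) {
    connectivity <- connectivity[, common, drop = FALSE]
    motif_profiles <- motif_profiles[, common, drop = FALSE]
  }
  out <- suppressWarnings(stats::cor(t(connectivity), t(motif_profiles)))
  dimnames(out) <- list(rownames(connectivity), rownames(motif_profiles))
  out
}

#' Per-module motif enrichment profile matrix
#'
#' Convenience builder for [connectivity_motif_agreement()]: for each module
#' and motif, the fraction of the module's regions carrying the motif.
#'
#' @param region_modules named character vector region -> module.
#' @param hit_table data.frame (region_id, motif_id).
#' @return motifs x modules matrix of hit fractions.
#' @export
motif_profile_matrix <- function(region_modules, hit_table) {
  region_modules <- region_modules[!is.na(region_modules)]
  mods <- sort(unique(region_modules))
  motifs <- sort(unique(hit_table$motif_id))
  out <- matrix(0, length(motifs), length(mods), dimnames = list(motifs, mods))
  for (m in mods) {
    regions <- names(region_modules)[region_modules == m]
    ht <- hit_table[hit_table$region_id %in% regions, ]
    if (nrow(ht)) {
      frac <- table(factor(ht$motif_id, motifs)) / length(regions)
      out[, m] <- as.numeric(frac)
    }
  }
  out
}
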