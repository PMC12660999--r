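#' Synthetic multiome study configuration
#'
#' Builds and validates the configuration for the synthetic multiome
#' generator. The defaults emulate a whole-animal single-cell study design:
#' around ten cell types with skewed abundances (one dominant stem-cell-like
#' type plus progressively rarer differentiated types), planted co-expression
#' modules that are elevated in one or several member types, one driving TF
#' per module whose expression tracks the module profile, open chromatin
#' regions (OCRs) co-accessible in the member types and placed near member
#' gene TSSs carrying the driving TF's motif, and a replicated two-condition
#' knockdown in which one TF's targets are suppressed in two cell types and
#' those clusters shrink.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param cells_per_type integer vector of cells per type; recycled/validated
#'   against `n_cell_types`. Defaults are deliberately skewed.
#' @param n_genes total number of genes, including module genes and TF genes.
#' @param module_specs list of module specifications, each a list with
#'   `module_id`, `member_cell_types` (indices into the cell types),
#'   `n_genes`, and `fold_elevation` (> 1).
#' @param n_tfs number of TF genes; `tf_module` maps each TF to the module it
#'   drives (NA for a TF without a module).
#' @param tf_module integer vector of length `n_tfs`.
#' @param n_ocrs total number of OCRs (module OCRs plus background).
#' @param ocrs_per_module OCRs planted per module.
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp*mu^2).
#' @param base_mean baseline per-cell mean count of a background gene.
#' @param libsize_sigma sd of the per-cell log-normal library size factor.
#' @param tf_noise_sd sd of multiplicative noise on TF profiles (controls how
#'   tightly a TF tracks its module; default targets r ~ 0.8 at pseudobulk
#'   level).
#' @param ocr_fold accessibility fold elevation of module OCRs in member
#'   types.
#' @param ocr_base_mean baseline per-cell mean accessibility count.
#' @param ocr_tss_window maximum distance (bp) between a planted module OCR
#'   and its member gene TSS.
#' @param background_motif_rate probability that a random (region, motif)
#'   pair is a background hit.
#' @param genome_span length (bp) of the single linear pseudo-chromosome.
#' @param knockdown_spec list with `tf` (TF index), `affected_cell_types`
#'   (two type indices), `target_suppression_factor` in (0,1),
#'   `abundance_reduction` in (0,1), `n_replicates` >= 2.
#' @param seed integer seed; all generation is reproducible given the seed.
#'
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cell_types = 10,
                             cells_per_type = c(500, 320, 260, 210, 170, 140, 110, 90, 70, 60),
                             n_genes = 2000,
                             module_specs = NULL,
                             n_tfs = 6,
                             tf_module = seq_len(n_tfs),
                             n_ocrs = 600,
                             ocrs_per_module = 40,
                             nb_dispersion = 0.4,
                             base_mean = 0.3,
                             libsize_sigma = 0.3,
                             tf_noise_sd = 0.35,
                             ocr_fold = 6,
                             ocr_base_mean = 0.3,
                             ocr_tss_window = 5000,
                             background_motif_rate = 0.02,
                             genome_span = NULL,
                             knockdown_spec = NULL,
                             seed = 1L) {
  if (is.null(module_specs)) {
    # 3 single-type + 3 multi-type modules; type 1 is the stem-cell-like
    # type and is left module-free so one-vs-type-1 contrasts are clean.
    module_specs <- list(
      list(module_id = "M1", member_cell_types = 2L, n_genes = 60L, fold_elevation = 8),
      list(module_id = "M2", member_cell_types = 4L, n_genes = 60L, fold_elevation = 8),
      list(module_id = "M3", member_cell_types = 7L, n_genes = 60L, fold_elevation = 8),
      list(module_id = "M4", member_cell_types = c(2L, 3L), n_genes = 60L, fold_elevation = 8),
      list(module_id = "M5", member_cell_types = c(5L, 6L), n_genes = 60L, fold_elevation = 8),
      list(module_id = "M6", member_cell_types = c(8L, 9L), n_genes = 60L, fold_elevation = 8)
    )
  }
  if (is.null(knockdown_spec)) {
    knockdown_spec <- list(tf = 4L, affected_cell_types = c(2L, 3L),
                           target_suppression_factor = 0.3,
                           abundance_reduction = 0.5, n_replicates = 2L)
  }
  if (is.null(genome_span)) genome_span <- n_genes * 20000
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = as.integer(n_genes),
              module_specs = module_specs,
              n_tfs = as.integer(n_tfs),
              tf_module = as.integer(tf_module),
              n_ocrs = as.integer(n_ocrs),
              ocrs_per_module = as.integer(ocrs_per_module),
              nb_dispersion = nb_dispersion,
              base_mean = base_mean,
              libsize_sigma = libsize_sigma,
              tf_noise_sd = tf_noise_sd,
              ocr_fold = ocr_fold,
              ocr_base_mean = ocr_base_mean,
              ocr_tss_window = as.integer(ocr_tss_window),
              background_motif_rate = background_motif_rate,
              genome_span = as.integer(genome_span),
              knockdown_spec = knockdown_spec,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_cell_types >= 2,
            length(cfg$cells_per_type) == cfg$n_cell_types,
            all(cfg$cells_per_type > 0),
            cfg$n_genes > 0, cfg$n_ocrs > 0,
            cfg$nb_dispersion > 0, cfg$base_mean > 0,
            length(cfg$tf_module) == cfg$n_tfs)
  for (ms in cfg$module_specs) {
    if (length(ms$member_cell_types) < 1)
      stop("module ", ms$module_id, ": empty member set")
    if (!all(ms$member_cell_types %in% seq_len(cfg$n_cell_types)))
      stop("module ", ms$module_id, ": member types outside 1..n_cell_types")
    if (ms$fold_elevation <= 1 && !isTRUE(all.equal(ms$fold_elevation, 1)))
      stop("module ", ms$module_id, ": fold_elevation must be >= 1")
  }
  demand <- sum(vapply(cfg$module_specs, function(m) m$n_genes, 0)) + cfg$n_tfs
  if (demand > cfg$n_genes)
    stop("n_genes (", cfg$n_genes, ") smaller than module gene demand plus TFs (",
         demand, ")")
  ks <- cfg$knockdown_spec
  if (!is.null(ks)) {
    stopifnot(ks$tf %in% seq_len(cfg$n_tfs),
              all(ks$affected_cell_types %in% seq_len(cfg$n_cell_types)),
              ks$target_suppression_factor > 0, ks$target_suppression_factor <= 1,
              ks$abundance_reduction >= 0, ks$abundance_reduction < 1,
              ks$n_replicates >= 2)
  }
  invisible(cfg)
}

# Per-(gene, type) expected mean matrix implied by the config (library factor
# excluded). Rows = genes, cols = cell types. Module genes get
# base * fold_elevation in member types; TF gene g driving module m follows
# the same elevated pattern.
synthetic_mean_matrix <- function(cfg, gene_base, truth) {
  mu <- matrix(gene_base, nrow = cfg$n_genes, ncol = cfg$n_cell_types)
  for (i in seq_along(cfg$module_specs)) {
    ms <- cfg$module_specs[[i]]
    genes <- truth$module_genes[[ms$module_id]]
    mu[genes, ms$member_cell_types] <- mu[genes, ms$member_cell_types] * ms$fold_elevation
  }
  for (t in seq_len(cfg$n_tfs)) {
    m <- cfg$tf_module[t]
    if (is.na(m)) next
    ms <- cfg$module_specs[[m]]
    g <- truth$tf_genes[t]
    mu[g, ms$member_cell_types] <- mu[g, ms$member_cell_types] * ms$fold_elevation
  }
  mu
}

# Gamma-Poisson draw of an NB count matrix with per-cell library factors and
# optional per-entry noise already folded into `mu` (genes x cells).
rnb_matrix <- function(mu, dispersion) {
  n <- length(mu)
  lam <- mu * stats::rgamma(n, shape = 1 / dispersion, scale = dispersion)
  matrix(stats::rpois(n, lam), nrow = nrow(mu))
}

#' Generate a synthetic single-cell expression matrix with planted modules
#'
#' Draws a genes x cells UMI count matrix by a gamma-Poisson (negative
#' binomial) model. Module member genes have their mean multiplied by the
#' module's `fold_elevation` in member cell types; each TF gene follows its
#' module's elevated profile with multiplicative noise so that its pseudobulk
#' correlation with the module average is high by construction. Per-cell
#' library size factors are log-normal.
#'
#' @param config a `synthetic_config`.
#' @return list with `counts` (sparse dgCMatrix genes x cells), `annotation`
#'   (data.frame: cell, cluster, broad_type, library), and `truth` (ground
#'   truth: gene/module maps, TF genes, expected means).
#' @export
generate_expression <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  cfg <- config
  n_cells <- sum(cfg$cells_per_type)
  type_of_cell <- rep(seq_len(cfg$n_cell_types), cfg$cells_per_type)

  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  # allocate module genes then TF genes from the front, background after
  truth <- list()
  cursor <- 0L
  truth$module_genes <- list()
  gene2module <- setNames(rep(NA_character_, cfg$n_genes), gene_ids)
  for (ms in cfg$module_specs) {
    idx <- cursor + seq_len(ms$n_genes)
    truth$module_genes[[ms$module_id]] <- idx
    gene2module[idx] <- ms$module_id
    cursor <- cursor + ms$n_genes
  }
  truth$tf_genes <- cursor + seq_len(cfg$n_tfs)
  names(truth$tf_genes) <- sprintf("tf%02d", seq_len(cfg$n_tfs))
  cursor <- cursor + cfg$n_tfs
  truth$gene_ids <- gene_ids
  truth$gene2module <- gene2module
  truth$tf2motif <- setNames(sprintf("motif%02d", seq_len(cfg$n_tfs)),
                             names(truth$tf_genes))
  truth$tf2targets <- lapply(seq_len(cfg$n_tfs), function(t) {
    m <- cfg$tf_module[t]
    if (is.na(m)) integer(0) else truth$module_genes[[cfg$module_specs[[m]]$module_id]]
  })
  names(truth$tf2targets) <- names(truth$tf_genes)

  # baseline per-gene means, log-normal spread around base_mean
  gene_base <- cfg$base_mean * exp(stats::rnorm(cfg$n_genes, 0, 0.5))
  mu_type <- synthetic_mean_matrix(cfg, gene_base, truth)
  truth$expected_mean <- mu_type
  truth$cell_types <- sprintf("ct%02d", seq_len(cfg$n_cell_types))
  dimnames(truth$expected_mean) <- list(gene_ids, truth$cell_types)

  lib_factor <- exp(stats::rnorm(n_cells, 0, cfg$libsize_sigma))
  mu <- mu_type[, type_of_cell, drop = FALSE] *
    rep(lib_factor, each = cfg$n_genes)
  # TF-specific multiplicative noise decorrelates TFs from a perfect module
  # track (target pseudobulk r ~ 0.8)
  for (t in seq_len(cfg$n_tfs)) {
    g <- truth$tf_genes[t]
    mu[g, ] <- mu[g, ] * exp(stats::rnorm(n_cells, 0, cfg$tf_noise_sd))
  }
  counts <- rnb_matrix(mu, cfg$nb_dispersion)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(gene_ids, cell_ids)

  broad <- c("stem", rep(c("groupA", "groupB", "groupC"),
                         length.out = cfg$n_cell_types - 1))
  annotation <- data.frame(
    cell = cell_ids,
    cluster = truth$cell_types[type_of_cell],
    broad_type = broad[type_of_cell],
    library = sprintf("lib%d", (seq_len(n_cells) - 1L) %% 3L + 1L),
    stringsAsFactors = FALSE)
  list(counts = as_sparse(counts),
       annotation = annotation, truth = truth)
}

#' Generate synthetic accessibility data matching an expression ground truth
#'
#' Places one gene locus every `genome_span / n_genes` bp on a single linear
#' pseudo-chromosome (TSS = interval start, + strand), plants module OCRs
#' within `ocr_tss_window` bp of member-gene TSSs with elevated accessibility
#' in member cell types, and writes motif hits: the driving TF's motif in the
#' module's OCRs and member-gene promoters, plus background hits at
#' `background_motif_rate`.
#'
#' @param config a `synthetic_config`.
#' @param truth ground truth from [generate_expression()].
#' @return list with `counts` (OCR x cell sparse matrix), `ocr_bed` and
#'   `tss_bed` (`genomic_intervals`), `motif_hits` (data.frame region_id,
#'   motif_id, count), and `truth` extended with `ocr2module` and `ocr_genes`.
#' @export
generate_accessibility <- function(config, truth) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  spacing <- cfg$genome_span %/% (cfg$n_genes + 1L)
  if (spacing <= 2L * cfg$ocr_tss_window + 600L)
    stop("genome_span too small to place ", cfg$n_genes,
         " loci without overlapping OCR windows")
  tss_pos <- spacing * seq_len(cfg$n_genes)
  tss_bed <- genomic_intervals(chrom = "chr1", start = tss_pos,
                               end = tss_pos + 1L, id = truth$gene_ids,
                               strand = "+")

  n_module_ocr <- cfg$ocrs_per_module * length(cfg$module_specs)
  if (n_module_ocr > cfg$n_ocrs)
    stop("n_ocrs smaller than planted module OCR demand")
  ocr_ids <- sprintf("ocr%04d", seq_len(cfg$n_ocrs))
  ocr2module <- setNames(rep(NA_character_, cfg$n_ocrs), ocr_ids)
  ocr_gene <- integer(cfg$n_ocrs)
  ocr_start <- integer(cfg$n_ocrs)
  width <- 200L
  k <- 0L
  for (mi in seq_along(cfg$module_specs)) {
    ms <- cfg$module_specs[[mi]]
    host <- sample(truth$module_genes[[ms$module_id]], cfg$ocrs_per_module,
                   replace = cfg$ocrs_per_module > length(truth$module_genes[[ms$module_id]]))
    off <- sample(seq(-cfg$ocr_tss_window, cfg$ocr_tss_window - width), cfg$ocrs_per_module)
    idx <- k + seq_len(cfg$ocrs_per_module)
    ocr2module[idx] <- ms$module_id
    ocr_gene[idx] <- host
    ocr_start[idx] <- tss_pos[host] + off
    k <- k + cfg$ocrs_per_module
  }
  # background OCRs near random gene TSSs (outside no gene exists on the
  # pseudo-chromosome anyway); keep within the same window so nearest-gene
  # assignment is unambiguous
  n_bg <- cfg$n_ocrs - n_module_ocr
  host_bg <- sample(seq_len(cfg$n_genes), n_bg, replace = TRUE)
  off_bg <- sample(seq(-cfg$ocr_tss_window, cfg$ocr_tss_window - width), n_bg,
                   replace = TRUE)
  idx <- n_module_ocr + seq_len(n_bg)
  ocr_gene[idx] <- host_bg
  ocr_start[idx] <- tss_pos[host_bg] + off_bg
  ocr_start <- pmax(ocr_start, 0L)
  ocr_bed <- genomic_intervals(chrom = "chr1", start = ocr_start,
                               end = ocr_start + width, id = ocr_ids,
                               strand = ".")

  # accessibility counts
  n_cells <- sum(cfg$cells_per_type)
  type_of_cell <- rep(seq_len(cfg$n_cell_types), cfg$cells_per_type)
  ocr_base <- cfg$ocr_base_mean * exp(stats::rnorm(cfg$n_ocrs, 0, 0.4))
  mu_type <- matrix(ocr_base, nrow = cfg$n_ocrs, ncol = cfg$n_cell_types)
  for (ms in cfg$module_specs) {
    rows <- which(ocr2module == ms$module_id)
    mu_type[rows, ms$member_cell_types] <- mu_type[rows, ms$member_cell_types] * cfg$ocr_fold
  }
  lib_factor <- exp(stats::rnorm(n_cells, 0, cfg$libsize_sigma))
  mu <- mu_type[, type_of_cell, drop = FALSE] * rep(lib_factor, each = cfg$n_ocrs)
  counts <- rnb_matrix(mu, cfg$nb_dispersion)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(ocr_ids, cell_ids)

  # motif hits: planted driver motifs + background
  hits <- list()
  promoter_ids <- paste0("prom_", truth$gene_ids)
  for (t in seq_len(cfg$n_tfs)) {
    m <- cfg$tf_module[t]
    if (is.na(m)) next
    mid <- cfg$module_specs[[m]]$module_id
    motif <- truth$tf2motif[t]
    regions <- c(ocr_ids[which(ocr2module == mid)],
                 promoter_ids[truth$module_genes[[mid]]])
    hits[[length(hits) + 1L]] <- data.frame(region_id = regions,
                                            motif_id = unname(motif),
                                            count = 1L,
                                            stringsAsFactors = FALSE)
  }
  if (cfg$background_motif_rate > 0) {
    all_regions <- c(ocr_ids, promoter_ids)
    n_pairs <- length(all_regions) * cfg$n_tfs
    bg <- which(stats::runif(n_pairs) < cfg$background_motif_rate)
    if (length(bg)) {
      ri <- (bg - 1L) %% length(all_regions) + 1L
      mi <- (bg - 1L) %/% length(all_regions) + 1L
      hits[[length(hits) + 1L]] <- data.frame(region_id = all_regions[ri],
                                              motif_id = unname(truth$tf2motif[mi]),
                                              count = 1L, stringsAsFactors = FALSE)
    }
  }
  motif_hits <- do.call(rbind, hits)
  motif_hits <- motif_hits[!duplicated(motif_hits[c("region_id", "motif_id")]), ]
  rownames(motif_hits) <- NULL

  truth$ocr2module <- ocr2module
  truth$ocr_genes <- data.frame(ocr = ocr_ids, gene = truth$gene_ids[ocr_gene],
                                stringsAsFactors = FALSE)
  list(counts = as_sparse(counts),
       ocr_bed = ocr_bed, tss_bed = tss_bed,
       motif_hits = motif_hits, truth = truth)
}

#' Generate a replicated two-condition knockdown experiment
#'
#' The control condition reproduces the base expression model; the knockdown
#' condition multiplies the target genes' means by
#' `target_suppression_factor` in the affected cell types only, and shrinks
#' the affected types' cell numbers by `abundance_reduction`. Each replicate
#' of each condition is an independent draw.
#'
#' @param config a `synthetic_config` with `knockdown_spec` set.
#' @param truth ground truth from [generate_expression()].
#' @return list with `counts` (genes x cells), `annotation` (cell, cluster,
#'   broad_type, library, condition, replicate), and `truth` extended with
#'   the knockdown's target set and affected types.
#' @export
generate_knockdown <- function(config, truth) {
  cfg <- config
  ks <- cfg$knockdown_spec
  if (is.null(ks)) stop("knockdown_spec not set")
  set.seed(cfg$seed + 2L)
  mu_ctrl <- truth$expected_mean
  mu_kd <- mu_ctrl
  targets <- truth$tf2targets[[ks$tf]]
  tf_gene <- truth$tf_genes[ks$tf]
  mu_kd[c(targets, tf_gene), ks$affected_cell_types] <-
    mu_kd[c(targets, tf_gene), ks$affected_cell_types] * ks$target_suppression_factor

  blocks <- list()
  ann <- list()
  cell_counter <- 0L
  for (cond in c("control", "knockdown")) {
    mu_type <- if (cond == "control") mu_ctrl else mu_kd
    ncells_type <- cfg$cells_per_type
    if (cond == "knockdown")
      ncells_type[ks$affected_cell_types] <-
        pmax(1L, as.integer(round(ncells_type[ks$affected_cell_types] * (1 - ks$abundance_reduction))))
    for (rep_i in seq_len(ks$n_replicates)) {
      n_cells <- sum(ncells_type)
      type_of_cell <- rep(seq_len(cfg$n_cell_types), ncells_type)
      lib_factor <- exp(stats::rnorm(n_cells, 0, cfg$libsize_sigma))
      mu <- mu_type[, type_of_cell, drop = FALSE] * rep(lib_factor, each = cfg$n_genes)
      m <- rnb_matrix(mu, cfg$nb_dispersion)
      ids <- sprintf("kdcell%06d", cell_counter + seq_len(n_cells))
      cell_counter <- cell_counter + n_cells
      dimnames(m) <- list(truth$gene_ids, ids)
      blocks[[length(blocks) + 1L]] <- m
      ann[[length(ann) + 1L]] <- data.frame(
        cell = ids, cluster = truth$cell_types[type_of_cell],
        broad_type = NA_character_,
        library = sprintf("%s_rep%d", cond, rep_i),
        condition = cond, replicate = sprintf("rep%d", rep_i),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  annotation <- do.call(rbind, ann)
  truth$knockdown <- list(tf = names(truth$tf_genes)[ks$tf],
                          tf_gene = truth$gene_ids[tf_gene],
                          targets = truth$gene_ids[targets],
                          affected_cell_types = truth$cell_types[ks$affected_cell_types],
                          suppression = ks$target_suppression_factor,
                          abundance_reduction = ks$abundance_reduction)
  list(counts = as_sparse(counts),
       annotation = annotation, truth = truth)
}
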