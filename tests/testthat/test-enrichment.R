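# exhaustive enumeration oracle for the upper-tail hypergeometric:
# P[X >= x] by enumerating all choose(N, n) draws is infeasible; instead sum
# the exact pmf terms choose(K, k) choose(N-K, n-k) / choose(N, n).
hyper_upper <- function(x, K, N, n) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

test_that("hypergeometric enrichment matches exact enumeration", {
  # fg 5/5 hits, bg 0/95: p = 1/choose(100, 5)
  fg <- sprintf("f%d", 1:5)
  bg <- sprintf("b%d", 1:95)
  hits <- data.frame(region_id = fg, motif_id = "mA")
  tab <- hypergeometric_enrichment(fg, bg, hits)
  expect_equal(tab$p[tab$term == "mA"], 1 / choose(100, 5), tolerance = 1e-12)
  expect_true(tab$significant[tab$term == "mA"])
  # small universes (<= 12): agree with the enumeration oracle
  set.seed(8)
  for (rep in 1:20) {
    N <- sample(6:12, 1)
    n_fg <- sample(2:(N - 2), 1)
    ids <- sprintf("r%02d", 1:N)
    fg <- ids[1:n_fg]; bg <- ids[(n_fg + 1):N]
    hit_ids <- sample(ids, sample(1:N, 1))
    hits <- data.frame(region_id = hit_ids, motif_id = "m")
    tab <- hypergeometric_enrichment(fg, bg, hits)
    x <- sum(fg %in% hit_ids)
    expect_equal(tab$p, hyper_upper(x, length(hit_ids), N, n_fg),
                 tolerance = 1e-12)
  }
  # null: equal hit rates, large n -> not significant
  fg <- sprintf("f%d", 1:100); bg <- sprintf("b%d", 1:900)
  hits0 <- data.frame(region_id = c(fg[1:20], bg[1:180]), motif_id = "m0")
  tab0 <- hypergeometric_enrichment(fg, bg, hits0)
  expect_gt(tab0$p, 0.3)
  expect_false(tab0$significant)
  expect_error(hypergeometric_enrichment(c("a", "b"), c("b", "c"),
                                         data.frame(region_id = "a",
                                                    motif_id = "m")),
               "disjoint")
})

test_that("BH q-values are monotone in p within a call", {
  set.seed(9)
  ids <- sprintf("r%03d", 1:60)
  fg <- ids[1:20]; bg <- ids[21:60]
  hits <- do.call(rbind, lapply(1:8, function(k)
    data.frame(region_id = sample(ids, 25), motif_id = paste0("m", k))))
  tab <- hypergeometric_enrichment(fg, bg, hits)
  expect_true(all(diff(tab$q[order(tab$p)]) >= -1e-12))
  expect_true(all(tab$q >= tab$p - 1e-12))
})

test_that("functional enrichment applies the Fisher test and term-size floor", {
  universe <- sprintf("g%03d", 1:1000)
  gene2term <- rbind(
    data.frame(gene = universe[1:15], term = "T_enriched"),
    data.frame(gene = universe[c(1:4)], term = "T_small"),      # 4 genes: out
    data.frame(gene = universe[sample(1000, 50)], term = "T_flat"))
  set_ids <- universe[1:100]
  tab <- functional_enrichment(set_ids, universe, gene2term)
  expect_false("T_small" %in% tab$term)
  # 2x2 table (10, 90, 5, 895) checked against the enumeration oracle
  g2t <- data.frame(gene = universe[c(1:10, 101:105)], term = "T_x")
  tab2 <- functional_enrichment(universe[1:100], universe, g2t)
  expect_equal(tab2$p[tab2$term == "T_x"],
               hyper_upper(10, 15, 1000, 100), tolerance = 1e-10)
  # fully contained term: minimal p
  g2t3 <- data.frame(gene = universe[1:8], term = "T_in")
  tab3 <- functional_enrichment(universe[1:100], universe, g2t3)
  expect_equal(tab3$p[tab3$term == "T_in"],
               hyper_upper(8, 8, 1000, 100), tolerance = 1e-10)
})

test_that("nearest TSS assignment follows the reference-sign convention", {
  tss <- genomic_intervals("chr1", c(1050, 1300, 5000), c(1051, 1301, 5001),
                           id = c("gIn", "gRight", "gFar"))
  ocrs <- genomic_intervals("chr1", c(1000, 2000), c(1100, 2100),
                            id = c("oSpan", "oMid"))
  map <- nearest_tss(ocrs, tss)
  expect_equal(map$distance[map$ocr == "oSpan"], 0)        # TSS inside
  expect_equal(map$gene[map$ocr == "oSpan"], "gIn")
  # [2000,2100) vs TSS 1300: TSS left -> negative, distance to start
  expect_equal(map$gene[map$ocr == "oMid"], "gRight")
  expect_equal(map$distance[map$ocr == "oMid"], 1300 - 2000)
  # interval-arithmetic oracle: [1000,1100) with TSS at 1300 -> +200
  map2 <- nearest_tss(genomic_intervals("chr1", 1000, 1100, id = "o"),
                      genomic_intervals("chr1", 1300, 1301, id = "g"))
  expect_equal(map2$distance, 200)
  # equidistant TSSs: the lower coordinate wins, deterministically
  tss_tie <- genomic_intervals("chr1", c(900, 1200), c(901, 1201),
                               id = c("gLo", "gHi"))
  map3 <- nearest_tss(genomic_intervals("chr1", 1000, 1100, id = "o"), tss_tie)
  expect_equal(map3$gene, "gLo")
  # translation invariance
  shift <- 5000L
  tss_s <- genomic_intervals("chr1", tss$start + shift, tss$end + shift,
                             id = tss$id)
  ocrs_s <- genomic_intervals("chr1", ocrs$start + shift, ocrs$end + shift,
                              id = ocrs$id)
  map_s <- nearest_tss(ocrs_s, tss_s)
  expect_equal(map_s$gene, map$gene)
  expect_equal(map_s$distance, map$distance)
})

test_that("OCR/gene pair enrichment lights the matched module pairs only", {
  fx <- default_fixture()
  map <- nearest_tss(fx$ac$ocr_bed, fx$ac$tss_bed)
  gm <- fx$ex$truth$gene2module; gm <- gm[!is.na(gm)]
  om <- fx$ac$truth$ocr2module; om <- om[!is.na(om)]
  pe <- ocr_gene_pair_enrichment(gm, om, map)
  mods <- sprintf("M%d", 1:6)
  expect_true(all(diag(pe$q[mods, mods]) < 0.05))
  off <- pe$p[mods, mods][row(diag(6)) != col(diag(6))]
  expect_true(all(off > 0.05))
  # permuted gene-module labels: p roughly uniform (mean near 0.5)
  set.seed(10)
  gm_perm <- setNames(sample(gm), names(gm))
  pe_perm <- ocr_gene_pair_enrichment(gm_perm, om, map)
  expect_gt(mean(pe_perm$p), 0.25)
})

test_that("connectivity and motif enrichment profiles agree for a driving TF", {
  fx <- default_fixture()
  md <- module_fixture()
  prof <- module_profiles(md$assignment, fx$wpb$normalized_weighted)
  tf_ids <- fx$ex$truth$gene_ids[fx$ex$truth$tf_genes]
  tf_rows <- fx$wpb$normalized_weighted[
    intersect(tf_ids, rownames(fx$wpb$normalized_weighted)), , drop = FALSE]
  conn <- tf_connectivity(tf_rows, prof$average)
  rownames(conn) <- names(fx$ex$truth$tf_genes)[match(rownames(conn), tf_ids)]
  # per-module motif profiles over the detected modules' OCR counterparts:
  # use planted OCR modules relabelled to the detected expression modules by
  # majority gene overlap
  truth_mod <- fx$ex$truth$gene2module
  det2planted <- sapply(sort(unique(stats::na.omit(md$assignment$module))),
                        function(m) {
    members <- names(md$assignment$module)[
      !is.na(md$assignment$module) & md$assignment$module == m]
    names(which.max(table(truth_mod[members])))
  })
  om <- fx$ac$truth$ocr2module
  om_det <- setNames(names(det2planted)[match(om, det2planted)], names(om))
  mp <- motif_profile_matrix(om_det[!is.na(om_det)], fx$ac$motif_hits)
  agree <- connectivity_motif_agreement(conn, mp)
  for (t in seq_len(fx$cfg$n_tfs)) {
    tf <- names(fx$ex$truth$tf_genes)[t]
    own <- fx$ex$truth$tf2motif[[t]]
    if (!tf %in% rownames(agree)) next
    expect_gt(agree[tf, own], 0.7)
  }
  # shuffled module labels: agreement collapses towards zero
  set.seed(11)
  om_shuf <- setNames(sample(om_det[!is.na(om_det)]),
                      names(om_det[!is.na(om_det)]))
  mp_shuf <- motif_profile_matrix(om_shuf, fx$ac$motif_hits)
  agree_shuf <- connectivity_motif_agreement(conn, mp_shuf)
  own_r <- vapply(rownames(agree_shuf), function(tf)
    agree_shuf[tf, fx$ex$truth$tf2motif[[tf]]], 0)
  expect_lt(mean(abs(own_r), na.rm = TRUE), 0.6)
  # constant enrichment profile -> NA
  mp_const <- mp; mp_const[1, ] <- 0.5
  agree_c <- connectivity_motif_agreement(conn, mp_const)
  expect_true(all(is.na(agree_c[, rownames(mp_const)[1]])))
})
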