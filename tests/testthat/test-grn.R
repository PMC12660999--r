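test_that("weighted binding applies the distance-decay kernel exactly", {
  hits <- data.frame(region_id = c("o1", "o2"), motif_id = c("mA", "mA"))
  tf2motif <- c(tfA = "mA", tfB = "mB")
  acc <- c(o1 = 2, o2 = 3)
  map <- data.frame(ocr = c("o1", "o2"), gene = c("g1", "g1"),
                    distance = c(0, 25000))
  expect_message(
    B <- weighted_binding(hits, acc, map, tf2motif, genes = c("g1", "g2"),
                          lambda = 25000),
    "tfB")
  expect_equal(unname(B["tfA", "g1"]), 2 + 3 * exp(-1))
  expect_equal(unname(B["tfA", "g2"]), 0)
  expect_true(all(B["tfB", ] == 0))   # no motif annotation
  # beyond the window: excluded
  map2 <- data.frame(ocr = "o1", gene = "g1", distance = 2e5)
  B2 <- suppressMessages(weighted_binding(hits, acc, map2, tf2motif,
                                          genes = "g1", window = 1e5))
  expect_equal(unname(B2["tfA", "g1"]), 0)
  # multi-OCR random case vs direct summation oracle
  set.seed(18)
  map3 <- data.frame(ocr = sprintf("o%d", 1:20),
                     gene = sample(c("g1", "g2", "g3"), 20, TRUE),
                     distance = sample(-5e4:5e4, 20))
  acc3 <- setNames(runif(20, 0, 5), map3$ocr)
  hits3 <- data.frame(region_id = sprintf("o%d", seq(1, 20, 2)), motif_id = "mA")
  B3 <- suppressMessages(weighted_binding(hits3, acc3, map3, tf2motif,
                                          genes = c("g1", "g2", "g3")))
  for (g in c("g1", "g2", "g3")) {
    rows <- map3$gene == g & map3$ocr %in% hits3$region_id
    expect_equal(unname(B3["tfA", g]),
                 sum(acc3[map3$ocr[rows]] * exp(-abs(map3$distance[rows]) / 25000)))
  }
})

test_that("interaction scores average four scaled rank components", {
  set.seed(19)
  B <- matrix(runif(12), 3, 4, dimnames = list(sprintf("tf%d", 1:3),
                                               sprintf("g%d", 1:4)))
  expr <- setNames(runif(7), c(sprintf("g%d", 1:4), sprintf("gt%d", 1:3)))
  tf_gene <- setNames(sprintf("gt%d", 1:3), sprintf("tf%d", 1:3))
  net <- interaction_scores(B, expr, tf_gene)
  expect_true(all(net$score >= 0 & net$score <= 1))
  # direct four-component oracle for one pair
  s01 <- function(x) (x - min(x)) / (max(x) - min(x))
  r_tf <- s01(rank(expr[tf_gene]))
  r_tg <- s01(rank(expr[colnames(B)]))
  r_b <- matrix(s01(rank(B)), 3)
  r_act <- s01(rank(rowMeans(B)))
  i <- 2; j <- 3
  row <- net[net$tf == "tf2" & net$target == "g3", ]
  expect_equal(row$score,
               unname(r_tf[i] + r_tg[j] + r_b[i, j] + r_act[i]) / 4,
               tolerance = 1e-12)
  # a pair maximal in all four components scores exactly 1
  B1 <- B; B1["tf1", "g1"] <- 10; B1["tf1", ] <- B1["tf1", ] + 5
  expr1 <- expr; expr1["gt1"] <- 10; expr1["g1"] <- 9
  net1 <- interaction_scores(B1, expr1, tf_gene)
  expect_equal(net1$score[net1$tf == "tf1" & net1$target == "g1"], 1)
  # gene-order invariance
  perm <- c(3, 1, 4, 2)
  netp <- interaction_scores(B[, perm], expr, tf_gene)
  merged <- merge(net, netp, by = c("tf", "target"))
  expect_equal(merged$score.x, merged$score.y, tolerance = 1e-12)
  # uniform scaling of accessibility (binding) leaves scores unchanged
  nets <- interaction_scores(B * 7, expr, tf_gene)
  expect_equal(nets$score, net$score, tolerance = 1e-12)
})

test_that("network pruning is strict at the threshold and drops isolates", {
  net <- data.frame(tf = c("t1", "t1", "t2"), target = c("a", "b", "c"),
                    score = c(0.80, 0.85, 0.9))
  g <- prune_network(net, 0.8)
  expect_equal(igraph::ecount(g), 2)          # the 0.80 edge is excluded
  expect_false("a" %in% igraph::V(g)$name)    # its endpoint never enters
  expect_warning(g0 <- prune_network(net, 0.95), "empty")
  expect_equal(igraph::vcount(g0), 0)
  expect_true(all(igraph::degree(g) > 0))
})

test_that("network metrics match hand counts and a power-iteration oracle", {
  star <- data.frame(tf = "hub", target = sprintf("t%d", 1:5), score = 0.9)
  g <- prune_network(star, 0.5)
  m <- network_metrics(g)
  hub <- m$table[m$table$gene == "hub", ]
  expect_equal(hub$outdegree, 5)
  expect_equal(hub$relative_outdegree, 1)
  sink <- m$table[m$table$gene == "t1", ]
  expect_equal(sink$relative_outdegree, 0)
  expect_equal(m$active_tfs, 1)
  # literal variant flips the ratio
  ml <- network_metrics(g, variant = "literal")
  expect_equal(ml$table$relative_outdegree[ml$table$gene == "hub"], 0)
  # chain graph: PageRank vs an explicit damped power iteration
  chain <- data.frame(tf = c("a", "b", "c"), target = c("b", "c", "d"),
                      score = 1)
  gc <- prune_network(chain, 0.5)
  mc <- network_metrics(gc)
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "b"] <- A["b", "c"] <- A["c", "d"] <- 1
  d <- 0.85; n <- 4
  v <- rep(1 / n, n)
  for (it in 1:200) {
    out <- rowSums(A)
    M <- A / ifelse(out > 0, out, 1)
    dangling <- sum(v[out == 0]) / n
    v <- (1 - d) / n + d * (drop(v %*% M) + dangling)
  }
  expect_equal(mc$table$centrality[match(letters[1:4], mc$table$gene)],
               unname(v), tolerance = 1e-6)
})

test_that("centrality similarity is Pearson with a ward tree", {
  set.seed(20)
  base <- runif(10)
  cent <- cbind(f1 = base, f2 = base, f3 = runif(10))
  cs <- centrality_similarity(cent)
  expect_equal(unname(cs$cor["f1", "f2"]), 1)
  expect_equal(unname(cs$cor["f1", "f3"]), cor(base, cent[, "f3"]))
  expect_s3_class(cs$tree, "hclust")
})

test_that("influence ranks the planted driver and is scale-invariant", {
  fx <- default_fixture()
  map <- nearest_tss(fx$ac$ocr_bed, fx$ac$tss_bed)
  wpb_acc <- weighted_pseudobulk(fx$ac$counts, fx$ex$annotation, "cluster",
                                 min_counts = 10)
  tf_gene <- setNames(fx$ex$truth$gene_ids[fx$ex$truth$tf_genes],
                      names(fx$ex$truth$tf_genes))
  pbs <- pb_aggregate(fx$ex$counts, fx$ex$annotation, c("cluster", "library"))
  sel <- pbs$groups$cluster %in% c("ct01", "ct02")
  dge <- suppressMessages(nb_wald_test(pbs$counts[, sel],
                                       pbs$groups$cluster[sel],
                                       "ct02", "ct01"))
  B <- suppressMessages(weighted_binding(
    fx$ac$motif_hits, wpb_acc$normalized[, "ct02"], map,
    fx$ex$truth$tf2motif, genes = rownames(fx$wpb$normalized)))
  net <- interaction_scores(B, fx$wpb$normalized[, "ct02"], tf_gene)
  infl <- influence_scores(net, dge, tf_gene)
  # ct02 is driven by the M1 TF (tf01) and the knockdown TF (tf04, module M4)
  expect_lte(which(infl$tf == "tf04"), 3)
  expect_true(all(infl$influence >= 0 & infl$influence <= 1))
  # doubling all log2FC rescales supports but keeps the ranking
  dge2 <- dge; dge2$log2FC <- dge2$log2FC * 2
  infl2 <- influence_scores(net, dge2, tf_gene)
  expect_identical(infl$tf, infl2$tf)
  # no upregulated DEGs: all-zero with warning
  dge0 <- dge; dge0$padj <- 1
  expect_warning(i0 <- influence_scores(net, dge0, tf_gene), "no upregulated")
  expect_true(all(i0$influence == 0))
})

test_that("true TF-target edges outscore non-edges in their own fate", {
  fx <- default_fixture()
  map <- nearest_tss(fx$ac$ocr_bed, fx$ac$tss_bed)
  wpb_acc <- weighted_pseudobulk(fx$ac$counts, fx$ex$annotation, "cluster",
                                 min_counts = 10)
  tf_gene <- setNames(fx$ex$truth$gene_ids[fx$ex$truth$tf_genes],
                      names(fx$ex$truth$tf_genes))
  types <- planted_member_types(fx$cfg)
  tf_mod <- vapply(seq_len(fx$cfg$n_tfs), function(t)
    fx$cfg$module_specs[[fx$cfg$tf_module[t]]]$module_id, "")
  aucs <- c()
  for (ct in unique(unlist(types))) {
    active <- names(fx$ex$truth$tf_genes)[vapply(tf_mod, function(m)
      ct %in% types[[m]], NA)]
    if (!length(active)) next
    B <- suppressMessages(weighted_binding(
      fx$ac$motif_hits, wpb_acc$normalized[, ct], map,
      fx$ex$truth$tf2motif, genes = rownames(fx$wpb$normalized)))
    net <- interaction_scores(B, fx$wpb$normalized[, ct], tf_gene)
    sub <- net[net$tf %in% active, ]
    truth_key <- unlist(lapply(active, function(t)
      paste(t, fx$ex$truth$gene_ids[fx$ex$truth$tf2targets[[t]]])))
    lab <- paste(sub$tf, sub$target) %in% truth_key
    r <- rank(sub$score)
    aucs[ct] <- (mean(r[lab]) - (sum(lab) + 1) / 2) / sum(!lab)
  }
  expect_gte(min(aucs), 0.9)
})

test_that("co-influence clustering separates orthogonal profiles", {
  infl <- rbind(tfA = c(1, 0.9, 0, 0), tfB = c(0.8, 1, 0, 0.1),
                tfC = c(0, 0.1, 1, 0.9), tfD = c(0.1, 0, 0.9, 1))
  cl <- coinfluence_clusters(infl, cut = 0.7)
  expect_equal(length(unique(cl$clusters)), 2)
  expect_equal(cl$clusters[["tfA"]], cl$clusters[["tfB"]])
  expect_equal(cl$clusters[["tfC"]], cl$clusters[["tfD"]])
  solo <- coinfluence_clusters(infl[1, , drop = FALSE])
  expect_equal(unname(solo$clusters), 1L)
  expect_equal(solo$top[["1"]], "tfA")
})

test_that("top targets keep the upper quantile including ties", {
  net <- data.frame(tf = "t", target = sprintf("g%03d", 1:100),
                    score = seq(0.01, 1, length.out = 100))
  tt <- top_targets(net, "t", 0.95)
  expect_equal(nrow(tt), 5)
  # ties at the cutoff are kept
  net2 <- data.frame(tf = "t", target = sprintf("g%d", 1:10),
                     score = c(rep(0.5, 8), 0.9, 0.9))
  tt2 <- top_targets(net2, "t", 0.9)
  expect_true(all(tt2$score == 0.9))
  expect_equal(nrow(tt2), 2)
  expect_equal(nrow(top_targets(net, "absent")), 0)
})
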