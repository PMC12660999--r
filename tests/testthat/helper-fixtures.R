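# Shared seeded fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (!exists("fix", envir = .fixture_env)) {
    cfg <- synthetic_config(seed = 101)
    ex <- generate_expression(cfg)
    ac <- generate_accessibility(cfg, ex$truth)
    wpb <- weighted_pseudobulk(ex$counts, ex$annotation, "cluster")
    .fixture_env$fix <- list(cfg = cfg, ex = ex, ac = ac, wpb = wpb)
  }
  .fixture_env$fix
}

# expression module detection on the default fixture (cached: used by
# several files)
module_fixture <- function() {
  if (!exists("mods", envir = .fixture_env)) {
    fx <- default_fixture()
    m <- filter_by_cv(fx$wpb$normalized_weighted, 1.25)
    sc <- t(scale(t(m)))
    adj <- abs(stats::cor(t(sc)))^8
    tm <- tom(adj)
    asg <- detect_modules(tm, min_module_size = 50)
    .fixture_env$mods <- list(mat = m, tom = tm, assignment = asg)
  }
  .fixture_env$mods
}

# adjusted Rand index (closed form on the contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

# member cell types of each planted module, as group labels
planted_member_types <- function(cfg) {
  lapply(stats::setNames(cfg$module_specs,
                         vapply(cfg$module_specs, `[[`, "", "module_id")),
         function(ms) sprintf("ct%02d", ms$member_cell_types))
}
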