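test_that("ranking is descending with lexicographic tie-breaking and input-order invariant", {
  tbl <- tibble::tibble(site_id = c("s_lo", "s_hi"), t_mod = c(-1, 2))
  r <- rank_sites(tbl)
  expect_identical(r$site_id, c("s_hi", "s_lo"))

  ties <- tibble::tibble(site_id = c("c", "a", "b"), t_mod = c(1, 1, 1))
  expect_identical(rank_sites(ties)$site_id, c("a", "b", "c"))

  set.seed(3)
  tbl2 <- tibble::tibble(site_id = sprintf("s%03d", 1:40), t_mod = rnorm(40))
  shuffled <- tbl2[sample(40), ]
  expect_identical(rank_sites(tbl2), rank_sites(shuffled))

  # untested (NA metric) sites are dropped
  tbl3 <- tibble::tibble(site_id = c("a", "b"), t_mod = c(NA, 1))
  expect_identical(rank_sites(tbl3)$site_id, "b")
})

test_that("enrichment score equals hand and brute-force computations", {
  # 5-item hand example: metrics [3,2,1,-1,-2], set = top two, weight 1
  ranked <- tibble::tibble(site_id = sprintf("s%d", 1:5),
                           metric = c(3, 2, 1, -1, -2))
  es <- enrichment_score(ranked, c("s1", "s2"), weight_p = 1)
  # running sum: 3/5, 5/5, then -1/3 steps; supremum = 1
  expect_equal(es$es, 1)
  expect_identical(es$leading_edge, c("s1", "s2"))
  expect_false(es$degenerate)
  expect_equal(nrow(es$running_sum), 5L)
  expect_equal(es$running_sum$running[2], 1)

  # unweighted top-k block: ES = 1 - k/N at the block end per brute force
  ranked2 <- tibble::tibble(site_id = sprintf("s%02d", 1:10),
                            metric = 10:1)
  es2 <- enrichment_score(ranked2, sprintf("s%02d", 1:3), weight_p = 0)
  expect_equal(es2$es,
               es_brute(ranked2$metric, ranked2$site_id,
                        sprintf("s%02d", 1:3), weight_p = 0))
  expect_gt(es2$es, 0)

  # whole-list set is degenerate and scores 0
  es3 <- enrichment_score(ranked2, ranked2$site_id)
  expect_true(es3$degenerate)
  expect_equal(es3$es, 0)

  expect_error(enrichment_score(ranked, c("zz")), "intersect")
})

test_that("streaming ES equals exhaustive recomputation over all small subsets", {
  set.seed(11)
  for (rep in 1:3) {
    N <- sample(5:12, 1)
    ids <- sprintf("x%02d", 1:N)
    metric <- round(rnorm(N), 3)
    ranked <- rank_sites(tibble::tibble(site_id = ids, t_mod = metric))
    for (k in 1:3) {
      combos <- utils::combn(ids, k)
      for (j in seq_len(ncol(combos))) {
        set <- combos[, j]
        expect_equal(enrichment_score(ranked, set)$es,
                     es_brute(metric, ids, set),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("negating metrics and reversing the list negates the score", {
  set.seed(21)
  metric <- sort(rnorm(30), decreasing = TRUE)
  ids <- sprintf("s%02d", 1:30)
  ranked <- tibble::tibble(site_id = ids, metric = metric)
  flipped <- tibble::tibble(site_id = rev(ids), metric = rev(-metric))
  for (i in 1:5) {
    set <- sample(ids, 4)
    expect_equal(enrichment_score(ranked, set)$es,
                 -enrichment_score(flipped, set)$es,
                 tolerance = 1e-12)
  }
})

test_that("permutation null is seeded, validated, and falls back below 7 per group", {
  cfg <- tiny_cfg(seed = 8)
  dat <- simulate_cohort(cfg)
  lg <- log2_transform(dat$sites)
  set <- dat$sites$site_id[1:10]
  expect_error(ksea_null(lg, dat$groups, set, n_perm = 0), "positive")
  # 6 per group -> phenotype mode must warn and fall back to set mode
  expect_warning(ksea_null(lg, dat$groups, set, n_perm = 20,
                           mode = "phenotype", seed = 1),
                 "falling back")
  n1 <- ksea_null(lg, dat$groups, set, n_perm = 50, seed = 4)
  n2 <- ksea_null(lg, dat$groups, set, n_perm = 50, seed = 4)
  expect_identical(n1, n2)
  expect_length(n1, 50)
  expect_true(all(abs(n1) <= 1))
})

test_that("ksea results are internally coherent", {
  cfg <- tiny_cfg(seed = 15, active_kinases = "KIN_002",
                  substrates_per_active = 15)
  dat <- simulate_cohort(cfg)
  lg <- log2_transform(dat$sites)
  res <- suppressMessages(ksea(lg, dat$groups, dat$motifs, n_perm = 100,
                               seed = 2, min_size = 3))
  expect_s3_class(res, "ksea_result")
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_true(all(res$nes == sort(res$nes, decreasing = TRUE)))
  # leading edges are subsets of the substrate sets
  memb <- attr(res, "memberships")
  for (i in seq_len(nrow(res))) {
    expect_true(all(res$leading_edge[[i]] %in%
                      memb$site_id[memb$kinase == res$kinase[i]]))
  }
  # determinism
  res2 <- suppressMessages(ksea(lg, dat$groups, dat$motifs, n_perm = 100,
                                seed = 2, min_size = 3))
  expect_equal(as.data.frame(tidy(res)), as.data.frame(tidy(res2)))
})

test_that("a single kinase set gets q equal to its nominal p", {
  cfg <- tiny_cfg(seed = 16)
  dat <- simulate_cohort(cfg)
  lg <- log2_transform(dat$sites)
  memb <- tibble::tibble(kinase = "only", site_id = dat$sites$site_id[1:12])
  res <- ksea(lg, dat$groups, memb, n_perm = 99, seed = 3)
  expect_equal(nrow(res), 1L)
  expect_equal(res$q, res$p)
})

test_that("NES grows with the planted effect size below saturation", {
  # NES saturates (~2-3) once every substrate separates cleanly, so the
  # monotonicity of the normalized score is probed in the sub-saturation
  # regime, averaging over replicate cohorts to tame Monte-Carlo noise.
  mean_nes <- vapply(c(0, 0.1, 0.25), function(fc) {
    mean(vapply(1:6, function(r) {
      cfg <- sim_config(seed = 500 + r, n_sites = 300, n_proteins = 60,
                        n_kinase_motifs = 10, n_phosphatase_motifs = 0,
                        n_sh2_motifs = 0, active_kinases = "KIN_001",
                        substrates_per_active = 20, effect_log2fc = fc,
                        missing_rate_base = 0)
      dat <- simulate_cohort(cfg)
      res <- suppressMessages(
        ksea(log2_transform(dat$sites), dat$groups, dat$motifs,
             n_perm = 200, seed = r))
      res$nes[res$kinase == "KIN_001"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_nes) > 0))
  # the raw enrichment score is monotone through saturation as well
  es_at <- vapply(c(0.5, 1.5, 3), function(fc) {
    cfg <- sim_config(seed = 77, n_sites = 300, n_proteins = 60,
                      n_kinase_motifs = 10, n_phosphatase_motifs = 0,
                      n_sh2_motifs = 0, active_kinases = "KIN_001",
                      substrates_per_active = 20, effect_log2fc = fc,
                      missing_rate_base = 0)
    dat <- simulate_cohort(cfg)
    res <- suppressMessages(
      ksea(log2_transform(dat$sites), dat$groups, dat$motifs,
           n_perm = 100, mode = "set", seed = 5))
    res$es[res$kinase == "KIN_001"]
  }, numeric(1))
  expect_true(all(diff(es_at) > 0))
})

test_that("nominal p-values are roughly uniform on null data", {
  cfg <- sim_config(seed = 55, n_sites = 500, n_proteins = 100,
                    n_kinase_motifs = 50, n_phosphatase_motifs = 0,
                    n_sh2_motifs = 0)
  dat <- simulate_cohort(cfg)
  res <- suppressMessages(ksea(log2_transform(dat$sites), dat$groups,
                               dat$motifs, n_perm = 200, seed = 6))
  expect_gt(mean(res$p), 0.3)
  expect_lt(mean(res$p), 0.7)
  expect_lt(mean(res$p < 0.1), 0.3)
})

test_that("the enrichment statistic agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(4)
  N <- 200
  ids <- sprintf("s%03d", seq_len(N))
  metric <- rnorm(N)
  ranked <- rank_sites(tibble::tibble(site_id = ids, t_mod = metric))
  stats <- stats::setNames(ranked$metric, ranked$site_id)
  for (i in 1:20) {
    set <- sample(ids, sample(3:25, 1))
    mine <- enrichment_score(ranked, set)$es
    theirs <- fgsea::calcGseaStat(
      stats, selectedStats = which(names(stats) %in% set), gseaParam = 1)
    expect_equal(mine, theirs, tolerance = 1e-10)
  }
})
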