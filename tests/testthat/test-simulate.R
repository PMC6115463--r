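test_that("motif library has the configured category counts and is deterministic", {
  lib <- simulate_motif_library(sim_config())
  expect_equal(nrow(lib), 327L)
  expect_equal(sum(lib$category == "kinase"), 224L)
  expect_equal(sum(lib$category == "phosphatase"), 23L)
  expect_equal(sum(lib$category == "sh2"), 80L)
  expect_false(anyDuplicated(lib$name) > 0)
  # center slot is a nonempty subset of S/T/Y
  expect_true(all(grepl("^[STY]+$", lib$pos_08)))

  empty <- simulate_motif_library(sim_config(n_kinase_motifs = 0,
                                             n_phosphatase_motifs = 0,
                                             n_sh2_motifs = 0))
  expect_equal(nrow(empty), 0L)

  again <- simulate_motif_library(sim_config())
  expect_identical(lib, again)
})

test_that("planted sites match their motif by construction and truth is recoverable", {
  cfg <- tiny_cfg(active_kinases = c("KIN_001", "KIN_002"),
                  substrates_per_active = 10)
  lib <- simulate_motif_library(cfg)
  pr <- simulate_proteome(cfg, lib)
  expect_equal(nrow(pr$truth), 20L)
  for (i in seq_len(nrow(pr$truth))) {
    s <- pr$sites[pr$sites$site_id == pr$truth$site_id[i], ]
    motif <- lib[lib$name == pr$truth$motif[i], ]
    expect_true(match_motif(s$flank, motif))
  }
  # re-running the matcher recovers >= 95% of planted memberships
  hits <- suppressMessages(build_kinase_sets(pr$sites, lib, min_size = 1))
  found <- dplyr::inner_join(pr$truth, hits,
                             by = c(site_id = "site_id", motif = "kinase"))
  expect_gte(nrow(found) / nrow(pr$truth), 0.95)

  # no active kinases -> empty truth table
  pr0 <- simulate_proteome(tiny_cfg(), simulate_motif_library(tiny_cfg()))
  expect_equal(nrow(pr0$truth), 0L)
})

test_that("proteome generator validates impossible requests", {
  cfg <- tiny_cfg()
  lib <- simulate_motif_library(cfg)
  cfg0 <- tiny_cfg(); cfg0$n_proteins <- 0L
  expect_error(simulate_proteome(cfg0, lib), "n_proteins")
  cfg_big <- tiny_cfg(); cfg_big$n_sites <- 10000L
  expect_error(simulate_proteome(cfg_big, lib), "synthesizable")
  expect_error(simulate_proteome(tiny_cfg(active_kinases = "NOPE"), lib),
               "not in motif library")
})

test_that("site matrix has calibrated effects, missingness, and determinism", {
  # planted effect recovered on average within +/- 0.2
  cfg <- sim_config(seed = 3, n_sites = 400, n_proteins = 80,
                    n_kinase_motifs = 5, n_phosphatase_motifs = 0,
                    n_sh2_motifs = 0, active_kinases = "KIN_001",
                    substrates_per_active = 30, effect_log2fc = 2,
                    noise_sd = 0.3, missing_rate_base = 0)
  lib <- simulate_motif_library(cfg)
  pr <- simulate_proteome(cfg, lib)
  sm <- simulate_site_matrix(cfg, pr$sites)
  planted <- attr(sm, "truth")
  groups <- attr(sm, "sample_groups")
  x <- log2(as.matrix(sm[groups$sample]))
  rel <- groups$sample[groups$group == "relapsed"]
  non <- groups$sample[groups$group == "non-relapsed"]
  fc <- rowMeans(x[, rel]) - rowMeans(x[, non])
  expect_lt(abs(mean(fc[planted]) - 2), 0.2)
  expect_lt(abs(mean(fc[!planted])), 0.1)
  expect_false(anyNA(x))

  # dropout hits its target rate and is biased toward low intensities
  cfg2 <- sim_config(seed = 4, n_sites = 1000, n_proteins = 200,
                     n_kinase_motifs = 2, n_phosphatase_motifs = 0,
                     n_sh2_motifs = 0, missing_rate_base = 0.2)
  sm2 <- simulate_site_matrix(cfg2, simulate_proteome(cfg2, simulate_motif_library(cfg2))$sites)
  x2 <- as.matrix(sm2[attr(sm2, "sample_groups")$sample])
  expect_lt(abs(mean(is.na(x2)) - 0.2), 0.03)
  miss_by_site <- rowMeans(is.na(x2))
  base <- rowMeans(log2(x2), na.rm = TRUE)
  expect_lt(cor(base, miss_by_site, use = "complete.obs"), -0.3)

  # byte-identical under a fixed seed
  sm_again <- simulate_site_matrix(cfg, pr$sites)
  expect_identical(as.data.frame(sm), as.data.frame(sm_again))

  cfg_bad <- tiny_cfg(); cfg_bad$noise_sd <- 0
  expect_error(simulate_site_matrix(cfg_bad, pr$sites), "noise_sd")
})

test_that("null site matrix gives nominal two-sample t rejection rates", {
  cfg <- sim_config(seed = 11, n_sites = 1000, n_proteins = 200,
                    n_kinase_motifs = 2, n_phosphatase_motifs = 0,
                    n_sh2_motifs = 0, effect_log2fc = 0,
                    missing_rate_base = 0)
  sm <- simulate_site_matrix(cfg, simulate_proteome(cfg, simulate_motif_library(cfg))$sites)
  groups <- attr(sm, "sample_groups")
  x <- log2(as.matrix(sm[groups$sample]))
  rel <- groups$group == "relapsed"
  p <- apply(x, 1, function(v) t.test(v[rel], v[!rel])$p.value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("clinical generator recovers planted hazard ratios", {
  # no planted effect: mean log-HR over three n = 2000 cohorts stays near 0
  b0 <- vapply(5:7, function(sd_) {
    cfg0 <- sim_config(seed = sd_, n_patients = 2000, kinase_hr = c("K-high" = 1))
    cl0 <- simulate_clinical(cfg0)
    cl0$khigh <- unname(k_high(binarize_quartile(cl0)))
    cox_fit(cl0, c("khigh", "T", "N", "G", "age"))$coef$beta[1]
  }, numeric(1))
  expect_lt(abs(mean(b0)), 0.1)

  # planted HR 9.22 on K-high recovered within 25% at n = 2000
  cfg1 <- sim_config(seed = 6, n_patients = 2000)
  cl1 <- simulate_clinical(cfg1)
  cl1$khigh <- unname(k_high(binarize_quartile(cl1)))
  f1 <- cox_fit(cl1, c("khigh", "T", "N", "G", "age"))
  expect_lt(abs(f1$coef$hr[1] / 9.22 - 1), 0.25)

  # the generator's own status matrix agrees with binarize_quartile
  truth <- attr(cl1, "truth")
  st <- binarize_quartile(cl1)
  expect_equal(unname(as.matrix(st[signature_kinases()])),
               unname(truth$status))

  # censoring fraction near its target
  expect_lt(abs(mean(cl1$event == 0) - cfg1$censor_rate), 0.05)

  expect_equal(as.data.frame(simulate_clinical(cfg1)),
               as.data.frame(cl1[setdiff(names(cl1), "khigh")]),
               ignore_attr = TRUE)
})

test_that("growth generator obeys its model and seed", {
  cfg <- sim_config(growth_noise_sd = 0,
                    growth_effect = c(vehicle = 1, a = 1, b = 0))
  g <- simulate_growth(cfg)
  # multiplier 1 arm grows exactly like vehicle -> TGI 0
  expect_equal(tgi(g, "a", "vehicle")$tgi, 0, tolerance = 1e-12)
  # multiplier 0 arm is static
  expect_equal(tgi(g, "b", "vehicle")$ratio_treated, 1, tolerance = 1e-12)
  g2 <- simulate_growth(cfg)
  expect_identical(g, g2)
})

test_that("sim_config validates its fields", {
  expect_error(sim_config(missing_rate_base = 1.5), "missing_rate_base")
  expect_error(sim_config(censor_rate = -0.1), "censor_rate")
  expect_error(sim_config(kinase_hr = c(BADKIN = 2)), "unknown")
  expect_error(sim_config(kinase_hr = c("K-high" = -1)), "positive")
  expect_error(sim_config(growth_effect = c(treated = 1)), "vehicle")
})
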