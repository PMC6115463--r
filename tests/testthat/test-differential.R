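mk_sites <- function(x, ids = sprintf("s%02d", seq_len(nrow(x)))) {
  tibble::tibble(site_id = ids, protein_id = "p", residue = "S", position = 8,
                 flank = strrep("A", 7) |> paste0("S", strrep("A", 7))) |>
    dplyr::bind_cols(tibble::as_tibble(x))
}

mk_groups <- function(n1, n2) {
  tibble::tibble(sample = c(sprintf("a%d", 1:n1), sprintf("b%d", 1:n2)),
                 group = rep(c("relapsed", "non-relapsed"), c(n1, n2)))
}

test_that("protein normalization divides by matched abundances", {
  x <- matrix(c(4, 8, 6, 10, 12, 2), nrow = 3)
  colnames(x) <- c("a1", "a2")
  sites <- mk_sites(x)
  sites$protein_id <- c("p1", "p1", "p2")
  ab_one <- tibble::tibble(protein_id = c("p1", "p2"), a1 = 1, a2 = 1)
  expect_equal(normalize_by_protein(sites, ab_one)[c("a1", "a2")],
               sites[c("a1", "a2")])
  # doubling one sample's abundance halves that sample's values
  ab2 <- tibble::tibble(protein_id = c("p1", "p2"), a1 = 1, a2 = 2)
  nm <- normalize_by_protein(sites, ab2)
  expect_equal(nm$a2, sites$a2 / 2)
  expect_equal(nm$a1, sites$a1)
  # 3 x 2 hand-computed quotient
  ab3 <- tibble::tibble(protein_id = c("p1", "p2"), a1 = c(2, 3), a2 = c(4, 5))
  nm3 <- normalize_by_protein(sites, ab3)
  expect_equal(nm3$a1, c(4 / 2, 8 / 2, 6 / 3))
  expect_equal(nm3$a2, c(10 / 4, 12 / 4, 2 / 5))
  # missing abundance leaves the value missing, with a warning
  ab_na <- tibble::tibble(protein_id = "p1", a1 = 1, a2 = 1)
  expect_warning(nm4 <- normalize_by_protein(sites, ab_na), "missing")
  expect_true(all(is.na(nm4$a1[3])))
})

test_that("log2 transform maps positives and keeps zero/missing as missing", {
  x <- matrix(c(8, 0, NA, 1), nrow = 2)
  colnames(x) <- c("a1", "a2")
  lg <- log2_transform(mk_sites(x))
  expect_equal(lg$a1, c(3, NA_real_))
  expect_equal(lg$a2, c(NA_real_, 0))
  # round trip on positive values
  expect_equal(2^lg$a1[1], 8)
})

test_that("moderated test matches limma and reduces to ordinary t without shrinkage", {
  set.seed(42)
  n <- 80
  x <- matrix(rnorm(n * 10, mean = 20), n, 10)
  colnames(x) <- mk_groups(5, 5)$sample
  sites <- mk_sites(x)
  groups <- mk_groups(5, 5)

  d <- phospho_diff(sites, groups)
  # independent limma run
  design <- model.matrix(~ rep(c(1, 0), each = 5))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(d$t_mod, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(d$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
  # the fast internal statistic agrees with limma too (shared by ksea)
  internal <- phosksea:::.mod_t(x, 1:5, 6:10, shrink = TRUE)
  expect_equal(internal$t, unname(fit$t[, 2]), tolerance = 1e-8)

  # shrink = FALSE equals the textbook pooled two-sample t
  d0 <- phospho_diff(sites, groups, shrink = FALSE)
  t_hand <- apply(x, 1, function(v) {
    m1 <- mean(v[1:5]); m2 <- mean(v[6:10])
    sp <- sqrt(((4 * var(v[1:5])) + (4 * var(v[6:10]))) / 8)
    (m1 - m2) / (sp * sqrt(1 / 5 + 1 / 5))
  })
  expect_equal(d0$t_mod, unname(t_hand), tolerance = 1e-10)

  # symmetry: identical group means at large n gives t near 0 on average
  expect_lt(abs(mean(d$t_mod)), 0.2)
})

test_that("sites with under two observations per group are reported untested", {
  x <- matrix(rnorm(40, 20), 4, 10)
  colnames(x) <- mk_groups(5, 5)$sample
  x[1, 1:4] <- NA
  sites <- mk_sites(x)
  d <- phospho_diff(sites, mk_groups(5, 5))
  expect_false(d$tested[1])
  expect_true(is.na(d$q[1]) && !d$selected[1])
  expect_true(all(d$tested[2:4]))

  small <- mk_sites(matrix(rnorm(8, 20), 2, 4,
                           dimnames = list(NULL, c("a1", "a2", "a3", "b1"))))
  expect_error(phospho_diff(small, mk_groups(3, 1)), "at least 2 samples")
})

test_that("BH adjustment matches a brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("null differential selections stay at or below the nominal FDR", {
  props <- vapply(1:20, function(r) {
    cfg <- sim_config(seed = 300 + r, n_sites = 500, n_proteins = 100,
                      n_kinase_motifs = 2, n_phosphatase_motifs = 0,
                      n_sh2_motifs = 0, effect_log2fc = 0)
    sm <- simulate_site_matrix(cfg, simulate_proteome(cfg, simulate_motif_library(cfg))$sites)
    d <- phospho_diff(log2_transform(sm), attr(sm, "sample_groups"))
    mean(d$selected[d$tested])
  }, numeric(1))
  expect_lte(mean(props), 0.15 + 2 * sd(props) / sqrt(20) + 1e-9)
})

test_that("consensus clustering is degenerate-exact and recovers planted blobs", {
  set.seed(5)
  # two well-separated sample blobs over 60 sites
  n <- 60
  base <- rnorm(n, 20, 2)
  shift <- c(rep(0, n / 2), rep(6, n / 2))
  x <- cbind(
    sapply(1:6, function(i) base + shift + rnorm(n, sd = 0.3)),
    sapply(1:6, function(i) base - shift + rnorm(n, sd = 0.3)))
  colnames(x) <- sprintf("s%02d", 1:12)
  sites <- mk_sites(x)

  # degenerate resampling: one iteration, no subsampling -> 0/1 consensus
  cc1 <- consensus_cluster(sites, k_range = 2, n_iter = 1, subsample_frac = 1,
                           seed = 1)
  expect_true(all(cc1$k2$consensus %in% c(0, 1)))
  expect_true(isSymmetric(cc1$k2$consensus))
  expect_true(all(diag(cc1$k2$consensus) == 1))

  cc <- consensus_cluster(sites, k_range = 2, n_iter = 100,
                          subsample_frac = 0.8, seed = 2)
  truth <- rep(1:2, each = 6)
  got <- cc$k2$assignment
  # Adjusted Rand Index against the planted split must be exactly 1
  tab <- table(got, truth)
  ari <- function(tab) {
    a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
    cc_ <- sum(choose(colSums(tab), 2)); d <- choose(sum(tab), 2)
    (a - b * cc_ / d) / ((b + cc_) / 2 - b * cc_ / d)
  }
  expect_equal(ari(tab), 1)
  expect_true(all(cc$k2$consensus >= 0 & cc$k2$consensus <= 1, na.rm = TRUE))

  # constant-profile sample is excluded with a warning
  x2 <- x; x2[, 1] <- 5
  expect_warning(consensus_cluster(mk_sites(x2), k_range = 2, n_iter = 5,
                                   subsample_frac = 1, seed = 1),
                 "constant")
})
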