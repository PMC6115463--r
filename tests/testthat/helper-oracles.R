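# Independent brute-force oracles, deliberately naive: they re-derive the
# statistics step by step and never share code with the package internals.

# Exhaustive running-sum enrichment score: walk the whole ranked list.
es_brute <- function(metric, ids, set, weight_p = 1) {
  o <- order(-metric, ids)
  metric <- metric[o]; ids <- ids[o]
  N <- length(ids)
  hit <- ids %in% set
  K <- sum(hit)
  stopifnot(K >= 1, K < N)
  w <- abs(metric)^weight_p
  W <- sum(w[hit])
  if (W == 0) { w[hit] <- 1; W <- K }
  running <- numeric(N)
  r <- 0
  for (i in seq_len(N)) {
    r <- if (hit[i]) r + w[i] / W else r - 1 / (N - K)
    running[i] <- r
  }
  # signed supremum; |max| ties resolve toward the positive extremum
  if (max(running) >= -min(running) - 1e-12) max(running) else min(running)
}

# Step-up BH by hand.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact Cox partial log-likelihood (no ties) maximized on a grid.
cox_grid_beta <- function(time, event, x) {
  pl <- function(b) {
    s <- 0
    for (i in seq_along(time)) {
      if (event[i] == 1) {
        risk <- which(time >= time[i])
        s <- s + b * x[i] - log(sum(exp(b * x[risk])))
      }
    }
    s
  }
  coarse <- seq(-5, 5, by = 1e-3)
  b0 <- coarse[which.max(vapply(coarse, pl, numeric(1)))]
  fine <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-6)
  fine[which.max(vapply(fine, pl, numeric(1)))]
}

# small simulation configs used across tests
tiny_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_sites = 120, n_proteins = 30,
             n_samples_per_group = 6,
             n_kinase_motifs = 8, n_phosphatase_motifs = 2, n_sh2_motifs = 2,
             n_patients = 40, ...)
}
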