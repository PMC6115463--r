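# core running-sum extremum from hit positions only.
# pos: sorted 1-based ranks of the set members; w: |metric|^p at those ranks
# (same order); N: length of the ranked list. O(K) instead of O(N).
.es_core <- function(pos, w, N) {
  K <- length(pos)
  if (K == 0L) abort("empty set.")
  if (K == N) return(list(es = 0, at = NA_integer_, degenerate = TRUE))
  W <- sum(w)
  if (W == 0) { w <- rep(1, K); W <- K }
  cum <- cumsum(w) / W
  dec <- (pos - seq_len(K)) / (N - K)
  tops <- cum - dec
  bottoms <- tops - w / W
  i_max <- which.max(tops); i_min <- which.min(bottoms)
  # |max| ties (exact rational ties occur) resolve toward the positive extremum
  if (tops[i_max] >= -bottoms[i_min] - 1e-12) {
    list(es = tops[i_max], at = i_max, degenerate = FALSE)
  } else {
    list(es = bottoms[i_min], at = i_min, degenerate = FALSE)
  }
}

#' Rank phosphosites for enrichment analysis
#'
#' Orders sites by a signed metric, descending, with deterministic
#' lexicographic tie-breaking on `site_id`.
#'
#' @param tbl Tibble with `site_id` and the metric column (a
#'   [phospho_diff()] result, or any table carrying the metric).
#' @param metric `"signed_t"` (moderated t, column `t_mod`), `"log2fc"`, or
#'   the name of any numeric column of `tbl`.
#'
#' @return Tibble `site_id`, `metric`, ordered; rows with missing metric
#'   (untested sites) are dropped.
#' @export
rank_sites <- function(tbl, metric = c("signed_t", "log2fc")) {
  metric <- metric[1]
  col <- switch(metric, signed_t = "t_mod", log2fc = "log2fc", metric)
  if (!col %in% names(tbl)) abort(sprintf("metric column `%s` not found.", col))
  out <- tibble(site_id = tbl$site_id, metric = tbl[[col]])
  out <- dplyr::filter(out, !is.na(.data$metric))
  out[order(-out$metric, out$site_id), ]
}

#' Weighted running-sum enrichment score for one kinase set
#'
#' Walks the ranked list from top to bottom: set members ("hits") increment
#' the running sum by their `|metric|^weight_p` share of the set total, misses
#' decrement by `1/(N - K)`. The enrichment score is the signed supremum of
#' the running sum. A set spanning the entire list is degenerate (the miss
#' decrement is undefined) and scores 0 with a flag.
#'
#' @param ranked Ranked list from [rank_sites()].
#' @param set Character vector of member `site_id`s (must intersect the list).
#' @param weight_p Metric weight exponent (default 1, the classic weighted
#'   Kolmogorov-Smirnov statistic; 0 gives the unweighted statistic).
#'
#' @return List with `es`, `running_sum` (tibble `rank`, `site_id`, `running`,
#'   `hit`, for enrichment-plot style charts), `leading_edge` (member ids at or
#'   before the extremum for positive scores, at or after it for negative) and
#'   `degenerate`.
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  ids <- ranked$site_id
  N <- length(ids)
  inset <- ids %in% set
  if (!any(inset)) abort("set does not intersect the ranked list.")
  pos <- which(inset)
  w <- abs(ranked$metric[pos])^weight_p
  core <- .es_core(pos, w, N)
  K <- length(pos)
  # full running sum for plotting
  if (core$degenerate) {
    running <- cumsum(abs(ranked$metric)^weight_p /
                        max(sum(abs(ranked$metric)^weight_p), 1))
    le <- character()
  } else {
    W <- sum(w); if (W == 0) { w <- rep(1, K); W <- K }
    step <- rep(-1 / (N - K), N)
    step[pos] <- w / W
    running <- cumsum(step)
    le <- if (core$es >= 0) ids[pos[seq_len(core$at)]]
          else ids[pos[core$at:K]]
  }
  list(es = core$es,
       running_sum = tibble(rank = seq_len(N), site_id = ids,
                            running = running, hit = inset),
       leading_edge = le,
       degenerate = core$degenerate)
}

# positions and weights of each set under one ordering; sets_idx is a list of
# integer site indices (into the metric vector)
.es_all_sets <- function(metric, id_rank, sets_idx, weight_p) {
  N <- length(metric)
  ord <- order(-metric, id_rank)
  posvec <- integer(N); posvec[ord] <- seq_len(N)
  am <- abs(metric)^weight_p
  vapply(sets_idx, function(ix) {
    pos <- posvec[ix]
    o <- order(pos)
    .es_core(pos[o], am[ix][o], N)$es
  }, numeric(1))
}

# moderated t for many permuted group labelings at once.
# x: sites x samples (log2, NAs allowed); P: samples x B matrix, 1 = case.
# Returns sites x B matrix of moderated (or ordinary) t statistics; sites
# with <2 observations in a group under a permutation get 0 (mid-rank).
.mod_t_many <- function(x, P, shrink = TRUE) {
  a <- !is.na(x) * 1
  x0 <- ifelse(is.na(x), 0, x)
  Q <- 1 - P
  n1 <- a %*% P; n2 <- a %*% Q
  s1 <- x0 %*% P; s2 <- x0 %*% Q
  q1 <- x0^2 %*% P; q2 <- x0^2 %*% Q
  m1 <- s1 / n1; m2 <- s2 / n2
  ss <- (q1 - n1 * m1^2) + (q2 - n2 * m2^2)
  df <- n1 + n2 - 2
  ok <- n1 >= 2 & n2 >= 2
  out <- matrix(0, nrow(x), ncol(P))
  for (b in seq_len(ncol(P))) {
    kb <- ok[, b]
    s2p <- pmax(ss[kb, b] / df[kb, b], 0)
    s2post <- if (shrink) limma::squeezeVar(s2p, df = df[kb, b])$var.post else s2p
    tb <- (m1[kb, b] - m2[kb, b]) / sqrt(s2post * (1 / n1[kb, b] + 1 / n2[kb, b]))
    out[kb, b] <- tb
  }
  out
}

#' Permutation null distribution of the enrichment score
#'
#' Phenotype mode relabels the sample groups, recomputes the ranking metric
#' and rescoring for each permutation; set mode keeps the observed ranking and
#' scores random same-size site sets. Phenotype permutation requires at least
#' seven samples per group, otherwise the function falls back to set
#' permutation with a warning (small-cohort convention).
#'
#' @param sites Site tibble on the log2 scale.
#' @param groups Sample-group tibble (`sample`, `group`).
#' @param set Character vector of member site ids.
#' @param n_perm Number of permutations (> 0).
#' @param mode `"auto"`, `"phenotype"` or `"set"`.
#' @param metric,weight_p,case As in [ksea()].
#' @param seed Optional RNG seed.
#'
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
ksea_null <- function(sites, groups = NULL, set, n_perm = 1000L,
                      mode = c("auto", "phenotype", "set"),
                      metric = "signed_t", weight_p = 1, case = NULL,
                      seed = NULL) {
  mode <- match.arg(mode)
  prep <- .ksea_prepare(sites, groups, case, metric)
  run <- function() {
    .ksea_nulls(prep, list(which(prep$ids %in% set)),
                n_perm = n_perm, mode = mode,
                weight_p = weight_p)[[1]]
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

# shared preparation: log2 matrix restricted to tested sites + observed metric
.ksea_prepare <- function(sites, groups, case, metric) {
  groups <- groups %||% attr(sites, "sample_groups")
  if (is.null(groups)) abort("`groups` is required (tibble with sample, group).")
  samp <- intersect(.sample_cols(sites), groups$sample)
  g <- setNames(groups$group, groups$sample)[samp]
  lv <- unique(g)
  if (length(lv) != 2L) abort("exactly two groups are required.")
  case <- case %||% (if ("relapsed" %in% lv) "relapsed" else lv[1])
  x <- as.matrix(sites[samp])
  rownames(x) <- sites$site_id
  i1 <- which(g == case); i2 <- which(g != case)
  tested <- rowSums(!is.na(x[, i1, drop = FALSE])) >= 2 &
    rowSums(!is.na(x[, i2, drop = FALSE])) >= 2
  x <- x[tested, , drop = FALSE]
  m <- .mod_t(x, i1, i2, shrink = TRUE)
  obs_metric <- switch(metric, signed_t = m$t, log2fc = m$log2fc,
                       abort("metric must be \"signed_t\" or \"log2fc\"."))
  ids <- rownames(x)
  list(x = x, ids = ids, id_rank = rank(ids, ties.method = "first"),
       i1 = i1, i2 = i2, case = case, control = setdiff(lv, case),
       metric = metric, obs_metric = unname(obs_metric))
}

# null ES lists (one numeric vector per set) under the chosen permutation mode
.ksea_nulls <- function(prep, sets_idx, n_perm, mode, weight_p) {
  if (n_perm < 1L) abort("n_perm must be positive.")
  n1 <- length(prep$i1); n2 <- length(prep$i2)
  if (mode == "auto") {
    mode <- if (min(n1, n2) >= 7L) "phenotype" else "set"
  } else if (mode == "phenotype" && min(n1, n2) < 7L) {
    warn("fewer than 7 samples per group: falling back to set permutation.")
    mode <- "set"
  }
  N <- length(prep$ids)
  if (mode == "phenotype") {
    ncols <- n1 + n2
    P <- matrix(0, ncols, n_perm)
    for (b in seq_len(n_perm)) P[sample(ncols, n1), b] <- 1
    tmat <- .mod_t_many(prep$x, P, shrink = TRUE)
    if (prep$metric == "log2fc") {
      # group-mean difference under each relabeling
      a <- (!is.na(prep$x)) * 1; x0 <- ifelse(is.na(prep$x), 0, prep$x)
      tmat <- (x0 %*% P) / pmax(a %*% P, 1) -
        (x0 %*% (1 - P)) / pmax(a %*% (1 - P), 1)
    }
    es_mat <- matrix(NA_real_, length(sets_idx), n_perm)
    for (b in seq_len(n_perm)) {
      es_mat[, b] <- .es_all_sets(tmat[, b], prep$id_rank, sets_idx, weight_p)
    }
    lapply(seq_len(nrow(es_mat)), function(i) es_mat[i, ])
  } else {
    ord <- order(-prep$obs_metric, prep$id_rank)
    am <- abs(prep$obs_metric)^weight_p
    am_ord <- am[ord]
    sizes <- lengths(sets_idx)
    null_by_size <- lapply(unique(sizes), function(K) {
      vapply(seq_len(n_perm), function(b) {
        pos <- sort(sample(N, K))
        .es_core(pos, am_ord[pos], N)$es
      }, numeric(1))
    })
    names(null_by_size) <- as.character(unique(sizes))
    lapply(sizes, function(K) null_by_size[[as.character(K)]])
  }
}

#' Kinase-set enrichment analysis (KSEA)
#'
#' The full GSEA-style procedure on phosphosites: sites are ranked by a signed
#' group-contrast metric (moderated t by default), each kinase's substrate set
#' is scored with the weighted running-sum enrichment statistic, a permutation
#' null yields nominal p-values, sign-matched normalized enrichment scores
#' (NES), and FDR q-values computed over the pooled signed-NES null. Kinase,
#' phosphatase and SH2 motif sets are all scored identically and keep their
#' category label.
#'
#' @param sites Site tibble on the log2 scale (e.g. from [log2_transform()]).
#' @param groups Sample-group tibble (`sample`, `group`); defaults to the
#'   `sample_groups` attribute.
#' @param sets Either a motif library tibble (matched against the sites'
#'   flanking windows via [build_kinase_sets()]) or a membership tibble with
#'   columns `kinase` and `site_id`.
#' @param metric Ranking metric: `"signed_t"` (default) or `"log2fc"`.
#' @param weight_p Weight exponent of the running-sum statistic (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param mode Permutation mode (`"auto"` picks phenotype permutation at >= 7
#'   samples per group, set permutation otherwise).
#' @param min_size,max_size Substrate-set size bounds when `sets` is a motif
#'   library.
#' @param case Case group name (positive scores mean case-enriched); defaults
#'   to `"relapsed"` when present.
#' @param fdr,fdr_relaxed Strict and relaxed significance boundaries on the
#'   q-value (defaults 0.05 and 0.25).
#' @param seed Optional RNG seed for the permutations.
#'
#' @return A tibble of class `ksea_result`: `kinase`, `category`, `size`,
#'   `es`, `nes`, `p`, `q`, `direction`, `significant` (q < `fdr`), `relaxed`
#'   (q < `fdr_relaxed`), `degenerate` and list-column `leading_edge`, sorted
#'   by decreasing NES. The ranked list and memberships are attached as
#'   attributes `ranked` and `memberships` for plotting.
#' @export
ksea <- function(sites, groups = NULL, sets, metric = c("signed_t", "log2fc"),
                 weight_p = 1, n_perm = 1000L,
                 mode = c("auto", "phenotype", "set"),
                 min_size = 5L, max_size = 500L, case = NULL,
                 fdr = 0.05, fdr_relaxed = 0.25, seed = NULL) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (n_perm < 1L) abort("n_perm must be positive.")
  run <- function() {
    prep <- .ksea_prepare(sites, groups, case, metric)
    if (all(c("name", "category", "pos_01") %in% names(sets))) {
      memb <- build_kinase_sets(sites, sets, min_size = min_size,
                                max_size = max_size)
    } else if (all(c("kinase", "site_id") %in% names(sets))) {
      memb <- sets
      if (!("category" %in% names(memb))) memb$category <- NA_character_
    } else {
      abort("`sets` must be a motif library or a (kinase, site_id) table.")
    }
    memb <- dplyr::filter(memb, .data$site_id %in% prep$ids)
    if (!nrow(memb)) abort("no substrate set intersects the tested sites.")
    split_sets <- split(memb$site_id, memb$kinase)
    cats <- dplyr::distinct(memb, .data$kinase, .data$category)
    keep <- lengths(split_sets) >= 1L
    split_sets <- split_sets[keep]
    sets_idx <- lapply(split_sets, function(s) which(prep$ids %in% s))
    N <- length(prep$ids)
    ord <- order(-prep$obs_metric, prep$id_rank)
    posvec <- integer(N); posvec[ord] <- seq_len(N)
    am <- abs(prep$obs_metric)^weight_p
    obs <- lapply(sets_idx, function(ix) {
      pos <- posvec[ix]; o <- order(pos)
      core <- .es_core(pos[o], am[ix][o], N)
      le_idx <- if (core$degenerate) integer()
                else if (core$es >= 0) ix[o][seq_len(core$at)]
                else ix[o][core$at:length(ix)]
      list(es = core$es, degenerate = core$degenerate,
           leading_edge = prep$ids[le_idx])
    })
    es_obs <- vapply(obs, `[[`, numeric(1), "es")
    nulls <- .ksea_nulls(prep, sets_idx, n_perm = n_perm, mode = mode,
                         weight_p = weight_p)
    norm_one <- function(e, null) {
      mu_pos <- mean(null[null > 0]); mu_neg <- mean(abs(null[null < 0]))
      if (!is.finite(mu_pos) || is.nan(mu_pos)) mu_pos <- mean(abs(null))
      if (!is.finite(mu_neg) || is.nan(mu_neg)) mu_neg <- mean(abs(null))
      ifelse(e >= 0, e / mu_pos, e / mu_neg)
    }
    nes_obs <- vapply(seq_along(es_obs), function(i) {
      norm_one(es_obs[i], nulls[[i]])
    }, numeric(1))
    nes_null <- lapply(seq_along(es_obs), function(i) {
      norm_one(nulls[[i]], nulls[[i]])
    })
    p_nom <- vapply(seq_along(es_obs), function(i) {
      e <- es_obs[i]; null <- nulls[[i]]
      same <- if (e >= 0) null[null >= 0] else null[null < 0]
      (1 + sum(abs(same) >= abs(e))) / (1 + length(same))
    }, numeric(1))
    pool <- unlist(nes_null)
    q <- vapply(seq_along(nes_obs), function(i) {
      v <- nes_obs[i]
      if (length(nes_obs) == 1L) return(p_nom[i])
      if (v >= 0) {
        num <- mean(pool >= v); den_pool <- mean(pool >= 0)
        obs_frac <- sum(nes_obs >= v) / max(sum(nes_obs >= 0), 1)
      } else {
        num <- mean(pool <= v); den_pool <- mean(pool < 0)
        obs_frac <- sum(nes_obs <= v) / max(sum(nes_obs < 0), 1)
      }
      min(1, (num / max(den_pool, 1e-12)) / max(obs_frac, 1e-12))
    }, numeric(1))
    kin <- names(split_sets)
    res <- tibble(
      kinase = kin,
      category = cats$category[match(kin, cats$kinase)],
      size = lengths(sets_idx),
      es = unname(es_obs),
      nes = unname(nes_obs),
      p = unname(p_nom),
      q = unname(q),
      direction = ifelse(es_obs >= 0,
                         paste0(prep$case, "-enriched"),
                         paste0(prep$control, "-enriched")),
      significant = q < fdr,
      relaxed = q < fdr_relaxed,
      degenerate = vapply(obs, `[[`, logical(1), "degenerate"),
      leading_edge = lapply(obs, `[[`, "leading_edge"))
    res <- dplyr::arrange(res, dplyr::desc(.data$nes))
    attr(res, "ranked") <- tibble(site_id = prep$ids[ord],
                                  metric = prep$obs_metric[ord])
    attr(res, "memberships") <- memb
    attr(res, "weight_p") <- weight_p
    class(res) <- c("ksea_result", class(res))
    res
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}
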