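#' Normalize phosphosite intensities by protein abundance
#'
#' Divides each site's intensity by the abundance of its parent protein in the
#' same sample, so that phosphorylation changes are read on top of protein
#' level changes. Samples in which the protein abundance is missing keep a
#' missing site value (with a warning summarising how many values were
#' affected).
#'
#' @param sites Site tibble (annotation columns + per-sample intensities).
#' @param protein_abundance Tibble with `protein_id` and the same sample
#'   columns as `sites`; abundances must be positive where present.
#'
#' @return The site tibble with normalized intensities.
#' @export
normalize_by_protein <- function(sites, protein_abundance) {
  samp <- .sample_cols(sites)
  missing_samp <- setdiff(samp, names(protein_abundance))
  if (length(missing_samp)) {
    abort(sprintf("protein_abundance lacks sample column(s): %s",
                  paste(missing_samp, collapse = ", ")))
  }
  ab <- protein_abundance[match(sites$protein_id, protein_abundance$protein_id), samp]
  ab_mat <- as.matrix(ab)
  if (any(ab_mat <= 0, na.rm = TRUE)) abort("protein abundances must be positive.")
  x <- as.matrix(sites[samp])
  lost <- sum(!is.na(x) & is.na(ab_mat))
  if (lost > 0) {
    warn(sprintf("%d site intensities left missing: protein abundance unavailable.",
                 lost))
  }
  sites[samp] <- as_tibble(x / ab_mat)
  sites
}

#' Log2-transform site intensities
#'
#' Positive intensities are replaced by their base-2 logarithm; zeros and
#' missing values stay missing (an intensity of zero is "below detection", not
#' a measurement of zero).
#'
#' @param sites Site tibble with raw intensities.
#' @return Site tibble on the log2 scale.
#' @export
log2_transform <- function(sites) {
  samp <- .sample_cols(sites)
  for (s in samp) {
    v <- sites[[s]]
    v[!is.na(v) & v <= 0] <- NA_real_
    sites[[s]] <- log2(v)
  }
  sites
}

# fast pooled-variance moderated t for a two-group design on a matrix with NAs.
# Equals limma's lmFit+eBayes t for the same design (asserted in the tests);
# used on permuted labels inside ksea() where speed matters.
.mod_t <- function(x, g1, g2, shrink = TRUE) {
  a <- !is.na(x)
  x0 <- ifelse(a, x, 0)
  n1 <- rowSums(a[, g1, drop = FALSE]); n2 <- rowSums(a[, g2, drop = FALSE])
  s1 <- rowSums(x0[, g1, drop = FALSE]); s2 <- rowSums(x0[, g2, drop = FALSE])
  q1 <- rowSums(x0[, g1, drop = FALSE]^2); q2 <- rowSums(x0[, g2, drop = FALSE]^2)
  m1 <- s1 / n1; m2 <- s2 / n2
  ss <- (q1 - n1 * m1^2) + (q2 - n2 * m2^2)
  df <- n1 + n2 - 2
  tested <- n1 >= 2 & n2 >= 2
  s2p <- ifelse(tested, ss / pmax(df, 1), NA_real_)
  s2p <- pmax(s2p, 0)
  if (shrink) {
    sv <- limma::squeezeVar(s2p[tested], df = df[tested])
    s2post <- s2p; s2post[tested] <- sv$var.post
    df_tot <- df + ifelse(is.finite(sv$df.prior), sv$df.prior, Inf)
  } else {
    s2post <- s2p
    df_tot <- df
  }
  se <- sqrt(s2post * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  tstat[!tested] <- NA_real_
  p <- 2 * pt(-abs(tstat), df = pmin(df_tot, .Machine$double.xmax))
  list(log2fc = m1 - m2, t = tstat, p = p, df = df_tot,
       n1 = n1, n2 = n2, tested = tested)
}

#' Moderated two-group differential phosphorylation test
#'
#' Fits a two-group linear model per phosphosite on log2 intensities with
#' limma's empirical-Bayes variance shrinkage, computes two-sided moderated-t
#' p-values, adjusts them with Benjamini-Hochberg, and flags sites below the
#' FDR threshold (default 0.15) as differentially phosphorylated. Sites with
#' fewer than two observed values in either group are reported untested; no
#' imputation is performed.
#'
#' @param sites Site tibble on the log2 scale (see [log2_transform()]).
#' @param groups Tibble with columns `sample`, `group`; defaults to the
#'   `sample_groups` attribute set by [simulate_site_matrix()]. Exactly two
#'   groups; the first level (alphabetically last, i.e. "relapsed" vs
#'   "non-relapsed") can be forced with `case`.
#' @param case Name of the case group (log2 fold change is case minus
#'   control); default `"relapsed"` when present, else the first group.
#' @param fdr Selection threshold on the BH-adjusted q-value (default 0.15).
#' @param shrink If `FALSE`, skip variance shrinkage (ordinary pooled t);
#'   equivalent to a prior df of zero.
#'
#' @return Tibble `site_id`, `log2fc`, `t_mod`, `df`, `p`, `q`, `selected`,
#'   `n_case`, `n_control`, `tested`, ordered as the input.
#' @export
phospho_diff <- function(sites, groups = NULL, case = NULL, fdr = 0.15,
                         shrink = TRUE) {
  groups <- groups %||% attr(sites, "sample_groups")
  if (is.null(groups)) abort("`groups` is required (tibble with sample, group).")
  samp <- intersect(.sample_cols(sites), groups$sample)
  if (!length(samp)) abort("no sample columns match `groups$sample`.")
  g <- setNames(groups$group, groups$sample)[samp]
  lv <- unique(g)
  if (length(lv) != 2L) abort("exactly two groups are required.")
  case <- case %||% (if ("relapsed" %in% lv) "relapsed" else lv[1])
  if (!case %in% lv) abort(sprintf("case group %s not found.", case))
  ctrl <- setdiff(lv, case)
  x <- as.matrix(sites[samp])
  rownames(x) <- sites$site_id
  i1 <- which(g == case); i2 <- which(g == ctrl)
  if (length(i1) < 2L || length(i2) < 2L) {
    abort("each group needs at least 2 samples.")
  }
  if (shrink) {
    design <- stats::model.matrix(~ factor(g, levels = c(ctrl, case)))
    colnames(design) <- c("intercept", "case")
    tested <- rowSums(!is.na(x[, i1, drop = FALSE])) >= 2 &
      rowSums(!is.na(x[, i2, drop = FALSE])) >= 2
    fit <- limma::lmFit(x[tested, , drop = FALSE], design)
    fit <- limma::eBayes(fit)
    res <- list(log2fc = rep(NA_real_, nrow(x)), t = rep(NA_real_, nrow(x)),
                p = rep(NA_real_, nrow(x)), df = rep(NA_real_, nrow(x)),
                tested = tested)
    res$log2fc[tested] <- fit$coefficients[, "case"]
    res$t[tested] <- fit$t[, "case"]
    res$p[tested] <- fit$p.value[, "case"]
    res$df[tested] <- fit$df.total
    n1 <- rowSums(!is.na(x[, i1, drop = FALSE]))
    n2 <- rowSums(!is.na(x[, i2, drop = FALSE]))
  } else {
    m <- .mod_t(x, i1, i2, shrink = FALSE)
    res <- list(log2fc = m$log2fc, t = m$t, p = m$p, df = m$df, tested = m$tested)
    n1 <- m$n1; n2 <- m$n2
  }
  q <- rep(NA_real_, nrow(x))
  q[res$tested] <- p.adjust(res$p[res$tested], method = "BH")
  tibble(site_id = sites$site_id,
         log2fc = unname(res$log2fc),
         t_mod = unname(res$t),
         df = unname(res$df),
         p = unname(res$p),
         q = unname(q),
         selected = !is.na(q) & q < fdr,
         n_case = unname(n1),
         n_control = unname(n2),
         tested = unname(res$tested))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (wrapper around
#' `p.adjust(..., "BH")` with input validation).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, capped at 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Consensus clustering of sample phosphoprofiles
#'
#' Resampling-based cluster stability assessment: in each iteration a fraction
#' of the samples is drawn, the subset is clustered hierarchically (average
#' linkage) using one minus the pairwise Pearson correlation of site profiles
#' as the distance, and for every `k` the consensus matrix accumulates how
#' often each co-sampled pair lands in the same cluster. The final assignment
#' cuts a hierarchical tree of `1 - consensus`.
#'
#' @param sites Site tibble (log2 intensities).
#' @param k_range Integer vector of cluster numbers to evaluate.
#' @param n_iter Number of resampling iterations (default 1000).
#' @param subsample_frac Fraction of samples drawn per iteration (default 0.8).
#' @param seed Optional seed for the resampling.
#'
#' @return A list of class `consensus_result`, one element per `k`, each with
#'   `consensus` (sample x sample matrix) and `assignment` (named integer
#'   vector). Samples with constant (zero-variance) profiles are excluded with
#'   a warning.
#' @export
consensus_cluster <- function(sites, k_range = 2:4, n_iter = 1000L,
                              subsample_frac = 0.8, seed = NULL) {
  samp <- .sample_cols(sites)
  x <- as.matrix(sites[samp])
  sds <- apply(x, 2, sd, na.rm = TRUE)
  const <- is.na(sds) | sds == 0
  if (any(const)) {
    warn(sprintf("excluding constant-profile sample(s): %s",
                 paste(samp[const], collapse = ", ")))
    samp <- samp[!const]
    x <- x[, !const, drop = FALSE]
  }
  ns <- length(samp)
  if (ns < 2L * max(k_range)) abort("need at least 2 * max(k_range) samples.")
  n_draw <- max(2L, ceiling(subsample_frac * ns))
  run <- function() {
    hit <- lapply(k_range, function(k) matrix(0, ns, ns))
    names(hit) <- as.character(k_range)
    tog <- matrix(0, ns, ns)
    for (it in seq_len(n_iter)) {
      idx <- sort(sample(ns, n_draw))
      cc <- suppressWarnings(cor(x[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      hc <- hclust(as.dist(1 - cc), method = "average")
      tog[idx, idx] <- tog[idx, idx] + 1
      for (k in k_range) {
        cl <- cutree(hc, k = min(k, length(idx)))
        same <- outer(cl, cl, "==") * 1
        hit[[as.character(k)]][idx, idx] <- hit[[as.character(k)]][idx, idx] + same
      }
    }
    out <- lapply(k_range, function(k) {
      cons <- hit[[as.character(k)]] / pmax(tog, 1)
      cons[tog == 0] <- NA_real_
      diag(cons) <- ifelse(diag(tog) > 0, 1, NA_real_)
      dimnames(cons) <- list(samp, samp)
      cfill <- cons; cfill[is.na(cfill)] <- 0.5
      hc <- hclust(as.dist(1 - cfill), method = "average")
      list(consensus = cons, assignment = setNames(cutree(hc, k = k), samp))
    })
    names(out) <- paste0("k", k_range)
    structure(out, class = "consensus_result")
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}
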