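#' Immunohistochemistry H-score
#'
#' Combines the percentages of tissue area with high, medium and low staining
#' into a single score: `(high*3 + med*2 + low*1) / 100`, giving a value in
#' `[0, 3]`. Vectorized over patients.
#'
#' @param area_pct_high,area_pct_med,area_pct_low Staining area percentages
#'   (each >= 0, jointly summing to at most 100 per patient).
#' @return Numeric H-scores in `[0, 3]`.
#' @export
#' @examples
#' h_score(50, 30, 20) # 2.3
h_score <- function(area_pct_high, area_pct_med, area_pct_low) {
  if (any(c(area_pct_high, area_pct_med, area_pct_low) < 0, na.rm = TRUE)) {
    abort("staining area percentages must be >= 0.")
  }
  tot <- area_pct_high + area_pct_med + area_pct_low
  if (any(tot > 100 + 1e-9, na.rm = TRUE)) {
    abort("staining area percentages must sum to at most 100.")
  }
  (area_pct_high * 3 + area_pct_med * 2 + area_pct_low * 1) / 100
}

#' Binarize kinase H-scores at the cohort 75th percentile
#'
#' Per kinase, computes the cohort 75th percentile (linear-interpolation
#' quantile) of the H-scores and encodes patients strictly above it as 1,
#' everyone else (including ties at the threshold) as 0. With continuous
#' scores roughly 25% of patients are positive per kinase.
#'
#' @param clinical Tibble with `patient_id` and per-kinase H-score columns.
#' @param kinases Kinase names; H-scores are read from columns `hs_<kinase>`
#'   (or columns named exactly after the kinase). Default: the six signature
#'   kinases.
#' @param probs Quantile used as the threshold (default 0.75).
#'
#' @return A tibble of class `kinase_status`: `patient_id` plus one 0/1 column
#'   per kinase. Per-kinase thresholds and the quantile definition are stored
#'   in the `derivation` attribute.
#' @export
binarize_quartile <- function(clinical, kinases = signature_kinases(),
                              probs = 0.75) {
  if (nrow(clinical) < 4L) abort("need at least 4 patients to take quartiles.")
  cols <- vapply(kinases, function(k) {
    if (paste0("hs_", k) %in% names(clinical)) paste0("hs_", k)
    else if (k %in% names(clinical)) k
    else abort(sprintf("no H-score column for kinase %s.", k))
  }, character(1))
  out <- tibble(patient_id = clinical$patient_id)
  thresholds <- numeric(length(kinases))
  for (i in seq_along(kinases)) {
    v <- clinical[[cols[i]]]
    thr <- unname(quantile(v, probs = probs, type = 7, na.rm = TRUE))
    thresholds[i] <- thr
    out[[kinases[i]]] <- as.integer(!is.na(v) & v > thr)
  }
  attr(out, "derivation") <- list(
    thresholds = setNames(thresholds, kinases),
    quantile = probs, quantile_type = 7, ties = "strictly above -> 1")
  class(out) <- c("kinase_status", class(out))
  out
}

#' K-high indicator
#'
#' A patient is K-high (1) when one or more of the six signature kinases has a
#' status of 1 (H-score above the cohort 75th percentile), and 0 only when all
#' six are below.
#'
#' @param status A [binarize_quartile()] status tibble.
#' @param kinases Kinase columns to combine (default: all six signature
#'   kinases, which must be present).
#' @return Integer vector (0/1), one per patient, named by `patient_id`.
#' @export
k_high <- function(status, kinases = signature_kinases()) {
  missing_cols <- setdiff(kinases, names(status))
  if (length(missing_cols)) {
    abort(sprintf("status matrix lacks kinase column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(status[kinases])
  setNames(as.integer(rowSums(m) >= 1L), status$patient_id)
}

#' K-test combination variables
#'
#' Builds per-patient indicators equal to the logical OR of the statuses over
#' chosen kinase subsets (size 2-5 combinations used to benchmark K-high).
#'
#' @param status A [binarize_quartile()] status tibble.
#' @param combos Named list of character vectors, each a nonempty subset of
#'   the status kinase columns.
#' @return Tibble `patient_id` plus one 0/1 column per combination.
#' @export
k_test_variables <- function(status, combos) {
  if (!length(combos)) abort("`combos` must list at least one kinase subset.")
  if (is.null(names(combos)) || any(!nzchar(names(combos)))) {
    names(combos) <- paste0("K-test_", seq_along(combos))
  }
  out <- tibble(patient_id = status$patient_id)
  for (nm in names(combos)) {
    ks <- combos[[nm]]
    if (!length(ks)) abort(sprintf("combination %s is empty.", nm))
    missing_cols <- setdiff(ks, names(status))
    if (length(missing_cols)) {
      abort(sprintf("combination %s references unknown kinase(s): %s",
                    nm, paste(missing_cols, collapse = ", ")))
    }
    out[[nm]] <- as.integer(rowSums(as.matrix(status[ks])) >= 1L)
  }
  out
}

#' Enumerate kinase activation patterns
#'
#' Renders each patient's per-kinase statuses as a bitstring in the fixed
#' signature order and tabulates the distinct observed patterns, their patient
#' counts, relapse counts, and whether a pattern occurs exclusively among
#' relapsed patients. With k kinases the theoretical pattern space has `2^k`
#' members (64 for the six-kinase signature).
#'
#' @param status A [binarize_quartile()] status tibble (complete, no missing
#'   statuses).
#' @param relapse Optional 0/1 vector of relapse events aligned with the rows
#'   of `status` (e.g. the clinical `event` column).
#' @param kinases Kinase order used for the bitstring (default: the six
#'   signature kinases).
#'
#' @return A tibble of class `pattern_table`: `pattern`, `n`, `n_relapse`,
#'   `exclusive_to_relapsed`, sorted by decreasing count. Attributes
#'   `n_possible` (`2^k`) and `n_observed`.
#' @export
#' @examples
#' status <- tibble::tibble(patient_id = c("a", "b", "c"),
#'                          K1 = c(0L, 1L, 1L), K2 = c(0L, 0L, 0L))
#' enumerate_patterns(status, kinases = c("K1", "K2"))
enumerate_patterns <- function(status, relapse = NULL,
                               kinases = signature_kinases()) {
  missing_cols <- setdiff(kinases, names(status))
  if (length(missing_cols)) {
    abort(sprintf("status matrix lacks kinase column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(status[kinases])
  if (any(is.na(m))) abort("status matrix must be complete (no missing values).")
  pat <- apply(m, 1, paste, collapse = "")
  if (is.null(relapse)) relapse <- rep(NA_integer_, nrow(status))
  tab <- tibble(pattern = pat, relapse = relapse) |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(n = dplyr::n(),
                     n_relapse = sum(.data$relapse, na.rm = TRUE),
                     exclusive_to_relapsed =
                       all(!is.na(.data$relapse)) && all(.data$relapse == 1),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$pattern)
  attr(tab, "n_possible") <- as.integer(2^length(kinases))
  attr(tab, "n_observed") <- nrow(tab)
  attr(tab, "kinase_order") <- kinases
  class(tab) <- c("pattern_table", class(tab))
  tab
}

#' @export
print.pattern_table <- function(x, ...) {
  cat(sprintf("Kinase activation patterns: %d observed out of %d possible\n",
              attr(x, "n_observed"), attr(x, "n_possible")))
  NextMethod()
}

#' Pairwise kinase co-linearity
#'
#' Pairwise Pearson correlation matrix of the per-kinase H-scores, used to
#' check that the signature kinases carry non-redundant information.
#'
#' @param clinical Tibble with H-score columns.
#' @param kinases Kinase names (columns `hs_<kinase>` or bare names).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
kinase_colinearity <- function(clinical, kinases = signature_kinases()) {
  cols <- vapply(kinases, function(k) {
    if (paste0("hs_", k) %in% names(clinical)) paste0("hs_", k) else k
  }, character(1))
  missing_cols <- setdiff(cols, names(clinical))
  if (length(missing_cols)) {
    abort(sprintf("missing H-score column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(clinical[cols])
  colnames(m) <- kinases
  cor(m, use = "pairwise.complete.obs")
}

#' Overlay mutation profiles on kinase activation patterns
#'
#' Pure tabulation: for every observed kinase activation pattern, lists the
#' distinct mutation profiles (bitstrings over the supplied genes) found among
#' its patients and their counts. No inference is performed.
#'
#' @param status A [binarize_quartile()] status tibble.
#' @param mutations Tibble with `patient_id` and one 0/1 column per gene.
#' @param kinases Kinase order for the pattern bitstring.
#' @return Tibble `pattern`, `mutation_profile`, `n`.
#' @export
overlay_mutations <- function(status, mutations,
                              kinases = signature_kinases()) {
  genes <- setdiff(names(mutations), "patient_id")
  if (!length(genes)) abort("mutation table has no gene columns.")
  missing_cols <- setdiff(kinases, names(status))
  if (length(missing_cols)) {
    abort(sprintf("status matrix lacks kinase column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  joined <- dplyr::inner_join(status, mutations, by = "patient_id")
  if (!nrow(joined)) abort("no patients shared between status and mutations.")
  pat <- apply(as.matrix(joined[kinases]), 1, paste, collapse = "")
  prof <- apply(as.matrix(joined[genes]), 1, paste, collapse = "")
  tibble(pattern = pat, mutation_profile = prof) |>
    dplyr::count(.data$pattern, .data$mutation_profile, name = "n") |>
    dplyr::arrange(.data$pattern, dplyr::desc(.data$n))
}
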