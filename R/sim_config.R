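#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. Defaults emulate the study design the pipeline targets: a discovery
#' cohort of relapsed vs non-relapsed tumors profiled at 1000 phosphosites, a
#' motif library of 327 linear motifs (224 kinase, 23 phosphatase, 80 SH2), a
#' 113-patient validation cohort with six signature kinases scored by
#' immunohistochemistry, and exponential xenograft growth curves.
#'
#' @param seed Integer seed; a fixed seed makes every generator byte-identical.
#' @param n_samples_per_group Tumors per group ("relapsed" / "non-relapsed").
#' @param n_proteins,n_sites Proteome size and number of quantified phosphosites.
#' @param n_kinase_motifs,n_phosphatase_motifs,n_sh2_motifs Motif counts per
#'   category (defaults 224 / 23 / 80, i.e. 327 total).
#' @param active_kinases Character vector of motif names whose substrates carry
#'   a planted intensity shift in the relapsed group.
#' @param substrates_per_active Planted substrate sites per active kinase.
#' @param effect_log2fc Planted mean log2 shift for substrates of active
#'   kinases (relapsed minus non-relapsed).
#' @param noise_sd Standard deviation of log2 intensities around the site mean.
#' @param missing_rate_base Overall dropout target in `[0,1]`; dropout is
#'   intensity-dependent (more likely at low intensity).
#' @param n_patients Clinical cohort size.
#' @param kinase_hr Named numeric vector of planted hazard ratios. Names must
#'   be signature kinases or the special name `"K-high"` (hazard multiplied by
#'   the value when the patient's K-high indicator is 1).
#' @param censor_rate Target fraction of censored patients in `[0,1]`.
#' @param baseline_hazard Baseline monthly relapse hazard.
#' @param growth_rate_vehicle Tumor growth rate (per day) in the vehicle arm.
#' @param growth_effect Named numeric vector of per-arm growth-rate multipliers
#'   (must include `"vehicle" = 1`).
#' @param n_animals_per_arm,growth_days,growth_noise_sd Animals per arm,
#'   measurement days, and lognormal measurement noise (sdlog).
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, active_kinases = "KIN_001")
#' cfg$n_sites
sim_config <- function(seed = 1L,
                       n_samples_per_group = 10L,
                       n_proteins = 200L,
                       n_sites = 1000L,
                       n_kinase_motifs = 224L,
                       n_phosphatase_motifs = 23L,
                       n_sh2_motifs = 80L,
                       active_kinases = character(),
                       substrates_per_active = 30L,
                       effect_log2fc = 2,
                       noise_sd = 0.3,
                       missing_rate_base = 0.1,
                       n_patients = 113L,
                       kinase_hr = c("K-high" = 9.22),
                       censor_rate = 0.5,
                       baseline_hazard = 0.004,
                       growth_rate_vehicle = 0.1,
                       growth_effect = c(vehicle = 1, treated = 0.4),
                       n_animals_per_arm = 6L,
                       growth_days = seq(0, 21, by = 3),
                       growth_noise_sd = 0.05) {
  .assert_scalar_number(seed, "seed")
  .assert_scalar_number(n_samples_per_group, "n_samples_per_group", lower = 1)
  .assert_scalar_number(n_proteins, "n_proteins", lower = 0)
  .assert_scalar_number(n_sites, "n_sites", lower = 0)
  .assert_scalar_number(n_kinase_motifs, "n_kinase_motifs", lower = 0)
  .assert_scalar_number(n_phosphatase_motifs, "n_phosphatase_motifs", lower = 0)
  .assert_scalar_number(n_sh2_motifs, "n_sh2_motifs", lower = 0)
  .assert_scalar_number(effect_log2fc, "effect_log2fc")
  .assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  .assert_scalar_number(missing_rate_base, "missing_rate_base", 0, 1)
  .assert_scalar_number(censor_rate, "censor_rate", 0, 1)
  .assert_scalar_number(baseline_hazard, "baseline_hazard", lower = 1e-12)
  .assert_scalar_number(n_patients, "n_patients", lower = 0)
  if (length(kinase_hr)) {
    if (is.null(names(kinase_hr)) || any(!nzchar(names(kinase_hr)))) {
      abort("`kinase_hr` must be a named numeric vector.")
    }
    bad <- setdiff(names(kinase_hr), c(SIGNATURE_KINASES, "K-high"))
    if (length(bad)) {
      abort(sprintf("`kinase_hr` names must be signature kinases or \"K-high\"; unknown: %s",
                    paste(bad, collapse = ", ")))
    }
    if (any(kinase_hr <= 0)) abort("hazard ratios must be positive.")
  }
  if (!("vehicle" %in% names(growth_effect))) {
    abort("`growth_effect` must include a \"vehicle\" arm.")
  }
  structure(
    list(seed = as.integer(seed),
         n_samples_per_group = as.integer(n_samples_per_group),
         n_proteins = as.integer(n_proteins),
         n_sites = as.integer(n_sites),
         n_kinase_motifs = as.integer(n_kinase_motifs),
         n_phosphatase_motifs = as.integer(n_phosphatase_motifs),
         n_sh2_motifs = as.integer(n_sh2_motifs),
         active_kinases = as.character(active_kinases),
         substrates_per_active = as.integer(substrates_per_active),
         effect_log2fc = effect_log2fc,
         noise_sd = noise_sd,
         missing_rate_base = missing_rate_base,
         n_patients = as.integer(n_patients),
         kinase_hr = kinase_hr,
         censor_rate = censor_rate,
         baseline_hazard = baseline_hazard,
         growth_rate_vehicle = growth_rate_vehicle,
         growth_effect = growth_effect,
         n_animals_per_arm = as.integer(n_animals_per_arm),
         growth_days = growth_days,
         growth_noise_sd = growth_noise_sd),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d+%d samples | %d sites on %d proteins\n",
              x$seed, x$n_samples_per_group, x$n_samples_per_group,
              x$n_sites, x$n_proteins))
  cat(sprintf("  motifs: %d kinase, %d phosphatase, %d SH2\n",
              x$n_kinase_motifs, x$n_phosphatase_motifs, x$n_sh2_motifs))
  if (length(x$active_kinases)) {
    cat(sprintf("  planted: %s (log2FC %.2g, %d substrates each)\n",
                paste(x$active_kinases, collapse = ", "),
                x$effect_log2fc, x$substrates_per_active))
  }
  cat(sprintf("  clinical: n = %d, censor ~ %.0f%%\n",
              x$n_patients, 100 * x$censor_rate))
  invisible(x)
}
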