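#' Tumor volume from caliper diameters
#'
#' Ellipsoid approximation `V = D * d^2 / 2` where `D` is the largest and `d`
#' the shortest diameter (mm). Note: some printed renderings of this formula
#' corrupt the exponent/operator typographically; the implemented form is the
#' standard caliper approximation consistent with the diameter roles.
#'
#' @param D Largest diameter (mm); must satisfy `D >= d`.
#' @param d Shortest diameter (mm); must be > 0.
#' @return Volume in mm^3. Vectorized.
#' @export
#' @examples
#' tumor_volume(10, 5) # 125
tumor_volume <- function(D, d) {
  if (any(d <= 0, na.rm = TRUE)) abort("shortest diameter d must be > 0.")
  if (any(D < d, na.rm = TRUE)) abort("largest diameter D must be >= d.")
  D * d^2 / 2
}

#' Tumor growth inhibition (TGI)
#'
#' `TGI = (1 - (TF/T0)_treated / (TF/T0)_vehicle) * 100`, where `TF/T0` is the
#' ratio of a treatment arm's mean tumor volume at the final and initial time
#' points. `tF` defaults to the last day at which both arms were measured
#' (i.e. the last time point of the arm terminated first). A static treated
#' tumor under a doubling vehicle scores 50; regression below the starting
#' volume pushes TGI above the vehicle-matched ceiling toward 100.
#'
#' @param growth Growth tibble (`animal_id`, `arm`, `day`, `volume`; see
#'   [read_growth()] — diameters are converted with [tumor_volume()] if no
#'   volume column is present).
#' @param treated,vehicle Arm labels.
#' @param t0,tF Initial and final days; defaults: first common day and last
#'   common day of the two arms.
#' @param ratio How the arm growth ratio is formed: `"of_means"` (ratio of arm
#'   mean volumes, default) or `"mean_of_ratios"` (mean of per-animal ratios).
#'
#' @return A tibble of class `tgi_result`: `arm`, `t0`, `tF`, `ratio_treated`,
#'   `ratio_vehicle`, `tgi`.
#' @export
#' @examples
#' g <- simulate_growth(sim_config(growth_noise_sd = 0))
#' tgi(g, treated = "treated", vehicle = "vehicle")
tgi <- function(growth, treated, vehicle, t0 = NULL, tF = NULL,
                ratio = c("of_means", "mean_of_ratios")) {
  ratio <- match.arg(ratio)
  if (!("volume" %in% names(growth))) {
    if (!all(c("D", "d") %in% names(growth))) {
      abort("growth table needs `volume` or `D`/`d` columns.")
    }
    growth$volume <- tumor_volume(growth$D, growth$d)
  }
  g <- dplyr::filter(growth, .data$arm %in% c(treated, vehicle))
  if (!nrow(g)) abort("arms not found in growth table.")
  common <- intersect(g$day[g$arm == treated], g$day[g$arm == vehicle])
  if (!length(common)) abort("arms share no measurement day.")
  t0 <- t0 %||% min(common)
  tF <- tF %||% max(common)
  arm_ratio <- function(a) {
    v0 <- g |> dplyr::filter(.data$arm == a, .data$day == t0)
    vF <- g |> dplyr::filter(.data$arm == a, .data$day == tF)
    if (!nrow(v0) || !nrow(vF)) {
      abort(sprintf("arm %s lacks measurements at day %s or %s.", a, t0, tF))
    }
    missing_an <- union(setdiff(vF$animal_id, v0$animal_id),
                        setdiff(v0$animal_id, vF$animal_id))
    if (ratio == "of_means") {
      mean(vF$volume) / mean(v0$volume)
    } else {
      if (length(missing_an)) {
        abort(sprintf("animal(s) missing a time point in arm %s: %s",
                      a, paste(missing_an, collapse = ", ")))
      }
      mean(vF$volume[match(v0$animal_id, vF$animal_id)] / v0$volume)
    }
  }
  r_t <- arm_ratio(treated)
  r_v <- arm_ratio(vehicle)
  if (r_v <= 0) abort("vehicle growth ratio must be > 0.")
  out <- tibble(arm = treated, t0 = t0, tF = tF,
                ratio_treated = r_t, ratio_vehicle = r_v,
                tgi = (1 - r_t / r_v) * 100)
  class(out) <- c("tgi_result", class(out))
  out
}

#' Compare tumor burdens between two arms
#'
#' Welch (unequal-variance) two-sample t-test on per-animal tumor volumes at a
#' chosen day.
#'
#' @param growth Growth tibble.
#' @param arm1,arm2 Arm labels; the statistic is `mean(arm1) - mean(arm2)`
#'   scaled.
#' @param day Measurement day (default: last common day).
#' @return Tibble `day`, `t`, `df`, `p`, `mean_arm1`, `mean_arm2`.
#' @export
arm_compare <- function(growth, arm1, arm2, day = NULL) {
  g <- dplyr::filter(growth, .data$arm %in% c(arm1, arm2))
  day <- day %||% max(intersect(g$day[g$arm == arm1], g$day[g$arm == arm2]))
  v1 <- g$volume[g$arm == arm1 & g$day == day]
  v2 <- g$volume[g$arm == arm2 & g$day == day]
  if (length(v1) < 2L || length(v2) < 2L) {
    abort("need at least 2 animals per arm at the chosen day.")
  }
  tt <- t.test(v1, v2, var.equal = FALSE)
  tibble(day = day, t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_arm1 = mean(v1), mean_arm2 = mean(v2))
}
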