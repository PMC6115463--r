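#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a KSEA result
#'
#' @param x A [ksea()] result.
#' @param ... Unused.
#' @return Tibble with one row per kinase set (leading edge flattened to a
#'   comma-separated string).
#' @export
tidy.ksea_result <- function(x, ...) {
  out <- as_tibble(x)
  out$leading_edge <- vapply(out$leading_edge, paste, character(1), collapse = ",")
  out
}

#' @rdname tidy.ksea_result
#' @return `glance()`: one-row summary (sets scored, significant counts).
#' @export
glance.ksea_result <- function(x, ...) {
  tibble(n_sets = nrow(x),
         n_significant = sum(x$significant),
         n_relaxed = sum(x$relaxed),
         top_kinase = if (nrow(x)) x$kinase[which.max(x$nes)] else NA_character_,
         top_nes = if (nrow(x)) max(x$nes) else NA_real_)
}

#' Tidy a Cox fit
#'
#' @param x A [cox_fit()] result.
#' @param ... Unused.
#' @return Tibble of per-term estimates (`term`, `beta`, `hr`, `se`, `z`, `p`).
#' @export
tidy.cox_fit <- function(x, ...) x$coef

#' @rdname tidy.cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event, converged = x$converged,
         unstable = x$unstable)
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x A [km_fit()] result.
#' @param ... Unused.
#' @return The per-group survival curve tibble.
#' @export
tidy.km_fit <- function(x, ...) x$curve

#' @rdname tidy.km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tidyr::pivot_wider(x$median, names_from = "group",
                     values_from = "median_time",
                     names_prefix = "median_")
}
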