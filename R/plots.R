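#' Enrichment running-sum plot for one kinase
#'
#' GSEA-style chart: the running enrichment score across the ranked site list
#' with a rug of substrate positions ("hits").
#'
#' @param result A [ksea()] result.
#' @param kinase Kinase (motif) name present in the result.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(result, kinase) {
  stopifnot(inherits(result, "ksea_result"))
  ranked <- attr(result, "ranked")
  memb <- attr(result, "memberships")
  set <- memb$site_id[memb$kinase == kinase]
  if (!length(set)) abort(sprintf("kinase %s not in result.", kinase))
  es <- enrichment_score(ranked, set, weight_p = attr(result, "weight_p") %||% 1)
  rs <- es$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = rs[rs$hit, ], sides = "b", colour = "black",
                      length = ggplot2::unit(0.04, "npc")) +
    ggplot2::labs(title = sprintf("%s  (ES = %.3f)", kinase, es$es),
                  x = "rank in site list", y = "running enrichment score") +
    ggplot2::theme_minimal()
}

#' @rdname plot_enrichment
#' @param object,x Objects being plotted.
#' @param ... Unused.
#' @export
autoplot.ksea_result <- function(object, ...) {
  df <- as_tibble(object)
  df$kinase <- factor(df$kinase, levels = rev(df$kinase))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$kinase,
                                   fill = .data$q)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "#d7301f", high = "#fdcc8a",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL, fill = "FDR q") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curve plot
#'
#' Step plot of the survival curves per group.
#'
#' @param object A [km_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_fit <- function(object, ...) {
  cv <- object$curve |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, surv = 1), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "relapse-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kinase activation pattern bar chart
#'
#' Observed pattern frequencies, relapsed-exclusive patterns highlighted.
#'
#' @param object A [enumerate_patterns()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pattern_table <- function(object, ...) {
  df <- as_tibble(object)
  df$pattern <- factor(df$pattern, levels = df$pattern)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$n,
                                   fill = .data$exclusive_to_relapsed)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey50", `TRUE` = "#d7301f")) +
    ggplot2::labs(x = "kinase activation pattern", y = "patients",
                  fill = "relapsed-only") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Tumor growth curve plot
#'
#' Mean volume per arm over time with per-animal traces.
#'
#' @param growth Growth tibble.
#' @return A ggplot object.
#' @export
plot_growth <- function(growth) {
  ggplot2::ggplot(growth, ggplot2::aes(x = .data$day, y = .data$volume,
                                       colour = .data$arm)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$animal_id), alpha = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1.1) +
    ggplot2::labs(x = "day", y = expression(volume ~ (mm^3)), colour = NULL) +
    ggplot2::theme_minimal()
}
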