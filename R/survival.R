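#' Kaplan-Meier estimate of relapse-free survival
#'
#' Product-limit estimator (via `survival::survfit`), optionally stratified by
#' a grouping variable; at tied times events precede censorings, per the
#' standard convention. The median is the smallest time at which the survival
#' curve drops to 0.5 or below, reported as `NA` ("not reached") otherwise.
#'
#' @param data Data frame of patient records.
#' @param time,event Column names of the follow-up time (> 0) and the 0/1
#'   event indicator.
#' @param group Optional column name of a stratifying variable.
#'
#' @return A list of class `km_fit` with `curve` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `surv`), `median` (tibble `group`,
#'   `median_time`; `NA` = not reached), and the underlying `survfit` object.
#' @export
km_fit <- function(data, time = "time", event = "event", group = NULL) {
  tt <- data[[time]]; ev <- data[[event]]
  if (any(tt <= 0)) abort("times must be > 0.")
  if (!all(ev %in% c(0, 1))) abort("event must be 0/1.")
  df <- data.frame(.time = tt, .event = ev)
  if (is.null(group)) {
    df$.group <- "all"
  } else {
    df$.group <- as.character(data[[group]])
  }
  fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
  sm <- summary(fit, censored = FALSE)
  grp <- if (length(sm$time) == 0L) character()
         else if (is.null(sm$strata)) rep(unique(df$.group)[1], length(sm$time))
         else sub("^\\.group=", "", as.character(sm$strata))
  curve <- tibble(group = grp,
                  time = as.numeric(sm$time),
                  n_risk = as.numeric(sm$n.risk),
                  n_event = as.numeric(sm$n.event),
                  surv = as.numeric(sm$surv))
  med <- purrr::map_dfr(sort(unique(df$.group)), function(g) {
    hit <- curve$time[curve$group == g & curve$surv <= 0.5]
    tibble(group = g, median_time = if (length(hit)) min(hit) else NA_real_)
  })
  structure(list(curve = curve, median = med, survfit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit>\n")
  print(x$median)
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square across two or more
#' groups (via `survival::survdiff`), with `groups - 1` degrees of freedom.
#'
#' @inheritParams km_fit
#' @param group Column name of the grouping variable (required).
#' @return Tibble with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(data, time = "time", event = "event", group) {
  g <- as.factor(data[[group]])
  if (nlevels(g) < 2L) abort("log-rank test needs at least 2 groups.")
  df <- data.frame(.time = data[[time]], .event = data[[event]], .group = g)
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
  df_stat <- length(sd$n) - 1L
  tibble(chisq = unname(sd$chisq), df = df_stat,
         p = stats::pchisq(sd$chisq, df_stat, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Multivariate Cox partial-likelihood fit (via `survival::coxph`, Efron
#' approximation for tied event times) of a kinase indicator adjusted for T and
#' N status, grade, and age. Ordinal T/N/G enter as numeric scores by default.
#'
#' @param data Data frame of patient records.
#' @param covariates Character vector of covariate column names; the first is
#'   conventionally the kinase indicator of interest.
#' @param time,event Column names of follow-up time and event indicator.
#' @param ties Tie handling (`"efron"` default, or `"breslow"`).
#'
#' @return A list of class `cox_fit` with `coef` (tibble `term`, `beta`, `hr`,
#'   `se`, `z`, `p`), `n`, `n_event`, `converged` and the `coxph` object.
#'   Fits with fewer events than covariates are flagged `unstable`.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    ties = "efron") {
  missing_cols <- setdiff(c(covariates, time, event), names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2L) {
      abort(sprintf("covariate %s is constant.", cv))
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  s <- summary(fit)
  co <- tibble(term = rownames(s$coefficients),
               beta = unname(s$coefficients[, "coef"]),
               hr = unname(s$coefficients[, "exp(coef)"]),
               se = unname(s$coefficients[, "se(coef)"]),
               z = unname(s$coefficients[, "z"]),
               p = unname(s$coefficients[, "Pr(>|z|)"]))
  n_event <- sum(data[[event]])
  unstable <- n_event < length(covariates)
  if (unstable) warn("fewer events than covariates: estimates may be unstable.")
  structure(list(coef = co, n = nrow(data), n_event = n_event,
                 unstable = unstable,
                 converged = fit$iter < 100, coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d\n", x$n, x$n_event))
  print(x$coef)
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for each of the m p-values.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
#' @examples
#' bonferroni(c(0.01, 0.04))
bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "bonferroni")
}

#' Per-kinase prognostic screen
#'
#' For each kinase indicator (and any derived variable such as K-high), runs
#' the univariate log-rank test and a multivariate Cox model adjusted for T,
#' N, grade and age, then Bonferroni-adjusts the Cox p-values across the
#' kinase variables tested.
#'
#' @param clinical Clinical tibble (with `time`, `event` and adjustment
#'   columns).
#' @param indicators Tibble of 0/1 patient indicators (`patient_id` plus one
#'   column per variable), e.g. a [binarize_quartile()] status matrix joined
#'   with a K-high column.
#' @param adjust Adjustment covariates (default `T`, `N`, `G`, `age`).
#'
#' @return A tibble of class `kinase_screen`: `variable`, `logrank_p`, `beta`,
#'   `hr`, `se`, `cox_p`, `p_bonferroni`.
#' @export
kinase_screen <- function(clinical, indicators,
                          adjust = c("T", "N", "G", "age")) {
  vars <- setdiff(names(indicators), "patient_id")
  if (!length(vars)) abort("no indicator variables supplied.")
  dat <- dplyr::inner_join(clinical, indicators, by = "patient_id")
  rows <- purrr::map_dfr(vars, function(v) {
    lr <- tryCatch(logrank_test(dat, group = v)$p, error = function(e) NA_real_)
    cf <- tryCatch({
      fit <- cox_fit(dat, covariates = c(v, adjust))
      fit$coef[fit$coef$term == sprintf("`%s`", v) | fit$coef$term == v, ]
    }, error = function(e) NULL)
    if (is.null(cf) || !nrow(cf)) {
      tibble(variable = v, logrank_p = lr, beta = NA_real_, hr = NA_real_,
             se = NA_real_, cox_p = NA_real_)
    } else {
      tibble(variable = v, logrank_p = lr, beta = cf$beta[1], hr = cf$hr[1],
             se = cf$se[1], cox_p = cf$p[1])
    }
  })
  rows$p_bonferroni <- bonferroni(rows$cox_p)
  class(rows) <- c("kinase_screen", class(rows))
  rows
}
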