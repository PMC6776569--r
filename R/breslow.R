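#' Breslow-profiled baseline increments for sales
#'
#' Step-function estimate of the cumulative baseline sales intensity given
#' regression parameters and frailties: at each distinct sale age the
#' increment is the number of sales at that age divided by the weighted
#' risk-set total
#' `sum_v sum_{b != s} Y_v(a) Y_b(t_v(a)) Z_s Z_b^{-1} R_v(a, b; beta)`.
#' Ties on the monthly grid are aggregated Breslow-style through the
#' numerator count.
#'
#' @param h An `event_history` with at least one sale.
#' @param params A [hazard_params()].
#' @param frailty A [frailty_state()].
#' @return A tibble with one row per distinct sale age: `age`, `increment`,
#'   `n_events`, `denominator`.
#' @export
breslow_sale <- function(h, params, frailty) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  if (length(mf$sale_ages) == 0) abort("no sale events in the data")
  Z <- as_frailty_Z(frailty, mf)
  D <- sale_denominator(mf, params, Z, mf$sale_ages)
  if (any(D <= 0)) {
    abort(sprintf("zero risk-set denominator at sale age(s) %s",
                  paste(mf$sale_ages[D <= 0], collapse = ", ")))
  }
  tibble(age = mf$sale_ages, increment = mf$dN_sale / D,
         n_events = mf$dN_sale, denominator = D)
}

#' Breslow-profiled baseline increments for scrapping
#'
#' As [breslow_sale()] but for the scrap hazard: increments are scrap counts
#' divided by `sum_v Y_v(a) Z_s Q_v(a; theta)`. With `theta = 0` and unit
#' frailties this is the Nelson-Aalen estimator on vessels.
#'
#' @inheritParams breslow_sale
#' @return A tibble with `age`, `increment`, `n_events`, `denominator`.
#' @export
breslow_scrap <- function(h, params, frailty) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  if (length(mf$scrap_ages) == 0) abort("no scrap events in the data")
  Z <- as_frailty_Z(frailty, mf)
  D <- scrap_denominator(mf, params, Z, mf$scrap_ages)
  if (any(D <= 0)) {
    abort(sprintf("zero risk-set denominator at scrap age(s) %s",
                  paste(mf$scrap_ages[D <= 0], collapse = ", ")))
  }
  tibble(age = mf$scrap_ages, increment = mf$dN_scrap / D,
         n_events = mf$dN_scrap, denominator = D)
}

#' Profile both baselines at once
#'
#' Convenience wrapper returning a [baseline_increments()] object holding the
#' Breslow-profiled sale baseline and, when the data contain scrap events,
#' the scrap baseline.
#'
#' @inheritParams breslow_sale
#' @return A [baseline_increments()].
#' @export
breslow_baselines <- function(h, params, frailty) {
  sale <- if (any(h$spells$end_type == "sale")) {
    breslow_sale(h, params, frailty)[c("age", "increment")]
  }
  scrap <- if (any(h$spells$end_type == "scrap")) {
    breslow_scrap(h, params, frailty)[c("age", "increment")]
  }
  baseline_increments(sale = sale, scrap = scrap)
}

#' Plot estimated cumulative baselines
#'
#' Draws the cumulative baseline sales intensity and scrap hazard as
#' right-continuous step functions of vessel age, optionally rescaled by the
#' relative risk at user-chosen covariate values (so the curves can be read
#' as cumulative intensities for a reference vessel/company profile).
#'
#' @param object A [baseline_increments()] (or the tibble returned by
#'   [breslow_sale()]/[breslow_scrap()] wrapped via [baseline_increments()]).
#' @param rescale Named numeric of length up to 2, multiplicative factors
#'   `c(sale = ..., scrap = ...)` applied to the cumulative curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.baseline_increments <- function(object, rescale = c(sale = 1, scrap = 1),
                                         ...) {
  df <- dplyr::bind_rows(
    sale = object$sale, scrap = object$scrap, .id = "transition"
  )
  df <- dplyr::group_by(df, .data$transition)
  df <- dplyr::mutate(df, cumulative = cumsum(.data$increment) *
                        unname(rescale[dplyr::cur_group()$transition]))
  df <- dplyr::ungroup(df)
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$cumulative,
                                   colour = .data$transition)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "vessel age (months)", y = "cumulative baseline",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
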