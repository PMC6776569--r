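#' Regression parameters of the dual-frailty model
#'
#' Bundles the regression coefficient blocks of the sales intensity and the
#' scrap hazard. The sales intensity for vessel `v`, owner `s` and candidate
#' buyer `b` at vessel age `a` (calendar time `t`) is
#' `Z_s / Z_b * alpha0(a) * exp(beta_V x_v(a) + beta_S x_s + beta_B x_b + beta_E x_E(t))`,
#' and the scrap hazard is
#' `Z_s * lambda0(a) * exp(theta_V x_v(a) + theta_S x_s + theta_E x_E(t))`.
#'
#' @param beta_V,beta_S,beta_B,beta_E Sale-model coefficient vectors for the
#'   vessel, selling-company, buying-company and exogenous covariate blocks.
#' @param theta_V,theta_S,theta_E Scrap-model coefficient vectors.
#' @param prev_owners If `TRUE`, the vessel covariate block is extended with
#'   the (left-limit) number of previous owners, so `beta_V`/`theta_V` carry
#'   one extra trailing coefficient.
#' @return An object of class `hazard_params`.
#' @export
hazard_params <- function(beta_V = numeric(), beta_S = numeric(),
                          beta_B = numeric(), beta_E = numeric(),
                          theta_V = numeric(), theta_S = numeric(),
                          theta_E = numeric(), prev_owners = FALSE) {
  p <- list(beta_V = as.numeric(beta_V), beta_S = as.numeric(beta_S),
            beta_B = as.numeric(beta_B), beta_E = as.numeric(beta_E),
            theta_V = as.numeric(theta_V), theta_S = as.numeric(theta_S),
            theta_E = as.numeric(theta_E), prev_owners = isTRUE(prev_owners))
  bad <- names(p)[vapply(p[1:7], function(x) any(!is.finite(x)), TRUE)]
  if (length(bad)) {
    abort(paste0("non-finite entries in: ", paste(bad, collapse = ", ")))
  }
  structure(p, class = "hazard_params")
}

check_dims <- function(mf, params) {
  chk <- function(coef, p, lab) {
    if (length(coef) > 0 && length(coef) != p) {
      abort(sprintf("length(%s) = %d but the data carry %d covariate(s)",
                    lab, length(coef), p))
    }
  }
  chk(params$beta_V, mf$p_vessel, "beta_V")
  chk(params$theta_V, mf$p_vessel, "theta_V")
  chk(params$beta_S, mf$p_company, "beta_S")
  chk(params$beta_B, mf$p_company, "beta_B")
  chk(params$theta_S, mf$p_company, "theta_S")
  invisible(params)
}

#' Company frailties and their variance
#'
#' The frailty `Z_c = exp(S_c)` of company `c` is a positive multiplicative
#' random effect: it scales up the intensity of every sale (and scrap) by
#' `c` as owner and scales down, through `1/Z_c`, the intensity of every
#' purchase by `c`. A priori the `Z_c` are independent
#' `Gamma(1/xi, rate 1/xi)`, so each has mean 1 and variance `xi`.
#'
#' @param Z Positive numeric vector of frailties, one per company in the
#'   company-table order, optionally named by company id. A scalar is
#'   recycled.
#' @param xi Positive frailty variance.
#' @param n Number of companies, used to recycle a scalar `Z`.
#' @return An object of class `frailty_state`.
#' @export
frailty_state <- function(Z = 1, xi = 0.2, n = length(Z)) {
  Z <- rep_len(as.numeric(Z), n)
  if (any(!is.finite(Z)) || any(Z <= 0)) abort("all frailties must be positive")
  if (!is.finite(xi) || xi <= 0) abort("`xi` must be positive")
  structure(list(Z = Z, xi = xi), class = "frailty_state")
}

as_frailty_Z <- function(frailty, mf) {
  Z <- rep_len(frailty$Z, mf$n_company)
  if (!is.null(names(frailty$Z)) && length(frailty$Z) == mf$n_company) {
    Z <- frailty$Z[mf$h$companies$company_id]
  }
  unname(Z)
}

#' Baseline increment step functions
#'
#' The nonparametric baselines enter as step functions of vessel age: the
#' cumulative baseline sales intensity `A0(u)` and cumulative baseline scrap
#' hazard `L0(u)` place increments at event ages only.
#'
#' @param sale Data frame with columns `age` and `increment` for sales (may
#'   be empty).
#' @param scrap Data frame with columns `age` and `increment` for scrapping.
#' @return An object of class `baseline_increments`.
#' @export
baseline_increments <- function(sale = NULL, scrap = NULL) {
  mk <- function(df) {
    if (is.null(df)) df <- tibble(age = numeric(), increment = numeric())
    df <- as_tibble(df)[c("age", "increment")]
    df <- df[order(df$age), ]
    if (any(df$increment < 0)) abort("baseline increments must be >= 0")
    if (anyDuplicated(df$age)) abort("duplicated baseline ages")
    df
  }
  structure(list(sale = mk(sale), scrap = mk(scrap)),
            class = "baseline_increments")
}

#' Evaluate a cumulative baseline
#'
#' @param baselines A `baseline_increments` object.
#' @param type `"sale"` or `"scrap"`.
#' @param ages Ages at which to evaluate the (right-continuous) cumulative
#'   step function.
#' @return Numeric vector of cumulative baseline values.
#' @export
baseline_cumulative <- function(baselines, type = c("sale", "scrap"), ages) {
  type <- match.arg(type)
  b <- baselines[[type]]
  cum <- c(0, cumsum(b$increment))
  cum[findInterval(ages, b$age) + 1L]
}

#' Relative risk of a sale to a specific buyer
#'
#' The covariate part `R_v(a, b; beta)` of the sales intensity: the
#' exponential of the four inner products (vessel, seller, buyer, exogenous),
#' excluding the baseline and the frailty ratio.
#'
#' @param h An `event_history`.
#' @param vessel_id Vessel identifier.
#' @param age Vessel age (months); seller and history covariates are
#'   evaluated in the left-limit sense at this age.
#' @param buyer_id Candidate buying company (must differ from the owner).
#' @param params A [hazard_params()].
#' @return A positive scalar.
#' @export
relative_risk_sale <- function(h, vessel_id, age, buyer_id, params) {
  ctx <- risk_context(h, vessel_id, age, params)
  bix <- match(as.character(buyer_id), h$companies$company_id)
  if (is.na(bix)) abort(sprintf("unknown buyer '%s'", buyer_id))
  if (bix == ctx$oidx) abort("buyer equals the current owner")
  eta <- ctx$eta_vs_sale
  if (length(params$beta_B)) {
    eta <- eta + drop(ctx$mf$XC[bix, , drop = FALSE] %*% params$beta_B)
  }
  unname(exp(eta))
}

#' Relative risk of scrapping
#'
#' The covariate part `Q_v(a; theta)` of the scrap hazard (no buyer block).
#'
#' @inheritParams relative_risk_sale
#' @return A positive scalar.
#' @export
relative_risk_scrap <- function(h, vessel_id, age, params) {
  ctx <- risk_context(h, vessel_id, age, params)
  unname(exp(ctx$eta_vs_scrap))
}

# owner, spell and seller-side linear predictors of a vessel at an age
risk_context <- function(h, vessel_id, age, params) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  vix <- match(as.character(vessel_id), h$vessels$vessel_id)
  if (is.na(vix)) abort(sprintf("unknown vessel '%s'", vessel_id))
  s <- which(mf$spell$vidx == vix & mf$spell$start < age & age <= mf$spell$end)
  if (length(s) != 1) {
    abort(sprintf("vessel '%s' is not at risk at age %g", vessel_id, age))
  }
  t_cal <- mf$delivery[vix] + age
  eta_vs_sale <- 0
  eta_vs_scrap <- 0
  if (length(params$beta_V)) {
    eta_vs_sale <- eta_vs_sale + drop(mf$spell$XV[s, , drop = FALSE] %*% params$beta_V)
  }
  if (length(params$beta_S)) {
    eta_vs_sale <- eta_vs_sale + drop(mf$spell$XC_owner[s, , drop = FALSE] %*% params$beta_S)
  }
  if (uses_exo(mf, params$beta_E)) {
    eta_vs_sale <- eta_vs_sale + drop(exogenous_at(h$exogenous, t_cal) %*% params$beta_E)
  }
  if (length(params$theta_V)) {
    eta_vs_scrap <- eta_vs_scrap + drop(mf$spell$XV[s, , drop = FALSE] %*% params$theta_V)
  }
  if (length(params$theta_S)) {
    eta_vs_scrap <- eta_vs_scrap + drop(mf$spell$XC_owner[s, , drop = FALSE] %*% params$theta_S)
  }
  if (uses_exo(mf, params$theta_E)) {
    eta_vs_scrap <- eta_vs_scrap + drop(exogenous_at(h$exogenous, t_cal) %*% params$theta_E)
  }
  list(mf = mf, spell = s, oidx = mf$spell$oidx[s], t = t_cal,
       eta_vs_sale = eta_vs_sale, eta_vs_scrap = eta_vs_scrap)
}

#' Total sales intensity of a vessel
#'
#' Sums the per-buyer intensities over every active company other than the
#' current owner:
#' `a0 * Z_s * sum_{b != s active} Z_b^{-1} R_v(a, b; beta)`.
#'
#' @inheritParams relative_risk_sale
#' @param frailty A [frailty_state()].
#' @param a0 Baseline intensity value at this age (positive scalar).
#' @return A non-negative scalar (0 when no eligible buyer is active).
#' @export
sale_intensity_total <- function(h, vessel_id, age, params, frailty, a0) {
  if (!is.finite(a0) || a0 <= 0) abort("`a0` must be positive")
  ctx <- risk_context(h, vessel_id, age, params)
  mf <- ctx$mf
  Z <- as_frailty_Z(frailty, mf)
  bw <- company_buyer_weights(mf, params$beta_B, Z)
  active <- mf$act_start <= ctx$t & ctx$t < mf$act_end
  active[ctx$oidx] <- FALSE
  a0 * Z[ctx$oidx] * exp(ctx$eta_vs_sale) * sum(bw$wBz[active])
}

#' Cumulative sale and scrap intensities of a vessel
#'
#' Stieltjes sums of the at-risk intensities against the baseline
#' increments, piecewise over ownership spells (owner and eligible-buyer set
#' change at each sale).
#'
#' @inheritParams sale_intensity_total
#' @param up_to_age Upper limit `u` of the accumulation.
#' @param baselines A [baseline_increments()].
#' @return Named numeric vector `c(A = A_v(u), L = Lambda_v(u))`.
#' @export
cumulative_intensities <- function(h, vessel_id, up_to_age, params, frailty,
                                   baselines) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  Z <- as_frailty_Z(frailty, mf)
  vix <- match(as.character(vessel_id), h$vessels$vessel_id)
  if (is.na(vix)) abort(sprintf("unknown vessel '%s'", vessel_id))
  A <- vessel_cumulative(mf, params, Z, baselines, vix, up_to_age, "sale")
  L <- vessel_cumulative(mf, params, Z, baselines, vix, up_to_age, "scrap")
  c(A = A, L = L)
}

vessel_cumulative <- function(mf, params, Z, baselines, vix, up_to_age, type) {
  b <- baselines[[type]]
  keep <- b$age <= up_to_age
  if (!any(keep)) return(0)
  ages <- b$age[keep]
  inc <- b$increment[keep]
  spells <- which(mf$spell$vidx == vix)
  total <- 0
  bw <- company_buyer_weights(mf, params$beta_B, Z)
  m0f <- if (type == "sale") activity_step_fun(mf, bw$wBz) else NULL
  wgt <- if (type == "sale") {
    spell_seller_weight(mf, params$beta_V, params$beta_S)
  } else {
    spell_scrap_weight(mf, params$theta_V, params$theta_S)
  }
  coef_E <- if (type == "sale") params$beta_E else params$theta_E
  for (s in spells) {
    at <- ages > mf$spell$start[s] & ages <= mf$spell$end[s]
    if (!any(at)) next
    t_cal <- mf$delivery[vix] + ages[at]
    exo <- exo_multiplier(mf, coef_E, t_cal)
    o <- mf$spell$oidx[s]
    if (type == "sale") {
      m0 <- drop(m0f(t_cal))
      total <- total + sum(inc[at] * exo * Z[o] * wgt[s] *
                             pmax(m0 - bw$wBz[o], 0))
    } else {
      total <- total + sum(inc[at] * exo * Z[o] * wgt[s])
    }
  }
  total
}

#' Full-data log-likelihood
#'
#' The log of the product over vessels of
#' `(prod over sales of the sale intensity) * exp(-A_v) * lambda_v^delta * exp(-Lambda_v)`,
#' with intensities evaluated through the given baseline increments:
#' point-mass terms `log(Z_s Z_b^{-1} dA0(a) R_v)` at sale ages,
#' `log(Z_s dL0(a) Q_v)` at scrap ages, minus the cumulative intensities.
#'
#' @inheritParams cumulative_intensities
#' @param params A [hazard_params()].
#' @param frailty A [frailty_state()].
#' @param baselines A [baseline_increments()]; every observed event age must
#'   carry a strictly positive increment of the matching type.
#' @return A scalar log-likelihood.
#' @export
full_loglik <- function(h, params, frailty, baselines) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  Z <- as_frailty_Z(frailty, mf)

  ll <- 0
  # sale point masses
  ev <- sale_events(mf)
  if (length(ev$s)) {
    inc <- increment_at(baselines$sale, ev$age, "sale")
    eta <- sale_event_eta(mf, params, ev)
    ll <- ll + sum(log(Z[ev$oidx]) - log(Z[ev$bidx]) + log(inc) + eta)
  }
  # scrap point masses
  sv <- scrap_events(mf)
  if (length(sv$s)) {
    inc <- increment_at(baselines$scrap, sv$age, "scrap")
    eta <- scrap_event_eta(mf, params, sv)
    ll <- ll + sum(log(Z[sv$oidx]) + log(inc) + eta)
  }
  # integrated intensities: sum_v A_v = sum_a dA0(a) * Denom(a), likewise scrap
  if (nrow(baselines$sale)) {
    D <- sale_denominator(mf, params, Z, baselines$sale$age)
    ll <- ll - sum(baselines$sale$increment * D)
  }
  if (nrow(baselines$scrap)) {
    D <- scrap_denominator(mf, params, Z, baselines$scrap$age)
    ll <- ll - sum(baselines$scrap$increment * D)
  }
  ll
}

increment_at <- function(tab, ages, what) {
  idx <- match(ages, tab$age)
  inc <- tab$increment[idx]
  if (anyNA(inc) || any(inc <= 0)) {
    abort(sprintf("baselines carry no positive %s increment at one or more event ages",
                  what))
  }
  inc
}
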