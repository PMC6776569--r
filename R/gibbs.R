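#' Sufficient statistics of a company's frailty full conditional
#'
#' As a function of a single company frailty `Z_c`, the full-data likelihood
#' is proportional to `Z_c^M exp(-D1 Z_c - D2 / Z_c)`:
#' `M` is the number of vessels the company sold or scrapped minus the
#' number it purchased; `D1` accumulates, over the baseline increments at
#' ages where the company owns an at-risk vessel, the cumulative sale and
#' scrap intensity factors that multiply `Z_c`; `D2` accumulates, over ages
#' where the company is an active eligible buyer of someone else's at-risk
#' vessel, the purchase intensity factors that multiply `1/Z_c`. `Z_c`
#' itself is excluded from both, while the current values of all other
#' frailties enter through the buyer sums.
#'
#' @inheritParams full_loglik
#' @param company A company id.
#' @return A list with elements `M` (integer), `D1`, `D2` (non-negative
#'   reals).
#' @export
gibbs_stats <- function(h, company, params, frailty, baselines) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  Z <- as_frailty_Z(frailty, mf)
  cix <- match(as.character(company), h$companies$company_id)
  if (is.na(cix)) abort(sprintf("unknown company '%s'", company))
  gibbs_stats_core(mf, params, Z, baselines, cix)
}

gibbs_stats_core <- function(mf, params, Z, baselines, cix) {
  o <- mf$spell$oidx
  bw <- company_buyer_weights(mf, params$beta_B, Z)
  D1 <- 0; D2 <- 0

  bs <- baselines$sale
  if (nrow(bs)) {
    eVS <- spell_seller_weight(mf, params$beta_V, params$beta_S)
    pr <- sale_pairs(mf, bs$age)
    u <- bs$increment[pr$a] * eVS[pr$s] * exo_multiplier(mf, params$beta_E, pr$t)
    own <- o[pr$s] == cix
    if (any(own)) {
      m0f <- activity_step_fun(mf, bw$wBz)
      m0 <- drop(m0f(pr$t[own]))
      D1 <- D1 + sum(u[own] * pmax(m0 - bw$wBz[cix], 0))
    }
    oth <- !own & mf$act_start[cix] <= pr$t & pr$t < mf$act_end[cix]
    if (any(oth)) {
      D2 <- bw$wB[cix] * sum(u[oth] * Z[o[pr$s[oth]]])
    }
  }
  bl <- baselines$scrap
  if (nrow(bl)) {
    eQ <- spell_scrap_weight(mf, params$theta_V, params$theta_S)
    prs <- sale_pairs(mf, bl$age)
    own <- o[prs$s] == cix
    if (any(own)) {
      v <- bl$increment[prs$a[own]] * eQ[prs$s[own]] *
        exo_multiplier(mf, params$theta_E, prs$t[own])
      D1 <- D1 + sum(v)
    }
  }
  list(M = mf$M[cix], D1 = D1, D2 = D2)
}

#' One Gibbs sweep over the company frailties
#'
#' Updates every company frailty in fixed ascending company order, each from
#' its generalised inverse Gaussian full conditional with
#' `lambda = M + 1/xi`, `chi = 2 D2`, `psi = 2 (D1 + 1/xi)`, where `D1` and
#' `D2` are evaluated with the most recent values of all other frailties
#' (buyer-sum aggregates are updated incrementally after each draw).
#'
#' @inheritParams full_loglik
#' @return An updated [frailty_state()] (the frailty variance is untouched).
#' @export
gibbs_update_Z <- function(h, params, frailty, baselines) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  Z <- as_frailty_Z(frailty, mf)
  Z_new <- gibbs_update_Z_core(mf, params, Z, frailty$xi, baselines)
  frailty_state(Z = Z_new, xi = frailty$xi)
}

gibbs_update_Z_core <- function(mf, params, Z, xi, baselines) {
  fast <- mf$all_full_window &&
    !uses_exo(mf, params$beta_E) && !uses_exo(mf, params$theta_E)
  if (fast) {
    P <- owner_exposure(mf, baselines$sale,
                        spell_seller_weight(mf, params$beta_V, params$beta_S))
    Psc <- owner_exposure(mf, baselines$scrap,
                          spell_scrap_weight(mf, params$theta_V, params$theta_S))
    wB <- company_buyer_weights(mf, params$beta_B, Z = rep(1, mf$n_company))$wB
    .gibbs_sweep_cpp(Z, P, Psc, wB, as.integer(mf$M), xi)
  } else {
    for (cix in seq_len(mf$n_company)) {
      st <- gibbs_stats_core(mf, params, Z, baselines, cix)
      Z[cix] <- rgig(1, st$M + 1 / xi, 2 * st$D2, 2 * (st$D1 + 1 / xi))
    }
    Z
  }
}

# per-company sum, over its spells, of the spell weight times the baseline
# mass falling in the spell's at-risk span (start, end]
owner_exposure <- function(mf, btab, wgt) {
  out <- numeric(mf$n_company)
  if (nrow(btab) == 0) return(out)
  cum <- c(0, cumsum(btab$increment))
  lo <- findInterval(mf$spell$start, btab$age)
  hi <- findInterval(mf$spell$end, btab$age)
  mass <- cum[hi + 1L] - cum[lo + 1L]
  sums <- rowsum(wgt * mass, group = mf$spell$oidx)
  out[as.integer(rownames(sums))] <- sums
  out
}
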