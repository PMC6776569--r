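# Internal indexed representation of an event history, shared by the
# likelihood, Breslow, fitting and MCMC code. Everything downstream works
# with integer indices into `companies`/`vessels` and with per-spell
# covariate rows, so that quantities that are constant within an ownership
# spell are computed once per spell rather than once per (age, vessel) pair.

model_frame <- function(h, prev_owners = FALSE) {
  co <- h$companies
  ve <- h$vessels
  sp <- h$spells

  XC <- as.matrix(co[covariate_cols(co, "x_C_")])
  XV <- as.matrix(ve[covariate_cols(ve, "x_V_")])
  storage.mode(XC) <- "double"
  storage.mode(XV) <- "double"

  vidx <- match(sp$vessel_id, ve$vessel_id)
  oidx <- match(sp$owner_id, co$company_id)
  bidx <- match(sp$buyer_id, co$company_id)

  # spell order within vessel gives the previous-owner count at spell start
  ord <- order(vidx, sp$start_age)
  sp <- sp[ord, , drop = FALSE]
  vidx <- vidx[ord]; oidx <- oidx[ord]; bidx <- bidx[ord]
  nprev <- stats::ave(sp$start_age, vidx, FUN = seq_along) - 1

  XV_spell <- XV[vidx, , drop = FALSE]
  if (prev_owners) {
    XV_spell <- cbind(XV_spell, x_V_prev_owners = nprev)
  }
  XC_owner <- XC[oidx, , drop = FALSE]

  is_sale <- sp$end_type == "sale"
  is_scrap <- sp$end_type == "scrap"

  sale_ages <- sort(unique(sp$end_age[is_sale]))
  scrap_ages <- sort(unique(sp$end_age[is_scrap]))
  dN_sale <- as.numeric(table(factor(sp$end_age[is_sale], levels = sale_ages)))
  dN_scrap <- as.numeric(table(factor(sp$end_age[is_scrap], levels = scrap_ages)))

  N <- nrow(co)
  M <- integer(N)
  tab <- tabulate(oidx[is_sale | is_scrap], nbins = N)
  buy <- tabulate(bidx[is_sale], nbins = N)
  M <- tab - buy

  tau1 <- h$window[["tau1"]]; tau <- h$window[["tau"]]
  full_window <- co$activity_start <= tau1 + 1e-9 & co$activity_end >= tau - 1e-9

  list(
    h = h,
    XC = XC, XV = XV,
    act_start = co$activity_start, act_end = co$activity_end,
    full_window = full_window, all_full_window = all(full_window),
    delivery = ve$delivery_time,
    spell = list(vidx = vidx, oidx = oidx, bidx = bidx,
                 start = sp$start_age, end = sp$end_age,
                 end_type = sp$end_type, nprev = nprev,
                 XV = XV_spell, XC_owner = XC_owner,
                 is_sale = is_sale, is_scrap = is_scrap),
    sale_ages = sale_ages, dN_sale = dN_sale,
    scrap_ages = scrap_ages, dN_scrap = dN_scrap,
    M = M,
    n_company = N, n_vessel = nrow(ve),
    p_vessel = ncol(XV_spell), p_company = ncol(XC),
    has_exo = !is.null(h$exogenous),
    prev_owners = prev_owners
  )
}

# Grid positions of the at-risk span of each spell on a sorted age grid:
# ages a with start < a <= end, i.e. indices (lo..hi) with
# lo = #(grid <= start) + 1, hi = #(grid <= end).
spell_span <- function(mf, ages) {
  list(lo = findInterval(mf$spell$start, ages) + 1L,
       hi = findInterval(mf$spell$end, ages))
}

# Sum per-spell weights over each grid age covered by the spell's at-risk
# span. `w` may be a vector or a matrix (one column per accumulated
# quantity); returns a length-n vector or n x q matrix.
interval_accumulate <- function(lo, hi, w, n) {
  w <- as.matrix(w)
  keep <- hi >= lo
  out <- matrix(0, n + 1L, ncol(w))
  if (any(keep)) {
    lo <- lo[keep]; hi <- hi[keep]
    w <- w[keep, , drop = FALSE]
    delta <- rowsum(rbind(w, -w), group = c(lo, hi + 1L))
    out[as.integer(rownames(delta)), ] <- delta
    out <- apply(out, 2, cumsum)
  }
  out <- out[seq_len(n), , drop = FALSE]
  if (ncol(out) == 1L) drop(out) else out
}

# ---- parameter-dependent weights ------------------------------------------

# exp(beta_B' x_c) per company, and the same divided by Z (the buyer-side
# weight Z_b^{-1} exp(beta_B' x_b)).
company_buyer_weights <- function(mf, beta_B, Z) {
  wB <- if (length(beta_B)) exp(drop(mf$XC %*% beta_B)) else rep(1, mf$n_company)
  list(wB = wB, wBz = wB / Z)
}

# exp(beta_V' x_v(a) + beta_S' x_s) per spell (constant within spell).
spell_seller_weight <- function(mf, beta_V, beta_S) {
  eta <- rep(0, length(mf$spell$start))
  if (length(beta_V)) eta <- eta + drop(mf$spell$XV %*% beta_V)
  if (length(beta_S)) eta <- eta + drop(mf$spell$XC_owner %*% beta_S)
  exp(eta)
}

# exp(theta_V' x_v(a) + theta_S' x_s) per spell.
spell_scrap_weight <- function(mf, theta_V, theta_S) {
  spell_seller_weight(mf, theta_V, theta_S)
}

# Right-continuous step function of calendar time giving the sum of a
# per-company weight over the companies active at t. Returns a lookup
# closure; `wmat` is N x q.
activity_step_fun <- function(mf, wmat) {
  wmat <- as.matrix(wmat)
  q <- ncol(wmat)
  if (mf$all_full_window) {
    tot <- colSums(wmat)
    return(function(t) matrix(tot, length(t), q, byrow = TRUE))
  }
  brk <- sort(unique(c(mf$act_start, mf$act_end)))
  delta <- matrix(0, length(brk) + 1L, q)
  i0 <- match(mf$act_start, brk)
  i1 <- match(mf$act_end, brk)
  add <- rowsum(rbind(wmat, -wmat), group = c(i0, i1))
  delta[as.integer(rownames(add)), ] <- add
  cum <- apply(delta, 2, cumsum)[seq_along(brk), , drop = FALSE]
  function(t) {
    idx <- findInterval(t, brk)
    out <- matrix(0, length(t), q)
    pos <- idx >= 1L
    out[pos, ] <- cum[idx[pos], , drop = FALSE]
    out
  }
}

# Exogenous multiplier exp(beta_E' x_E(t)) at calendar times t (1 when the
# model carries no exogenous block).
exo_multiplier <- function(mf, beta_E, t) {
  if (!mf$has_exo || length(beta_E) == 0) return(rep(1, length(t)))
  xe <- exogenous_at(mf$h$exogenous, t)
  exp(drop(xe %*% beta_E))
}

uses_exo <- function(mf, coef_E) {
  mf$has_exo && length(coef_E) > 0
}

# ---- risk-set denominators -------------------------------------------------

# Weighted risk-set total for sales at each age of `ages`:
#   sum_{v at risk} Z_s e^{bV xv + bS xs (+ bE xE)} (sum_{b != s active} Z_b^{-1} e^{bB xb})
sale_denominator <- function(mf, params, Z, ages) {
  if (length(ages) == 0) return(numeric(0))
  bw <- company_buyer_weights(mf, params$beta_B, Z)
  eVS <- spell_seller_weight(mf, params$beta_V, params$beta_S)
  o <- mf$spell$oidx
  if (!uses_exo(mf, params$beta_E) && mf$all_full_window) {
    m0 <- sum(bw$wBz)
    g <- Z[o] * eVS * (m0 - bw$wBz[o])
    sspan <- spell_span(mf, ages)
    interval_accumulate(sspan$lo, sspan$hi, g, length(ages))
  } else {
    pr <- sale_pairs(mf, ages)
    m0f <- activity_step_fun(mf, bw$wBz)
    m0 <- drop(m0f(pr$t))
    exo <- exo_multiplier(mf, params$beta_E, pr$t)
    d <- Z[o[pr$s]] * eVS[pr$s] * exo * pmax(m0 - bw$wBz[o[pr$s]], 0)
    rowsum_by_age(d, pr$a, length(ages))
  }
}

# Weighted risk-set total for scrapping: sum_{v at risk} Z_s Q_v(a; theta).
scrap_denominator <- function(mf, params, Z, ages) {
  if (length(ages) == 0) return(numeric(0))
  eQ <- spell_scrap_weight(mf, params$theta_V, params$theta_S)
  o <- mf$spell$oidx
  if (!uses_exo(mf, params$theta_E)) {
    g <- Z[o] * eQ
    sspan <- spell_span(mf, ages)
    interval_accumulate(sspan$lo, sspan$hi, g, length(ages))
  } else {
    pr <- sale_pairs(mf, ages)
    exo <- exo_multiplier(mf, params$theta_E, pr$t)
    d <- Z[o[pr$s]] * eQ[pr$s] * exo
    rowsum_by_age(d, pr$a, length(ages))
  }
}

# Long (age x at-risk spell) expansion over an age grid. Columns: spell
# index `s`, age-grid index `a`, calendar time `t`.
sale_pairs <- function(mf, ages) {
  sspan <- spell_span(mf, ages)
  len <- pmax(sspan$hi - sspan$lo + 1L, 0L)
  s <- rep.int(seq_along(len), len)
  a <- sequence(len, from = sspan$lo)
  t <- mf$delivery[mf$spell$vidx[s]] + ages[a]
  list(s = s, a = a, t = t)
}

rowsum_by_age <- function(x, a, n) {
  out <- numeric(n)
  if (length(x)) {
    sums <- rowsum(x, group = a)
    out[as.integer(rownames(sums))] <- sums
  }
  out
}

# ---- event-level quantities ------------------------------------------------

# One row per sale event: spell index, seller/buyer/vessel indices, age, and
# calendar time.
sale_events <- function(mf) {
  i <- which(mf$spell$is_sale)
  list(s = i, oidx = mf$spell$oidx[i], bidx = mf$spell$bidx[i],
       age = mf$spell$end[i],
       t = mf$delivery[mf$spell$vidx[i]] + mf$spell$end[i])
}

scrap_events <- function(mf) {
  i <- which(mf$spell$is_scrap)
  list(s = i, oidx = mf$spell$oidx[i], age = mf$spell$end[i],
       t = mf$delivery[mf$spell$vidx[i]] + mf$spell$end[i])
}

# Linear predictor of each sale event under `params` (without the frailty
# log-ratio, which is handled by the caller).
sale_event_eta <- function(mf, params, ev = sale_events(mf)) {
  eta <- rep(0, length(ev$s))
  if (length(params$beta_V)) {
    eta <- eta + drop(mf$spell$XV[ev$s, , drop = FALSE] %*% params$beta_V)
  }
  if (length(params$beta_S)) {
    eta <- eta + drop(mf$spell$XC_owner[ev$s, , drop = FALSE] %*% params$beta_S)
  }
  if (length(params$beta_B)) {
    eta <- eta + drop(mf$XC[ev$bidx, , drop = FALSE] %*% params$beta_B)
  }
  if (uses_exo(mf, params$beta_E)) {
    eta <- eta + drop(exogenous_at(mf$h$exogenous, ev$t) %*% params$beta_E)
  }
  eta
}

scrap_event_eta <- function(mf, params, ev = scrap_events(mf)) {
  eta <- rep(0, length(ev$s))
  if (length(params$theta_V)) {
    eta <- eta + drop(mf$spell$XV[ev$s, , drop = FALSE] %*% params$theta_V)
  }
  if (length(params$theta_S)) {
    eta <- eta + drop(mf$spell$XC_owner[ev$s, , drop = FALSE] %*% params$theta_S)
  }
  if (uses_exo(mf, params$theta_E)) {
    eta <- eta + drop(exogenous_at(mf$h$exogenous, ev$t) %*% params$theta_E)
  }
  eta
}
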