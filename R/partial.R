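#' Log partial likelihood for the sales model
#'
#' Cox-type partial likelihood of the observed sale attributions given the
#' sale ages: for each sale, the log of its pair intensity
#' `Z_s Z_b^{-1} R_v(a, b; beta)` minus the log of the weighted risk-set
#' total over all at-risk (vessel, eligible buyer) pairs at that age. Ties
#' are handled Breslow-style (individual numerators, aggregated
#' denominator). Plugging the Breslow baselines into the full-data
#' likelihood and dropping terms free of `beta` gives exactly this function,
#' so it is also the profile-likelihood target used in the MCMC regression
#' updates.
#'
#' @inheritParams breslow_sale
#' @param derivatives If `TRUE`, attach the score vector and the negated
#'   observed information as attributes `"gradient"` and `"hessian"`
#'   (parameter order: `beta_V`, `beta_S`, `beta_B`, `beta_E`).
#' @return Scalar log partial likelihood (with optional derivative
#'   attributes).
#' @export
partial_loglik_sale <- function(h, params, frailty = frailty_state(1, 1, 1),
                                derivatives = FALSE) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  Z <- as_frailty_Z(frailty, mf)
  q <- partial_quantities_sale(mf, params, Z, deriv = derivatives)
  out <- q$loglik
  if (derivatives) {
    attr(out, "gradient") <- q$grad
    attr(out, "hessian") <- q$hess
  }
  out
}

#' Log partial likelihood for the scrap model
#'
#' Standard Cox partial likelihood (Breslow ties) on the vessel age scale
#' with per-spell linear predictor
#' `theta_V x_v(a) + theta_S x_s + theta_E x_E(t)` and multiplicative owner
#' frailty `Z_s`. Multiplying all frailties by a constant shifts only the
#' baseline, leaving this function unchanged up to an additive constant in
#' `log c` times the event count minus itself (i.e. invariant).
#'
#' @inheritParams partial_loglik_sale
#' @return Scalar log partial likelihood (with optional derivative
#'   attributes; parameter order `theta_V`, `theta_S`, `theta_E`).
#' @export
partial_loglik_scrap <- function(h, params, frailty = frailty_state(1, 1, 1),
                                 derivatives = FALSE) {
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  Z <- as_frailty_Z(frailty, mf)
  q <- partial_quantities_scrap(mf, params, Z, deriv = derivatives)
  out <- q$loglik
  if (derivatives) {
    attr(out, "gradient") <- q$grad
    attr(out, "hessian") <- q$hess
  }
  out
}

# row-wise Kronecker product: out[i, (j-1)*pb + k] = A[i, j] * B[i, k]
rowkron <- function(A, B) {
  pa <- ncol(A); pb <- ncol(B)
  A[, rep(seq_len(pa), each = pb), drop = FALSE] *
    B[, rep(seq_len(pb), times = pa), drop = FALSE]
}

fold_sq <- function(v, pa, pb) {
  # inverse of the rowkron column layout after colSums: returns pa x pb
  t(matrix(v, nrow = pb, ncol = pa))
}

# Score/information engine for the sales partial likelihood. Works on the
# spell-aggregated fast path when there is no exogenous block and every
# company is active over the whole window, otherwise on the general
# (age x spell) pair expansion with activity-window step aggregates.
partial_quantities_sale <- function(mf, params, Z, deriv = FALSE) {
  ages <- mf$sale_ages
  if (length(ages) == 0) abort("no sale events in the data")
  nA <- length(ages)
  dN <- mf$dN_sale
  ev <- sale_events(mf)
  use_exo <- uses_exo(mf, params$beta_E)
  p3 <- if (use_exo) length(params$beta_E) else 0L
  pV <- mf$p_vessel; p2 <- mf$p_company
  pOS <- pV + p2 + p3   # owner-side blocks: V, S, E

  bw <- company_buyer_weights(mf, params$beta_B, Z)
  eVS <- spell_seller_weight(mf, params$beta_V, params$beta_S)
  o <- mf$spell$oidx
  XC_o <- mf$spell$XC_owner

  fast <- !use_exo && mf$all_full_window
  if (fast) {
    m0 <- sum(bw$wBz)
    m1 <- colSums(bw$wBz * mf$XC)
    e <- Z[o] * eVS
    B <- pmax(m0 - bw$wBz[o], 0)
    g <- e * B
    sspan <- spell_span(mf, ages)
    D <- interval_accumulate(sspan$lo, sspan$hi, g, nA)
  } else {
    pr <- sale_pairs(mf, ages)
    m0f <- activity_step_fun(mf, bw$wBz)
    m1f <- activity_step_fun(mf, bw$wBz * mf$XC)
    m0p <- drop(m0f(pr$t))
    exo <- exo_multiplier(mf, params$beta_E, pr$t)
    e <- Z[o[pr$s]] * eVS[pr$s] * exo
    B <- pmax(m0p - bw$wBz[o[pr$s]], 0)
    g <- e * B
    D <- rowsum_by_age(g, pr$a, nA)
  }
  if (any(D <= 0)) {
    abort(sprintf("empty risk set at sale age(s) %s",
                  paste(ages[D <= 0], collapse = ", ")))
  }

  eta_ev <- sale_event_eta(mf, params, ev) +
    log(Z[ev$oidx]) - log(Z[ev$bidx])
  loglik <- sum(eta_ev) - sum(dN * log(D))
  if (!deriv) return(list(loglik = loglik))

  # final parameter order: beta_V, beta_S, beta_B, beta_E
  # internal order:        V, S, E (owner side) then B (buyer side)
  perm <- c(seq_len(pV + p2), pOS + seq_len(p2),
            if (p3) pV + p2 + seq_len(p3))

  # event design in internal order (V, S, E owner side, then buyer B)
  Xev <- cbind(mf$spell$XV[ev$s, , drop = FALSE],
               XC_o[ev$s, , drop = FALSE],
               if (p3) exogenous_at(mf$h$exogenous, ev$t),
               mf$XC[ev$bidx, , drop = FALSE])
  sum_ev <- colSums(Xev)

  if (fast) {
    Xos <- cbind(mf$spell$XV, XC_o)
    m2 <- crossprod(mf$XC, bw$wBz * mf$XC)
    mb1 <- matrix(m1, length(o), p2, byrow = TRUE) - bw$wBz[o] * XC_o
    mb2 <- matrix(as.vector(m2), length(o), p2 * p2, byrow = TRUE) -
      bw$wBz[o] * rowkron(XC_o, XC_o)
    acc <- cbind(g * Xos, e * mb1,
                 g * rowkron(Xos, Xos), e * rowkron(Xos, mb1), e * mb2)
    S <- interval_accumulate(sspan$lo, sspan$hi, acc, nA)
  } else {
    m2f <- activity_step_fun(
      mf, rowkron(mf$XC, mf$XC) * bw$wBz)
    Xos <- cbind(mf$spell$XV[pr$s, , drop = FALSE],
                 XC_o[pr$s, , drop = FALSE],
                 if (p3) exogenous_at(mf$h$exogenous, pr$t))
    XC_op <- XC_o[pr$s, , drop = FALSE]
    mb1 <- m1f(pr$t) - bw$wBz[o[pr$s]] * XC_op
    mb2 <- m2f(pr$t) - bw$wBz[o[pr$s]] * rowkron(XC_op, XC_op)
    acc <- cbind(g * Xos, e * mb1,
                 g * rowkron(Xos, Xos), e * rowkron(Xos, mb1), e * mb2)
    S <- rowsum_by_age_mat(acc, pr$a, nA)
  }

  i1 <- seq_len(pOS)
  i2 <- pOS + seq_len(p2)
  i3 <- pOS + p2 + seq_len(pOS * pOS)
  i4 <- pOS + p2 + pOS * pOS + seq_len(pOS * p2)
  i5 <- pOS + p2 + pOS * pOS + pOS * p2 + seq_len(p2 * p2)

  xbar <- cbind(S[, i1, drop = FALSE], S[, i2, drop = FALSE]) / D
  grad_int <- sum_ev - colSums(dN * xbar)

  w2 <- dN / D
  M11 <- fold_sq(colSums(S[, i3, drop = FALSE] * w2), pOS, pOS)
  M12 <- fold_sq(colSums(S[, i4, drop = FALSE] * w2), pOS, p2)
  M22 <- fold_sq(colSums(S[, i5, drop = FALSE] * w2), p2, p2)
  M2 <- rbind(cbind(M11, M12), cbind(t(M12), M22))
  xbar_w <- sqrt(dN) * xbar
  hess_int <- -(M2 - crossprod(xbar_w))

  nm <- c(block_names("beta_V", colnames(mf$spell$XV), pV),
          block_names("beta_S", colnames(mf$XC), p2),
          block_names("beta_B", colnames(mf$XC), p2),
          if (p3) block_names("beta_E", covariate_cols(mf$h$exogenous, "x_E_"), p3))
  grad <- grad_int[perm]
  hess <- hess_int[perm, perm, drop = FALSE]
  names(grad) <- nm
  dimnames(hess) <- list(nm, nm)
  list(loglik = loglik, grad = grad, hess = hess, terms = nm)
}

partial_quantities_scrap <- function(mf, params, Z, deriv = FALSE) {
  ages <- mf$scrap_ages
  if (length(ages) == 0) abort("no scrap events in the data")
  nA <- length(ages)
  dN <- mf$dN_scrap
  ev <- scrap_events(mf)
  use_exo <- uses_exo(mf, params$theta_E)
  p3 <- if (use_exo) length(params$theta_E) else 0L
  pV <- mf$p_vessel; p2 <- mf$p_company
  pOS <- pV + p2 + p3

  eQ <- spell_scrap_weight(mf, params$theta_V, params$theta_S)
  o <- mf$spell$oidx

  if (!use_exo) {
    e <- Z[o] * eQ
    sspan <- spell_span(mf, ages)
    D <- interval_accumulate(sspan$lo, sspan$hi, e, nA)
    if (deriv) {
      Xos <- cbind(mf$spell$XV, mf$spell$XC_owner)
      acc <- cbind(e * Xos, e * rowkron(Xos, Xos))
      S <- interval_accumulate(sspan$lo, sspan$hi, acc, nA)
    }
  } else {
    pr <- sale_pairs(mf, ages)
    exo <- exo_multiplier(mf, params$theta_E, pr$t)
    e <- Z[o[pr$s]] * eQ[pr$s] * exo
    D <- rowsum_by_age(e, pr$a, nA)
    if (deriv) {
      Xos <- cbind(mf$spell$XV[pr$s, , drop = FALSE],
                   mf$spell$XC_owner[pr$s, , drop = FALSE],
                   exogenous_at(mf$h$exogenous, pr$t))
      acc <- cbind(e * Xos, e * rowkron(Xos, Xos))
      S <- rowsum_by_age_mat(acc, pr$a, nA)
    }
  }
  if (any(D <= 0)) {
    abort(sprintf("empty risk set at scrap age(s) %s",
                  paste(ages[D <= 0], collapse = ", ")))
  }

  eta_ev <- scrap_event_eta(mf, params, ev) + log(Z[ev$oidx])
  loglik <- sum(eta_ev) - sum(dN * log(D))
  if (!deriv) return(list(loglik = loglik))

  Xev <- cbind(mf$spell$XV[ev$s, , drop = FALSE],
               mf$spell$XC_owner[ev$s, , drop = FALSE],
               if (p3) exogenous_at(mf$h$exogenous, ev$t))
  xbar <- S[, seq_len(pOS), drop = FALSE] / D
  grad <- colSums(Xev) - colSums(dN * xbar)
  w2 <- dN / D
  M2 <- fold_sq(colSums(S[, pOS + seq_len(pOS * pOS), drop = FALSE] * w2),
                pOS, pOS)
  hess <- -(M2 - crossprod(sqrt(dN) * xbar))

  nm <- c(block_names("theta_V", colnames(mf$spell$XV), pV),
          block_names("theta_S", colnames(mf$XC), p2),
          if (p3) block_names("theta_E", covariate_cols(mf$h$exogenous, "x_E_"), p3))
  names(grad) <- nm
  dimnames(hess) <- list(nm, nm)
  list(loglik = loglik, grad = grad, hess = hess, terms = nm)
}

block_names <- function(block, covs, p) {
  if (p == 0) return(character())
  if (is.null(covs) || length(covs) != p) covs <- paste0("x", seq_len(p))
  paste(block, covs, sep = ":")
}

rowsum_by_age_mat <- function(X, a, n) {
  out <- matrix(0, n, ncol(X))
  if (nrow(X)) {
    sums <- rowsum(X, group = a)
    out[as.integer(rownames(sums)), ] <- sums
  }
  out
}
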