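#' Fit the sales and/or scrap models ignoring frailty
#'
#' Maximises the Cox partial likelihoods with all frailties fixed at one, by
#' Newton-Raphson from zero with step-halving whenever a step fails to
#' increase the likelihood, stopping when the score max-norm drops below
#' `tol`. Standard errors come from the inverse observed information at the
#' maximum. When company heterogeneity is present but ignored in this way,
#' vessel- and seller-side coefficients are attenuated towards zero, which is
#' exactly what this fitter is for quantifying (and it supplies the initial
#' values for the full MCMC).
#'
#' @param h An `event_history`.
#' @param which `"sale"`, `"scrap"` or `"both"` (models with no events of the
#'   requested type are an error).
#' @param prev_owners Include the number-of-previous-owners vessel covariate.
#' @param use_exogenous Include the exogenous covariate block when the data
#'   carry one (default `TRUE`).
#' @param max_iter,tol Newton-Raphson controls.
#' @return An object of class `nofrailty_fit` with elements `sale` and/or
#'   `scrap`, each holding `estimate`, `std_error`, `vcov`, `loglik`,
#'   `null_loglik`, `iterations`, `converged`, `gradient`.
#' @seealso [tidy.nofrailty_fit()], [glance.nofrailty_fit()]
#' @export
fit_no_frailty <- function(h, which = c("both", "sale", "scrap"),
                           prev_owners = FALSE, use_exogenous = TRUE,
                           max_iter = 50L, tol = 1e-8) {
  which <- match.arg(which)
  mf <- model_frame(h, prev_owners = prev_owners)
  Z <- rep(1, mf$n_company)
  p3 <- if (mf$has_exo && use_exogenous) {
    length(covariate_cols(h$exogenous, "x_E_"))
  } else 0L

  out <- list()
  if (which %in% c("both", "sale")) {
    if (length(mf$sale_ages) == 0) abort("no sale events to fit")
    np <- mf$p_vessel + 2L * mf$p_company + p3
    fn <- function(phi) {
      params <- unpack_sale(phi, mf, p3, prev_owners)
      partial_quantities_sale(mf, params, Z, deriv = TRUE)
    }
    out$sale <- newton_fit(fn, np, max_iter, tol)
  }
  if (which %in% c("both", "scrap")) {
    if (length(mf$scrap_ages) == 0) abort("no scrap events to fit")
    np <- mf$p_vessel + mf$p_company + p3
    fn <- function(phi) {
      params <- unpack_scrap(phi, mf, p3, prev_owners)
      partial_quantities_scrap(mf, params, Z, deriv = TRUE)
    }
    out$scrap <- newton_fit(fn, np, max_iter, tol)
  }
  structure(c(out, list(which = which, prev_owners = prev_owners,
                        p3 = p3, n_company = mf$n_company,
                        n_vessel = mf$n_vessel)),
            class = "nofrailty_fit")
}

unpack_sale <- function(phi, mf, p3, prev_owners) {
  pV <- mf$p_vessel; p2 <- mf$p_company
  hazard_params(
    beta_V = phi[seq_len(pV)],
    beta_S = phi[pV + seq_len(p2)],
    beta_B = phi[pV + p2 + seq_len(p2)],
    beta_E = if (p3) phi[pV + 2 * p2 + seq_len(p3)] else numeric(),
    prev_owners = prev_owners
  )
}

unpack_scrap <- function(phi, mf, p3, prev_owners) {
  pV <- mf$p_vessel; p2 <- mf$p_company
  hazard_params(
    theta_V = phi[seq_len(pV)],
    theta_S = phi[pV + seq_len(p2)],
    theta_E = if (p3) phi[pV + p2 + seq_len(p3)] else numeric(),
    prev_owners = prev_owners
  )
}

newton_fit <- function(fn, np, max_iter, tol) {
  phi <- numeric(np)
  q <- fn(phi)
  null_loglik <- q$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(q$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-q$hess, q$grad),
                     error = function(e) abort("singular observed information"))
    lambda <- 1
    repeat {
      phi_new <- phi + lambda * step
      q_new <- tryCatch(fn(phi_new), error = function(e) NULL)
      if (!is.null(q_new) && is.finite(q_new$loglik) &&
          q_new$loglik >= q$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        abort("step-halving failed to find an uphill step")
      }
    }
    # float-limited optimum: no measurable likelihood progress left
    if (abs(q_new$loglik - q$loglik) < 1e-10 * (abs(q$loglik) + 1) &&
        max(abs(q_new$grad)) < 1e-3) {
      phi <- phi_new
      q <- q_new
      converged <- TRUE
      break
    }
    phi <- phi_new
    q <- q_new
  }
  if (!converged && max(abs(q$grad)) < tol) converged <- TRUE
  if (!converged) {
    warn(sprintf("Newton-Raphson did not converge in %d iterations (max |score| = %.2e)",
                 max_iter, max(abs(q$grad))))
  }
  vcov <- solve(-q$hess)
  est <- setNames(phi, q$terms)
  list(estimate = est, std_error = setNames(sqrt(diag(vcov)), q$terms),
       vcov = vcov, loglik = q$loglik, null_loglik = null_loglik,
       iterations = iter, converged = converged, gradient = q$grad)
}

#' Extract fitted hazard parameters
#'
#' Converts a `nofrailty_fit` into the [hazard_params()] object holding its
#' point estimates (used, e.g., to initialise the MCMC).
#'
#' @param fit A `nofrailty_fit`.
#' @return A [hazard_params()].
#' @export
coef_hazard_params <- function(fit) {
  grab <- function(model, block) {
    if (is.null(model)) return(numeric())
    est <- model$estimate
    unname(est[startsWith(names(est), paste0(block, ":"))])
  }
  hazard_params(
    beta_V = grab(fit$sale, "beta_V"), beta_S = grab(fit$sale, "beta_S"),
    beta_B = grab(fit$sale, "beta_B"), beta_E = grab(fit$sale, "beta_E"),
    theta_V = grab(fit$scrap, "theta_V"), theta_S = grab(fit$scrap, "theta_S"),
    theta_E = grab(fit$scrap, "theta_E"), prev_owners = fit$prev_owners
  )
}

#' @export
print.nofrailty_fit <- function(x, ...) {
  cat("<nofrailty_fit>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a no-frailty fit
#'
#' One row per coefficient with the estimate, its information-based standard
#' error and the Wald statistic, mirroring the usual flat
#' parameter/estimate/SE/Wald result layout.
#'
#' @param x A `nofrailty_fit`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `block`, `covariate`, `term`,
#'   `estimate`, `std.error`, `statistic`.
#' @export
tidy.nofrailty_fit <- function(x, ...) {
  one <- function(m, name) {
    if (is.null(m)) return(NULL)
    terms <- names(m$estimate)
    parts <- strsplit(terms, ":", fixed = TRUE)
    tibble(model = name,
           block = vapply(parts, `[[`, "", 1),
           covariate = vapply(parts, `[[`, "", 2),
           term = terms,
           estimate = unname(m$estimate),
           std.error = unname(m$std_error),
           statistic = unname(m$estimate / m$std_error))
  }
  dplyr::bind_rows(one(x$sale, "sale"), one(x$scrap, "scrap"))
}

#' Glance at a no-frailty fit
#'
#' @param x A `nofrailty_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted model: maximised and null log
#'   partial likelihoods, iteration count and convergence flag.
#' @export
glance.nofrailty_fit <- function(x, ...) {
  one <- function(m, name) {
    if (is.null(m)) return(NULL)
    tibble(model = name, logLik = m$loglik,
           null_logLik = m$null_loglik,
           df = length(m$estimate),
           iterations = m$iterations, converged = m$converged)
  }
  dplyr::bind_rows(one(x$sale, "sale"), one(x$scrap, "scrap"))
}
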