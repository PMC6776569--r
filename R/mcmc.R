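#' MCMC configuration
#'
#' Settings for the Metropolis-Hastings-within-Gibbs sampler. Defaults
#' follow the tuning used in the package's simulation-study protocol:
#' Gaussian random-walk increments with standard deviation 0.07 for the
#' regression blocks and 0.02 for `log(xi)`, all frailties initialised at
#' one, the frailty variance initialised at the low value 0.01, and
#' regression parameters initialised from a no-frailty fit.
#'
#' @param n_iter Total iterations (including burn-in).
#' @param burn_in Iterations discarded before recording.
#' @param beta_sd Proposal SD(s) for the sale-model regression block; a
#'   scalar or one value per coefficient (coefficients on covariates with a
#'   much wider scale warrant a smaller SD, e.g. 0.002 for a deadweight-like
#'   covariate spanning tens of units).
#' @param theta_sd Proposal SD(s) for the scrap-model block.
#' @param logxi_sd Proposal SD for `log(xi)`.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param init `"from_no_frailty"` (default) or `"zeros"` for the regression
#'   parameters; ignored when `init_params` is given.
#' @param init_params Optional [hazard_params()] starting values.
#' @param Z_init Initial frailty value(s), default 1.
#' @param xi_init Initial frailty variance, default 0.01.
#' @param prev_owners Include the previous-owners vessel covariate.
#' @param use_exogenous Include the exogenous block when the data carry one.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 13000L, burn_in = 3000L, beta_sd = 0.07,
                        theta_sd = 0.07, logxi_sd = 0.02, seed = NULL,
                        init = c("from_no_frailty", "zeros"),
                        init_params = NULL, Z_init = 1, xi_init = 0.01,
                        prev_owners = FALSE, use_exogenous = TRUE) {
  init <- match.arg(init)
  if (!(burn_in < n_iter)) abort("`burn_in` must be smaller than `n_iter`")
  if (any(beta_sd < 0) || any(theta_sd < 0) || logxi_sd < 0) {
    abort("proposal standard deviations must be non-negative")
  }
  if (xi_init <= 0) abort("`xi_init` must be positive")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 beta_sd = beta_sd, theta_sd = theta_sd, logxi_sd = logxi_sd,
                 seed = seed, init = init, init_params = init_params,
                 Z_init = Z_init, xi_init = xi_init,
                 prev_owners = prev_owners, use_exogenous = use_exogenous),
            class = "mcmc_config")
}

#' Single Metropolis-Hastings block update
#'
#' Random-walk update of one parameter block. For `"beta"` and `"theta"` the
#' target is the profile likelihood with the baseline re-profiled under the
#' proposal, which reduces exactly to the corresponding partial likelihood
#' at fixed frailties. For `"logxi"` the target is the gamma prior density
#' of the current frailties under `Gamma(1/xi, 1/xi)` with a flat prior on
#' `log(xi)`. A non-finite proposal target is rejected with a warning.
#'
#' @inheritParams full_loglik
#' @param block `"beta"`, `"theta"` or `"logxi"`.
#' @param config An [mcmc_config()] (supplies the proposal SDs).
#' @param baselines Unused for these profiled targets; accepted for
#'   interface symmetry.
#' @return A list with the updated `params`, `frailty`, logical `accept`,
#'   and the `target` value of the retained state.
#' @export
mh_update_block <- function(h, block = c("beta", "theta", "logxi"), params,
                            frailty, config = mcmc_config(), baselines = NULL) {
  block <- match.arg(block)
  mf <- model_frame(h, prev_owners = params$prev_owners)
  check_dims(mf, params)
  Z <- as_frailty_Z(frailty, mf)
  st <- list(params = params, frailty = frailty)
  if (block == "beta") {
    cur <- partial_quantities_sale(mf, params, Z)$loglik
    up <- mh_regression(function(p) partial_quantities_sale(mf, p, Z)$loglik,
                        params, "beta", config$beta_sd, cur, mf, config)
    list(params = up$params, frailty = frailty, accept = up$accept,
         target = up$target)
  } else if (block == "theta") {
    cur <- partial_quantities_scrap(mf, params, Z)$loglik
    up <- mh_regression(function(p) partial_quantities_scrap(mf, p, Z)$loglik,
                        params, "theta", config$theta_sd, cur, mf, config)
    list(params = up$params, frailty = frailty, accept = up$accept,
         target = up$target)
  } else {
    up <- mh_logxi(Z, frailty$xi, config$logxi_sd)
    list(params = params, frailty = frailty_state(Z, up$xi),
         accept = up$accept, target = up$target)
  }
}

pack_block <- function(params, block) {
  if (block == "beta") {
    c(params$beta_V, params$beta_S, params$beta_B, params$beta_E)
  } else {
    c(params$theta_V, params$theta_S, params$theta_E)
  }
}

unpack_block <- function(params, block, phi) {
  if (block == "beta") {
    n <- c(length(params$beta_V), length(params$beta_S),
           length(params$beta_B), length(params$beta_E))
    idx <- split(seq_len(sum(n)), rep.int(1:4, n))
    params$beta_V <- phi[idx[["1"]]] %||% numeric()
    params$beta_S <- phi[idx[["2"]]] %||% numeric()
    params$beta_B <- phi[idx[["3"]]] %||% numeric()
    params$beta_E <- phi[idx[["4"]]] %||% numeric()
  } else {
    n <- c(length(params$theta_V), length(params$theta_S),
           length(params$theta_E))
    idx <- split(seq_len(sum(n)), rep.int(1:3, n))
    params$theta_V <- phi[idx[["1"]]] %||% numeric()
    params$theta_S <- phi[idx[["2"]]] %||% numeric()
    params$theta_E <- phi[idx[["3"]]] %||% numeric()
  }
  params
}

mh_regression <- function(target_fn, params, block, sd, cur, mf, config) {
  phi <- pack_block(params, block)
  phi_new <- phi + rnorm(length(phi), 0, rep_len(sd, length(phi)))
  prop <- unpack_block(params, block, phi_new)
  new <- tryCatch(target_fn(prop), error = function(e) -Inf)
  if (!is.finite(new)) {
    if (!identical(new, -Inf)) warn("non-finite MH target; proposal rejected")
    return(list(params = params, accept = FALSE, target = cur))
  }
  if (log(runif(1)) <= new - cur) {
    list(params = prop, accept = TRUE, target = new)
  } else {
    list(params = params, accept = FALSE, target = cur)
  }
}

mh_logxi <- function(Z, xi, sd) {
  lx <- log(xi)
  lx_new <- lx + rnorm(1, 0, sd)
  xi_new <- exp(lx_new)
  tgt <- function(x) sum(dgamma(Z, shape = 1 / x, rate = 1 / x, log = TRUE))
  cur <- tgt(xi)
  new <- tgt(xi_new)
  if (is.finite(new) && log(runif(1)) <= new - cur) {
    list(xi = xi_new, accept = TRUE, target = new)
  } else {
    list(xi = xi, accept = FALSE, target = cur)
  }
}

#' Run the MH-within-Gibbs sampler
#'
#' Per iteration: (1) profile the baseline increments by the Breslow
#' formulas at the current parameters and frailties; (2) joint random-walk
#' MH update of the sale-model regression block against its profiled
#' (partial-likelihood) target; (3) the same for the scrap block when the
#' data contain scrap events; (4) a Gibbs sweep over all company frailties
#' from their generalised inverse Gaussian full conditionals, using the
#' iteration's profiled baselines; (5) MH update of `log(xi)` against the
#' gamma prior of the frailties. States after burn-in are recorded. Given a
#' seed the entire chain is deterministic.
#'
#' @param h An `event_history` with at least one event.
#' @param config An [mcmc_config()].
#' @return An object of class `dualfrailty_mcmc`: retained draws
#'   (`$draws`: one row per kept iteration with the regression parameters,
#'   `xi` and the profiled log-likelihood), per-company frailty posterior
#'   summaries (`$frailty`), acceptance rates (`$acceptance`), and the
#'   configuration.
#' @export
run_mcmc <- function(h, config = mcmc_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  mf <- model_frame(h, prev_owners = config$prev_owners)
  has_sale <- length(mf$sale_ages) > 0
  has_scrap <- length(mf$scrap_ages) > 0
  if (!has_sale && !has_scrap) abort("no events in the data")

  p3 <- if (mf$has_exo && config$use_exogenous) {
    length(covariate_cols(h$exogenous, "x_E_"))
  } else 0L

  params <- init_mcmc_params(h, mf, config, p3, has_sale, has_scrap)
  check_dims(mf, params)
  Z <- rep_len(as.numeric(config$Z_init), mf$n_company)
  xi <- config$xi_init

  n_beta <- length(pack_block(params, "beta"))
  n_theta <- length(pack_block(params, "theta"))
  beta_sd <- rep_len(config$beta_sd, max(n_beta, 1L))
  theta_sd <- rep_len(config$theta_sd, max(n_theta, 1L))

  keep <- config$n_iter - config$burn_in
  beta_trace <- matrix(NA_real_, keep, n_beta)
  theta_trace <- matrix(NA_real_, keep, n_theta)
  xi_trace <- numeric(keep)
  ll_trace <- numeric(keep)
  z_sum <- numeric(mf$n_company)
  z_sum2 <- numeric(mf$n_company)
  acc <- c(beta = 0, theta = 0, logxi = 0)

  ev <- if (has_sale) sale_events(mf)
  sv <- if (has_scrap) scrap_events(mf)

  sale_target <- function(p, D) {
    sum(sale_event_eta(mf, p, ev) + log(Z[ev$oidx]) - log(Z[ev$bidx])) -
      sum(mf$dN_sale * log(D))
  }
  scrap_target <- function(p, D) {
    sum(scrap_event_eta(mf, p, sv) + log(Z[sv$oidx])) -
      sum(mf$dN_scrap * log(D))
  }

  for (iter in seq_len(config$n_iter)) {
    # (1) profile baselines at the iteration-start state
    D_sale <- if (has_sale) sale_denominator(mf, params, Z, mf$sale_ages)
    D_scrap <- if (has_scrap) scrap_denominator(mf, params, Z, mf$scrap_ages)
    if (has_sale && any(D_sale <= 0)) abort("zero sale risk-set denominator")
    if (has_scrap && any(D_scrap <= 0)) abort("zero scrap risk-set denominator")
    baselines <- list(
      sale = if (has_sale) {
        tibble(age = mf$sale_ages, increment = mf$dN_sale / D_sale)
      } else tibble(age = numeric(), increment = numeric()),
      scrap = if (has_scrap) {
        tibble(age = mf$scrap_ages, increment = mf$dN_scrap / D_scrap)
      } else tibble(age = numeric(), increment = numeric())
    )

    # (2) sale regression block
    if (has_sale && n_beta > 0) {
      cur <- sale_target(params, D_sale)
      phi <- pack_block(params, "beta")
      prop <- unpack_block(params, "beta",
                           phi + rnorm(n_beta, 0, beta_sd))
      D_prop <- sale_denominator(mf, prop, Z, mf$sale_ages)
      new <- if (all(D_prop > 0)) sale_target(prop, D_prop) else -Inf
      if (is.finite(new) && log(runif(1)) <= new - cur) {
        params <- prop
        acc["beta"] <- acc["beta"] + 1
      }
    }

    # (3) scrap regression block
    if (has_scrap && n_theta > 0) {
      cur <- scrap_target(params, D_scrap)
      phi <- pack_block(params, "theta")
      prop <- unpack_block(params, "theta",
                           phi + rnorm(n_theta, 0, theta_sd))
      D_prop <- scrap_denominator(mf, prop, Z, mf$scrap_ages)
      new <- if (all(D_prop > 0)) scrap_target(prop, D_prop) else -Inf
      if (is.finite(new) && log(runif(1)) <= new - cur) {
        params <- prop
        acc["theta"] <- acc["theta"] + 1
      }
    }

    # (4) Gibbs sweep over frailties (baselines held at the profiled values)
    Z <- gibbs_update_Z_core(mf, params, Z, xi, baselines)

    # (5) frailty variance
    up <- mh_logxi(Z, xi, config$logxi_sd)
    xi <- up$xi
    acc["logxi"] <- acc["logxi"] + up$accept

    if (iter > config$burn_in) {
      k <- iter - config$burn_in
      beta_trace[k, ] <- pack_block(params, "beta")
      theta_trace[k, ] <- pack_block(params, "theta")
      xi_trace[k] <- xi
      ll <- 0
      if (has_sale) {
        Ds <- sale_denominator(mf, params, Z, mf$sale_ages)
        ll <- ll + sale_target(params, Ds) +
          sum(mf$dN_sale * log(mf$dN_sale)) - sum(mf$dN_sale)
      }
      if (has_scrap) {
        Dl <- scrap_denominator(mf, params, Z, mf$scrap_ages)
        ll <- ll + scrap_target(params, Dl) +
          sum(mf$dN_scrap * log(mf$dN_scrap)) - sum(mf$dN_scrap)
      }
      ll_trace[k] <- ll
      z_sum <- z_sum + Z
      z_sum2 <- z_sum2 + Z^2
    }
  }

  nm_beta <- sale_term_names(mf, p3)
  nm_theta <- scrap_term_names(mf, p3, has_scrap)
  draws <- tibble(.iter = config$burn_in + seq_len(keep))
  if (n_beta) for (j in seq_len(n_beta)) draws[[nm_beta[j]]] <- beta_trace[, j]
  if (n_theta) for (j in seq_len(n_theta)) draws[[nm_theta[j]]] <- theta_trace[, j]
  draws$xi <- xi_trace
  draws$loglik <- ll_trace

  zm <- z_sum / keep
  zsd <- sqrt(pmax(z_sum2 / keep - zm^2, 0) * keep / max(keep - 1, 1))
  structure(list(
    draws = draws,
    frailty = tibble(company_id = h$companies$company_id,
                     post_mean_Z = zm, post_sd_Z = zsd),
    acceptance = tibble(block = names(acc),
                        rate = unname(acc) / config$n_iter),
    config = config,
    param_names = c(nm_beta, nm_theta)
  ), class = "dualfrailty_mcmc")
}

init_mcmc_params <- function(h, mf, config, p3, has_sale, has_scrap) {
  if (!is.null(config$init_params)) return(config$init_params)
  if (config$init == "from_no_frailty") {
    which <- if (has_sale && has_scrap) "both" else if (has_sale) "sale" else "scrap"
    fit <- fit_no_frailty(h, which, prev_owners = config$prev_owners,
                          use_exogenous = config$use_exogenous && p3 > 0)
    coef_hazard_params(fit)
  } else {
    z <- function(p) rep(0, p)
    hazard_params(
      beta_V = if (has_sale) z(mf$p_vessel) else numeric(),
      beta_S = if (has_sale) z(mf$p_company) else numeric(),
      beta_B = if (has_sale) z(mf$p_company) else numeric(),
      beta_E = if (has_sale && p3) z(p3) else numeric(),
      theta_V = if (has_scrap) z(mf$p_vessel) else numeric(),
      theta_S = if (has_scrap) z(mf$p_company) else numeric(),
      theta_E = if (has_scrap && p3) z(p3) else numeric(),
      prev_owners = config$prev_owners
    )
  }
}

sale_term_names <- function(mf, p3) {
  c(block_names("beta_V", colnames(mf$spell$XV), mf$p_vessel),
    block_names("beta_S", colnames(mf$XC), mf$p_company),
    block_names("beta_B", colnames(mf$XC), mf$p_company),
    if (p3) block_names("beta_E", covariate_cols(mf$h$exogenous, "x_E_"), p3))
}

scrap_term_names <- function(mf, p3, has_scrap) {
  if (!has_scrap) return(character())
  c(block_names("theta_V", colnames(mf$spell$XV), mf$p_vessel),
    block_names("theta_S", colnames(mf$XC), mf$p_company),
    if (p3) block_names("theta_E", covariate_cols(mf$h$exogenous, "x_E_"), p3))
}

#' @export
print.dualfrailty_mcmc <- function(x, ...) {
  cat(sprintf("<dualfrailty_mcmc> %d retained draws (of %d, burn-in %d)\n",
              nrow(x$draws), x$config$n_iter, x$config$burn_in))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Posterior summaries of an MCMC run
#'
#' One row per model parameter with the posterior mean, the within-run
#' posterior standard deviation (the "estimated SE" when tabulating
#' simulation results) and central 95% interval.
#'
#' @param x A `dualfrailty_mcmc`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `mean`, `sd`, `q2.5`, `q97.5`.
#' @export
tidy.dualfrailty_mcmc <- function(x, ...) {
  terms <- c(x$param_names, "xi")
  purrr::map_dfr(terms, function(tm) {
    v <- x$draws[[tm]]
    tibble(term = tm, mean = mean(v), sd = sd(v),
           q2.5 = unname(quantile(v, 0.025)),
           q97.5 = unname(quantile(v, 0.975)))
  })
}

#' @rdname tidy.dualfrailty_mcmc
#' @export
glance.dualfrailty_mcmc <- function(x, ...) {
  tibble(n_draws = nrow(x$draws),
         n_iter = x$config$n_iter, burn_in = x$config$burn_in,
         xi_mean = mean(x$draws$xi),
         accept_beta = x$acceptance$rate[x$acceptance$block == "beta"],
         accept_logxi = x$acceptance$rate[x$acceptance$block == "logxi"])
}

#' @rdname tidy.dualfrailty_mcmc
#' @param object A `dualfrailty_mcmc`.
#' @export
summary.dualfrailty_mcmc <- function(object, ...) {
  list(parameters = tidy(object), acceptance = object$acceptance,
       frailty = object$frailty)
}

#' Trace plots for an MCMC run
#'
#' @param object A `dualfrailty_mcmc`.
#' @param pars Parameters to show (default: all regression parameters and
#'   `xi`).
#' @param ... Unused.
#' @return A ggplot object with one facet per parameter.
#' @export
autoplot.dualfrailty_mcmc <- function(object, pars = NULL, ...) {
  pars <- pars %||% c(object$param_names, "xi")
  df <- tidyr::pivot_longer(object$draws[c(".iter", pars)],
                            -".iter", names_to = "term")
  ggplot2::ggplot(df, ggplot2::aes(.data$.iter, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}
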