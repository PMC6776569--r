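#' Simulation configuration
#'
#' Describes a synthetic fleet and its generating mechanism. The defaults
#' reproduce the package's reference simulation design: 500 companies and
#' 1000 vessels followed for 500 months from a common delivery time, a
#' baseline sales intensity of 1e-5 per month for every (vessel, eligible
#' buyer) pair, two vessel covariates (binary, and uniform on +/-20 — a
#' vessel-category and centred-deadweight stand-in), two binary company
#' covariates, coefficients `beta_V = (0.3, -0.01)`, `beta_S = (0.4, -0.2)`,
#' `beta_B = (-0.2, 0.1)`, gamma frailties with variance `xi`, no scrapping,
#' no exogenous series and all companies active throughout. Under these
#' settings a dataset typically contains on the order of 1800-2000 sales.
#'
#' @param n_companies,n_vessels Population sizes.
#' @param horizon Follow-up length in months (censoring time).
#' @param baseline Baseline sales intensity per (vessel, buyer) pair per
#'   month.
#' @param beta_V,beta_S,beta_B Generating sale-model coefficients.
#' @param xi Frailty variance (`0` switches frailty off, all `Z = 1`).
#' @param vessel_covariates,company_covariates Named lists of generator
#'   functions `function(n)` producing each covariate column.
#' @param scrap `NULL` (no scrapping) or a list with elements `baseline`
#'   (per-month scrap hazard: scalar or `function(age)`), `theta_V`,
#'   `theta_S`.
#' @param exogenous `NULL` or a list with `series` (a data frame of `time`
#'   and `x_E_*` columns), `beta_E` and optionally `theta_E`.
#' @param activity `NULL` (all companies active throughout) or a data frame
#'   `company` (integer index), `activity_start`, `activity_end`.
#' @param deliveries Delivery calendar time(s): scalar or length
#'   `n_vessels`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_companies = 500L, n_vessels = 1000L, horizon = 500,
                       baseline = 1e-5,
                       beta_V = c(0.3, -0.01), beta_S = c(0.4, -0.2),
                       beta_B = c(-0.2, 0.1), xi = 0.2,
                       vessel_covariates = list(
                         x_V_1 = function(n) rbinom(n, 1, 0.5),
                         x_V_2 = function(n) runif(n, -20, 20)
                       ),
                       company_covariates = list(
                         x_C_1 = function(n) rbinom(n, 1, 0.5),
                         x_C_2 = function(n) rbinom(n, 1, 0.5)
                       ),
                       scrap = NULL, exogenous = NULL, activity = NULL,
                       deliveries = 0, seed = NULL) {
  stopifnot(n_companies >= 2, n_vessels >= 1, horizon > 0, baseline > 0,
            xi >= 0)
  structure(list(n_companies = as.integer(n_companies),
                 n_vessels = as.integer(n_vessels), horizon = horizon,
                 baseline = baseline, beta_V = beta_V, beta_S = beta_S,
                 beta_B = beta_B, xi = xi,
                 vessel_covariates = vessel_covariates,
                 company_covariates = company_covariates,
                 scrap = scrap, exogenous = exogenous, activity = activity,
                 deliveries = deliveries, seed = seed),
            class = "sim_config")
}

#' Draw the company and vessel population
#'
#' Samples covariates from the configured generators, frailties from
#' `Gamma(1/xi, 1/xi)` (all one when `xi = 0`), and each vessel's first
#' owner uniformly at random among the companies.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `companies` and `vessels`, the numeric
#'   frailty vector `Z` and integer `first_owner` indices.
#' @export
draw_population <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$n_companies
  K <- config$n_vessels
  co <- tibble(company_id = sprintf("c%0*d", nchar(N), seq_len(N)))
  for (nm in names(config$company_covariates)) {
    co[[nm]] <- as.numeric(config$company_covariates[[nm]](N))
  }
  deliveries <- rep_len(config$deliveries, K)
  horizon_end <- max(deliveries) + config$horizon
  if (is.null(config$activity)) {
    co$activity_start <- min(0, min(deliveries))
    co$activity_end <- horizon_end
  } else {
    co$activity_start <- config$activity$activity_start
    co$activity_end <- config$activity$activity_end
  }
  ve <- tibble(vessel_id = sprintf("v%0*d", nchar(K), seq_len(K)),
               delivery_time = deliveries)
  for (nm in names(config$vessel_covariates)) {
    ve[[nm]] <- as.numeric(config$vessel_covariates[[nm]](K))
  }
  Z <- if (config$xi > 0) {
    rgamma(N, shape = 1 / config$xi, rate = 1 / config$xi)
  } else {
    rep(1, N)
  }
  first_owner <- sample.int(N, K, replace = TRUE)
  list(companies = co, vessels = ve, Z = Z, first_owner = first_owner)
}

#' Simulate a dual-frailty transaction history
#'
#' Discrete-time simulation on a monthly grid. Each month, each in-use
#' vessel faces per-buyer sale rates
#' `baseline * Z_s / Z_b * exp(beta_V x_v + beta_S x_s + beta_B x_b [+ beta_E x_E(t)])`
#' over the active companies other than its owner, plus (optionally) a
#' competing scrap hazard. An event occurs with probability
#' `1 - exp(-total rate)`; its type and, for sales, the buyer are drawn in
#' proportion to the rates, so at most one event happens per vessel per
#' month. Ownership transfers from the following month. Surviving vessels
#' are censored at the horizon. Recorded event ages are month indices,
#' deliberately producing the heavy ties the Breslow-style estimators must
#' aggregate.
#'
#' @param config A [sim_config()].
#' @param population Optionally a population from [draw_population()] (drawn
#'   afresh otherwise).
#' @return A validated [event_history()].
#' @export
simulate_fleet <- function(config, population = NULL) {
  if (is.null(population)) {
    population <- draw_population(config)   # also sets the seed
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  co <- population$companies
  ve <- population$vessels
  Z <- population$Z
  N <- nrow(co)
  K <- nrow(ve)
  XC <- as.matrix(co[covariate_cols(co, "x_C_")])
  XV <- as.matrix(ve[covariate_cols(ve, "x_V_")])

  wB <- exp(drop(XC %*% config$beta_B)) / Z
  eS <- exp(drop(XC %*% config$beta_S))   # seller-company factor
  eV <- exp(drop(XV %*% config$beta_V))   # vessel factor
  has_scrap <- !is.null(config$scrap)
  if (has_scrap) {
    eVq <- exp(drop(XV %*% config$scrap$theta_V))
    eSq <- exp(drop(XC %*% config$scrap$theta_S))
    lam0 <- config$scrap$baseline
    lam0_at <- if (is.function(lam0)) lam0 else function(a) rep(lam0, length(a))
  }
  exo <- config$exogenous
  exo_sale_at <- function(t) {
    if (is.null(exo)) rep(1, length(t))
    else exp(drop(exogenous_at(exo$series, t) %*% exo$beta_E))
  }
  exo_scrap_at <- function(t) {
    if (is.null(exo) || is.null(exo$theta_E)) rep(1, length(t))
    else exp(drop(exogenous_at(exo$series, t) %*% exo$theta_E))
  }

  act_start <- co$activity_start
  act_end <- co$activity_end
  all_active <- all(act_start <= min(0, ve$delivery_time)) &&
    all(act_end >= max(ve$delivery_time) + config$horizon)

  owner <- population$first_owner
  alive <- rep(TRUE, K)
  # event log: per vessel, growing lists of (age, buyer) plus final fate
  ev_vessel <- integer(0)
  ev_age <- numeric(0)
  ev_buyer <- integer(0)   # NA for scrap
  horizon <- config$horizon
  # monthly event opportunities at ages 1..horizon-1; survivors are censored
  # at age `horizon`, so no spell can be empty
  for (m in seq_len(horizon - 1)) {
    act_v <- which(alive)
    if (length(act_v) == 0) break
    tv <- ve$delivery_time[act_v] + m
    if (all_active) {
      Wz <- sum(wB)
      Wz_v <- rep(Wz, length(act_v))
    } else {
      stepf <- local({
        brk <- sort(unique(c(act_start, act_end)))
        delta <- numeric(length(brk) + 1)
        add <- rowsum(c(wB, -wB), group = c(match(act_start, brk),
                                            match(act_end, brk)))
        delta[as.integer(rownames(add))] <- add
        cum <- cumsum(delta)[seq_along(brk)]
        function(t) {
          i <- findInterval(t, brk)
          out <- numeric(length(t)); out[i >= 1] <- cum[i[i >= 1]]; out
        }
      })
      Wz_v <- stepf(tv)
    }
    o <- owner[act_v]
    own_active <- act_start[o] <= tv & tv < act_end[o]
    rate_sale <- config$baseline * exo_sale_at(tv) * Z[o] * eV[act_v] * eS[o] *
      pmax(Wz_v - wB[o] * own_active, 0)
    rate_scrap <- if (has_scrap) {
      lam0_at(rep(m, length(act_v))) * exo_scrap_at(tv) * Z[o] *
        eVq[act_v] * eSq[o]
    } else {
      numeric(length(act_v))
    }
    total <- rate_sale + rate_scrap
    u <- runif(length(act_v))
    hit <- which(u < 1 - exp(-total))
    for (j in hit) {
      v <- act_v[j]
      is_scrap <- has_scrap &&
        runif(1) < rate_scrap[j] / (rate_sale[j] + rate_scrap[j])
      if (is_scrap) {
        ev_vessel <- c(ev_vessel, v); ev_age <- c(ev_age, m)
        ev_buyer <- c(ev_buyer, NA_integer_)
        alive[v] <- FALSE
      } else {
        w <- wB
        tvj <- ve$delivery_time[v] + m
        if (!all_active) w <- w * (act_start <= tvj & tvj < act_end)
        w[owner[v]] <- 0
        if (sum(w) <= 0) next   # no eligible buyer this month
        b <- sample.int(N, 1, prob = w)
        ev_vessel <- c(ev_vessel, v); ev_age <- c(ev_age, m)
        ev_buyer <- c(ev_buyer, b)
        owner[v] <- b
      }
    }
  }

  spells <- build_spells(ve, co, population$first_owner,
                         ev_vessel, ev_age, ev_buyer, horizon)
  event_history(companies = co, vessels = ve, spells = spells,
                exogenous = if (!is.null(exo)) as_tibble(exo$series),
                window = c(min(0, min(ve$delivery_time)),
                           max(ve$delivery_time),
                           max(ve$delivery_time) + horizon))
}

build_spells <- function(ve, co, first_owner, ev_vessel, ev_age, ev_buyer,
                         horizon) {
  K <- nrow(ve)
  rows <- vector("list", K)
  for (v in seq_len(K)) {
    idx <- which(ev_vessel == v)
    idx <- idx[order(ev_age[idx])]
    owners <- first_owner[v]
    starts <- 0
    ends <- numeric(0)
    types <- character(0)
    buyers <- character(0)
    for (i in idx) {
      if (is.na(ev_buyer[i])) {
        ends <- c(ends, ev_age[i]); types <- c(types, "scrap")
        buyers <- c(buyers, NA_character_)
      } else {
        ends <- c(ends, ev_age[i]); types <- c(types, "sale")
        buyers <- c(buyers, co$company_id[ev_buyer[i]])
        owners <- c(owners, ev_buyer[i])
        starts <- c(starts, ev_age[i])
      }
    }
    if (length(types) == 0 || types[length(types)] == "sale") {
      ends <- c(ends, horizon); types <- c(types, "censor")
      buyers <- c(buyers, NA_character_)
    }
    rows[[v]] <- tibble(
      vessel_id = ve$vessel_id[v],
      owner_id = co$company_id[owners],
      start_age = starts, end_age = ends, end_type = types,
      buyer_id = buyers
    )
  }
  dplyr::bind_rows(rows)
}

#' Summarise a (simulated or real) event history
#'
#' Counts mirroring a transactions-data overview: vessels by fate, total
#' sales, and the distribution of the number of owners per vessel.
#'
#' @param h An `event_history`.
#' @return A tibble with columns `measure` and `value`; rows `owners_k` give
#'   the number of vessels with exactly `k` owners.
#' @export
sim_summary <- function(h) {
  sp <- h$spells
  per_v <- split(sp$end_type, sp$vessel_id)
  fate <- vapply(per_v, function(x) x[length(x)], "")
  n_owners <- vapply(per_v, length, 0L)
  owners_tab <- table(n_owners)
  tibble(
    measure = c("n_companies", "n_vessels", "n_censored", "n_scrapped",
                "n_sales", paste0("owners_", names(owners_tab))),
    value = c(nrow(h$companies), nrow(h$vessels),
              sum(fate == "censor"), sum(fate == "scrap"),
              sum(sp$end_type == "sale"), as.integer(owners_tab))
  )
}
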