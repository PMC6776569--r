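test_that("sale partial likelihood matches hand enumeration and invariances", {
  p0 <- hazard_params(beta_V = c(0, 0), beta_S = c(0, 0), beta_B = c(0, 0))
  h1 <- toy_onesale()
  expect_equal(partial_loglik_sale(h1, p0, frailty_state(1, 0.2, 3)),
               log(1 / 4))

  # invariant under Z -> cZ (ratio structure)
  h <- toy_history()
  p <- ref_params()
  fr <- frailty_state(c(1.3, 0.7, 1.2), 0.3)
  expect_equal(partial_loglik_sale(h, p, fr),
               partial_loglik_sale(h, p, frailty_state(fr$Z * 11, fr$xi)))
  expect_equal(partial_loglik_scrap(h, p, fr),
               partial_loglik_scrap(h, p, frailty_state(fr$Z * 11, fr$xi)))
})

test_that("partial likelihood is the profiled full likelihood in beta", {
  h <- random_history(17, scrap = FALSE)
  fr <- frailty_state(1, 0.2, nrow(h$companies))
  n_sales <- sum(h$spells$end_type == "sale")
  mk <- function(b1) hazard_params(beta_V = c(b1, 0), beta_S = c(0, 0),
                                   beta_B = c(0, 0))
  grid <- seq(-0.5, 1, by = 0.25)
  gap <- vapply(grid, function(b1) {
    p <- mk(b1)
    bl <- breslow_baselines(h, p, fr)
    dn <- breslow_sale(h, p, fr)$n_events
    full_loglik(h, p, fr, bl) - partial_loglik_sale(h, p, fr)
  }, 0)
  # the difference sum(dN log dN) - n_events is free of beta
  expect_equal(max(gap) - min(gap), 0, tolerance = 1e-6)
  dN <- breslow_sale(h, mk(0), fr)$n_events
  expect_equal(gap[1], sum(dN * log(dN)) - n_sales, tolerance = 1e-8)
})

test_that("scrap partial likelihood matches a hand-computed Cox toy", {
  # 3 vessels, single owner each, scrap times 1 < 2, third censored at 3;
  # scalar covariate x = (1, 0, 2) via x_V_1, theta = 0.5
  companies <- tibble::tibble(company_id = c("c1", "c2"), x_C_1 = c(0, 0),
                              activity_start = 0, activity_end = 10)
  vessels <- tibble::tibble(vessel_id = c("v1", "v2", "v3"), delivery_time = 0,
                            x_V_1 = c(1, 0, 2))
  spells <- tibble::tibble(vessel_id = c("v1", "v2", "v3"),
                           owner_id = "c1", start_age = 0,
                           end_age = c(1, 2, 3),
                           end_type = c("scrap", "scrap", "censor"),
                           buyer_id = NA_character_)
  h <- event_history(companies, vessels, spells, window = c(0, 0, 10))
  th <- 0.5
  p <- hazard_params(theta_V = th, theta_S = 0)
  want <- (th * 1 - log(exp(th) + 1 + exp(2 * th))) +
    (th * 0 - log(1 + exp(2 * th)))
  expect_equal(partial_loglik_scrap(h, p, frailty_state(1, 0.2, 2)), want)

  # theta = 0 gives sum log(1 / #at-risk)
  p0 <- hazard_params(theta_V = 0, theta_S = 0)
  expect_equal(partial_loglik_scrap(h, p0, frailty_state(1, 0.2, 2)),
               log(1 / 3) + log(1 / 2))
})

test_that("analytic derivatives match numerical differentiation", {
  h <- random_history(23)
  N <- nrow(h$companies)
  set.seed(12)
  fr <- frailty_state(rgamma(N, 4, 4), 0.25)
  phi0 <- c(0.3, -0.01, 0.4, -0.2, -0.2, 0.1)
  f_sale <- function(phi) {
    partial_loglik_sale(h, hazard_params(beta_V = phi[1:2], beta_S = phi[3:4],
                                         beta_B = phi[5:6]), fr)
  }
  an <- partial_loglik_sale(h, hazard_params(beta_V = phi0[1:2],
                                             beta_S = phi0[3:4],
                                             beta_B = phi0[5:6]),
                            fr, derivatives = TRUE)
  expect_equal(unname(attr(an, "gradient")), numDeriv::grad(f_sale, phi0),
               tolerance = 1e-6)
  expect_equal(unname(attr(an, "hessian")), numDeriv::hessian(f_sale, phi0),
               tolerance = 1e-5)

  phs <- c(0.1, 0.02, -0.1, 0.2)
  f_scrap <- function(phi) {
    partial_loglik_scrap(h, hazard_params(theta_V = phi[1:2],
                                          theta_S = phi[3:4]), fr)
  }
  an2 <- partial_loglik_scrap(h, hazard_params(theta_V = phs[1:2],
                                               theta_S = phs[3:4]),
                              fr, derivatives = TRUE)
  expect_equal(unname(attr(an2, "gradient")), numDeriv::grad(f_scrap, phs),
               tolerance = 1e-6)
  expect_equal(unname(attr(an2, "hessian")), numDeriv::hessian(f_scrap, phs),
               tolerance = 1e-5)
})

test_that("derivatives also match on the pair-level path with an exogenous block", {
  h <- random_history(29, scrap = FALSE, n_companies = 6, n_vessels = 10)
  h <- event_history(h$companies, h$vessels, h$spells,
                     exogenous = tibble::tibble(time = c(0, 50, 100),
                                                x_E_1 = c(-1, 0.5, 1)),
                     window = h$window)
  fr <- frailty_state(1, 0.2, 6)
  phi0 <- c(0.2, -0.02, 0.3, -0.1, -0.15, 0.05, 0.4)
  f <- function(phi) {
    partial_loglik_sale(h, hazard_params(beta_V = phi[1:2], beta_S = phi[3:4],
                                         beta_B = phi[5:6], beta_E = phi[7]),
                        fr)
  }
  an <- partial_loglik_sale(h, hazard_params(beta_V = phi0[1:2],
                                             beta_S = phi0[3:4],
                                             beta_B = phi0[5:6],
                                             beta_E = phi0[7]),
                            fr, derivatives = TRUE)
  expect_equal(unname(attr(an, "gradient")), numDeriv::grad(f, phi0),
               tolerance = 1e-6)
  expect_equal(unname(attr(an, "hessian")), numDeriv::hessian(f, phi0),
               tolerance = 1e-5)
})
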