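# brute-force Breslow oracle built from risk_set() enumeration only
brute_breslow_sale <- function(h, params, frailty) {
  Z <- setNames(rep_len(frailty$Z, nrow(h$companies)), h$companies$company_id)
  sales <- h$spells[h$spells$end_type == "sale", ]
  ages <- sort(unique(sales$end_age))
  inc <- vapply(ages, function(a) {
    rs <- risk_set(h, a)
    den <- 0
    for (i in seq_len(nrow(rs))) {
      for (b in rs$buyers[[i]]) {
        den <- den + Z[[rs$owner_id[i]]] / Z[[b]] *
          relative_risk_sale(h, rs$vessel_id[i], a, b, params)
      }
    }
    sum(sales$end_age == a) / den
  }, 0)
  tibble::tibble(age = ages, increment = inc)
}

test_that("sale baseline increments match hand enumeration", {
  p0 <- hazard_params(beta_V = c(0, 0), beta_S = c(0, 0), beta_B = c(0, 0))
  h1 <- toy_onesale()     # one sale, 2 at-risk vessels x 2 buyers each
  b1 <- breslow_sale(h1, p0, frailty_state(1, 0.2, 3))
  expect_equal(b1$increment, 1 / 4)
  expect_equal(b1$denominator, 4)

  # Z = (2, 1, 1), owners (c1, c2): denominator 2*2 + 1*1.5 = 5.5
  b2 <- breslow_sale(h1, p0, frailty_state(c(2, 1, 1), 0.2))
  expect_equal(b2$increment, 2 / 11)

  # beta = 0, Z = 1: total mass equals sum over events of 1 / #pairs
  h <- toy_history()
  b3 <- breslow_sale(h, p0, frailty_state(1, 0.2, 3))
  expect_equal(sum(b3$increment), 1 / 4 + 1 / 2)
})

test_that("Breslow estimators agree with brute-force pair enumeration", {
  for (seed in c(2, 7)) {
    h <- random_history(seed, scrap = FALSE, n_companies = 5, n_vessels = 5,
                        horizon = 120, baseline = 2e-3)
    if (!any(h$spells$end_type == "sale")) next
    p <- hazard_params(beta_V = c(0.3, -0.01), beta_S = c(0.4, -0.2),
                       beta_B = c(-0.2, 0.1))
    set.seed(seed)
    fr <- frailty_state(rgamma(5, 4, 4), 0.25)
    got <- breslow_sale(h, p, fr)
    want <- brute_breslow_sale(h, p, fr)
    expect_equal(got$age, want$age)
    expect_equal(got$increment, want$increment, tolerance = 1e-10)
  }
})

test_that("scrap baseline reduces to Nelson-Aalen and handles frailty weights", {
  h <- toy_history()
  p0 <- hazard_params(theta_V = c(0, 0), theta_S = c(0, 0))
  b <- breslow_scrap(h, p0, frailty_state(1, 0.2, 3))
  expect_equal(b$increment, 1 / 2)   # 1 scrap, 2 vessels at risk at age 90

  # owner-weighted: at 90 owners are c2 (v1) and c2 (v2) -> denominator 2*Z_c2
  fr <- frailty_state(c(1, 2, 1), 0.2)
  b2 <- breslow_scrap(h, p0, fr)
  expect_equal(b2$increment, 1 / 4)

  # ties aggregate through the numerator on simulated data
  hs <- random_history(5)
  skip_if(sum(hs$spells$end_type == "scrap") < 2)
  bs <- breslow_scrap(hs, ref_params(), frailty_state(1, 0.2, nrow(hs$companies)))
  expect_equal(sum(bs$n_events), sum(hs$spells$end_type == "scrap"))
  expect_false(anyDuplicated(bs$age) > 0)

  # Nelson-Aalen on vessels, against the survival package
  dat <- hs$spells
  fitNA <- survival::survfit(
    survival::Surv(dat$start_age, dat$end_age, dat$end_type == "scrap") ~ 1)
  na_inc <- fitNA$n.event / fitNA$n.risk
  na_inc <- na_inc[fitNA$n.event > 0]
  b0 <- breslow_scrap(hs, hazard_params(theta_V = c(0, 0), theta_S = c(0, 0)),
                      frailty_state(1, 0.2, nrow(hs$companies)))
  expect_equal(b0$increment, unname(na_inc), tolerance = 1e-10)
})

test_that("spell-aggregated and pair-level engine paths agree", {
  # attaching a zero-coefficient exogenous block forces the pair-level path
  # without changing the model
  h <- random_history(21, scrap = FALSE)
  h_exo <- event_history(h$companies, h$vessels, h$spells,
                         exogenous = tibble::tibble(time = c(0, 40, 90),
                                                    x_E_1 = c(0.5, 1.5, 1)),
                         window = h$window)
  p_fast <- hazard_params(beta_V = c(0.3, -0.01), beta_S = c(0.4, -0.2),
                          beta_B = c(-0.2, 0.1))
  p_pair <- hazard_params(beta_V = c(0.3, -0.01), beta_S = c(0.4, -0.2),
                          beta_B = c(-0.2, 0.1), beta_E = 0)
  set.seed(8)
  fr <- frailty_state(rgamma(nrow(h$companies), 4, 4), 0.25)
  expect_equal(breslow_sale(h_exo, p_pair, fr)$increment,
               breslow_sale(h, p_fast, fr)$increment, tolerance = 1e-12)
  expect_equal(partial_loglik_sale(h_exo, p_pair, fr),
               partial_loglik_sale(h, p_fast, fr), tolerance = 1e-12)
})

test_that("baseline plotting returns a step-function ggplot", {
  h <- toy_history()
  b <- breslow_baselines(h, ref_params(), frailty_state(1, 0.2, 3))
  pl <- autoplot(b, rescale = c(sale = 2, scrap = 1))
  expect_s3_class(pl, "ggplot")
})
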