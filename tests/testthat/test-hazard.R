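test_that("relative risks are exponentials of the block inner products", {
  h <- toy_history()
  p0 <- hazard_params(beta_V = c(0, 0), beta_S = c(0, 0), beta_B = c(0, 0),
                      theta_V = c(0, 0), theta_S = c(0, 0))
  expect_equal(relative_risk_sale(h, "v1", 30, "c2", p0), 1)
  expect_equal(relative_risk_scrap(h, "v1", 30, p0), 1)

  # hand-summed exponent: x_v = (1, 10), x_s = x_c1 = (1, 0), x_b = x_c2 = (0, 1)
  p <- ref_params()
  expect_equal(relative_risk_sale(h, "v1", 30, "c2", p), exp(0.7))
  expect_equal(relative_risk_scrap(h, "v1", 30, p),
               exp(0.1 * 1 + 0.02 * 10 - 0.1 * 1 + 0.2 * 0))

  # shifting one covariate multiplies the risk by exp(coefficient * delta)
  h2 <- toy_history()
  h2$vessels$x_V_2[1] <- h2$vessels$x_V_2[1] + 3
  expect_equal(relative_risk_sale(h2, "v1", 30, "c2", p),
               relative_risk_sale(h, "v1", 30, "c2", p) * exp(-0.01 * 3))

  expect_error(relative_risk_sale(h, "v1", 30, "c1", p), "owner")
  expect_error(relative_risk_sale(h, "v1", 30, "c9", p), "unknown buyer")
})

test_that("total sale intensity sums per-buyer intensities over the risk set", {
  h <- toy_history()
  p0 <- hazard_params(beta_V = c(0, 0), beta_S = c(0, 0), beta_B = c(0, 0))
  fr1 <- frailty_state(1, 0.2, n = 3)
  # m = 2 active non-owner buyers
  expect_equal(sale_intensity_total(h, "v1", 30, p0, fr1, 1e-5), 2e-5)

  fr <- frailty_state(c(2, 1, 1), 0.2)     # owner c1 at age 30
  expect_equal(sale_intensity_total(h, "v1", 30, p0, fr, 1), 2 * (1 + 1))

  # doubling the owner's frailty doubles the total; doubling all leaves the
  # seller/buyer ratio unchanged
  base <- sale_intensity_total(h, "v1", 30, p0, fr, 1)
  fr2 <- frailty_state(c(4, 1, 1), 0.2)
  expect_equal(sale_intensity_total(h, "v1", 30, p0, fr2, 1), 2 * base)
  frc <- frailty_state(c(2, 1, 1) * 5, 0.2)
  expect_equal(sale_intensity_total(h, "v1", 30, p0, frc, 1), base)

  expect_error(sale_intensity_total(h, "v1", 30, p0, fr, 0), "positive")
})

test_that("cumulative intensities are Stieltjes sums over the at-risk span", {
  h <- toy_history()
  p0 <- hazard_params(beta_V = c(0, 0), beta_S = c(0, 0), beta_B = c(0, 0))
  fr <- frailty_state(c(2, 1, 1), 0.2)
  b <- baseline_increments(sale = data.frame(age = 30, increment = 0.25))
  expect_equal(cumulative_intensities(h, "v1", 0, p0, fr, b),
               c(A = 0, L = 0))
  # single increment: non-baseline factor Z_c1 * (1/Z_c2 + 1/Z_c3) = 4
  expect_equal(cumulative_intensities(h, "v1", 50, p0, fr, b),
               c(A = 1, L = 0))

  bb <- breslow_baselines(h, ref_params(), fr)
  ages <- c(0, 59, 60, 100, 150, 250)
  A <- vapply(ages, function(u)
    cumulative_intensities(h, "v1", u, ref_params(), fr, bb)[["A"]], 0)
  expect_true(all(diff(A) >= 0))
})

test_that("full log-likelihood matches its event/exposure decomposition", {
  # no events, zero baselines -> 0
  h0 <- toy_staggered()
  p1 <- hazard_params(beta_V = 0.2, beta_S = 0.1)
  expect_equal(full_loglik(h0, p1, frailty_state(1, 0.2, 4),
                           baseline_increments()), 0)

  # as a function of one frailty it matches the M log Z - D1 Z - D2/Z kernel
  h <- random_history(13)
  p <- ref_params()
  N <- nrow(h$companies)
  set.seed(31)
  fr <- frailty_state(rgamma(N, 4, 4), 0.25)
  b <- breslow_baselines(h, p, fr)
  for (cid in h$companies$company_id[c(2, 5)]) {
    st <- gibbs_stats(h, cid, p, fr, b)
    ci <- match(cid, h$companies$company_id)
    vals <- vapply(c(0.4, 0.7, 1, 1.6, 2.5), function(z) {
      Z <- fr$Z; Z[ci] <- z
      full_loglik(h, p, frailty_state(Z, fr$xi), b) -
        (st$M * log(z) - st$D1 * z - st$D2 / z)
    }, 0)
    expect_equal(max(vals) - min(vals), 0, tolerance = 1e-9)
  }

  # with no scrap events the likelihood is exactly invariant under Z -> cZ
  hn <- toy_noscrap()
  frn <- frailty_state(c(1.4, 0.6, 1.1), 0.3)
  bn <- breslow_baselines(hn, p, frn)
  l1 <- full_loglik(hn, p, frn, bn)
  l2 <- full_loglik(hn, p, frailty_state(frn$Z * 7.3, frn$xi), bn)
  expect_equal(l1, l2, tolerance = 1e-12)
  # ... and with scrap events it is not
  hs <- toy_history()
  bs <- breslow_baselines(hs, p, frn)
  expect_false(isTRUE(all.equal(
    full_loglik(hs, p, frn, bs),
    full_loglik(hs, p, frailty_state(frn$Z * 7.3, frn$xi), bs))))

  # an event age without a positive increment is an inconsistency
  expect_error(
    full_loglik(hs, p, frn,
                baseline_increments(sale = data.frame(age = 60, increment = 0.1),
                                    scrap = data.frame(age = 90, increment = 0.2))),
    "no positive sale increment")
})
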