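# Fixtures are built in code; nothing is read from disk.

# toy_history() from the package: 3 companies, 2 vessels, sales at ages 60
# and 120, scrap at 90.

# Variant without the scrap event (v2 censored instead).
toy_noscrap <- function() {
  h <- toy_history()
  sp <- h$spells
  sp$end_type[sp$vessel_id == "v2"] <- "censor"
  event_history(h$companies, h$vessels, sp, window = h$window)
}

# One sale only: v1 sold at 60 then censored; v2 censored. With unit
# frailties and zero coefficients the single Breslow denominator counts 4
# at-risk (vessel, buyer) pairs.
toy_onesale <- function() {
  h <- toy_history()
  sp <- tibble::tibble(
    vessel_id = c("v1", "v1", "v2"),
    owner_id = c("c1", "c2", "c2"),
    start_age = c(0, 60, 0),
    end_age = c(60, 120, 90),
    end_type = c("sale", "censor", "censor"),
    buyer_id = c("c2", NA, NA)
  )
  event_history(h$companies, h$vessels, sp, window = h$window)
}

# Staggered deliveries and a company whose activity ends mid-window:
# c4 is active on calendar [0, 100); vessel v2 is delivered at 50, so at
# age 60 (calendar 110) c4 is no longer an eligible buyer for v2 while it
# still is for v1 (calendar 60).
toy_staggered <- function() {
  companies <- tibble::tibble(
    company_id = c("c1", "c2", "c3", "c4"),
    x_C_1 = c(1, 0, 1, 0),
    activity_start = 0,
    activity_end = c(300, 300, 300, 100)
  )
  vessels <- tibble::tibble(
    vessel_id = c("v1", "v2"), delivery_time = c(0, 50), x_V_1 = c(1, 0)
  )
  spells <- tibble::tibble(
    vessel_id = c("v1", "v2"),
    owner_id = c("c1", "c2"),
    start_age = 0, end_age = c(200, 150),
    end_type = "censor", buyer_id = NA_character_
  )
  event_history(companies, vessels, spells, window = c(0, 50, 250))
}

# Small random histories for property tests (valid by construction).
random_history <- function(seed, scrap = TRUE, n_companies = 8, n_vessels = 15,
                           horizon = 150, baseline = 4e-4) {
  cfg <- sim_config(
    n_companies = n_companies, n_vessels = n_vessels, horizon = horizon,
    baseline = baseline, xi = 0.3, seed = seed,
    scrap = if (scrap) list(baseline = 8e-4, theta_V = c(0.1, 0),
                            theta_S = c(0.2, -0.1))
  )
  simulate_fleet(cfg)
}

ref_params <- function() {
  hazard_params(beta_V = c(0.3, -0.01), beta_S = c(0.4, -0.2),
                beta_B = c(-0.2, 0.1),
                theta_V = c(0.1, 0.02), theta_S = c(-0.1, 0.2))
}
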