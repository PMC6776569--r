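test_that("event histories validate and print", {
  h <- toy_history()
  expect_s3_class(h, "event_history")
  expect_equal(nrow(h$companies), 3)
  expect_equal(nrow(h$vessels), 2)
  expect_output(print(h), "2 sales, 1 scraps")
})

test_that("invariant violations are reported with row context", {
  h <- toy_history()
  sp <- h$spells

  bad <- sp; bad$buyer_id[1] <- "c1"   # buyer equals owner for the age-60 sale
  expect_error(event_history(h$companies, h$vessels, bad),
               "buyer equals owner")

  bad <- sp; bad$start_age[2] <- 70    # gap between v1's first two spells
  expect_error(event_history(h$companies, h$vessels, bad), "gap/overlap")

  bad <- sp; bad$buyer_id[1] <- "c9"
  expect_error(event_history(h$companies, h$vessels, bad), "unknown buyer")

  bad <- sp; bad$end_type[3] <- "sale"; bad$buyer_id[3] <- "c1"
  expect_error(event_history(h$companies, h$vessels, bad),
               "final spell ends in a sale")

  co <- h$companies; co$activity_end[co$company_id == "c3"] <- 150
  expect_error(event_history(co, h$vessels, sp), "inactive over part")

  expect_error(event_history(h$companies[-1], h$vessels, h$spells),
               "required column|unknown owner")
})

test_that("write/read round-trips exactly", {
  dir <- withr::local_tempdir()
  h <- toy_history(exogenous = TRUE)
  write_event_history(h, dir)
  h2 <- read_event_history(dir)
  expect_equal(h2$companies, h$companies)
  expect_equal(h2$vessels, h$vessels)
  expect_equal(h2$spells, h$spells)
  expect_equal(h2$exogenous, h$exogenous)
  expect_equal(h2$window, h$window)

  # a second round trip is the identity
  dir2 <- withr::local_tempdir()
  write_event_history(h2, dir2)
  expect_equal(read_event_history(dir2), h2)
})

test_that("read_event_history supports schema renames and reports missing columns", {
  dir <- withr::local_tempdir()
  h <- toy_history()
  write_event_history(h, dir)
  sp <- readr::read_csv(file.path(dir, "spells.csv"), show_col_types = FALSE)
  names(sp)[names(sp) == "owner_id"] <- "seller"
  readr::write_csv(sp, file.path(dir, "spells.csv"))
  expect_error(read_event_history(dir), "missing required column")
  h2 <- read_event_history(dir, schema = list(spells = c(owner_id = "seller")))
  expect_equal(h2$spells, h$spells)
})

test_that("previous_owners counts completed ownership changes", {
  h <- toy_history()   # v1 sold at ages 60 and 120
  expect_equal(previous_owners(h, "v1", 0), 0)
  expect_equal(previous_owners(h, "v1", 90), 1)
  expect_equal(previous_owners(h, "v1", 60), 1)   # right-continuous count
  expect_equal(previous_owners(h, "v1", 59.99), 0)
  expect_error(previous_owners(h, "zz", 10), "unknown vessel")

  # non-decreasing in age, bounded by spells - 1
  ages <- seq(0, 200, by = 10)
  counts <- vapply(ages, function(a) previous_owners(h, "v1", a), 0)
  expect_true(all(diff(counts) >= 0))
  expect_true(max(counts) <= sum(h$spells$vessel_id == "v1") - 1)
})

test_that("risk sets pair at-risk vessels with active non-owner buyers", {
  h <- toy_history()
  expect_equal(nrow(risk_set(h, 500)), 0)
  rs <- risk_set(h, 70)
  expect_equal(rs$vessel_id, c("v1", "v2"))
  expect_equal(rs$owner_id, c("c2", "c2"))
  expect_equal(rs$buyers, list(c("c1", "c3"), c("c1", "c3")))

  # left-limit convention: the vessel is still at risk at its own event age,
  # with the pre-event owner
  rs60 <- risk_set(h, 60)
  expect_equal(rs60$owner_id[rs60$vessel_id == "v1"], "c1")

  # cardinality non-increasing once all vessels are delivered
  sizes <- vapply(seq(1, 250, by = 5), function(a) nrow(risk_set(h, a)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("activity windows exclude a lapsed buyer per-vessel, not globally", {
  h <- toy_staggered()   # c4 active on [0, 100); v2 delivered at 50
  rs <- risk_set(h, 60)  # v1 at calendar 60, v2 at calendar 110
  buyers_v1 <- rs$buyers[[which(rs$vessel_id == "v1")]]
  buyers_v2 <- rs$buyers[[which(rs$vessel_id == "v2")]]
  expect_true("c4" %in% buyers_v1)
  expect_false("c4" %in% buyers_v2)
  expect_setdiff_empty <- setdiff(buyers_v2, c("c1", "c3"))
  expect_length(expect_setdiff_empty, 0)
})

test_that("exogenous step lookup is right-continuous, lagged and clamped", {
  ser <- tibble::tibble(time = c(0, 10), x_E_1 = c(1, 2))
  expect_equal(unname(drop(exogenous_at(ser, 3))), 1)
  expect_equal(unname(drop(exogenous_at(ser, 10))), 2)   # right-continuity
  expect_equal(unname(drop(exogenous_at(ser, 12, lag = 6))), 1)
  const <- tibble::tibble(time = 0, x_E_1 = 7)
  expect_equal(unname(drop(exogenous_at(const, 55, lag = 13))), 7)
  expect_warning(v <- exogenous_at(ser, -5), "clamping")
  expect_silent(exogenous_at(ser, 99))
  expect_equal(unname(drop(v)), 1)
  expect_error(exogenous_at(ser[0, ], 1), "empty")

  lagged <- lag_exogenous(ser, 6)
  expect_equal(lagged$time, c(6, 16))
  expect_named(lagged, c("time", "x_E_1_lag6"))
})
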