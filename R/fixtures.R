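#' A small worked event history
#'
#' Three companies and two vessels: vessel `v1` is sold by `c1` to `c2` at
#' age 60 and by `c2` to `c3` at age 120, then censored at 200; vessel `v2`
#' is scrapped by `c2` at age 90. All companies are active over the whole
#' window. Handy for examples and quick experiments.
#'
#' @param exogenous Attach a two-breakpoint exogenous series.
#' @return An [event_history()].
#' @export
toy_history <- function(exogenous = FALSE) {
  companies <- tibble(
    company_id = c("c1", "c2", "c3"),
    x_C_1 = c(1, 0, 1), x_C_2 = c(0, 1, 1),
    activity_start = 0, activity_end = 200
  )
  vessels <- tibble(
    vessel_id = c("v1", "v2"), delivery_time = 0,
    x_V_1 = c(1, 0), x_V_2 = c(10, -5)
  )
  spells <- tibble(
    vessel_id = c("v1", "v1", "v1", "v2"),
    owner_id = c("c1", "c2", "c3", "c2"),
    start_age = c(0, 60, 120, 0),
    end_age = c(60, 120, 200, 90),
    end_type = c("sale", "sale", "censor", "scrap"),
    buyer_id = c("c2", "c3", NA, NA)
  )
  exo <- if (exogenous) {
    tibble(time = c(0, 100), x_E_1 = c(1, 2))
  }
  event_history(companies, vessels, spells, exogenous = exo,
                window = c(0, 0, 200))
}
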