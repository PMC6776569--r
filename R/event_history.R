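#' Assemble and validate an ownership event history
#'
#' An event history bundles the long-format tables describing a fleet of
#' vessels traded among companies: one row per company (with its activity
#' window and covariates), one row per vessel (with its delivery time and
#' static covariates), one row per ownership spell (with the spell's start and
#' end age and how it ended), and an optional exogenous covariate series
#' recorded as a right-continuous step function of calendar time.
#'
#' Times are in months. A vessel delivered at calendar time `d` reaches age
#' `a` at calendar time `d + a`, so spells, recorded on the age scale,
#' implicitly cover calendar intervals. Spells partition `[0, T)` where `T` is
#' the vessel's final observed age; every spell but the last ends in a sale,
#' and the last ends in scrapping or censoring.
#'
#' Covariate columns follow a fixed naming scheme: `x_C_*` for company
#' covariates, `x_V_*` for vessel covariates and `x_E_*` for exogenous
#' covariates. Identifier columns are coerced to character.
#'
#' @param companies Data frame with columns `company_id`, `activity_start`,
#'   `activity_end` and zero or more `x_C_*` covariate columns.
#' @param vessels Data frame with columns `vessel_id`, `delivery_time` and
#'   zero or more `x_V_*` covariate columns.
#' @param spells Data frame with columns `vessel_id`, `owner_id`,
#'   `start_age`, `end_age`, `end_type` (one of `"sale"`, `"scrap"`,
#'   `"censor"`) and `buyer_id` (non-missing exactly for sales).
#' @param exogenous Optional data frame with a strictly increasing `time`
#'   column and `x_E_*` value columns, or `NULL`.
#' @param window Length-3 numeric `(tau1, tau2, tau)`: start and end of the
#'   delivery interval and the censoring time, all in calendar months.
#'   Derived from the data when `NULL`.
#' @param validate Run the full invariant checks (default `TRUE`).
#'
#' @return An object of class `event_history`: a list with elements
#'   `companies`, `vessels`, `spells`, `exogenous` (tibbles or `NULL`) and
#'   `window`.
#' @export
#' @examples
#' h <- toy_history()
#' h
#' risk_set(h, 12)
event_history <- function(companies, vessels, spells, exogenous = NULL,
                          window = NULL, validate = TRUE) {
  companies <- as_tibble(companies)
  vessels <- as_tibble(vessels)
  spells <- as_tibble(spells)
  if (!is.null(exogenous)) exogenous <- as_tibble(exogenous)

  need <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(sprintf("`%s` is missing required column(s): %s",
                    name, paste(miss, collapse = ", ")))
    }
  }
  need(companies, c("company_id", "activity_start", "activity_end"), "companies")
  need(vessels, c("vessel_id", "delivery_time"), "vessels")
  need(spells, c("vessel_id", "owner_id", "start_age", "end_age", "end_type"),
       "spells")
  if (!"buyer_id" %in% names(spells)) spells$buyer_id <- NA_character_
  if (!is.null(exogenous)) need(exogenous, "time", "exogenous")

  companies$company_id <- as.character(companies$company_id)
  vessels$vessel_id <- as.character(vessels$vessel_id)
  spells$vessel_id <- as.character(spells$vessel_id)
  spells$owner_id <- as.character(spells$owner_id)
  spells$buyer_id <- as.character(spells$buyer_id)

  companies <- companies[c("company_id", covariate_cols(companies, "x_C_"),
                           "activity_start", "activity_end")]
  vessels <- vessels[c("vessel_id", "delivery_time",
                       covariate_cols(vessels, "x_V_"))]
  spells <- spells[order(spells$vessel_id, spells$start_age),
                   c("vessel_id", "owner_id", "start_age", "end_age",
                     "end_type", "buyer_id")]
  if (!is.null(exogenous)) {
    exogenous <- exogenous[c("time", covariate_cols(exogenous, "x_E_"))]
  }

  if (is.null(window)) {
    deliv <- vessels$delivery_time
    last_end <- vapply(split(spells$end_age, spells$vessel_id), max, 0)
    final_cal <- deliv + last_end[vessels$vessel_id]
    window <- c(tau1 = min(deliv, 0), tau2 = max(deliv),
                tau = max(final_cal, deliv))
  } else {
    window <- setNames(as.numeric(window), c("tau1", "tau2", "tau"))
  }

  h <- structure(
    list(companies = companies, vessels = vessels, spells = spells,
         exogenous = exogenous, window = window),
    class = "event_history"
  )
  if (validate) validate_event_history(h)
  h
}

covariate_cols <- function(df, prefix) {
  names(df)[startsWith(names(df), prefix)]
}

#' Check the structural invariants of an event history
#'
#' Verifies, with per-row diagnostics, that activity windows are proper
#' intervals, spells partition each vessel's follow-up without gaps or
#' overlaps, ownership chains through buyers (the owner of spell `k+1` is the
#' buyer of spell `k`), buyers differ from owners and resolve to known
#' companies, every spell lies inside its owner's activity window, only the
#' final spell of a vessel ends in scrapping or censoring, and exogenous
#' breakpoints are strictly increasing.
#'
#' @param h An `event_history`.
#' @return `h`, invisibly, if valid; otherwise an error listing every
#'   violation found.
#' @export
validate_event_history <- function(h) {
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))

  co <- h$companies
  if (anyDuplicated(co$company_id)) note("duplicated company_id in `companies`")
  bad <- which(!(co$activity_start < co$activity_end))
  for (i in bad) note("company %s: activity_start >= activity_end", co$company_id[i])

  ve <- h$vessels
  if (anyDuplicated(ve$vessel_id)) note("duplicated vessel_id in `vessels`")

  sp <- h$spells
  unknown_v <- setdiff(sp$vessel_id, ve$vessel_id)
  for (v in unknown_v) note("spell references unknown vessel %s", v)
  unknown_o <- setdiff(sp$owner_id, co$company_id)
  for (o in unknown_o) note("spell references unknown owner %s", o)
  unknown_b <- setdiff(sp$buyer_id[!is.na(sp$buyer_id)], co$company_id)
  for (b in unknown_b) note("spell references unknown buyer %s", b)

  bad <- which(!(sp$start_age < sp$end_age))
  for (i in bad) {
    note("vessel %s spell starting at %g: start_age >= end_age",
         sp$vessel_id[i], sp$start_age[i])
  }
  bad <- which(!sp$end_type %in% c("sale", "scrap", "censor"))
  for (i in bad) {
    note("vessel %s spell starting at %g: unknown end_type '%s'",
         sp$vessel_id[i], sp$start_age[i], sp$end_type[i])
  }
  is_sale <- sp$end_type == "sale"
  bad <- which(is_sale & is.na(sp$buyer_id))
  for (i in bad) {
    note("vessel %s sale at age %g: missing buyer_id",
         sp$vessel_id[i], sp$end_age[i])
  }
  bad <- which(!is_sale & !is.na(sp$buyer_id))
  for (i in bad) {
    note("vessel %s spell ending at %g: buyer_id given but end_type is '%s'",
         sp$vessel_id[i], sp$end_age[i], sp$end_type[i])
  }
  bad <- which(is_sale & !is.na(sp$buyer_id) & sp$buyer_id == sp$owner_id)
  for (i in bad) {
    note("vessel %s sale at age %g: buyer equals owner (%s)",
         sp$vessel_id[i], sp$end_age[i], sp$owner_id[i])
  }

  cidx <- match(sp$owner_id, co$company_id)
  didx <- match(sp$vessel_id, ve$vessel_id)
  for (v in split(seq_len(nrow(sp)), sp$vessel_id)) {
    rows <- sp[v, , drop = FALSE]
    id <- rows$vessel_id[1]
    if (rows$start_age[1] != 0) {
      note("vessel %s: first spell starts at %g, not 0", id, rows$start_age[1])
    }
    k <- nrow(rows)
    if (k > 1) {
      gaps <- which(rows$start_age[-1] != rows$end_age[-k])
      for (g in gaps) {
        note("vessel %s: spell gap/overlap between ages %g and %g",
             id, rows$end_age[g], rows$start_age[g + 1])
      }
      if (any(rows$end_type[-k] != "sale")) {
        note("vessel %s: a non-final spell does not end in a sale", id)
      }
      chain <- which(rows$owner_id[-1] != rows$buyer_id[-k])
      for (g in chain) {
        note("vessel %s: owner of spell %d (%s) is not the buyer of spell %d (%s)",
             id, g + 1, rows$owner_id[g + 1], g,
             rows$buyer_id[g] %||% NA_character_)
      }
    }
    if (rows$end_type[k] == "sale") {
      note("vessel %s: final spell ends in a sale (expected scrap or censor)", id)
    }
  }

  # owner must be active over the calendar span of the spell
  ok <- !is.na(cidx) & !is.na(didx)
  if (any(ok)) {
    t0 <- ve$delivery_time[didx[ok]] + sp$start_age[ok]
    t1 <- ve$delivery_time[didx[ok]] + sp$end_age[ok]
    a0 <- co$activity_start[cidx[ok]]
    a1 <- co$activity_end[cidx[ok]]
    bad <- which(t0 < a0 - 1e-9 | t1 > a1 + 1e-9)
    rows <- which(ok)[bad]
    for (i in rows) {
      note("vessel %s spell [%g,%g): owner %s inactive over part of its calendar span",
           sp$vessel_id[i], sp$start_age[i], sp$end_age[i], sp$owner_id[i])
    }
    tau <- h$window[["tau"]]
    late <- which(t1 > tau + 1e-9)
    for (i in which(ok)[late]) {
      note("vessel %s spell ends at calendar time beyond the observation window",
           sp$vessel_id[i])
    }
  }

  ex <- h$exogenous
  if (!is.null(ex)) {
    if (nrow(ex) == 0) note("exogenous series is empty")
    if (is.unsorted(ex$time, strictly = TRUE)) {
      note("exogenous breakpoints are not strictly increasing")
    }
  }

  if (length(problems) > 0) {
    abort(paste0("invalid event history:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  invisible(h)
}

#' @export
print.event_history <- function(x, ...) {
  n_sale <- sum(x$spells$end_type == "sale")
  n_scrap <- sum(x$spells$end_type == "scrap")
  cat(sprintf("<event_history> %d companies, %d vessels, %d spells\n",
              nrow(x$companies), nrow(x$vessels), nrow(x$spells)))
  cat(sprintf("  events: %d sales, %d scraps; window [%g, %g], follow-up to %g\n",
              n_sale, n_scrap, x$window[["tau1"]], x$window[["tau2"]],
              x$window[["tau"]]))
  if (!is.null(x$exogenous)) {
    cat(sprintf("  exogenous series: %d breakpoints, %d covariate(s)\n",
                nrow(x$exogenous), ncol(x$exogenous) - 1L))
  }
  invisible(x)
}

#' Number of previous owners of a vessel
#'
#' Counts the ownership changes a vessel has undergone by a given age: the
#' number of its sales at ages `<= age`. The count is right-continuous — at
#' exactly a sale age the change has taken effect (the new spell is current).
#' Model code evaluating this quantity as a covariate for an event at age `a`
#' uses the left limit, i.e. the count just before `a`.
#'
#' @param h An `event_history`.
#' @param vessel_id A single vessel identifier.
#' @param age Vessel age in months, `0 <= age`.
#' @return Non-negative integer count.
#' @export
previous_owners <- function(h, vessel_id, age) {
  vessel_id <- as.character(vessel_id)
  if (!vessel_id %in% h$vessels$vessel_id) {
    abort(sprintf("unknown vessel '%s'", vessel_id))
  }
  stopifnot(age >= 0)
  sp <- h$spells
  sum(sp$vessel_id == vessel_id & sp$end_type == "sale" & sp$end_age <= age)
}

#' Risk set at a vessel age
#'
#' For a given age, returns every vessel still in use at that age together
#' with its current owner and the set of companies eligible to buy it: the
#' companies other than the owner that are active at the vessel's own
#' calendar time for that age.
#'
#' Evaluation is in the left-limit (predictable) sense: a vessel whose spell
#' covers `(start, end]` in ages is at risk at `age` when
#' `start < age <= end`, so a vessel is still counted at the exact age of its
#' own event, with ownership as of just before the event.
#'
#' @param h An `event_history`.
#' @param age Vessel age in months.
#' @return A tibble with one row per at-risk vessel: `vessel_id`, `owner_id`
#'   and a list-column `buyers` of eligible buyer ids.
#' @export
risk_set <- function(h, age) {
  stopifnot(age >= 0)
  sp <- h$spells
  at <- sp$start_age < age & age <= sp$end_age
  if (age == 0 || !any(at)) {
    return(tibble(vessel_id = character(), owner_id = character(),
                  buyers = list()))
  }
  sp <- sp[at, , drop = FALSE]
  deliv <- h$vessels$delivery_time[match(sp$vessel_id, h$vessels$vessel_id)]
  t_cal <- deliv + age
  co <- h$companies
  buyers <- lapply(seq_len(nrow(sp)), function(i) {
    act <- co$activity_start <= t_cal[i] & t_cal[i] < co$activity_end
    setdiff(co$company_id[act], sp$owner_id[i])
  })
  tibble(vessel_id = sp$vessel_id, owner_id = sp$owner_id, buyers = buyers)
}

#' Evaluate an exogenous step-function series
#'
#' Exogenous covariates (market indices and similar) are stored as
#' right-continuous step functions of calendar time. `exogenous_at` returns
#' the value at `t - lag`; querying outside the covered range clamps to the
#' nearest endpoint with a warning, so lagged lookups at the start of
#' follow-up remain defined.
#'
#' @param series A data frame with a `time` column and `x_E_*` value columns
#'   (e.g. the `exogenous` element of an `event_history`).
#' @param t Calendar time(s) in months.
#' @param lag Lag in months subtracted from `t` before lookup (default 0).
#' @return A numeric matrix with one row per element of `t` and one column
#'   per exogenous covariate.
#' @export
exogenous_at <- function(series, t, lag = 0) {
  if (is.null(series) || nrow(series) == 0) {
    abort("empty exogenous series")
  }
  tq <- t - lag
  lo <- series$time[1]
  # right-continuation past the last breakpoint is the natural step-function
  # semantics; only lookups before the first breakpoint need clamping
  if (any(tq < lo)) {
    warn("exogenous lookup before the first breakpoint; clamping to it")
    tq <- pmax(tq, lo)
  }
  idx <- findInterval(tq, series$time)
  vals <- as.matrix(series[covariate_cols(series, "x_E_")])
  vals[idx, , drop = FALSE]
}

#' Lag an exogenous series
#'
#' Returns a series whose value at calendar time `t` equals the original
#' value at `t - lag`, with value columns renamed with a `_lag<lag>` suffix.
#' Useful for entering both a market index and its lagged version as separate
#' model covariates.
#'
#' @param series A data frame with `time` and `x_E_*` columns.
#' @param lag Lag in months (positive shifts the series forward in time).
#' @return A tibble of the same shape with shifted breakpoints.
#' @export
lag_exogenous <- function(series, lag) {
  out <- as_tibble(series)
  out$time <- out$time + lag
  cc <- covariate_cols(out, "x_E_")
  names(out)[match(cc, names(out))] <- paste0(cc, "_lag", lag)
  out
}
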