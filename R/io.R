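#' Read an event history from delimited text files
#'
#' Reads the four-table on-disk representation: `companies.csv`,
#' `vessels.csv`, `spells.csv` and (optionally) `exogenous.csv`. `paths` may
#' be a single directory containing files with those names, or a named
#' character vector/list with elements `companies`, `vessels`, `spells` and
#' optionally `exogenous`.
#'
#' `schema` allows files whose columns are named differently: a named list
#' per table mapping canonical column names to the names found in the file,
#' e.g. `list(spells = c(owner_id = "seller"))`.
#'
#' @param paths Directory or named paths, see Details.
#' @param schema Optional per-table column-name maps.
#' @return A validated [event_history()].
#' @export
read_event_history <- function(paths, schema = NULL) {
  paths <- resolve_paths(paths)
  rd <- function(key) {
    p <- paths[[key]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
    df <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    map <- schema[[key]]
    if (!is.null(map)) {
      hit <- match(unname(map), names(df))
      if (anyNA(hit)) {
        abort(sprintf("%s: schema refers to missing column(s): %s", key,
                      paste(unname(map)[is.na(hit)], collapse = ", ")))
      }
      names(df)[hit] <- names(map)
    }
    df
  }
  for (key in c("companies", "vessels", "spells")) {
    if (is.null(paths[[key]])) abort(sprintf("no path given for '%s'", key))
  }
  event_history(companies = rd("companies"), vessels = rd("vessels"),
                spells = rd("spells"), exogenous = rd("exogenous"))
}

resolve_paths <- function(paths) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    files <- c(companies = "companies.csv", vessels = "vessels.csv",
               spells = "spells.csv", exogenous = "exogenous.csv")
    out <- as.list(file.path(paths, files))
    names(out) <- names(files)
    if (!file.exists(out$exogenous)) out$exogenous <- NULL
    return(out)
  }
  as.list(paths)
}

#' Write an event history to delimited text files
#'
#' Inverse of [read_event_history()]: writes `companies.csv`, `vessels.csv`,
#' `spells.csv` and, when present, `exogenous.csv`. The files round-trip
#' exactly (`read_event_history()` on the output reproduces the input
#' structure).
#'
#' @param h An `event_history`.
#' @param paths A directory (created if needed) or named file paths as in
#'   [read_event_history()].
#' @return `paths`, invisibly.
#' @export
write_event_history <- function(h, paths) {
  if (length(paths) == 1 && is.null(names(paths))) {
    if (!dir.exists(paths)) dir.create(paths, recursive = TRUE)
  }
  paths <- resolve_paths_write(paths, has_exo = !is.null(h$exogenous))
  readr::write_csv(h$companies, paths$companies, progress = FALSE)
  readr::write_csv(h$vessels, paths$vessels, progress = FALSE)
  readr::write_csv(h$spells, paths$spells, progress = FALSE)
  if (!is.null(h$exogenous)) {
    readr::write_csv(h$exogenous, paths$exogenous, progress = FALSE)
  }
  invisible(paths)
}

resolve_paths_write <- function(paths, has_exo) {
  if (length(paths) == 1 && is.null(names(paths))) {
    files <- c(companies = "companies.csv", vessels = "vessels.csv",
               spells = "spells.csv", exogenous = "exogenous.csv")
    out <- as.list(file.path(paths, files))
    names(out) <- names(files)
    if (!has_exo) out$exogenous <- NULL
    return(out)
  }
  as.list(paths)
}
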