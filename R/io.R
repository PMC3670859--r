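# Serialisation: tidy CSV time series plus a JSON metadata sidecar that is
# sufficient to re-run a simulation exactly.

#' Write simulation traces and metadata
#'
#' Writes `<stem>.csv` (the tidy trace table, RFC-4180) and `<stem>.json`
#' (parameters, solver settings, convergence report) so a run can be
#' reproduced and re-analysed without the originating session.
#'
#' @param sim A `cvs_simulation`.
#' @param stem Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_simulation <- function(sim, stem) {
  stopifnot(inherits(sim, "cvs_simulation"))
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  readr::write_csv(sim$traces, csv)
  meta <- list(
    package = "atrisim",
    params = unclass(sim$params),
    settings = sim$settings,
    n_cycles = sim$n_cycles,
    converged = sim$converged,
    cycles_run = sim$cycles_run,
    final_state = as.list(sim$final_state)
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' Read simulation traces written by [write_simulation()]
#'
#' Accepts any CSV with at least `time`, `P_la`, `P_lv` columns, so traces
#' from other sources can be analysed too.
#'
#' @param path CSV file path.
#' @return A tibble of traces.
#' @export
read_traces <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time", "P_la", "P_lv") %in% names(tr))) {
    stop("not a trace file: needs columns time, P_la, P_lv", call. = FALSE)
  }
  tr
}

#' Write a hemodynamic index report as JSON
#'
#' @param indices A one-row tibble from [compute_indices()], or the
#'   comparison table from [ivco_comparison()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_indices <- function(indices, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(indices, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
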