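# broom-style verbs for simulation objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into long format
#'
#' @param x A `cvs_simulation`.
#' @param variables Which trace columns to pivot (default: all pressures,
#'   volumes and flows).
#' @param ... Ignored.
#' @return A tibble with columns `time`, `cycle`, `variable`, `value`.
#' @method tidy cvs_simulation
#' @export
tidy.cvs_simulation <- function(x, variables = NULL, ...) {
  tr <- x$traces
  if (is.null(variables)) {
    variables <- grep("^(P|V|Q)_", names(tr), value = TRUE)
  }
  tidyr::pivot_longer(
    dplyr::select(tr, "time", "cycle", dplyr::all_of(variables)),
    cols = dplyr::all_of(variables),
    names_to = "variable", values_to = "value"
  )
}

#' One-row summary of a simulation
#'
#' @param x A `cvs_simulation`.
#' @param ... Ignored.
#' @return A one-row tibble: cycles run, convergence flag, total-blood-volume
#'   drift (relative), systolic/diastolic pressures of the systemic and
#'   pulmonary arteries and the LA pressure extrema.
#' @method glance cvs_simulation
#' @export
glance.cvs_simulation <- function(x, ...) {
  tr <- x$traces
  tot <- rowSums(tr[, c("V_la", "V_lv", "V_rv", "V_ao", "V_vc", "V_pa",
                        "V_pu")])
  tibble::tibble(
    n_cycles = x$n_cycles,
    cycles_run = if (is.null(x$cycles_run)) NA_integer_ else x$cycles_run,
    converged = x$converged,
    volume_drift = diff(range(tot)) / mean(tot),
    P_ao_sys = max(tr$P_ao), P_ao_dia = min(tr$P_ao),
    P_pa_sys = max(tr$P_pa), P_pa_dia = min(tr$P_pa),
    P_la_max = max(tr$P_la), P_la_min = min(tr$P_la)
  )
}

#' Tidy an IVCO run into a baseline/occlusion index table
#'
#' @param x A `cvs_ivco`.
#' @param ... Ignored.
#' @return The [ivco_comparison()] tibble.
#' @method tidy cvs_ivco
#' @export
tidy.cvs_ivco <- function(x, ...) ivco_comparison(x)
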