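# Parameter registry: every model constant with its published default.
#
# Unit conventions (fixed by the schema, never configurable per key):
#   concentrations uM, lengths um (sarcomere) / cm (chamber), time s,
#   volume ml, pressure mmHg, force per area mN/mm^2 (= kPa),
#   elastance mmHg/ml, resistance mmHg.s/ml.

#' Conversion constant: kilopascal per millimetre of mercury
#'
#' Wall force per unit area is carried in mN/mm^2 (identically kPa); chamber
#' pressures are reported in mmHg. 1 mmHg = 0.133322 kPa.
#'
#' @export
KPA_PER_MMHG <- 0.133322

#' Default cardiovascular system parameters
#'
#' Returns the full parameter set of the dog-calibrated multi-scale model as a
#' validated named list of class `cvs_params`. Any subset of values can be
#' overridden through `...`; unknown names are an error so typos never pass
#' silently.
#'
#' The set covers five groups:
#' \describe{
#'   \item{calcium transients}{`T1_lv`, `T2_lv`, `Ca_max_lv`, `T1_la`,
#'     `T2_la`, `Ca_max_la` (uM), and the atrial activation lead `shift_la`
#'     (s). The atrial transient leads ventricular activation so that atrial
#'     contraction falls at end of ventricular diastole.}
#'   \item{sarcomere kinetics}{rate constants `Y1` (uM^-1 s^-1), `Z1`, `Y2`,
#'     `Z2`, `Y3` (s^-1), `Z3` (uM^-1 s^-1), `Y4` (s^-1), `Yd` (s um^-2);
#'     total troponin `Tt` (uM); cross-bridge rate `B` (s^-1) and reference
#'     elongation `h_c` (um); overlap centre `L_a` (um) and width `R_sens`
#'     (um^-2); unstressed half-sarcomere length `L0` (um).}
#'   \item{force scaling}{active gains `A_la`, `A_lv`
#'     (mN mm^-2 um^-1 uM^-1) and passive stiffnesses `K_la`, `K_lv`
#'     (mN mm^-2 um^-1), chamber specific.}
#'   \item{chamber geometry}{unstressed radii `R0_la`, `R0_lv` and effective
#'     wall thicknesses `t_la`, `t_lv` (cm). The ventricular thickness is an
#'     adjusted effective parameter, not an anatomical measurement.}
#'   \item{circulation}{elastances `E_ao`, `E_vc`, `E_pa`, `E_pu`, `E_rv`
#'     (mmHg/ml); resistances `R_sys`, `R_pul`, `R_mt`, `R_av`, `R_tc`,
#'     `R_pv`, `R_prox` (mmHg.s/ml) where `R_pv` is the pulmonary *valve* and
#'     `R_prox` the proximal pulmonary vein; right-ventricular driver
#'     constants `A1..A3` (dimensionless), `B1..B3` (s^-2), `C1..C3` (s)
#'     plus the driver timing offset `shift_rv` (s, default 0: the driver is
#'     anchored to ventricular activation);
#'     cardiac `period` (s); total stressed blood volume `V_stressed` (ml).}
#' }
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of class `cvs_params`.
#' @examples
#' p <- cvs_params()
#' p$R_sys
#' cvs_params(period = 0.9)$period
#' @export
cvs_params <- function(...) {
  p <- list(
    # intracellular calcium transients
    T1_lv = 0.0305, T2_lv = 0.0977, Ca_max_lv = 1.47,
    T1_la = 0.0084, T2_la = 0.0300, Ca_max_la = 1.33,
    shift_la = 0.085,
    shift_rv = 0,
    # chemical kinetics (shared by both chambers)
    Y1 = 39, Z1 = 30, Y2 = 1.3, Z2 = 1.3, Y3 = 30, Z3 = 1560, Y4 = 40,
    Yd = 9, Tt = 70, B = 1200, h_c = 0.005, L_a = 1.17, R_sens = 20,
    # cross-bridge and parallel elastic force scaling
    A_la = 577.51, K_la = 20.00, A_lv = 944.58, K_lv = 0.4853, L0 = 0.97,
    # force-length to pressure-volume conversion
    R0_la = 1.66, t_la = 1.98, R0_lv = 1.62, t_lv = 6.36,
    # hemodynamic parameters
    E_pa = 2.29, E_pu = 0.0881, E_ao = 6.94, E_vc = 1.3077, E_rv = 2.10,
    R_pul = 2.454, R_sys = 3.61, R_av = 0.0846, R_mt = 0.0278,
    R_pv = 0.03, R_tc = 0.279, R_prox = 0.108,
    V_stressed = 273,
    # right-ventricle driver function
    A1 = 0.955, A2 = 0.624, A3 = 0.018,
    B1 = 454, B2 = 400, B3 = 7511,
    C1 = 0.1745, C2 = 0.097, C3 = 0.143,
    period = 0.45
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_cvs_params(structure(p, class = "cvs_params"))
}

validate_cvs_params <- function(p) {
  num1 <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                 logical(1))
  if (!all(num1)) {
    stop("parameter(s) not finite scalars: ",
         paste(names(p)[!num1], collapse = ", "), call. = FALSE)
  }
  positive <- c(
    "T1_lv", "T2_lv", "Ca_max_lv", "T1_la", "T2_la", "Ca_max_la",
    "Y1", "Z1", "Y2", "Z2", "Y3", "Z3", "Y4", "Yd", "Tt", "B", "h_c",
    "L_a", "R_sens", "L0", "R0_la", "t_la", "R0_lv", "t_lv",
    "E_pa", "E_pu", "E_ao", "E_vc", "E_rv",
    "R_pul", "R_sys", "R_av", "R_mt", "R_pv", "R_tc", "R_prox",
    "V_stressed", "period"
  )
  bad <- positive[vapply(positive, function(k) p[[k]] <= 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nonneg <- c("shift_la", "A_la", "A_lv", "K_la", "K_lv")  # shift_rv may take either sign
  bad <- nonneg[vapply(nonneg, function(k) p[[k]] < 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p
}

#' @export
print.cvs_params <- function(x, ...) {
  cat("<cvs_params> ", length(x), " parameters\n", sep = "")
  cat("  period: ", x$period, " s;  stressed volume: ", x$V_stressed,
      " ml\n", sep = "")
  invisible(x)
}

#' Load a run configuration from a flat YAML file
#'
#' The configuration schema is the flat key-value set of [cvs_params()]
#' (model constants) plus the run settings `n_cycles`, `max_cycles`,
#' `steady_tol`, `rtol`, `atol`, `dt_out`, `ivco_multiplier` and
#' `ivco_post_beats`. Keys omitted from the file keep their defaults; unknown
#' keys are an error naming the offending key.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A list with elements `params` (a `cvs_params`) and `settings`
#'   (run settings).
#' @examples
#' cfg <- load_config(NULL)
#' cfg$params$R_sys
#' @export
load_config <- function(path = NULL) {
  settings <- list(
    n_cycles = 30, max_cycles = 50, steady_tol = 1e-4,
    rtol = 1e-7, atol = 1e-9, dt_out = 5e-4,
    ivco_multiplier = 4, ivco_post_beats = 5
  )
  overrides <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    overrides <- yaml::read_yaml(path)
    if (length(overrides) && is.null(names(overrides))) {
      stop("config must be a flat key-value mapping", call. = FALSE)
    }
  }
  par_defaults <- unclass(cvs_params())
  unknown <- setdiff(names(overrides), c(names(par_defaults), names(settings)))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  set_keys <- intersect(names(overrides), names(settings))
  settings[set_keys] <- overrides[set_keys]
  par_keys <- intersect(names(overrides), names(par_defaults))
  params <- do.call(cvs_params, overrides[par_keys])
  list(params = params, settings = settings)
}
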