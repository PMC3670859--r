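# Lumped closed-loop circulation: passive elastance chambers, a
# time-varying-elastance right ventricle, Poiseuille resistances and
# diode valves.
#
# Network topology (arrows = flow direction at positive gradient):
#   lv -(mitral? no: aortic valve R_av)-> ao -(R_sys)-> vc -(tricuspid R_tc)->
#   rv -(pulmonary valve R_pv)-> pa -(R_pul)-> pu -(R_prox)-> la
#   -(mitral valve R_mt)-> lv

#' Pressure of a passive elastance chamber
#'
#' `P = E V` with constant elastance.
#'
#' @param V Stressed volume (ml), >= 0.
#' @param E Elastance (mmHg/ml), > 0.
#' @return Pressure (mmHg).
#' @export
elastic_pressure <- function(V, E) {
  if (E <= 0) stop("elastance must be positive", call. = FALSE)
  E * V
}

#' Normalised right-ventricular driver function
#'
#' Sum of three Gaussians, `e(t) = sum_i A_i exp(-B_i (t - C_i)^2)`,
#' evaluated on `t mod period`; strictly positive and periodic. The
#' Gaussians decay to negligible amplitude well within one cycle, so no
#' wrap-around summation is applied. The timing offset `shift_rv` (default 0)
#' translates the driver relative to ventricular activation; the relative
#' timing of the right-heart driver is not tightly constrained by left-heart
#' data, so it is exposed as an explicit parameter.
#'
#' @param t Time (s). Vectorised.
#' @param params A [cvs_params()] list.
#' @return Dimensionless elastance fraction, > 0.
#' @export
rv_driver <- function(t, params = cvs_params()) {
  u <- (t + params$shift_rv) %% params$period
  params$A1 * exp(-params$B1 * (u - params$C1)^2) +
    params$A2 * exp(-params$B2 * (u - params$C2)^2) +
    params$A3 * exp(-params$B3 * (u - params$C3)^2)
}

#' Right-ventricular pressure (time-varying elastance)
#'
#' `P_rv = E_rv e(t) V`, with the normalisation of the driver folded into
#' the single published scale `E_rv`.
#'
#' @param V Right-ventricular volume (ml), >= 0.
#' @param t Time (s).
#' @param params A [cvs_params()] list.
#' @return Pressure (mmHg).
#' @export
rv_pressure <- function(V, t, params = cvs_params()) {
  params$E_rv * rv_driver(t, params) * V
}

#' Flow through a resistance (Poiseuille)
#'
#' `Q = (P_up - P_down)/R`; signed, so backward flow is possible through
#' non-valve resistances.
#'
#' @param P_up,P_down Upstream and downstream pressures (mmHg).
#' @param R Resistance (mmHg.s/ml), > 0.
#' @return Flow (ml/s).
#' @export
resistive_flow <- function(P_up, P_down, R) {
  if (R <= 0) stop("resistance must be positive", call. = FALSE)
  (P_up - P_down) / R
}

#' Flow through a valve (perfect diode)
#'
#' Ramp of the pressure gradient: `Q = max(P_up - P_down, 0)/R`. Continuous
#' in the pressures and exactly zero for any negative gradient.
#'
#' @inheritParams resistive_flow
#' @return Non-negative flow (ml/s).
#' @export
valve_flow <- function(P_up, P_down, R) {
  if (R <= 0) stop("resistance must be positive", call. = FALSE)
  pmax(P_up - P_down, 0) / R
}

#' Chamber volume derivative (continuity)
#'
#' @param Q_in,Q_out Inflow and outflow (ml/s).
#' @return `dV/dt = Q_in - Q_out` (ml/s).
#' @export
volume_rhs <- function(Q_in, Q_out) {
  Q_in - Q_out
}
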