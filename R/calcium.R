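# Cosine-fitted intracellular calcium transients driving the two sarcomeres.

#' Describe a cosine-fitted intracellular calcium transient
#'
#' The driving input of each sarcomere is a smooth calcium pulse built from
#' two cosine half-waves: concentration rises from 0 to `Ca_max` over `T1`
#' seconds as `Ca_max/2 * (1 - cos(pi t / T1))`, falls back to 0 over `T2`
#' seconds as `Ca_max/2 * (1 + cos(pi (t - T1) / T2))`, and stays 0 for the
#' remainder of the cardiac cycle. The pulse is C1-continuous (zero slope at
#' onset, peak and end) and periodic with the cardiac period.
#'
#' `shift` moves activation earlier in the cycle: the transient is evaluated
#' at `(t + shift) mod period`. A positive shift on the atrial transient makes
#' the atrium lead the ventricle, placing atrial contraction at the end of
#' ventricular diastole.
#'
#' @param T1 Rise time constant (s), > 0.
#' @param T2 Decay time constant (s), > 0.
#' @param Ca_max Peak calcium concentration (uM), > 0.
#' @param period Cardiac period (s), > 0; must exceed `T1 + T2`.
#' @param shift Activation lead (s), >= 0. Default 0.
#' @return An object of class `calcium_transient`.
#' @seealso [eval_calcium()], [calcium_transients()]
#' @examples
#' tr <- calcium_transient(0.0305, 0.0977, 1.47, period = 0.45)
#' eval_calcium(0.0305, tr)  # peak: 1.47
#' @export
calcium_transient <- function(T1, T2, Ca_max, period, shift = 0) {
  if (!is.numeric(T1) || T1 <= 0 || !is.numeric(T2) || T2 <= 0) {
    stop("T1 and T2 must be positive", call. = FALSE)
  }
  if (!is.numeric(Ca_max) || Ca_max <= 0) {
    stop("Ca_max must be positive", call. = FALSE)
  }
  if (!is.numeric(period) || period <= 0) {
    stop("period must be positive", call. = FALSE)
  }
  if (T1 + T2 >= period) {
    stop("pulse duration T1 + T2 must be shorter than the period",
         call. = FALSE)
  }
  if (!is.numeric(shift) || shift < 0) {
    stop("shift must be non-negative", call. = FALSE)
  }
  structure(
    list(T1 = T1, T2 = T2, Ca_max = Ca_max, period = period, shift = shift),
    class = "calcium_transient"
  )
}

#' The two calcium transients of a parameter set
#'
#' @param params A [cvs_params()] list.
#' @return Named list with elements `lv` and `la`, each a
#'   `calcium_transient`. Only the atrial transient carries the activation
#'   lead `shift_la`.
#' @export
calcium_transients <- function(params = cvs_params()) {
  list(
    lv = calcium_transient(params$T1_lv, params$T2_lv, params$Ca_max_lv,
                           period = params$period),
    la = calcium_transient(params$T1_la, params$T2_la, params$Ca_max_la,
                           period = params$period, shift = params$shift_la)
  )
}

#' Evaluate a calcium transient
#'
#' Vectorised in `t`; evaluation is periodic with the cardiac period and
#' non-negative everywhere, with maximum `Ca_max` attained once per cycle.
#'
#' @param t Time (s), any finite value(s).
#' @param transient A [calcium_transient()].
#' @return Calcium concentration(s) (uM), same length as `t`.
#' @export
eval_calcium <- function(t, transient) {
  stopifnot(inherits(transient, "calcium_transient"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("t must be finite", call. = FALSE)
  }
  u <- (t + transient$shift) %% transient$period
  ca <- numeric(length(u))
  up <- u < transient$T1
  ca[up] <- transient$Ca_max / 2 * (1 - cos(pi * u[up] / transient$T1))
  down <- !up & u < transient$T1 + transient$T2
  ca[down] <- transient$Ca_max / 2 *
    (1 + cos(pi * (u[down] - transient$T1) / transient$T2))
  ca
}
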