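# Equivalent half-sarcomere contraction model (four-state troponin /
# cross-bridge kinetics with velocity-dependent detachment).
#
# Kinetic cycle (concentrations uM, attached species marked *):
#   T + Ca  -> TCa      rate Y1 * Ca * T
#   TCa     -> T + Ca   rate Z1 * TCa
#   TCa     -> TCa*     rate Y2 * ov(L) * TCa       (cross-bridge attachment)
#   TCa*    -> TCa      rate Z2 * TCa*  + Yd * (dX/dt)^2 * TCa*
#   TCa*    -> T* + Ca  rate Y3 * TCa*
#   T* + Ca -> TCa*     rate Z3 * Ca * T*
#   T*      -> T        rate Y4 * T*   + Yd * (dX/dt)^2 * T*
# The cycle structure conserves total troponin Tt exactly.
#
# Cross-bridge elongation: dh/dt = dL/dt - B (h - h_c), so the filament
# sliding velocity is dX/dt = d(L - h)/dt = B (h - h_c).
# Overlap/length sensitivity: ov(L) = exp(-R_sens (L - L_a)^2) scales the
# forward attachment rate — filament overlap limits how many cross-bridges
# can attach, which is what makes contraction preload-dependent.

#' Chamber-specific sarcomere parameters
#'
#' Extracts the kinetic constants shared by both chambers together with the
#' chamber-specific active gain `A` and passive stiffness `K` from a full
#' parameter set.
#'
#' @param params A [cvs_params()] list.
#' @param chamber `"la"` or `"lv"`.
#' @return Named list of class `sarcomere_params`.
#' @export
sarcomere_params <- function(params = cvs_params(), chamber = c("lv", "la")) {
  chamber <- match.arg(chamber)
  sp <- params[c("Y1", "Z1", "Y2", "Z2", "Y3", "Z3", "Y4", "Yd", "Tt",
                 "B", "h_c", "L_a", "R_sens", "L0")]
  sp$A <- if (chamber == "la") params$A_la else params$A_lv
  sp$K <- if (chamber == "la") params$K_la else params$K_lv
  sp$chamber <- chamber
  structure(sp, class = "sarcomere_params")
}

#' Construct a sarcomere state
#'
#' The four troponin species must sum to the total troponin concentration
#' `Tt`; the default is the resting state (all troponin free, cross-bridge
#' elongation at its unloaded reference `h_c`).
#'
#' @param sp A [sarcomere_params()] list.
#' @param TCa,TCa_star,T_star Concentrations (uM) of calcium-bound/detached,
#'   calcium-bound/attached and calcium-free/attached troponin. The free
#'   species is `T_free = Tt - TCa - TCa_star - T_star`.
#' @param h Cross-bridge elongation (um).
#' @return Named numeric vector `c(TCa, TCa_star, T_star, T_free, h)`.
#' @export
sarcomere_state <- function(sp, TCa = 0, TCa_star = 0, T_star = 0,
                            h = sp$h_c) {
  s <- c(TCa = TCa, TCa_star = TCa_star, T_star = T_star,
         T_free = sp$Tt - TCa - TCa_star - T_star, h = h)
  if (any(s[1:4] < 0)) {
    stop("troponin species concentrations must be non-negative and sum to Tt",
         call. = FALSE)
  }
  s
}

#' Time derivatives of the sarcomere state
#'
#' Right-hand side of the troponin/cross-bridge kinetics at calcium
#' concentration `Ca`, half-sarcomere length `L` and lengthening velocity
#' `dLdt`. The returned troponin derivatives sum to zero exactly.
#'
#' @param state Named vector from [sarcomere_state()] (components `TCa`,
#'   `TCa_star`, `T_star`, `T_free`, `h`).
#' @param Ca Calcium concentration (uM), >= 0.
#' @param L Half-sarcomere length (um).
#' @param dLdt Rate of change of `L` (um/s).
#' @param sp A [sarcomere_params()] list.
#' @return Named vector of derivatives `d(TCa, TCa_star, T_star, T_free, h)/dt`.
#' @export
kinetics_rhs <- function(state, Ca, L, dLdt, sp) {
  if (Ca < 0) stop("calcium concentration must be non-negative", call. = FALSE)
  if (any(state[c("TCa", "TCa_star", "T_star", "T_free")] < -1e-9)) {
    stop("invalid sarcomere state: negative troponin concentration",
         call. = FALSE)
  }
  ov <- exp(-sp$R_sens * (L - sp$L_a)^2)
  dXdt <- sp$B * (state[["h"]] - sp$h_c)
  yd <- sp$Yd * dXdt^2
  q1 <- sp$Y1 * Ca * state[["T_free"]] - sp$Z1 * state[["TCa"]]
  q2 <- sp$Y2 * ov * state[["TCa"]] - sp$Z2 * state[["TCa_star"]]
  q3 <- sp$Y3 * state[["TCa_star"]] - sp$Z3 * Ca * state[["T_star"]]
  q4 <- sp$Y4 * state[["T_star"]]
  qd1 <- yd * state[["TCa_star"]]
  qd2 <- yd * state[["T_star"]]
  c(
    TCa = q1 - q2 + qd1,
    TCa_star = q2 - q3 - qd1,
    T_star = q3 - q4 - qd2,
    T_free = q4 - q1 + qd2,
    h = dLdt - sp$B * (state[["h"]] - sp$h_c)
  )
}

#' Active force of the equivalent half-sarcomere
#'
#' Proportional to the concentration of attached cross-bridge species and to
#' the cross-bridge elongation: `F_a = A (TCa* + T*) h`, in mN/mm^2.
#'
#' @inheritParams kinetics_rhs
#' @return Active force per unit area (mN/mm^2).
#' @export
active_force <- function(state, sp) {
  sp$A * (state[["TCa_star"]] + state[["T_star"]]) * state[["h"]]
}

#' Passive force of the equivalent half-sarcomere
#'
#' Linear parallel elastic element: `F_b = K (L - L0)`, zero at the
#' unstressed length.
#'
#' @param L Half-sarcomere length (um), > 0.
#' @param sp A [sarcomere_params()] list.
#' @return Passive force per unit area (mN/mm^2); negative below `L0`.
#' @export
passive_force <- function(L, sp) {
  if (any(L <= 0)) stop("half-sarcomere length must be positive", call. = FALSE)
  sp$K * (L - sp$L0)
}

#' Total force of the equivalent half-sarcomere
#'
#' @inheritParams kinetics_rhs
#' @return `active_force(state, sp) + passive_force(L, sp)` (mN/mm^2).
#' @export
total_force <- function(state, L, sp) {
  active_force(state, sp) + passive_force(L, sp)
}
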