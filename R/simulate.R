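# Assembled ODE system: two equivalent half-sarcomeres (5 states each) plus
# seven chamber volumes, integrated with a stiff-capable adaptive solver.

# fixed state layout
.state_names <- c(
  "la_TCa", "la_TCa_star", "la_T_star", "la_T_free", "la_h",
  "lv_TCa", "lv_TCa_star", "lv_T_star", "lv_T_free", "lv_h",
  "V_la", "V_lv", "V_rv", "V_ao", "V_vc", "V_pa", "V_pu"
)
.vol_names <- .state_names[11:17]

#' Initial state of the closed-loop model
#'
#' Both sarcomeres start at rest (all troponin free, cross-bridge elongation
#' at `h_c`); the stressed blood volume is distributed across the seven
#' chambers in fixed proportions (ao 10, vc 90, pa 25, pu 100, lv 25, rv 15,
#' la 8 out of 273, rescaled to `V_stressed`). Cycling to the periodic steady
#' state erases this choice; only the limit cycle is analysed.
#'
#' @param params A [cvs_params()] list.
#' @return Named numeric state vector (10 sarcomere states + 7 volumes).
#' @export
cvs_initial_state <- function(params = cvs_params()) {
  split <- c(V_la = 8, V_lv = 25, V_rv = 15, V_ao = 10, V_vc = 90,
             V_pa = 25, V_pu = 100)
  vols <- split / sum(split) * params$V_stressed
  y <- c(
    la_TCa = 0, la_TCa_star = 0, la_T_star = 0, la_T_free = params$Tt,
    la_h = params$h_c,
    lv_TCa = 0, lv_TCa_star = 0, lv_T_star = 0, lv_T_free = params$Tt,
    lv_h = params$h_c,
    vols[.vol_names]
  )
  names(y) <- .state_names
  y
}

# Full right-hand side plus observables, as one scalar-arithmetic pass.
# Returns list(derivatives, observables); the module-level functions in
# sarcomere.R / chamber.R / circulation.R define the same sub-models and are
# used as an independent cross-check in the tests.
.cvs_rhs_core <- function(t, y, p, tr) {
  V_la <- y[[11]]; V_lv <- y[[12]]; V_rv <- y[[13]]; V_ao <- y[[14]]
  V_vc <- y[[15]]; V_pa <- y[[16]]; V_pu <- y[[17]]
  if (V_la <= 0 || V_lv <= 0 || V_rv <= 0 || V_ao <= 0 || V_vc <= 0 ||
      V_pa <= 0 || V_pu <= 0) {
    stop("chamber volume dropped to zero or below at t = ", signif(t, 6),
         " s (parameter error?); volumes: ",
         paste(signif(c(V_la, V_lv, V_rv, V_ao, V_vc, V_pa, V_pu), 4),
               collapse = ", "), call. = FALSE)
  }

  # geometry and half-sarcomere lengths
  R_la <- (3 * V_la / (2 * pi))^(1 / 3)
  R_lv <- (3 * V_lv / (2 * pi))^(1 / 3)
  L_la <- p$L0 * R_la / p$R0_la
  L_lv <- p$L0 * R_lv / p$R0_lv

  # calcium inputs (atrial transient leads by shift_la)
  u_lv <- t %% p$period
  Ca_lv <- if (u_lv < p$T1_lv) {
    p$Ca_max_lv / 2 * (1 - cos(pi * u_lv / p$T1_lv))
  } else if (u_lv < p$T1_lv + p$T2_lv) {
    p$Ca_max_lv / 2 * (1 + cos(pi * (u_lv - p$T1_lv) / p$T2_lv))
  } else 0
  u_la <- (t + p$shift_la) %% p$period
  Ca_la <- if (u_la < p$T1_la) {
    p$Ca_max_la / 2 * (1 - cos(pi * u_la / p$T1_la))
  } else if (u_la < p$T1_la + p$T2_la) {
    p$Ca_max_la / 2 * (1 + cos(pi * (u_la - p$T1_la) / p$T2_la))
  } else 0

  # wall forces and cavity pressures (Laplace, kPa -> mmHg)
  F_la <- p$A_la * (y[[2]] + y[[3]]) * y[[5]] + p$K_la * (L_la - p$L0)
  F_lv <- p$A_lv * (y[[7]] + y[[8]]) * y[[10]] + p$K_lv * (L_lv - p$L0)
  P_la <- 2 * F_la * p$t_la / R_la / KPA_PER_MMHG
  P_lv <- 2 * F_lv * p$t_lv / R_lv / KPA_PER_MMHG
  u_rv <- (t + p$shift_rv) %% p$period
  e_t <- p$A1 * exp(-p$B1 * (u_rv - p$C1)^2) +
    p$A2 * exp(-p$B2 * (u_rv - p$C2)^2) +
    p$A3 * exp(-p$B3 * (u_rv - p$C3)^2)
  P_rv <- p$E_rv * e_t * V_rv
  P_ao <- p$E_ao * V_ao
  P_vc <- p$E_vc * V_vc
  P_pa <- p$E_pa * V_pa
  P_pu <- p$E_pu * V_pu

  # flows: diode valves and signed resistances
  Q_mt <- max(P_la - P_lv, 0) / p$R_mt
  Q_av <- max(P_lv - P_ao, 0) / p$R_av
  Q_sys <- (P_ao - P_vc) / p$R_sys
  Q_tc <- max(P_vc - P_rv, 0) / p$R_tc
  Q_pv <- max(P_rv - P_pa, 0) / p$R_pv
  Q_pul <- (P_pa - P_pu) / p$R_pul
  Q_prox <- (P_pu - P_la) / p$R_prox

  # continuity
  dV_la <- Q_prox - Q_mt
  dV_lv <- Q_mt - Q_av
  dV_rv <- Q_tc - Q_pv
  dV_ao <- Q_av - Q_sys
  dV_vc <- Q_sys - Q_tc
  dV_pa <- Q_pv - Q_pul
  dV_pu <- Q_pul - Q_prox

  # half-sarcomere lengthening velocities (chain rule through geometry)
  dL_la <- p$L0 / p$R0_la * dV_la / (2 * pi * R_la^2)
  dL_lv <- p$L0 / p$R0_lv * dV_lv / (2 * pi * R_lv^2)

  # troponin / cross-bridge kinetics, both chambers
  ov_la <- exp(-p$R_sens * (L_la - p$L_a)^2)
  dX_la <- p$B * (y[[5]] - p$h_c)
  yd_la <- p$Yd * dX_la^2
  q1 <- p$Y1 * Ca_la * y[[4]] - p$Z1 * y[[1]]
  q2 <- p$Y2 * ov_la * y[[1]] - p$Z2 * y[[2]]
  q3 <- p$Y3 * y[[2]] - p$Z3 * Ca_la * y[[3]]
  q4 <- p$Y4 * y[[3]]
  qd1 <- yd_la * y[[2]]
  qd2 <- yd_la * y[[3]]
  d_la <- c(q1 - q2 + qd1, q2 - q3 - qd1, q3 - q4 - qd2, q4 - q1 + qd2,
            dL_la - p$B * (y[[5]] - p$h_c))

  ov_lv <- exp(-p$R_sens * (L_lv - p$L_a)^2)
  dX_lv <- p$B * (y[[10]] - p$h_c)
  yd_lv <- p$Yd * dX_lv^2
  q1 <- p$Y1 * Ca_lv * y[[9]] - p$Z1 * y[[6]]
  q2 <- p$Y2 * ov_lv * y[[6]] - p$Z2 * y[[7]]
  q3 <- p$Y3 * y[[7]] - p$Z3 * Ca_lv * y[[8]]
  q4 <- p$Y4 * y[[8]]
  qd1 <- yd_lv * y[[7]]
  qd2 <- yd_lv * y[[8]]
  d_lv <- c(q1 - q2 + qd1, q2 - q3 - qd1, q3 - q4 - qd2, q4 - q1 + qd2,
            dL_lv - p$B * (y[[10]] - p$h_c))

  list(
    c(d_la, d_lv, dV_la, dV_lv, dV_rv, dV_ao, dV_vc, dV_pa, dV_pu),
    c(P_la = P_la, P_lv = P_lv, P_rv = P_rv, P_ao = P_ao, P_vc = P_vc,
      P_pa = P_pa, P_pu = P_pu,
      Q_mt = Q_mt, Q_av = Q_av, Q_tc = Q_tc, Q_pv = Q_pv,
      Q_sys = Q_sys, Q_pul = Q_pul, Q_prox = Q_prox,
      Ca_la = Ca_la, Ca_lv = Ca_lv)
  )
}

#' Full model right-hand side
#'
#' State derivative of the assembled system at time `t`: sarcomere kinetics
#' driven by the calcium transients and by the half-sarcomere length implied
#' by chamber volume; atrial/ventricular pressures via Laplace's law; other
#' pressures via (time-varying) elastances; flows via valve/resistance laws;
#' volumes via continuity. Aborts with a diagnostic if any volume is
#' non-positive.
#'
#' @param t Time (s).
#' @param state Named state vector as produced by [cvs_initial_state()].
#' @param params A [cvs_params()] list.
#' @return List with `derivatives` (named vector, same layout as `state`)
#'   and `observables` (named vector of pressures, flows and calcium inputs).
#' @export
cvs_rhs <- function(t, state, params = cvs_params()) {
  out <- .cvs_rhs_core(t, unname(state[.state_names]), params, NULL)
  list(derivatives = stats::setNames(out[[1]], .state_names),
       observables = out[[2]])
}

.simulate_raw <- function(params, times, y0, rtol, atol) {
  p <- params
  out <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, parms) .cvs_rhs_core(t, y, p, NULL),
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol,
    maxsteps = 100000
  )
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed; last valid time ", max(out[, 1]), call. = FALSE)
  }
  out
}

.traces_tibble <- function(out, params, t0 = 0) {
  df <- tibble::as_tibble(as.data.frame(out))
  names(df)[1:18] <- c("time", .state_names)
  df$time <- df$time + t0
  df$cycle <- floor(df$time / params$period + 1e-9)
  df[, c("time", "cycle",
         "P_la", "P_lv", "P_rv", "P_ao", "P_vc", "P_pa", "P_pu",
         .vol_names,
         "Q_mt", "Q_av", "Q_tc", "Q_pv", "Q_sys", "Q_pul", "Q_prox",
         "Ca_la", "Ca_lv",
         .state_names[1:10])]
}

#' Simulate the closed-loop cardiovascular model
#'
#' Integrates the assembled ODE system over `n_cycles` cardiac cycles with
#' the stiff-capable adaptive solver `lsoda`, sampling dense output every
#' `dt_out` seconds.
#'
#' @param params A [cvs_params()] list.
#' @param n_cycles Number of cardiac cycles to integrate (>= 1).
#' @param init Initial state (defaults to [cvs_initial_state()]).
#' @param dt_out Output sampling interval (s), default 0.5 ms.
#' @param rtol,atol Solver tolerances.
#' @param t0 Time offset applied to the reported time axis (s).
#' @return A `cvs_simulation` object: list with `traces` (tibble of time,
#'   cycle, pressures mmHg, volumes ml, flows ml/s, calcium inputs uM and
#'   sarcomere states), `params`, `final_state`, `n_cycles`, `converged`
#'   (NA here; set by [run_to_steady_state()]) and solver settings.
#' @examples
#' \donttest{
#' sim <- simulate_cvs(cvs_params(), n_cycles = 2)
#' dplyr::glimpse(sim$traces)
#' }
#' @export
simulate_cvs <- function(params = cvs_params(), n_cycles = 10, init = NULL,
                         dt_out = 5e-4, rtol = 1e-7, atol = 1e-9, t0 = 0) {
  stopifnot(n_cycles >= 1)
  y0 <- if (is.null(init)) cvs_initial_state(params) else init[.state_names]
  times <- seq(0, n_cycles * params$period, by = dt_out)
  out <- .simulate_raw(params, times, y0, rtol, atol)
  final <- stats::setNames(as.numeric(out[nrow(out), 1 + seq_along(.state_names)]),
                           .state_names)
  structure(
    list(traces = .traces_tibble(out, params, t0), params = params,
         final_state = final, n_cycles = n_cycles, converged = NA,
         settings = list(dt_out = dt_out, rtol = rtol, atol = atol)),
    class = "cvs_simulation"
  )
}

#' @export
print.cvs_simulation <- function(x, ...) {
  cat("<cvs_simulation> ", x$n_cycles, " cycle(s), ",
      nrow(x$traces), " samples", sep = "")
  if (!is.na(x$converged)) {
    cat(if (x$converged) ", converged to periodic steady state" else
      ", NOT converged")
  }
  cat("\n")
  invisible(x)
}

.cycle_extrema <- function(out) {
  vols <- out[, .vol_names, drop = FALSE]
  c(apply(vols, 2, min), apply(vols, 2, max))
}

#' Integrate to the periodic steady state
#'
#' Repeats single cardiac cycles until, for every chamber, the relative
#' change of both per-cycle volume extrema between consecutive cycles falls
#' below `tol`; then re-integrates one final cycle from the converged state
#' at fine output sampling and returns it (time axis starting at 0).
#'
#' @param params A [cvs_params()] list.
#' @param max_cycles Give up (with an error carrying the convergence trend)
#'   after this many cycles.
#' @param tol Relative convergence tolerance on per-cycle volume extrema.
#' @param init Initial state; default [cvs_initial_state()].
#' @param dt_out Output sampling of the returned steady cycle (s).
#' @param rtol,atol Solver tolerances.
#' @return A `cvs_simulation` of the single converged cycle, with
#'   `converged = TRUE`, `cycles_run` and the per-cycle convergence history
#'   in `convergence`.
#' @export
run_to_steady_state <- function(params = cvs_params(), max_cycles = 50,
                                tol = 1e-4, init = NULL, dt_out = 5e-4,
                                rtol = 1e-7, atol = 1e-9) {
  stopifnot(max_cycles >= 2)
  y <- if (is.null(init)) cvs_initial_state(params) else init[.state_names]
  # coarse sampling is sufficient to track volume extrema during transients
  times <- seq(0, params$period, by = 2e-3)
  prev <- NULL
  history <- numeric(0)
  converged <- FALSE
  for (k in seq_len(max_cycles)) {
    out <- .simulate_raw(params, times, y, rtol, atol)
    y <- stats::setNames(as.numeric(out[nrow(out), 1 + seq_along(.state_names)]),
                         .state_names)
    ext <- .cycle_extrema(out)
    if (!is.null(prev)) {
      delta <- max(abs(ext - prev) / pmax(abs(prev), 1e-8))
      history <- c(history, delta)
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    prev <- ext
  }
  if (!converged) {
    stop("no periodic steady state within ", max_cycles,
         " cycles; last relative changes: ",
         paste(signif(utils::tail(history, 5), 3), collapse = ", "),
         call. = FALSE)
  }
  sim <- simulate_cvs(params, n_cycles = 1, init = y, dt_out = dt_out,
                      rtol = rtol, atol = atol)
  sim$converged <- TRUE
  sim$cycles_run <- k
  sim$convergence <- history
  sim
}

#' Simulated preload reduction (inferior vena cava occlusion)
#'
#' Reproduces a vena-cava-occlusion manoeuvre by multiplying the pulmonary
#' vascular resistance `R_pul` by `multiplier` at a cycle boundary of the
#' baseline periodic steady state, integrating `post_beats` further beats,
#' and returning the baseline steady cycle together with the last
#' post-occlusion beat.
#'
#' @param params A [cvs_params()] list.
#' @param multiplier Factor applied to `R_pul` (default 4).
#' @param post_beats Number of beats integrated after the change; the
#'   `post_beats`-th beat is returned (default 5).
#' @param baseline Optionally, a converged baseline `cvs_simulation` from
#'   [run_to_steady_state()] (re-used as-is); computed if missing.
#' @param ... Passed to [run_to_steady_state()].
#' @return A `cvs_ivco` object: list with `baseline` and `ivco`
#'   (`cvs_simulation` objects for one cycle each), `params`, `multiplier`
#'   and `post_beats`. Time in the `ivco` traces is relative to the start of
#'   the returned (last) beat.
#' @export
run_ivco <- function(params = cvs_params(), multiplier = 4, post_beats = 5,
                     baseline = NULL, ...) {
  stopifnot(multiplier > 0, post_beats >= 1)
  if (is.null(baseline)) {
    baseline <- run_to_steady_state(params, ...)
  } else if (!isTRUE(baseline$converged)) {
    stop("baseline simulation has not converged", call. = FALSE)
  }
  occluded <- cvs_params()
  occluded[names(params)] <- unclass(params)[names(params)]
  occluded$R_pul <- params$R_pul * multiplier
  occluded <- validate_cvs_params(occluded)
  y <- baseline$final_state
  dt_out <- baseline$settings$dt_out
  rtol <- baseline$settings$rtol
  atol <- baseline$settings$atol
  if (post_beats > 1) {
    pre <- simulate_cvs(occluded, n_cycles = post_beats - 1, init = y,
                        dt_out = 2e-3, rtol = rtol, atol = atol)
    y <- pre$final_state
  }
  last <- simulate_cvs(occluded, n_cycles = 1, init = y, dt_out = dt_out,
                       rtol = rtol, atol = atol)
  last$converged <- NA
  structure(
    list(baseline = baseline, ivco = last, params = params,
         multiplier = multiplier, post_beats = post_beats),
    class = "cvs_ivco"
  )
}

#' @export
print.cvs_ivco <- function(x, ...) {
  cat("<cvs_ivco> R_pul x", x$multiplier, ", beat ", x$post_beats,
      " after occlusion (plus baseline steady cycle)\n", sep = "")
  invisible(x)
}
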