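# Synthetic LA/LV pressure and mitral-flow waveforms with exactly known
# fiducial points, used to validate the analysis layer independently of the
# simulator. Entirely deterministic piecewise-linear constructions.

#' Synthetic pressure/flow waveforms with known fiducial ground truth
#'
#' Builds one cardiac cycle of left-atrial and left-ventricular pressure and
#' transmitral flow from piecewise-linear segments whose break points are
#' the fiducial points themselves, so every detected quantity has an exact
#' analytic reference. The reference shape (at the default parameters, on
#' the phase axis anchored at mitral opening):
#' \itemize{
#'   \item v-wave peak (F) 14 mmHg at phase 0; atrial pressure falls to the
#'     a-wave onset B (7 mmHg at 0.10 s), rises linearly to the a-wave peak
#'     C (B + `a_amp` at 0.16 s; slope `a_amp`/0.06 mmHg/s), falls to 8.5 at
#'     0.20 s, dips to the v-wave onset D (8 mmHg at 0.22 s) and rises
#'     linearly back to F.
#'   \item ventricular pressure starts at 14, falls to its minimum A
#'     (5 mmHg at 0.05 s), rises to cross the atrial trace at E
#'     (mitral closing, 0.18 s), peaks at `lv_peak` (0.30 s) and returns.
#'   \item transmitral flow: triangular E wave (70 ml/s peak at 0.06 s) and
#'     A wave (100 ml/s peak at 0.165 s) over a plateau of `diastasis_flow`
#'     ml/s, zero while the valve is closed (0.19 s to the cycle end).
#' }
#' Setting `a_amp = 0` removes the a wave (the atrial trace stays flat from
#' B through 0.20 s), which makes fiducial detection fail with its
#' documented error — the degenerate-input fixture.
#'
#' @param dt Sampling interval (s), default 0.5 ms.
#' @param period Cardiac period (s); the reference shape (defined for
#'   0.45 s) is scaled in time by `period / 0.45`.
#' @param phase0 Rotation applied to the emitted traces (s); ground truth
#'   times are rotated identically. Lets tests exercise cycle-wrap handling.
#' @param a_amp a-wave amplitude above its onset (mmHg), default 3.
#' @param lv_peak Systolic ventricular peak pressure (mmHg), default 120.
#' @param diastasis_flow Flow level separating the E and A waves (ml/s);
#'   the default 10 fuses the waves, 0 separates them.
#' @return A list with `traces` (tibble `time`, `P_la`, `P_lv`, `Q_mt`) and
#'   `truth`: the exact fiducial tibble (`point`, `phase`, `time`,
#'   `pressure`), `indices` (one-row tibble as [compute_indices()]), and
#'   `mitral` (E/A peak flows, times and fusion flag).
#' @examples
#' fx <- fixture_waveforms()
#' fx$truth$indices$slope_a_wave  # 50 mmHg/s by construction
#' @export
fixture_waveforms <- function(dt = 5e-4, period = 0.45, phase0 = 0,
                              a_amp = 3, lv_peak = 120,
                              diastasis_flow = 10) {
  if (dt <= 0 || period <= 0) stop("dt and period must be positive",
                                   call. = FALSE)
  if (a_amp < 0) stop("a_amp must be non-negative", call. = FALSE)
  sc <- period / 0.45
  # break points (phase anchored at mitral opening F)
  tB <- 0.10 * sc; tC <- 0.16 * sc; tE <- 0.18 * sc
  tD <- 0.22 * sc; tA <- 0.05 * sc
  pF <- 14; pB <- 7; pC <- pB + a_amp; pA <- 5; pD <- 8
  la_knots_t <- c(0, tB, tC, 0.20 * sc, tD, period)
  la_knots_p <- c(pF, pB, pC, if (a_amp > 0) 8.5 else pB, pD, pF)
  # LV knots; pE is where the LV line from A hits the LA trace at tE
  la_at <- function(u) stats::approx(la_knots_t, la_knots_p, u)$y
  pE <- la_at(tE)
  lv_knots_t <- c(0, tA, tE, 0.30 * sc, period)
  lv_knots_p <- c(pF, pA, pE, lv_peak, pF)
  q_knots_t <- c(0, 0.01, 0.06, 0.11, 0.165, 0.19, period / sc) * sc
  q_knots_t[7] <- period
  q_knots_p <- c(0, diastasis_flow, 70, diastasis_flow, 100, 0, 0)
  u <- seq(0, period - dt / 2, by = dt)
  ur <- (u - phase0) %% period
  traces <- tibble::tibble(
    time = u,
    P_la = stats::approx(la_knots_t, la_knots_p, ur)$y,
    P_lv = stats::approx(lv_knots_t, lv_knots_p, ur)$y,
    Q_mt = stats::approx(q_knots_t, q_knots_p, ur)$y
  )
  points <- tibble::tibble(
    point = c("A", "B", "C", "D", "E", "F"),
    trace = c("P_lv", "P_la", "P_la", "P_la", "P_lv", "P_la"),
    phase = c(tA, tB, tC, tD, tE, 0),
    pressure = c(pA, pB, pC, pD, pE, pF)
  )
  points$time <- (points$phase + phase0) %% period
  # exact indices from the segment construction
  lv_at <- function(u) stats::approx(lv_knots_t, lv_knots_p, u)$y
  grad_max <- function(lo, hi) {
    kn <- sort(unique(c(lo, hi,
                        la_knots_t[la_knots_t > lo & la_knots_t < hi],
                        lv_knots_t[lv_knots_t > lo & lv_knots_t < hi])))
    max(la_at(kn) - lv_at(kn))
  }
  indices <- tibble::tibble(
    max_a_wave_pressure = pC,
    max_v_wave_pressure = pF,
    min_ventricular_pressure = pA,
    end_diastolic_ventricular_pressure = pE,
    slope_a_wave = (pC - pB) / (tC - tB),
    slope_v_wave = (pF - pD) / (period - tD),
    max_early_gradient = grad_max(0, tB),
    max_late_gradient = grad_max(tB, tE)
  )
  mitral <- tibble::tibble(
    e_flow = 70, e_time = (0.06 * sc + phase0) %% period,
    a_flow = 100, a_time = (0.165 * sc + phase0) %% period,
    fused = diastasis_flow > 0.05 * 70
  )
  list(traces = traces,
       truth = list(points = points, indices = indices, mitral = mitral))
}
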