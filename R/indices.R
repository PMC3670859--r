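# Analysis layer: fiducial points on LA/LV pressure traces, hemodynamic
# indices, atrial PV-loop lobe decomposition and transmitral E/A features.
#
# All functions take a data frame of one steady cycle (uniformly sampled
# columns time, P_la, P_lv, and for the flow/loop functions Q_mt / V_la) or a
# `cvs_simulation`, and return tibbles.

.one_cycle <- function(traces, need = c("time", "P_la", "P_lv")) {
  if (inherits(traces, "cvs_simulation")) traces <- traces$traces
  traces <- as.data.frame(traces)
  miss <- setdiff(need, names(traces))
  if (length(miss)) {
    stop("trace columns missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(traces)
  if (n < 16) stop("trace too short for cycle analysis", call. = FALSE)
  dt <- diff(traces$time[1:2])
  if (any(abs(diff(traces$time) - dt) > dt * 1e-6)) {
    stop("trace must be uniformly sampled", call. = FALSE)
  }
  # drop a duplicated cycle endpoint (t = 0 and t = period both present)
  if (isTRUE(all.equal(traces$P_la[1], traces$P_la[n], tolerance = 1e-3)) &&
      isTRUE(all.equal(traces$P_lv[1], traces$P_lv[n], tolerance = 1e-3))) {
    traces <- traces[-n, , drop = FALSE]
  }
  traces
}

.movavg_periodic <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  k <- min(w, n)
  xx <- c(utils::tail(x, k), x, utils::head(x, k))
  stats::filter(xx, rep(1 / k, k), sides = 2)[(k + 1):(k + n)]
}

# strict local maxima of a periodic series (wrap-aware), as indices
.locmax_periodic <- function(x) {
  n <- length(x)
  xm <- c(x[n], x, x[1])
  which(xm[2:(n + 1)] > xm[1:n] & xm[2:(n + 1)] > xm[3:(n + 2)])
}

#' Count prominent maxima of a periodic trace
#'
#' Wrap-aware local maxima whose prominence (drop to the highest of the two
#' flanking minima along the cycle) exceeds `min_prominence` times the
#' peak-to-peak range. Used for waveform morphology checks (e.g. the
#' biphasic a/v atrial pressure wave has exactly two).
#'
#' @param x Numeric vector, one uniformly sampled cycle (no duplicated
#'   endpoint).
#' @param min_prominence Fraction of the peak-to-peak range (default 0.02).
#' @return Integer vector of peak indices.
#' @export
prominent_maxima <- function(x, min_prominence = 0.02) {
  n <- length(x)
  pk <- .locmax_periodic(x)
  if (!length(pk)) return(integer(0))
  rng <- diff(range(x))
  if (rng == 0) return(integer(0))
  keep <- logical(length(pk))
  for (i in seq_along(pk)) {
    others <- pk[-i]
    if (!length(others)) {
      keep[i] <- TRUE
      next
    }
    # cyclic walk from this peak to the nearest higher-or-equal peak on each
    # side; prominence = peak minus the higher of the two interval minima
    lows <- vapply(others, function(j) {
      seg <- if (j > pk[i]) pk[i]:j else c(pk[i]:n, 1:j)
      min(x[seg])
    }, numeric(1))
    higher <- x[others] >= x[pk[i]]
    prom <- x[pk[i]] - if (any(higher)) max(lows[higher]) else min(lows)
    keep[i] <- prom >= min_prominence * rng
  }
  pk[keep]
}

# interpolated crossings of d = P_lv - P_la; direction "down" = LV falls
# below LA (mitral opening), "up" = LV rises above LA (mitral closing)
.crossings <- function(d) {
  n <- length(d)
  nxt <- c(2:n, 1)
  down <- which(d >= 0 & d[nxt] < 0)
  up <- which(d <= 0 & d[nxt] > 0 & d[nxt] - d > 0)
  down <- down[d[down] - d[nxt][down] > 0]
  frac <- function(i) d[i] / (d[i] - d[nxt][i])
  list(down = down, up = up, frac_down = vapply(down, frac, numeric(1)),
       frac_up = vapply(up, frac, numeric(1)))
}

# workhorse: rotate one cycle to start at mitral opening (point F) and locate
# all six fiducial points on the sample grid / by interpolation
.analyse_cycle <- function(traces, smooth = 0, pad = 0.02) {
  tr <- .one_cycle(traces)
  n <- nrow(tr)
  dt <- diff(tr$time[1:2])
  period <- n * dt
  P_la <- .movavg_periodic(tr$P_la, smooth)
  P_lv <- .movavg_periodic(tr$P_lv, smooth)
  d <- P_lv - P_la
  cr <- .crossings(d)
  if (!length(cr$down)) {
    stop("fiducial point F not found: LA and LV pressures never cross ",
         "(mitral opening missing)", call. = FALSE)
  }
  if (!length(cr$up)) {
    stop("fiducial point E not found: LA and LV pressures never cross ",
         "(mitral closing missing)", call. = FALSE)
  }
  # F = downward crossing at the highest atrial pressure (the v-wave peak)
  p_at <- function(i, frac, x) {
    j <- if (i == n) 1 else i + 1
    x[i] + frac * (x[j] - x[i])
  }
  pF_all <- mapply(p_at, cr$down, cr$frac_down, MoreArgs = list(x = P_la))
  kF <- which.max(pF_all)
  iF <- cr$down[kF]
  fracF <- cr$frac_down[kF]
  pF <- pF_all[kF]
  # phase coordinate: time since (interpolated) F, in [0, period)
  phase_of <- function(i, frac = 0) ((i - 1 + frac) - (iF - 1 + fracF)) %% n * dt
  # E = first upward crossing after F in cycle order
  phE_all <- mapply(phase_of, cr$up, cr$frac_up)
  kE <- which.min(phE_all)
  phE <- phE_all[kE]
  pE <- p_at(cr$up[kE], cr$frac_up[kE], P_lv)
  # rotated sample grid (first sample at or after F)
  rot <- (seq_len(n) + ceiling(iF - 1 + fracF) - 1) %% n + 1
  la <- P_la[rot]
  lv <- P_lv[rot]
  ph <- (phase_of(rot[1]) + (seq_len(n) - 1) * dt)
  iE <- max(2L, sum(ph <= phE))          # last grid index before closing
  # A: minimum LV pressure (diastolic trough)
  iA <- which.min(lv)
  # B: onset of the a wave = atrial minimum between opening and closing
  iB <- which.min(la[1:iE])
  # C: a-wave peak = most prominent atrial local max after B, allowing a
  # short overrun past E (the peak can fall at mitral closing itself)
  hiC <- min(n, iE + round(pad / dt))
  cand <- .locmax_periodic(la)
  cand <- cand[cand > iB & cand <= hiC]
  if (!length(cand)) {
    stop("fiducial point C not found: no a-wave peak on the atrial ",
         "pressure between its diastolic minimum and mitral closing",
         call. = FALSE)
  }
  iC <- cand[which.max(la[cand])]
  if (iC == iB) stop("degenerate a wave: peak coincides with onset",
                     call. = FALSE)
  # D: onset of the v wave = atrial minimum between closing and next opening
  iD <- iE + which.min(la[iE:n]) - 1L
  points <- tibble::tibble(
    point = c("A", "B", "C", "D", "E", "F"),
    trace = c("P_lv", "P_la", "P_la", "P_la", "P_lv", "P_la"),
    phase = c(ph[iA], ph[iB], ph[iC], ph[iD], phE, 0),
    pressure = c(lv[iA], la[iB], la[iC], la[iD], pE, pF)
  )
  points$time <- (points$phase + tr$time[1] +
                    (iF - 1 + fracF) * dt - tr$time[1]) %% period + tr$time[1]
  list(points = points, la = la, lv = lv, phase = ph, dt = dt,
       period = period, iB = iB, iC = iC, iD = iD, iE = iE, phE = phE)
}

#' Detect the six fiducial points of one cardiac cycle
#'
#' Locates, on aligned uniformly sampled left-atrial and left-ventricular
#' pressure traces of one steady cycle: A (minimum LV pressure), B (onset of
#' the atrial a wave), C (a-wave peak), D (onset of the v wave), E (LA/LV
#' crossover at mitral closing) and F (LA/LV crossover at mitral opening,
#' which carries the v-wave peak). Crossovers are located by linear
#' interpolation between bracketing samples; the other points sit on the
#' sample grid. The onsets B and D are the atrial pressure minima preceding
#' their respective peaks (C and F).
#'
#' @param traces Data frame with columns `time`, `P_la`, `P_lv` covering one
#'   cycle, or a `cvs_simulation` of one cycle.
#' @param smooth Optional moving-average window (samples) applied before
#'   detection; 0 (default) disables smoothing. Simulated traces are smooth;
#'   the option exists for noisy external recordings.
#' @return A tibble with columns `point`, `trace`, `phase` (seconds since
#'   mitral opening), `time` (on the input time axis) and `pressure` (mmHg).
#' @examples
#' fx <- fixture_waveforms()
#' detect_fiducials(fx$traces)
#' @export
detect_fiducials <- function(traces, smooth = 0) {
  .analyse_cycle(traces, smooth = smooth)$points
}

#' Hemodynamic indices of atrial and ventricular function
#'
#' Computes, from one steady cycle, the eight indices used to quantify
#' preload-reduction responses: maximum a- and v-wave pressures (points C
#' and F), minimum and end-diastolic ventricular pressures (points A and E),
#' the slopes of the a and v waves (lines BC and DF), and the maximum
#' transmitral pressure gradients during early (mitral opening to a-wave
#' onset) and late (a-wave onset to mitral closing) ventricular filling.
#'
#' @inheritParams detect_fiducials
#' @param points Optional pre-computed result of [detect_fiducials()] on the
#'   same trace; detection is re-run when omitted. Supplying `points` does
#'   not change the result, only skips repeated detection.
#' @return A one-row tibble with columns `max_a_wave_pressure`,
#'   `max_v_wave_pressure`, `min_ventricular_pressure`,
#'   `end_diastolic_ventricular_pressure` (mmHg), `slope_a_wave`,
#'   `slope_v_wave` (mmHg/s), `max_early_gradient`, `max_late_gradient`
#'   (mmHg).
#' @examples
#' fx <- fixture_waveforms()
#' compute_indices(fx$traces)
#' @export
compute_indices <- function(traces, points = NULL, smooth = 0) {
  an <- .analyse_cycle(traces, smooth = smooth)
  pts <- an$points
  if (!is.null(points)) {
    if (!all(c("point", "phase", "pressure") %in% names(points))) {
      stop("`points` must come from detect_fiducials()", call. = FALSE)
    }
    pts <- points
  }
  g <- function(k, col) pts[[col]][match(k, pts$point)]
  if (g("C", "phase") <= g("B", "phase")) {
    stop("degenerate a wave: non-increasing time from B to C", call. = FALSE)
  }
  grad <- an$la - an$lv
  early_win <- an$phase < g("B", "phase")
  late_win <- an$phase >= g("B", "phase") & an$phase <= an$phE
  if (!any(early_win) || !any(late_win)) {
    stop("empty filling window; cannot compute transmitral gradients",
         call. = FALSE)
  }
  tibble::tibble(
    max_a_wave_pressure = g("C", "pressure"),
    max_v_wave_pressure = g("F", "pressure"),
    min_ventricular_pressure = g("A", "pressure"),
    end_diastolic_ventricular_pressure = g("E", "pressure"),
    slope_a_wave = (g("C", "pressure") - g("B", "pressure")) /
      (g("C", "phase") - g("B", "phase")),
    slope_v_wave = (g("F", "pressure") - g("D", "pressure")) /
      (an$period - g("D", "phase")),
    max_early_gradient = max(grad[early_win]),
    max_late_gradient = max(grad[late_win])
  )
}

#' Extract and decompose a pressure-volume loop
#'
#' Treats one steady cycle of (volume, pressure) samples as a closed
#' polygonal trajectory, locates its self-intersection if present, and
#' splits the trajectory into two lobes. For the left atrium the loop is a
#' figure eight: the active "a" lobe at lower volumes and the passive "v"
#' lobe at higher volumes. Lobe areas are signed shoelace areas of each
#' sub-polygon (mmHg.ml); `area_abs` is their magnitude.
#'
#' @param traces Data frame (or `cvs_simulation`) holding one cycle.
#' @param pressure,volume Column names of the loop coordinates (defaults
#'   `P_la`, `V_la`).
#' @return A list of class `pv_loop`: `loop` (tibble `volume`, `pressure`),
#'   `two_lobes` (flag), `crossing` (tibble with the self-intersection
#'   coordinates, empty if none) and `lobes` (tibble `lobe`, `area`,
#'   `area_abs`, `mean_volume`; a single row labelled `"loop"` when no
#'   self-intersection exists).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 400)[-400]
#' ellipse <- data.frame(time = th, P_la = 10 + 5 * sin(th),
#'                       P_lv = 0, V_la = 20 + 10 * cos(th))
#' extract_pv_loop(ellipse)$lobes
#' @export
extract_pv_loop <- function(traces, pressure = "P_la", volume = "V_la") {
  tr <- if (inherits(traces, "cvs_simulation")) traces$traces else
    as.data.frame(traces)
  if (!all(c(pressure, volume) %in% names(tr))) {
    stop("columns not found: ", pressure, ", ", volume, call. = FALSE)
  }
  P <- tr[[pressure]]
  V <- tr[[volume]]
  n <- length(P)
  if (n > 2 && abs(P[1] - P[n]) < 1e-9 && abs(V[1] - V[n]) < 1e-9) {
    P <- P[-n]; V <- V[-n]; n <- n - 1
  }
  if (n < 8) stop("loop too short", call. = FALSE)
  # normalised coordinates so the intersection test is scale-free
  x <- (V - min(V)) / max(diff(range(V)), 1e-12)
  y <- (P - min(P)) / max(diff(range(P)), 1e-12)
  nxt <- c(2:n, 1)
  crossings <- list()
  for (i in seq_len(n - 2)) {
    j <- seq.int(i + 2L, n)
    j <- j[!(i == 1L & j == n)]
    if (!length(j)) next
    x1 <- x[i]; y1 <- y[i]; x2 <- x[nxt[i]]; y2 <- y[nxt[i]]
    x3 <- x[j]; y3 <- y[j]; x4 <- x[nxt[j]]; y4 <- y[nxt[j]]
    den <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
    su <- ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / den
    sv <- ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / den
    hit <- which(is.finite(su) & is.finite(sv) &
                   su > 0 & su < 1 & sv > 0 & sv < 1)
    for (h in hit) {
      crossings[[length(crossings) + 1]] <-
        list(i = i, j = j[h], s = su[h])
    }
  }
  shoelace <- function(xx, yy) {
    m <- length(xx)
    sum(xx * yy[c(2:m, 1)] - xx[c(2:m, 1)] * yy) / 2
  }
  loop <- tibble::tibble(volume = V, pressure = P)
  if (!length(crossings)) {
    return(structure(list(
      loop = loop, two_lobes = FALSE,
      crossing = tibble::tibble(volume = numeric(0), pressure = numeric(0)),
      lobes = tibble::tibble(lobe = "loop", area = shoelace(V, P),
                             area_abs = abs(shoelace(V, P)),
                             mean_volume = mean(V))
    ), class = "pv_loop"))
  }
  # with several near-tangent hits keep the crossing splitting the loop into
  # the two most balanced lobes
  pick <- which.max(vapply(crossings, function(cr) {
    k <- (cr$j - cr$i) %% n
    min(k, n - k)
  }, numeric(1)))
  cr <- crossings[[pick]]
  Vx <- V[cr$i] + cr$s * (V[nxt[cr$i]] - V[cr$i])
  Px <- P[cr$i] + cr$s * (P[nxt[cr$i]] - P[cr$i])
  idx1 <- (cr$i + 1):cr$j
  idx2 <- c(if (cr$j < n) (cr$j + 1):n, 1:cr$i)
  lobe_row <- function(idx) {
    vv <- c(Vx, V[idx]); pp <- c(Px, P[idx])
    a <- shoelace(vv, pp)
    tibble::tibble(area = a, area_abs = abs(a), mean_volume = mean(vv))
  }
  lobes <- rbind(lobe_row(idx1), lobe_row(idx2))
  lobes$lobe <- ""
  ord <- order(lobes$mean_volume)
  lobes$lobe[ord] <- c("a", "v")
  lobes <- tibble::as_tibble(
    lobes[order(lobes$lobe), c("lobe", "area", "area_abs", "mean_volume")]
  )
  structure(list(
    loop = loop, two_lobes = TRUE,
    crossing = tibble::tibble(volume = Vx, pressure = Px),
    lobes = lobes
  ), class = "pv_loop")
}

#' @export
print.pv_loop <- function(x, ...) {
  cat("<pv_loop> ", if (x$two_lobes) "figure-eight (two lobes)" else
    "single lobe", "\n", sep = "")
  print(x$lobes)
  invisible(x)
}

#' Transmitral flow wave features (E and A waves)
#'
#' Identifies the early-filling (E) and atrial-contraction (A) peaks of the
#' transmitral flow over one cycle and reports whether the two waves are
#' fused, i.e. not separated by a near-zero diastasis phase. With a short
#' cardiac period the E and A waves merge; a single detected peak is
#' reported as fused by convention.
#'
#' @param traces Data frame (or `cvs_simulation`) with columns `time`,
#'   `Q_mt` over one cycle.
#' @param min_peak Fraction of the maximum flow below which local maxima are
#'   ignored (default 0.05).
#' @param diastasis Flow threshold, as a fraction of the E-peak flow, under
#'   which the inter-wave minimum counts as diastasis (default 0.05).
#' @return One-row tibble: `e_flow`, `e_time`, `a_flow`, `a_time` (`NA` when
#'   the A wave is absent), `inter_min` (minimum flow between the peaks) and
#'   `fused` (logical).
#' @export
mitral_wave_features <- function(traces, min_peak = 0.05, diastasis = 0.05) {
  tr <- if (inherits(traces, "cvs_simulation")) traces$traces else
    as.data.frame(traces)
  if (!all(c("time", "Q_mt") %in% names(tr))) {
    stop("trace columns missing: time, Q_mt", call. = FALSE)
  }
  q <- tr$Q_mt
  n <- length(q)
  if (abs(q[1] - q[n]) < 1e-9) {
    q <- q[-n]
    tr <- tr[-n, , drop = FALSE]
    n <- n - 1
  }
  if (max(q) <= 0) stop("transmitral flow is zero everywhere", call. = FALSE)
  pk <- .locmax_periodic(q)
  pk <- pk[q[pk] >= min_peak * max(q)]
  if (!length(pk)) stop("no transmitral flow peak found", call. = FALSE)
  # order peaks by phase within the filling window: start of flow = first
  # sample with q > 0 following a zero-flow sample (cyclic)
  prev <- c(n, seq_len(n - 1))
  onset <- which(q > 0 & q[prev] == 0)
  anchor <- if (length(onset)) onset[1] else which.max(q)
  phase <- ((pk - anchor) %% n)
  pk <- pk[order(phase)]
  e <- pk[1]
  if (length(pk) == 1) {
    return(tibble::tibble(e_flow = q[e], e_time = tr$time[e],
                          a_flow = NA_real_, a_time = NA_real_,
                          inter_min = NA_real_, fused = TRUE))
  }
  a <- pk[length(pk)]
  seg <- if (a > e) e:a else c(e:n, 1:a)
  inter <- min(q[seg])
  tibble::tibble(e_flow = q[e], e_time = tr$time[e],
                 a_flow = q[a], a_time = tr$time[a],
                 inter_min = inter, fused = inter > diastasis * q[e])
}

#' Side-by-side index comparison for a preload-reduction run
#'
#' @param x A `cvs_ivco` object from [run_ivco()].
#' @return A tibble with one row per index: `measurement`, `units`,
#'   `baseline`, `ivco`, `decreased`.
#' @export
ivco_comparison <- function(x) {
  stopifnot(inherits(x, "cvs_ivco"))
  b <- compute_indices(x$baseline)
  i <- compute_indices(x$ivco)
  units <- c(rep("mmHg", 4), rep("mmHg/s", 2), rep("mmHg", 2))
  tibble::tibble(
    measurement = names(b),
    units = units,
    baseline = as.numeric(b[1, ]),
    ivco = as.numeric(i[1, ]),
    decreased = as.numeric(i[1, ]) < as.numeric(b[1, ])
  )
}
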