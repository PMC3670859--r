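test_that("detection recovers every fixture fiducial within one sample", {
  for (ph in c(0, 0.12, 0.31)) {
    fx <- fixture_waveforms(phase0 = ph)
    pts <- detect_fiducials(fx$traces)
    truth <- fx$truth$points
    m <- match(truth$point, pts$point)
    expect_true(all(abs(pts$phase[m] - truth$phase) <= 5e-4 + 1e-9))
    expect_true(all(abs(pts$pressure[m] - truth$pressure) <= 0.05))
  }
})

test_that("crossover points sit exactly on both traces", {
  fx <- fixture_waveforms()
  pts <- detect_fiducials(fx$traces)
  # at E and F, the interpolated LA and LV pressures coincide
  la_at <- stats::approxfun(fx$traces$time, fx$traces$P_la)
  lv_at <- stats::approxfun(fx$traces$time, fx$traces$P_lv)
  for (pt in c("E", "F")) {
    t0 <- pts$time[pts$point == pt]
    expect_equal(la_at(t0), lv_at(t0), tolerance = 1e-6)
  }
})

test_that("crossovers of a sine/constant pair are located analytically", {
  dt <- 5e-4
  t <- seq(0, 0.45 - dt / 2, by = dt)
  d <- (10 + 8 * sin(2 * pi * t / 0.45)) - 10  # P_lv - P_la
  cr <- atrisim:::.crossings(d)
  t_down <- (cr$down - 1 + cr$frac_down) * dt
  t_up <- (cr$up - 1 + cr$frac_up) * dt
  expect_equal(t_down, 0.225, tolerance = dt)
  expect_equal(min(t_up %% 0.45, 0.45 - t_up %% 0.45), 0, tolerance = dt)
})

test_that("indices match the analytic fixture construction exactly", {
  fx <- fixture_waveforms()
  idx <- compute_indices(fx$traces)
  expect_equal(as.numeric(idx), as.numeric(fx$truth$indices),
               tolerance = 1e-6)
  expect_equal(idx$slope_a_wave, 50)
  # supplying pre-detected points skips re-detection, never changes values
  expect_equal(compute_indices(fx$traces,
                               points = detect_fiducials(fx$traces)), idx)
})

test_that("pressure indices are translation- and scale-covariant", {
  fx <- fixture_waveforms()
  idx <- compute_indices(fx$traces)

  shifted <- fx$traces
  shifted$P_la <- shifted$P_la + 5
  shifted$P_lv <- shifted$P_lv + 5
  idx_s <- compute_indices(shifted)
  expect_equal(idx_s$slope_a_wave, idx$slope_a_wave)
  expect_equal(idx_s$slope_v_wave, idx$slope_v_wave)
  expect_equal(idx_s$max_early_gradient, idx$max_early_gradient)
  expect_equal(idx_s$max_late_gradient, idx$max_late_gradient)
  expect_equal(idx_s$max_a_wave_pressure, idx$max_a_wave_pressure + 5)

  scaled <- fx$traces
  scaled$P_la <- scaled$P_la * 3
  scaled$P_lv <- scaled$P_lv * 3
  idx_k <- compute_indices(scaled)
  expect_equal(as.numeric(idx_k), 3 * as.numeric(idx), tolerance = 1e-9)
})

test_that("missing waves raise named detection errors", {
  fx <- fixture_waveforms(a_amp = 0)
  expect_error(detect_fiducials(fx$traces), "point C")
  flat <- data.frame(time = seq(0, 0.449, by = 1e-3),
                     P_la = 10, P_lv = 12)
  expect_error(detect_fiducials(flat), "point F")
})

test_that("event order on the fixture follows the cardiac cycle", {
  fx <- fixture_waveforms()
  pts <- detect_fiducials(fx$traces)
  phase <- stats::setNames(pts$phase, pts$point)
  expect_true(phase[["F"]] < phase[["A"]])
  expect_true(phase[["A"]] < phase[["B"]])
  expect_true(phase[["B"]] < phase[["C"]])
  expect_true(phase[["C"]] < phase[["E"]])
  expect_true(phase[["E"]] <= phase[["D"]])
})

test_that("an ellipse trajectory yields one lobe with area pi*a*b", {
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  el <- data.frame(P_la = 10 + 5 * sin(th), V_la = 20 + 10 * cos(th))
  pv <- extract_pv_loop(el)
  expect_false(pv$two_lobes)
  expect_equal(nrow(pv$crossing), 0)
  expect_equal(pv$lobes$area_abs, pi * 5 * 10, tolerance = 1e-3)
})

test_that("a figure-eight splits into two lobes matching the shoelace oracle", {
  th <- seq(0, 2 * pi, length.out = 1601)[-1601]
  f8 <- data.frame(P_la = 10 + 5 * sin(th), V_la = 20 + 8 * sin(2 * th))
  pv <- extract_pv_loop(f8)
  expect_true(pv$two_lobes)
  expect_equal(pv$crossing$volume, 20, tolerance = 1e-3)
  expect_equal(pv$crossing$pressure, 10, tolerance = 1e-3)
  # independent oracle: shoelace area of each analytic half
  t1 <- seq(0, pi, length.out = 4001)[-4001]
  t2 <- seq(pi, 2 * pi, length.out = 4001)[-4001]
  oracle <- sort(c(abs(shoelace(20 + 8 * sin(2 * t1), 10 + 5 * sin(t1))),
                   abs(shoelace(20 + 8 * sin(2 * t2), 10 + 5 * sin(t2)))))
  expect_equal(sort(pv$lobes$area_abs), oracle, tolerance = 1e-3)
})

test_that("lobe labels follow volume: the a lobe sits at lower volumes", {
  th <- seq(0, 2 * pi, length.out = 1601)[-1601]
  # asymmetric eight: one lobe pushed to higher volumes
  V <- 20 + 8 * sin(2 * th) + 4 * pmax(sin(th), 0)
  f8 <- data.frame(P_la = 10 + 5 * sin(th), V_la = V)
  pv <- extract_pv_loop(f8)
  expect_true(pv$two_lobes)
  a <- pv$lobes[pv$lobes$lobe == "a", ]
  v <- pv$lobes[pv$lobes$lobe == "v", ]
  expect_lt(a$mean_volume, v$mean_volume)
})

test_that("mitral wave features distinguish fused and separated patterns", {
  fused <- fixture_waveforms()
  mf <- mitral_wave_features(fused$traces)
  expect_true(mf$fused)
  expect_equal(mf$e_flow, 70)
  expect_equal(mf$a_flow, 100)
  expect_equal(mf$e_time, fused$truth$mitral$e_time, tolerance = 5e-4)

  sep <- fixture_waveforms(diastasis_flow = 0)
  mf2 <- mitral_wave_features(sep$traces)
  expect_false(mf2$fused)
  expect_equal(mf2$inter_min, 0)

  # single bump: A wave absent, fused by convention
  t <- seq(0, 0.449, by = 1e-3)
  one <- data.frame(time = t, Q_mt = pmax(0, sin(pi * (t - 0.05) / 0.2)) * 80)
  mf3 <- mitral_wave_features(one)
  expect_true(mf3$fused)
  expect_true(is.na(mf3$a_flow))

  expect_error(mitral_wave_features(data.frame(time = t, Q_mt = 0)),
               "zero")
})

test_that("prominent-maxima counting ignores sub-threshold ripples", {
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  # two bumps of different height, like the atrial a and v waves
  x <- exp(-10 * (th - 2)^2) + 0.6 * exp(-10 * (th - 4.5)^2)
  expect_length(prominent_maxima(x), 2)
  ripple <- x + 0.004 * sin(40 * th)
  expect_length(prominent_maxima(ripple), 2)
  expect_gt(length(atrisim:::.locmax_periodic(ripple)), 2)
})
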