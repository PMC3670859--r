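p <- cvs_params()

test_that("volume derivatives always sum to zero (closed loop)", {
  set.seed(21)
  y <- cvs_initial_state(p)
  for (i in 1:25) {
    y2 <- y
    y2[11:17] <- y[11:17] * stats::runif(7, 0.5, 1.5)
    y2[c(1:3, 6:8)] <- stats::runif(6, 0, 5)
    y2[c(4, 9)] <- p$Tt - y2[c(1, 6)] - y2[c(2, 7)] - y2[c(3, 8)]
    d <- cvs_rhs(stats::runif(1, 0, p$period), y2, p)$derivatives
    expect_equal(sum(d[11:17]), 0, tolerance = 1e-10)
  }
})

test_that("a single RHS evaluation matches the hand-composed sub-models", {
  # independently recompose the derivative from the module-level functions
  y <- cvs_initial_state(p)
  y[c("la_TCa", "la_TCa_star", "la_T_star")] <- c(4, 1.5, 0.8)
  y["la_T_free"] <- p$Tt - 4 - 1.5 - 0.8
  y[c("lv_TCa", "lv_TCa_star", "lv_T_star")] <- c(6, 2.5, 1.2)
  y["lv_T_free"] <- p$Tt - 6 - 2.5 - 1.2
  y["la_h"] <- 0.0045
  y["lv_h"] <- 0.0058
  t0 <- 0.12
  got <- cvs_rhs(t0, y, p)

  tr <- calcium_transients(p)
  sp <- list(la = sarcomere_params(p, "la"), lv = sarcomere_params(p, "lv"))
  R <- list(la = radius_from_volume(y[["V_la"]]),
            lv = radius_from_volume(y[["V_lv"]]))
  L <- list(la = sarcomere_length_from_radius(R$la, p$R0_la, p$L0),
            lv = sarcomere_length_from_radius(R$lv, p$R0_lv, p$L0))
  st <- list(la = y[1:5], lv = y[6:10])
  names(st$la) <- names(st$lv) <- c("TCa", "TCa_star", "T_star", "T_free", "h")
  P <- c(
    la = pressure_from_force(total_force(st$la, L$la, sp$la), R$la, p$t_la),
    lv = pressure_from_force(total_force(st$lv, L$lv, sp$lv), R$lv, p$t_lv),
    rv = rv_pressure(y[["V_rv"]], t0, p),
    ao = elastic_pressure(y[["V_ao"]], p$E_ao),
    vc = elastic_pressure(y[["V_vc"]], p$E_vc),
    pa = elastic_pressure(y[["V_pa"]], p$E_pa),
    pu = elastic_pressure(y[["V_pu"]], p$E_pu)
  )
  Q <- c(
    mt = valve_flow(P[["la"]], P[["lv"]], p$R_mt),
    av = valve_flow(P[["lv"]], P[["ao"]], p$R_av),
    sys = resistive_flow(P[["ao"]], P[["vc"]], p$R_sys),
    tc = valve_flow(P[["vc"]], P[["rv"]], p$R_tc),
    pv = valve_flow(P[["rv"]], P[["pa"]], p$R_pv),
    pul = resistive_flow(P[["pa"]], P[["pu"]], p$R_pul),
    prox = resistive_flow(P[["pu"]], P[["la"]], p$R_prox)
  )
  dV <- c(
    V_la = volume_rhs(Q[["prox"]], Q[["mt"]]),
    V_lv = volume_rhs(Q[["mt"]], Q[["av"]]),
    V_rv = volume_rhs(Q[["tc"]], Q[["pv"]]),
    V_ao = volume_rhs(Q[["av"]], Q[["sys"]]),
    V_vc = volume_rhs(Q[["sys"]], Q[["tc"]]),
    V_pa = volume_rhs(Q[["pv"]], Q[["pul"]]),
    V_pu = volume_rhs(Q[["pul"]], Q[["prox"]])
  )
  dL <- list(
    la = p$L0 / p$R0_la * dV[["V_la"]] / (2 * pi * R$la^2),
    lv = p$L0 / p$R0_lv * dV[["V_lv"]] / (2 * pi * R$lv^2)
  )
  dsar <- c(
    kinetics_rhs(st$la, eval_calcium(t0, tr$la), L$la, dL$la, sp$la),
    kinetics_rhs(st$lv, eval_calcium(t0, tr$lv), L$lv, dL$lv, sp$lv)
  )
  expect_equal(unname(got$derivatives), unname(c(dsar, dV)),
               tolerance = 1e-12)
  expect_equal(got$observables[paste0("P_", names(P))],
               stats::setNames(P, paste0("P_", names(P))), tolerance = 1e-12)
  expect_equal(got$observables[paste0("Q_", names(Q))],
               stats::setNames(Q, paste0("Q_", names(Q))), tolerance = 1e-12)
})

test_that("a pressure-equilibrated state with closed valves is stationary", {
  # choose volumes so every chamber sits at the same pressure; all gradients
  # vanish, so every flow and every volume derivative must be zero
  target <- 8
  t0 <- 0.21  # driver value is well above zero here
  y <- cvs_initial_state(p)
  y["V_ao"] <- target / p$E_ao
  y["V_vc"] <- target / p$E_vc
  y["V_pa"] <- target / p$E_pa
  y["V_pu"] <- target / p$E_pu
  y["V_rv"] <- target / (p$E_rv * rv_driver(t0, p))
  passive_volume <- function(R0, t_wall, K) {
    f <- function(V) {
      R <- radius_from_volume(V)
      L <- p$L0 * R / R0
      2 * K * (L - p$L0) * t_wall / R / KPA_PER_MMHG - target
    }
    stats::uniroot(f, c(volume_from_radius(R0) + 1e-9, 500),
                   tol = 1e-12)$root
  }
  y["V_la"] <- passive_volume(p$R0_la, p$t_la, p$K_la)
  y["V_lv"] <- passive_volume(p$R0_lv, p$t_lv, p$K_lv)
  out <- cvs_rhs(t0, y, p)
  expect_lt(max(abs(out$derivatives[11:17])), 1e-6)
  expect_lt(max(abs(out$observables[paste0(
    "Q_", c("mt", "av", "sys", "tc", "pv", "pul", "prox"))])), 1e-6)
})

test_that("short simulations conserve blood volume and troponin", {
  sim <- simulate_cvs(p, n_cycles = 3, dt_out = 1e-3)
  tot <- total_volume(sim$traces)
  expect_true(all(abs(tot - 273) < 0.1))
  for (ch in c("la", "lv")) {
    s <- rowSums(sim$traces[, paste0(ch, c("_TCa", "_TCa_star", "_T_star",
                                           "_T_free"))])
    expect_lt(max(abs(s - p$Tt)), 1e-9 * p$Tt)
  }
  # diode contract at every output sample
  for (q in c("Q_mt", "Q_av", "Q_tc", "Q_pv")) {
    expect_true(all(sim$traces[[q]] >= 0))
  }
})

test_that("negative chamber volume aborts with a diagnostic", {
  y <- cvs_initial_state(p)
  y["V_vc"] <- -1
  expect_error(cvs_rhs(0.1, y, p), "volume")
})

test_that("steady-state cycling converges and is periodic", {
  sim <- baseline_sim()
  expect_true(sim$converged)
  expect_lte(sim$cycles_run, 50)
  first <- as.numeric(sim$traces[1, c("P_la", "P_lv", "V_la", "V_lv")])
  last <- as.numeric(sim$traces[nrow(sim$traces),
                                c("P_la", "P_lv", "V_la", "V_lv")])
  expect_equal(first, last, tolerance = 5e-3)
  g <- glance(sim)
  expect_lt(g$volume_drift, 1e-6)
})

test_that("steady cycle is stable under solver tolerance refinement", {
  sim <- baseline_sim()
  fine <- run_to_steady_state(p, init = sim$final_state,
                              rtol = sim$settings$rtol / 2,
                              atol = sim$settings$atol / 2)
  for (col in c("P_la", "P_pa")) {
    expect_equal(max(fine$traces[[col]]), max(sim$traces[[col]]),
                 tolerance = 1e-3)
    expect_equal(min(fine$traces[[col]]), min(sim$traces[[col]]),
                 tolerance = 1e-3)
  }
})

test_that("preload reduction multiplies only the pulmonary resistance", {
  iv <- ivco_run()
  expect_s3_class(iv, "cvs_ivco")
  expect_equal(iv$multiplier * p$R_pul, 9.816)
  # occlusion redistributes, never removes, blood volume
  expect_true(all(abs(total_volume(iv$ivco$traces) - 273) < 0.1))
  for (q in c("Q_mt", "Q_av", "Q_tc", "Q_pv")) {
    expect_true(all(iv$ivco$traces[[q]] >= 0))
  }
  expect_error(run_ivco(p, baseline = simulate_cvs(p, n_cycles = 1)),
               "not converged")
})
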