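# Integration, periodicity detection, cycle extraction, conservation.

test_that("RC discharge fixture matches the closed form", {
  fx <- make_fixture("rc_discharge", R = 1, C = 1, P0 = 1)
  times <- seq(0, 5, by = 1e-3)
  out <- fx$simulate(times)
  expect_equal(tail(out$P, 1), exp(-5), tolerance = 1e-3)
  expect_lt(max(abs(out$P - fx$analytic(times))), 1e-6)
})

test_that("two-element Windkessel matches the analytic impedance solution", {
  R <- 0.15; C <- 6; omega <- 2 * pi / 0.684
  fx <- make_fixture("windkessel2", R = R, C = C, Q0 = 1, omega = omega)
  times <- seq(0, 40 * 0.684, by = 1e-3)
  out <- fx$simulate(times)
  # after transients (> 5 R*C), amplitude and phase from the last cycles
  tail_i <- times > max(times) - 2 * 0.684
  sim <- out$P[tail_i]
  ana <- fx$analytic(times[tail_i])
  amp_sim <- (max(sim) - min(sim)) / 2
  expect_equal(amp_sim, fx$amplitude, tolerance = 0.005)
  expect_lt(max(abs(sim - ana)) / fx$amplitude, 0.005)
})

test_that("full model reaches the periodic stability criterion", {
  w <- baseline_waveform()
  cc <- cycle_convergence(w)
  expect_true(cc$converged)
  expect_lt(tail(cc$delta, 1), 0.01)
  # consecutive-cycle change of mean aortic flow < 1%
  expect_lt(tail(cc$delta_flow, 1), 0.01)
})

test_that("cycle convergence sees constructed decay and exact periodicity", {
  w <- baseline_waveform()
  # synthetic: perfectly periodic channel -> all changes zero
  T <- w$period
  n_cyc <- 8
  tgrid <- seq(0, n_cyc * T, by = w$dt)
  mk <- function(vals) {
    ws <- w
    ws$time <- tgrid
    ws$channels <- data.frame(Q_av = vals, P_art = vals)
    ws
  }
  periodic <- mk(sin(2 * pi * tgrid / T) + 2)
  cc <- cycle_convergence(periodic)
  expect_true(all(cc$delta < 1e-10))
  # 5% geometric decay per cycle -> first relative change ~ 0.05
  decaying <- mk((0.95 ^ (tgrid / T)) * (sin(2 * pi * tgrid / T) + 2))
  cc2 <- cycle_convergence(decaying)
  expect_equal(cc2$delta_flow[1], 0.05, tolerance = 0.01)
  short <- mk(sin(2 * pi * tgrid / T) + 2)
  keep <- tgrid < 1.5 * T
  short$time <- tgrid[keep]
  short$channels <- short$channels[keep, ]
  expect_error(cycle_convergence(short), "two complete periods")
})

test_that("final-cycle extraction is period-aligned", {
  w <- baseline_waveform()
  w2 <- extract_final_cycles(w, 2)
  expect_equal(max(w2$time) - min(w2$time), 2 * 0.684, tolerance = 1e-9)
  # one tooth of a synthetic sawtooth
  fx <- make_fixture("sawtooth", period = 0.5)
  tg <- seq(0, 3, by = 1e-3)
  ws <- w
  ws$period <- 0.5
  ws$time <- tg
  ws$channels <- data.frame(P = fx$analytic(tg))
  w1 <- extract_final_cycles(ws, 1)
  expect_equal(max(w1$time) - min(w1$time), 0.5, tolerance = 1e-9)
  expect_equal(min(w1$channels$P), 0, tolerance = 2e-3)
  expect_equal(max(w1$channels$P), 1, tolerance = 2e-3)
  expect_error(extract_final_cycles(w, 99), "complete")
})

test_that("total blood volume is conserved through the simulation", {
  w <- baseline_waveform()
  tv <- total_volume(w)
  expect_lt((max(tv) - min(tv)) / tv[1], 1e-3)
  # and over the final two cycles specifically
  w2 <- extract_final_cycles(w, 2)
  tv2 <- total_volume(w2)
  expect_lt((max(tv2) - min(tv2)) / tv2[1], 1e-3)
})

test_that("steady cycle is independent of volume-preserving initial conditions", {
  m <- default_model()
  base <- cycle_metrics(baseline_waveform())
  init <- default_initial_state(m)
  # redistribute: move 10 mL from the ventricles into the venous nodes,
  # keeping the total volume identical
  alt <- init
  alt["V_lv"] <- init[["V_lv"]] - 5000
  alt["V_rv"] <- init[["V_rv"]] - 5000
  extra <- 10000 / (m$central_venous$C + m$other_organs$C)
  alt["P_cv"] <- init[["P_cv"]] + extra
  alt["P_oth"] <- init[["P_oth"]] + extra
  w_alt <- run_simulation(m, init = alt)
  alt_m <- cycle_metrics(w_alt)
  expect_equal(alt_m$CO, base$CO, tolerance = 0.01)
  expect_equal(alt_m$SBP, base$SBP, tolerance = 0.01)
  expect_equal(alt_m$SV, base$SV, tolerance = 0.01)
})

test_that("halving the time step leaves the final-cycle CO unchanged", {
  m <- default_model()
  co <- function(dt, n) {
    w <- run_simulation(m, simulation_settings(dt = dt, n_steps = n))
    compute_cardiac_metrics(w)$CO
  }
  co1 <- baseline_metrics()$CO
  co2 <- co(5e-4, 16000)
  expect_lt(abs(co2 - co1) / co1, 0.002)
})

test_that("simulation errors are informative", {
  m <- default_model()
  expect_error(run_simulation(m, simulation_settings(n_steps = 100)),
               "4 cardiac periods")
  expect_error(run_simulation(m, init = rep(1, 3)), "state layout")
})
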