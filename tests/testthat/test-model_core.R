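# Circuit elements: elastance waveform, chamber pressure, valve law,
# and the assembled right-hand side.

test_that("elastance waveform hits its landmark values", {
  p <- elastance_params(E_max = 0.394, E_min = 9e-5, T = 0.684,
                        t_max = 0.377, t_toRelax = 0.104, V0 = 10000)
  expect_equal(elastance_at(p$t_max, p), p$E_max)
  expect_equal(elastance_at(1e-12, p), p$E_min, tolerance = 1e-6)
  expect_equal(elastance_at(p$t_max / 2, p), (p$E_max + p$E_min) / 2)
  # peak value at t = 0.377 s with the left-ventricle parameters
  expect_equal(elastance_at(0.377, p), 0.394)
  expect_error(elastance_at(p$T, p), "modulo")
  expect_error(elastance_at(-0.01, p), "modulo")
})

test_that("elastance is continuous at both phase boundaries", {
  p <- elastance_params(E_max = 0.394, E_min = 9e-5, T = 0.684,
                        t_max = 0.377, t_toRelax = 0.104, V0 = 10000)
  eps <- 1e-10
  expect_lt(abs(elastance_at(p$t_max - eps, p) - elastance_at(p$t_max + eps, p)),
            1e-12)
  tb <- p$t_max + p$t_toRelax
  expect_lt(abs(elastance_at(tb - eps, p) - p$E_min), 1e-12)
  expect_lt(abs(elastance_at(tb + eps, p) - p$E_min), 1e-12)
})

test_that("elastance parameter invariants are enforced", {
  expect_error(elastance_params(0.1, 0.2, 0.684, 0.377, 0.104, 1e4),
               "E_max > E_min")
  expect_error(elastance_params(0.394, 9e-5, 0.4, 0.377, 0.104, 1e4),
               "t_max")
  expect_error(elastance_params(0.394, 9e-5, 0.684, 0.377, 0.104, -1),
               "V0")
})

test_that("chamber pressure follows the linear elastance relation", {
  expect_equal(chamber_pressure(12345, 0.2, 12345), 0)
  expect_equal(chamber_pressure(60000, 0.394, 10000), 19700)
  expect_equal(chamber_pressure(110000, 9e-5, 10000), 9)
  # negative pressure below the unstressed volume is allowed
  expect_lt(chamber_pressure(5000, 0.1, 10000), 0)
  expect_error(chamber_pressure(-1, 0.1, 10000), ">= 0")
})

test_that("valve openness is a smooth diode with the tanh law", {
  v <- valve_params(R = 1e-5, L = 1e-5)
  expect_equal(valve_openness(0, v), 0.5)
  expect_lt(abs(valve_openness(10 * v$steepness, v) - 1), 1e-8)
  expect_lt(abs(valve_openness(-10 * v$steepness, v)), 1e-8)
  dP <- seq(-100, 100, length.out = 201)
  o <- valve_openness(dP, v)
  expect_true(all(diff(o) >= 0))       # monotone (saturates in the tails)
  core <- abs(dP[-1]) < 5 * v$steepness
  expect_true(all(diff(o)[core] > 0))  # strictly monotone in the transition
  expect_true(all(o >= 0 & o <= 1))
})

test_that("RHS conserves volume exactly at arbitrary states", {
  m <- default_model()
  Ctot <- c(V_lv = 1, V_rv = 1, Q_mv = 0, Q_av = 0, Q_tv = 0, Q_puv = 0,
            P_ha = m$hepatic$C_ha, P_dig = m$digestive$C,
            P_pv = m$hepatic$C_pv, P_hs = m$hepatic$C_hs,
            P_oth = m$other_organs$C, P_lung = m$lung$C,
            P_cv = m$central_venous$C, P_la = m$C_la, P_ra = m$C_ra)
  for (seed in 1:20) {
    s <- random_state(m, seed)
    r <- assemble_rhs(runif(1, 0, m$left_ventricle$T), s, m)
    rate <- sum(Ctot * r$dstate[names(Ctot)])
    scale <- sum(abs(Ctot * r$dstate[names(Ctot)]))
    expect_lt(abs(rate) / max(scale, 1), 1e-10)
  }
})

test_that("RHS flags non-finite states as integration faults", {
  m <- default_model()
  s <- default_initial_state(m)
  s["P_cv"] <- NaN
  expect_error(assemble_rhs(0, s, m), "integration fault")
})

test_that("R and compiled right-hand sides produce the same trajectory", {
  m <- default_model()
  s <- simulation_settings(n_steps = 3000)
  wR <- run_simulation(m, s, engine = "R")
  wC <- run_simulation(m, s, engine = "compiled")
  for (ch in c("V_lv", "P_art", "Q_av", "P_hs", "P_cv")) {
    scale <- max(abs(wC$channels[[ch]]))
    expect_lt(max(abs(wR$channels[[ch]] - wC$channels[[ch]])) / scale, 1e-6)
  }
})

test_that("model constructor validates component classes and atria", {
  m <- default_model()
  expect_s3_class(m, "circulation_model")
  expect_length(m$state_layout, 15)
  expect_false(any(duplicated(m$state_layout)))
  expect_error(circulation_model(m$left_ventricle, m$right_ventricle,
                                 m$mitral, m$aortic, m$tricuspid, m$pulmonary,
                                 m$lung, m$digestive, m$other_organs,
                                 m$central_venous, m$hepatic,
                                 C_la = -1, C_ra = 2),
               "atrial")
  expect_error(circulation_model(m$left_ventricle, m$right_ventricle,
                                 m$mitral, m$aortic, m$tricuspid, m$pulmonary,
                                 m$lung, m$digestive, m$hepatic,  # wrong class
                                 m$central_venous, m$hepatic, 10, 2),
               "rcr_params")
})

test_that("valve rectification: backward flow stays below 1% of peak forward", {
  w <- extract_final_cycles(baseline_waveform(), 1)
  for (q in c("Q_mv", "Q_av", "Q_tv", "Q_puv")) {
    fwd <- max(w$channels[[q]])
    bwd <- max(0, -min(w$channels[[q]]))
    expect_lt(bwd, 0.01 * fwd)
  }
})
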