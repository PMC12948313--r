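# Fixed-grid integration of the circulation model, periodic steady-state
# detection, and extraction of the final cycles.

#' Simulation settings
#'
#' @param dt Output time step, s.  Default 0.001 s.
#' @param n_steps Number of steps.  Default 8000 (8 s of simulated time,
#'   about 11.7 cardiac cycles at T = 0.684 s).
#' @param convergence_threshold Relative cycle-to-cycle change in
#'   cycle-averaged aortic flow and pressure below which the solution is
#'   declared periodic.  Default 0.01 (1 percent).
#' @param n_report_cycles Number of final cycles kept for analysis.
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(dt = 0.001, n_steps = 8000,
                                convergence_threshold = 0.01,
                                n_report_cycles = 2) {
  if (!(dt > 0)) stop("simulation_settings: dt must be > 0")
  if (n_steps < 1) stop("simulation_settings: n_steps must be >= 1")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 convergence_threshold = convergence_threshold,
                 n_report_cycles = as.integer(n_report_cycles)),
            class = "simulation_settings")
}

.AUX_NAMES <- c("P_lv", "P_rv", "P_art", "P_vj",
                "Q_ha_d", "Q_pv_d", "Q_hs_out", "Q_dig_out", "Q_oth_out")

#' Run a closed-loop circulation simulation
#'
#' Integrates the model ODEs on a fixed output grid with `deSolve`'s
#' `lsoda` solver (adaptive-order stiff/non-stiff switching; the sharp
#' open/close valve transitions make the system intermittently stiff).
#' Accuracy is controlled by the solver tolerances, so the solution on
#' the fixed grid is well above second-order accurate.
#'
#' @param m A [circulation_model()].
#' @param s A [simulation_settings()].
#' @param init Initial state vector in `m$state_layout` order; default
#'   [default_initial_state()].
#' @param engine `"compiled"` (default, C right-hand side) or `"R"`
#'   (reference implementation [assemble_rhs()]; slow, used for
#'   cross-checking).
#' @param rtol,atol Solver tolerances.
#' @return A `waveform_set`: list with `time` (s), `channels` (data frame
#'   of all state and auxiliary channels, internal units), `period` (s),
#'   `dt`, and the model.
#' @export
run_simulation <- function(m, s = simulation_settings(),
                           init = default_initial_state(m),
                           engine = c("compiled", "R"),
                           rtol = 1e-8, atol = 1e-6) {
  stopifnot(inherits(m, "circulation_model"), inherits(s, "simulation_settings"))
  engine <- match.arg(engine)
  T <- m$left_ventricle$T
  if (s$n_steps * s$dt < 4 * T)
    stop("run_simulation: simulated span must cover >= 4 cardiac periods")
  if (length(init) != length(m$state_layout))
    stop("run_simulation: init does not match the state layout")
  init <- stats::setNames(as.numeric(init), m$state_layout)
  times <- seq(0, s$n_steps * s$dt, by = s$dt)

  if (engine == "compiled") {
    out <- deSolve::ode(y = init, times = times, func = "circ_derivs",
                        parms = .pack_params(m), dllname = "hepacirc",
                        initfunc = "circ_initmod",
                        nout = length(.AUX_NAMES), outnames = .AUX_NAMES,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  } else {
    rhs <- function(t, y, p) {
      r <- assemble_rhs(t, y, m, with_aux = TRUE)
      list(r$dstate, r$aux)
    }
    out <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  }
  out <- as.data.frame(out)
  bad <- !stats::complete.cases(out) | apply(abs(out) > 1e12, 1, any)
  if (any(bad)) {
    i <- which(bad)[1]
    col <- names(out)[-1][which(!is.finite(as.numeric(out[i, -1])) |
                                  abs(as.numeric(out[i, -1])) > 1e12)[1]]
    stop(sprintf("run_simulation: integration failure at t = %.4f s (variable %s)",
                 out$time[i], col))
  }
  structure(list(time = out$time,
                 channels = out[, -1, drop = FALSE],
                 period = T, dt = s$dt, settings = s, model = m),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("waveform_set: %d samples, dt = %g s, span %.3f s (%.1f cycles of T = %.3f s)\n",
              length(x$time), x$dt, max(x$time) - min(x$time),
              (max(x$time) - min(x$time)) / x$period, x$period))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

# Indices of samples belonging to complete cycle k (0-based), i.e.
# t in [k*T, (k+1)*T], aligned to the elastance clock (cycle starts at
# t mod T = 0).
.cycle_window <- function(w, k) {
  which(w$time >= k * w$period - 1e-9 & w$time <= (k + 1) * w$period + 1e-9)
}

# Number of complete cycles in the waveform span.
.n_complete_cycles <- function(w) {
  floor((max(w$time) + 1e-9) / w$period)
}

#' Cycle-to-cycle convergence of the periodic steady state
#'
#' Computes, for each pair of consecutive complete cycles, the relative
#' change of the cycle-averaged aortic flow and aortic pressure, and
#' flags convergence when the last change falls below the threshold.
#'
#' @param w A `waveform_set` spanning at least two full periods.
#' @param threshold Relative-change threshold; defaults to the value in
#'   the settings the waveform was produced with (0.01).
#' @return List with `delta_flow`, `delta_pressure` (relative changes per
#'   cycle pair), `delta` (their elementwise max) and `converged`.
#' @export
cycle_convergence <- function(w, threshold = NULL) {
  stopifnot(inherits(w, "waveform_set"))
  if (is.null(threshold))
    threshold <- if (!is.null(w$settings)) w$settings$convergence_threshold else 0.01
  nc <- .n_complete_cycles(w)
  if (nc < 2) stop("cycle_convergence: need at least two complete periods")
  mq <- mp <- numeric(nc)
  for (k in seq_len(nc)) {
    i <- .cycle_window(w, k - 1)
    mq[k] <- mean(w$channels$Q_av[i])
    mp[k] <- mean(w$channels$P_art[i])
  }
  rel <- function(x) abs(diff(x)) / pmax(abs(x[-length(x)]), .Machine$double.eps)
  dq <- rel(mq); dp <- rel(mp)
  d <- pmax(dq, dp)
  list(delta_flow = dq, delta_pressure = dp, delta = d,
       converged = d[length(d)] < threshold)
}

#' Extract the final complete cycles from a waveform set
#'
#' Restricts the waveform to the last `n` complete periods, aligned to
#' period boundaries (cycle start = onset of the elastance rise).
#'
#' @param w A `waveform_set`.
#' @param n Number of final cycles to keep.
#' @return A `waveform_set` covering exactly `n * T` seconds.
#' @export
extract_final_cycles <- function(w, n = 2) {
  stopifnot(inherits(w, "waveform_set"))
  nc <- .n_complete_cycles(w)
  if (n > nc)
    stop(sprintf("extract_final_cycles: requested %d cycles but only %d complete", n, nc))
  i <- which(w$time >= (nc - n) * w$period - 1e-9 &
             w$time <= nc * w$period + 1e-9)
  w2 <- w
  w2$time <- w$time[i]
  w2$channels <- w$channels[i, , drop = FALSE]
  w2
}

#' Total blood volume held in the circuit
#'
#' Chamber volumes plus the stressed volume `C * P` of every capacitor
#' node; conserved by the closed loop.
#'
#' @param w A `waveform_set`.
#' @return Numeric vector (mm^3) along the time grid.
#' @export
total_volume <- function(w) {
  ch <- w$channels; m <- w$model; h <- m$hepatic
  ch$V_lv + ch$V_rv +
    m$lung$C * ch$P_lung + m$digestive$C * ch$P_dig +
    m$other_organs$C * ch$P_oth + m$central_venous$C * ch$P_cv +
    h$C_pv * ch$P_pv + h$C_ha * ch$P_ha + h$C_hs * ch$P_hs +
    m$C_la * ch$P_la + m$C_ra * ch$P_ra
}

#' Export waveforms as a CSV table in reporting units
#'
#' Writes one row per time step with pressures in mmHg, flows in mL/s and
#' volumes in mL; column names carry the unit suffix.
#'
#' @param w A `waveform_set`.
#' @param path Output file path.
#' @return The exported data frame, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform_set"))
  ch <- w$channels
  df <- data.frame(time = w$time)
  for (nm in names(ch)) {
    if (startsWith(nm, "P_")) {
      df[[paste0(nm, "_mmHg")]] <- pa_to_mmhg(ch[[nm]])
    } else if (startsWith(nm, "Q_")) {
      df[[paste0(nm, "_mL_s")]] <- ch[[nm]] / 1000
    } else if (startsWith(nm, "V_")) {
      df[[paste0(nm, "_mL")]] <- mm3_to_ml(ch[[nm]])
    } else {
      df[[nm]] <- ch[[nm]]
    }
  }
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}
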