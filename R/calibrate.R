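# Calibration of the peripheral scaling coefficients and cardiac
# parameters against healthy aortic pressure-flow targets, and the
# manual portal:arterial flow-split adjustment.

#' Healthy aortic calibration targets
#'
#' Normative aortic targets for a healthy adult: mean aortic flow
#' 5 L/min, peak aortic flow 30 L/min, diastolic pressure 80 mmHg,
#' systolic pressure 120 mmHg.
#'
#' @return Named list with `QAortaMean`, `QAortaMax` (L/min),
#'   `PAortaMin`, `PAortaMax` (mmHg).
#' @export
default_targets <- function() {
  list(QAortaMean = 5, QAortaMax = 30, PAortaMin = 80, PAortaMax = 120)
}

# Table of search ranges for the free calibration parameters.
.calib_bounds <- function() {
  rbind(A1 = c(0.1, 10), A2 = c(0.1, 10), A3 = c(0.1, 10),
        E_maxL = c(1e-5, 1), E_minL = c(1e-5, 1),
        E_maxR = c(1e-5, 1), E_minR = c(1e-5, 1),
        T = c(0.5, 2), t_max = c(0.1, 0.5), t_toRelax = c(0.05, 0.2))
}

#' Calibration specification
#'
#' Bundles the free parameters, their physiological search ranges, the
#' aortic targets, and the optimizer settings for [calibrate_model()].
#' The free parameters are the three peripheral scaling coefficients
#' (`A1`: all distal resistances, `A2`: all proximal resistances, `A3`:
#' all compliances) and the seven cardiac parameters (`E_maxL`, `E_minL`,
#' `E_maxR`, `E_minR`, `T`, `t_max`, `t_toRelax`; the timing parameters
#' are shared by both ventricles).
#'
#' @param free Character vector of free parameter names (subset of the
#'   rows of the bounds table).
#' @param targets Aortic targets, see [default_targets()].
#' @param max_evaluations Nelder-Mead function-evaluation budget per
#'   start.
#' @param tolerance Relative convergence tolerance on the loss.
#' @param n_starts Number of random initializations.
#' @param seed Integer seed for the start points.
#' @param settings [simulation_settings()] used for every evaluation.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(free = c("A1", "A2", "A3", "E_maxL", "E_minL",
                                      "E_maxR", "E_minR", "T", "t_max",
                                      "t_toRelax"),
                             targets = default_targets(),
                             max_evaluations = 300, tolerance = 1e-4,
                             n_starts = 8, seed = 1,
                             settings = simulation_settings()) {
  b <- .calib_bounds()
  if (!all(free %in% rownames(b)))
    stop("calibration_spec: unknown free parameters: ",
         paste(setdiff(free, rownames(b)), collapse = ", "))
  structure(list(free = free, bounds = b[free, , drop = FALSE],
                 targets = targets,
                 max_evaluations = max_evaluations, tolerance = tolerance,
                 n_starts = n_starts, seed = seed, settings = settings),
            class = "calibration_spec")
}

#' Calibration loss against aortic targets
#'
#' Sum of the four absolute relative deviations of mean aortic flow,
#' systolic pressure, diastolic pressure and peak aortic flow from their
#' targets.  Dimensionless; invariant under unit changes.
#'
#' @param m A `cycle_metrics` record (or any list providing `CO`,
#'   `Q_aorta_max`, `SBP`, `DBP`).
#' @param targets See [default_targets()].
#' @return Non-negative scalar loss.
#' @export
calibration_loss <- function(m, targets = default_targets()) {
  tg <- unlist(targets)
  if (any(!is.finite(tg)) || any(tg <= 0))
    stop("calibration_loss: targets must be positive")
  abs(m$CO - targets$QAortaMean) / targets$QAortaMean +
    abs(m$SBP - targets$PAortaMax) / targets$PAortaMax +
    abs(m$DBP - targets$PAortaMin) / targets$PAortaMin +
    abs(m$Q_aorta_max - targets$QAortaMax) / targets$QAortaMax
}

#' Apply peripheral scaling coefficients
#'
#' Multiplies every peripheral distal resistance by `A1`, every proximal
#' resistance by `A2` and every compliance by `A3`.  "Peripheral" covers
#' the four RCR compartments, the whole hepatic subsystem and the atrial
#' compliances; heart valve parameters are untouched.
#'
#' @param base A [circulation_model()].
#' @param A1,A2,A3 Dimensionless scaling coefficients (distal
#'   resistances, proximal resistances, compliances).
#' @return The scaled model.
#' @export
apply_scalings <- function(base, A1 = 1, A2 = 1, A3 = 1) {
  stopifnot(inherits(base, "circulation_model"))
  b <- .calib_bounds()
  for (v in c("A1", "A2", "A3")) {
    x <- get(v)
    if (x < b[v, 1] || x > b[v, 2])
      stop("apply_scalings: ", v, " outside its search range")
  }
  m <- base
  for (comp in c("lung", "digestive", "other_organs", "central_venous")) {
    m[[comp]]$R_d <- m[[comp]]$R_d * A1
    m[[comp]]$R_p <- m[[comp]]$R_p * A2
    m[[comp]]$C <- m[[comp]]$C * A3
  }
  h <- m$hepatic
  for (f in c("R_pv_d", "R_ha_d", "R_hs", "R_lhv", "R_mhv", "R_rhv"))
    h[[f]] <- h[[f]] * A1
  for (f in c("R_pv_p", "R_ha_p")) h[[f]] <- h[[f]] * A2
  for (f in c("C_pv", "C_ha", "C_hs")) h[[f]] <- h[[f]] * A3
  m$hepatic <- h
  m$C_la <- m$C_la * A3
  m$C_ra <- m$C_ra * A3
  m
}

# Build a model from a named parameter vector over the calibration space.
.apply_calib_params <- function(base, theta) {
  m <- base
  A1 <- if ("A1" %in% names(theta)) theta[["A1"]] else 1
  A2 <- if ("A2" %in% names(theta)) theta[["A2"]] else 1
  A3 <- if ("A3" %in% names(theta)) theta[["A3"]] else 1
  m <- apply_scalings(m, A1, A2, A3)
  hv <- list(E_maxL = c("left_ventricle", "E_max"),
             E_minL = c("left_ventricle", "E_min"),
             E_maxR = c("right_ventricle", "E_max"),
             E_minR = c("right_ventricle", "E_min"))
  for (nm in names(hv)) if (nm %in% names(theta))
    m[[hv[[nm]][1]]][[hv[[nm]][2]]] <- theta[[nm]]
  for (nm in c("T", "t_max", "t_toRelax")) if (nm %in% names(theta)) {
    m$left_ventricle[[nm]] <- theta[[nm]]
    m$right_ventricle[[nm]] <- theta[[nm]]
  }
  m
}

#' Calibrate the model to aortic targets by multi-start Nelder-Mead
#'
#' Each evaluation applies the candidate parameters, simulates to
#' periodic steady state, computes the cycle metrics and the
#' [calibration_loss()].  Out-of-bounds proposals receive a soft penalty
#' (loss + 1e6), keeping the simplex inside the physiological ranges.
#' Start points are drawn uniformly inside the bounds from `spec$seed`;
#' the first start is the unscaled base model when it is admissible.
#'
#' @param spec A [calibration_spec()].
#' @param base The base [circulation_model()] to scale.
#' @return List with `par` (best parameters), `loss`, `model` (fitted
#'   model), `trace` (best-so-far loss per evaluation), `at_bounds`
#'   (logical: any fitted parameter within 1% of a bound), `converged`,
#'   and per-start diagnostics.
#' @export
calibrate_model <- function(spec, base) {
  stopifnot(inherits(spec, "calibration_spec"),
            inherits(base, "circulation_model"))
  lo <- spec$bounds[, 1]; hi <- spec$bounds[, 2]
  K <- length(spec$free)
  trace_env <- new.env()
  trace_env$trace <- numeric(0)
  trace_env$best <- Inf

  objective <- function(x) {
    names(x) <- spec$free
    if (any(x < lo | x > hi)) {
      val <- 1e6 + sum(pmax(lo - x, 0) + pmax(x - hi, 0))
    } else {
      val <- tryCatch({
        m <- .apply_calib_params(base, x)
        w <- run_simulation(m, spec$settings)
        suppressWarnings(calibration_loss(compute_cardiac_metrics(w), spec$targets))
      }, error = function(e) 1e6)
    }
    trace_env$best <- min(trace_env$best, val)
    trace_env$trace <- c(trace_env$trace, trace_env$best)
    val
  }

  # timing parameters must stay admissible jointly (t_max + t_toRelax < T)
  admissible <- function(x) {
    th <- stats::setNames(x, spec$free)
    Tv <- if ("T" %in% spec$free) th[["T"]] else base$left_ventricle$T
    tm <- if ("t_max" %in% spec$free) th[["t_max"]] else base$left_ventricle$t_max
    tr <- if ("t_toRelax" %in% spec$free) th[["t_toRelax"]] else base$left_ventricle$t_toRelax
    em <- c(E_maxL = base$left_ventricle$E_max, E_minL = base$left_ventricle$E_min,
            E_maxR = base$right_ventricle$E_max, E_minR = base$right_ventricle$E_min)
    for (nm in names(em)) if (nm %in% spec$free) em[nm] <- th[[nm]]
    tm + tr < Tv && em["E_maxL"] > em["E_minL"] && em["E_maxR"] > em["E_minR"]
  }

  set.seed(spec$seed)
  starts <- vector("list", spec$n_starts)
  base_theta <- stats::setNames(rep(1, K), spec$free)
  for (nm in c("E_maxL", "E_minL", "E_maxR", "E_minR", "T", "t_max", "t_toRelax"))
    if (nm %in% spec$free) {
      src <- switch(nm, E_maxL = base$left_ventricle$E_max,
                    E_minL = base$left_ventricle$E_min,
                    E_maxR = base$right_ventricle$E_max,
                    E_minR = base$right_ventricle$E_min,
                    T = base$left_ventricle$T,
                    t_max = base$left_ventricle$t_max,
                    t_toRelax = base$left_ventricle$t_toRelax)
      base_theta[nm] <- src
    }
  starts[[1]] <- pmin(pmax(base_theta, lo), hi)
  i <- 2
  while (i <= spec$n_starts) {
    cand <- lo + stats::runif(K) * (hi - lo)
    if (admissible(cand)) {
      starts[[i]] <- cand
      i <- i + 1
    }
  }

  # each start gets one restart from its incumbent with a fresh simplex
  # (guards against premature simplex collapse), sharing the budget
  runs <- lapply(starts, function(x0) {
    half <- ceiling(spec$max_evaluations / 2)
    r1 <- stats::optim(x0, objective, method = "Nelder-Mead",
                       control = list(maxit = half, reltol = spec$tolerance))
    r2 <- stats::optim(r1$par, objective, method = "Nelder-Mead",
                       control = list(maxit = half, reltol = spec$tolerance))
    out <- if (r2$value <= r1$value) r2 else r1
    # converged if either phase met the tolerance or the restart gained
    # less than it
    out$settled <- r1$convergence == 0 || r2$convergence == 0 ||
      abs(r1$value - r2$value) < spec$tolerance * (abs(r1$value) + spec$tolerance)
    out
  })
  losses <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(losses)]]
  par <- stats::setNames(best$par, spec$free)
  near_bound <- abs(par - lo) < 0.01 * (hi - lo) |
    abs(hi - par) < 0.01 * (hi - lo)
  conv <- any(vapply(runs, function(r) isTRUE(r$settled), logical(1)))
  if (!conv)
    warning("calibrate_model: no start converged within max_evaluations; ",
            "returning best-so-far")
  list(par = par, loss = best$value,
       model = .apply_calib_params(base, par),
       trace = trace_env$trace,
       at_bounds = stats::setNames(near_bound, spec$free),
       converged = conv,
       start_losses = losses)
}

#' Tune the portal : hepatic-arterial flow split
#'
#' Scales the distal hepatic-artery resistance by bisection until the
#' cycle-mean portal fraction of hepatic inflow reaches the target
#' (healthy liver: about 75% portal / 25% arterial).  The fraction is a
#' monotone function of the arterial-to-portal resistance ratio.
#'
#' @param m A calibrated [circulation_model()].
#' @param target_portal_fraction Desired portal share of hepatic inflow,
#'   in `(0, 1)`; default 0.75.
#' @param tol Acceptable deviation of the achieved fraction; default 0.01.
#' @param max_iter Maximum bisection steps; default 60.
#' @param settings [simulation_settings()] for the evaluations.
#' @return The tuned model, with attributes `achieved_fraction` and
#'   `scale` (the factor applied to `R_ha_d`).
#' @export
tune_portal_ratio <- function(m, target_portal_fraction = 0.75, tol = 0.01,
                              max_iter = 60, settings = simulation_settings()) {
  stopifnot(inherits(m, "circulation_model"),
            target_portal_fraction > 0, target_portal_fraction < 1)
  frac_at <- function(s) {
    m2 <- m
    m2$hepatic$R_ha_d <- m$hepatic$R_ha_d * s
    hm <- compute_hepatic_metrics(run_simulation(m2, settings))
    hm$portal_fraction / 100
  }
  f1 <- frac_at(1)
  if (abs(f1 - target_portal_fraction) <= tol) {
    attr(m, "achieved_fraction") <- f1
    attr(m, "scale") <- 1
    return(m)
  }
  # increasing R_ha_d raises the portal fraction
  lo <- 1; hi <- 1
  if (f1 < target_portal_fraction) {
    while (frac_at(hi <- hi * 2) < target_portal_fraction && hi < 2^12) NULL
  } else {
    while (frac_at(lo <- lo / 2) > target_portal_fraction && lo > 2^-12) NULL
  }
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    fm <- frac_at(mid)
    if (abs(fm - target_portal_fraction) <= tol) {
      m$hepatic$R_ha_d <- m$hepatic$R_ha_d * mid
      attr(m, "achieved_fraction") <- fm
      attr(m, "scale") <- mid
      return(m)
    }
    if (fm < target_portal_fraction) lo <- mid else hi <- mid
  }
  stop(sprintf("tune_portal_ratio: target fraction %.2f not reached in %d steps (achieved %.3f)",
               target_portal_fraction, max_iter, fm))
}
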