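# Circuit element types and the closed-loop network.
#
# Internal unit system: pressure Pa, volume mm^3, time s.  Hence
# resistance Pa.s.mm^-3, compliance mm^3.Pa^-1, inertance Pa.s^2.mm^-3.
# User-facing reports use mmHg / mL / L.min^-1 (see units.R).

#' Time-varying elastance parameters for one ventricle
#'
#' The ventricle is modelled with the classical time-varying elastance
#' relation \eqn{P(t) = E(t)\,[V(t) - V_0]}, where \eqn{E(t)} follows a
#' triphasic piecewise waveform: a raised-cosine rise from `E_min` to
#' `E_max` over `[0, t_max]` (contraction), a raised-cosine fall back to
#' `E_min` over `(t_max, t_max + t_toRelax]` (relaxation), and constant
#' `E_min` for the remainder of the cardiac period `T` (diastasis).
#'
#' @param E_max Peak elastance, Pa/mm^3.
#' @param E_min Baseline (diastolic) elastance, Pa/mm^3.
#' @param T Cardiac period, s.
#' @param t_max Time from cycle onset to peak elastance, s.
#' @param t_toRelax Duration of the relaxation phase, s.
#' @param V0 Unstressed ventricular volume, mm^3 (volume at zero pressure).
#' @return An object of class `elastance_params`.
#' @seealso [elastance_at()], [chamber_pressure()]
#' @export
elastance_params <- function(E_max, E_min, T, t_max, t_toRelax, V0) {
  stopifnot(is.numeric(E_max), is.numeric(E_min), is.numeric(T),
            is.numeric(t_max), is.numeric(t_toRelax), is.numeric(V0))
  if (!(E_max > E_min && E_min > 0))
    stop("elastance_params: need E_max > E_min > 0")
  if (!(t_max > 0 && t_max + t_toRelax < T))
    stop("elastance_params: need 0 < t_max and t_max + t_toRelax < T")
  if (V0 < 0) stop("elastance_params: V0 must be >= 0")
  structure(list(E_max = E_max, E_min = E_min, T = T,
                 t_max = t_max, t_toRelax = t_toRelax, V0 = V0),
            class = "elastance_params")
}

#' Heart valve (smooth diode) parameters
#'
#' Valves are unidirectional hyperbolic-tangent resistors in series with an
#' inertance: the effective resistance interpolates smoothly between the
#' open value `R` and `closed_resistance_factor * R` as the transvalvular
#' pressure difference changes sign.
#'
#' @param R Open-valve resistance, Pa.s/mm^3.
#' @param L Inertance, Pa.s^2/mm^3.
#' @param steepness Pressure scale of the open/close transition, Pa.
#'   Default 2.7 Pa (0.02 mmHg), sharp enough that closure reversal stays
#'   below 1 percent of peak forward flow through every valve.
#' @param closed_resistance_factor Dimensionless multiplier giving the
#'   closed-valve resistance; default 1e6.
#' @return An object of class `valve_params`.
#' @seealso [valve_openness()]
#' @export
valve_params <- function(R, L, steepness = 2.7, closed_resistance_factor = 1e6) {
  if (!(R > 0 && L > 0 && steepness > 0))
    stop("valve_params: R, L and steepness must be positive")
  if (closed_resistance_factor < 1e4)
    stop("valve_params: closed_resistance_factor must be >= 1e4")
  structure(list(R = R, L = L, steepness = steepness,
                 closed_resistance_factor = closed_resistance_factor),
            class = "valve_params")
}

#' Three-element Windkessel (RCR) compartment parameters
#'
#' @param R_p Proximal resistance, Pa.s/mm^3.
#' @param C Compliance, mm^3/Pa.
#' @param R_d Distal resistance, Pa.s/mm^3.
#' @return An object of class `rcr_params`.
#' @export
rcr_params <- function(R_p, C, R_d) {
  if (R_p < 0 || R_d < 0) stop("rcr_params: resistances must be >= 0")
  if (!(C > 0)) stop("rcr_params: compliance must be > 0")
  structure(list(R_p = R_p, C = C, R_d = R_d), class = "rcr_params")
}

#' Hepatic subsystem parameters
#'
#' The liver receives blood from two supplies: the portal vein (proximal
#' resistance `R_pv_p`, compliance `C_pv`, distal/presinusoidal resistance
#' `R_pv_d`) fed by the digestive-organ outflow, and the hepatic artery
#' (`R_ha_p`, `C_ha`, `R_ha_d`) fed from the systemic arterial node.  Both
#' converge at the sinusoid node (`C_hs`), which drains through the
#' sinusoidal resistance `R_hs` into three parallel hepatic veins
#' (`R_lhv`, `R_mhv`, `R_rhv`) toward the central venous compartment.
#'
#' @param R_pv_p,R_pv_d Proximal / distal (presinusoidal) portal-vein
#'   resistances, Pa.s/mm^3.
#' @param C_pv Portal-vein compliance, mm^3/Pa.
#' @param R_ha_p,R_ha_d Proximal / distal hepatic-artery resistances,
#'   Pa.s/mm^3.
#' @param C_ha Hepatic-artery compliance, mm^3/Pa.
#' @param R_hs Sinusoidal resistance, Pa.s/mm^3.
#' @param C_hs Sinusoidal compliance, mm^3/Pa.
#' @param R_lhv,R_mhv,R_rhv Left / middle / right hepatic-vein resistances,
#'   Pa.s/mm^3.
#' @return An object of class `hepatic_params`.
#' @export
hepatic_params <- function(R_pv_p, R_pv_d, C_pv, R_ha_p, R_ha_d, C_ha,
                           R_hs, C_hs, R_lhv, R_mhv, R_rhv) {
  vals <- c(R_pv_p = R_pv_p, R_pv_d = R_pv_d, C_pv = C_pv,
            R_ha_p = R_ha_p, R_ha_d = R_ha_d, C_ha = C_ha,
            R_hs = R_hs, C_hs = C_hs,
            R_lhv = R_lhv, R_mhv = R_mhv, R_rhv = R_rhv)
  if (any(vals <= 0))
    stop("hepatic_params: all resistances and compliances must be > 0; ",
         "offending: ", paste(names(vals)[vals <= 0], collapse = ", "))
  structure(as.list(vals), class = "hepatic_params")
}

# Canonical ordering of the 15 state variables.  Chamber volumes first,
# then valve (inductor) flows, then capacitor node pressures.
.state_names <- c("V_lv", "V_rv",
                  "Q_mv", "Q_av", "Q_tv", "Q_puv",
                  "P_ha", "P_dig", "P_pv", "P_hs", "P_oth", "P_lung", "P_cv",
                  "P_la", "P_ra")

#' Assemble the full closed-loop circulation model
#'
#' Builds the fixed network: left ventricle -> aortic valve -> systemic
#' arterial junction feeding three parallel branches (hepatic artery RCR,
#' digestive-organ RCR, other-organ RCR); the digestive outflow perfuses
#' the portal vein, which together with the hepatic artery converges at
#' the hepatic sinusoid; the sinusoid drains through three parallel
#' hepatic veins into the central venous compartment and the right
#' atrium, then through the tricuspid valve into the right ventricle, the
#' pulmonary valve, the lung RCR, the left atrium and back through the
#' mitral valve.
#'
#' Each atrium is a passive compliance reservoir: the left atrium sits
#' between the lung distal resistance and the mitral valve, the right
#' atrium between the central-venous distal resistance and the tricuspid
#' valve.  Without them a ventricular stroke would have to be absorbed by
#' the small lung compliance while both left-heart valves are shut.
#'
#' @param left_ventricle,right_ventricle [elastance_params()] objects.
#' @param mitral,aortic,tricuspid,pulmonary [valve_params()] objects.
#' @param lung,digestive,other_organs,central_venous [rcr_params()] objects.
#' @param hepatic A [hepatic_params()] object.
#' @param C_la,C_ra Passive left- and right-atrial compliances, mm^3/Pa.
#' @return An object of class `circulation_model` with a `state_layout`
#'   naming the 15 state variables (2 chamber volumes, 4 inductor flows,
#'   9 capacitor node pressures).
#' @seealso [default_model()], [assemble_rhs()]
#' @export
circulation_model <- function(left_ventricle, right_ventricle,
                              mitral, aortic, tricuspid, pulmonary,
                              lung, digestive, other_organs, central_venous,
                              hepatic, C_la, C_ra) {
  chk <- function(x, cls, nm) {
    if (!inherits(x, cls)) stop("circulation_model: ", nm, " must be a ", cls)
    x
  }
  m <- structure(list(
    left_ventricle  = chk(left_ventricle, "elastance_params", "left_ventricle"),
    right_ventricle = chk(right_ventricle, "elastance_params", "right_ventricle"),
    mitral    = chk(mitral, "valve_params", "mitral"),
    aortic    = chk(aortic, "valve_params", "aortic"),
    tricuspid = chk(tricuspid, "valve_params", "tricuspid"),
    pulmonary = chk(pulmonary, "valve_params", "pulmonary"),
    lung           = chk(lung, "rcr_params", "lung"),
    digestive      = chk(digestive, "rcr_params", "digestive"),
    other_organs   = chk(other_organs, "rcr_params", "other_organs"),
    central_venous = chk(central_venous, "rcr_params", "central_venous"),
    hepatic = chk(hepatic, "hepatic_params", "hepatic"),
    C_la = C_la, C_ra = C_ra,
    state_layout = .state_names
  ), class = "circulation_model")
  if (!(is.numeric(m$C_la) && m$C_la > 0 && is.numeric(m$C_ra) && m$C_ra > 0))
    stop("circulation_model: atrial compliances C_la, C_ra must be > 0")
  m
}

#' @export
print.circulation_model <- function(x, ...) {
  cat("Closed-loop lumped-parameter circulation model\n")
  cat(sprintf("  heart period T = %.3f s (%.1f bpm), E_maxL = %.3g Pa/mm^3\n",
              x$left_ventricle$T, 60 / x$left_ventricle$T,
              x$left_ventricle$E_max))
  cat(sprintf("  hepatic: R_pv_d = %.5g, R_ha_d = %.5g, R_hs = %.5g Pa.s/mm^3\n",
              x$hepatic$R_pv_d, x$hepatic$R_ha_d, x$hepatic$R_hs))
  cat(sprintf("  state variables: %s\n", paste(x$state_layout, collapse = ", ")))
  invisible(x)
}

#' Healthy baseline circulation model
#'
#' The shipped parameter set of the healthy control configuration:
#' valve resistances and inertances, ventricular elastance waveform
#' parameters (T = 0.684 s, 87.7 bpm; V0 = 10 mL for both ventricles), and
#' the RCR / hepatic values of the calibrated baseline.  Equivalent to
#' loading the packaged `default_model.yaml` with [load_model_config()].
#'
#' @return A [circulation_model()].
#' @export
default_model <- function() {
  circulation_model(
    left_ventricle  = elastance_params(E_max = 0.394, E_min = 9e-5,
                                       T = 0.684, t_max = 0.377,
                                       t_toRelax = 0.104, V0 = 10000),
    right_ventricle = elastance_params(E_max = 0.152, E_min = 9e-5,
                                       T = 0.684, t_max = 0.377,
                                       t_toRelax = 0.104, V0 = 10000),
    mitral    = valve_params(R = 3.9e-4, L = 1e-5),
    aortic    = valve_params(R = 1e-5,  L = 1e-5),
    tricuspid = valve_params(R = 1e-5,  L = 1e-5),
    pulmonary = valve_params(R = 1e-5,  L = 1e-5),
    lung           = rcr_params(R_p = 0.00027, C = 1.000,  R_d = 0.00265),
    digestive      = rcr_params(R_p = 0.05607, C = 0.630,  R_d = 0.58110),
    other_organs   = rcr_params(R_p = 0.01869, C = 6.302,  R_d = 0.19370),
    central_venous = rcr_params(R_p = 0.00014, C = 12.000, R_d = 0.00142),
    hepatic = hepatic_params(R_pv_p = 0.00318, R_pv_d = 0.03184, C_pv = 1.200,
                             R_ha_p = 0.17755, R_ha_d = 1.84015, C_ha = 0.630,
                             R_hs = 0.00884, C_hs = 1.000,
                             R_lhv = 1e-5, R_mhv = 1e-5, R_rhv = 1e-5),
    C_la = 10, C_ra = 2
  )
}

#' Triphasic time-varying elastance
#'
#' Evaluates the ventricular elastance waveform at time `t` within the
#' cardiac cycle: raised-cosine rise on `[0, t_max]`, raised-cosine fall on
#' `(t_max, t_max + t_toRelax]`, and `E_min` thereafter.  Continuous at
#' both breakpoints.
#'
#' @param t Time within the cycle, s; must satisfy `0 <= t < T`
#'   (callers reduce modulo `T`).  Vectorized.
#' @param p An [elastance_params()] object.
#' @return Elastance in Pa/mm^3.
#' @export
elastance_at <- function(t, p) {
  stopifnot(inherits(p, "elastance_params"))
  if (any(t < 0 | t >= p$T))
    stop("elastance_at: t must lie in [0, T); reduce modulo T first")
  dE <- p$E_max - p$E_min
  E <- rep(p$E_min, length(t))
  i1 <- t <= p$t_max
  E[i1] <- p$E_min + 0.5 * dE * (1 - cos(pi * t[i1] / p$t_max))
  i2 <- t > p$t_max & t <= p$t_max + p$t_toRelax
  E[i2] <- p$E_min + 0.5 * dE * (1 + cos(pi * (t[i2] - p$t_max) / p$t_toRelax))
  E
}

#' Chamber pressure from the elastance relation
#'
#' `P = E * (V - V0)`.  Negative pressure when `V < V0` is permitted (the
#' linear relation is used as stated, without an unstressed-volume floor).
#'
#' @param V Chamber volume, mm^3.
#' @param E Instantaneous elastance, Pa/mm^3.
#' @param V0 Unstressed volume, mm^3.
#' @return Pressure in Pa.
#' @export
chamber_pressure <- function(V, E, V0) {
  if (any(V < 0)) stop("chamber_pressure: V must be >= 0")
  E * (V - V0)
}

#' Valve opening fraction
#'
#' Smooth diode law `0.5 * (1 + tanh(dP / steepness))`: approaches 1 for
#' forward pressure differences much larger than `steepness`, 0 for
#' reverse differences, and equals 0.5 at `dP = 0`.
#'
#' @param dP Pressure difference across the valve (upstream minus
#'   downstream), Pa.  Vectorized.
#' @param v A [valve_params()] object.
#' @return Opening fraction in `[0, 1]`.
#' @export
valve_openness <- function(dP, v) {
  stopifnot(inherits(v, "valve_params"))
  0.5 * (1 + tanh(dP / v$steepness))
}

# Effective valve resistance: R / openness, capped at the closed value.
.valve_reff <- function(dP, v) {
  o <- valve_openness(dP, v)
  v$R / pmax(o, 1 / v$closed_resistance_factor)
}

#' Right-hand side of the circulation ODE system
#'
#' Reference (pure R) implementation of the coupled balance laws:
#' `dV/dt = Q_in - Q_out` for each chamber, `C dP/dt = sum(Q_in) -
#' sum(Q_out)` for each capacitor node, and `L dQ/dt = dP - R_eff Q` for
#' each valve branch, with `R_eff` interpolating the open/closed valve
#' resistance through [valve_openness()].  The two purely resistive
#' junction nodes (systemic arterial, hepatic-venous confluence) are
#' eliminated algebraically, so the instantaneous sum of all volume-rate
#' contributions is exactly zero (closed loop).
#'
#' The compiled equivalent of this function drives [run_simulation()];
#' this R version is the readable reference and is cross-checked against
#' the compiled one in the test suite.
#'
#' @param t Time, s.
#' @param state Numeric state vector in `m$state_layout` order.
#' @param m A [circulation_model()].
#' @param with_aux If `TRUE`, also return the auxiliary algebraic
#'   quantities (chamber and junction pressures, branch flows).
#' @return Named list: `dstate` (derivative vector) and, with
#'   `with_aux = TRUE`, `aux`.
#' @export
assemble_rhs <- function(t, state, m, with_aux = FALSE) {
  stopifnot(inherits(m, "circulation_model"),
            length(state) == length(m$state_layout))
  if (any(!is.finite(state)))
    stop("assemble_rhs: non-finite state (integration fault)")
  s <- as.list(stats::setNames(as.numeric(state), m$state_layout))
  lv <- m$left_ventricle; rv <- m$right_ventricle; h <- m$hepatic

  tc <- t %% lv$T
  P_lv <- chamber_pressure(s$V_lv, elastance_at(tc, lv), lv$V0)
  P_rv <- chamber_pressure(s$V_rv, elastance_at(tc, rv), rv$V0)

  # systemic arterial junction (algebraic): aortic-valve inflow splits over
  # the hepatic-artery, digestive and other-organ proximal resistances
  g_ha <- 1 / h$R_ha_p; g_dig <- 1 / m$digestive$R_p; g_oth <- 1 / m$other_organs$R_p
  P_art <- (s$Q_av + s$P_ha * g_ha + s$P_dig * g_dig + s$P_oth * g_oth) /
    (g_ha + g_dig + g_oth)

  # hepatic-venous confluence (algebraic): sinusoid and other-organ
  # outflows meet and enter the central venous compartment through R_p
  R_hv <- 1 / (1 / h$R_lhv + 1 / h$R_mhv + 1 / h$R_rhv)
  R_sin_out <- h$R_hs + R_hv
  g_sin <- 1 / R_sin_out; g_oo <- 1 / m$other_organs$R_d; g_cv <- 1 / m$central_venous$R_p
  P_vj <- (s$P_hs * g_sin + s$P_oth * g_oo + s$P_cv * g_cv) / (g_sin + g_oo + g_cv)

  # valve branches (lung proximal resistance folded into the pulmonary
  # branch: no node intervenes between the valve and the lung capacitor)
  dQ_mv  <- (s$P_la - P_lv -
             .valve_reff(s$P_la - P_lv, m$mitral) * s$Q_mv) / m$mitral$L
  dQ_av  <- (P_lv - P_art -
             .valve_reff(P_lv - P_art, m$aortic) * s$Q_av) / m$aortic$L
  dQ_tv  <- (s$P_ra - P_rv -
             .valve_reff(s$P_ra - P_rv, m$tricuspid) * s$Q_tv) / m$tricuspid$L
  dQ_puv <- (P_rv - s$P_lung -
             (.valve_reff(P_rv - s$P_lung, m$pulmonary) + m$lung$R_p) * s$Q_puv) /
            m$pulmonary$L

  # branch flows
  Q_ha_in  <- (P_art - s$P_ha) * g_ha
  Q_ha_d   <- (s$P_ha - s$P_hs) / h$R_ha_d
  Q_dig_in <- (P_art - s$P_dig) * g_dig
  Q_dig_out <- (s$P_dig - s$P_pv) / (m$digestive$R_d + h$R_pv_p)
  Q_pv_d   <- (s$P_pv - s$P_hs) / h$R_pv_d
  Q_hs_out <- (s$P_hs - P_vj) * g_sin
  Q_oth_in <- (P_art - s$P_oth) * g_oth
  Q_oth_out <- (s$P_oth - P_vj) * g_oo
  Q_cv_in  <- (P_vj - s$P_cv) * g_cv
  Q_lung_out <- (s$P_lung - s$P_la) / m$lung$R_d
  Q_cv_out <- (s$P_cv - s$P_ra) / m$central_venous$R_d

  dstate <- c(
    V_lv  = s$Q_mv - s$Q_av,
    V_rv  = s$Q_tv - s$Q_puv,
    Q_mv  = dQ_mv, Q_av = dQ_av, Q_tv = dQ_tv, Q_puv = dQ_puv,
    P_ha  = (Q_ha_in - Q_ha_d) / h$C_ha,
    P_dig = (Q_dig_in - Q_dig_out) / m$digestive$C,
    P_pv  = (Q_dig_out - Q_pv_d) / h$C_pv,
    P_hs  = (Q_pv_d + Q_ha_d - Q_hs_out) / h$C_hs,
    P_oth = (Q_oth_in - Q_oth_out) / m$other_organs$C,
    P_lung = (s$Q_puv - Q_lung_out) / m$lung$C,
    P_cv  = (Q_cv_in - Q_cv_out) / m$central_venous$C,
    P_la  = (Q_lung_out - s$Q_mv) / m$C_la,
    P_ra  = (Q_cv_out - s$Q_tv) / m$C_ra
  )
  if (!with_aux) return(list(dstate = dstate))
  list(dstate = dstate,
       aux = c(P_lv = P_lv, P_rv = P_rv, P_art = P_art, P_vj = P_vj,
               Q_ha_d = Q_ha_d, Q_pv_d = Q_pv_d, Q_hs_out = Q_hs_out,
               Q_dig_out = Q_dig_out, Q_oth_out = Q_oth_out))
}

# Flatten a circulation_model into the fixed-order parameter vector shared
# with the compiled right-hand side (src/circ.c).  Order must match the
# #defines there.
.pack_params <- function(m) {
  lv <- m$left_ventricle; rv <- m$right_ventricle; h <- m$hepatic
  vp <- function(v) c(v$R, v$L, v$steepness, v$closed_resistance_factor)
  rc <- function(r) c(r$R_p, r$C, r$R_d)
  c(lv$E_max, lv$E_min, lv$V0, rv$E_max, rv$E_min, rv$V0,
    lv$T, lv$t_max, lv$t_toRelax,
    vp(m$mitral), vp(m$aortic), vp(m$tricuspid), vp(m$pulmonary),
    rc(m$lung), rc(m$digestive), rc(m$other_organs), rc(m$central_venous),
    h$R_pv_p, h$R_pv_d, h$C_pv, h$R_ha_p, h$R_ha_d, h$C_ha,
    h$R_hs, h$C_hs, h$R_lhv, h$R_mhv, h$R_rhv,
    m$C_la, m$C_ra)
}

# Sum of all compliances (stressed-volume bookkeeping helper).
.total_compliance <- function(m) {
  h <- m$hepatic
  m$lung$C + m$digestive$C + m$other_organs$C + m$central_venous$C +
    h$C_pv + h$C_ha + h$C_hs + m$C_la + m$C_ra
}

#' Default initial state
#'
#' All capacitor node pressures at 10 mmHg, both ventricular volumes at
#' 120 mL, all valve flows zero.  In a closed loop the initial state fixes
#' the total blood volume, which is conserved thereafter; the transient is
#' discarded by the periodicity criterion.
#'
#' @param m A [circulation_model()].
#' @param node_pressure_mmHg Initial node pressure, mmHg.
#' @param ventricle_volume_mL Initial volume of each ventricle, mL.
#' @return Named state vector in `m$state_layout` order.
#' @export
default_initial_state <- function(m, node_pressure_mmHg = 10,
                                  ventricle_volume_mL = 120) {
  P0 <- node_pressure_mmHg * .PA_PER_MMHG
  V0 <- ventricle_volume_mL * 1000
  stats::setNames(
    c(V0, V0, 0, 0, 0, 0, rep(P0, 9)),
    m$state_layout)
}
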