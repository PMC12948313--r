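# Scalar hemodynamic indices computed from a steady-cycle waveform set.

#' Pressure-volume loop area (shoelace)
#'
#' Signed polygon area of an ordered, closed `(V, P)` loop; positive for
#' the physiologic counter-clockwise traversal in the volume-pressure
#' plane.  Units follow the inputs (mmHg * mL when called on reporting
#' units).
#'
#' @param V,P Ordered coordinates of the loop; the first and last points
#'   must (approximately) coincide.
#' @return Signed area.
#' @export
loop_area <- function(V, P) {
  if (length(V) != length(P)) stop("loop_area: V and P lengths differ")
  if (length(V) < 3) stop("loop_area: need at least 3 points")
  # close the polygon if the caller did not repeat the first vertex
  span <- max(V) - min(V) + max(P) - min(P)
  if (abs(V[1] - V[length(V)]) + abs(P[1] - P[length(P)]) > 0.05 * span)
    stop("loop_area: loop is not closed (first and last points differ)")
  n <- length(V)
  i <- seq_len(n - 1)
  # shoelace in (V, P); counter-clockwise in (V, P) -> positive
  0.5 * sum(V[i] * P[i + 1] - V[i + 1] * P[i])
}

# Restrict to the last complete cycle of a steady waveform.
.last_cycle <- function(w) extract_final_cycles(w, 1)

#' Cardiac indices of one steady cycle
#'
#' Computes, over the final complete cycle of `w`:
#' cardiac output `CO` (cycle-mean aortic-valve flow), peak aortic flow,
#' systolic/diastolic/mean aortic pressure, end-diastolic and
#' end-systolic left-ventricular volumes (max/min of the stressed volume
#' `V - V0` over the cycle), stroke volume `SV = EDV - ESV`, stroke work `SW` (shoelace area of the
#' pressure-volume loop), end-systolic pressure `ESP` (left-ventricular
#' pressure at aortic-valve closure, detected as the instant after peak
#' ejection when aortic flow falls below 0.5 percent of its peak),
#' effective arterial elastance `Ea = ESP / SV` and ejection fraction
#' `LVEF = SV / EDV * 100`.
#'
#' @param w A steady `waveform_set` (at least one complete cycle; the
#'   last one is used).
#' @return Named list in reporting units (L/min, mmHg, mL, mmHg*mL, %).
#' @export
compute_cardiac_metrics <- function(w) {
  stopifnot(inherits(w, "waveform_set"))
  cc <- cycle_convergence(w)
  if (!cc$converged)
    warning("compute_cardiac_metrics: waveform not periodic to within the threshold")
  wc <- .last_cycle(w)
  ch <- wc$channels
  CO <- mm3s_to_lmin(mean(ch$Q_av))
  Qmax <- mm3s_to_lmin(max(ch$Q_av))
  SBP <- pa_to_mmhg(max(ch$P_art))
  DBP <- pa_to_mmhg(min(ch$P_art))
  MAP <- pa_to_mmhg(mean(ch$P_art))
  # volumes reported as stressed volume (V - V0), the convention under
  # which ESV ~ ESP / E_max and the ejection fraction is defined
  V0 <- wc$model$left_ventricle$V0
  EDV <- mm3_to_ml(max(ch$V_lv) - V0)
  ESV <- mm3_to_ml(min(ch$V_lv) - V0)
  SV <- EDV - ESV
  V_ml <- mm3_to_ml(ch$V_lv)
  P_mmhg <- pa_to_mmhg(ch$P_lv)
  # Close the loop explicitly; time-forward traversal (fill along the
  # bottom, pressurize, eject along the top, relax) is counter-clockwise
  # in (V, P), so the shoelace area is already positive.
  SW <- loop_area(c(V_ml, V_ml[1]), c(P_mmhg, P_mmhg[1]))
  ip <- which.max(ch$Q_av)
  after <- seq(ip, nrow(ch))
  icl <- after[which(ch$Q_av[after] < 0.005 * max(ch$Q_av))[1]]
  if (is.na(icl)) icl <- after[which.min(ch$Q_av[after])]
  ESP <- pa_to_mmhg(ch$P_lv[icl])
  list(CO = CO, Q_aorta_max = Qmax, SBP = SBP, DBP = DBP, MAP = MAP,
       EDV = EDV, ESV = ESV, SV = SV, SW = SW, ESP = ESP,
       Ea = ESP / SV, LVEF = SV / EDV * 100)
}

#' Hepatic indices of one steady cycle
#'
#' Cycle-mean flows entering the sinusoid from the portal vein (`Q_pv`)
#' and hepatic artery (`Q_ha`), total hepatic venous outflow
#' (`Q_hv_total`), the arterial fraction of hepatic inflow, the mean
#' portal pressure `P_pv_mean` and the mean hepatic-vein pressure
#' `P_hv_mean`.  Portal pressure is read at the sinusoid-inlet node,
#' i.e. downstream of the presinusoidal resistance -- the site whose
#' pressure the wedged hepatic venous pressure approximates clinically.
#'
#' @param w A steady `waveform_set`.
#' @return Named list: flows in L/min, pressures in mmHg, fraction in %.
#' @export
compute_hepatic_metrics <- function(w) {
  stopifnot(inherits(w, "waveform_set"))
  wc <- .last_cycle(w)
  ch <- wc$channels
  Q_pv <- mm3s_to_lmin(mean(ch$Q_pv_d))
  Q_ha <- mm3s_to_lmin(mean(ch$Q_ha_d))
  Q_hv <- mm3s_to_lmin(mean(ch$Q_hs_out))
  list(Q_pv = Q_pv, Q_ha = Q_ha, Q_hv_total = Q_hv,
       arterial_fraction = 100 * Q_ha / (Q_pv + Q_ha),
       portal_fraction = 100 * Q_pv / (Q_pv + Q_ha),
       P_pv_mean = pa_to_mmhg(mean(ch$P_hs)),
       P_hv_mean = pa_to_mmhg(mean(ch$P_vj)))
}

#' All steady-cycle metrics
#'
#' Combines [compute_cardiac_metrics()] and [compute_hepatic_metrics()]
#' into one `cycle_metrics` record.
#'
#' @param w A steady `waveform_set`.
#' @return An object of class `cycle_metrics` (named list).
#' @export
cycle_metrics <- function(w) {
  out <- c(compute_cardiac_metrics(w), compute_hepatic_metrics(w))
  structure(out, class = "cycle_metrics")
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat(sprintf("CO %.2f L/min | SV %.2f mL | SW %.0f mmHg.mL | Ea %.2f mmHg/mL | LVEF %.1f%%\n",
              x$CO, x$SV, x$SW, x$Ea, x$LVEF))
  cat(sprintf("SBP/DBP %.1f/%.1f mmHg (MAP %.1f) | ESP %.1f mmHg\n",
              x$SBP, x$DBP, x$MAP, x$ESP))
  cat(sprintf("Q_pv %.2f, Q_ha %.2f L/min (arterial %.1f%%) | P_portal %.1f, P_hv %.1f mmHg\n",
              x$Q_pv, x$Q_ha, x$arterial_fraction, x$P_pv_mean, x$P_hv_mean))
  invisible(x)
}

#' Write a metrics table (one row per scenario) to CSV
#'
#' @param metrics A named list or list of `cycle_metrics` records.
#' @param path Output path.
#' @return The data frame written, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  if (inherits(metrics, "cycle_metrics")) metrics <- list(metrics)
  df <- do.call(rbind, lapply(metrics, function(m) as.data.frame(unclass(m))))
  if (!is.null(names(metrics))) df <- cbind(scenario = names(metrics), df)
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}
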