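#' Calibrate the valve opening/closure rate coefficient
#'
#' Starting from a low value, the rate coefficient is increased on a
#' geometric grid (factor 1.25) until the valve reaches the fully open
#' state over the ejection window; the opening and closure coefficients
#' are assumed equal.  The returned value is the smallest grid value
#' achieving `target_zeta`.
#'
#' @param cardiac,valve,tree,control Simulation configuration (the
#'   valve's `kvo` is ignored).
#' @param target_zeta Opening threshold counted as "fully open".
#' @param kvo_seed Smallest trial rate, 1/(mmHg s).
#' @param factor Geometric grid factor.
#' @param kvo_cap Largest admissible rate; reaching it without full
#'   opening is an error (the last achieved maximum state is reported).
#' @return List with `kvo`, `max_zeta`, and `trials` (the search path).
#' @export
calibrate_valve_rates <- function(cardiac, valve, tree = default_tree(),
                                  control = sim_control(),
                                  target_zeta = 0.999, kvo_seed = 0.002,
                                  factor = 1.25, kvo_cap = 2000) {
  kvo <- kvo_seed
  state <- NULL
  trials <- data.frame(kvo = numeric(0), max_zeta = numeric(0))
  repeat {
    v <- valve
    v$kvo <- v$kvc <- kvo
    sim <- av_simulate(cardiac, v, tree, control, state = state)
    state <- sim$state
    mz <- max(sim$cycles$max_zeta)
    trials <- rbind(trials, data.frame(kvo = kvo, max_zeta = mz))
    if (mz >= target_zeta)
      return(list(kvo = kvo, max_zeta = mz, trials = trials))
    if (kvo >= kvo_cap)
      stop(sprintf(paste0("valve rate calibration failed: cap %.3g reached ",
                          "with max zeta %.4f < %.4f"), kvo_cap, mz,
                   target_zeta))
    kvo <- kvo * factor
  }
}

#' Calibrate a case to target afterload
#'
#' Fixed-point loop matching the achieved afterload indices to their
#' targets: total vascular resistance is the waveform ratio MAP/CO and
#' total arterial compliance the structural aggregate evaluated at the
#' achieved mean pressure (wall compliance is pressure-dependent, so a
#' case whose operating pressure moves must be re-scaled and re-run).
#' After each converged simulation the terminal resistances and the
#' compliances are rescaled toward the targets via [scale_afterload()]
#' until both achieved values are within `tol`.
#'
#' @param cardiac,valve,tree,control Simulation configuration.
#' @param tvr_target Target total vascular resistance, mmHg s/mL.
#' @param tac_target Target total arterial compliance, mL/mmHg.
#' @param tol Relative tolerance on both indices.
#' @param max_iter Maximum outer iterations.
#' @param quiet Suppress the non-convergence warning.
#' @return List with the final `sim` (`av_sim`), the rescaled `tree`,
#'   `achieved` (list tvr/tac), `iterations`, and the per-iteration
#'   `history`.
#' @export
calibrate_case <- function(cardiac, valve, tree = default_tree(),
                           control = sim_control(),
                           tvr_target = 1.2, tac_target = 1.1,
                           tol = 0.01, max_iter = 10, quiet = FALSE) {
  # structural pre-scaling gives a good starting point
  tree <- scale_afterload(tree, tvr = tvr_target, tac = tac_target)
  if (is.null(valve$kvo)) {
    cal <- calibrate_valve_rates(cardiac, valve, tree, control)
    valve$kvo <- valve$kvc <- cal$kvo
  }
  state <- NULL
  history <- data.frame(iter = integer(0), tvr = numeric(0),
                        tac = numeric(0), err = numeric(0))
  for (it in seq_len(max_iter)) {
    sim <- av_simulate(cardiac, valve, tree, control, state = state)
    state <- sim$state
    ach <- list(tvr = sim$summary$map / sim$summary$co,
                tac = aggregate_afterload(tree, sim$summary$map)$tac)
    err <- max(abs(ach$tvr - tvr_target) / tvr_target,
               abs(ach$tac - tac_target) / tac_target)
    history <- rbind(history, data.frame(iter = it, tvr = ach$tvr,
                                         tac = ach$tac, err = err))
    if (err < tol)
      return(list(sim = sim, tree = tree, achieved = ach,
                  iterations = it, history = history, converged = TRUE))
    agg <- aggregate_afterload(tree)
    # clamp the per-iteration correction: keeps the loop stable when an
    # early (far-from-periodic) estimate is badly off
    f_tvr <- min(max(tvr_target / ach$tvr, 0.5), 2)
    f_tac <- min(max(tac_target / ach$tac, 0.5), 2)
    tree <- scale_afterload(tree, tvr = agg$tvr * f_tvr,
                            tac = agg$tac * f_tac)
  }
  if (!quiet)
    warning(sprintf(paste0("afterload calibration did not reach %.1f%% in ",
                           "%d iterations (last error %.2f%%)"),
                    100 * tol, max_iter, 100 * history$err[nrow(history)]))
  list(sim = sim, tree = tree, achieved = ach, iterations = max_iter,
       history = history, converged = FALSE)
}

#' Tune contractility to a target stroke volume
#'
#' Bisection on the end-systolic elastance until the calibrated
#' simulation's stroke volume matches the target: used for the
#' stress/rest worked examples where stroke volume, not contractility,
#' is the measured quantity.
#'
#' @param sv_target Target stroke volume, mL.
#' @param cardiac,valve,tree,control Base configuration (`cardiac$ees` is
#'   overridden by the search).
#' @param tvr_target,tac_target Afterload targets held during the search.
#' @param ees_range Bracketing interval for the elastance, mmHg/mL.
#' @param tol_ml Stroke-volume tolerance, mL.
#' @param max_iter Maximum bisection steps.
#' @return List with `ees`, the final calibrated `case` (see
#'   [calibrate_case()]), and the achieved `sv`.
#' @export
tune_ees_for_sv <- function(sv_target, cardiac = cardiac_params(),
                            valve = valve_params(),
                            tree = default_tree(),
                            control = sim_control(),
                            tvr_target = 1.2, tac_target = 1.1,
                            ees_range = c(0.8, 12), tol_ml = 1,
                            max_iter = 30) {
  run_sv <- function(ees) {
    cp <- cardiac; cp$ees <- ees
    cc <- calibrate_case(cp, valve, tree, control,
                         tvr_target = tvr_target, tac_target = tac_target,
                         quiet = TRUE)
    list(sv = cc$sim$summary$sv, case = cc)
  }
  lo <- ees_range[1]; hi <- ees_range[2]
  r_lo <- run_sv(lo); r_hi <- run_sv(hi)
  if (r_lo$sv > sv_target || r_hi$sv < sv_target)
    stop(sprintf("stroke-volume target %.1f mL outside the achievable range [%.1f, %.1f]",
                 sv_target, r_lo$sv, r_hi$sv))
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- run_sv(mid)
    best <- r
    if (abs(r$sv - sv_target) < tol_ml) break
    if (r$sv < sv_target) lo <- mid else hi <- mid
  }
  list(ees = mid, case = best$case, sv = best$sv)
}
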