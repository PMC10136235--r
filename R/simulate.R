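#' Numerical control settings for the coupled simulator
#'
#' @param dx_cm Target spatial resolution of the 1D solver, cm.
#' @param dt Time step, s; `NULL` selects the largest stable step from a
#'   conservative CFL estimate (capped for the valve dynamics) and rounds
#'   it so the heart period is an integer number of steps.
#' @param dt_cap Upper cap on the time step, s.
#' @param max_cycles Maximum number of cardiac cycles.
#' @param tol Relative periodic-steady-state tolerance on stroke volume
#'   and mean aortic pressure between consecutive cycles.
#' @param p_init Uniform initial tree pressure, mmHg.
#' @param mu Blood dynamic viscosity, poise.
#' @param gamma_v Velocity-profile parameter of the friction law
#'   \eqn{f = -2(\gamma_v + 2)\pi\mu Q/(\rho A)}; 9 approximates a flat
#'   (Womersley-like) profile, 2 recovers Poiseuille.
#' @param rho Blood density, g/cm^3.
#' @param lvedp_tol Tolerance on the auto-tuned end-diastolic pressure,
#'   mmHg.
#' @param stride Store every `stride`-th step of the waveforms.
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(dx_cm = 1, dt = NULL, dt_cap = 2.5e-4,
                        max_cycles = 25, tol = 1e-3, p_init = 80,
                        mu = 0.04, gamma_v = 9, rho = 1.06,
                        lvedp_tol = 0.2, stride = 1L) {
  stopifnot(dx_cm > 0, is.null(dt) || dt > 0, max_cycles >= 3, tol > 0)
  structure(list(dx_cm = dx_cm, dt = dt, dt_cap = dt_cap,
                 max_cycles = max_cycles, tol = tol, p_init = p_init,
                 mu = mu, gamma_v = gamma_v, rho = rho,
                 lvedp_tol = lvedp_tol, stride = as.integer(stride)),
            class = "sim_control")
}

# assemble engine argument lists (CGS) from the user-facing objects
.engine_args <- function(cardiac, valve, tree, control) {
  g <- .discretize(tree, control$dx_cm, control$mu, control$gamma_v,
                   control$rho)
  dt <- control$dt
  if (is.null(dt)) dt <- min(.auto_dt(g), control$dt_cap)
  dt <- cardiac$t_hp / ceiling(cardiac$t_hp / dt)
  ao <- if (is.null(valve$ao)) tree$area_prox_cm2[tree$parent_id == 0] else valve$ao
  if (valve$ava > ao)
    stop("valve area exceeds the unobstructed (root) area of the tree")
  pla0 <- if (is.null(cardiac$atrial_pressure)) cardiac$lvedp + 1
          else cardiac$atrial_pressure
  list(
    geom = g, dt = dt, ao = ao,
    cardiac = list(Ees = cardiac$ees * .MMHG, Eed = cardiac$eed * .MMHG,
                   T = cardiac$t_hp, tmax = cardiac$t_max,
                   LVEDP = cardiac$lvedp * .MMHG, Vd = cardiac$vd,
                   Pla = pla0 * .MMHG,
                   Rmit = cardiac$mitral_resistance * .MMHG,
                   atrial_auto = is.null(cardiac$atrial_pressure),
                   lvedp_tol = control$lvedp_tol * .MMHG,
                   en_type = if (identical(cardiac$en, "hill")) 1L else 0L,
                   en_rel = cardiac$en_rel,
                   en_n1 = cardiac$en_shape[["n1"]],
                   en_n2 = cardiac$en_shape[["n2"]],
                   en_a1 = cardiac$en_shape[["a1"]],
                   en_a2 = cardiac$en_shape[["a2"]]),
    valve = list(Ames = valve$ava, leff = valve$leff, Ao = ao,
                 Kt = valve$kt, Kvo = valve$kvo,
                 Kvc = if (is.null(valve$kvc)) valve$kvo else valve$kvc,
                 zeta_min = valve$zeta_min))
}

#' Run the coupled heart-valve-arterial model to periodic steady state
#'
#' Simulates cardiac cycles until stroke volume and mean aortic pressure
#' change by less than the control tolerance between consecutive cycles
#' (and, when the atrial pressure is auto-tuned, until the end-diastolic
#' pressure matches its target).  Returns the last cycle's waveforms and
#' hemodynamic summary.
#'
#' @param cardiac A [cardiac_params()] object.
#' @param valve A [valve_params()] object; a `NULL` opening coefficient
#'   `kvo` triggers automatic calibration via [calibrate_valve_rates()].
#' @param tree An `av_tree` geometry (default: the packaged 24-segment
#'   synthetic tree).
#' @param control A [sim_control()] object.
#' @param state Optional warm-start state from a previous `av_sim` run on
#'   the same discretization.
#' @return An object of class `av_sim` with elements `waveforms` (one
#'   cycle: `t`, `p_lv`, `p_ao`, `q_av`, `zeta`, `v_lv`, `tpg`),
#'   `summary` (a `hemo_summary`), `cycles` (per-cycle convergence
#'   metrics), `converged`, `state`, and the configuration.
#' @examples
#' \donttest{
#' sim <- av_simulate(cardiac_params(), valve_params(ava = 0.6, kvo = 0.3))
#' summary(sim)
#' }
#' @export
av_simulate <- function(cardiac = cardiac_params(),
                        valve = valve_params(),
                        tree = default_tree(),
                        control = sim_control(),
                        state = NULL) {
  stopifnot(inherits(cardiac, "cardiac_params"),
            inherits(valve, "valve_params"))
  if (is.null(valve$kvo)) {
    cal <- calibrate_valve_rates(cardiac, valve, tree, control)
    valve$kvo <- cal$kvo
    valve$kvc <- cal$kvo
  }
  ea <- .engine_args(cardiac, valve, tree, control)
  ctrl <- list(dt = ea$dt, max_cycles = control$max_cycles,
               tol = control$tol, P_init = control$p_init * .MMHG,
               mode = 0L, stride = control$stride, probes = integer(0))
  # retry with a finer step if the advective velocity of an extreme case
  # exceeds the CFL margin assumed by the automatic step selection
  out <- NULL
  for (try in 1:3) {
    out <- tryCatch(cpp_run(ea$geom, ea$cardiac, ea$valve, ctrl, state),
                    error = function(e) e)
    if (!inherits(out, "error")) break
    if (!grepl("CFL", conditionMessage(out)) || try == 3) stop(out)
    ctrl$dt <- cardiac$t_hp / ceiling(cardiac$t_hp / (ctrl$dt / 1.5))
  }

  wf <- data.frame(t = out$waves$t,
                   p_lv = out$waves$p_lv / .MMHG,
                   p_ao = out$waves$p_ao / .MMHG,
                   q_av = out$waves$q_av,
                   zeta = out$waves$zeta,
                   v_lv = out$waves$v_lv)
  wf$tpg <- wf$p_lv - wf$p_ao
  cyc <- data.frame(sv = out$cycles$sv,
                    map = out$cycles$map / .MMHG,
                    edp = out$cycles$edp / .MMHG,
                    pla = out$cycles$pla / .MMHG,
                    max_zeta = out$cycles$max_zeta,
                    vol_in = out$cycles$vol_in,
                    vol_out = out$cycles$vol_out,
                    tree_vol0 = out$cycles$tree_vol0,
                    tree_vol1 = out$cycles$tree_vol1,
                    p_min = out$cycles$p_min / .MMHG,
                    p_max = out$cycles$p_max / .MMHG)
  summ <- summarize_cycle(wf, t_hp = cardiac$t_hp,
                          zeta_min = valve$zeta_min)
  valve$ao <- ea$ao
  structure(list(waveforms = wf, summary = summ, cycles = cyc,
                 converged = out$converged, n_cycles = out$n_cycles,
                 dt = out$dt, state = out$state,
                 cardiac = cardiac, valve = valve, tree = tree,
                 control = control),
            class = "av_sim")
}

#' Hemodynamic summary of one converged cycle
#'
#' The ejection window is the longest contiguous interval with the valve
#' open (`zeta > zeta_min`) and forward transvalvular flow.  Mean and
#' maximum TPG are taken over that window; stroke volume integrates the
#' forward transvalvular flow over the cycle (the Doppler-equivalent
#' ejected volume; the small reverse closing volume is excluded);
#' acceleration time runs from ejection onset to peak flow.
#'
#' @param wf Waveform data.frame with columns `t`, `p_lv`, `p_ao`,
#'   `q_av`, `zeta` (and optionally `v_lv`).
#' @param t_hp Heart period, s (defaults to the waveform span).
#' @param zeta_min Valve-state floor defining "open".
#' @return An object of class `hemo_summary`: sv (mL), co (mL/s), map,
#'   sbp, dbp, pp, mbp, mean_tpg, max_tpg (mmHg), ejection_time,
#'   acceleration_time (s), and `degenerate` (no ejection detected).
#' @export
summarize_cycle <- function(wf, t_hp = NULL, zeta_min = 1e-4) {
  stopifnot(all(c("t", "p_lv", "p_ao", "q_av", "zeta") %in% names(wf)))
  n <- nrow(wf)
  dtv <- diff(wf$t)
  dt <- stats::median(dtv)
  if (is.null(t_hp)) t_hp <- wf$t[n] - wf$t[1] + dt
  sv <- sum(pmax(wf$q_av, 0)) * dt
  co <- sv / t_hp
  map <- mean(wf$p_ao)
  sbp <- max(wf$p_ao); dbp <- min(wf$p_ao)

  open <- wf$zeta > zeta_min & wf$q_av > 0
  runs <- rle(open)
  if (!any(runs$values)) {
    ej <- integer(0)
  } else {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    k <- which(runs$values)[which.max(runs$lengths[runs$values])]
    ej <- starts[k]:ends[k]
  }
  degenerate <- length(ej) < 3
  if (!degenerate) {
    tpg <- wf$p_lv[ej] - wf$p_ao[ej]
    mean_tpg <- mean(tpg)
    max_tpg <- max(tpg)
    ejection_time <- length(ej) * dt
    acceleration_time <- (which.max(wf$q_av[ej]) - 1) * dt
  } else {
    mean_tpg <- max_tpg <- ejection_time <- acceleration_time <- NA_real_
  }
  structure(list(sv = sv, co = co, map = map, mbp = map,
                 sbp = sbp, dbp = dbp, pp = sbp - dbp,
                 mean_tpg = mean_tpg, max_tpg = max_tpg,
                 ejection_time = ejection_time,
                 acceleration_time = acceleration_time,
                 degenerate = degenerate),
            class = "hemo_summary")
}

#' Estimate afterload indices from simulated waveforms
#'
#' The clinical estimators: TVR as mean aortic pressure over cardiac
#' output, TAC as stroke volume over pulse pressure.
#'
#' @param x An `av_sim` object or a `hemo_summary`.
#' @return List with `tvr` (mmHg s/mL) and `tac` (mL/mmHg).
#' @export
estimate_afterload <- function(x) {
  s <- if (inherits(x, "av_sim")) x$summary else x
  stopifnot(inherits(s, "hemo_summary"))
  if (s$pp <= 0) stop("pulse pressure must be positive")
  list(tvr = s$map / s$co, tac = s$sv / s$pp)
}

#' Run a tree with prescribed root inflow
#'
#' Replaces the ventricle/valve with a prescribed inflow waveform at the
#' root: the workhorse for verifying the 1D solver (wave speeds, friction
#' pressure drops, junction reflections) on simple geometries.
#'
#' @param tree An `av_tree` geometry.
#' @param inflow Function of time (s) returning flow (mL/s), or a numeric
#'   vector sampled at the solver step.
#' @param t_end Duration, s (ignored when `inflow` is a vector).
#' @param probes Data.frame with columns `segment` (id) and `pos_cm`
#'   (distance from the proximal end) at which to record pressure/flow.
#' @param control A [sim_control()] object.
#' @return List with `t`, matrices `p` and `q` (columns = probes), the
#'   solver step `dt`, and the final `state`.
#' @export
simulate_inflow <- function(tree, inflow, t_end = 1,
                            probes = NULL, control = sim_control()) {
  g <- .discretize(tree, control$dx_cm, control$mu, control$gamma_v,
                   control$rho)
  dt <- control$dt
  if (is.null(dt)) dt <- min(.auto_dt(g), control$dt_cap)
  qv <- if (is.function(inflow)) inflow(seq(0, t_end, by = dt)) else inflow
  pidx <- integer(0)
  if (!is.null(probes)) {
    pidx <- vapply(seq_len(nrow(probes)), function(i) {
      s <- match(probes$segment[i], tree$id)
      j <- round(probes$pos_cm[i] / g$dx[s])
      j <- max(0, min(g$nn[s] - 1, j))
      as.integer(g$off[s] + j)
    }, integer(1))
  }
  cardiac <- list(Ees = 1, Eed = 0.5, T = t_end, tmax = t_end / 3,
                  LVEDP = 10 * .MMHG, Vd = 0, Pla = 10 * .MMHG,
                  Rmit = .MMHG, atrial_auto = FALSE, lvedp_tol = .MMHG,
                  en_type = 0L, en_rel = 0.9,
                  en_n1 = 1.32, en_n2 = 8, en_a1 = 0.269, en_a2 = 0.55)
  valve <- list(Ames = 1, leff = 1.5, Ao = 2, Kt = 1.5, Kvo = 0.1,
                Kvc = 0.1, zeta_min = 1e-4)
  ctrl <- list(dt = dt, max_cycles = 1L, tol = 1e-3,
               P_init = control$p_init * .MMHG, mode = 1L,
               stride = control$stride, inflow = qv, probes = pidx)
  out <- cpp_run(g, cardiac, valve, ctrl, NULL)
  p <- if (length(pidx)) sapply(out$probe_p, function(v) v / .MMHG) else NULL
  q <- if (length(pidx)) sapply(out$probe_q, identity) else NULL
  list(t = out$waves$t, p = p, q = q, dt = dt, state = out$state,
       root_p = out$waves$p_ao / .MMHG,
       cycles = lapply(out$cycles, function(v) v),
       vol_in = out$cycles$vol_in, vol_out = out$cycles$vol_out)
}
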