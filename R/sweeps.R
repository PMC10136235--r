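#' Baseline configuration of the sensitivity study
#'
#' The held-fixed operating point from which each determinant is varied.
#' Cardiac values are anchored to the validation patient (Ees 3.3, Eed
#' 0.1 mmHg/mL, LVEDP 11 mmHg, Vd 39.3 mL); afterload sits mid-range of
#' the physiological sweep intervals (TVR 1.2 mmHg s/mL, TAC 1.1
#' mL/mmHg); heart period 0.8 s with peak elastance at 0.30 s.
#'
#' @param ... Named overrides of any baseline entry.
#' @return A named list.
#' @export
baseline_config <- function(...) {
  base <- list(ees = 3.3, eed = 0.1, t_hp = 0.8, t_max_frac = 0.375,
               lvedp = 11, vd = 39.3, tvr = 1.2, tac = 1.1)
  mod <- list(...)
  stopifnot(all(names(mod) %in% names(base)))
  base[names(mod)] <- mod
  base
}

#' Specification of a one-parameter sensitivity sweep
#'
#' @param param One of `"ees"`, `"eed"`, `"tvr"`, `"tac"`.
#' @param min,max Sweep range in the parameter's natural units.
#' @param n Number of evenly spaced values (default 10).
#' @param ava Aortic-valve-area levels, cm^2.
#' @param baseline Held-fixed values for all other parameters, see
#'   [baseline_config()].
#' @param coupling `"none"`, or `"hyperbolic"` to co-vary TAC with TVR
#'   along `tac = constant / tvr` (adjusted-TVR sweep).
#' @param couple_constant Hyperbola constant, mmHg s^2 x (mL/mmHg)...;
#'   defaults to the baseline product `tvr * tac`.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(param = c("ees", "eed", "tvr", "tac"),
                       min, max, n = 10,
                       ava = c(0.6, 1.0, 1.5, 2.0),
                       baseline = baseline_config(),
                       coupling = c("none", "hyperbolic"),
                       couple_constant = NULL) {
  param <- match.arg(param)
  coupling <- match.arg(coupling)
  stopifnot(min < max, n >= 3, all(ava > 0))
  if (coupling == "hyperbolic" && param != "tvr")
    stop("hyperbolic coupling applies to the tvr sweep")
  if (coupling == "hyperbolic" && is.null(couple_constant))
    couple_constant <- baseline$tvr * baseline$tac
  structure(list(param = param, min = min, max = max, n = n, ava = ava,
                 baseline = baseline, coupling = coupling,
                 couple_constant = couple_constant,
                 values = seq(min, max, length.out = n)),
            class = "sweep_spec")
}

#' The study's default sweep battery
#'
#' Four independent sweeps (Ees 0.5-6 mmHg/mL, Eed 0.03-0.31 mmHg/mL,
#' TVR 0.6-1.8 mmHg s/mL, TAC 0.5-2 mL/mmHg; 10 evenly spaced values
#' each) over four AVA levels (160 cases), plus the hyperbolically
#' coupled TAC-TVR sweep (40 additional cases).
#'
#' @param baseline See [baseline_config()].
#' @return Named list of [sweep_spec()] objects (`ees`, `eed`, `tvr`,
#'   `tac`, `tvr_adj`).
#' @export
default_sweeps <- function(baseline = baseline_config()) {
  list(
    ees = sweep_spec("ees", 0.5, 6, baseline = baseline),
    eed = sweep_spec("eed", 0.03, 0.31, baseline = baseline),
    tvr = sweep_spec("tvr", 0.6, 1.8, baseline = baseline),
    tac = sweep_spec("tac", 0.5, 2, baseline = baseline),
    tvr_adj = sweep_spec("tvr", 0.6, 1.8, baseline = baseline,
                         coupling = "hyperbolic"))
}

#' Hyperbolic TAC-TVR coupling
#'
#' In vivo the two afterload components do not vary independently; the
#' coupled sweep ties them along `tac = constant / tvr`.
#'
#' @param tvr Total vascular resistance, mmHg s/mL.
#' @param constant Hyperbola constant (product of baseline TVR and TAC by
#'   default).
#' @return TAC, mL/mmHg.
#' @export
hyperbolic_couple <- function(tvr, constant) {
  stopifnot(all(tvr > 0))
  constant / tvr
}

#' Run a sensitivity sweep
#'
#' One calibrated, converged simulation per grid point and AVA level.
#' The valve rate coefficient is calibrated once per AVA level at the
#' baseline configuration; afterload is re-calibrated for every case so
#' the held-fixed (or coupled) parameters match their set values within
#' the calibration tolerance.  Failed cases are dropped with a warning;
#' more than 20% failures aborts.
#'
#' @param spec A [sweep_spec()].
#' @param tree Geometry (default packaged tree).
#' @param control A [sim_control()].
#' @param kvo_margin Factor applied to the calibrated minimal valve rate
#'   coefficient so the valve reliably reaches its full measured area
#'   during ejection (AVA as a controlled variable); opening times land
#'   in the echocardiographic range and the mean gradient is insensitive
#'   to the exact factor.
#' @param kvo_table Optional named numeric vector (names = AVA values)
#'   of pre-calibrated valve rate coefficients, bypassing the per-AVA
#'   calibration (they depend only on the AVA level and baseline).
#' @param quiet Suppress per-case progress output.
#' @return A data.frame of class `av_sweep` with one row per case:
#'   `param`, `value`, `ava_cm2`, `mean_tpg_mmhg`, `max_tpg_mmhg`,
#'   `sv_ml`, `map_mmhg`, `sbp_mmhg`, `dbp_mmhg`, `achieved_tvr`,
#'   `achieved_tac`, `ees`, `eed`.
#' @export
run_sweep <- function(spec, tree = default_tree(), control = sim_control(),
                      kvo_margin = 8, kvo_table = NULL, quiet = TRUE) {
  stopifnot(inherits(spec, "sweep_spec"))
  bl <- spec$baseline
  rows <- list()
  failures <- 0L
  for (ava in spec$ava) {
    # per-AVA valve-rate calibration at the baseline configuration
    cp0 <- .sweep_cardiac(spec, bl, value = NULL)
    vp0 <- valve_params(ava = ava)
    tree_a <- scale_afterload(tree, tvr = bl$tvr, tac = bl$tac)
    kvo <- if (!is.null(kvo_table) && !is.na(kvo_table[as.character(ava)]))
      kvo_table[[as.character(ava)]]
    else kvo_margin * calibrate_valve_rates(cp0, vp0, tree_a, control)$kvo
    vp0$kvo <- vp0$kvc <- kvo
    tree_cur <- tree_a
    for (v in spec$values) {
      cp <- .sweep_cardiac(spec, bl, value = v)
      targets <- .sweep_targets(spec, bl, value = v)
      res <- tryCatch(
        calibrate_case(cp, vp0, tree_cur, control,
                       tvr_target = targets$tvr, tac_target = targets$tac,
                       quiet = TRUE),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("case %s = %.3g at AVA %.2g failed: %s",
                        spec$param, v, ava, conditionMessage(res)))
        failures <- failures + 1L
        next
      }
      tree_cur <- res$tree  # warm start for the next grid point
      s <- res$sim$summary
      if (!quiet)
        message(sprintf("%s = %.3g, AVA %.2g: mean TPG %.1f mmHg, SV %.1f mL",
                        spec$param, v, ava, s$mean_tpg, s$sv))
      rows[[length(rows) + 1L]] <- data.frame(
        param = if (spec$coupling == "hyperbolic") "tvr_adj" else spec$param,
        value = v, ava_cm2 = ava,
        mean_tpg_mmhg = s$mean_tpg, max_tpg_mmhg = s$max_tpg,
        sv_ml = s$sv, map_mmhg = s$map, sbp_mmhg = s$sbp,
        dbp_mmhg = s$dbp,
        achieved_tvr = res$achieved$tvr, achieved_tac = res$achieved$tac,
        ees = cp$ees, eed = cp$eed)
    }
  }
  ncases <- length(spec$values) * length(spec$ava)
  if (failures > 0.2 * ncases)
    stop(sprintf("sweep aborted: %d of %d cases failed", failures, ncases))
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  class(out) <- c("av_sweep", "data.frame")
  out
}

.sweep_cardiac <- function(spec, bl, value = NULL) {
  ees <- bl$ees; eed <- bl$eed
  if (!is.null(value)) {
    if (spec$param == "ees") ees <- value
    if (spec$param == "eed") eed <- value
  }
  cardiac_params(ees = ees, eed = eed, t_hp = bl$t_hp,
                 t_max = bl$t_max_frac * bl$t_hp,
                 lvedp = bl$lvedp, vd = bl$vd)
}

.sweep_targets <- function(spec, bl, value = NULL) {
  tvr <- bl$tvr; tac <- bl$tac
  if (!is.null(value)) {
    if (spec$param == "tvr") {
      tvr <- value
      if (spec$coupling == "hyperbolic")
        tac <- hyperbolic_couple(value, spec$couple_constant)
    }
    if (spec$param == "tac") tac <- value
  }
  list(tvr = tvr, tac = tac)
}

#' Ordinary-least-squares effect of a determinant on mean TPG
#'
#' Fits `y ~ x` by OLS and reports the slope (per natural unit), its
#' standard error, the two-sided t-test p-value, and the effect per 10%
#' increase of the determinant (`beta * 0.1 * baseline`, with the
#' baseline operating value of the determinant as reference).
#'
#' @param x Determinant values (natural units).
#' @param y Mean TPG, mmHg.
#' @param baseline Reference value for the per-10% scaling; defaults to
#'   the mean of `x`.
#' @return List of class `av_ols`: `beta`, `se`, `p`, `r2`, `n`,
#'   `baseline`, `beta_per_10pct`, `se_per_10pct`.
#' @export
tpg_ols <- function(x, y, baseline = mean(x)) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("regressor is constant (rank deficient)")
  fit <- lm(y ~ x)
  # summary.lm warns on an exactly collinear response; a perfect fit is a
  # legitimate input here (noise-free sweeps), so the SE is floored instead
  smry <- suppressWarnings(summary(fit))
  cf <- smry$coefficients
  beta <- cf["x", "Estimate"]
  se <- max(cf["x", "Std. Error"], .Machine$double.eps)
  p <- cf["x", "Pr(>|t|)"]
  structure(list(beta = beta, se = se, p = p,
                 r2 = smry$r.squared, n = length(x),
                 baseline = baseline,
                 beta_per_10pct = beta * 0.1 * baseline,
                 se_per_10pct = se * 0.1 * baseline),
            class = "av_ols")
}

#' Per-determinant effect table across AVA levels
#'
#' Assembles the per-10% regression effects (with standard errors and
#' p-values) of each determinant on mean TPG, one column set per AVA
#' level: rows Ees, Eed, TAC, TVR and the hyperbolically adjusted TVR.
#' The per-10% scaling uses each determinant's baseline operating value.
#'
#' @param sweeps Named list of `av_sweep` results, as produced by running
#'   [default_sweeps()] through [run_sweep()] (names `ees`, `eed`, `tac`,
#'   `tvr`, `tvr_adj`).
#' @return A data.frame of class `av_table1` with columns `param`,
#'   `ava_cm2`, `beta_per_10pct`, `se_per_10pct`, `p`, `beta_per_unit`,
#'   `baseline`.
#' @export
table1_report <- function(sweeps) {
  order_rows <- c("ees", "eed", "tac", "tvr", "tvr_adj")
  rows <- list()
  for (nm in intersect(order_rows, names(sweeps))) {
    sw <- sweeps[[nm]]
    stopifnot(inherits(sw, "av_sweep"))
    spec <- attr(sw, "spec")
    bl_value <- spec$baseline[[spec$param]]
    for (ava in sort(unique(sw$ava_cm2))) {
      d <- sw[sw$ava_cm2 == ava, ]
      fit <- tpg_ols(d$value, d$mean_tpg_mmhg, baseline = bl_value)
      rows[[length(rows) + 1L]] <- data.frame(
        param = nm, ava_cm2 = ava,
        beta_per_10pct = fit$beta_per_10pct,
        se_per_10pct = fit$se_per_10pct, p = fit$p,
        beta_per_unit = fit$beta, baseline = bl_value)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("av_table1", "data.frame")
  out
}

#' Stroke volume versus mean TPG at fixed valve area
#'
#' Varies contractility over a grid to span stroke volume at a fixed
#' AVA, returning the (SV, mean TPG) relation: the in-silico analogue of
#' a dobutamine challenge moving a patient along the curve of their own
#' valve.
#'
#' @param ava Valve area, cm^2.
#' @param ees_grid Contractility grid, mmHg/mL.
#' @param tree,control,baseline Configuration.
#' @return Data.frame with `ees`, `sv_ml`, `mean_tpg_mmhg`.
#' @export
sv_tpg_curve <- function(ava, ees_grid = seq(1, 6, length.out = 6),
                         tree = default_tree(), control = sim_control(),
                         baseline = baseline_config()) {
  spec <- sweep_spec("ees", min(ees_grid), max(ees_grid),
                     n = length(ees_grid), ava = ava, baseline = baseline)
  spec$values <- ees_grid
  sw <- run_sweep(spec, tree, control)
  data.frame(ees = sw$value, sv_ml = sw$sv_ml,
             mean_tpg_mmhg = sw$mean_tpg_mmhg)
}

#' Blood-pressure versus TPG map over afterload combinations
#'
#' Full factorial over TAC and TVR grids at fixed ventricular function:
#' demonstrates that distinct mean TPGs coexist with comparable
#' peripheral pressures.
#'
#' @param tac_grid,tvr_grid Afterload grids.
#' @param ava Valve area, cm^2.
#' @param tree,control,baseline Configuration.
#' @param kvo_margin See [run_sweep()].
#' @return Data.frame with `tvr`, `tac`, `sbp_mmhg`, `mbp_mmhg`,
#'   `mean_tpg_mmhg`, `sv_ml`.
#' @export
bp_tpg_map <- function(tac_grid = seq(0.5, 2, length.out = 4),
                       tvr_grid = seq(0.6, 1.8, length.out = 4),
                       ava = 0.6, tree = default_tree(),
                       control = sim_control(),
                       baseline = baseline_config(), kvo_margin = 8) {
  cp <- cardiac_params(ees = baseline$ees, eed = baseline$eed,
                       t_hp = baseline$t_hp,
                       t_max = baseline$t_max_frac * baseline$t_hp,
                       lvedp = baseline$lvedp, vd = baseline$vd)
  tree0 <- scale_afterload(tree, tvr = baseline$tvr, tac = baseline$tac)
  vp <- valve_params(ava = ava)
  vp$kvo <- vp$kvc <- kvo_margin *
    calibrate_valve_rates(cp, vp, tree0, control)$kvo
  rows <- list()
  tree_cur <- tree0
  for (tvr in tvr_grid) for (tac in tac_grid) {
    cc <- calibrate_case(cp, vp, tree_cur, control,
                         tvr_target = tvr, tac_target = tac, quiet = TRUE)
    tree_cur <- cc$tree
    s <- cc$sim$summary
    rows[[length(rows) + 1L]] <- data.frame(
      tvr = tvr, tac = tac, sbp_mmhg = s$sbp, mbp_mmhg = s$mbp,
      mean_tpg_mmhg = s$mean_tpg, sv_ml = s$sv)
  }
  do.call(rbind, rows)
}
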