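# S3 methods for the simulation and sweep result classes.

#' @export
print.av_sim <- function(x, ...) {
  cat("Coupled heart-valve-arterial simulation\n")
  cat(sprintf("  AVA %.2f cm^2, Ees %.2f, Eed %.3f mmHg/mL, T %.2f s\n",
              x$valve$ava, x$cardiac$ees, x$cardiac$eed, x$cardiac$t_hp))
  cat(sprintf("  %s after %d cycles (dt %.2e s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_cycles, x$dt))
  s <- x$summary
  if (!s$degenerate)
    cat(sprintf("  mean TPG %.1f mmHg (max %.1f), SV %.1f mL, MAP %.1f mmHg\n",
                s$mean_tpg, s$max_tpg, s$sv, s$map))
  else cat("  degenerate run: no ejection detected\n")
  invisible(x)
}

#' @export
summary.av_sim <- function(object, ...) object$summary

#' @export
coef.av_sim <- function(object, ...) {
  s <- object$summary
  c(mean_tpg = s$mean_tpg, max_tpg = s$max_tpg, sv = s$sv, co = s$co,
    map = s$map, sbp = s$sbp, dbp = s$dbp, pp = s$pp,
    ejection_time = s$ejection_time,
    acceleration_time = s$acceleration_time)
}

#' @export
print.hemo_summary <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate cycle: no ejection detected\n")
    return(invisible(x))
  }
  cat("Hemodynamic summary (one cycle)\n")
  cat(sprintf("  SV %.1f mL, CO %.1f mL/s, ejection %.0f ms (accel. %.0f ms)\n",
              x$sv, x$co, 1000 * x$ejection_time,
              1000 * x$acceleration_time))
  cat(sprintf("  aortic %0.f/%0.f mmHg (MAP %.1f, PP %.1f)\n",
              x$sbp, x$dbp, x$map, x$pp))
  cat(sprintf("  TPG mean %.1f mmHg, max %.1f mmHg\n", x$mean_tpg, x$max_tpg))
  invisible(x)
}

#' Plot method for coupled simulations
#'
#' Two panels: ventricular and aortic pressure (with the TPG shaded
#' implicitly by their separation) and transvalvular flow with the valve
#' state.
#'
#' @param x An `av_sim` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.av_sim <- function(x, ...) {
  wf <- x$waveforms
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 4))
  on.exit(par(op))
  plot(wf$t, wf$p_lv, type = "l", col = "firebrick",
       xlab = "time (s)", ylab = "pressure (mmHg)",
       ylim = range(c(wf$p_lv, wf$p_ao)), ...)
  lines(wf$t, wf$p_ao, col = "navy")
  legend("topright", bty = "n", lty = 1, col = c("firebrick", "navy"),
         legend = c("LV", "aorta"))
  plot(wf$t, wf$q_av, type = "l", col = "darkgreen",
       xlab = "time (s)", ylab = "valve flow (mL/s)")
  par(new = TRUE)
  plot(wf$t, wf$zeta, type = "l", lty = 2, axes = FALSE,
       xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("valve state", side = 4, line = 2.5)
  invisible(x)
}

#' @export
print.av_sweep <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Sensitivity sweep: %s over [%.3g, %.3g] (%d values), AVA {%s}\n",
              spec$param, spec$min, spec$max, spec$n,
              paste(spec$ava, collapse = ", ")))
  if (spec$coupling == "hyperbolic")
    cat(sprintf("  TAC coupled as %.3g / TVR\n", spec$couple_constant))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot method for sensitivity sweeps
#'
#' Mean TPG versus the swept determinant, one line per AVA level.
#'
#' @param x An `av_sweep` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.av_sweep <- function(x, ...) {
  spec <- attr(x, "spec")
  avas <- sort(unique(x$ava_cm2))
  cols <- grDevices::hcl.colors(max(length(avas), 2), "Dark 2")
  plot(range(x$value), range(x$mean_tpg_mmhg), type = "n",
       xlab = spec$param, ylab = "mean TPG (mmHg)", ...)
  for (i in seq_along(avas)) {
    d <- x[x$ava_cm2 == avas[i], ]
    lines(d$value, d$mean_tpg_mmhg, type = "b", col = cols[i], pch = 16)
  }
  legend("topright", bty = "n", col = cols[seq_along(avas)], lty = 1,
         pch = 16, legend = sprintf("AVA %.1f", avas))
  invisible(x)
}

#' @export
print.av_ols <- function(x, ...) {
  cat(sprintf("OLS effect on mean TPG: beta %.3g +/- %.3g per unit (p %.3g)\n",
              x$beta, x$se, x$p))
  cat(sprintf("  per 10%% of baseline (%.3g): %.3g +/- %.3g mmHg\n",
              x$baseline, x$beta_per_10pct, x$se_per_10pct))
  invisible(x)
}

#' @export
print.av_table1 <- function(x, ...) {
  cat("Per-10% effect of each determinant on mean TPG, by AVA level\n")
  avas <- sort(unique(x$ava_cm2))
  for (p in unique(x$param)) {
    cells <- vapply(avas, function(a) {
      r <- x[x$param == p & x$ava_cm2 == a, ]
      if (!nrow(r)) return("      -      ")
      sprintf("%6.2f (%.2f)", r$beta_per_10pct, r$se_per_10pct)
    }, character(1))
    cat(sprintf("  %-8s %s\n", p, paste(cells, collapse = "  ")))
  }
  cat(sprintf("  %-8s %s\n", "AVA", paste(sprintf("%10.1f cm2", avas),
                                          collapse = "  ")))
  invisible(x)
}
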