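#' Left-ventricular (varying elastance) parameters
#'
#' The ventricle is modelled with a prescribed periodic elastance
#' \eqn{E(t) = (E_{es} - E_{ed}) E_N(t) + E_{ed}} acting on the volume above
#' the dead volume: \eqn{P_{LV}(t) = E(t) (V_{LV}(t) - V_d)}.  \eqn{E_N} is a
#' smooth normalized curve (product of two Hill functions) rescaled in time
#' so its maximum (value 1) falls at `t_max` and \eqn{E_N(0) = 0}.
#'
#' Two normalized-curve families are available.  The default (`en =
#' "cosine"`) is a half-cosine upstroke followed by a cosine relaxation
#' lasting `en_rel * t_max`: it emulates the published population-average
#' normalized elastance (roughly half the peak at ~1.5 t_max, fully
#' relaxed by ~2 t_max) and relaxes *exactly* to zero within diastole, so
#' the diastolic stiffness floor is `eed` for every contractility.  `en =
#' "hill"` is a smooth double-Hill product with shape parameters
#' `en_shape`; its power-law tail leaves a small residual elastance deep
#' into diastole that scales with `ees`, which impairs filling for
#' strongly contractile ventricles.
#'
#' Diastolic filling is closed with a constant-pressure atrium behind a
#' linear diode resistance; when `atrial_pressure` is `NULL` it is
#' auto-tuned during simulation so that the end-diastolic left-ventricular
#' pressure matches `lvedp`.
#'
#' @param ees End-systolic elastance, mmHg/mL.  Contractility index.
#' @param eed End-diastolic elastance, mmHg/mL.  Diastolic stiffness index.
#' @param t_hp Heart period, s.
#' @param t_max Time of maximum elastance, s (default 0.375 of the
#'   period, i.e. 0.30 s at 75 bpm, matching measured human time to peak
#'   elastance).
#' @param lvedp Target left-ventricular end-diastolic pressure, mmHg.
#' @param vd Dead volume, mL (volume intercept of the elastance relation).
#' @param atrial_pressure Filling source pressure, mmHg, or `NULL` to
#'   auto-tune until end-diastolic pressure reaches `lvedp`.
#' @param mitral_resistance Linear filling resistance, mmHg s/mL.
#' @param en Normalized-elastance curve family: `"cosine"` (default) or
#'   `"hill"`.
#' @param en_rel Relaxation duration of the cosine curve, as a fraction
#'   of `t_max`.
#' @param en_shape Named numeric vector of double-Hill shape parameters
#'   `n1`, `n2`, `a1`, `a2` (exponents and time constants as fractions of
#'   the heart period); used when `en = "hill"`.
#' @return An object of class `cardiac_params`.
#' @examples
#' p <- cardiac_params(ees = 3.3, eed = 0.1)
#' elastance_at(p$t_max, p)  # = ees at the elastance peak
#' @export
cardiac_params <- function(ees = 3.3, eed = 0.1, t_hp = 0.8,
                           t_max = 0.375 * t_hp, lvedp = 11, vd = 39.3,
                           atrial_pressure = NULL,
                           mitral_resistance = 0.005,
                           en = c("cosine", "hill"), en_rel = 0.9,
                           en_shape = c(n1 = 1.32, n2 = 8,
                                        a1 = 0.269, a2 = 0.55)) {
  en <- match.arg(en)
  stopifnot(en_rel > 0, t_max * (1 + en_rel) < t_hp)
  stopifnot(is.numeric(ees), is.numeric(eed), length(ees) == 1L)
  if (!(ees > eed && eed > 0))
    stop("cardiac parameters require ees > eed > 0 (got ees = ", ees,
         ", eed = ", eed, ")")
  if (!(t_max > 0 && t_max < t_hp))
    stop("t_max must lie inside the heart period (0, ", t_hp, ")")
  if (vd < 0) stop("dead volume vd must be >= 0")
  if (lvedp <= 0) stop("lvedp must be > 0")
  if (mitral_resistance <= 0) stop("mitral_resistance must be > 0")
  sh <- en_shape[c("n1", "n2", "a1", "a2")]
  if (anyNA(sh)) stop("en_shape must provide n1, n2, a1, a2")
  structure(list(ees = ees, eed = eed, t_hp = t_hp, t_max = t_max,
                 lvedp = lvedp, vd = vd,
                 atrial_pressure = atrial_pressure,
                 mitral_resistance = mitral_resistance,
                 en = en, en_rel = en_rel, en_shape = sh),
            class = "cardiac_params")
}

#' Normalized elastance curve
#'
#' Evaluates the normalized elastance \eqn{E_N} as a function of time in
#' units of the time to peak elastance (`t_norm = t / t_max`), wrapped into
#' one heart period.  By construction \eqn{E_N(0) = 0} and
#' \eqn{E_N(1) = 1} (the curve maximum, at `t = t_max`).
#'
#' @param t_norm Dimensionless time `t / t_max`, any non-negative value.
#' @param t_max_frac `t_max / t_hp`: peak time as a fraction of the period.
#' @param en Curve family, see [cardiac_params()].
#' @param en_rel Cosine relaxation duration as a fraction of `t_max`.
#' @param en_shape Double-Hill shape parameters, see [cardiac_params()].
#' @return Values in \[0, 1\].
#' @export
normalized_elastance <- function(t_norm, t_max_frac = 0.375,
                                 en = c("cosine", "hill"), en_rel = 0.9,
                                 en_shape = c(n1 = 1.32, n2 = 8,
                                              a1 = 0.269, a2 = 0.55)) {
  en <- match.arg(en)
  stopifnot(all(t_norm >= 0), t_max_frac > 0, t_max_frac < 1)
  phi <- t_norm * t_max_frac
  if (en == "cosine")
    cpp_en_curve_cos(phi, t_max_frac, en_rel)
  else
    cpp_en_curve(phi, t_max_frac, en_shape[["n1"]], en_shape[["n2"]],
                 en_shape[["a1"]], en_shape[["a2"]])
}

#' Instantaneous left-ventricular elastance
#'
#' \eqn{E(t) = (E_{es} - E_{ed}) E_N(t) + E_{ed}}, so the maximum over the
#' cycle is `ees` (at `t_max`) and the diastolic floor is `eed`.
#'
#' @param t Time, s (wrapped into the heart period).
#' @param p A [cardiac_params()] object.
#' @return Elastance, mmHg/mL.
#' @export
elastance_at <- function(t, p) {
  stopifnot(inherits(p, "cardiac_params"))
  en <- normalized_elastance(t / p$t_max, p$t_max / p$t_hp,
                             en = p$en, en_rel = p$en_rel,
                             en_shape = p$en_shape)
  (p$ees - p$eed) * en + p$eed
}

#' Left-ventricular pressure from the elastance relation
#'
#' \eqn{P_{LV} = E(t) (V - V_d)}.
#'
#' @param t Time, s.
#' @param v Ventricular volume, mL; must be at least the dead volume.
#' @param p A [cardiac_params()] object.
#' @return Pressure, mmHg.
#' @export
lv_pressure <- function(t, v, p) {
  stopifnot(inherits(p, "cardiac_params"))
  if (any(v < p$vd))
    stop("nonphysical ventricular state: volume below dead volume vd")
  elastance_at(t, p) * (v - p$vd)
}

#' End-diastolic volume implied by the elastance relation
#'
#' Inverts \eqn{LVEDP = E_{ed} (V_{ed} - V_d)}.
#'
#' @param p A [cardiac_params()] object.
#' @return Volume, mL.
#' @export
end_diastolic_volume <- function(p) {
  stopifnot(inherits(p, "cardiac_params"))
  p$lvedp / p$eed + p$vd
}

#' @export
print.cardiac_params <- function(x, ...) {
  cat("Varying-elastance ventricle\n")
  cat(sprintf("  Ees %.3g, Eed %.3g mmHg/mL; T %.3g s, t_max %.3g s\n",
              x$ees, x$eed, x$t_hp, x$t_max))
  cat(sprintf("  LVEDP %.3g mmHg, Vd %.3g mL, atrium %s\n", x$lvedp, x$vd,
              if (is.null(x$atrial_pressure)) "auto-tuned"
              else sprintf("%.3g mmHg", x$atrial_pressure)))
  invisible(x)
}
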