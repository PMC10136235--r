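#' Dynamic stenotic aortic valve parameters
#'
#' The instantaneous transvalvular pressure gradient is the sum of an
#' inertial and a turbulent (Bernoulli) loss,
#' \eqn{\Delta P = L \, dQ/dt + \beta Q |Q|}, with
#' \eqn{L = \rho l_{eff} / A_{eff}} and
#' \eqn{\beta = K_t (\rho/2) (1/A_{eff} - 1/A_o)^2}.  The effective orifice
#' is \eqn{A_{eff} = A_{mes} \zeta(t)} with the valve state
#' \eqn{0 \le \zeta \le 1} driven by the instantaneous gradient:
#' opening at rate \eqn{(1-\zeta) K_{vo} \Delta P} when \eqn{\Delta P \ge 0}
#' and closing at rate \eqn{\zeta K_{vc} \Delta P} otherwise.
#'
#' @param ava Maximal (anatomical/measured) valve area \eqn{A_{mes}}, cm^2.
#' @param leff Effective valve length, cm.
#' @param ao Unobstructed channel area (ascending aorta cross-section),
#'   cm^2; `NULL` takes the proximal area of the root segment at
#'   simulation time.
#' @param kt Dimensionless turbulence coefficient (1.5).
#' @param kvo Opening rate coefficient, 1/(mmHg s); `NULL` requests
#'   automatic calibration (smallest rate achieving full opening, see
#'   [calibrate_valve_rates()]).
#' @param kvc Closing rate coefficient; defaults to `kvo` (opening and
#'   closure rates assumed equal).
#' @param rho Blood density, g/cm^3.
#' @param zeta_min Small floor on the valve state preventing singular
#'   inertance/Bernoulli coefficients when closed.
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(ava = 0.6, leff = 1.5, ao = NULL, kt = 1.5,
                         kvo = NULL, kvc = kvo, rho = 1.06,
                         zeta_min = 1e-4) {
  if (!(ava > 0)) stop("ava must be > 0")
  if (!is.null(ao) && ava > ao)
    stop("valve area ava must not exceed the unobstructed area ao")
  if (kt < 0) stop("kt must be >= 0")
  if (!is.null(kvo) && kvo <= 0) stop("kvo must be > 0")
  if (!is.null(kvc) && kvc <= 0) stop("kvc must be > 0")
  if (leff < 0) stop("leff must be >= 0")
  if (rho <= 0) stop("rho must be > 0")
  structure(list(ava = ava, leff = leff, ao = ao, kt = kt,
                 kvo = kvo, kvc = kvc, rho = rho, zeta_min = zeta_min),
            class = "valve_params")
}

#' Effective valve orifice area
#'
#' \eqn{A_{eff} = A_{mes} \max(\zeta, \zeta_{min})}; the small floor keeps
#' the inertance and Bernoulli coefficients finite when the valve closes.
#'
#' @param zeta Valve state in \[0, 1\].
#' @param ames Maximal valve area, cm^2.
#' @param zeta_min State floor.
#' @return Area, cm^2.
#' @export
effective_area <- function(zeta, ames, zeta_min = 1e-4) {
  stopifnot(all(zeta >= 0), all(zeta <= 1))
  ames * pmax(zeta, zeta_min)
}

#' Valve inertance
#'
#' \eqn{L = \rho l_{eff} / A_{eff}}, reported in clinical units.
#'
#' @param aeff Effective orifice area, cm^2.
#' @param leff Effective valve length, cm.
#' @param rho Blood density, g/cm^3.
#' @return Inertance, mmHg s^2/mL.
#' @export
valve_inertance <- function(aeff, leff, rho = 1.06) {
  stopifnot(all(aeff > 0))
  rho * leff / aeff / .MMHG
}

#' Turbulent (Bernoulli) loss coefficient
#'
#' \eqn{\beta = K_t (\rho/2)(1/A_{eff} - 1/A_o)^2}, zero exactly when the
#' orifice matches the unobstructed channel area.
#'
#' @param aeff Effective orifice area, cm^2.
#' @param ao Unobstructed channel area, cm^2.
#' @param kt Turbulence coefficient.
#' @param rho Blood density, g/cm^3.
#' @return Coefficient, mmHg s^2/mL^2.
#' @export
bernoulli_coeff <- function(aeff, ao, kt = 1.5, rho = 1.06) {
  stopifnot(all(aeff > 0), all(ao > 0))
  kt * (rho / 2) * (1 / aeff - 1 / ao)^2 / .MMHG
}

#' Instantaneous transvalvular pressure gradient
#'
#' \eqn{\Delta P = L \, dQ/dt + \beta Q |Q|}.  The signed turbulent term
#' preserves the direction of the loss for reverse flow.
#'
#' @param q Transvalvular flow, mL/s.
#' @param dqdt Flow acceleration, mL/s^2.
#' @param l Inertance, mmHg s^2/mL.
#' @param beta Bernoulli coefficient, mmHg s^2/mL^2.
#' @return Pressure gradient, mmHg.
#' @export
valve_dp <- function(q, dqdt, l, beta) {
  l * dqdt + beta * q * abs(q)
}

#' One step of the valve-state rate equation
#'
#' Opening rate \eqn{(1 - \zeta) K_{vo} \Delta P} for a non-negative
#' gradient, closing rate \eqn{\zeta K_{vc} \Delta P} for a negative one;
#' the result is clipped to \[0, 1\].
#'
#' @param zeta Current valve state.
#' @param dp Instantaneous transvalvular gradient, mmHg.
#' @param dt Time step, s.
#' @param kvo,kvc Opening/closing rate coefficients, 1/(mmHg s).
#' @return Updated valve state.
#' @export
valve_zeta_step <- function(zeta, dp, dt, kvo, kvc = kvo) {
  stopifnot(zeta >= 0, zeta <= 1, dt > 0)
  cpp_zeta_step(zeta, dp, dt, kvo, kvc)
}

#' One explicit step of the transvalvular flow equation
#'
#' Advances \eqn{dQ/dt = (\Delta P - \beta Q |Q|) / L} by `dt` (the same
#' update the coupled engine uses).  With `leff = 0` the inertance
#' vanishes and the algebraic form \eqn{Q = sign(\Delta P)
#' \sqrt{|\Delta P| / \beta}} is returned.  When the valve is closed
#' (`zeta <= zeta_min`) and the gradient is negative, the flow is forced
#' to zero (diode rule: no regurgitation through a closed valve).
#'
#' @param q Current flow, mL/s.
#' @param dp Driving gradient (left ventricle minus aortic root), mmHg.
#' @param zeta Valve state.
#' @param dt Time step, s.
#' @param vp A [valve_params()] object with a concrete `ao`.
#' @return Updated flow, mL/s.
#' @export
valve_flow_step <- function(q, dp, zeta, dt, vp) {
  stopifnot(inherits(vp, "valve_params"), !is.null(vp$ao))
  if (zeta <= vp$zeta_min && dp < 0) return(0)
  aeff <- effective_area(zeta, vp$ava, vp$zeta_min)
  beta <- bernoulli_coeff(aeff, vp$ao, vp$kt, vp$rho)
  if (vp$leff > 0) {
    l <- valve_inertance(aeff, vp$leff, vp$rho)
    q + dt * (dp - beta * q * abs(q)) / l
  } else {
    sign(dp) * sqrt(abs(dp) / beta)
  }
}

#' @export
print.valve_params <- function(x, ...) {
  cat("Dynamic stenotic aortic valve\n")
  cat(sprintf("  AVA %.3g cm^2, leff %.3g cm, Ao %s, Kt %.3g\n",
              x$ava, x$leff,
              if (is.null(x$ao)) "from root segment" else sprintf("%.3g cm^2", x$ao),
              x$kt))
  cat(sprintf("  Kvo %s 1/(mmHg s), Kvc %s\n",
              if (is.null(x$kvo)) "auto" else sprintf("%.4g", x$kvo),
              if (is.null(x$kvc)) "= Kvo" else sprintf("%.4g", x$kvc)))
  invisible(x)
}
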