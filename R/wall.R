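#' Arctangent pressure-area relation of an arterial segment
#'
#' \eqn{A(P) = A_{max} (1/2 + \arctan((P - P_0)/P_1)/\pi)}: a sigmoidal
#' wall law, strictly increasing in pressure, with maximal compliance at
#' the inflection pressure \eqn{P_0} and asymptotic area \eqn{A_{max}}.
#'
#' @param p Pressure, mmHg.
#' @param amax Asymptotic area, cm^2.
#' @param p0 Inflection pressure, mmHg.
#' @param p1 Width pressure, mmHg.
#' @return Area, cm^2.
#' @export
langewouters_area <- function(p, amax, p0, p1) {
  stopifnot(amax > 0, p1 > 0, all(is.finite(p)))
  cpp_lange_area(as.numeric(p), amax, p0, p1)
}

#' Inverse of the arctangent wall law
#'
#' @param a Area, cm^2 (strictly inside (0, amax)).
#' @inheritParams langewouters_area
#' @return Pressure, mmHg.
#' @export
langewouters_pressure <- function(a, amax, p0, p1) {
  stopifnot(amax > 0, p1 > 0, all(a > 0), all(a < amax))
  cpp_lange_pressure(as.numeric(a), amax, p0, p1)
}

#' Local area compliance of the arctangent wall law
#'
#' \eqn{dA/dP = A_{max} / (\pi P_1 (1 + ((P-P_0)/P_1)^2))}; maximal at
#' \eqn{P = P_0} where it equals \eqn{A_{max}/(\pi P_1)}.
#'
#' @inheritParams langewouters_area
#' @return Compliance, cm^2/mmHg.
#' @export
langewouters_compliance <- function(p, amax, p0, p1) {
  stopifnot(amax > 0, p1 > 0)
  cpp_lange_dadp(as.numeric(p), amax, p0, p1)
}

#' One step of a three-element Windkessel outlet
#'
#' Advances the compartment pressure by the exact solution of
#' \eqn{dP_c/dt = (Q_{in} - P_c/R_2)/C_t} over `dt` (so a zero-inflow
#' decay is exactly exponential with time constant \eqn{R_2 C_t}), and
#' returns the outlet pressure \eqn{P = P_c + Q_{in} R_1}.
#'
#' @param pc Stored compartment pressure, mmHg.
#' @param qin Inflow, mL/s.
#' @param dt Time step, s.
#' @param r1 Proximal resistance, mmHg s/mL.
#' @param r2 Distal resistance, mmHg s/mL.
#' @param ct Terminal compliance, mL/mmHg.
#' @return List with `pc` (updated compartment pressure) and `p` (outlet
#'   pressure at the step start).
#' @export
windkessel_step <- function(pc, qin, dt, r1, r2, ct) {
  stopifnot(dt > 0, r1 > 0, r2 > 0, ct > 0)
  out <- cpp_windkessel_step(pc, qin, dt, r1, r2, ct)
  list(pc = out$Pc, p = out$P)
}
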