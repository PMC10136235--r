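#' Aggregate afterload of an arterial tree
#'
#' Total vascular resistance (TVR) is the parallel combination of the
#' terminal series resistances \eqn{R_1 + R_2}; total arterial compliance
#' (TAC) is the summed vessel compliance \eqn{\int (dA/dP) dx} evaluated
#' at the reference pressure plus the summed terminal compliances
#' \eqn{C_t}.
#'
#' @param tree An `av_tree` data.frame.
#' @param pressure Pressure at which vessel compliance is evaluated, mmHg.
#' @return List with `tvr` (mmHg s/mL), `tac` (mL/mmHg), and the split
#'   `tac_vessel` / `tac_terminal`.
#' @export
aggregate_afterload <- function(tree, pressure = 100) {
  validate_geometry(tree)
  is_term <- !(tree$id %in% tree$parent_id)
  tvr <- 1 / sum(1 / (tree$terminal_r1[is_term] + tree$terminal_r2[is_term]))
  kap <- .kappa(tree$p1_mmhg, tree$p0_mmhg, pressure)
  # dA/dP = kappa * A(pressure); areas interpolate linearly, so the segment
  # compliance integral is kappa * mean area * length, rescaled from the
  # 100 mmHg reference area to the requested pressure
  a_ref <- (tree$area_prox_cm2 + tree$area_dist_cm2) / 2
  u100 <- (100 - tree$p0_mmhg) / tree$p1_mmhg
  up <- (pressure - tree$p0_mmhg) / tree$p1_mmhg
  a_p <- a_ref * (0.5 + atan(up) / pi) / (0.5 + atan(u100) / pi)
  tac_vessel <- sum(kap * a_p * tree$length_cm)
  tac_terminal <- sum(tree$terminal_ct[is_term])
  list(tvr = tvr, tac = tac_vessel + tac_terminal,
       tac_vessel = tac_vessel, tac_terminal = tac_terminal)
}

#' Scale a tree to target aggregate afterload
#'
#' All terminal resistances are scaled by a common factor so the
#' aggregate TVR matches the target exactly (closed form).  All terminal
#' compliances and all segment wall compliances are scaled by a common
#' factor so the aggregate TAC at the reference pressure matches the
#' target; segment compliance scaling re-solves each segment's width
#' pressure `p1_mmhg` so that the local compliance at the reference
#' pressure scales exactly while the reference areas are preserved.
#'
#' @param tree An `av_tree` data.frame.
#' @param tvr Target TVR, mmHg s/mL (`NULL` leaves resistances untouched).
#' @param tac Target TAC, mL/mmHg (`NULL` leaves compliances untouched).
#' @param pressure Reference pressure for the compliance evaluation, mmHg.
#' @param bounds Admissible (physiological) range for each target; targets
#'   outside are rejected.
#' @return The rescaled `av_tree`.
#' @export
scale_afterload <- function(tree, tvr = NULL, tac = NULL, pressure = 100,
                            bounds = list(tvr = c(0.2, 5), tac = c(0.1, 6))) {
  validate_geometry(tree)
  agg <- aggregate_afterload(tree, pressure)
  is_term <- !(tree$id %in% tree$parent_id)
  if (!is.null(tvr)) {
    if (tvr < bounds$tvr[1] || tvr > bounds$tvr[2])
      stop(sprintf("TVR target %.3g outside physiological bounds [%g, %g]",
                   tvr, bounds$tvr[1], bounds$tvr[2]))
    f <- tvr / agg$tvr
    tree$terminal_r1[is_term] <- tree$terminal_r1[is_term] * f
    tree$terminal_r2[is_term] <- tree$terminal_r2[is_term] * f
  }
  if (!is.null(tac)) {
    if (tac < bounds$tac[1] || tac > bounds$tac[2])
      stop(sprintf("TAC target %.3g outside physiological bounds [%g, %g]",
                   tac, bounds$tac[1], bounds$tac[2]))
    s <- tac / agg$tac
    # wall compliance saturates at the arctangent ceiling; any remainder is
    # carried by the terminal compartments so the aggregate stays exact
    kap_cur <- .kappa(tree$p1_mmhg, tree$p0_mmhg, pressure)
    kap_max <- vapply(tree$p0_mmhg, function(p0)
      0.95 * optimize(function(lp) .kappa(10^lp, p0, pressure),
                      c(-2, 5), maximum = TRUE)$objective, numeric(1))
    kap_new <- pmin(s * kap_cur, kap_max)
    u100 <- (100 - tree$p0_mmhg) / tree$p1_mmhg
    up <- (pressure - tree$p0_mmhg) / tree$p1_mmhg
    a_p <- (tree$area_prox_cm2 + tree$area_dist_cm2) / 2 *
      (0.5 + atan(up) / pi) / (0.5 + atan(u100) / pi)
    vessel_new <- sum(kap_new * a_p * tree$length_cm)
    ct_new <- tac - vessel_new
    if (ct_new <= 0)
      stop(sprintf(paste0("TAC target %.3g infeasible: vessel compliance ",
                          "alone exceeds it"), tac))
    tree$terminal_ct[is_term] <- tree$terminal_ct[is_term] *
      ct_new / agg$tac_terminal
    tree$p1_mmhg <- vapply(seq_len(nrow(tree)), function(i)
      .solve_p1(kap_new[i], tree$p0_mmhg[i], pressure), numeric(1))
  }
  tree
}
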