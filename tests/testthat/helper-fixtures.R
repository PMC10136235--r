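# Shared fixtures: simple tube geometries built in code, and a cached
# baseline calibrated run so the heavier integration tests share one
# simulation.

# a straight tube (optionally split into nseg chained segments) with a
# matched-ish Windkessel termination
make_tube <- function(len = 60, area = 4, c_ref = 450, p0 = 70,
                      nseg = 1, r1 = NULL, r2 = 8, ct = 0.05,
                      area_dist = area) {
  p1 <- stenosim:::.p1_from_wave_speed(c_ref, p0)
  if (is.null(r1)) r1 <- 1.06 * c_ref / area_dist / 1333.22
  bounds <- seq(area, area_dist, length.out = nseg + 1)
  tree <- data.frame(
    id = seq_len(nseg),
    parent_id = c(0L, seq_len(nseg - 1L)),
    length_cm = len / nseg,
    area_prox_cm2 = bounds[-(nseg + 1)],
    area_dist_cm2 = bounds[-1],
    p0_mmhg = p0, p1_mmhg = p1, visc_coeff = 0,
    terminal_r1 = NA_real_, terminal_r2 = NA_real_, terminal_ct = NA_real_)
  tree$terminal_r1[nseg] <- r1
  tree$terminal_r2[nseg] <- r2
  tree$terminal_ct[nseg] <- ct
  class(tree) <- c("av_tree", "data.frame")
  tree
}

# narrow Gaussian flow pulse
gauss_pulse <- function(t0 = 0.05, width = 0.01, amp = 5) {
  function(t) amp * exp(-((t - t0) / width)^2)
}

# first time the series rises above baseline + frac * (max - baseline)
foot_time <- function(t, x, frac = 0.05) {
  x0 <- x[1]
  thr <- x0 + frac * (max(x) - x0)
  t[which(x > thr)[1]]
}

# cached baseline calibrated severe-stenosis case (built once per test run)
.sim_cache <- new.env(parent = emptyenv())
baseline_case <- function() {
  if (is.null(.sim_cache$case)) {
    tree <- default_tree()
    .sim_cache$case <- calibrate_case(
      cardiac_params(), valve_params(ava = 0.6, kvo = 2.4), tree,
      tvr_target = 1.2, tac_target = 1.1, quiet = TRUE)
  }
  .sim_cache$case
}
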