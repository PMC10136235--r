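# The full sensitivity battery (4 determinants + coupled afterload, 4 AVA
# levels, 10 points each) is expensive; it is computed once per test run
# at the coarse battery resolution and shared by the quantitative
# acceptance checks.
battery_results <- function() {
  if (is.null(.sim_cache$battery)) {
    tree <- default_tree()
    control <- sim_control(dt_cap = 4e-4)
    bl <- baseline_config()
    cp0 <- cardiac_params(ees = bl$ees, eed = bl$eed, t_hp = bl$t_hp,
                          t_max = bl$t_max_frac * bl$t_hp,
                          lvedp = bl$lvedp, vd = bl$vd)
    tree_b <- scale_afterload(tree, tvr = bl$tvr, tac = bl$tac)
    avas <- c(0.6, 1.0, 1.5, 2.0)
    kvo <- vapply(avas, function(a)
      8 * calibrate_valve_rates(cp0, valve_params(ava = a), tree_b,
                                control, kvo_seed = 0.05)$kvo,
      numeric(1))
    names(kvo) <- as.character(avas)
    sweeps <- lapply(default_sweeps(bl), function(spec)
      run_sweep(spec, tree, control, kvo_table = kvo))
    .sim_cache$battery <- list(sweeps = sweeps,
                               table = table1_report(sweeps),
                               kvo = kvo, control = control, bl = bl)
  }
  .sim_cache$battery
}
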