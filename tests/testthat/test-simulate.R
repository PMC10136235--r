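test_that("baseline severe-stenosis case converges with closed physics", {
  cc <- baseline_case()
  sim <- cc$sim
  expect_true(sim$converged)
  s <- sim$summary
  wf <- sim$waveforms

  # valve state bounded at every stored step
  expect_true(all(wf$zeta >= 0 & wf$zeta <= 1))

  # closed pressure-volume loop: start/end volumes within 0.5% of SV
  expect_lt(abs(wf$v_lv[1] - wf$v_lv[nrow(wf)]), 0.005 * s$sv)

  # PV-loop width equals the aortic flow integral within 1%
  pv_width <- max(wf$v_lv) - min(wf$v_lv)
  expect_lt(abs(pv_width - s$sv) / s$sv, 0.01)

  # summary invariants
  expect_gt(s$sbp, s$dbp)
  expect_equal(s$pp, s$sbp - s$dbp)
  expect_lte(s$mean_tpg, s$max_tpg)
  expect_equal(s$sv, s$co * sim$cardiac$t_hp, tolerance = 0.005)

  # cycle volume conservation: inflow = terminal outflow + stored change
  cyc <- tail(sim$cycles, 1)
  mismatch <- cyc$vol_in - cyc$vol_out - (cyc$tree_vol1 - cyc$tree_vol0)
  expect_lt(abs(mismatch), 0.01 * s$sv)

  # LV pressure exceeds aortic pressure while flow accelerates (late
  # ejection reverses the gradient through the inertial term)
  acc <- seq_len(which.max(wf$q_av))
  acc <- acc[wf$q_av[acc] > 50]
  expect_true(all(wf$p_lv[acc] > wf$p_ao[acc]))

  # end-diastolic state honours the LVEDP target
  expect_lt(abs(tail(sim$cycles$edp, 1) - sim$cardiac$lvedp), 0.25)
})

test_that("calibrated afterload satisfies the Ohmic mean-pressure relation", {
  cc <- baseline_case()
  s <- cc$sim$summary
  # MAP = CO * TVR within 2% (venous pressure 0)
  expect_lt(abs(s$map - s$co * 1.2) / s$map, 0.02)
})

test_that("identical configuration reproduces waveforms bit-identically", {
  tree <- default_tree()
  cp <- cardiac_params()
  vp <- valve_params(ava = 1.0, kvo = 1)
  ctrl <- sim_control(max_cycles = 4)
  a <- av_simulate(cp, vp, tree, ctrl)
  b <- av_simulate(cp, vp, tree, ctrl)
  expect_identical(a$waveforms, b$waveforms)
})

test_that("the ideal-valve limit imposes no transvalvular gradient", {
  # orifice equal to the unobstructed area: the turbulent loss vanishes
  # when fully open and only the small inertial term remains
  tree <- default_tree()
  ao <- tree$area_prox_cm2[tree$parent_id == 0]
  vp <- valve_params(ava = ao, ao = ao, kt = 0, leff = 0.1, kvo = 20)
  sim <- av_simulate(cardiac_params(), vp, tree, sim_control())
  expect_lt(abs(sim$summary$mean_tpg), 1)
})

test_that("halving the time step leaves the summary nearly unchanged", {
  cc <- baseline_case()
  ctrl2 <- cc$sim$control
  ctrl2$dt <- cc$sim$dt / 2
  sim2 <- av_simulate(cc$sim$cardiac, cc$sim$valve, cc$tree, ctrl2)
  s1 <- cc$sim$summary; s2 <- sim2$summary
  expect_lt(abs(s1$sv - s2$sv) / s1$sv, 0.005)
  expect_lt(abs(s1$mean_tpg - s2$mean_tpg) / s1$mean_tpg, 0.005)
})

test_that("halving the spatial step leaves the summary nearly unchanged", {
  cc <- baseline_case()
  ctrl2 <- cc$sim$control
  ctrl2$dx_cm <- ctrl2$dx_cm / 2
  sim2 <- av_simulate(cc$sim$cardiac, cc$sim$valve, cc$tree, ctrl2)
  s1 <- cc$sim$summary; s2 <- sim2$summary
  expect_lt(abs(s1$sv - s2$sv) / s1$sv, 0.01)
  expect_lt(abs(s1$mean_tpg - s2$mean_tpg) / s1$mean_tpg, 0.01)
})

test_that("simulated gradient decomposes into the valve's two loss terms", {
  # independent reconstruction: beta(zeta) Q|Q| plus the inertial term
  # from the stored waveforms must reproduce the engine's TPG
  cc <- baseline_case()
  wf <- cc$sim$waveforms
  vp <- cc$sim$valve
  dt <- median(diff(wf$t))
  ej <- which(wf$zeta > 0.02 & wf$q_av > 1)
  ej <- ej[-c(1, length(ej))]
  aeff <- effective_area(wf$zeta[ej], vp$ava, vp$zeta_min)
  beta <- bernoulli_coeff(aeff, vp$ao, vp$kt, vp$rho)
  l <- valve_inertance(aeff, vp$leff, vp$rho)
  dqdt <- (wf$q_av[ej + 1] - wf$q_av[ej - 1]) / (2 * dt)
  rec <- valve_dp(wf$q_av[ej], dqdt, l, beta)
  expect_lt(mean(abs(rec - wf$tpg[ej])) / mean(abs(wf$tpg[ej])), 0.02)
})

test_that("the mean gradient saturates once the valve opens promptly", {
  # doubling the rate coefficient beyond the experiments' margin moves
  # the mean TPG by only a few percent
  cc <- baseline_case()
  v2 <- cc$sim$valve
  v2$kvo <- v2$kvc <- 2 * v2$kvo
  sim2 <- av_simulate(cc$sim$cardiac, v2, cc$tree, cc$sim$control)
  expect_lt(abs(sim2$summary$mean_tpg - cc$sim$summary$mean_tpg) /
              cc$sim$summary$mean_tpg, 0.05)
})

test_that("cycle summary computes its metrics from constructed waveforms", {
  # constant TPG of 10 mmHg over a synthetic ejection window
  n <- 1000
  t <- seq(0, 0.8, length.out = n)
  ej <- t >= 0.1 & t < 0.4
  q <- ifelse(ej, 200, 0)
  wf <- data.frame(t = t, p_lv = ifelse(ej, 110, 20),
                   p_ao = ifelse(ej, 100, 90),
                   q_av = q, zeta = ifelse(ej, 1, 0))
  s <- summarize_cycle(wf, t_hp = 0.8)
  expect_equal(s$mean_tpg, 10)
  expect_equal(s$max_tpg, 10)
  expect_equal(s$sv, sum(q) * diff(t)[1], tolerance = 1e-12)

  # triangular flow peaking at one third of ejection
  ejn <- sum(ej)
  peak <- ceiling(ejn / 3)
  tri <- c(seq(0, 300, length.out = peak),
           seq(300, 0, length.out = ejn - peak + 1)[-1])
  wf2 <- wf
  wf2$q_av[ej] <- pmax(tri, 1e-3)
  s2 <- summarize_cycle(wf2, t_hp = 0.8)
  expect_equal(s2$acceleration_time / s2$ejection_time, 1 / 3,
               tolerance = 0.02)

  # no ejection at all flags a degenerate run
  wf3 <- wf; wf3$zeta <- 0; wf3$q_av <- 0
  expect_true(summarize_cycle(wf3, t_hp = 0.8)$degenerate)
})

test_that("afterload estimators are the clinical ratios", {
  s <- structure(list(sv = 80, co = 83.3, map = 93.3, mbp = 93.3,
                      sbp = 120, dbp = 80, pp = 40, mean_tpg = 10,
                      max_tpg = 20, ejection_time = 0.3,
                      acceleration_time = 0.1, degenerate = FALSE),
                 class = "hemo_summary")
  est <- estimate_afterload(s)
  expect_equal(est$tvr, 93.3 / 83.3)
  expect_equal(est$tac, 2.0)
})
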