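test_that("arctangent wall law: anchors, asymptote, and analytic compliance", {
  expect_equal(langewouters_area(70, amax = 4, p0 = 70, p1 = 30), 2)
  expect_lt(abs(langewouters_area(1e7, 4, 70, 30) - 4), 1e-4)
  tt <- seq(20, 200, by = 5)
  expect_true(all(diff(langewouters_area(tt, 4, 70, 30)) > 0))
  # dA/dP at the inflection = Amax / (pi P1), against a centered difference
  h <- 1e-3
  num <- (langewouters_area(70 + h, 4, 70, 30) -
            langewouters_area(70 - h, 4, 70, 30)) / (2 * h)
  expect_equal(langewouters_compliance(70, 4, 70, 30), 4 / (pi * 30),
               tolerance = 1e-9)
  expect_equal(langewouters_compliance(70, 4, 70, 30), num, tolerance = 1e-6)
  # inverse round-trip
  a <- langewouters_area(c(60, 100, 140), 4, 70, 30)
  expect_equal(langewouters_pressure(a, 4, 70, 30), c(60, 100, 140),
               tolerance = 1e-8)
})

test_that("Windkessel step: steady asymptote, exact decay, R1 jump", {
  r1 <- 0.1; r2 <- 1.2; ct <- 1.5
  # constant inflow held long: P -> Q (R1 + R2)
  pc <- 0
  for (i in 1:4000) {
    st <- windkessel_step(pc, qin = 80, dt = 0.01, r1, r2, ct)
    pc <- st$pc
  }
  expect_equal(pc + 80 * r1, 80 * (r1 + r2), tolerance = 1e-3)
  # zero inflow: exponential decay with tau = R2 Ct, vs closed form
  pc <- 100; tt <- 0.37
  n <- 370
  for (i in 1:n) pc <- windkessel_step(pc, 0, tt / n, r1, r2, ct)$pc
  expect_equal(pc, 100 * exp(-tt / (r2 * ct)), tolerance = 1e-3 * 100)
  # series resistor: outlet pressure jumps by Q R1 immediately
  st <- windkessel_step(50, qin = 40, dt = 1e-4, r1, r2, ct)
  expect_equal(st$p, 50 + 40 * r1)
})

test_that("a pulse propagates at the analytic wave speed", {
  tube <- make_tube(len = 60, area = 4, c_ref = 450, r2 = 1e3, ct = 1)
  ctrl <- sim_control(dx_cm = 0.5, p_init = 100)
  probes <- data.frame(segment = 1, pos_cm = c(10, 40))
  out <- simulate_inflow(tube, gauss_pulse(amp = 5), t_end = 0.25,
                         probes = probes, control = ctrl)
  t1 <- foot_time(out$t, out$p[, 1])
  t2 <- foot_time(out$t, out$p[, 2])
  c_meas <- 30 / (t2 - t1)
  expect_lt(abs(c_meas - 450) / 450, 0.05)
})

test_that("steady flow through a uniform tube obeys the friction law", {
  # gamma_v = 2 recovers Poiseuille: dP = 8 pi mu L Q / A^2 (CGS)
  tube <- make_tube(len = 50, area = 0.5, c_ref = 600, r1 = 2, r2 = 8,
                    ct = 0.02)
  ctrl <- sim_control(dx_cm = 1, gamma_v = 2, p_init = 100)
  probes <- data.frame(segment = 1, pos_cm = c(0, 50))
  out <- simulate_inflow(tube, function(t) rep(10, length(t)), t_end = 2,
                         probes = probes, control = ctrl)
  n <- length(out$t)
  drop <- mean(out$p[(n - 200):n, 1] - out$p[(n - 200):n, 2])
  drop_an <- 8 * pi * 0.04 * 50 * 10 / (0.5^2) / 1333.22
  expect_lt(abs(drop - drop_an) / drop_an, 0.02)
})

test_that("uniform quiescent tube is a numerical equilibrium", {
  tube <- make_tube(len = 40, area = 2, c_ref = 500, r2 = 1e4, ct = 1)
  ctrl <- sim_control(dx_cm = 1, p_init = 90)
  probes <- data.frame(segment = 1, pos_cm = c(5, 35))
  out <- simulate_inflow(tube, function(t) rep(0, length(t)), t_end = 0.5,
                         probes = probes, control = ctrl)
  # terminal compartment starts at p_init; nothing should move beyond
  # roundoff except the slow Windkessel discharge through R2
  expect_lt(max(abs(out$p - 90)), 0.5)
  expect_lt(max(abs(out$q)), 0.5)
})

test_that("junctions conserve flow and are transparent when property-matched", {
  # same tube as one segment vs split into two: probe mid-way, compare
  one <- make_tube(len = 60, area = 4, c_ref = 450, r2 = 1e3, ct = 1)
  two <- make_tube(len = 60, area = 4, c_ref = 450, nseg = 2, r2 = 1e3, ct = 1)
  ctrl <- sim_control(dx_cm = 0.5, p_init = 100)
  p1 <- data.frame(segment = 1, pos_cm = 45)
  p2 <- data.frame(segment = 2, pos_cm = 15)
  o1 <- simulate_inflow(one, gauss_pulse(), t_end = 0.2, probes = p1,
                        control = ctrl)
  o2 <- simulate_inflow(two, gauss_pulse(), t_end = 0.2, probes = p2,
                        control = ctrl)
  amp <- max(o1$p) - 100
  expect_lt(max(abs(o1$p - o2$p)) / amp, 0.02)
  # mass conservation through the junction: inflow volume reappears
  expect_equal(o2$vol_in, sum(gauss_pulse()(seq(0, 0.2, by = o2$dt))) * o2$dt,
               tolerance = 1e-6)
})

test_that("an area mismatch reflects a pulse per characteristic impedance", {
  # parent A1 = 4, c1 = 400 into child A2 = 1, c2 = 600 (stiffer, narrower):
  # linear theory: R = (Z2 - Z1)/(Z2 + Z1) with Z = rho c / A
  tree <- make_tube(len = 40, area = 4, c_ref = 450)
  tree$terminal_r1[1] <- tree$terminal_r2[1] <- tree$terminal_ct[1] <- NA_real_
  p1c <- stenosim:::.p1_from_wave_speed(600, 70)
  child <- data.frame(id = 2, parent_id = 1, length_cm = 120,
                      area_prox_cm2 = 1, area_dist_cm2 = 1,
                      p0_mmhg = 70, p1_mmhg = p1c, visc_coeff = 0,
                      terminal_r1 = 1.06 * 600 / 1 / 1333.22,
                      terminal_r2 = 8, terminal_ct = 0.02)
  tree <- rbind(as.data.frame(tree), child)
  class(tree) <- c("av_tree", "data.frame")
  ctrl <- sim_control(dx_cm = 0.5, p_init = 100, mu = 0)
  probes <- data.frame(segment = 1, pos_cm = 20)
  out <- simulate_inflow(tree, gauss_pulse(t0 = 0.03, width = 0.008, amp = 2),
                         t_end = 0.3, probes = probes, control = ctrl)
  p <- out$p[, 1] - 100
  # incident peak ~ t0 + 20/400, reflected ~ t0 + 60/400
  inc_win <- out$t > 0.05 & out$t < 0.11
  ref_win <- out$t > 0.14 & out$t < 0.22
  r_meas <- max(p[ref_win]) / max(p[inc_win])
  z1 <- 1.06 * 450 / 4; z2 <- 1.06 * 600 / 1
  r_an <- (z2 - z1) / (z2 + z1)
  expect_lt(abs(r_meas - r_an) / r_an, 0.10)
})

test_that("aggregate afterload composes resistances and compliances", {
  # root feeding two identical terminals of R1 + R2 = 2 -> TVR = 1
  p1 <- stenosim:::.p1_from_wave_speed(600, 70)
  seg <- function(id, parent, term) data.frame(
    id = id, parent_id = parent, length_cm = 10,
    area_prox_cm2 = if (parent == 0) 2 else 1,
    area_dist_cm2 = if (parent == 0) 2 else 1,
    p0_mmhg = 70, p1_mmhg = p1, visc_coeff = 0,
    terminal_r1 = if (term) 0.5 else NA_real_,
    terminal_r2 = if (term) 1.5 else NA_real_,
    terminal_ct = if (term) 0.3 else NA_real_)
  tr <- rbind(seg(1, 0, FALSE), seg(2, 1, TRUE), seg(3, 1, TRUE))
  class(tr) <- c("av_tree", "data.frame")
  agg <- aggregate_afterload(tr)
  expect_equal(agg$tvr, 1)
  expect_equal(agg$tac_terminal, 0.6)
  # doubling every compliance doubles TAC (scale_afterload exactness)
  tr2 <- scale_afterload(tr, tac = 2 * agg$tac)
  expect_equal(aggregate_afterload(tr2)$tac, 2 * agg$tac, tolerance = 1e-6)
  # rigid-wall limit: only terminal compliances remain
  tr3 <- tr
  tr3$p1_mmhg <- 1e7
  expect_equal(aggregate_afterload(tr3)$tac, agg$tac_terminal,
               tolerance = 1e-3)
})

test_that("afterload rescaling is exact and respects bounds", {
  tree <- synthetic_tree(24, seed = 7)
  agg0 <- aggregate_afterload(tree)
  # identity
  same <- scale_afterload(tree, tvr = agg0$tvr, tac = agg0$tac)
  expect_equal(aggregate_afterload(same)$tvr, agg0$tvr, tolerance = 1e-12)
  # doubling TVR doubles every terminal resistance
  dbl <- scale_afterload(tree, tvr = 2 * agg0$tvr)
  is_term <- !(tree$id %in% tree$parent_id)
  expect_equal(dbl$terminal_r1[is_term], 2 * tree$terminal_r1[is_term])
  expect_equal(dbl$terminal_r2[is_term], 2 * tree$terminal_r2[is_term])
  # TAC recovery within 0.5%
  for (target in c(0.5, 1.3, 2.0)) {
    sc <- scale_afterload(tree, tac = target)
    expect_lt(abs(aggregate_afterload(sc)$tac - target) / target, 0.005)
  }
  expect_error(scale_afterload(tree, tvr = 50), "bounds")
})

test_that("geometry validation catches malformed trees", {
  tree <- synthetic_tree(24, seed = 7)
  expect_silent(validate_geometry(tree))
  bad <- tree; bad$parent_id[1] <- 99
  expect_error(validate_geometry(bad), "unknown|root")
  bad2 <- tree; bad2$length_cm[3] <- -1
  expect_error(validate_geometry(bad2), "positive")
  bad3 <- tree; bad3$parent_id[2] <- 0
  expect_error(validate_geometry(bad3), "root")
  is_term <- !(tree$id %in% tree$parent_id)
  bad4 <- tree; bad4$terminal_ct[which(is_term)[1]] <- NA
  expect_error(validate_geometry(bad4), "terminal")
})
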