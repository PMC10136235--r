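test_that("generated trees validate, are deterministic, and are scalable", {
  t24 <- synthetic_tree(24, seed = 7)
  expect_silent(validate_geometry(t24))
  expect_equal(nrow(t24), 24)

  # determinism: same seed gives byte-identical CSV
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_geometry(synthetic_tree(24, seed = 11), f1)
  write_geometry(synthetic_tree(24, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed does not
  f3 <- tempfile(fileext = ".csv")
  write_geometry(synthetic_tree(24, seed = 12), f3)
  expect_false(identical(readLines(f1), readLines(f3)))

  # large blueprint: 103 connected segments, same physics
  t103 <- synthetic_tree(103, seed = 7)
  expect_equal(nrow(t103), 103)
  expect_silent(validate_geometry(t103))

  # aggregate afterload in the physiological window and scalable across
  # the full sweep ranges without violating positivity
  agg <- aggregate_afterload(t24)
  expect_gte(agg$tac, 0.5); expect_lte(agg$tac, 2)
  for (tv in c(0.6, 1.8)) {
    sc <- scale_afterload(t24, tvr = tv)
    expect_silent(validate_geometry(sc))
    expect_equal(aggregate_afterload(sc)$tvr, tv, tolerance = 1e-9)
  }
})

test_that("the packaged tree matches its generator", {
  t24 <- synthetic_tree(24, seed = 7)
  pkg <- default_tree()
  attr(t24, "names_long") <- NULL
  expect_equal(as.data.frame(pkg), as.data.frame(t24), tolerance = 1e-9)
})

test_that("a generated tree simulates to convergence", {
  sim <- av_simulate(cardiac_params(), valve_params(ava = 1.5, kvo = 2),
                     synthetic_tree(24, seed = 3), sim_control())
  expect_true(sim$converged)
  expect_false(sim$summary$degenerate)
})

test_that("patient fixtures carry the published inputs", {
  dek <- patient_fixture("dekker_av_stenosis")
  expect_equal(dek$cardiac$ees, 3.3)
  expect_equal(dek$cardiac$eed, 0.1)
  expect_equal(dek$cardiac$vd, 39.3)
  expect_equal(dek$cardiac$lvedp, 11)
  expect_equal(dek$valve$ava, 0.6)

  expect_equal(patient_fixture("dobutamine_rest")$sv_target, 67)
  st <- patient_fixture("dobutamine_stress")
  expect_equal(st$sv_target, 87)
  expect_equal(st$valve$ava, 0.88)
  expect_error(patient_fixture("nobody"), "arg")
})

test_that("configurations survive a YAML round trip", {
  fix <- patient_fixture("dekker_av_stenosis")
  path <- tempfile(fileext = ".yaml")
  write_sim_config(fix$cardiac, fix$valve, path,
                   extra = list(targets = list(tvr = 1.2, tac = 1.1)))
  back <- read_sim_config(path)
  expect_equal(back$cardiac, fix$cardiac)
  expect_equal(back$valve$ava, fix$valve$ava)
  expect_equal(back$valve$kt, fix$valve$kt)
  expect_equal(back$targets$tvr, 1.2)
})
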