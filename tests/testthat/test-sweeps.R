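test_that("the default sweep battery matches the study design", {
  sw <- default_sweeps()
  expect_named(sw, c("ees", "eed", "tvr", "tac", "tvr_adj"))
  # 4 independent sweeps x 4 AVA levels x 10 values = 160 cases
  n_uncoupled <- sum(vapply(sw[1:4], function(s)
    s$n * length(s$ava), numeric(1)))
  expect_equal(n_uncoupled, 160)
  # coupled sweep adds 40 cases
  expect_equal(sw$tvr_adj$n * length(sw$tvr_adj$ava), 40)
  # ranges and even spacing
  expect_equal(sw$ees$values[c(1, 10)], c(0.5, 6))
  expect_equal(unique(round(diff(sw$eed$values), 10)),
               round((0.31 - 0.03) / 9, 10))
  expect_equal(sw$tvr$values[c(1, 10)], c(0.6, 1.8))
  expect_equal(sw$tac$values[c(1, 10)], c(0.5, 2.0))
})

test_that("hyperbolic coupling keeps the TAC-TVR product invariant", {
  const <- 1.2 * 1.1
  tvr <- seq(0.6, 1.8, length.out = 10)
  tac <- hyperbolic_couple(tvr, const)
  expect_lt(max(abs(tac * tvr - const)), 1e-12)
  expect_equal(hyperbolic_couple(1.2, const), 1.1)
  expect_equal(hyperbolic_couple(2.4, const), 0.55)
})

test_that("OLS effect estimates behave on known data", {
  # exact line: slope recovered, SE floored, p below machine resolution
  x <- 1:10
  fit <- tpg_ols(x, 2 * x + 1, baseline = 2)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(fit$p, 1e-12)
  expect_equal(fit$beta_per_10pct, 2 * 0.1 * 2)
  expect_equal(fit$beta_per_10pct, fit$beta * 0.1 * fit$baseline)

  # Monte-Carlo: noisy line recovers its slope within 3 SE
  set.seed(42)
  x <- runif(1000, 0, 10)
  y <- 3 * x + rnorm(1000)
  fit2 <- tpg_ols(x, y)
  expect_lt(abs(fit2$beta - 3), 3 * fit2$se)
  expect_gt(fit2$r2, 0.9)

  expect_error(tpg_ols(rep(1, 5), 1:5), "constant")
  expect_error(tpg_ols(1:2, 1:2), "length")
})

test_that("a miniature contractility sweep is monotone in TPG and SV", {
  spec <- sweep_spec("ees", 2, 6, n = 3, ava = 0.6)
  sw <- run_sweep(spec, default_tree(), sim_control(),
                  kvo_table = c("0.6" = 2.4))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$mean_tpg_mmhg) > 0))
  expect_true(all(diff(sw$sv_ml) > 0))
  # larger SV accompanies larger TPG at fixed AVA
  expect_true(cor(sw$sv_ml, sw$mean_tpg_mmhg) > 0.99)
  # achieved afterload matches the held-fixed baseline for every case
  expect_true(all(abs(sw$achieved_tvr - 1.2) / 1.2 < 0.011))
  expect_true(all(abs(sw$achieved_tac - 1.1) / 1.1 < 0.011))
})

test_that("table assembly scales per-10% effects by the baseline value", {
  # two synthetic sweeps with known linear responses
  mk <- function(param, values, beta, ava) {
    spec <- sweep_spec(param, min(values), max(values), n = length(values),
                       ava = ava)
    out <- data.frame(param = param, value = values, ava_cm2 = ava,
                      mean_tpg_mmhg = 5 + beta * values,
                      max_tpg_mmhg = NA, sv_ml = NA, map_mmhg = NA,
                      sbp_mmhg = NA, dbp_mmhg = NA, achieved_tvr = NA,
                      achieved_tac = NA, ees = NA, eed = NA)
    attr(out, "spec") <- spec
    class(out) <- c("av_sweep", "data.frame")
    out
  }
  v <- seq(0.5, 6, length.out = 10)
  tab <- table1_report(list(ees = mk("ees", v, 2, 0.6)))
  expect_equal(tab$beta_per_unit, 2, tolerance = 1e-10)
  expect_equal(tab$beta_per_10pct, 2 * 0.1 * baseline_config()$ees,
               tolerance = 1e-10)
})
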