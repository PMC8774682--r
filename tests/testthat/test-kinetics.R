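test_that("initial_rate recovers slopes exactly, within 1% under noise, and flags curvature", {
  # exact linear curve
  cv <- progress_curve(seq(0, 100, 5), 0.01 * seq(0, 100, 5))
  expect_equal(initial_rate(cv)$rate, 0.01, tolerance = 1e-12)
  expect_error(initial_rate(cv, window = c(-10, 50)), "window")

  # Monte Carlo: 50 points, 1% additive noise -> rate within 1% in >= 95/100
  tr <- kinetic_truth(Vmax = 2e-6, Km = 1, Ki = Inf,
                      substrate_grid = 1, inhibitor_grid = 0)
  hits <- vapply(1:100, function(s) {
    cfg <- synth_config(s, "gaussian_additive", 0.01)
    cv <- gen_progress_curves(tr, duration = 245, sampling = 5, cfg = cfg)[[1]]
    est <- initial_rate(cv)$rate
    abs(est - cv$meta$rate_true * 13600) / (cv$meta$rate_true * 13600) < 0.01
  }, logical(1))
  expect_gte(sum(hits), 95)

  # two-phase curve: early window is clean, late residuals trend
  t2 <- seq(0, 400, 5)
  a2 <- ifelse(t2 <= 150, 0.002 * t2, 0.3 + 0.0005 * (t2 - 150))
  ir <- initial_rate(progress_curve(t2, a2), window = c(0, 150))
  expect_equal(ir$rate, 0.002, tolerance = 1e-9)
  expect_true(ir$curvature_flag)
})

test_that("relative_activity is a plain ratio with a guarded control", {
  expect_equal(relative_activity(c(1, 0, 0.5), 1), c(100, 0, 50))
  expect_error(relative_activity(1, 0), "v_control")
})

test_that("fit_ic50 is exact on clean data and rejects ill-posed inputs", {
  grid <- c(0, 1, 2, 5, 10, 20, 50, 100)
  dr <- gen_dose_response(10, 1, grid, cfg_clean())
  f <- fit_ic50(dr)
  expect_equal(f$ic50, 10, tolerance = 1e-9)
  expect_equal(f$hill, 1, tolerance = 1e-9)
  # monotone increasing activity: wrong sign
  up <- data.frame(I = grid, activity = seq(10, 80, length.out = 8))
  expect_error(fit_ic50(up), "increases")
  # no 50% crossing
  shallow <- data.frame(I = grid, activity = seq(100, 80, length.out = 8))
  expect_error(fit_ic50(shallow), "50%")
})

test_that("reversibility verdicts distinguish origin lines from shifted lines", {
  E <- c(0.5, 1, 1.5, 2)
  lev <- c(0, 2, 4)
  slope <- c(1, 0.6, 0.4)
  origin <- do.call(rbind, lapply(seq_along(lev), function(i) {
    data.frame(E = E, v = slope[i] * E, I = lev[i])
  }))
  expect_equal(reversibility_test(origin)$verdict, "reversible")
  # common positive x-intercept: the titration pattern of covalent loss
  shifted <- do.call(rbind, lapply(seq_along(lev), function(i) {
    data.frame(E = E, v = pmax(0, slope[i] * (E - 0.4)), I = lev[i])
  }))
  expect_equal(reversibility_test(shifted)$verdict, "irreversible-like")
  expect_error(reversibility_test(origin[origin$I == 0, ]), "levels")
})

test_that("zero-noise competitive tables are recovered exactly by both routes", {
  tr <- kinetic_truth(Vmax = 1, Km = 2, Ki = 5,
                      substrate_grid = c(0.5, 1, 2, 4, 8, 16),
                      inhibitor_grid = c(0, 5, 10))
  f <- fit_inhibition(gen_rate_table(tr, cfg_clean()))
  expect_equal(f$Km, 2, tolerance = 1e-9)
  expect_equal(f$Ki, 5, tolerance = 1e-9)
  expect_equal(f$Vmax, 1, tolerance = 1e-9)
  expect_equal(f$inhibition_type, "competitive")
  # linear and nonlinear routes agree in the zero-noise limit
  expect_equal(f$nonlinear$Km, f$Km, tolerance = 1e-9)
  expect_equal(f$nonlinear$Ki, f$Ki, tolerance = 1e-9)
  # uninhibited line alone: apparent Km equals Km
  expect_equal(unname(f$Km_app["0"]), 2, tolerance = 1e-9)
})

test_that("rows with vanishing rates are dropped with a warning", {
  tr <- kinetic_truth(Vmax = 1, Km = 2, Ki = 5,
                      substrate_grid = c(0.5, 1, 2, 4, 8),
                      inhibitor_grid = c(0, 5, 10))
  tab <- gen_rate_table(tr, cfg_clean())
  tab$v[1] <- 0
  expect_warning(f <- fit_inhibition(tab), "dropped")
  expect_equal(f$Ki, 5, tolerance = 1e-9)
})

test_that("linear and nonlinear Ki estimates diverge more as noise grows", {
  tr <- ref_kinetic_truth()
  gap <- vapply(c(0.01, 0.05), function(sc) {
    gaps <- vapply(1:20, function(s) {
      f <- suppressWarnings(
        fit_inhibition(gen_rate_table(tr, cfg_noisy(s, sc))))
      if (is.null(f$nonlinear)) return(NA_real_)
      abs(f$Ki - f$nonlinear$Ki)
    }, 1)
    mean(gaps, na.rm = TRUE)
  }, 1)
  expect_lt(gap[1], gap[2])
})

test_that("direct IC50 at fixed substrate matches the Cheng-Prusoff prediction", {
  Km <- 1.674; Ki <- 4.32; S <- 2
  Igrid <- c(0, 1, 2, 4, 8, 16, 32)
  v <- S / (Km * (1 + Igrid / Ki) + S)
  dr <- data.frame(I = Igrid, activity = relative_activity(v, v[1]))
  f <- fit_ic50(dr)
  expect_equal(f$ic50, Ki * (1 + S / Km), tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-6)
})

test_that("mechanism classification is exact on noise-free instances of all four types", {
  set.seed(42)
  types <- c("competitive", "noncompetitive", "uncompetitive", "mixed")
  for (m in types) {
    for (i in 1:5) {
      Km <- runif(1, 0.5, 5); Ki <- runif(1, 1, 20); Vmax <- runif(1, 0.5, 5)
      tr <- kinetic_truth(Vmax = Vmax, Km = Km, Ki = Ki, model = m,
                          Ki2 = if (m == "mixed") Ki * runif(1, 2.5, 6),
                          substrate_grid = Km * c(0.25, 0.5, 1, 2, 4, 8),
                          inhibitor_grid = c(0, Ki * c(0.5, 1, 2)))
      f <- suppressWarnings(fit_inhibition(gen_rate_table(tr, cfg_clean(i))))
      expect_equal(f$inhibition_type, m)
    }
  }
  # degenerate: identical lines cannot be classified
  lines <- data.frame(I = c(0, 5, 10), intercept = 1, slope = 2,
                      intercept_se = 0, slope_se = 0)
  expect_error(classify_inhibition_type(lines), "identical")
})

test_that("the secondary plot returns Km and Ki from apparent Km growth", {
  sec <- ki_secondary_plot(c(2, 4, 6), c(0, 5, 10))
  expect_equal(sec$Km, 2, tolerance = 1e-12)
  expect_equal(sec$Ki, 5, tolerance = 1e-12)
  expect_equal(sec$r.squared, 1)
  # jittered points: truth within the delta-method CI
  set.seed(3)
  ok <- vapply(1:50, function(i) {
    I <- c(0, 2, 5, 10)
    km_app <- 2 * (1 + I / 5) * (1 + rnorm(4, 0, 0.02))
    sec <- ki_secondary_plot(km_app, I)
    abs(sec$Ki - 5) < 3 * sec$Ki_se
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  expect_error(ki_secondary_plot(c(6, 4, 2), c(0, 5, 10)), "slope")
  expect_error(ki_secondary_plot(c(2, 4, 6), c(1, 5, 10)), "I = 0")
})
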