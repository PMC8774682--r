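test_that("generators are bit-identical under the same config and differ across seeds", {
  tr <- ref_kinetic_truth()
  a <- gen_rate_table(tr, cfg_noisy(7))
  b <- gen_rate_table(tr, cfg_noisy(7))
  expect_identical(a, b)
  c2 <- gen_rate_table(tr, cfg_noisy(8))
  expect_false(identical(a$v, c2$v))

  bt <- ref_binding_truth()
  s1 <- gen_quench_titration(bt, cfg_noisy(7))
  s2 <- gen_quench_titration(bt, cfg_noisy(7))
  expect_identical(s1$F, s2$F)
})

test_that("noise-free rate tables equal the closed-form rate law at every point", {
  tr <- kinetic_truth(Vmax = 1, Km = 2, Ki = 5,
                      substrate_grid = c(0.5, 1, 2, 4),
                      inhibitor_grid = c(0, 5))
  tab <- gen_rate_table(tr, cfg_clean())
  expect_equal(tab$v, 1 * tab$S / (2 * (1 + tab$I / 5) + tab$S))
  # direct evaluations of the competitive law
  expect_equal(tab$v[tab$S == 2 & tab$I == 5][1], 1 / 3)
  # half-saturation identity at S = Km, no inhibitor
  tr0 <- kinetic_truth(Vmax = 1, Km = 1, Ki = Inf,
                       substrate_grid = 1, inhibitor_grid = 0)
  expect_equal(gen_rate_table(tr0, cfg_clean())$v, 0.5)
})

test_that("empty or malformed grids are rejected with the field named", {
  expect_error(kinetic_truth(1, 1, 1, numeric(0), 0), "substrate_grid")
  expect_error(kinetic_truth(1, 1, 1, c(2, 1), 0), "substrate_grid")
  expect_error(kinetic_truth(1, 1, 1, 1, numeric(0)), "inhibitor_grid")
  expect_error(binding_truth(Ka = 1e4, Pt = 1e-7, quencher_grid = numeric(0)),
               "quencher_grid")
  expect_error(binding_truth(Ka = 1e4, Pt = 1e-7, quencher_grid = c(1e-6, 2e-6)),
               "quencher_grid")
})

test_that("progress curves accumulate absorbance linearly at the rate-law rate", {
  tr <- kinetic_truth(Vmax = 1e-6, Km = 1, Ki = Inf,
                      substrate_grid = 1, inhibitor_grid = 0)
  curves <- gen_progress_curves(tr, duration = 245, sampling = 5,
                                cfg = cfg_clean(), epsilon = 13600)
  cv <- curves[[1]]
  # rate = Vmax/2 at S = Km; A412 slope = epsilon * rate
  expect_equal(diff(cv$A412[1:2]) / 5, 13600 * 0.5e-6, tolerance = 1e-12)
  # noise-free slope equals the generating rate exactly
  ir <- initial_rate(cv)
  expect_equal(ir$rate, 13600 * 0.5e-6, tolerance = 1e-9)
  expect_error(gen_progress_curves(tr, 100, 0, cfg_clean()), "sampling")
})

test_that("dose-response generator honours the log-logistic identities", {
  g <- gen_dose_response(10, 1, c(0, 5, 10, 20), cfg_clean())
  expect_equal(g$activity[g$I == 0], 100)
  expect_equal(g$activity[g$I == 10], 50)
  # hill solved from a reported (dose, activity) endpoint reproduces it
  h <- hill_from_endpoints(6.42, 26.7, 10)
  g2 <- gen_dose_response(6.42, h, c(6.42, 26.7), cfg_clean())
  expect_equal(g2$activity, c(50, 10), tolerance = 1e-12)
  expect_equal(100 / (1 + 26.7 / 6.42), 19.4, tolerance = 1e-3)
  expect_error(gen_dose_response(6.42, 1, c(-1, 2), cfg_clean()), "grid")
})

test_that("inactivation time courses satisfy the first-order identities", {
  k <- 1.48e-4
  tt <- c(0, log(2) / k, 2 * log(2) / k)
  tc <- gen_inactivation_timecourse(k, tt, cfg_clean())
  expect_equal(tc$activity, c(100, 50, 25), tolerance = 1e-12)
  expect_error(gen_inactivation_timecourse(k, c(10, 5), cfg_clean()),
               "increasing")
  expect_error(gen_inactivation_timecourse(-1, tt, cfg_clean()), "positive")
})

test_that("the 1:1 binding quadratic is monotone, bounded and mass-consistent", {
  Pt <- 1.7e-7
  Qt <- seq(0, 16e-6, length.out = 25)
  for (Ka in c(1e3, 6.66e4, 1e7)) {
    PQ <- solve_bound_complex(Ka, Pt, Qt)
    expect_true(all(diff(PQ) >= -1e-18))           # monotone in Qt
    expect_true(all(PQ <= pmin(Pt, Qt) + 1e-18))   # stoichiometric bound
    # equilibrium relation holds to high relative accuracy
    nz <- Qt > 0
    resid <- Ka - PQ[nz] / ((Pt - PQ[nz]) * (Qt[nz] - PQ[nz]))
    expect_lt(max(abs(resid)) / Ka, 1e-9)
    # mass conservation: free + bound quencher = total
    expect_equal((Qt - PQ) + PQ, Qt, tolerance = 1e-12)
  }
  # monotone in Ka at fixed Qt
  kas <- 10^seq(2, 8, length.out = 13)
  pq_by_ka <- vapply(kas, function(K) solve_bound_complex(K, Pt, 8e-6), 1)
  expect_true(all(diff(pq_by_ka) > 0))
  # stoichiometric limit: Ka -> Inf, Qt >= Pt drives F to 0
  expect_equal(solve_bound_complex(1e15, Pt, 8e-6), Pt, tolerance = 1e-6)
})

test_that("quench titrations obey F(Qt=0) = F0 and the static-quenching model", {
  bt <- ref_binding_truth()
  s <- gen_quench_titration(bt, cfg_clean())
  pk <- peak_metrics(s)
  expect_equal(pk$F_max[1], bt$F0, tolerance = 1e-9)
  PQ <- solve_bound_complex(bt$Ka, bt$Pt, bt$quencher_grid)
  expect_equal(pk$F_max, bt$F0 * (1 - PQ / bt$Pt), tolerance = 1e-9)
})

test_that("inner-filter attenuation is imprinted as 10^(-(Aex+Aem)/2)", {
  grid <- seq(0, 16e-6, length.out = 6)
  bt <- binding_truth(Ka = 6.66e4, Pt = 1.7e-7, quencher_grid = grid,
                      A_ex = seq(0, 0.25, length.out = 6),
                      A_em = seq(0, 0.1, length.out = 6))
  bt0 <- binding_truth(Ka = 6.66e4, Pt = 1.7e-7, quencher_grid = grid)
  s_att <- gen_quench_titration(bt, cfg_clean())
  s_raw <- gen_quench_titration(bt0, cfg_clean())
  fac <- 10^(-(bt$A_ex + bt$A_em) / 2)
  expect_equal(s_att$F, s_raw$F * fac, tolerance = 1e-12)
})

test_that("synchronous generator produces the configured shift and quench endpoint", {
  s <- gen_synchronous(60, shift_total = 2, quench_endpoint = 0.6383,
                       cfg = cfg_clean())
  m <- sync_metrics(s)
  expect_equal(m$rsfq[1], 0)
  expect_equal(m$rsfq[length(m$rsfq)], 0.6383, tolerance = 1e-9)
  expect_equal(m$total_shift, 2, tolerance = 0.1)
  # unquenched series: RSFQ identically zero
  s0 <- gen_synchronous(15, shift_total = 0, quench_endpoint = 0,
                        cfg = cfg_clean())
  expect_equal(sync_metrics(s0)$rsfq, rep(0, 9), tolerance = 1e-12)
  expect_error(gen_synchronous(30, 1, 0.5), "delta_lambda")
  expect_error(gen_synchronous(15, 100, 0.5), "window")
})
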