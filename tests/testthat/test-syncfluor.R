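test_that("channel comparison reports shifts, RSFQ endpoints and the dominant residue", {
  s15 <- gen_synchronous(15, shift_total = 1, quench_endpoint = 0.5848,
                         cfg = cfg_clean())
  s60 <- gen_synchronous(60, shift_total = 2, quench_endpoint = 0.6383,
                         cfg = cfg_clean())
  res <- analyze_sync(s15, s60)
  expect_equal(res$comparison$final_rsfq_trp, 0.6383, tolerance = 1e-6)
  expect_equal(res$comparison$final_rsfq_tyr, 0.5848, tolerance = 1e-6)
  expect_equal(res$comparison$dominant_residue, "Trp")
  expect_equal(res$trp$total_shift, 2, tolerance = 0.1)
  expect_equal(res$tyr$total_shift, 1, tolerance = 0.1)
  expect_equal(res$trp$residue, "Trp")
  expect_equal(res$tyr$residue, "Tyr")
})

test_that("identical unquenched channels give zero RSFQ, zero shift and a tie", {
  s15 <- gen_synchronous(15, 0, 0, cfg = cfg_clean())
  s60 <- gen_synchronous(60, 0, 0, cfg = cfg_clean())
  res <- analyze_sync(s15, s60)
  expect_equal(res$tyr$rsfq, rep(0, 9), tolerance = 1e-12)
  expect_equal(res$trp$total_shift, 0, tolerance = 1e-9)
  expect_equal(res$comparison$dominant_residue, "tie")
})

test_that("a hypsochromic drift is reported with a negative sign", {
  s <- gen_synchronous(60, shift_total = -2, quench_endpoint = 0.3,
                       cfg = cfg_clean())
  expect_equal(sync_metrics(s)$total_shift, -2, tolerance = 0.1)
})

test_that("RSFQ is monotone when peak heights decay monotonically", {
  s <- gen_synchronous(60, shift_total = 1.5, quench_endpoint = 0.7,
                       cfg = cfg_clean(), n_points = 12)
  r <- sync_metrics(s)$rsfq
  expect_true(all(diff(r) > -1e-12))
  # area-based variant agrees for pure Gaussian bands of fixed width
  r_area <- sync_metrics(s, use_area = TRUE)$rsfq
  expect_equal(r_area, r, tolerance = 1e-3)
})

test_that("mismatched titration grids and wrong offsets are rejected", {
  s15 <- gen_synchronous(15, 1, 0.5, cfg = cfg_clean(), n_points = 9)
  s60 <- gen_synchronous(60, 1, 0.5, cfg = cfg_clean(), n_points = 8)
  expect_error(analyze_sync(s15, s60), "mismatched")
  expect_error(analyze_sync(s60, s15), "delta-lambda")
  em <- gen_quench_titration(ref_binding_truth(), cfg_clean())
  expect_error(sync_metrics(em), "delta_lambda")
})
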