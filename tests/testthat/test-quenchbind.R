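make_series <- function(Fpeak, Qt = seq(0, 16e-6, length.out = length(Fpeak)),
                        Pt = 1.7e-7, temperature = 298.15,
                        A_ex = NULL, A_em = NULL) {
  wl <- seq(290, 450, by = 1)
  shape <- exp(-(wl - 343)^2 / (2 * 25^2))
  spectrum_series(wl, outer(Fpeak, shape), Qt, Pt = Pt,
                  temperature = temperature, A_ex = A_ex, A_em = A_em)
}

test_that("inner-filter correction is the exact inverse of the imprinted attenuation", {
  Fpeak <- seq(1000, 400, length.out = 6)
  A_ex <- seq(0, 0.2, length.out = 6)
  A_em <- seq(0, 0.1, length.out = 6)
  s <- make_series(Fpeak, A_ex = A_ex, A_em = A_em)
  s_att <- s
  s_att$F <- s$F * 10^(-(A_ex + A_em) / 2)
  rec <- inner_filter_correct(s_att)
  expect_equal(rec$F, s$F, tolerance = 1e-12)
  # zero absorbance is the identity
  s0 <- make_series(Fpeak, A_ex = rep(0, 6), A_em = rep(0, 6))
  expect_equal(inner_filter_correct(s0)$F, s0$F)
  # scalar check: 100 * 10^((0.2+0.1)/2) = 141.25
  expect_equal(100 * 10^((0.2 + 0.1) / 2), 141.25, tolerance = 1e-4)
  # absent absorbances: no-op with warning
  expect_warning(inner_filter_correct(make_series(Fpeak)), "skipped")
  s_neg <- make_series(Fpeak, A_ex = c(-0.1, rep(0, 5)), A_em = rep(0, 6))
  expect_error(inner_filter_correct(s_neg), "non-negative")
})

test_that("peak metrics interpolate sub-grid maxima and reject edge/flat spectra", {
  wl <- seq(290, 450, by = 1)
  on_grid <- spectrum_series(wl, matrix(exp(-(wl - 343)^2 / 800), 1), 0)
  expect_equal(peak_metrics(on_grid)$lambda_max, 343)
  off_grid <- spectrum_series(wl, matrix(exp(-(wl - 343.4)^2 / 800), 1), 0)
  expect_equal(peak_metrics(off_grid)$lambda_max, 343.4, tolerance = 0.05)
  flat <- spectrum_series(wl, matrix(1, 1, length(wl)), 0)
  expect_error(peak_metrics(flat), "flat")
  edge <- spectrum_series(wl, matrix(exp(-(wl - 290)^2 / 800), 1), 0)
  expect_error(peak_metrics(edge), "edge")
})

test_that("Stern-Volmer slope is exact on ideal data and scale-invariant", {
  Qt <- seq(0, 16e-6, length.out = 10)
  Fpeak <- 1000 / (1 + 1e5 * Qt)
  f <- stern_volmer_fit(make_series(Fpeak))
  expect_equal(f$KSV, 1e5, tolerance = 1e-9)
  expect_equal(f$Kq, 1e5 / 1e-8, tolerance = 1e-9)
  # uniform rescaling of F leaves the slope unchanged
  f2 <- stern_volmer_fit(make_series(Fpeak * 37.3))
  expect_equal(f2$KSV, f$KSV, tolerance = 1e-12)
  # saturating titration curves downward and trips the linearity warning
  bt_sat <- binding_truth(Ka = 1e6, Pt = 8e-6,
                          quencher_grid = seq(0, 16e-6, length.out = 10))
  s_sat <- gen_quench_titration(bt_sat, cfg_clean())
  f_sat <- stern_volmer_fit(s_sat)
  expect_true(length(f_sat$warnings) > 0)
  expect_lt(f_sat$r.squared, 0.98)
})

test_that("quenching classification needs both the KSV trend and the Kq criterion", {
  fits_static <- lapply(1:3, function(i) {
    Qt <- seq(0, 16e-6, length.out = 10)
    KSV <- c(6.45e4, 5.78e4, 5.22e4)[i]
    Tk <- as_kelvin(c(25, 31, 37))[i]
    stern_volmer_fit(make_series(1000 / (1 + KSV * Qt), temperature = Tk))
  })
  expect_equal(classify_quenching(fits_static)$mode, "static")
  # increasing KSV with Kq below the ceiling: dynamic
  fits_dyn <- lapply(1:3, function(i) {
    Qt <- seq(0, 16e-3, length.out = 10)
    KSV <- c(1e3, 2e3, 3e3)[i]
    Tk <- as_kelvin(c(25, 31, 37))[i]
    stern_volmer_fit(make_series(1000 / (1 + KSV * Qt), Qt = Qt,
                                 temperature = Tk),
                     tau0 = 2e-7)
  })
  expect_true(all(vapply(fits_dyn, `[[`, 1, "Kq") <= 2e10))
  expect_equal(classify_quenching(fits_dyn)$mode, "dynamic")
  # flat trend is indeterminate
  fits_flat <- lapply(as_kelvin(c(25, 31, 37)), function(Tk) {
    Qt <- seq(0, 16e-6, length.out = 10)
    stern_volmer_fit(make_series(1000 / (1 + 5e4 * Qt), temperature = Tk))
  })
  expect_equal(classify_quenching(fits_flat)$mode, "indeterminate")
  # single temperature: Kq-only verdict, flagged
  one <- classify_quenching(fits_static[[1]])
  expect_equal(one$mode, "static")
  expect_match(one$flags, "single temperature")
})

test_that("the double-log fit inverts the 1:1 equilibrium generator", {
  s <- gen_quench_titration(ref_binding_truth(), cfg_clean())
  f <- double_log_fit(s)
  expect_equal(f$Ka, 6.66e4, tolerance = 5e-3)
  expect_equal(f$n, 1, tolerance = 0.02)
  # two-point construction with hand-computed slope and intercept
  F0 <- 1000; Fq <- c(800, 500); Qt <- c(0, 4e-6, 12e-6); Pt <- 1e-7
  qfree <- Qt[-1] - (F0 - Fq) * Pt / F0
  y <- log10((F0 - Fq) / Fq)
  slope <- diff(y) / diff(log10(qfree))
  intercept <- y[1] - slope * log10(qfree[1])
  s2 <- make_series(c(F0, Fq), Qt = Qt, Pt = Pt)
  f2 <- double_log_fit(s2)
  expect_equal(f2$n, slope, tolerance = 1e-9)
  expect_equal(f2$Ka, 10^(intercept / slope), tolerance = 1e-9)
  # no quenching at all is an error
  s3 <- make_series(rep(1000, 6))
  expect_error(double_log_fit(s3), "no quenching")
  # over-titration inconsistency: implied free quencher non-positive
  s4 <- make_series(c(1000, 1), Qt = c(0, 4e-6), Pt = 1e-2)
  expect_error(double_log_fit(s4), "free-quencher")
})

test_that("van't Hoff analysis round-trips exact thermodynamics and flags 2-point fits", {
  R <- 8.314
  dH <- -17; dS <- 20
  Tk <- as_kelvin(c(25, 31, 37))
  Ka <- 10^(-dH * 1000 / (2.303 * R * Tk) + dS / (2.303 * R))
  th <- vant_hoff(data.frame(T = Tk, Ka = Ka))
  expect_equal(th$dH, dH, tolerance = 1e-6)
  expect_equal(th$dS, dS, tolerance = 1e-6)
  expect_equal(unname(th$dG), dH - Tk * dS / 1000, tolerance = 1e-6)
  # the Gibbs-route entropy agrees up to the ln(10)-vs-2.303 convention
  expect_equal(unname(th$dS_gibbs), rep(dS, 3), tolerance = 2e-3)
  # constant Ka: zero slope, dH = 0
  th0 <- vant_hoff(data.frame(T = Tk, Ka = rep(5e4, 3)))
  expect_equal(th0$dH, 0, tolerance = 1e-9)
  expect_warning(vant_hoff(data.frame(T = Tk[1:2], Ka = Ka[1:2])), "2 temperatures")
  expect_error(vant_hoff(data.frame(T = Tk, Ka = c(1, -1, 1))), "positive")
})

test_that("full binding round trip recovers the generating thermodynamics at zero noise", {
  R <- 8.314
  dH <- -17; dS <- 20
  Tk <- as_kelvin(c(25, 31, 37))
  Ka_true <- 10^(-dH * 1000 / (2.303 * R * Tk) + dS / (2.303 * R))
  ka_fit <- vapply(seq_along(Tk), function(i) {
    bt <- binding_truth(Ka = Ka_true[i], Pt = 1.7e-7,
                        quencher_grid = seq(0, 16e-6, length.out = 10))
    double_log_fit(gen_quench_titration(bt, cfg_clean(), temperature = Tk[i]))$Ka
  }, 1)
  th <- vant_hoff(data.frame(T = Tk, Ka = ka_fit))
  expect_equal(th$dH, dH, tolerance = 0.01)
  expect_equal(th$dS, dS, tolerance = 0.01)
})

test_that("force classification follows the thermodynamic sign rules", {
  expect_equal(classify_forces(-17.01, 19.15),
               "hydrogen bonds + hydrophobic interactions")
  expect_equal(classify_forces(-10, -10), "van der Waals + hydrogen bonds")
  expect_equal(classify_forces(5, 30), "hydrophobic interactions")
  expect_equal(classify_forces(5, -30), "electrostatic (atypical)")
  expect_match(classify_forces(0.01, 30), "indeterminate")
  expect_error(classify_forces(NA, 1), "finite")
})

test_that("inner-filter correction commutes with peak extraction for flat absorbance", {
  Fpeak <- seq(1000, 400, length.out = 6)
  A <- rep(0.15, 6)
  s <- make_series(Fpeak, A_ex = A, A_em = A)
  pk_then_corr <- peak_metrics(s)$F_max * 10^((A + A) / 2)
  corr_then_pk <- peak_metrics(inner_filter_correct(s))$F_max
  expect_equal(pk_then_corr, corr_then_pk, tolerance = 1e-12)
})
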