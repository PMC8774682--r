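#' True kinetic parameters for synthetic rate data
#'
#' Bundles the generating parameters of a Michaelis-Menten enzyme with a
#' reversible inhibitor, together with the substrate and inhibitor
#' concentration grids over which rates are simulated.
#'
#' @param Vmax Maximum rate (any consistent rate unit, e.g. dA412/min).
#' @param Km Michaelis constant, in the units of `substrate_grid`.
#' @param Ki Inhibition constant, in the units of `inhibitor_grid`. Use
#'   `Inf` for an inhibitor-free enzyme.
#' @param substrate_grid Strictly increasing substrate concentrations.
#' @param inhibitor_grid Strictly increasing inhibitor concentrations
#'   (include 0 for the control).
#' @param model Inhibition mechanism used to generate rates: competitive
#'   (inhibitor binds free enzyme only), noncompetitive (free enzyme and
#'   ES complex equally), uncompetitive (ES complex only), or mixed.
#' @param Ki2 Secondary constant for the mixed mechanism (binding to ES);
#'   ignored otherwise.
#' @return An object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(Vmax, Km, Ki = Inf,
                          substrate_grid, inhibitor_grid = 0,
                          model = c("competitive", "noncompetitive",
                                    "uncompetitive", "mixed"),
                          Ki2 = NULL) {
  model <- match.arg(model)
  if (!all(c(Vmax, Km) > 0) || Ki <= 0) {
    stop("'Vmax', 'Km' and 'Ki' must be positive", call. = FALSE)
  }
  if (length(substrate_grid) == 0L) {
    stop("'substrate_grid' is empty", call. = FALSE)
  }
  if (length(inhibitor_grid) == 0L) {
    stop("'inhibitor_grid' is empty", call. = FALSE)
  }
  if (any(diff(substrate_grid) <= 0) || any(substrate_grid <= 0)) {
    stop("'substrate_grid' must be positive and strictly increasing",
         call. = FALSE)
  }
  if (any(diff(inhibitor_grid) <= 0) || any(inhibitor_grid < 0)) {
    stop("'inhibitor_grid' must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (model == "mixed") {
    if (is.null(Ki2) || Ki2 <= 0) {
      stop("mixed mechanism requires a positive 'Ki2'", call. = FALSE)
    }
  }
  structure(
    list(Vmax = Vmax, Km = Km, Ki = Ki,
         substrate_grid = as.numeric(substrate_grid),
         inhibitor_grid = as.numeric(inhibitor_grid),
         model = model, Ki2 = Ki2),
    class = "kinetic_truth"
  )
}

#' True binding parameters for synthetic quenching titrations
#'
#' @param Ka Association constant, L mol^-1.
#' @param n_sites Number of binding sites (the generator itself simulates a
#'   1:1 equilibrium; `n_sites` is carried as provenance).
#' @param Pt Total protein concentration, mol L^-1.
#' @param quencher_grid Total quencher concentrations, mol L^-1,
#'   non-negative and increasing, starting at 0.
#' @param F0 Unquenched peak fluorescence (arbitrary units).
#' @param peak_center,peak_width Gaussian emission-band center and standard
#'   deviation, nm.
#' @param A_ex,A_em Optional per-point excitation/emission absorbances used
#'   to imprint an inner-filter attenuation on the observed spectra.
#' @return An object of class `binding_truth`.
#' @export
binding_truth <- function(Ka, n_sites = 1, Pt, quencher_grid,
                          F0 = 1000, peak_center = 343, peak_width = 25,
                          A_ex = NULL, A_em = NULL) {
  if (Ka <= 0) stop("'Ka' must be positive", call. = FALSE)
  if (Pt <= 0) stop("'Pt' must be positive", call. = FALSE)
  if (F0 <= 0) stop("'F0' must be positive", call. = FALSE)
  if (length(quencher_grid) == 0L) {
    stop("'quencher_grid' is empty", call. = FALSE)
  }
  if (quencher_grid[1] != 0 || any(diff(quencher_grid) <= 0)) {
    stop("'quencher_grid' must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  structure(
    list(Ka = Ka, n_sites = n_sites, Pt = Pt,
         quencher_grid = as.numeric(quencher_grid),
         F0 = F0, peak_center = peak_center, peak_width = peak_width,
         A_ex = A_ex, A_em = A_em),
    class = "binding_truth"
  )
}

#' Hill coefficient implied by two points of a dose-response curve
#'
#' Solves `activity = 100 / (1 + (I/ic50)^h)` for `h` given one observed
#' (concentration, activity) pair away from the half-inhibition point.
#' Useful when a study reports an IC50 together with the inhibition
#' attained at some higher dose.
#'
#' @param ic50 Half-inhibition concentration.
#' @param I Concentration of the second point.
#' @param activity Residual activity (%) at `I`.
#' @return The Hill coefficient.
#' @examples
#' hill_from_endpoints(6.42, 26.7, 10)  # ~1.54
#' @export
hill_from_endpoints <- function(ic50, I, activity) {
  if (ic50 <= 0 || I <= 0) stop("concentrations must be positive", call. = FALSE)
  if (activity <= 0 || activity >= 100) {
    stop("'activity' must be strictly between 0 and 100%", call. = FALSE)
  }
  if (I == ic50) stop("'I' must differ from 'ic50'", call. = FALSE)
  log(100 / activity - 1) / log(I / ic50)
}

# Michaelis-Menten rate under the four classical reversible mechanisms.
rate_law <- function(S, I, truth) {
  with(truth, switch(model,
    competitive    = Vmax * S / (Km * (1 + I / Ki) + S),
    noncompetitive = Vmax * S / ((Km + S) * (1 + I / Ki)),
    uncompetitive  = Vmax * S / (Km + S * (1 + I / Ki)),
    mixed          = Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / Ki2))
  ))
}

#' Simulate an initial-rate table over a substrate x inhibitor grid
#'
#' Evaluates the selected inhibition rate law on the full grid and applies
#' the configured noise. The generating truth is attached as metadata so
#' downstream fits can be validated by parameter recovery.
#'
#' @param truth A [kinetic_truth()].
#' @param cfg A [synth_config()].
#' @return A data.frame with columns `S`, `I`, `v` (and `rep` when
#'   `cfg$replicates > 1`), carrying the truth in `attr(, "truth")`.
#' @examples
#' tr <- kinetic_truth(Vmax = 1, Km = 2, Ki = 5,
#'                     substrate_grid = c(1, 2, 4, 8),
#'                     inhibitor_grid = c(0, 5, 10))
#' gen_rate_table(tr, synth_config(seed = 1))
#' @export
gen_rate_table <- function(truth, cfg) {
  stopifnot(inherits(truth, "kinetic_truth"), inherits(cfg, "synth_config"))
  set.seed(child_seed(cfg, "rate_table"))
  grid <- expand.grid(S = truth$substrate_grid, I = truth$inhibitor_grid,
                      rep = seq_len(cfg$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  v0 <- rate_law(grid$S, grid$I, truth)
  out <- data.frame(S = grid$S, I = grid$I, v = apply_noise(v0, cfg))
  if (cfg$replicates > 1L) out$rep <- grid$rep
  attr(out, "truth") <- truth
  attr(out, "config") <- cfg
  out
}

#' Simulate Ellman-type absorbance progress curves
#'
#' For each point of the truth's concentration grid, product accumulates at
#' the rate-law rate over an initial linear window and the chromophore is
#' read out as absorbance: `A412(t) = A0 + epsilon * l * [product](t)`.
#' Over the simulated window accumulation is linear, which is the regime an
#' initial-rate analysis assumes.
#'
#' @param truth A [kinetic_truth()] with `Vmax` expressed in mol L^-1 s^-1
#'   of product (the default `epsilon` then converts to absorbance), or in
#'   absorbance units per second if `epsilon = 1, path_length = 1`.
#' @param duration Total monitored time, s.
#' @param sampling Sampling interval, s (the classical Ellman protocol
#'   reads every 5 s).
#' @param cfg A [synth_config()].
#' @param A0 Initial absorbance.
#' @param epsilon Molar extinction coefficient of the chromophore,
#'   M^-1 cm^-1. Defaults to 13600, the standard value for the Ellman
#'   thionitrobenzoate product.
#' @param path_length Optical path length, cm.
#' @return A list of [progress_curve()] objects, one per (S, I) pair.
#' @export
gen_progress_curves <- function(truth, duration, sampling, cfg,
                                A0 = 0, epsilon = 13600, path_length = 1) {
  stopifnot(inherits(truth, "kinetic_truth"), inherits(cfg, "synth_config"))
  if (sampling <= 0) stop("'sampling' must be positive", call. = FALSE)
  if (duration < 4 * sampling) {
    stop("'duration' too short for an initial-rate window", call. = FALSE)
  }
  set.seed(child_seed(cfg, "progress"))
  tt <- seq(0, duration, by = sampling)
  grid <- expand.grid(S = truth$substrate_grid, I = truth$inhibitor_grid,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    rate <- rate_law(grid$S[i], grid$I[i], truth)      # product, M s^-1
    A <- A0 + epsilon * path_length * rate * tt
    progress_curve(tt, apply_noise(A, cfg),
                   meta = list(S = grid$S[i], I = grid$I[i],
                               rate_true = rate, A0 = A0,
                               epsilon = epsilon, path_length = path_length))
  })
}

#' Simulate a dose-response (relative activity) curve
#'
#' Two-parameter log-logistic model with fixed asymptotes (100% at zero
#' dose, 0% at saturating dose): `activity = 100 / (1 + (I/ic50)^hill)`.
#'
#' @param ic50 Half-inhibition concentration.
#' @param hill Hill coefficient (> 0).
#' @param grid Inhibitor concentrations (non-negative).
#' @param cfg A [synth_config()].
#' @return A data.frame with columns `I` and `activity` (%), truth attached
#'   as attributes.
#' @export
gen_dose_response <- function(ic50, hill, grid, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (ic50 <= 0) stop("'ic50' must be positive", call. = FALSE)
  if (hill <= 0) stop("'hill' must be positive", call. = FALSE)
  if (any(grid < 0)) stop("concentrations in 'grid' must be >= 0", call. = FALSE)
  set.seed(child_seed(cfg, "dose"))
  act0 <- 100 / (1 + (grid / ic50)^hill)
  out <- data.frame(I = grid, activity = apply_noise(act0, cfg))
  attr(out, "truth") <- list(ic50 = ic50, hill = hill)
  attr(out, "config") <- cfg
  out
}

#' Simulate first-order inactivation time courses
#'
#' Relative activity decays monophasically from 100% towards a floor:
#' `activity(t) = A_inf + (100 - A_inf) * exp(-k t)`.
#'
#' @param k First-order rate constants, s^-1, one per inhibitor level.
#' @param times Sampling times, s, increasing.
#' @param cfg A [synth_config()].
#' @param A_inf Plateau activity (%) approached at long times.
#' @param inhibitor Optional inhibitor concentrations labelling each `k`.
#' @return A data.frame with columns `t`, `activity`, `I` (long format),
#'   truth attached as attributes.
#' @export
gen_inactivation_timecourse <- function(k, times, cfg, A_inf = 0,
                                        inhibitor = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (any(k <= 0)) stop("all rate constants 'k' must be positive", call. = FALSE)
  if (A_inf < 0 || A_inf >= 100) stop("'A_inf' must be in [0, 100)", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (is.null(inhibitor)) inhibitor <- seq_along(k)
  if (length(inhibitor) != length(k)) {
    stop("'inhibitor' must label each rate constant", call. = FALSE)
  }
  set.seed(child_seed(cfg, "inactivation"))
  out <- do.call(rbind, lapply(seq_along(k), function(i) {
    act0 <- A_inf + (100 - A_inf) * exp(-k[i] * times)
    data.frame(t = times, activity = apply_noise(act0, cfg),
               I = inhibitor[i])
  }))
  attr(out, "truth") <- list(k = k, A_inf = A_inf, inhibitor = inhibitor)
  attr(out, "config") <- cfg
  out
}

#' Bound-complex concentration of a 1:1 binding equilibrium
#'
#' Solves `Ka = [PQ] / (([P]t - [PQ]) ([Q]t - [PQ]))` for the complex
#' concentration, taking the physically meaningful root of the quadratic
#' (the smaller root, which lies in `[0, min(Pt, Qt)]`).
#'
#' @param Ka Association constant, L mol^-1.
#' @param Pt Total protein, mol L^-1.
#' @param Qt Total quencher, mol L^-1 (vectorized).
#' @return Complex concentration(s), mol L^-1.
#' @export
solve_bound_complex <- function(Ka, Pt, Qt) {
  if (Ka <= 0 || Pt <= 0 || any(Qt < 0)) {
    stop("'Ka' and 'Pt' must be positive, 'Qt' non-negative", call. = FALSE)
  }
  b <- Ka * (Pt + Qt) + 1
  cc <- Ka * Pt * Qt
  disc <- b^2 - 4 * Ka * cc
  if (any(disc < 0)) {
    stop("no real root for the binding quadratic (check Ka, Pt, Qt)",
         call. = FALSE)
  }
  # numerically stable form of (b - sqrt(disc)) / (2 Ka)
  PQ <- 2 * cc / (b + sqrt(disc))
  pmin(PQ, pmin(Pt, Qt))   # clamp round-off at the stoichiometric limit
}

#' Simulate a fluorescence-quenching titration
#'
#' Generates one spectrum per titration point. In the default
#' `"equilibrium"` regime the quenched peak intensity follows the 1:1
#' static-quenching model `F = F0 (1 - PQ/Pt)`, with the bound complex
#' `PQ` from [solve_bound_complex()]. In the `"linear"` regime the peak
#' follows the ideal Stern-Volmer law `F = F0 / (1 + Ka Qt)` exactly, which
#' is the limit of the equilibrium model as `Pt -> 0`. Each spectrum is a
#' Gaussian band of the corresponding height; if the truth carries
#' `A_ex`/`A_em`, the observed spectra are attenuated by
#' `10^(-(A_ex + A_em)/2)` to emulate the inner-filter effect.
#'
#' @param truth A [binding_truth()].
#' @param cfg A [synth_config()].
#' @param regime `"equilibrium"` (mass-action 1:1 binding) or `"linear"`
#'   (ideal Stern-Volmer dilution limit).
#' @param temperature Temperature in K, stored in the series.
#' @param wl_grid Wavelength grid, nm (default 290-450 nm at 1 nm).
#' @return A [spectrum_series()].
#' @export
gen_quench_titration <- function(truth, cfg,
                                 regime = c("equilibrium", "linear"),
                                 temperature = 298.15,
                                 wl_grid = seq(290, 450, by = 1)) {
  stopifnot(inherits(truth, "binding_truth"), inherits(cfg, "synth_config"))
  regime <- match.arg(regime)
  set.seed(child_seed(cfg, "quench"))
  Qt <- truth$quencher_grid
  Fpeak <- switch(regime,
    equilibrium = {
      PQ <- solve_bound_complex(truth$Ka, truth$Pt, Qt)
      truth$F0 * (1 - PQ / truth$Pt)
    },
    linear = truth$F0 / (1 + truth$Ka * Qt)
  )
  shape <- exp(-(wl_grid - truth$peak_center)^2 / (2 * truth$peak_width^2))
  FF <- outer(Fpeak, shape)
  if (!is.null(truth$A_ex) || !is.null(truth$A_em)) {
    A_ex <- if (is.null(truth$A_ex)) rep(0, length(Qt)) else truth$A_ex
    A_em <- if (is.null(truth$A_em)) rep(0, length(Qt)) else truth$A_em
    FF <- FF * 10^(-(A_ex + A_em) / 2)
  } else {
    A_ex <- A_em <- NULL
  }
  FF <- apply_noise(FF, cfg)
  FF[FF < 0] <- 0
  spectrum_series(
    wavelength = wl_grid, F = FF, Qt = Qt, Pt = truth$Pt,
    temperature = temperature, A_ex = A_ex, A_em = A_em,
    meta = list(truth = truth, regime = regime, config = cfg)
  )
}

#' Simulate a synchronous-fluorescence titration series
#'
#' Gaussian peaks whose center drifts linearly with titration index (a
#' positive `shift_total` is a bathochromic/red shift) and whose height
#' decays linearly from F0 to `(1 - quench_endpoint) * F0`.
#'
#' @param delta_lambda Scan offset, nm; 15 probes tyrosine, 60 tryptophan.
#' @param shift_total Total peak displacement over the titration, nm
#'   (signed; positive = towards longer wavelengths).
#' @param quench_endpoint Final fractional quench of the peak height,
#'   in [0, 1).
#' @param grid_step Wavelength sampling step, nm (<= 1).
#' @param cfg A [synth_config()].
#' @param n_points Number of titration points including Qt = 0.
#' @param Qt Total quencher grid, mol L^-1; defaults to an even 0-16 uM
#'   titration.
#' @param peak_center Initial peak position, nm; defaults to the classical
#'   tyrosine (294 nm) or tryptophan (285 nm) synchronous peak of an
#'   acetylcholinesterase-type protein depending on `delta_lambda`.
#' @param peak_width Gaussian standard deviation, nm.
#' @param F0 Unquenched peak height.
#' @return A [spectrum_series()] with `delta_lambda` recorded.
#' @export
gen_synchronous <- function(delta_lambda, shift_total, quench_endpoint,
                            grid_step = 1, cfg = synth_config(),
                            n_points = 9,
                            Qt = seq(0, 16e-6, length.out = n_points),
                            peak_center = if (delta_lambda == 15) 294 else 285,
                            peak_width = 8, F0 = 1000) {
  if (!delta_lambda %in% c(15, 60)) {
    stop("'delta_lambda' must be 15 or 60 nm", call. = FALSE)
  }
  if (grid_step > 1) stop("'grid_step' must be <= 1 nm", call. = FALSE)
  if (quench_endpoint < 0 || quench_endpoint >= 1) {
    stop("'quench_endpoint' must be in [0, 1)", call. = FALSE)
  }
  stopifnot(inherits(cfg, "synth_config"))
  # window: peak +- 4 widths, extended to contain the drifted peak
  lo <- peak_center - 4 * peak_width + min(0, shift_total)
  hi <- peak_center + 4 * peak_width + max(0, shift_total)
  if (abs(shift_total) > 4 * peak_width) {
    stop("'shift_total' exceeds the spectral window", call. = FALSE)
  }
  set.seed(child_seed(cfg, "sync"))
  wl <- seq(lo, hi, by = grid_step)
  n <- length(Qt)
  frac <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  centers <- peak_center + frac * shift_total
  heights <- F0 * (1 - frac * quench_endpoint)
  FF <- t(vapply(seq_len(n), function(i) {
    heights[i] * exp(-(wl - centers[i])^2 / (2 * peak_width^2))
  }, numeric(length(wl))))
  FF <- apply_noise(FF, cfg)
  FF[FF < 0] <- 0
  spectrum_series(
    wavelength = wl, F = FF, Qt = Qt, temperature = 298.15,
    delta_lambda = delta_lambda,
    meta = list(shift_total = shift_total,
                quench_endpoint = quench_endpoint,
                peak_center = peak_center, peak_width = peak_width,
                F0 = F0, config = cfg)
  )
}
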