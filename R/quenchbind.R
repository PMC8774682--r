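#' Correct a titration series for the inner-filter effect
#'
#' Absorption of the exciting and emitted light by the titrant attenuates
#' the observed fluorescence; the standard correction restores
#' `F_corr = F_obs * 10^((A_ex + A_em)/2)` per titration point, with
#' `A_ex`/`A_em` the solution absorbances at the excitation and emission
#' wavelengths.
#'
#' @param series A [spectrum_series()] carrying `A_ex` and `A_em`. If both
#'   are absent the series is returned unchanged with a warning.
#' @return The corrected [spectrum_series()] (absorbances zeroed out so
#'   the correction is not applied twice).
#' @export
inner_filter_correct <- function(series) {
  stopifnot(inherits(series, "spectrum_series"))
  if (is.null(series$A_ex) && is.null(series$A_em)) {
    warning("no excitation/emission absorbances recorded; ",
            "inner-filter correction skipped")
    return(series)
  }
  A_ex <- if (is.null(series$A_ex)) rep(0, length(series$Qt)) else series$A_ex
  A_em <- if (is.null(series$A_em)) rep(0, length(series$Qt)) else series$A_em
  if (any(A_ex < 0) || any(A_em < 0)) {
    stop("absorbances must be non-negative", call. = FALSE)
  }
  series$F <- series$F * 10^((A_ex + A_em) / 2)
  series$A_ex <- rep(0, length(series$Qt))
  series$A_em <- rep(0, length(series$Qt))
  series$meta$inner_filter_corrected <- TRUE
  series
}

#' Peak position and height per titration point
#'
#' Locates the discrete maximum of each spectrum and refines both the
#' position and the height by parabolic interpolation through the three
#' bracketing points, resolving sub-grid peak positions.
#'
#' @param series A [spectrum_series()].
#' @return A data.frame with columns `Qt`, `lambda_max` (nm), `F_max`.
#' @export
peak_metrics <- function(series) {
  stopifnot(inherits(series, "spectrum_series"))
  wl <- series$wavelength
  out <- lapply(seq_along(series$Qt), function(i) {
    y <- series$F[i, ]
    if (diff(range(y)) == 0) {
      stop("spectrum ", i, " is flat; no peak to locate", call. = FALSE)
    }
    j <- which.max(y)
    if (j == 1L || j == length(y)) {
      stop("spectrum ", i, " peaks at the grid edge; extend the window",
           call. = FALSE)
    }
    y1 <- y[j - 1L]; y2 <- y[j]; y3 <- y[j + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
    step <- wl[j + 1L] - wl[j]
    data.frame(Qt = series$Qt[i],
               lambda_max = wl[j] + delta * step,
               F_max = y2 - 0.25 * (y1 - y3) * delta)
  })
  do.call(rbind, out)
}

#' Stern-Volmer analysis of a quenching titration at one temperature
#'
#' Fits `F0/F = 1 + KSV [Q]` by least squares with the intercept fixed at
#' 1 (the form of the Stern-Volmer law); a free-intercept diagnostic line
#' is reported alongside. The bimolecular quenching rate constant follows
#' as `Kq = KSV / tau0`, with `tau0` the unquenched fluorophore lifetime.
#' Downward curvature of the plot (saturation of the quenched fraction)
#' is flagged through the R-squared of the constrained line.
#'
#' @param series A [spectrum_series()] (inner-filter corrected).
#' @param tau0 Fluorophore lifetime, s; 1e-8 s is the standard biopolymer
#'   value.
#' @param r2_warn Linearity threshold below which a warning is attached.
#' @return An object of class `quench_fit`: `KSV` (L mol^-1), `KSV_se`,
#'   `Kq` (L mol^-1 s^-1), `tau0`, `r.squared`, `free_fit` (intercept and
#'   slope of the unconstrained line), `temperature`, `warnings`.
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8, r2_warn = 0.98) {
  stopifnot(inherits(series, "spectrum_series"))
  if (length(series$Qt) < 5L) {
    stop("at least 5 titration points are required", call. = FALSE)
  }
  pk <- peak_metrics(series)
  if (any(pk$F_max <= 0)) stop("zero fluorescence in series", call. = FALSE)
  F0 <- pk$F_max[1]
  y <- F0 / pk$F_max
  x <- series$Qt
  # least squares with intercept fixed at 1: minimize sum((y - 1 - b x)^2)
  b <- sum(x * (y - 1)) / sum(x^2)
  res <- y - 1 - b * x
  dof <- length(x) - 1L
  b_se <- sqrt(sum(res^2) / dof / sum(x^2))
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  free <- stats::lm(y ~ x)
  warnings <- character()
  if (r2 < r2_warn) {
    warnings <- c(warnings, sprintf(
      "Stern-Volmer plot deviates from linearity (R^2 = %.4f); possible saturation or mixed quenching", r2))
  }
  structure(
    list(KSV = b, KSV_se = b_se, Kq = b / tau0, tau0 = tau0,
         r.squared = r2,
         free_fit = list(intercept = unname(stats::coef(free)[1]),
                         slope = unname(stats::coef(free)[2]),
                         r.squared = .lm_summary(free)$r.squared),
         temperature = series$temperature, warnings = warnings),
    class = "quench_fit"
  )
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer: KSV = %.4g L/mol (SE %.2g), R^2 = %.4f\n",
              x$KSV, x$KSV_se, x$r.squared))
  cat(sprintf("  Kq = %.3g L/mol/s (tau0 = %.1g s) at %.5g K\n",
              x$Kq, x$tau0, x$temperature))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Static quenching (ground-state complex formation) shows a Stern-Volmer
#' constant that *decreases* with temperature and an apparent bimolecular
#' rate constant far above the diffusion-collision ceiling of
#' 2.0e10 L mol^-1 s^-1; dynamic (collisional) quenching shows the
#' opposite trend with Kq at or below the ceiling. Both criteria are
#' evaluated separately and the verdict requires them to agree.
#'
#' @param fits A list of [stern_volmer_fit()] results at distinct
#'   temperatures (a single fit is allowed: the verdict then rests on the
#'   Kq criterion alone and is flagged).
#' @param kq_ceiling Diffusion-limited collisional ceiling, L mol^-1 s^-1.
#' @return A list with `mode` (`"static"`, `"dynamic"`, or
#'   `"indeterminate"`), `trend`, `kq_above_ceiling`, `flags`.
#' @export
classify_quenching <- function(fits, kq_ceiling = 2.0e10) {
  if (inherits(fits, "quench_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "quench_fit")))
  Tv <- vapply(fits, `[[`, numeric(1), "temperature")
  KSV <- vapply(fits, `[[`, numeric(1), "KSV")
  Kq <- vapply(fits, `[[`, numeric(1), "Kq")
  flags <- character()
  if (length(fits) == 1L) {
    mode <- if (Kq[1] > kq_ceiling) "static" else "dynamic"
    return(list(mode = mode, trend = NA_character_,
                kq_above_ceiling = Kq[1] > kq_ceiling,
                flags = "single temperature: verdict from Kq criterion only"))
  }
  if (anyDuplicated(Tv)) stop("temperatures must be distinct", call. = FALSE)
  ord <- order(Tv)
  KSV <- KSV[ord]; Kq <- Kq[ord]
  trend <- if (all(diff(KSV) < 0)) "decreasing"
           else if (all(diff(KSV) > 0)) "increasing"
           else "none"
  above <- all(Kq > kq_ceiling)
  below <- all(Kq <= kq_ceiling)
  mode <- if (trend == "decreasing" && above) "static"
          else if (trend == "increasing" && below) "dynamic"
          else "indeterminate"
  if (mode == "indeterminate") {
    flags <- c(flags, sprintf(
      "KSV trend with temperature: %s; Kq %s the %.2g L/mol/s collisional ceiling",
      trend,
      if (above) "above" else if (below) "at or below" else "straddles",
      kq_ceiling))
  }
  list(mode = mode, trend = trend, kq_above_ceiling = above, flags = flags)
}

#' Double-logarithmic binding fit (modified Stern-Volmer)
#'
#' Estimates the association constant and binding-site number of a 1:1
#' static-quenching equilibrium from the linearization
#' `log10((F0-F)/F) = n log10(Ka) + n log10([Q]_free)`, where the free
#' quencher concentration is inferred from the measured quench fraction:
#' `[Q]_free = Qt - (F0-F) Pt / F0`. The slope is the site number n and
#' the intercept divided by the slope is `log10(Ka)`.
#'
#' @param series A [spectrum_series()] with `Pt` recorded.
#' @return An object of class `binding_fit`: `Ka` (L mol^-1), `n`,
#'   standard errors, `r.squared`, `temperature`, and the `lm` fit.
#' @export
double_log_fit <- function(series) {
  stopifnot(inherits(series, "spectrum_series"))
  if (is.na(series$Pt) || series$Pt <= 0) {
    stop("'Pt' (total protein concentration) is required for the ",
         "double-logarithmic fit", call. = FALSE)
  }
  pk <- peak_metrics(series)
  F0 <- pk$F_max[1]
  Fq <- pk$F_max[-1]
  Qt <- series$Qt[-1]
  if (all(abs(Fq - F0) <= 1e-12 * F0)) {
    stop("no quenching observed (F = F0 at all points)", call. = FALSE)
  }
  if (any(Fq >= F0) || any(Fq <= 0)) {
    stop("require 0 < F < F0 at every non-zero titration point",
         call. = FALSE)
  }
  qfree <- Qt - (F0 - Fq) * series$Pt / F0
  if (any(qfree <= 0)) {
    stop("implied free-quencher concentration is non-positive; ",
         "titration is inconsistent with Pt (over-titration)", call. = FALSE)
  }
  d <- data.frame(x = log10(qfree), y = log10((F0 - Fq) / Fq))
  fit <- stats::lm(y ~ x, data = d)
  cf <- stats::coef(fit)
  se <- .lm_summary(fit)$coefficients[, 2]
  n <- unname(cf[2])
  if (n <= 0) stop("non-positive slope; no binding signal", call. = FALSE)
  ka <- 10^(unname(cf[1]) / n)
  structure(
    list(Ka = ka, n = n, n_se = unname(se[2]),
         intercept = unname(cf[1]), intercept_se = unname(se[1]),
         r.squared = .lm_summary(fit)$r.squared,
         temperature = series$temperature, fit = fit),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit: Ka = %.4g L/mol, n = %.3g (R^2 %.4f) at %.5g K\n",
              x$Ka, x$n, x$r.squared, x$temperature))
  invisible(x)
}

#' Van't Hoff analysis of temperature-dependent binding constants
#'
#' Linear regression of `log10(Ka)` on `1/T`:
#' `log10 Ka = -dH/(2.303 R T) + dS/(2.303 R)`, so the slope yields the
#' binding enthalpy and the intercept a (notoriously extrapolation-
#' sensitive) entropy estimate. The free energy at each temperature is
#' computed from `dG = dH - T dS` using the intercept entropy; a second
#' entropy estimate, `dS_gibbs = (dH - dG_direct)/T` with
#' `dG_direct = -R T ln(Ka)`, is reported as a consistency pair, since
#' the two need not agree when the Ka values carry rounding error.
#'
#' @param Ka_by_T Data.frame with columns `T` (K) and `Ka` (L mol^-1), or
#'   a named numeric vector of Ka with temperatures (K) as names.
#' @return An object of class `binding_thermo`: `dH` (kJ mol^-1), `dS`
#'   (intercept estimate, J mol^-1 K^-1), `dG` (kJ mol^-1 per input
#'   temperature, from dH - T dS), `dG_direct`, `dS_gibbs`,
#'   `r.squared`, `force_label`, `warnings`.
#' @export
vant_hoff <- function(Ka_by_T) {
  if (is.numeric(Ka_by_T) && !is.null(names(Ka_by_T))) {
    Ka_by_T <- data.frame(T = as.numeric(names(Ka_by_T)), Ka = unname(Ka_by_T))
  }
  stopifnot(is.data.frame(Ka_by_T), all(c("T", "Ka") %in% names(Ka_by_T)))
  if (any(Ka_by_T$Ka <= 0)) stop("'Ka' must be positive", call. = FALSE)
  if (any(Ka_by_T$T <= 0)) stop("temperatures must be in kelvin (> 0)",
                                call. = FALSE)
  nT <- nrow(Ka_by_T)
  warnings <- character()
  if (nT < 2L) stop("at least 2 temperatures are required", call. = FALSE)
  if (nT == 2L) {
    warning("only 2 temperatures: van't Hoff line has no residual degrees ",
            "of freedom")
    warnings <- c(warnings,
                  "only 2 temperatures: van't Hoff line has no residual df")
  }
  d <- data.frame(x = 1 / Ka_by_T$T, y = log10(Ka_by_T$Ka))
  fit <- stats::lm(y ~ x, data = d)
  cf <- stats::coef(fit)
  dH <- -2.303 * .R_GAS * unname(cf[2]) / 1000       # kJ/mol
  dS <- 2.303 * .R_GAS * unname(cf[1])               # J/mol/K
  dG <- dH - Ka_by_T$T * dS / 1000                   # kJ/mol per T
  dG_direct <- -.R_GAS * Ka_by_T$T * log(Ka_by_T$Ka) / 1000
  dS_gibbs <- (dH - dG_direct) * 1000 / Ka_by_T$T
  r2 <- if (nT > 2L) .lm_summary(fit)$r.squared else 1
  structure(
    list(dH = dH, dS = dS,
         dG = stats::setNames(dG, Ka_by_T$T),
         dG_direct = stats::setNames(dG_direct, Ka_by_T$T),
         dS_gibbs = stats::setNames(dS_gibbs, Ka_by_T$T),
         Ka = stats::setNames(Ka_by_T$Ka, Ka_by_T$T),
         r.squared = r2,
         force_label = classify_forces(dH, dS),
         warnings = warnings, fit = fit),
    class = "binding_thermo"
  )
}

#' @export
print.binding_thermo <- function(x, ...) {
  cat("Van't Hoff binding thermodynamics\n")
  cat(sprintf("  dH = %.4g kJ/mol, dS = %.4g J/mol/K (R^2 %.4f)\n",
              x$dH, x$dS, x$r.squared))
  for (i in seq_along(x$dG)) {
    cat(sprintf("  T = %s K: dG = %.4g kJ/mol (direct -RT ln Ka: %.4g)\n",
                names(x$dG)[i], x$dG[i], x$dG_direct[i]))
  }
  cat("  dominant forces: ", x$force_label, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T dS`, with dH in kJ mol^-1 and dS in J mol^-1 K^-1.
#'
#' @param dH Enthalpy change, kJ mol^-1.
#' @param dS Entropy change, J mol^-1 K^-1.
#' @param T_K Temperature(s), K.
#' @return Free energy, kJ mol^-1.
#' @examples
#' gibbs_free_energy(-17.01, 19.15, 298.15)  # about -22.72
#' @export
gibbs_free_energy <- function(dH, dS, T_K) {
  dH - T_K * dS / 1000
}

#' Dominant noncovalent forces from the signs of dH and dS
#'
#' The classical sign-rule mapping for small-molecule/protein binding:
#' negative enthalpy with positive entropy points to hydrogen bonding
#' plus hydrophobic interactions; both negative to van der Waals plus
#' hydrogen bonds; both positive to hydrophobic interactions; positive
#' enthalpy with negative entropy (rare) to electrostatics.
#'
#' @param dH Enthalpy change, kJ mol^-1.
#' @param dS Entropy change, J mol^-1 K^-1.
#' @param dead_band_H,dead_band_S Magnitudes below which the sign is
#'   treated as indeterminate (kJ mol^-1 and J mol^-1 K^-1).
#' @return A force label string.
#' @examples
#' classify_forces(-17.01, 19.15)
#' @export
classify_forces <- function(dH, dS, dead_band_H = 0.1, dead_band_S = 0.5) {
  if (!is.finite(dH) || !is.finite(dS)) {
    stop("'dH' and 'dS' must be finite", call. = FALSE)
  }
  if (abs(dH) < dead_band_H || abs(dS) < dead_band_S) {
    return("indeterminate (near-zero dH or dS)")
  }
  if (dH < 0 && dS > 0) "hydrogen bonds + hydrophobic interactions"
  else if (dH < 0 && dS < 0) "van der Waals + hydrogen bonds"
  else if (dH > 0 && dS > 0) "hydrophobic interactions"
  else "electrostatic (atypical)"
}

#' Convert Celsius to kelvin
#'
#' @param celsius Temperature(s) in degrees Celsius.
#' @return Temperature(s) in K (offset 273.15).
#' @export
as_kelvin <- function(celsius) celsius + 273.15
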