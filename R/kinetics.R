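#' Absorbance progress curve from a chromogenic enzyme assay
#'
#' @param time Sampling times, s, strictly increasing.
#' @param A412 Absorbance readings, same length as `time`.
#' @param meta Named list of assay metadata (enzyme/substrate/inhibitor
#'   concentrations, temperature, extinction coefficient...).
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(time, A412, meta = list()) {
  if (length(time) != length(A412)) {
    stop("'time' and 'A412' must have equal length", call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("'time' must be strictly increasing", call. = FALSE)
  }
  structure(list(time = as.numeric(time), A412 = as.numeric(A412),
                 meta = meta),
            class = "progress_curve")
}

#' Initial rate from a progress curve
#'
#' Ordinary least-squares slope of absorbance against time over the stated
#' window. If an extinction coefficient (M^-1 cm^-1) and path length are
#' supplied, the slope is also converted to a molar product rate. When the
#' curve extends beyond the window, the post-window residuals from the
#' fitted line are inspected: a strong monotone trend flags late-phase
#' curvature (substrate depletion), meaning the window choice matters.
#'
#' @param curve A [progress_curve()].
#' @param window Length-2 numeric, time window in s; defaults to the full
#'   curve.
#' @param epsilon,path_length Optional conversion to molar rate.
#' @return A list with `rate` (absorbance units s^-1), `rate_molar`
#'   (M s^-1 or `NA`), `r.squared`, `se`, `n`, and `curvature_flag`.
#' @export
initial_rate <- function(curve, window = range(curve$time),
                         epsilon = NULL, path_length = 1) {
  stopifnot(inherits(curve, "progress_curve"))
  if (window[1] < min(curve$time) || window[2] > max(curve$time)) {
    stop("'window' lies outside the recorded time range", call. = FALSE)
  }
  inside <- curve$time >= window[1] & curve$time <= window[2]
  if (sum(inside) < 5L) {
    stop("initial-rate window must contain at least 5 points", call. = FALSE)
  }
  fit <- stats::lm(A412 ~ time,
                   data = data.frame(time = curve$time[inside],
                                     A412 = curve$A412[inside]))
  sm <- .lm_summary(fit)
  slope <- unname(stats::coef(fit)[2])
  # late-phase curvature check on points beyond the window
  after <- curve$time > window[2]
  curvature <- FALSE
  if (sum(after) >= 5L) {
    resid_late <- curve$A412[after] -
      stats::predict(fit, data.frame(time = curve$time[after]))
    trend <- suppressWarnings(stats::cor(curve$time[after], resid_late))
    curvature <- is.finite(trend) && abs(trend) > 0.9 &&
      max(abs(resid_late)) > 10 * sm$sigma
  }
  list(
    rate = slope,
    rate_molar = if (!is.null(epsilon)) slope / (epsilon * path_length)
                 else NA_real_,
    r.squared = sm$r.squared,
    se = sm$coefficients[2, 2],
    n = sum(inside),
    curvature_flag = curvature
  )
}

#' Relative enzyme activity
#'
#' @param v Observed rate.
#' @param v_control Uninhibited control rate (> 0), defined as 100%.
#' @return Activity in percent.
#' @export
relative_activity <- function(v, v_control) {
  if (any(v_control <= 0)) stop("'v_control' must be positive", call. = FALSE)
  100 * v / v_control
}

#' Fit a dose-response curve and estimate the IC50
#'
#' Nonlinear least-squares fit of the two-parameter log-logistic model
#' `activity = 100 / (1 + (I/IC50)^h)` with fixed asymptotes at 100% and
#' 0%. Requires the data to actually cross 50% activity inside the tested
#' range; a monotone increase of activity with dose is rejected as a
#' wrong-sign input.
#'
#' @param dr Data.frame with columns `I` (concentration) and `activity`
#'   (%), e.g. from [gen_dose_response()] or [read_dose_response()].
#' @param conf_level Confidence level for the asymptotic interval.
#' @return An object of class `ic50_fit`: `ic50`, `hill`, standard errors,
#'   `ci` (matrix), and the `nls` fit.
#' @export
fit_ic50 <- function(dr, conf_level = 0.95) {
  stopifnot(is.data.frame(dr), all(c("I", "activity") %in% names(dr)))
  dr <- dr[order(dr$I), , drop = FALSE]
  if (length(unique(dr$I)) < 5L) {
    stop("at least 5 distinct concentrations are required", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor(dr$I, dr$activity, method = "spearman"))
  if (is.finite(ct) && ct > 0.5) {
    stop("activity increases with dose; an inhibition model cannot be fitted",
         call. = FALSE)
  }
  if (min(dr$activity) > 50 || max(dr$activity) < 50) {
    stop("data do not cross 50% activity; extend the concentration range",
         call. = FALSE)
  }
  # starting value: log-linear interpolation of the 50% crossing
  pos <- dr$I > 0
  i50 <- stats::approx(dr$activity[pos], log(dr$I[pos]), xout = 50,
                       ties = mean)$y
  start <- list(ic50 = exp(i50), h = 1)
  fit <- minpack.lm::nlsLM(
    activity ~ 100 / (1 + (I / ic50)^h),
    data = dr, start = start,
    lower = c(ic50 = 1e-12, h = 0.05), upper = c(ic50 = Inf, h = 20),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, 2]
  z <- stats::qt(1 - (1 - conf_level) / 2, df = stats::df.residual(fit))
  ci <- cbind(lower = est - z * se, upper = est + z * se)
  structure(
    list(ic50 = unname(est["ic50"]), hill = unname(est["h"]),
         se = se, ci = ci, conf_level = conf_level, fit = fit),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g (SE %.2g), Hill = %.3g (SE %.2g)\n",
              x$ic50, x$se["ic50"], x$hill, x$se["h"]))
  invisible(x)
}

#' Reversibility test from rate-versus-enzyme plots
#'
#' At each inhibitor level, the initial rate is regressed on total enzyme
#' concentration. A reversible inhibitor reduces the slope of these lines
#' while leaving them passing through the origin; an irreversible
#' (titrating) inhibitor displaces their intercept instead. The verdict is
#' "reversible" when every intercept's confidence interval covers zero and
#' the slopes decrease with inhibitor concentration.
#'
#' @param df Data.frame with columns `E` (enzyme concentration), `v`
#'   (rate) and `I` (inhibitor concentration).
#' @param conf_level Confidence level of the intercept-zero test.
#' @return An object of class `reversibility_result` with per-level
#'   `slopes`, `intercepts`, their CIs, and a `verdict`.
#' @export
reversibility_test <- function(df, conf_level = 0.95) {
  stopifnot(is.data.frame(df), all(c("E", "v", "I") %in% names(df)))
  levs <- sort(unique(df$I))
  if (length(levs) < 2L) {
    stop("at least 2 inhibitor levels are required", call. = FALSE)
  }
  res <- lapply(levs, function(ii) {
    d <- df[df$I == ii, , drop = FALSE]
    if (nrow(d) < 3L) {
      stop("at least 3 enzyme concentrations per inhibitor level",
           call. = FALSE)
    }
    fit <- stats::lm(v ~ E, data = d)
    # confint warns via summary.lm on zero-residual lines; synthetic
    # origin-line inputs hit that case legitimately
    ci <- suppressWarnings(stats::confint(fit, level = conf_level))
    list(I = ii, slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         intercept_ci = ci[1, ], r.squared = .lm_summary(fit)$r.squared)
  })
  slopes <- vapply(res, `[[`, numeric(1), "slope")
  intercept_zero <- vapply(res, function(r) {
    r$intercept_ci[1] <= 0 && 0 <= r$intercept_ci[2]
  }, logical(1))
  slopes_decreasing <- all(diff(slopes) < 0)
  verdict <- if (all(intercept_zero) && slopes_decreasing) {
    "reversible"
  } else {
    "irreversible-like"
  }
  structure(
    list(levels = levs, slopes = slopes,
         intercepts = vapply(res, `[[`, numeric(1), "intercept"),
         intercept_zero = intercept_zero,
         slopes_decreasing = slopes_decreasing,
         per_level = res, verdict = verdict),
    class = "reversibility_result"
  )
}

#' @export
print.reversibility_result <- function(x, ...) {
  cat("Reversibility test (", length(x$levels), " inhibitor levels): ",
      x$verdict, "\n", sep = "")
  invisible(x)
}

#' Fit the inhibition model to an initial-rate table
#'
#' Classical double-reciprocal analysis plus a global nonlinear fit.
#' Per inhibitor level, `1/v` is regressed on `1/S` (Lineweaver-Burk);
#' the line parameters give the apparent Michaelis constant
#' `Km_app = slope/intercept` and apparent maximum rate
#' `Vmax_app = 1/intercept`. The pattern of the lines classifies the
#' mechanism (see [classify_inhibition_type()]); for a competitive
#' pattern, `Km_app` grows linearly with inhibitor concentration and the
#' secondary plot (see [ki_secondary_plot()]) returns Km and Ki. A global
#' nonlinear fit of the competitive law
#' `v = Vmax S / (Km (1 + I/Ki) + S)` is reported alongside, since the
#' reciprocal transform distorts the error structure.
#'
#' @param table Data.frame with columns `S`, `I`, `v` (a rate table from
#'   [gen_rate_table()] or [read_rate_table()]).
#' @return An object of class `kinetic_fit` with elements `lines` (per-I
#'   reciprocal fits), `Km`, `Vmax`, `Ki`, `Km_app`, `inhibition_type`,
#'   `secondary` (the [ki_secondary_plot()] result), `nonlinear`
#'   (global-fit coefficients or `NULL`), and `warnings`.
#' @export
fit_inhibition <- function(table) {
  stopifnot(is.data.frame(table), all(c("S", "I", "v") %in% names(table)))
  warnings <- character()
  bad <- table$v <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with v <= 0 dropped (reciprocal undefined)")
    warnings <- c(warnings, "rows with non-positive rates dropped")
    table <- table[!bad, , drop = FALSE]
  }
  levs <- sort(unique(table$I))
  if (length(levs) < 3L || !(0 %in% levs)) {
    stop("need >= 3 inhibitor levels including I = 0", call. = FALSE)
  }
  lines <- do.call(rbind, lapply(levs, function(ii) {
    d <- table[table$I == ii, , drop = FALSE]
    if (length(unique(d$S)) < 4L) {
      stop("need >= 4 substrate levels at I = ", ii, call. = FALSE)
    }
    fit <- stats::lm(y ~ x, data = data.frame(x = 1 / d$S, y = 1 / d$v))
    cf <- stats::coef(fit)
    se <- .lm_summary(fit)$coefficients[, 2]
    data.frame(I = ii, intercept = unname(cf[1]), slope = unname(cf[2]),
               intercept_se = unname(se[1]), slope_se = unname(se[2]),
               r.squared = .lm_summary(fit)$r.squared)
  }))
  if (any(lines$intercept <= 0) || any(lines$slope <= 0)) {
    stop("non-positive reciprocal-plot parameters; data are not saturable",
         call. = FALSE)
  }
  lines$Km_app <- lines$slope / lines$intercept
  lines$Vmax_app <- 1 / lines$intercept
  type <- classify_inhibition_type(lines)

  sec <- tryCatch(ki_secondary_plot(lines$Km_app, lines$I),
                  error = function(e) {
                    warnings <<- c(warnings, conditionMessage(e))
                    NULL
                  })
  # global nonlinear fit of the competitive law
  nl <- tryCatch({
    start <- list(
      Vmax = lines$Vmax_app[lines$I == 0],
      Km = lines$Km_app[lines$I == 0],
      Ki = if (!is.null(sec) && is.finite(sec$Ki)) sec$Ki else 1
    )
    fit <- minpack.lm::nlsLM(
      v ~ Vmax * S / (Km * (1 + I / Ki) + S), data = table, start = start,
      lower = c(Vmax = 1e-12, Km = 1e-12, Ki = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15)
    )
    as.list(stats::coef(fit))
  }, error = function(e) {
    warnings <<- c(warnings, paste("global nonlinear fit failed:",
                                   conditionMessage(e)))
    NULL
  })

  structure(
    list(
      lines = lines,
      Km = if (!is.null(sec)) sec$Km else lines$Km_app[lines$I == 0],
      Vmax = lines$Vmax_app[lines$I == 0],
      Km_app = stats::setNames(lines$Km_app, lines$I),
      Ki = if (!is.null(sec)) sec$Ki else NA_real_,
      inhibition_type = type,
      secondary = sec,
      nonlinear = nl,
      warnings = warnings
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Inhibition kinetics (double-reciprocal analysis)\n")
  cat("  type: ", x$inhibition_type, "\n", sep = "")
  cat(sprintf("  Km = %.4g, Vmax = %.4g, Ki = %.4g\n", x$Km, x$Vmax, x$Ki))
  if (!is.null(x$nonlinear)) {
    cat(sprintf("  global fit: Km = %.4g, Vmax = %.4g, Ki = %.4g\n",
                x$nonlinear$Km, x$nonlinear$Vmax, x$nonlinear$Ki))
  }
  invisible(x)
}

# Tolerance for "constant across inhibitor levels": twice the pooled
# standard error, floored at a small relative epsilon so that noise-free
# tables (SEs ~ machine precision) still classify.
.const_tol <- function(values, ses) {
  2 * sqrt(mean(ses^2)) + 1e-8 * mean(abs(values))
}

#' Classify the inhibition mechanism from double-reciprocal lines
#'
#' Uses the canonical Lineweaver-Burk patterns. With `1/v = a + b/S` per
#' inhibitor level: a common intercept `a` with growing slope `b` means
#' competitive inhibition (lines meet on the 1/v axis); a common slope
#' with growing intercept means uncompetitive (parallel lines); a constant
#' apparent Km (`b/a`) with growing intercept means noncompetitive (lines
#' meet on the 1/S axis); anything else is mixed. "Constant" is judged
#' against twice the pooled standard error of the line parameters.
#'
#' @param lines Data.frame with one row per inhibitor level and columns
#'   `I`, `intercept`, `slope`, `intercept_se`, `slope_se` (as produced
#'   inside [fit_inhibition()]).
#' @return One of `"competitive"`, `"noncompetitive"`, `"uncompetitive"`,
#'   `"mixed"`.
#' @export
classify_inhibition_type <- function(lines) {
  stopifnot(is.data.frame(lines),
            all(c("I", "intercept", "slope") %in% names(lines)))
  if (nrow(lines) < 3L) {
    stop("need >= 3 inhibitor levels to classify", call. = FALSE)
  }
  if (!all(c("intercept_se", "slope_se") %in% names(lines))) {
    lines$intercept_se <- lines$slope_se <- 0
  }
  lines <- lines[order(lines$I), , drop = FALSE]
  int <- lines$intercept; slo <- lines$slope
  tol_int <- .const_tol(int, lines$intercept_se)
  tol_slo <- .const_tol(slo, lines$slope_se)
  km_app <- slo / int
  # delta-method SE of slope/intercept
  km_se <- abs(km_app) * sqrt((lines$slope_se / slo)^2 +
                              (lines$intercept_se / int)^2)
  tol_km <- .const_tol(km_app, km_se)

  int_const <- diff(range(int)) <= tol_int
  slo_const <- diff(range(slo)) <= tol_slo
  km_const <- diff(range(km_app)) <= tol_km
  if (int_const && slo_const) {
    stop("all reciprocal lines are identical; no inhibition to classify",
         call. = FALSE)
  }
  increasing <- function(x, tol) all(diff(x) > -tol)
  if (int_const && !slo_const && increasing(slo, tol_slo)) {
    "competitive"
  } else if (slo_const && !int_const && increasing(int, tol_int)) {
    "uncompetitive"
  } else if (km_const && !int_const && increasing(int, tol_int)) {
    "noncompetitive"
  } else {
    "mixed"
  }
}

#' Secondary plot: apparent Km versus inhibitor concentration
#'
#' For competitive inhibition the apparent Michaelis constant grows
#' linearly with inhibitor concentration,
#' `Km_app = (Km/Ki) I + Km`, so an ordinary least-squares line through
#' the (I, Km_app) points returns Km as its intercept and Ki as
#' intercept/slope.
#'
#' @param Km_app Apparent Michaelis constants, one per inhibitor level.
#' @param I Inhibitor concentrations (must include 0).
#' @return A list with `Ki`, `Km`, `slope`, `r.squared`, `Ki_se` (delta
#'   method), and the `lm` fit.
#' @examples
#' ki_secondary_plot(c(2, 4, 6), c(0, 5, 10))  # Km = 2, Ki = 5
#' @export
ki_secondary_plot <- function(Km_app, I) {
  if (length(Km_app) != length(I) || length(I) < 3L) {
    stop("need >= 3 (I, Km_app) points", call. = FALSE)
  }
  if (!0 %in% I) stop("'I' must include the uninhibited control (I = 0)",
                      call. = FALSE)
  fit <- stats::lm(Km_app ~ I)
  cf <- stats::coef(fit)
  if (cf[2] <= 0) {
    stop("secondary plot has non-positive slope; Ki is undefined ",
         "(apparent Km does not grow with inhibitor)", call. = FALSE)
  }
  se <- .lm_summary(fit)$coefficients[, 2]
  ki <- unname(cf[1] / cf[2])
  ki_se <- abs(ki) * sqrt((se[1] / cf[1])^2 + (se[2] / cf[2])^2)
  list(Ki = ki, Km = unname(cf[1]), slope = unname(cf[2]),
       r.squared = .lm_summary(fit)$r.squared, Ki_se = unname(ki_se), fit = fit)
}
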