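#' Fluorescence spectrum series across a quencher titration
#'
#' Container for a set of emission (or synchronous-scan) spectra recorded
#' while titrating a quencher into a fixed protein solution. The first
#' titration point must be the quencher-free spectrum, which defines F0.
#'
#' @param wavelength Numeric wavelength grid in nm, strictly increasing.
#' @param F Numeric matrix of fluorescence intensities, one row per
#'   titration point, one column per wavelength. All values must be >= 0.
#' @param Qt Total quencher concentration (mol L^-1) per titration point,
#'   non-negative and strictly increasing, `Qt[1] == 0`.
#' @param Pt Total protein concentration (mol L^-1).
#' @param temperature Temperature in K.
#' @param A_ex,A_em Optional per-point absorbances at the excitation and
#'   emission wavelengths, used by [inner_filter_correct()].
#' @param delta_lambda Optional synchronous-scan offset in nm (15 or 60),
#'   `NA` for ordinary emission spectra.
#' @param meta Optional named list of provenance metadata (e.g. generating
#'   parameters for synthetic series).
#' @return An object of class `spectrum_series`.
#' @seealso [gen_quench_titration()], [peak_metrics()], [stern_volmer_fit()]
#' @export
spectrum_series <- function(wavelength, F, Qt, Pt = NA_real_,
                            temperature = 298.15,
                            A_ex = NULL, A_em = NULL,
                            delta_lambda = NA_real_, meta = list()) {
  F <- as.matrix(F)
  if (any(diff(wavelength) <= 0)) {
    stop("'wavelength' must be strictly increasing", call. = FALSE)
  }
  if (nrow(F) != length(Qt) || ncol(F) != length(wavelength)) {
    stop("'F' must be a length(Qt) x length(wavelength) matrix",
         call. = FALSE)
  }
  if (any(F < 0)) stop("fluorescence intensities must be >= 0", call. = FALSE)
  if (length(Qt) < 1L || Qt[1] != 0) {
    stop("first titration point must have Qt = 0 (defines F0)", call. = FALSE)
  }
  if (any(diff(Qt) <= 0)) {
    stop("'Qt' must be strictly increasing", call. = FALSE)
  }
  for (a in list(A_ex, A_em)) {
    if (!is.null(a) && length(a) != length(Qt)) {
      stop("'A_ex'/'A_em' must have one value per titration point",
           call. = FALSE)
    }
  }
  structure(
    list(wavelength = as.numeric(wavelength), F = F, Qt = as.numeric(Qt),
         Pt = Pt, temperature = temperature,
         A_ex = A_ex, A_em = A_em, delta_lambda = delta_lambda, meta = meta),
    class = "spectrum_series"
  )
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat("Spectrum series: ", length(x$Qt), " titration points, ",
      length(x$wavelength), " wavelengths (",
      min(x$wavelength), "-", max(x$wavelength), " nm)\n", sep = "")
  cat("  Qt range: 0 - ", format(max(x$Qt), digits = 4), " mol/L",
      if (!is.na(x$Pt)) sprintf("; Pt = %.3g mol/L", x$Pt), "\n", sep = "")
  if (!is.na(x$delta_lambda)) {
    cat("  synchronous scan, delta-lambda = ", x$delta_lambda, " nm\n",
        sep = "")
  }
  cat("  temperature: ", x$temperature, " K\n", sep = "")
  invisible(x)
}
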