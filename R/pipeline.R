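#' Pipeline configuration
#'
#' Declares the input files for each analysis stage and the physical
#' constants shared across stages. Any stage may be omitted; the pipeline
#' runs whatever is configured.
#'
#' @param rate_table Path to a rate-table CSV (inhibition-kinetics stage).
#' @param dose_response Path to a dose-response CSV (IC50 stage).
#' @param timecourse Path to a long time-course CSV (inactivation stage).
#' @param spectra Character vector of spectrum-series CSV paths, one per
#'   temperature (quenching/binding stage).
#' @param ka_table Path to a Ka-by-temperature CSV; used for the
#'   thermodynamics stage when no spectra are given.
#' @param sync15,sync60 Paths to synchronous-scan CSVs at delta-lambda 15
#'   and 60 nm.
#' @param tau0 Fluorophore lifetime, s.
#' @param R_gas Gas constant, J mol^-1 K^-1 (fixed by nature; exposed for
#'   unit experiments only).
#' @param epsilon_TNB Extinction coefficient for absorbance-to-product
#'   conversion, M^-1 cm^-1.
#' @param ddG_temperature Temperature (K) at which inactivation
#'   free-energy changes are reported.
#' @param outdir Output directory for reports.
#' @param seed Seed recorded in the report provenance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(rate_table = NULL, dose_response = NULL,
                            timecourse = NULL, spectra = NULL,
                            ka_table = NULL, sync15 = NULL, sync60 = NULL,
                            tau0 = 1e-8, R_gas = 8.314,
                            epsilon_TNB = 13600,
                            ddG_temperature = 298,
                            outdir = NULL, seed = 1L) {
  paths <- c(rate_table, dose_response, timecourse, spectra, ka_table,
             sync15, sync60)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    stop("configured input file(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (tau0 <= 0 || R_gas <= 0 || epsilon_TNB <= 0 || ddG_temperature <= 0) {
    stop("physical constants must be positive", call. = FALSE)
  }
  structure(
    list(rate_table = rate_table, dose_response = dose_response,
         timecourse = timecourse, spectra = spectra, ka_table = ka_table,
         sync15 = sync15, sync60 = sync60,
         tau0 = tau0, R_gas = R_gas, epsilon_TNB = epsilon_TNB,
         ddG_temperature = ddG_temperature,
         outdir = outdir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the configured analysis stages
#'
#' Executes, in dependency order, whichever stages have inputs: rate
#' table -> inhibition fit and classification; dose response -> IC50;
#' time courses -> per-level first-order inactivation and transition
#' free energies; spectra -> Stern-Volmer fits, quenching
#' classification, double-log binding fits and Van't Hoff
#' thermodynamics (or thermodynamics alone from a Ka table); sync
#' pair -> residue-channel comparison. Warnings raised by any stage are
#' collected as first-class report fields.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `report_bundle`; see [render_report()] and
#'   [write_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- list()
  warnings <- character()
  note <- function(ws) {
    if (length(ws)) warnings <<- c(warnings, ws)
  }
  grab <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  if (!is.null(config$rate_table)) {
    tab <- read_rate_table(config$rate_table)
    fit <- grab(fit_inhibition(tab))
    note(fit$warnings)
    results$inhibition <- fit
  }
  if (!is.null(config$dose_response)) {
    dr <- read_dose_response(config$dose_response)
    results$ic50 <- grab(fit_ic50(dr))
  }
  if (!is.null(config$timecourse)) {
    tc <- read_timecourse(config$timecourse)
    levels <- sort(unique(tc$I))
    fits <- lapply(levels, function(ii) {
      d <- tc[tc$I == ii, ]
      grab(fit_first_order(
        activity_timecourse(d$t, d$activity, inhibitor = ii,
                            temperature = config$ddG_temperature)))
    })
    names(fits) <- levels
    results$inactivation <- fits
  }
  if (!is.null(config$spectra)) {
    series <- lapply(config$spectra, read_spectrum_series)
    series <- lapply(series, function(s) {
      if (!is.null(s$A_ex) || !is.null(s$A_em)) grab(inner_filter_correct(s))
      else s
    })
    sv <- lapply(series, function(s) {
      f <- grab(stern_volmer_fit(s, tau0 = config$tau0))
      note(f$warnings)
      f
    })
    results$stern_volmer <- sv
    cls <- classify_quenching(sv)
    note(cls$flags)
    results$quench_mode <- cls
    bind <- lapply(series, function(s) grab(double_log_fit(s)))
    results$binding <- bind
    ka_by_t <- data.frame(
      T = vapply(bind, `[[`, numeric(1), "temperature"),
      Ka = vapply(bind, `[[`, numeric(1), "Ka")
    )
    if (nrow(ka_by_t) >= 2L) {
      th <- grab(vant_hoff(ka_by_t))
      note(th$warnings)
      results$thermo <- th
    }
  } else if (!is.null(config$ka_table)) {
    th <- grab(vant_hoff(read_ka_table(config$ka_table)))
    note(th$warnings)
    results$thermo <- th
  }
  if (!is.null(config$sync15) && !is.null(config$sync60)) {
    results$sync <- analyze_sync(read_spectrum_series(config$sync15),
                                 read_spectrum_series(config$sync60))
  }
  structure(
    list(results = results, warnings = unique(warnings),
         provenance = list(
           package_version = as.character(utils::packageVersion("quenchkin")),
           seed = config$seed,
           constants = list(tau0 = config$tau0, R_gas = config$R_gas,
                            epsilon_TNB = config$epsilon_TNB,
                            ddG_temperature = config$ddG_temperature),
           inputs = config[c("rate_table", "dose_response", "timecourse",
                             "spectra", "ka_table", "sync15", "sync60")]
         )),
    class = "report_bundle"
  )
}

# Convert a report bundle into plain lists (JSON-ready), with units.
report_as_list <- function(bundle) {
  r <- bundle$results
  out <- list()
  if (!is.null(r$inhibition)) {
    f <- r$inhibition
    out$inhibition <- list(
      type = f$inhibition_type,
      Km = list(value = f$Km, units = "substrate concentration units"),
      Vmax = list(value = f$Vmax, units = "rate units"),
      Ki = list(value = f$Ki,
                se = if (!is.null(f$secondary)) f$secondary$Ki_se else NA,
                units = "inhibitor concentration units"),
      Km_app = as.list(f$Km_app),
      lines_r_squared = f$lines$r.squared,
      nonlinear = f$nonlinear
    )
  }
  if (!is.null(r$ic50)) {
    out$ic50 <- list(
      value = r$ic50$ic50, se = unname(r$ic50$se["ic50"]),
      hill = r$ic50$hill, units = "inhibitor concentration units"
    )
  }
  if (!is.null(r$inactivation)) {
    out$inactivation <- lapply(r$inactivation, function(f) {
      list(k = list(value = f$k, se = unname(f$se["k"]), units = "s^-1"),
           A_inf = list(value = f$A_inf, units = "percent"),
           phase = f$phase,
           ddG = list(value = f$ddG, units = "kJ mol^-1",
                      temperature_K = f$temperature),
           k_semilog = f$k_semilog,
           r_squared_semilog = f$r.squared_semilog)
    })
  }
  if (!is.null(r$stern_volmer)) {
    out$stern_volmer <- lapply(r$stern_volmer, function(f) {
      list(temperature_K = f$temperature,
           KSV = list(value = f$KSV, se = f$KSV_se, units = "L mol^-1"),
           Kq = list(value = f$Kq, units = "L mol^-1 s^-1"),
           r_squared = f$r.squared)
    })
    out$quench_mode <- r$quench_mode[c("mode", "trend")]
  }
  if (!is.null(r$binding)) {
    out$binding <- lapply(r$binding, function(f) {
      list(temperature_K = f$temperature,
           Ka = list(value = f$Ka, units = "L mol^-1"),
           n = list(value = f$n, se = f$n_se, units = "dimensionless"),
           r_squared = f$r.squared)
    })
  }
  if (!is.null(r$thermo)) {
    th <- r$thermo
    out$thermodynamics <- list(
      dH = list(value = th$dH, units = "kJ mol^-1"),
      dS = list(value = th$dS, units = "J mol^-1 K^-1",
                estimate = "van't Hoff intercept"),
      dS_gibbs = list(value = unname(th$dS_gibbs),
                      temperature_K = as.numeric(names(th$dS_gibbs)),
                      units = "J mol^-1 K^-1",
                      estimate = "(dH - dG_direct)/T consistency pair"),
      dG = list(value = unname(th$dG),
                temperature_K = as.numeric(names(th$dG)),
                units = "kJ mol^-1"),
      r_squared = th$r.squared,
      force_label = th$force_label
    )
  }
  if (!is.null(r$sync)) {
    out$synchronous <- list(
      tyr = list(delta_lambda_nm = r$sync$tyr$delta_lambda,
                 total_shift_nm = r$sync$tyr$total_shift,
                 final_rsfq = r$sync$tyr$rsfq[length(r$sync$tyr$rsfq)]),
      trp = list(delta_lambda_nm = r$sync$trp$delta_lambda,
                 total_shift_nm = r$sync$trp$total_shift,
                 final_rsfq = r$sync$trp$rsfq[length(r$sync$trp$rsfq)]),
      dominant_residue = r$sync$comparison$dominant_residue
    )
  }
  list(results = out, warnings = bundle$warnings,
       provenance = bundle$provenance)
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (machine-readable, loss-free re-parseable) and
#' `report.txt` (human-readable summary tables) into `outdir`.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the path of the JSON report.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report_as_list(bundle), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  writeLines(render_report(bundle), file.path(outdir, "report.txt"))
  invisible(json_path)
}

#' Render a human-readable report summary
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  r <- bundle$results
  out <- c("== Inhibitor characterization report ==", "")
  if (!is.null(r$ic50)) {
    out <- c(out, sprintf("IC50: %.4g (Hill %.3g)", r$ic50$ic50, r$ic50$hill))
  }
  if (!is.null(r$inhibition)) {
    f <- r$inhibition
    out <- c(out,
             sprintf("Inhibition type: %s", f$inhibition_type),
             sprintf("Km = %.4g, Vmax = %.4g, Ki = %.4g", f$Km, f$Vmax, f$Ki),
             "(Km/Ki in the units of the input concentration columns)")
  }
  if (!is.null(r$inactivation)) {
    out <- c(out, "", "Inactivation kinetics:",
             "  [I]    k (s^-1)      ddG (kJ/mol)  phase")
    for (nm in names(r$inactivation)) {
      f <- r$inactivation[[nm]]
      out <- c(out, sprintf("  %-6s %-13.4g %-13.4g %s",
                            nm, f$k, f$ddG, f$phase))
    }
  }
  if (!is.null(r$stern_volmer)) {
    out <- c(out, "", "Fluorescence quenching:",
             "  T (K)    KSV (L/mol)   Kq (L/mol/s)  R^2")
    for (f in r$stern_volmer) {
      out <- c(out, sprintf("  %-8.5g %-13.4g %-13.3g %.4f",
                            f$temperature, f$KSV, f$Kq, f$r.squared))
    }
    out <- c(out, sprintf("  quenching mode: %s", r$quench_mode$mode))
  }
  if (!is.null(r$binding)) {
    out <- c(out, "", "Binding (double-log fit):",
             "  T (K)    Ka (L/mol)    n       R^2")
    for (f in r$binding) {
      out <- c(out, sprintf("  %-8.5g %-13.4g %-7.3g %.4f",
                            f$temperature, f$Ka, f$n, f$r.squared))
    }
  }
  if (!is.null(r$thermo)) {
    th <- r$thermo
    out <- c(out, "", "Thermodynamics (van't Hoff):",
             sprintf("  dH = %.4g kJ/mol, dS = %.4g J/mol/K (intercept)",
                     th$dH, th$dS),
             sprintf("  dG(T): %s kJ/mol",
                     paste(sprintf("%.4g", th$dG), collapse = ", ")),
             sprintf("  dominant forces: %s", th$force_label))
  }
  if (!is.null(r$sync)) {
    cmp <- r$sync$comparison
    out <- c(out, "", "Synchronous fluorescence:",
             sprintf("  Tyr (d15): shift %+.2f nm, final RSFQ %.2f%%",
                     r$sync$tyr$total_shift, 100 * cmp$final_rsfq_tyr),
             sprintf("  Trp (d60): shift %+.2f nm, final RSFQ %.2f%%",
                     r$sync$trp$total_shift, 100 * cmp$final_rsfq_trp),
             sprintf("  dominant residue: %s", cmp$dominant_residue))
  }
  if (length(bundle$warnings)) {
    out <- c(out, "", "Warnings:",
             paste0("  - ", bundle$warnings))
  }
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  writeLines(render_report(x))
  invisible(x)
}

#' Write the full synthetic fixture family
#'
#' Generates, from one master seed, the complete set of CSV inputs the
#' analysis stages read: a competitive rate table, a dose-response curve,
#' first-order inactivation time courses at four inhibitor levels,
#' quenching titrations at three temperatures (with Ka following a
#' van't Hoff temperature dependence), and a synchronous-scan pair. All
#' files embed their generating truths in the header block, so any
#' downstream fit can be checked by parameter recovery.
#'
#' @param outdir Output directory, created if needed.
#' @param master_seed Integer master seed.
#' @param noise_model,noise_scale Passed to [synth_config()]; the default
#'   is noise-free, in which case every stage fit recovers its generating
#'   parameters exactly.
#' @return Invisibly, a named list of the written file paths.
#' @export
make_fixtures <- function(outdir, master_seed = 1L,
                          noise_model = "none", noise_scale = 0) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- function(offset) synth_config(seed = master_seed + offset,
                                       noise_model = noise_model,
                                       noise_scale = noise_scale)
  paths <- list()

  tr <- kinetic_truth(Vmax = 1, Km = 1.674, Ki = 4.32,
                      substrate_grid = c(0.5, 1, 2, 4, 8, 16),
                      inhibitor_grid = c(0, 4, 8, 10))
  paths$rate_table <- file.path(outdir, "rate_table.csv")
  write_rate_table(gen_rate_table(tr, cfg(0)), paths$rate_table,
                   units = list(S = "mM", I = "uM", v = "dA412/min"))

  dr <- gen_dose_response(ic50 = 6.42, hill = hill_from_endpoints(6.42, 26.7, 10),
                          grid = c(0, 0.5, 1, 2, 3.2, 5, 8, 12.7, 16, 20, 26.7),
                          cfg = cfg(1))
  paths$dose_response <- file.path(outdir, "dose_response.csv")
  write_dose_response(dr, paths$dose_response)

  times <- c(seq(0, 30, by = 3), seq(36, 60, by = 6), 70, 80) * 60
  tc <- gen_inactivation_timecourse(
    k = c(1.48e-4, 2.42e-4, 4.01e-4, 5.18e-4), times = times,
    cfg = cfg(2), A_inf = 0, inhibitor = c(2, 4, 8, 16))
  paths$timecourse <- file.path(outdir, "timecourse.csv")
  write_timecourse(tc, paths$timecourse)

  # Ka(T) on an exact van't Hoff line anchored at Ka(298.15) = 6.66e4
  dH <- -17.01; dS <- 35.4
  temps <- as_kelvin(c(25, 31, 37))
  ka <- 10^(-dH * 1000 / (2.303 * 8.314 * temps) + dS / (2.303 * 8.314))
  ka <- ka * 6.66e4 / ka[1]
  paths$spectra <- character(3)
  for (i in seq_along(temps)) {
    bt <- binding_truth(Ka = ka[i], Pt = 1.7e-7,
                        quencher_grid = seq(0, 16e-6, length.out = 10))
    s <- gen_quench_titration(bt, cfg(3 + i), temperature = temps[i])
    paths$spectra[i] <- file.path(outdir,
                                  sprintf("quench_%dK.csv", round(temps[i])))
    write_spectrum_series(s, paths$spectra[i])
  }

  s15 <- gen_synchronous(15, shift_total = 1, quench_endpoint = 0.5848,
                         cfg = cfg(7))
  s60 <- gen_synchronous(60, shift_total = 2, quench_endpoint = 0.6383,
                         cfg = cfg(8))
  paths$sync15 <- file.path(outdir, "sync_d15.csv")
  paths$sync60 <- file.path(outdir, "sync_d60.csv")
  write_spectrum_series(s15, paths$sync15)
  write_spectrum_series(s60, paths$sync60)

  invisible(paths)
}
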