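# CSV interchange: every writer emits a '#'-prefixed header block of
# key=value provenance lines (schema version, generating truth for
# synthetic files), and every reader returns those as attr(, "meta").

.SCHEMA_VERSION <- "quenchkin-csv-1"

write_header <- function(con, meta) {
  writeLines(paste0("# schema=", .SCHEMA_VERSION), con)
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.null(v) || length(v) == 0L) next
    writeLines(paste0("# ", nm, "=",
                      paste(format(v, digits = 17, trim = TRUE),
                            collapse = ",")), con)
  }
}

read_header <- function(path) {
  lines <- readLines(path, n = 200L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- lapply(vals, function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else v
  })
  stats::setNames(meta, keys)
}

read_csv_meta <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(df, "meta") <- read_header(path)
  df
}

#' Write / read an initial-rate table
#'
#' Columns `S`, `I`, `v`; provenance (including generating truth for
#' synthetic tables) goes into a `#`-commented key=value header.
#'
#' @param table A rate-table data.frame (e.g. from [gen_rate_table()]).
#' @param path File path.
#' @param units Optional named list of unit strings (`S`, `I`, `v`).
#' @return `write_rate_table()` returns `path` invisibly;
#'   `read_rate_table()` the data.frame with header metadata attached.
#' @export
write_rate_table <- function(table, path, units = NULL) {
  tr <- attr(table, "truth")
  meta <- list()
  if (!is.null(tr)) {
    meta <- list(Vmax = tr$Vmax, Km = tr$Km, Ki = tr$Ki, model = tr$model)
  }
  if (!is.null(units)) meta <- c(meta, stats::setNames(
    as.list(unlist(units)), paste0("units_", names(units))))
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, meta)
  utils::write.csv(as.data.frame(table)[c("S", "I", "v")], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) read_csv_meta(path, c("S", "I", "v"))

#' Write / read a dose-response table
#'
#' Columns `I`, `activity_percent`.
#'
#' @param dr Data.frame with `I`, `activity` (e.g. [gen_dose_response()]).
#' @param path File path.
#' @return The path (writer, invisibly) or a data.frame with columns
#'   `I`, `activity` (reader).
#' @export
write_dose_response <- function(dr, path) {
  tr <- attr(dr, "truth")
  meta <- if (!is.null(tr)) list(ic50 = tr$ic50, hill = tr$hill) else list()
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, meta)
  utils::write.csv(data.frame(I = dr$I, activity_percent = dr$activity),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  df <- read_csv_meta(path, c("I", "activity_percent"))
  out <- data.frame(I = df$I, activity = df$activity_percent)
  attr(out, "meta") <- attr(df, "meta")
  out
}

#' Write / read inactivation time courses (long format)
#'
#' Columns `t_s`, `activity_percent`, `I`.
#'
#' @param tc Long data.frame with `t`, `activity`, `I`
#'   (e.g. [gen_inactivation_timecourse()]).
#' @param path File path.
#' @return The path (writer, invisibly) or a long data.frame with columns
#'   `t`, `activity`, `I` (reader).
#' @export
write_timecourse <- function(tc, path) {
  tr <- attr(tc, "truth")
  meta <- if (!is.null(tr)) {
    list(k = tr$k, A_inf = tr$A_inf, inhibitor = tr$inhibitor)
  } else list()
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, meta)
  utils::write.csv(data.frame(t_s = tc$t, activity_percent = tc$activity,
                              I = tc$I), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- read_csv_meta(path, c("t_s", "activity_percent", "I"))
  out <- data.frame(t = df$t_s, activity = df$activity_percent, I = df$I)
  attr(out, "meta") <- attr(df, "meta")
  out
}

#' Write / read a spectrum series
#'
#' The CSV holds the wavelength grid in its first column
#' (`wavelength_nm`) and one intensity column per titration point, named
#' by the quencher concentration in micromolar. Scalar metadata (Pt,
#' temperature, delta-lambda) and per-point absorbances live in a JSON
#' sidecar at `<path>.json`.
#'
#' @param series A [spectrum_series()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return The path (writer, invisibly) or a [spectrum_series()] (reader).
#' @export
write_spectrum_series <- function(series, path) {
  stopifnot(inherits(series, "spectrum_series"))
  df <- data.frame(wavelength_nm = series$wavelength, check.names = FALSE)
  qt_um <- series$Qt * 1e6
  for (i in seq_along(series$Qt)) {
    df[[format(qt_um[i], digits = 15, trim = TRUE)]] <- series$F[i, ]
  }
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, list(columns = "Qt_uM"))
  utils::write.csv(df, con, row.names = FALSE)
  sidecar <- list(
    Pt = series$Pt, temperature = series$temperature,
    delta_lambda = series$delta_lambda,
    A_ex = series$A_ex, A_em = series$A_em
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_spectrum_series
#' @export
read_spectrum_series <- function(path) {
  df <- read_csv_meta(path, "wavelength_nm")
  sidecar_path <- paste0(path, ".json")
  side <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    list()
  }
  qcols <- setdiff(names(df), "wavelength_nm")
  Qt <- as.numeric(qcols) * 1e-6
  if (anyNA(Qt)) {
    stop("spectrum columns must be named by Qt in micromolar", call. = FALSE)
  }
  null2na <- function(x, default = NA_real_) {
    if (is.null(x) || length(x) == 0L) default else x
  }
  spectrum_series(
    wavelength = df$wavelength_nm,
    F = t(as.matrix(df[qcols])),
    Qt = Qt,
    Pt = null2na(side$Pt),
    temperature = null2na(side$temperature, 298.15),
    A_ex = if (length(side$A_ex)) side$A_ex else NULL,
    A_em = if (length(side$A_em)) side$A_em else NULL,
    delta_lambda = null2na(side$delta_lambda),
    meta = attr(df, "meta")
  )
}

#' Write / read a binding-constant-by-temperature table
#'
#' Columns `T_K`, `Ka` for the Van't Hoff stage.
#'
#' @param ka_by_t Data.frame with columns `T` (K) and `Ka` (L mol^-1).
#' @param path File path.
#' @return The path (writer, invisibly) or a data.frame with columns `T`
#'   and `Ka` (reader).
#' @export
write_ka_table <- function(ka_by_t, path) {
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, list())
  utils::write.csv(data.frame(T_K = ka_by_t$T, Ka = ka_by_t$Ka), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ka_table
#' @export
read_ka_table <- function(path) {
  df <- read_csv_meta(path, c("T_K", "Ka"))
  data.frame(T = df$T_K, Ka = df$Ka)
}
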