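#' Configuration for the synthetic-data generators
#'
#' Every generator in the package draws its randomness through a
#' `synth_config`, so that a dataset is fully determined by the
#' configuration: the same seed and noise settings always produce
#' bit-identical output.
#'
#' @param seed Integer master seed. Each generator derives a stage-specific
#'   child seed from it by a fixed offset (see [child_seed()]), so different
#'   stages driven by one master seed do not share random streams.
#' @param noise_model One of `"none"`, `"gaussian_additive"`,
#'   `"gaussian_multiplicative"`. Additive noise has standard deviation
#'   `noise_scale` times the mean absolute signal; multiplicative noise
#'   scales each point by `1 + N(0, noise_scale)`.
#' @param noise_scale Non-negative fraction of signal (e.g. `0.01` for 1%).
#' @param replicates Integer number of technical replicates to emit per
#'   design point.
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1, noise_model = "gaussian_multiplicative",
#'                     noise_scale = 0.01)
#' @export
synth_config <- function(seed = 1L,
                         noise_model = c("none", "gaussian_additive",
                                         "gaussian_multiplicative"),
                         noise_scale = 0,
                         replicates = 1L) {
  noise_model <- match.arg(noise_model)
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  if (!is.numeric(noise_scale) || length(noise_scale) != 1L || noise_scale < 0) {
    stop("'noise_scale' must be a single non-negative number", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  structure(
    list(seed = seed, noise_model = noise_model,
         noise_scale = noise_scale, replicates = replicates),
    class = "synth_config"
  )
}

# Fixed per-stage offsets; documented so that a pipeline run from one master
# seed has reproducible, non-overlapping streams per stage.
.stage_offsets <- c(
  rate_table   = 101L,
  progress     = 211L,
  dose         = 307L,
  inactivation = 401L,
  quench       = 503L,
  sync         = 601L
)

#' Derive a stage-specific child seed from a master seed
#'
#' @param cfg A [synth_config()].
#' @param stage Stage name, one of `names(quenchkin:::.stage_offsets)`.
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(cfg, stage) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!stage %in% names(.stage_offsets)) {
    stop("unknown stage '", stage, "'", call. = FALSE)
  }
  as.integer((as.double(cfg$seed) + 1009 * .stage_offsets[[stage]]) %%
               .Machine$integer.max)
}

# Apply the configured noise model to a numeric vector/matrix of model values.
# The caller is responsible for having seeded the RNG (via child_seed).
apply_noise <- function(x, cfg) {
  switch(cfg$noise_model,
    none = x,
    gaussian_additive = {
      sd <- cfg$noise_scale * mean(abs(x))
      x + stats::rnorm(length(x), 0, sd)
    },
    gaussian_multiplicative = {
      x * (1 + stats::rnorm(length(x), 0, cfg$noise_scale))
    }
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat("  seed:       ", x$seed, "\n", sep = "")
  cat("  noise:      ", x$noise_model,
      if (x$noise_model != "none") sprintf(" (scale %.3g)", x$noise_scale),
      "\n", sep = "")
  cat("  replicates: ", x$replicates, "\n", sep = "")
  invisible(x)
}
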