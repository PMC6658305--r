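#' Vaccine vocabulary
#'
#' The twelve vaccine labels recognised throughout the package. Combination
#' single-shot vaccines (DTaP, MMR) count as single vaccinations.
#'
#' @format Character vector of length 12.
#' @export
fever_vaccines <- c(
  "BCG", "chickenpox", "DTaP", "hepatitis A", "hepatitis B", "Hib",
  "influenza", "Japanese encephalitis", "MMR", "pneumococcus",
  "polio", "rotavirus"
)

#' Analysis configuration
#'
#' Collects every threshold and window used by the pipeline in one validated
#' object, so that all stages agree on what "fever", "high fever" and "the
#' observation window" mean.
#'
#' @param fever_threshold Fever threshold in degrees Celsius. A child is
#'   febrile when the (imputed) temperature is at or above this value.
#' @param high_fever_threshold Threshold for "relatively high fever", the
#'   outcome of the logistic model (degrees Celsius).
#' @param window_hours Length of the post-vaccination observation window in
#'   hours; readings and doses outside `(0, window_hours]` are ignored.
#' @param min_readings Minimum number of in-window temperature readings a
#'   vaccination record needs to be analyzable.
#' @param min_records_per_vaccine Minimum number of surviving records a
#'   vaccine needs to be retained in comparative analyses.
#' @param trajectory_window Two-element numeric, hours relative to fever
#'   onset spanned by the onset-aligned trajectory (negative before onset).
#' @param vif_limit Variance inflation factor above which predictors are
#'   flagged as collinear.
#' @param alpha Two-sided significance level.
#' @param temp_bounds Plausibility bounds (degrees Celsius) applied to
#'   caregiver-entered temperatures on load; readings outside are rejected.
#'
#' @return An object of class `fever_config` (a validated named list).
#' @examples
#' cfg <- fever_config()
#' cfg$fever_threshold
#' @export
fever_config <- function(fever_threshold = 38.0,
                         high_fever_threshold = 39.0,
                         window_hours = 48,
                         min_readings = 5,
                         min_records_per_vaccine = 100,
                         trajectory_window = c(-3, 24),
                         vif_limit = 10,
                         alpha = 0.05,
                         temp_bounds = c(34.0, 43.0)) {
  cfg <- list(
    fever_threshold = as.numeric(fever_threshold),
    high_fever_threshold = as.numeric(high_fever_threshold),
    window_hours = as.numeric(window_hours),
    min_readings = as.integer(min_readings),
    min_records_per_vaccine = as.integer(min_records_per_vaccine),
    trajectory_window = as.numeric(trajectory_window),
    vif_limit = as.numeric(vif_limit),
    alpha = as.numeric(alpha),
    temp_bounds = as.numeric(temp_bounds)
  )
  stopifnot(
    "fever_threshold must be below high_fever_threshold" =
      cfg$fever_threshold < cfg$high_fever_threshold,
    "window_hours must be positive" = cfg$window_hours > 0,
    "min_readings must be at least 2" = cfg$min_readings >= 2,
    "trajectory_window must straddle onset" =
      length(cfg$trajectory_window) == 2 &&
        cfg$trajectory_window[1] < 0 && cfg$trajectory_window[2] > 0,
    "vif_limit must exceed 1" = cfg$vif_limit > 1,
    "alpha must lie in (0, 1)" = cfg$alpha > 0 && cfg$alpha < 1,
    "temp_bounds must be an increasing pair" =
      length(cfg$temp_bounds) == 2 && cfg$temp_bounds[1] < cfg$temp_bounds[2]
  )
  class(cfg) <- "fever_config"
  cfg
}

#' @export
print.fever_config <- function(x, ...) {
  cat("Postvaccination fever analysis configuration\n")
  cat(sprintf("  fever threshold:        %.1f °C (high fever %.1f °C)\n",
              x$fever_threshold, x$high_fever_threshold))
  cat(sprintf("  observation window:     (0, %g] h after vaccination\n",
              x$window_hours))
  cat(sprintf("  analyzable record:      ≥ %d readings in window\n",
              x$min_readings))
  cat(sprintf("  vaccine retained with:  ≥ %d surviving records\n",
              x$min_records_per_vaccine))
  cat(sprintf("  trajectory window:      [%g, +%g] h around onset\n",
              x$trajectory_window[1], x$trajectory_window[2]))
  cat(sprintf("  VIF limit %g, alpha %g, plausible temperatures [%g, %g] °C\n",
              x$vif_limit, x$alpha, x$temp_bounds[1], x$temp_bounds[2]))
  invisible(x)
}

as_fever_config <- function(config) {
  if (inherits(config, "fever_config")) return(config)
  if (is.list(config)) return(do.call(fever_config, config))
  stop("`config` must be a fever_config object")
}
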