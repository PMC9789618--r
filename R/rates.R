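# Demographic rate schedules and simulation configuration ---------------------

FERTILE_AGES <- 15:49

#' Age-specific annual fertility and mortality rates
#'
#' Annual demographic rates per single year of age. Fertility is births per
#' person of age a per year (the model carries no sex dimension, so rates must
#' be calibrated per person, roughly half the conventional per-woman rate) and
#' must be zero outside ages 15-49. Mortality is the annual probability of
#' death, in \[0, 1\].
#'
#' @param fertility Numeric vector of length 101 (ages 0..100), non-negative,
#'   zero outside ages 15-49.
#' @param mortality Numeric vector of length 101, each value in \[0, 1\].
#'
#' @return An object of class `demographic_rates`.
#' @export
demographic_rates <- function(fertility, mortality) {
  stopifnot(length(fertility) == N_AGES, length(mortality) == N_AGES)
  if (anyNA(fertility) || anyNA(mortality)) {
    stop("demographic rates contain NA", call. = FALSE)
  }
  if (any(fertility < 0)) {
    stop(sprintf("negative fertility rate at age %d",
                 AGES[which(fertility < 0)[1L]]), call. = FALSE)
  }
  outside <- !(AGES %in% FERTILE_AGES)
  if (any(fertility[outside] > 0)) {
    stop(sprintf("fertility must be zero outside ages 15-49 (violated at age %d)",
                 AGES[outside][which(fertility[outside] > 0)[1L]]), call. = FALSE)
  }
  if (any(mortality < 0 | mortality > 1)) {
    stop(sprintf("mortality rate outside [0, 1] at age %d",
                 AGES[which(mortality < 0 | mortality > 1)[1L]]), call. = FALSE)
  }
  structure(list(fertility = as.numeric(fertility),
                 mortality = as.numeric(mortality)),
            class = "demographic_rates")
}

#' @export
print.demographic_rates <- function(x, ...) {
  cat("<demographic_rates>\n")
  cat(sprintf("  fertility: sum over ages 15-49 = %.3f births/person\n",
              sum(x$fertility)))
  cat(sprintf("  mortality: %.5f (age 0) .. %.3f (age 100)\n",
              x$mortality[1L], x$mortality[N_AGES]))
  invisible(x)
}

#' Simulation configuration
#'
#' @param start_year First calendar year of the simulation base population
#'   (outputs begin the following year).
#' @param horizon_years Number of simulated years (default 40).
#' @param step Days per time step (default 1, the model's native resolution).
#' @param rate_conversion How annual rates are scaled to a step of `dt` days:
#'   `"proportional"` (rate * dt/365, the System Dynamics convention; the
#'   daily loop then matches the annual closed form exactly) or
#'   `"exponential"` (compounding, 1 - (1 - rate)^(dt/365), applied to
#'   mortality).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(start_year = 2017L, horizon_years = 40L, step = 1L,
                       rate_conversion = c("proportional", "exponential")) {
  rate_conversion <- match.arg(rate_conversion)
  horizon_years <- as.integer(horizon_years)
  step <- as.integer(step)
  if (horizon_years < 1L) stop("horizon_years must be >= 1", call. = FALSE)
  if (step < 1L) stop("step must be >= 1 day", call. = FALSE)
  structure(list(start_year = as.integer(start_year),
                 horizon_years = horizon_years,
                 step = step,
                 rate_conversion = rate_conversion),
            class = "sim_config")
}
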