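# Age x stage population state ------------------------------------------------

# Model constants: single years of age 0..100 and four disease stages.
AGES <- 0:100
N_AGES <- 101L
STAGES <- c("healthy", "hearing_loss", "unilateral_ci", "bilateral_ci")
N_STAGES <- 4L
ADULT_MIN_AGE <- 20L
DAYS_PER_YEAR <- 365L

#' Age- and stage-structured population state
#'
#' The central container of the simulator: person counts indexed by single
#' year of age (0..100) and disease stage (healthy, CI-relevant hearing loss,
#' unilateral CI, bilateral CI). Hearing loss of children is ignored: stages
#' other than healthy must be empty below age 20.
#'
#' @param counts Numeric 101 x 4 matrix of non-negative person counts, rows in
#'   age order 0..100, columns in stage order healthy, hearing_loss,
#'   unilateral_ci, bilateral_ci. A 101-vector is accepted and taken as an
#'   all-healthy population.
#' @param day Integer day offset from simulation start (drives cohort aging,
#'   which fires every 365th day).
#'
#' @return An object of class `population_state`.
#' @export
population_state <- function(counts, day = 0L) {
  if (is.null(dim(counts))) {
    if (length(counts) != N_AGES) {
      stop("`counts` vector must have one entry per age 0..100", call. = FALSE)
    }
    m <- matrix(0, N_AGES, N_STAGES)
    m[, 1L] <- counts
    counts <- m
  }
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(N_AGES, N_STAGES))) {
    stop("`counts` must be a 101 x 4 matrix (ages 0..100 by 4 stages)",
         call. = FALSE)
  }
  dimnames(counts) <- list(age = AGES, stage = STAGES)
  out <- structure(list(counts = counts, day = as.integer(day)),
                   class = "population_state")
  validate_population_state(out)
  out
}

validate_population_state <- function(state) {
  counts <- state$counts
  if (anyNA(counts)) stop("population counts contain NA", call. = FALSE)
  if (any(counts < -1e-9)) {
    bad <- which(counts < -1e-9, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative population count at age %d, stage '%s'",
                 AGES[bad[1L]], STAGES[bad[2L]]), call. = FALSE)
  }
  child <- AGES < ADULT_MIN_AGE
  if (any(counts[child, 2:4] > 1e-9)) {
    bad_age <- AGES[child][which(rowSums(counts[child, 2:4, drop = FALSE]) > 1e-9)[1L]]
    stop(sprintf("ages below %d must be entirely healthy (violated at age %d)",
                 ADULT_MIN_AGE, bad_age), call. = FALSE)
  }
  invisible(state)
}

#' @export
print.population_state <- function(x, ...) {
  tot <- colSums(x$counts)
  cat("<population_state>  day", x$day, "\n")
  cat(sprintf("  total population: %.1f\n", sum(tot)))
  for (s in seq_along(STAGES)) {
    cat(sprintf("  %-14s %12.1f\n", STAGES[s], tot[s]))
  }
  invisible(x)
}

#' Total population of a state
#' @param state A [population_state()].
#' @return Total person count (all ages and stages).
#' @export
total_population <- function(state) sum(state$counts)

#' Per-stage population totals
#' @param state A [population_state()].
#' @return Named numeric vector of person counts per disease stage.
#' @export
stage_totals <- function(state) colSums(state$counts)

# Internal: number of devices implied by the implanted stock. Bilateral users
# carry two implants / two processors.
device_stock <- function(counts) {
  sum(counts[, 3L]) + 2 * sum(counts[, 4L])
}
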