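# Hearing-loss epidemiology: prevalence fit, incidence derivation -------------

#' Grouped hearing-loss prevalence table
#'
#' Prevalence of hearing loss above a severity threshold, reported by age
#' class (typically decades). The threshold tags which indication the table
#' describes: 60 dB HL is the severe-to-profound, CI-relevant definition;
#' 40 dB HL is the moderate, relaxed-indication definition.
#'
#' @param age_lower,age_upper Integer class bounds (inclusive). Use
#'   `age_upper = NA` (or 100) for an open-ended top class.
#' @param prevalence Proportion affected in each class, in \[0, 1\].
#' @param threshold_db Severity threshold in dB HL (default 60).
#'
#' @return An object of class `grouped_prevalence` (a data frame with the
#'   threshold as attribute).
#' @export
grouped_prevalence <- function(age_lower, age_upper, prevalence,
                               threshold_db = 60) {
  stopifnot(length(age_lower) == length(age_upper),
            length(age_lower) == length(prevalence))
  age_upper <- ifelse(is.na(age_upper), 100L, as.integer(age_upper))
  age_lower <- as.integer(age_lower)
  o <- order(age_lower)
  age_lower <- age_lower[o]; age_upper <- age_upper[o]
  prevalence <- as.numeric(prevalence)[o]
  if (any(age_upper < age_lower)) {
    stop("age_upper below age_lower in prevalence table", call. = FALSE)
  }
  if (length(age_lower) > 1L &&
      any(age_lower[-1L] <= age_upper[-length(age_upper)])) {
    stop("overlapping age classes in prevalence table", call. = FALSE)
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop(sprintf("prevalence outside [0, 1] in class %d-%d",
                 age_lower[which(prevalence < 0 | prevalence > 1)[1L]],
                 age_upper[which(prevalence < 0 | prevalence > 1)[1L]]),
         call. = FALSE)
  }
  out <- data.frame(age_lower = age_lower, age_upper = age_upper,
                    prevalence = prevalence)
  structure(out, threshold_db = threshold_db,
            class = c("grouped_prevalence", "data.frame"))
}

# Regression abscissa for an age class: the midpoint; an open-ended top class
# (upper bound 100 with a lower bound below 91) uses lower bound + 5.
class_midpoints <- function(gp) {
  mid <- (gp$age_lower + gp$age_upper) / 2
  open_top <- gp$age_upper >= 100L & gp$age_lower < 91L
  mid[open_top] <- gp$age_lower[open_top] + 5
  mid
}

#' Fit an exponential prevalence curve to grouped data
#'
#' Ordinary (nonlinear) least squares of the model p(age) = a * exp(b * age)
#' against class prevalences, with class midpoints as abscissae (an open-ended
#' top class is represented by its lower bound + 5 years). Levenberg-Marquardt
#' iterations start from the log-linear regression estimate.
#'
#' @param grouped A [grouped_prevalence()] with at least 3 age classes.
#' @return An object of class `prevalence_model` with elements `a`, `b`,
#'   `rss` (residual sum of squares), `threshold_db`, and the `fit` object.
#' @export
fit_prevalence <- function(grouped) {
  stopifnot(inherits(grouped, "grouped_prevalence"))
  if (nrow(grouped) < 3L) {
    stop("at least 3 age classes are required to fit the prevalence curve",
         call. = FALSE)
  }
  age <- class_midpoints(grouped)
  p <- grouped$prevalence
  # log-linear start values; floor avoids log(0) on degenerate rows
  lf <- stats::lm(log(pmax(p, 1e-12)) ~ age)
  b0 <- unname(stats::coef(lf)[2L])
  # a numerically tiny nonzero slope underflows the relative-step gradient in
  # the NLS machinery; snap it to an exact zero
  if (!is.finite(b0) || abs(b0) < 1e-10) b0 <- 0
  start <- list(a = exp(unname(stats::coef(lf)[1L])), b = b0)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ a * exp(b * age), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("prevalence fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 rss = sum(stats::resid(fit)^2),
                 threshold_db = attr(grouped, "threshold_db"),
                 fit = fit),
            class = "prevalence_model")
}

#' @export
print.prevalence_model <- function(x, ...) {
  cat(sprintf("<prevalence_model>  p(age) = %.6g * exp(%.6g * age)   [> %g dB HL]\n",
              x$a, x$b, x$threshold_db))
  cat(sprintf("  residual sum of squares: %.3g\n", x$rss))
  invisible(x)
}

#' Evaluate a fitted prevalence curve
#' @param model A [fit_prevalence()] result.
#' @param age Ages at which to evaluate.
#' @return Prevalence proportions, clipped to \[0, 1\].
#' @export
prevalence_at <- function(model, age) {
  pmin(pmax(model$a * exp(model$b * age), 0), 1)
}

#' Annual hearing-loss incidence schedule
#'
#' @param rate Numeric vector of annual incidence rates, one per age 0..100,
#'   each in \[0, 1\] and zero below age 20.
#' @return An object of class `incidence_schedule`.
#' @export
incidence_schedule <- function(rate) {
  stopifnot(length(rate) == N_AGES)
  if (any(rate < 0 | rate > 1)) {
    stop(sprintf("incidence rate outside [0, 1] at age %d",
                 AGES[which(rate < 0 | rate > 1)[1L]]), call. = FALSE)
  }
  if (any(rate[AGES < ADULT_MIN_AGE] > 0)) {
    stop("incidence must be zero below age 20", call. = FALSE)
  }
  structure(list(rate = as.numeric(rate)), class = "incidence_schedule")
}

#' Derive incidence from a fitted prevalence curve
#'
#' Incidence is taken as the first derivative of the prevalence curve with
#' respect to age: i(age) = a * b * exp(b * age), for ages 20..100, clipped to
#' \[0, 1\]; zero below age 20. A negative slope (b < 0) yields a negative
#' derivative, which is clipped to zero with a warning. This derivative rule
#' ignores differential mortality and remission; see the methods vignette for
#' the epidemiological caveat.
#'
#' @param model A [fit_prevalence()] result.
#' @return An [incidence_schedule()].
#' @export
incidence_from_prevalence <- function(model) {
  stopifnot(inherits(model, "prevalence_model"))
  rate <- numeric(N_AGES)
  adult <- AGES >= ADULT_MIN_AGE
  deriv <- model$a * model$b * exp(model$b * AGES[adult])
  if (any(deriv < 0)) {
    warning("negative prevalence slope: incidence clipped to 0", call. = FALSE)
    deriv <- pmax(deriv, 0)
  }
  rate[adult] <- pmin(deriv, 1)
  incidence_schedule(rate)
}

#' Apply hearing-loss incidence for one time step
#'
#' Moves new CI-relevant hearing-loss cases from the healthy stage to the
#' hearing-loss stage, for ages 20..100 only. The rate applies to the healthy
#' stock, so realized population incidence declines as the healthy pool of a
#' cohort depletes.
#'
#' @param state A [population_state()].
#' @param schedule An [incidence_schedule()].
#' @param dt Step length in days.
#' @return A list with `state` (updated) and `flow` (new cases per age,
#'   length 101).
#' @export
step_incidence <- function(state, schedule, dt = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(schedule, "incidence_schedule"), dt >= 1)
  flow <- state$counts[, 1L] * schedule$rate * (dt / DAYS_PER_YEAR)
  state$counts[, 1L] <- state$counts[, 1L] - flow
  state$counts[, 2L] <- state$counts[, 2L] + flow
  list(state = state, flow = unname(flow))
}
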