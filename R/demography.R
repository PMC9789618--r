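# Demographic update steps: fertility, mortality, cohort aging ----------------

# Scale an annual outflow rate to a step of dt days.
step_rate <- function(annual, dt, rate_conversion = "proportional") {
  if (rate_conversion == "exponential") 1 - (1 - annual)^(dt / DAYS_PER_YEAR)
  else annual * (dt / DAYS_PER_YEAR)
}

#' Apply fertility for one time step
#'
#' Births are computed from age-specific fertility over all stages of the
#' fertile ages (15-49) and added to the healthy newborn compartment
#' (age 0, stage healthy).
#'
#' @param state A [population_state()].
#' @param rates A [demographic_rates()].
#' @param dt Step length in days (>= 1).
#' @return A list with `state` (updated) and `births` (person count added).
#' @export
step_fertility <- function(state, rates, dt = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(rates, "demographic_rates"), dt >= 1)
  f_dt <- rates$fertility * (dt / DAYS_PER_YEAR)
  births <- sum(rowSums(state$counts) * f_dt)
  state$counts[1L, 1L] <- state$counts[1L, 1L] + births
  list(state = state, births = births)
}

#' Apply mortality for one time step
#'
#' Every compartment is reduced by age-specific mortality; disease stage does
#' not modify survival (hearing loss is nonlethal in the model).
#'
#' @inheritParams step_fertility
#' @param rate_conversion `"proportional"` or `"exponential"`; see
#'   [sim_config()].
#' @return A list with `state` (updated) and `deaths` (101 x 4 matrix of
#'   deaths by age and stage).
#' @export
step_mortality <- function(state, rates, dt = 1,
                           rate_conversion = "proportional") {
  stopifnot(inherits(state, "population_state"),
            inherits(rates, "demographic_rates"), dt >= 1)
  m_dt <- step_rate(rates$mortality, dt, rate_conversion)
  deaths <- state$counts * m_dt
  state$counts <- state$counts - deaths
  list(state = state, deaths = deaths)
}

#' Shift the population one year of age
#'
#' Cohort-synchronized aging: the whole compartment at age a moves to age
#' a + 1 (per stage) for a = 0..99. Age 100 is absorbing with respect to
#' aging: it receives the age-99 cohort and loses members only to mortality.
#' Intended to be called once every 365 simulated days.
#'
#' @param state A [population_state()].
#' @return The aged `population_state` (total population unchanged).
#' @export
step_aging <- function(state) {
  stopifnot(inherits(state, "population_state"))
  counts <- state$counts
  top <- counts[N_AGES, ]
  counts[2:N_AGES, ] <- counts[1:(N_AGES - 1L), ]
  counts[N_AGES, ] <- counts[N_AGES, ] + top
  counts[1L, ] <- 0
  state$counts <- counts
  state
}

#' Advance the simulation by one time step
#'
#' Applies, in order, fertility, mortality, hearing-loss incidence, unilateral
#' implantation and bilateral implantation, then computes the day's speech
#' processor exchanges and reimplantations (which do not move compartments).
#' Cohort aging fires when the state's day counter reaches a multiple of 365.
#'
#' @param state A [population_state()].
#' @param rates A [demographic_rates()].
#' @param hearing An [incidence_schedule()].
#' @param supply A [supply_schedules()].
#' @param devices A [device_parameters()].
#' @param dt Step length in days.
#' @param rate_conversion `"proportional"` (default) or `"exponential"`.
#' @return A list with the updated `state` and `deltas`, a list of the step's
#'   flows: `births`, `deaths`, `incident_cases`, `ci_unilateral`,
#'   `ci_bilateral` (each per age where applicable), `processors`,
#'   `reimplants`, and `aged` (logical).
#' @export
advance <- function(state, rates, hearing, supply, devices, dt = 1,
                    rate_conversion = "proportional") {
  fer <- step_fertility(state, rates, dt)
  mor <- step_mortality(fer$state, rates, dt, rate_conversion)
  inc <- step_incidence(mor$state, hearing, dt)
  uni <- step_unilateral(inc$state, supply, dt)
  bil <- step_bilateral(uni$state, supply, dt)
  state <- bil$state
  sn <- processor_exchanges(state, devices, dt)
  cin <- reimplantations(state, devices, dt)

  state$day <- state$day + as.integer(dt)
  aged <- state$day %% DAYS_PER_YEAR == 0L
  if (aged) state <- step_aging(state)

  list(state = state,
       deltas = list(births = fer$births,
                     deaths = mor$deaths,
                     incident_cases = inc$flow,
                     ci_unilateral = uni$flow,
                     ci_bilateral = bil$flow,
                     processors = sn,
                     reimplants = cin,
                     aged = aged))
}
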