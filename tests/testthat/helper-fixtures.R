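# Shared fixture builders (everything generated in code).

AGES_ <- 0:100

# State with counts placed at selected (age, stage) cells, empty elsewhere.
state_at <- function(ages, stages, counts, day = 0L) {
  m <- matrix(0, 101, 4)
  for (i in seq_along(ages)) m[ages[i] + 1L, stages[i]] <- counts[i]
  population_state(m, day = day)
}

# Rates with a constant mortality and a single-age or constant fertility.
flat_rates <- function(mortality = 0, fertility = 0, fertile_age = NULL) {
  f <- numeric(101)
  if (!is.null(fertile_age)) {
    f[fertile_age + 1L] <- fertility
  } else if (fertility > 0) {
    f[AGES_ %in% 15:49] <- fertility
  }
  demographic_rates(f, rep(mortality, 101))
}

# Constant adult supply schedules.
const_supply <- function(fe_u = 0, w_u = 0, fe_b = 0, w_b = 0) {
  adult <- as.numeric(AGES_ >= 20)
  supply_schedules(fe_u = fe_u * adult, w_u = w_u * adult,
                   fe_b = fe_b * adult, w_b = w_b * adult,
                   provenance = "scenario")
}

# Constant adult incidence.
const_incidence <- function(rate) {
  incidence_schedule(rate * as.numeric(AGES_ >= 20))
}

# Noiseless grouped prevalence generated from p(age) = a * exp(b * age) at the
# bundled decade classes (open 80+ top class, midpoint 85).
grouped_from_exp <- function(a, b, threshold_db = 60) {
  lower <- c(20L, 30L, 40L, 50L, 60L, 70L, 80L)
  upper <- c(29L, 39L, 49L, 59L, 69L, 79L, 100L)
  mid <- (lower + upper) / 2
  mid[length(mid)] <- 85
  grouped_prevalence(lower, upper, pmin(a * exp(b * mid), 1),
                     threshold_db = threshold_db)
}

# Small shared stylized bundle + config for scenario-level tests.
stylized_inputs <- function(...) make_stylized_country(fixture_spec(...))
short_config <- function(horizon = 10L) sim_config(horizon_years = horizon)
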