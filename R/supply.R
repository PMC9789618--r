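# CI supply: implantation flows, processor exchanges, reimplantations ---------

#' Per-age feasibility and willingness schedules
#'
#' Annual proportions per single year of age (0..100), zero below age 20:
#' `fe_u`/`w_u` for unilateral and `fe_b`/`w_b` for bilateral implantation.
#' Feasibility and willingness act as independent multiplicative factors on
#' the donor stage's stock.
#'
#' @param fe_u,w_u,fe_b,w_b Numeric vectors of length 101, values in \[0, 1\],
#'   zero below age 20.
#' @param provenance Where the values came from: `"survey"`, `"calibrated"` or
#'   `"scenario"`.
#' @return An object of class `supply_schedules`.
#' @export
supply_schedules <- function(fe_u, w_u, fe_b, w_b,
                             provenance = c("survey", "calibrated", "scenario")) {
  provenance <- match.arg(provenance)
  sched <- list(fe_u = fe_u, w_u = w_u, fe_b = fe_b, w_b = w_b)
  for (nm in names(sched)) {
    v <- sched[[nm]]
    if (length(v) != N_AGES) {
      stop(sprintf("`%s` must have one value per age 0..100", nm), call. = FALSE)
    }
    if (any(v < 0 | v > 1)) {
      stop(sprintf("`%s` outside [0, 1] at age %d", nm,
                   AGES[which(v < 0 | v > 1)[1L]]), call. = FALSE)
    }
    if (any(v[AGES < ADULT_MIN_AGE] > 0)) {
      stop(sprintf("`%s` must be zero below age 20", nm), call. = FALSE)
    }
    sched[[nm]] <- as.numeric(v)
  }
  structure(c(sched, list(provenance = provenance)),
            class = "supply_schedules")
}

#' @export
print.supply_schedules <- function(x, ...) {
  cat("<supply_schedules>  provenance:", x$provenance, "\n")
  adult <- AGES >= ADULT_MIN_AGE
  for (nm in c("fe_u", "w_u", "fe_b", "w_b")) {
    cat(sprintf("  %-5s range %.4f .. %.4f (ages 20..100)\n", nm,
                min(x[[nm]][adult]), max(x[[nm]][adult])))
  }
  invisible(x)
}

#' Device lifespans
#'
#' @param l_i Average implant lifespan in years (baseline 20).
#' @param l_s Average speech-processor lifespan in years (baseline 5).
#' @return An object of class `device_parameters`.
#' @export
device_parameters <- function(l_i = 20, l_s = 5) {
  if (l_i <= 0 || l_s <= 0) {
    stop("device lifespans must be positive", call. = FALSE)
  }
  structure(list(l_i = as.numeric(l_i), l_s = as.numeric(l_s)),
            class = "device_parameters")
}

#' Expand a grouped age table to a per-age schedule
#'
#' Step-function expansion: every single year of age in a group receives the
#' group's value. Groups must be contiguous starting at age 20; a top group
#' with upper bound >= 90 is extended through age 100. Ages below 20 get 0.
#'
#' @param group_table Data frame with columns `age_lower`, `age_upper`,
#'   `value`.
#' @return Numeric vector of length 101 (ages 0..100).
#' @export
expand_age_groups <- function(group_table) {
  stopifnot(all(c("age_lower", "age_upper", "value") %in% names(group_table)))
  gt <- group_table[order(group_table$age_lower), , drop = FALSE]
  if (gt$age_lower[1L] != ADULT_MIN_AGE) {
    stop("age groups must start at age 20", call. = FALSE)
  }
  up <- gt$age_upper
  up[length(up)] <- max(up[length(up)], 100L)
  if (nrow(gt) > 1L && any(gt$age_lower[-1L] != up[-length(up)] + 1L)) {
    bad <- which(gt$age_lower[-1L] != up[-length(up)] + 1L)[1L]
    stop(sprintf("age groups have a gap or overlap between %d-%d and %d-%d",
                 gt$age_lower[bad], up[bad],
                 gt$age_lower[bad + 1L], up[bad + 1L]), call. = FALSE)
  }
  if (up[length(up)] < 100L) {
    stop("age groups must cover through the top age class (90+)", call. = FALSE)
  }
  out <- numeric(N_AGES)
  for (i in seq_len(nrow(gt))) {
    out[AGES >= gt$age_lower[i] & AGES <= up[i]] <- gt$value[i]
  }
  out
}

# Internal: build supply_schedules from the two grouped survey tables.
schedules_from_tables <- function(fe_table = feasibility_table(),
                                  w_table = willingness_table(),
                                  provenance = "survey") {
  g <- function(tab, col) {
    expand_age_groups(data.frame(age_lower = tab$age_lower,
                                 age_upper = tab$age_upper,
                                 value = tab[[col]]))
  }
  supply_schedules(fe_u = g(fe_table, "unilateral"),
                   w_u = g(w_table, "unilateral"),
                   fe_b = g(fe_table, "bilateral"),
                   w_b = g(w_table, "bilateral"),
                   provenance = provenance)
}

#' Apply unilateral implantation for one time step
#'
#' Moves `P(a, hearing_loss) * fe_u(a) * w_u(a) * dt/365` persons from the
#' hearing-loss stage into the unilateral-CI stage, per age.
#'
#' @param state A [population_state()].
#' @param schedules A [supply_schedules()].
#' @param dt Step length in days.
#' @return A list with `state` (updated) and `flow` (new unilateral implants
#'   per age).
#' @export
step_unilateral <- function(state, schedules, dt = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(schedules, "supply_schedules"), dt >= 1)
  flow <- state$counts[, 2L] * schedules$fe_u * schedules$w_u *
    (dt / DAYS_PER_YEAR)
  state$counts[, 2L] <- state$counts[, 2L] - flow
  state$counts[, 3L] <- state$counts[, 3L] + flow
  list(state = state, flow = unname(flow))
}

#' Apply sequential bilateral implantation for one time step
#'
#' Moves `P(a, unilateral_ci) * fe_b(a) * w_b(a) * dt/365` persons from the
#' unilateral-CI stage into the bilateral-CI stage, per age. Age-related
#' hearing loss is symmetric, so every unilateral user is a potential
#' second-ear candidate.
#'
#' @inheritParams step_unilateral
#' @return A list with `state` (updated) and `flow` (new bilateral implants
#'   per age).
#' @export
step_bilateral <- function(state, schedules, dt = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(schedules, "supply_schedules"), dt >= 1)
  flow <- state$counts[, 3L] * schedules$fe_b * schedules$w_b *
    (dt / DAYS_PER_YEAR)
  state$counts[, 3L] <- state$counts[, 3L] - flow
  state$counts[, 4L] <- state$counts[, 4L] + flow
  list(state = state, flow = unname(flow))
}

#' Speech processor exchanges in one time step
#'
#' Continuous-turnover approximation: the implanted device stock (unilateral
#' users carry one processor, bilateral users two) is replaced at rate
#' 1 / l_s per year. Replacement does not move anyone between stages.
#'
#' @param state A [population_state()].
#' @param devices A [device_parameters()].
#' @param dt Step length in days.
#' @return Number of new speech processors in the step.
#' @export
processor_exchanges <- function(state, devices, dt = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(devices, "device_parameters"), dt >= 1)
  device_stock(state$counts) / devices$l_s * (dt / DAYS_PER_YEAR)
}

#' Reimplantations in one time step
#'
#' As [processor_exchanges()], with the implant lifespan l_i: the implant
#' stock turns over at rate 1 / l_i per year. State is unchanged.
#'
#' @inheritParams processor_exchanges
#' @return Number of reimplantations in the step.
#' @export
reimplantations <- function(state, devices, dt = 1) {
  stopifnot(inherits(state, "population_state"),
            inherits(devices, "device_parameters"), dt >= 1)
  device_stock(state$counts) / devices$l_i * (dt / DAYS_PER_YEAR)
}

#' Seed base-year CI user stocks
#'
#' Moves already-implanted persons from the hearing-loss stage into the
#' unilateral- and bilateral-CI stages, distributed over ages proportional to
#' the hearing-loss stock weighted by the respective feasibility x willingness
#' schedule (so the seeded users sit where implantation would have placed
#' them).
#'
#' @param state A [population_state()].
#' @param schedules A [supply_schedules()] providing the allocation weights.
#' @param totals Numeric length-2 vector: persons with a unilateral CI and
#'   persons with bilateral CIs at the base year.
#' @return The updated `population_state`.
#' @export
initialize_ci_stocks <- function(state, schedules, totals = c(0, 0)) {
  stopifnot(inherits(state, "population_state"),
            inherits(schedules, "supply_schedules"),
            length(totals) == 2, all(totals >= 0))
  alloc <- function(counts, total, weights, label) {
    if (total == 0) return(numeric(N_AGES))
    w <- counts[, 2L] * weights
    if (sum(w) <= 0) {
      stop(sprintf("no allocation weight available to place %s CI users", label),
           call. = FALSE)
    }
    share <- total * w / sum(w)
    if (any(share > counts[, 2L] + 1e-9)) {
      limit <- min((counts[, 2L] / (w / sum(w)))[w > 0])
      stop(sprintf(
        "%s total %.0f infeasible under proportional allocation (maximum %.0f)",
        label, total, floor(limit)), call. = FALSE)
    }
    share
  }
  uni <- alloc(state$counts, totals[1L], schedules$fe_u * schedules$w_u,
               "unilateral")
  state$counts[, 2L] <- state$counts[, 2L] - uni
  state$counts[, 3L] <- state$counts[, 3L] + uni
  bi <- alloc(state$counts, totals[2L], schedules$fe_b * schedules$w_b,
              "bilateral")
  state$counts[, 2L] <- state$counts[, 2L] - bi
  state$counts[, 4L] <- state$counts[, 4L] + bi
  validate_population_state(state)
  state
}
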