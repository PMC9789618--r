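# Scenario engine: ramps, named presets, full-horizon runs ---------------------

SCENARIO_NAMES <- c("baseline", "higher_willingness", "relaxed_indication",
                    "innovative_ci", "lifespan_increase",
                    "feasibility_willingness_increase", "mixed_prognosis")

# Baseline uniform willingness: the model-verification calibration value that
# reproduces current German implantation numbers (3,000-4,000 per year).
BASELINE_WILLINGNESS <- 0.01

#' Linear parameter ramp
#'
#' A parameter that increases linearly from `v0` at t = 0 to `v_end` at
#' t = `s` (years). Evaluated by [ramp_value()]. The alternative `compat`
#' form v0 * (1 + (v_end - v0)/s * t) reaches `v_end` at t = s only when
#' v0 = 1; it is kept as a switch for comparison but standard interpolation is
#' the default because scenario intents are stated as endpoint values.
#'
#' @param v0 Start value (at t = 0).
#' @param v_end End value (at t = s).
#' @param s Ramp horizon in years (> 0).
#' @param compat Use the multiplicative compatibility form.
#' @return An object of class `ramp_spec`.
#' @export
ramp_spec <- function(v0, v_end, s, compat = FALSE) {
  if (s <= 0) stop("ramp horizon s must be positive", call. = FALSE)
  structure(list(v0 = v0, v_end = v_end, s = s, compat = isTRUE(compat)),
            class = "ramp_spec")
}

#' Evaluate a ramp at time t
#'
#' @param ramp A [ramp_spec()].
#' @param t Time in years since simulation start; values outside \[0, s\] are
#'   clamped with a warning.
#' @return The ramped value at `t`.
#' @export
ramp_value <- function(ramp, t) {
  stopifnot(inherits(ramp, "ramp_spec"))
  if (any(t < 0 | t > ramp$s)) {
    warning("ramp evaluated outside [0, s]; clamped", call. = FALSE)
    t <- pmin(pmax(t, 0), ramp$s)
  }
  if (ramp$compat) {
    ramp$v0 * (1 + (ramp$v_end - ramp$v0) / ramp$s * t)
  } else {
    ramp$v0 + (ramp$v_end - ramp$v0) * t / ramp$s
  }
}

#' Scenario definition
#'
#' A bundle of parameter overrides applied on top of the shared inputs:
#' which willingness schedule is in force (a calibrated uniform value, the
#' surveyed age profile, or a per-age linear ramp between the two), an
#' optional feasibility multiplier ramp, the hearing-loss severity threshold
#' selecting the prevalence table, the unit-cost set, device lifespans
#' (values or ramps), and plain multiplicative scalings used by the
#' sensitivity analysis.
#'
#' @param name Scenario label.
#' @param willingness List with `mode` one of `"uniform"`, `"table"`,
#'   `"ramp"`; `value` the uniform (and ramp start) willingness; `table` the
#'   grouped willingness table used by `"table"`/`"ramp"` modes; optional
#'   `compat = TRUE` for the multiplicative ramp form (see [ramp_spec()]).
#' @param feasibility_ramp `NULL` or a [ramp_spec()] multiplier applied to
#'   both feasibility schedules (capped at 1).
#' @param prevalence_threshold 60 or 40 (dB HL), selecting which bundled
#'   prevalence table drives incidence.
#' @param cost_set `"baseline"` or `"innovative"`.
#' @param l_i,l_s Implant / processor lifespan override: a number, a
#'   [ramp_spec()], or `NULL` to use the cost set's value.
#' @param fe_scale,w_scale Multiplicative scalings of feasibility and
#'   willingness (used by [tornado()]; capped at 1 after application).
#' @param cost_scale Named numeric vector of multipliers on unit-cost
#'   parameters; names must be valid [cost_parameters()] fields.
#' @return An object of class `ci_scenario`.
#' @export
scenario <- function(name = "custom",
                     willingness = list(mode = "uniform",
                                        value = BASELINE_WILLINGNESS,
                                        table = willingness_table()),
                     feasibility_ramp = NULL,
                     prevalence_threshold = 60,
                     cost_set = c("baseline", "innovative"),
                     l_i = NULL, l_s = NULL,
                     fe_scale = 1, w_scale = 1,
                     cost_scale = NULL) {
  cost_set <- match.arg(cost_set)
  if (!willingness$mode %in% c("uniform", "table", "ramp")) {
    stop("unknown willingness mode '", willingness$mode, "'", call. = FALSE)
  }
  if (!prevalence_threshold %in% c(60, 40)) {
    stop("prevalence_threshold must be 60 or 40 dB HL", call. = FALSE)
  }
  if (!is.null(feasibility_ramp)) stopifnot(inherits(feasibility_ramp, "ramp_spec"))
  if (!is.null(cost_scale)) {
    known <- c("c_first_year", "c_second_year", "c_subsequent",
               "c_reimplant", "c_processor")
    bad <- setdiff(names(cost_scale), known)
    if (length(bad)) {
      stop("unknown cost parameter path(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(name = name, willingness = willingness,
                 feasibility_ramp = feasibility_ramp,
                 prevalence_threshold = prevalence_threshold,
                 cost_set = cost_set, l_i = l_i, l_s = l_s,
                 fe_scale = fe_scale, w_scale = w_scale,
                 cost_scale = cost_scale),
            class = "ci_scenario")
}

#' @export
print.ci_scenario <- function(x, ...) {
  cat("<ci_scenario>", x$name, "\n")
  cat("  willingness mode:", x$willingness$mode,
      if (x$willingness$mode != "table")
        sprintf("(uniform value %.4g)", x$willingness$value) else "", "\n")
  cat("  prevalence threshold:", x$prevalence_threshold, "dB HL;",
      "cost set:", x$cost_set, "\n")
  if (!is.null(x$feasibility_ramp)) {
    cat(sprintf("  feasibility multiplier ramp %g -> %g over %g yrs\n",
                x$feasibility_ramp$v0, x$feasibility_ramp$v_end,
                x$feasibility_ramp$s))
  }
  invisible(x)
}

#' Build a named scenario preset
#'
#' Presets:
#' \describe{
#'   \item{baseline}{uniform calibrated willingness 0.01, 60 dB HL threshold,
#'     baseline costs, l_i = 20, l_s = 5.}
#'   \item{higher_willingness}{surveyed willingness profile in place of the
#'     calibrated uniform value.}
#'   \item{relaxed_indication}{CI-relevant hearing loss extended to moderate
#'     (> 40 dB HL): the 40 dB prevalence table drives incidence.}
#'   \item{innovative_ci}{coated-implant cost set and implant lifespan 23
#'     years; everything else as baseline.}
#'   \item{lifespan_increase}{implant lifespan ramps 20 to 30 years and
#'     processor lifespan 5 to 10 years over the horizon.}
#'   \item{feasibility_willingness_increase}{feasibility doubles linearly over
#'     the horizon (capped at 1) and willingness ramps from 0.01 to the
#'     surveyed profile.}
#'   \item{mixed_prognosis}{union of lifespan_increase and
#'     feasibility_willingness_increase; costs stay at baseline.}
#' }
#'
#' @param name One of the preset names.
#' @param horizon_years Ramp horizon s for the ramped presets (default 40).
#' @return A [scenario()].
#' @export
build_scenario <- function(name, horizon_years = 40L) {
  if (!name %in% SCENARIO_NAMES) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(SCENARIO_NAMES, collapse = ", "), call. = FALSE)
  }
  s <- as.numeric(horizon_years)
  w_uniform <- list(mode = "uniform", value = BASELINE_WILLINGNESS,
                    table = willingness_table())
  w_table <- list(mode = "table", value = BASELINE_WILLINGNESS,
                  table = willingness_table())
  w_ramp <- list(mode = "ramp", value = BASELINE_WILLINGNESS,
                 table = willingness_table())
  switch(name,
    baseline = scenario("baseline", willingness = w_uniform),
    higher_willingness = scenario("higher_willingness", willingness = w_table),
    relaxed_indication = scenario("relaxed_indication",
                                  willingness = w_uniform,
                                  prevalence_threshold = 40),
    innovative_ci = scenario("innovative_ci", willingness = w_uniform,
                             cost_set = "innovative"),
    lifespan_increase = scenario("lifespan_increase", willingness = w_uniform,
                                 l_i = ramp_spec(20, 30, s),
                                 l_s = ramp_spec(5, 10, s)),
    feasibility_willingness_increase = scenario(
      "feasibility_willingness_increase", willingness = w_ramp,
      feasibility_ramp = ramp_spec(1, 2, s)),
    mixed_prognosis = scenario("mixed_prognosis", willingness = w_ramp,
                               feasibility_ramp = ramp_spec(1, 2, s),
                               l_i = ramp_spec(20, 30, s),
                               l_s = ramp_spec(5, 10, s))
  )
}

# Evaluate a lifespan override at year t: number, ramp, or cost-set default.
resolve_lifespan <- function(override, default, t) {
  if (is.null(override)) default
  else if (inherits(override, "ramp_spec")) ramp_value(override, t)
  else as.numeric(override)
}

# Effective per-age schedules for simulated year t (1-based; ramps evaluated
# at t so the final year of an s-year ramp uses the endpoint). Returns the
# four length-101 vectors plus the number of values capped at 1.
effective_schedules <- function(scn, base, t, s) {
  fmult <- if (is.null(scn$feasibility_ramp)) 1
           else ramp_value(scn$feasibility_ramp, min(t, scn$feasibility_ramp$s))
  fe_u <- base$fe_u * fmult * scn$fe_scale
  fe_b <- base$fe_b * fmult * scn$fe_scale

  w <- scn$willingness
  w_tab_u <- expand_age_groups(data.frame(age_lower = w$table$age_lower,
                                          age_upper = w$table$age_upper,
                                          value = w$table$unilateral))
  w_tab_b <- expand_age_groups(data.frame(age_lower = w$table$age_lower,
                                          age_upper = w$table$age_upper,
                                          value = w$table$bilateral))
  adult <- as.numeric(AGES >= ADULT_MIN_AGE)
  w_ramp <- function(tab) {
    tt <- min(t, s)
    if (isTRUE(w$compat)) w$value * (1 + (tab - w$value) * tt / s)
    else w$value + (tab - w$value) * tt / s
  }
  w_u <- switch(w$mode,
    uniform = w$value * adult,
    table = w_tab_u,
    ramp = w_ramp(w_tab_u) * adult)
  w_b <- switch(w$mode,
    uniform = w$value * adult,
    table = w_tab_b,
    ramp = w_ramp(w_tab_b) * adult)
  w_u <- w_u * scn$w_scale
  w_b <- w_b * scn$w_scale

  vals <- list(fe_u = fe_u, w_u = w_u, fe_b = fe_b, w_b = w_b)
  capped <- sum(vapply(vals, function(v) sum(v > 1), numeric(1L)))
  vals <- lapply(vals, function(v) pmin(pmax(v, 0), 1))
  vals$capped <- capped
  vals
}

#' Run a scenario over the full horizon
#'
#' Deterministic daily-step simulation: for each simulated year the effective
#' feasibility/willingness schedules and device lifespans are resolved (ramps
#' are step functions at year boundaries), 365 daily updates are applied in
#' the order fertility, mortality, incidence, unilateral implantation,
#' bilateral implantation, the cohort ages at the year boundary, and the
#' year's flows are priced by [annual_costs()].
#'
#' @param scn A [scenario()] or preset name accepted by [build_scenario()].
#' @param inputs List with elements `population` ([population_state()]),
#'   `rates` ([demographic_rates()]), `prevalence` (a named list
#'   `list("60" = ..., "40" = ...)` of [grouped_prevalence()] tables, or a
#'   single table), `schedules` (a [supply_schedules()] supplying the
#'   feasibility profiles), and optionally `ci_totals` (length-2 base-year
#'   unilateral/bilateral CI user counts seeded via [initialize_ci_stocks()]).
#' @param config A [sim_config()].
#' @param keep_age_detail Also record the year-end age-by-stage population of
#'   every simulated year (attribute `age_detail`, a list of 101 x 4
#'   matrices).
#' @return A data frame of class `annual_outputs`, one row per simulated
#'   calendar year: stage populations (year end), births, deaths, flows
#'   (`ciu`, `cib`, `sn`, `cin`) and the euro cost components with `total`.
#'   Attributes: `scenario`, `config`, `cap_events` (count of
#'   proportions capped at 1), and optionally `age_detail`.
#' @export
run_scenario <- function(scn, inputs, config = sim_config(),
                         keep_age_detail = FALSE) {
  if (is.character(scn)) scn <- build_scenario(scn, config$horizon_years)
  stopifnot(inherits(scn, "ci_scenario"), inherits(config, "sim_config"))
  state <- inputs$population
  rates <- inputs$rates
  stopifnot(inherits(state, "population_state"),
            inherits(rates, "demographic_rates"))
  if (DAYS_PER_YEAR %% config$step != 0L) {
    stop("step must divide 365 days", call. = FALSE)
  }

  prev_tab <- inputs$prevalence
  if (inherits(prev_tab, "grouped_prevalence")) {
    gp <- prev_tab
  } else {
    key <- as.character(scn$prevalence_threshold)
    if (!key %in% names(prev_tab)) {
      stop("inputs$prevalence has no table for threshold ", key, " dB HL",
           call. = FALSE)
    }
    gp <- prev_tab[[key]]
  }
  inc <- incidence_from_prevalence(fit_prevalence(gp))

  cost_set <- switch(scn$cost_set, baseline = baseline_cost_set(),
                     innovative = innovative_cost_set())
  params <- cost_set$costs
  if (!is.null(scn$cost_scale)) {
    for (nm in names(scn$cost_scale)) params[[nm]] <- params[[nm]] * scn$cost_scale[[nm]]
  }

  if (!is.null(inputs$ci_totals) && any(inputs$ci_totals > 0)) {
    state <- initialize_ci_stocks(state, inputs$schedules, inputs$ci_totals)
  }

  horizon <- config$horizon_years
  s_ramp <- as.numeric(horizon)
  dt <- config$step
  steps_per_year <- DAYS_PER_YEAR %/% dt
  counts <- state$counts
  proportional <- config$rate_conversion == "proportional"

  f_dt <- rates$fertility * (dt / DAYS_PER_YEAR)
  m_dt <- if (proportional) rates$mortality * (dt / DAYS_PER_YEAR)
          else 1 - (1 - rates$mortality)^(dt / DAYS_PER_YEAR)
  i_dt <- inc$rate * (dt / DAYS_PER_YEAR)

  cap_events <- 0L
  prev_flows <- NULL
  rows <- vector("list", horizon)
  age_detail <- if (keep_age_detail) vector("list", horizon) else NULL

  for (yr in seq_len(horizon)) {
    eff <- effective_schedules(scn, inputs$schedules, yr, s_ramp)
    cap_events <- cap_events + eff$capped
    u_dt <- eff$fe_u * eff$w_u * (dt / DAYS_PER_YEAR)
    b_dt <- eff$fe_b * eff$w_b * (dt / DAYS_PER_YEAR)
    l_i <- resolve_lifespan(scn$l_i, cost_set$devices$l_i, yr)
    l_s <- resolve_lifespan(scn$l_s, cost_set$devices$l_s, yr)
    sn_f <- (dt / DAYS_PER_YEAR) / l_s
    cin_f <- (dt / DAYS_PER_YEAR) / l_i

    births <- 0; deaths <- 0; sn <- 0; cin <- 0
    ciu <- numeric(N_AGES); cib <- numeric(N_AGES)

    for (k in seq_len(steps_per_year)) {
      b <- sum(rowSums(counts) * f_dt)
      counts[1L, 1L] <- counts[1L, 1L] + b
      births <- births + b
      d <- counts * m_dt
      counts <- counts - d
      deaths <- deaths + sum(d)
      flow <- counts[, 1L] * i_dt
      counts[, 1L] <- counts[, 1L] - flow
      counts[, 2L] <- counts[, 2L] + flow
      flow <- counts[, 2L] * u_dt
      counts[, 2L] <- counts[, 2L] - flow
      counts[, 3L] <- counts[, 3L] + flow
      ciu <- ciu + flow
      flow <- counts[, 3L] * b_dt
      counts[, 3L] <- counts[, 3L] - flow
      counts[, 4L] <- counts[, 4L] + flow
      cib <- cib + flow
      stock <- sum(counts[, 3L]) + 2 * sum(counts[, 4L])
      sn <- sn + stock * sn_f
      cin <- cin + stock * cin_f
    }
    # cohort aging at the year boundary (every 365th day)
    top <- counts[N_AGES, ]
    counts[2:N_AGES, ] <- counts[1:(N_AGES - 1L), ]
    counts[N_AGES, ] <- counts[N_AGES, ] + top
    counts[1L, ] <- 0

    state$counts <- counts
    state$day <- state$day + DAYS_PER_YEAR
    flows <- list(ciu = ciu, cib = cib, sn = sn, cin = cin)
    costs <- annual_costs(flows, prev_flows, state, params, rates)
    prev_flows <- flows

    rows[[yr]] <- data.frame(
      year = config$start_year + yr,
      population = sum(counts),
      healthy = sum(counts[, 1L]),
      hearing_loss = sum(counts[, 2L]),
      unilateral_ci = sum(counts[, 3L]),
      bilateral_ci = sum(counts[, 4L]),
      births = births, deaths = deaths,
      ciu = sum(ciu), cib = sum(cib), sn = sn, cin = cin,
      costs
    )
    if (keep_age_detail) {
      m <- counts
      dimnames(m) <- list(age = AGES, stage = STAGES)
      age_detail[[yr]] <- m
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("annual_outputs", "data.frame")
  attr(out, "scenario") <- scn
  attr(out, "config") <- config
  attr(out, "cap_events") <- cap_events
  if (keep_age_detail) {
    names(age_detail) <- out$year
    attr(out, "age_detail") <- age_detail
  }
  if (cap_events > 0) {
    message(sprintf("run_scenario('%s'): %d schedule value(s) capped at 1.0",
                    scn$name, cap_events))
  }
  out
}
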