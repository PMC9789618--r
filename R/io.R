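# Run configuration, simulation entry points, run directories -------------------
#
# These functions back the command-line wrapper shipped in inst/cli; they are
# ordinary package functions and can be used directly from R.

#' Read a run configuration file
#'
#' YAML (or JSON, which YAML subsumes) with keys: `scenario` (preset name,
#' default `"baseline"`), `start_year`, `horizon_years`, `step`,
#' `rate_conversion`, optional `ci_totals` (length-2 base-year unilateral /
#' bilateral CI user counts), optional `compat_ramp` (use the multiplicative
#' ramp form), and `inputs` - either `inputs: {stylized: {<fixture_spec
#' fields>}}` or file paths `inputs: {population, fertility, mortality,
#' prevalence_60, prevalence_40, schedules}`.
#'
#' @param path Config file path.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$scenario <- cfg$scenario %||% "baseline"
  if (!cfg$scenario %in% SCENARIO_NAMES) {
    stop(sprintf("%s: unknown scenario '%s'; valid: %s", path, cfg$scenario,
                 paste(SCENARIO_NAMES, collapse = ", ")), call. = FALSE)
  }
  cfg$start_year <- cfg$start_year %||% 2017L
  cfg$horizon_years <- cfg$horizon_years %||% 40L
  cfg$step <- cfg$step %||% 1L
  cfg$rate_conversion <- cfg$rate_conversion %||% "proportional"
  cfg$compat_ramp <- isTRUE(cfg$compat_ramp)
  if (is.null(cfg$inputs)) {
    stop(path, ": config must declare an `inputs` block", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

# Materialize the inputs block of a run_config into simulator objects.
build_inputs <- function(cfg, base_dir = ".") {
  inp <- cfg$inputs
  if (!is.null(inp$stylized)) {
    spec <- do.call(fixture_spec, inp$stylized)
    return(make_stylized_country(spec))
  }
  need <- c("population", "fertility", "mortality", "prevalence_60",
            "prevalence_40", "schedules")
  missing <- setdiff(need, names(inp))
  if (length(missing)) {
    stop("config inputs block missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- function(f) if (file.exists(f)) f else file.path(base_dir, f)
  pop <- load_age_table(p(inp$population), "population")
  rates <- demographic_rates(load_age_table(p(inp$fertility), "fertility"),
                             load_age_table(p(inp$mortality), "mortality"))
  list(population = pop, rates = rates,
       prevalence = list("60" = load_age_table(p(inp$prevalence_60), "prevalence"),
                         "40" = load_age_table(p(inp$prevalence_40), "prevalence")),
       schedules = load_age_table(p(inp$schedules), "schedules"))
}

config_to_sim <- function(cfg) {
  sim_config(start_year = cfg$start_year, horizon_years = cfg$horizon_years,
             step = cfg$step, rate_conversion = cfg$rate_conversion)
}

config_to_scenario <- function(cfg) {
  scn <- build_scenario(cfg$scenario, cfg$horizon_years)
  if (cfg$compat_ramp) {
    for (f in c("feasibility_ramp", "l_i", "l_s")) {
      if (inherits(scn[[f]], "ramp_spec")) scn[[f]]$compat <- TRUE
    }
    if (scn$willingness$mode == "ramp") scn$willingness$compat <- TRUE
  }
  scn
}

# Long (year, series, value) form of the annual outputs.
outputs_to_tidy <- function(out) {
  series <- setdiff(names(out), "year")
  do.call(rbind, lapply(series, function(s) {
    data.frame(year = out$year, series = s, value = out[[s]])
  }))
}

#' Run a simulation from a config file and write a run directory
#'
#' Writes `annual_outputs.csv` (tidy year/series/value, full precision),
#' `population_by_age.csv` (year, age, stage, count), `costs.csv` (year,
#' component, euros), a verbatim copy of the config, and `manifest.json`
#' (config snapshot, package version, input checksums, timestamp). Output is
#' written atomically: on any error nothing is left behind in `out_dir`.
#'
#' @param config_path Path to a [read_run_config()] file.
#' @param out_dir Output run directory (must not already contain a manifest).
#' @return `out_dir`, invisibly.
#' @export
ci_simulate <- function(config_path, out_dir) {
  cfg <- read_run_config(config_path)
  inputs <- build_inputs(cfg, base_dir = dirname(config_path))
  if (!is.null(cfg$ci_totals)) {
    inputs$ci_totals <- as.numeric(cfg$ci_totals)
  }
  sim <- config_to_sim(cfg)
  scn <- config_to_scenario(cfg)
  out <- run_scenario(scn, inputs, sim, keep_age_detail = TRUE)

  stage <- tempfile("cidemand_run_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  utils::write.csv(outputs_to_tidy(out),
                   file.path(stage, "annual_outputs.csv"), row.names = FALSE)
  detail <- attr(out, "age_detail")
  pop_long <- do.call(rbind, lapply(names(detail), function(y) {
    m <- detail[[y]]
    data.frame(year = as.integer(y),
               age = rep(AGES, times = N_STAGES),
               stage = rep(STAGES, each = N_AGES),
               count = as.vector(m))
  }))
  utils::write.csv(pop_long, file.path(stage, "population_by_age.csv"),
                   row.names = FALSE)
  costs_long <- outputs_to_tidy(out[c("year", COST_COMPONENTS, "total")])
  names(costs_long) <- c("year", "component", "euros")
  utils::write.csv(costs_long, file.path(stage, "costs.csv"),
                   row.names = FALSE)
  file.copy(config_path, file.path(stage, "config.yaml"))

  input_files <- if (is.null(cfg$inputs$stylized)) {
    vapply(cfg$inputs, function(f) {
      f <- as.character(f)
      if (file.exists(f)) f else file.path(dirname(config_path), f)
    }, character(1L))
  } else character(0L)
  manifest <- list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("cidemand")),
    input_checksums = as.list(tools::md5sum(input_files)),
    cap_events = attr(out, "cap_events"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(list.files(stage, full.names = TRUE), out_dir,
                  overwrite = TRUE)
  if (!all(ok)) stop("failed to write run directory ", out_dir, call. = FALSE)
  invisible(out_dir)
}

#' Compare two completed run directories
#'
#' Per-year and cumulative deltas (absolute and percent) for every series in
#' `annual_outputs.csv`. Percent deltas with a zero base are reported as `NA`
#' (undefined), not infinity.
#'
#' @param run_a,run_b Run directories written by [ci_simulate()]; `run_a` is
#'   the base.
#' @return A list with `per_year` (year, series, value_a, value_b, delta,
#'   pct_delta) and `cumulative` (series, total_a, total_b, delta, pct_delta).
#' @export
ci_compare <- function(run_a, run_b) {
  read_run <- function(d) {
    f <- file.path(d, "annual_outputs.csv")
    if (!file.exists(f)) stop("not a run directory: ", d, call. = FALSE)
    utils::read.csv(f)
  }
  a <- read_run(run_a)
  b <- read_run(run_b)
  if (!identical(sort(unique(a$year)), sort(unique(b$year)))) {
    stop("run horizons do not match", call. = FALSE)
  }
  m <- merge(a, b, by = c("year", "series"), suffixes = c("_a", "_b"))
  m$delta <- m$value_b - m$value_a
  m$pct_delta <- ifelse(m$value_a == 0, NA_real_, 100 * m$delta / m$value_a)
  cum <- stats::aggregate(cbind(value_a, value_b) ~ series, data = m, FUN = sum)
  names(cum) <- c("series", "total_a", "total_b")
  cum$delta <- cum$total_b - cum$total_a
  cum$pct_delta <- ifelse(cum$total_a == 0, NA_real_,
                          100 * cum$delta / cum$total_a)
  list(per_year = m[order(m$series, m$year), ],
       cumulative = cum)
}
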