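# Stylized-country input generator and CSV loaders ------------------------------

#' Specification of a stylized national population
#'
#' Parameters of the self-contained synthetic input bundle: an aging,
#' sub-replacement country loosely shaped like a Western European population,
#' with a baby-boom bulge in late middle age, Gompertz mortality and
#' exponentially age-increasing hearing-loss prevalence at both severity
#' thresholds (the moderate 40 dB HL table pointwise above the severe 60 dB HL
#' table).
#'
#' @param total_population Total person count (default 1e6; all model flows
#'   scale linearly in it).
#' @param pyramid_peak_age,pyramid_sd Gaussian age-pyramid shape: counts peak
#'   at `pyramid_peak_age` (default 45, placing more 50-year-olds than
#'   20-year-olds) with spread `pyramid_sd`.
#' @param fertility_total Lifetime births per person (default 0.75, i.e. a
#'   total fertility rate near 1.5 per woman - sub-replacement).
#' @param gompertz_m0,gompertz_slope Gompertz mortality m(a) = m0 * exp(slope
#'   * a) (defaults 1.6e-5 and 0.11: ~0.1 at age 80). Mortality is capped at 1
#'   and the top age is kept at >= 0.5 so the absorbing age-100 bin drains.
#' @param prev60,prev40 Length-2 vectors `c(a, b)` of the exponential
#'   prevalence curves p(age) = a * exp(b * age) for the severe (> 60 dB HL)
#'   and moderate (> 40 dB HL) thresholds.
#' @param noise_sd Gaussian noise added to the grouped prevalence values
#'   (default 0; used by fit-recovery tests).
#' @param seed Integer seed for the noise draws.
#' @param ci_uni_share,ci_bi_share Share of the base-year hearing-loss stock
#'   already using a unilateral / bilateral CI (default 0: no pre-existing
#'   users; see [german_like_spec()]).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(total_population = 1e6,
                         pyramid_peak_age = 45, pyramid_sd = 28,
                         fertility_total = 0.75,
                         gompertz_m0 = 1.6e-5, gompertz_slope = 0.11,
                         prev60 = c(a = 2e-4, b = 0.075),
                         prev40 = c(a = 1e-3, b = 0.075),
                         noise_sd = 0, seed = 1L,
                         ci_uni_share = 0, ci_bi_share = 0) {
  if (total_population <= 0) stop("total_population must be positive", call. = FALSE)
  if (gompertz_m0 * exp(gompertz_slope * 90) > 1) {
    stop("Gompertz parameters give mortality > 1 before extreme old age",
         call. = FALSE)
  }
  if (fertility_total < 0 || fertility_total > 2) {
    stop("fertility_total must be a plausible per-person lifetime rate in [0, 2]",
         call. = FALSE)
  }
  if (ci_uni_share < 0 || ci_bi_share < 0 || ci_uni_share + ci_bi_share >= 1) {
    stop("base-year CI user shares must be non-negative and sum below 1",
         call. = FALSE)
  }
  structure(list(total_population = total_population,
                 pyramid_peak_age = pyramid_peak_age, pyramid_sd = pyramid_sd,
                 fertility_total = fertility_total,
                 gompertz_m0 = gompertz_m0, gompertz_slope = gompertz_slope,
                 prev60 = prev60, prev40 = prev40,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 ci_uni_share = ci_uni_share, ci_bi_share = ci_bi_share),
            class = "fixture_spec")
}

#' German-like stylized fixture
#'
#' The default [fixture_spec()] with base-year CI user stocks switched on at
#' shares emulating the German 2017 starting point, where roughly 4% of the
#' severely hearing-impaired had a unilateral and 3% a bilateral CI. With
#' these stocks in place, speech-processor exchange is the largest cost
#' component from the start, as in current German CI care.
#'
#' @param ... Overrides passed to [fixture_spec()].
#' @return A `fixture_spec`.
#' @export
german_like_spec <- function(...) {
  fixture_spec(ci_uni_share = 0.04, ci_bi_share = 0.03, ...)
}

# Decade age classes used for the grouped prevalence tables (open top class).
PREV_CLASSES <- data.frame(age_lower = c(20L, 30L, 40L, 50L, 60L, 70L, 80L),
                           age_upper = c(29L, 39L, 49L, 59L, 69L, 79L, 100L))

grouped_from_curve <- function(ab, threshold_db, noise_sd = 0) {
  gp <- grouped_prevalence(PREV_CLASSES$age_lower, PREV_CLASSES$age_upper,
                           prevalence = rep(0, nrow(PREV_CLASSES)),
                           threshold_db = threshold_db)
  mid <- class_midpoints(gp)
  p <- ab[["a"]] * exp(ab[["b"]] * mid)
  if (noise_sd > 0) p <- p + stats::rnorm(length(p), 0, noise_sd)
  grouped_prevalence(PREV_CLASSES$age_lower, PREV_CLASSES$age_upper,
                     pmin(pmax(p, 0), 1), threshold_db = threshold_db)
}

#' Generate a stylized country input bundle
#'
#' Builds a mutually consistent set of simulator inputs from a
#' [fixture_spec()]: a declining-pyramid [population_state()] whose adult
#' hearing-loss stock is pre-seeded from the severe-threshold prevalence
#' curve, [demographic_rates()], grouped prevalence tables for both severity
#' thresholds, and the bundled survey feasibility/willingness schedules.
#' Deterministic given the spec (noise uses the spec's seed).
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `population`, `rates`, `prevalence`
#'   (`list("60" = ..., "40" = ...)`), `schedules`, and - when the spec sets
#'   base-year CI user shares - `ci_totals`; directly usable as the `inputs`
#'   of [run_scenario()].
#' @export
make_stylized_country <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  shape <- stats::dnorm(AGES, mean = 30, sd = 5.5)
  shape[!(AGES %in% FERTILE_AGES)] <- 0
  fert <- spec$fertility_total * shape / sum(shape)

  mort <- pmin(spec$gompertz_m0 * exp(spec$gompertz_slope * AGES), 1)
  mort[N_AGES] <- max(mort[N_AGES], 0.5)
  rates <- demographic_rates(fert, mort)

  # birth-cohort bulge attenuated by survivorship to the current age, so the
  # initial old-age counts are consistent with the mortality schedule and the
  # late-middle-age bulge genuinely ages the population going forward
  survivorship <- cumprod(c(1, 1 - mort[-N_AGES]))
  w <- exp(-0.5 * ((AGES - spec$pyramid_peak_age) / spec$pyramid_sd)^2) *
    survivorship
  pop <- spec$total_population * w / sum(w)

  if (spec$noise_sd > 0) set.seed(spec$seed)
  gp60 <- grouped_from_curve(spec$prev60, 60, spec$noise_sd)
  gp40 <- grouped_from_curve(spec$prev40, 40, spec$noise_sd)
  # the relaxed-indication table must nest the severe one
  gp40$prevalence <- pmax(gp40$prevalence, gp60$prevalence)

  counts <- matrix(0, N_AGES, N_STAGES)
  p_sev <- pmin(spec$prev60[["a"]] * exp(spec$prev60[["b"]] * AGES), 1)
  adult <- AGES >= ADULT_MIN_AGE
  counts[, 2L][adult] <- pop[adult] * p_sev[adult]
  counts[, 1L] <- pop - counts[, 2L]

  out <- list(population = population_state(counts),
              rates = rates,
              prevalence = list("60" = gp60, "40" = gp40),
              schedules = schedules_from_tables())
  if (spec$ci_uni_share > 0 || spec$ci_bi_share > 0) {
    hl <- sum(counts[, 2L])
    out$ci_totals <- c(spec$ci_uni_share * hl, spec$ci_bi_share * hl)
  }
  out
}

# --- CSV loaders / writers -----------------------------------------------------

AGE_TABLE_KINDS <- c("population", "fertility", "mortality", "prevalence",
                     "schedules")

read_csv_with_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(unit = "proportion", threshold_db = 60)
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*(\\w+)\\s*:\\s*(\\S+)", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  df <- utils::read.csv(text = lines, comment.char = "#",
                        stringsAsFactors = FALSE)
  list(df = df, unit = meta$unit, threshold_db = as.numeric(meta$threshold_db))
}

check_full_age_column <- function(age, path) {
  if (anyDuplicated(age)) {
    stop(sprintf("%s: duplicated age %d", path, age[duplicated(age)][1L]),
         call. = FALSE)
  }
  missing <- setdiff(AGES, age)
  if (length(missing)) {
    stop(sprintf("%s: missing age %d", path, missing[1L]), call. = FALSE)
  }
  extra <- setdiff(age, AGES)
  if (length(extra)) {
    stop(sprintf("%s: age %d outside 0..100", path, extra[1L]), call. = FALSE)
  }
}

#' Load a validated age-structured input table from CSV
#'
#' Layouts by kind (a leading `# unit: percent` comment line declares values
#' in percent, converted to proportions on load; default is proportion):
#' \describe{
#'   \item{population}{`age, value` (all healthy) or
#'     `age, healthy, hearing_loss, unilateral_ci, bilateral_ci`; ages must be
#'     exactly 0..100. Returns a [population_state()].}
#'   \item{fertility / mortality}{`age, value`, ages exactly 0..100. Returns a
#'     numeric vector of length 101.}
#'   \item{prevalence}{`age_lower, age_upper, prevalence` (optionally a
#'     `# threshold_db: 60` comment). Returns a [grouped_prevalence()].}
#'   \item{schedules}{`age_lower, age_upper, fe_u, w_u, fe_b, w_b`. Returns a
#'     [supply_schedules()].}
#' }
#' Gaps, duplicates and out-of-range values fail hard with a row-level
#' diagnostic.
#'
#' @param path CSV file path.
#' @param kind One of `"population"`, `"fertility"`, `"mortality"`,
#'   `"prevalence"`, `"schedules"`.
#' @return The typed object for the kind.
#' @export
load_age_table <- function(path, kind = AGE_TABLE_KINDS) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  x <- read_csv_with_meta(path)
  df <- x$df
  scale <- if (identical(x$unit, "percent")) 1 / 100 else 1

  if (kind %in% c("fertility", "mortality")) {
    stopifnot(all(c("age", "value") %in% names(df)))
    df <- df[order(df$age), ]
    check_full_age_column(df$age, path)
    v <- df$value * scale
    if (kind == "fertility") return(v)
    if (any(v < 0 | v > 1)) {
      stop(sprintf("%s: mortality outside [0, 1] at age %d", path,
                   df$age[which(v < 0 | v > 1)[1L]]), call. = FALSE)
    }
    return(v)
  }
  if (kind == "population") {
    stopifnot("age" %in% names(df))
    df <- df[order(df$age), ]
    check_full_age_column(df$age, path)
    if ("value" %in% names(df)) return(population_state(df$value))
    need <- STAGES
    if (!all(need %in% names(df))) {
      stop(path, ": population table needs columns age, value or age, ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    return(population_state(as.matrix(df[need])))
  }
  if (kind == "prevalence") {
    stopifnot(all(c("age_lower", "age_upper", "prevalence") %in% names(df)))
    return(grouped_prevalence(df$age_lower, df$age_upper,
                              df$prevalence * scale,
                              threshold_db = x$threshold_db))
  }
  # schedules
  need <- c("age_lower", "age_upper", "fe_u", "w_u", "fe_b", "w_b")
  if (!all(need %in% names(df))) {
    stop(path, ": schedules table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  g <- function(col) {
    expand_age_groups(data.frame(age_lower = df$age_lower,
                                 age_upper = df$age_upper,
                                 value = df[[col]] * scale))
  }
  supply_schedules(fe_u = g("fe_u"), w_u = g("w_u"),
                   fe_b = g("fe_b"), w_b = g("w_b"), provenance = "survey")
}

#' Write an age-structured table to CSV in the loader's layout
#'
#' Inverse of [load_age_table()]: writes the object in the exact layout the
#' loader accepts, so write-then-load round trips are lossless. Values are
#' always written as proportions at full precision.
#'
#' @param x A [population_state()], numeric length-101 rate vector,
#'   [grouped_prevalence()] or [supply_schedules()].
#' @param path Output CSV path.
#' @param kind As in [load_age_table()].
#' @return `path`, invisibly.
#' @export
write_age_table <- function(x, path, kind = AGE_TABLE_KINDS) {
  kind <- match.arg(kind)
  lines <- "# unit: proportion"
  if (kind == "population") {
    stopifnot(inherits(x, "population_state"))
    df <- data.frame(age = AGES, x$counts)
    names(df) <- c("age", STAGES)
  } else if (kind %in% c("fertility", "mortality")) {
    v <- if (inherits(x, "demographic_rates")) x[[kind]] else x
    stopifnot(length(v) == N_AGES)
    df <- data.frame(age = AGES, value = v)
  } else if (kind == "prevalence") {
    stopifnot(inherits(x, "grouped_prevalence"))
    lines <- c(lines, paste0("# threshold_db: ", attr(x, "threshold_db")))
    df <- as.data.frame(x)
  } else {
    stopifnot(inherits(x, "supply_schedules"))
    adult <- AGES >= ADULT_MIN_AGE
    df <- data.frame(age_lower = AGES[adult], age_upper = AGES[adult],
                     fe_u = x$fe_u[adult], w_u = x$w_u[adult],
                     fe_b = x$fe_b[adult], w_b = x$w_b[adult])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
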