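# One-way sensitivity (tornado) and willingness calibration --------------------

TORNADO_PARAMETERS <- c("feasibility", "willingness", "c_first_year",
                        "c_second_year", "c_subsequent", "c_reimplant",
                        "c_processor")

#' One-way tornado sensitivity analysis
#'
#' Each parameter is scaled down and up by `delta` (default 25%) in an
#' otherwise unchanged full simulation; the cumulative total cost of each run
#' is compared with the shared baseline run. Feasibility and willingness
#' scalings that push proportions above 1 are capped (and counted by the run).
#'
#' @param base_scenario A [scenario()] (typically `build_scenario("baseline")`).
#' @param inputs,config As in [run_scenario()].
#' @param parameters Subset of
#'   `c("feasibility", "willingness", "c_first_year", "c_second_year",
#'   "c_subsequent", "c_reimplant", "c_processor")`.
#' @param delta Proportional perturbation (default 0.25).
#' @return A data frame of class `tornado_result`, one row per parameter:
#'   `low_total`, `base_total`, `high_total` (cumulative euro),
#'   `delta_low`, `delta_high`, `max_abs_delta` and `bar_width`
#'   (`|high_total - low_total|`, the tornado bar length); rows ranked by
#'   `bar_width`, largest first (remaining ties keep the canonical parameter
#'   order).
#' @export
tornado <- function(base_scenario, inputs, config = sim_config(),
                    parameters = TORNADO_PARAMETERS, delta = 0.25) {
  bad <- setdiff(parameters, TORNADO_PARAMETERS)
  if (length(bad)) {
    stop("unknown tornado parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  total_cost <- function(scn) sum(run_scenario(scn, inputs, config)$total)
  perturb <- function(scn, param, factor) {
    if (param == "feasibility") {
      scn$fe_scale <- scn$fe_scale * factor
    } else if (param == "willingness") {
      scn$w_scale <- scn$w_scale * factor
    } else {
      cs <- scn$cost_scale %||% c()
      cs[param] <- (if (param %in% names(cs)) cs[[param]] else 1) * factor
      scn$cost_scale <- cs
    }
    scn
  }
  base_total <- total_cost(base_scenario)
  rows <- lapply(parameters, function(param) {
    lo <- total_cost(perturb(base_scenario, param, 1 - delta))
    hi <- total_cost(perturb(base_scenario, param, 1 + delta))
    data.frame(parameter = param, low_total = lo, base_total = base_total,
               high_total = hi, delta_low = lo - base_total,
               delta_high = hi - base_total,
               max_abs_delta = max(abs(lo - base_total), abs(hi - base_total)),
               bar_width = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$bar_width, -out$max_abs_delta), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate willingness to observed implantation counts
#'
#' Finds the willingness level that minimizes the squared error between
#' simulated and observed annual unilateral implantations over the observed
#' years. In `"uniform"` mode (the default, matching how the baseline value
#' 0.01 was set) a single scalar replaces all age-specific willingness values;
#' in `"scaled"` mode the surveyed age profile is multiplied by the scalar
#' instead. Simulated implantations are monotone non-decreasing in the
#' scalar, so the objective is unimodal and a Brent search on \[0, 1\]
#' (tolerance 1e-6) suffices.
#'
#' @param inputs,config As in [run_scenario()]; the simulation horizon is
#'   extended to cover the latest observed year.
#' @param observed Data frame with columns `year` and `implants` (observed
#'   unilateral implantations).
#' @param mode `"uniform"` or `"scaled"`.
#' @return An object of class `calibration_result`: `scalar` (fitted
#'   willingness), `mode`, `fit` (observed vs simulated per year) and
#'   `residual` (sum of squared errors).
#' @export
calibrate_willingness <- function(inputs, observed, config = sim_config(),
                                  mode = c("uniform", "scaled")) {
  mode <- match.arg(mode)
  stopifnot(all(c("year", "implants") %in% names(observed)),
            nrow(observed) >= 1L, all(observed$implants >= 0))
  yr_idx <- observed$year - config$start_year
  if (any(yr_idx < 1L)) {
    stop("observed years must fall after the base year ", config$start_year,
         call. = FALSE)
  }
  cfg <- config
  cfg$horizon_years <- max(yr_idx)

  simulate_ciu <- function(w) {
    scn <- if (mode == "uniform") {
      scenario("calibration",
               willingness = list(mode = "uniform", value = w,
                                  table = willingness_table()))
    } else {
      scenario("calibration",
               willingness = list(mode = "table", value = w,
                                  table = willingness_table()),
               w_scale = w)
    }
    out <- run_scenario(scn, inputs, cfg)
    out$ciu[yr_idx]
  }

  if (all(observed$implants == 0)) {
    sim <- simulate_ciu(0)
    return(structure(list(scalar = 0, mode = mode,
                          fit = data.frame(year = observed$year,
                                           observed = observed$implants,
                                           simulated = sim),
                          residual = sum(sim^2)),
                     class = "calibration_result"))
  }

  sim_max <- suppressMessages(simulate_ciu(1))
  if (any(sim_max < observed$implants)) {
    stop("observed implantations exceed the simulated maximum at willingness 1",
         call. = FALSE)
  }
  sse <- function(w) sum((suppressMessages(simulate_ciu(w)) - observed$implants)^2)
  opt <- stats::optimize(sse, interval = c(0, 1), tol = 1e-6)
  sim <- simulate_ciu(opt$minimum)
  structure(list(scalar = opt$minimum, mode = mode,
                 fit = data.frame(year = observed$year,
                                  observed = observed$implants,
                                  simulated = sim),
                 residual = opt$objective),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result>  %s willingness = %.6f (SSE %.4g)\n",
              x$mode, x$scalar, x$residual))
  print(x$fit)
  invisible(x)
}
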