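# Cost engine: annual payer cost components ------------------------------------

COST_COMPONENTS <- c("first_year_uni", "first_year_bi", "second_year",
                     "subsequent_years", "reimplant", "processor")

#' Unit costs of CI care (payer perspective)
#'
#' All amounts in nominal euro per event or per patient-year; costs are
#' assumed constant over the horizon and are not discounted.
#'
#' @param c_first_year Cost of the first year of an implantation event
#'   (surgery, device, first-year rehabilitation).
#' @param c_second_year Cost of the second year after an implantation event.
#' @param c_subsequent Annual follow-up cost per implanted patient from the
#'   third year after implantation until death.
#' @param c_reimplant Cost per reimplantation.
#' @param c_processor Cost per speech processor exchange.
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(c_first_year, c_second_year, c_subsequent,
                            c_reimplant, c_processor) {
  vals <- c(c_first_year = c_first_year, c_second_year = c_second_year,
            c_subsequent = c_subsequent, c_reimplant = c_reimplant,
            c_processor = c_processor)
  if (any(vals < 0)) {
    stop("unit costs must be non-negative (", names(vals)[vals < 0][1L], ")",
         call. = FALSE)
  }
  structure(as.list(vals), class = "cost_parameters")
}

#' Annual cost breakdown for one simulated year
#'
#' Event-ledger bookkeeping over the year's and the previous year's
#' implantation events:
#' \itemize{
#'   \item first-year cost: unit cost times this year's implantation events
#'     (unilateral and bilateral reported separately);
#'   \item second-year cost: unit cost times last year's events, decremented
#'     by one year of age-specific survival;
#'   \item subsequent-years cost: unit cost times implanted patients (stages
#'     unilateral + bilateral, each patient once) excluding patients whose
#'     most recent implantation event was within the last two years;
#'   \item reimplantation and processor cost: unit cost times the year's
#'     replacement flows.
#' }
#'
#' @param flows List for the current year with elements `ciu` and `cib`
#'   (implantation events per age, length 101) and scalars `sn` (processor
#'   exchanges) and `cin` (reimplantations).
#' @param prev_flows Same structure for the previous year, or `NULL` in the
#'   first simulated year (previous events then count as zero; base-year CI
#'   stocks, if any, fall into the subsequent-years component).
#' @param state The [population_state()] at the end of the year.
#' @param params A [cost_parameters()].
#' @param rates A [demographic_rates()] (mortality provides the one-year
#'   survival factor applied to last year's events).
#' @return A one-row data frame of class `cost_breakdown` with the six
#'   components and their `total` (euro).
#' @export
annual_costs <- function(flows, prev_flows, state, params, rates) {
  stopifnot(inherits(params, "cost_parameters"),
            inherits(state, "population_state"),
            inherits(rates, "demographic_rates"))
  ciu <- sum(flows$ciu)
  cib <- sum(flows$cib)
  if (is.null(prev_flows)) {
    prev_events_surviving <- 0
  } else {
    surv <- 1 - rates$mortality
    prev_events_surviving <- sum((prev_flows$ciu + prev_flows$cib) * surv)
  }
  implanted <- sum(state$counts[, 3L]) + sum(state$counts[, 4L])
  established <- max(0, implanted - (ciu + cib) - prev_events_surviving)

  out <- data.frame(
    first_year_uni = params$c_first_year * ciu,
    first_year_bi = params$c_first_year * cib,
    second_year = params$c_second_year * prev_events_surviving,
    subsequent_years = params$c_subsequent * established,
    reimplant = params$c_reimplant * flows$cin,
    processor = params$c_processor * flows$sn
  )
  out$total <- rowSums(out)
  class(out) <- c("cost_breakdown", "data.frame")
  out
}

#' Cumulate annual cost breakdowns over a horizon
#'
#' @param breakdowns Data frame of annual cost rows (one per year) holding the
#'   six component columns and `total`, e.g. the cost columns of a
#'   [run_scenario()] result.
#' @return A list with `total` (cumulative euro per component and overall),
#'   `annual_mean`, `years`, and `ordering` (components sorted by cumulative
#'   size, largest first, ties broken by the fixed component order).
#' @export
cumulate_costs <- function(breakdowns) {
  stopifnot(nrow(breakdowns) >= 1L,
            all(c(COST_COMPONENTS, "total") %in% names(breakdowns)))
  cols <- c(COST_COMPONENTS, "total")
  tot <- vapply(breakdowns[cols], sum, numeric(1L))
  comp <- tot[COST_COMPONENTS]
  # stable sort: ties keep the fixed component order
  ord <- COST_COMPONENTS[order(-comp, seq_along(comp))]
  list(total = tot,
       annual_mean = tot / nrow(breakdowns),
       years = nrow(breakdowns),
       ordering = ord)
}
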