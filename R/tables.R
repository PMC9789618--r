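# Packaged survey and cost tables ----------------------------------------------
#
# Feasibility and willingness by decade age group come from an online survey
# of 124 German ENT physicians (October 2019); the innovative-CI parameter set
# comes from a two-stage Delphi survey of six German CI experts (February
# 2020). Values are group means in percent, converted to proportions here.

#' Surveyed feasibility of CI implantation by age group
#'
#' Proportion of CI candidates (> 60 dB HL) judged medically suitable for
#' uni- or bilateral implantation, by decade age group. Feasibility decreases
#' strongly with age (contraindications such as low rehabilitation prospects,
#' dementia, anesthesia risk); feasibility for a second implant is slightly
#' higher than for the first in every age group.
#'
#' @return Data frame with columns `age_lower`, `age_upper`, `unilateral`,
#'   `bilateral` (proportions).
#' @export
feasibility_table <- function() {
  data.frame(
    age_lower  = c(20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L),
    age_upper  = c(29L, 39L, 49L, 59L, 69L, 79L, 89L, 100L),
    unilateral = c(76.57, 75.60, 71.04, 63.80, 58.36, 48.54, 35.82, 27.30) / 100,
    bilateral  = c(82.81, 79.74, 76.02, 69.63, 63.33, 50.87, 38.04, 30.94) / 100
  )
}

#' Surveyed willingness for CI implantation by age group
#'
#' Proportion of medically suitable patients estimated to actually undergo
#' implantation, by decade age group. Used directly only in the
#' higher-willingness and ramped scenarios; the baseline replaces it with the
#' calibrated uniform value 0.01.
#'
#' @return Data frame with columns `age_lower`, `age_upper`, `unilateral`,
#'   `bilateral` (proportions).
#' @export
willingness_table <- function() {
  data.frame(
    age_lower  = c(20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L),
    age_upper  = c(29L, 39L, 49L, 59L, 69L, 79L, 89L, 100L),
    unilateral = c(68.64, 67.82, 60.38, 53.36, 42.70, 30.94, 19.76, 13.12) / 100,
    bilateral  = c(72.92, 70.70, 65.97, 60.70, 46.62, 24.70, 17.08, 10.32) / 100
  )
}

#' Unit costs and device lifespans of the baseline CI system
#'
#' Payer-perspective unit costs (nominal euro, 2017) and average device
#' lifespans of current standard CI care.
#'
#' @return A list with a [cost_parameters()] element `costs` and a
#'   [device_parameters()] element `devices`.
#' @export
baseline_cost_set <- function() {
  list(costs = cost_parameters(c_first_year = 33442.86,
                               c_second_year = 3369.96,
                               c_subsequent = 620.73,
                               c_reimplant = 27449.19,
                               c_processor = 9847.02),
       devices = device_parameters(l_i = 20, l_s = 5))
}

#' Unit costs and device lifespans of the innovative (coated) CI
#'
#' Expert-panel estimates for an anti-inflammatory/anti-proliferative coated
#' implant: longer implant lifespan (23 years), higher implant unit costs,
#' lower follow-up costs. The processor (cost and lifespan) is unchanged.
#'
#' @return A list with elements `costs` and `devices`, as
#'   [baseline_cost_set()].
#' @export
innovative_cost_set <- function() {
  list(costs = cost_parameters(c_first_year = 37578.71,
                               c_second_year = 3310.69,
                               c_subsequent = 602.21,
                               c_reimplant = 31777.68,
                               c_processor = 9847.02),
       devices = device_parameters(l_i = 23, l_s = 5))
}
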