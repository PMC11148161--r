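#' Observed (and source-model predicted) qualification PK parameters
#'
#' Digitized comparison table: per study arm and metric, the clinically
#' observed value and, for reference, the prediction of the source model.
#' Units: AUC nmol*h/L over the dosing interval, concentrations nmol/L.
#' `NA` marks values the studies did not report.
#'
#' @return tibble `study`, `dose_mg`, `metric`, `observed`,
#'   `reference_predicted`.
#' @export
table3_observed <- function() {
  tibble::tribble(
    ~study, ~dose_mg, ~metric, ~observed, ~reference_predicted,
    "Planchard",  20, "AUC",      1964,  2591,
    "Planchard",  20, "Cmax",     106.4, 134.5,
    "Planchard",  20, "Ctrough",  51.2,  87.2,
    "Planchard",  40, "AUC",      5640,  5153,
    "Planchard",  40, "Cmax",     306.2, 261.3,
    "Planchard",  40, "Ctrough",  179.3, 168.0,
    "Planchard",  80, "AUC",      11930, 12382,
    "Planchard",  80, "Cmax",     623.8, 586.8,
    "Planchard",  80, "Ctrough",  386.4, 406.7,
    "Planchard", 160, "AUC",      23910, 26272,
    "Planchard", 160, "Cmax",     1255,  1180.7,
    "Planchard", 160, "Ctrough",  784.4, 805.5,
    "Planchard", 240, "AUC",      28310, 38188,
    "Planchard", 240, "Cmax",     1491,  1650.3,
    "Planchard", 240, "Ctrough",  929.1, 1118.6,
    "Zhao",       40, "AUC",      5698,  7105,
    "Zhao",       40, "Cmax",     303.4, 309.1,
    "Zhao",       40, "Ctrough",  183.0, 217.4,
    "Zhao",       80, "AUC",      9570,  12306,
    "Zhao",       80, "Cmax",     550.4, 598.5,
    "Zhao",       80, "Ctrough",  318.0, 377.0,
    "Harvey",     80, "AUC",      11530, 12923,
    "Harvey",     80, "Cmax",     620.1, 572.0,
    "Harvey",     80, "Ctrough",  291.8, 375.5,
    "Grande",     80, "AUC",      15780, 13447,
    "Grande",     80, "Cmax",     291.8, 535.7,
    "Grande",     80, "Ctrough",  NA,    350.0,
    "Goldstein",  80, "intracranial_Ctrough", 14.4, 12.0,
    "Yamaguchi",  80, "intracranial_Ctrough", 4.1,  10.3,
    "Leeuw",      80, "intracranial_Ctrough", 17.5, 12.6,
    "Fukuhara",   80, "intracranial_Ctrough", 18.3, 15.9,
    "Ekman",      80, "intracranial_Ctrough", 19.5, 15.3
  )
}

#' Published DDI exposure-ratio table
#'
#' The source model's predicted (and where available observed) plasma AUC
#' and Cmax ratios for the five perpetrators: the two replicated clinical
#' calendars and the 14-day continuous co-administration block.
#'
#' @return tibble.
#' @export
table4_ddi <- function() {
  tibble::tribble(
    ~perpetrator, ~scenario, ~auc_ratio_ref, ~cmax_ratio_ref,
    ~auc_ratio_obs, ~cmax_ratio_obs,
    "itraconazole", "single_dose_calendar", 1.60, 1.06, 1.26, 0.83,
    "rifampicin",   "steady_state_calendar", 0.16, 0.40, 0.20, 0.26,
    "itraconazole", "14_day", 2.21, 1.60, NA, NA,
    "fluconazole",  "14_day", 1.75, 1.32, NA, NA,
    "fluvoxamine",  "14_day", 1.41, 1.20, NA, NA,
    "rifampicin",   "14_day", 0.15, 0.38, NA, NA,
    "efavirenz",    "14_day", 0.28, 0.50, NA, NA
  )
}
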