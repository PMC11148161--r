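#' Load the perpetrator fixture table
#'
#' @param path YAML fixture (default: packaged file).
#' @return named list of perpetrator models.
#' @export
load_perpetrators <- function(path = system.file("extdata",
                                                 "perpetrators.yaml",
                                                 package = "pbpkeo")) {
  yaml::read_yaml(path)
}

perp_dose_times <- function(perp, days) {
  interval <- perp$regimen$interval
  per_day <- 24 / interval
  sort(as.vector(vapply(days, function(d) {
    (d - 1) * 24 + (seq_len(per_day) - 1) * interval
  }, numeric(per_day))))
}

#' Unbound perpetrator concentration profile
#'
#' Superposed one-compartment first-order oral doses, reported unbound;
#' the same closed form the ODE core evaluates internally.
#'
#' @param perp one perpetrator record from [load_perpetrators()].
#' @param horizon_h end of the profile, h.
#' @param days dosing days (1-based); default days 1..14.
#' @param dt_out grid step, h.
#' @return tibble `time_h`, `conc_uM` (unbound).
#' @export
perpetrator_unbound_profile <- function(perp, horizon_h = 14 * 24,
                                        days = 1:14, dt_out = 0.1) {
  td <- perp_dose_times(perp, days)
  ka <- perp$pk$ka
  ke <- perp$pk$cl_f / perp$pk$v_f
  d_umol <- mg_to_umol(perp$regimen$dose_mg, perp$molecular_weight)
  tt <- seq(0, horizon_h, by = dt_out)
  conc <- vapply(tt, function(t) {
    dt <- t - td
    dt <- dt[dt > 0]
    sum(d_umol * ka / (perp$pk$v_f * (ka - ke)) *
          (exp(-ke * dt) - exp(-ka * dt)))
  }, numeric(1))
  tibble::tibble(time_h = tt, conc_uM = perp$pk$fu * conc)
}

#' Static interaction algebra on per-enzyme clearances
#'
#' Competitive inhibition multiplier `1 / (1 + Iu/Ki)` and steady-state
#' induction fold `1 + Emax Iu / (EC50 + Iu)` per enzyme; the combined
#' multiplier scales that enzyme's intrinsic clearance. (The dynamic
#' simulation applies the same algebra with the induction fold relaxed
#' through enzyme turnover.)
#'
#' @param baseline_cl named numeric vector of per-enzyme clearances.
#' @param perpetrator_conc unbound perpetrator concentration, uM.
#' @param perp perpetrator record (for Ki/Emax/EC50 terms).
#' @return tibble `enzyme`, `baseline_cl`, `inhibition_mult`,
#'   `induction_fold`, `combined_mult`, `cl_effective`.
#' @export
apply_interaction <- function(baseline_cl, perpetrator_conc, perp) {
  stopifnot(all(baseline_cl >= 0), perpetrator_conc >= 0)
  enz <- names(baseline_cl)
  inh <- vapply(enz, function(e) {
    ki <- perp$inhibition[[e]]
    if (is.null(ki)) 1 else 1 / (1 + perpetrator_conc / ki)
  }, numeric(1))
  ind <- vapply(enz, function(e) {
    tr <- perp$induction[[e]]
    if (is.null(tr)) 1 else
      1 + tr$emax * perpetrator_conc / (tr$ec50_u + perpetrator_conc)
  }, numeric(1))
  tibble::tibble(enzyme = enz, baseline_cl = unname(baseline_cl),
                 inhibition_mult = unname(inh),
                 induction_fold = unname(ind),
                 combined_mult = unname(inh * ind),
                 cl_effective = unname(baseline_cl * inh * ind))
}

# fill the parameter vector with one perpetrator's PK and terms
set_perpetrator <- function(model, perp, days) {
  p <- model$parms
  get_ki <- function(e) {
    ki <- perp$inhibition[[e]]
    if (is.null(ki)) 0 else ki
  }
  get_ind <- function(e) {
    tr <- perp$induction[[e]]
    if (is.null(tr)) c(0, 1) else c(tr$emax, tr$ec50_u)
  }
  p[.pi$ki_1a2] <- get_ki("CYP1A2")
  p[.pi$ki_2c9] <- get_ki("CYP2C9")
  p[.pi$ki_3a4] <- get_ki("CYP3A4")
  p[c(.pi$emax_1a2, .pi$ec50_1a2)] <- get_ind("CYP1A2")
  p[c(.pi$emax_2c9, .pi$ec50_2c9)] <- get_ind("CYP2C9")
  p[c(.pi$emax_3a4, .pi$ec50_3a4)] <- get_ind("CYP3A4")
  p[.pi$perp_ka] <- perp$pk$ka
  p[.pi$perp_ke] <- perp$pk$cl_f / perp$pk$v_f
  p[.pi$perp_vf] <- perp$pk$v_f
  p[.pi$perp_fu] <- perp$pk$fu
  p[.pi$perp_dose] <- mg_to_umol(perp$regimen$dose_mg,
                                 perp$molecular_weight)
  td <- perp_dose_times(perp, days)
  if (length(td) > 64) stop("at most 64 perpetrator doses", call. = FALSE)
  p[.pi$n_dose_p] <- length(td)
  p[.pi$t_dose_p[seq_along(td)]] <- td
  model$parms <- p
  model
}

#' Co-administration scenario
#'
#' Simulates the victim regimen alone and with a perpetrator dosed over
#' `perp_days`, and computes exposure ratios on the final victim dosing
#' interval plus the intracranial occupancy under the perturbed profile.
#'
#' @param model a `pbpkeo_body_model` for the victim.
#' @param perp perpetrator record, or `NULL` for a null perpetrator.
#' @param regimen victim regimen (default 80 mg OD x 14 d).
#' @param perp_days perpetrator dosing days (default the same 14 days).
#' @param variants EGFR variants for the occupancy readout.
#' @return list of class `"pbpkeo_ddi"`: `$ratios` tibble (`auc_ratio`,
#'   `cmax_ratio`, `ctrough_ratio`), `$pk` per-arm summaries, `$eo` trough
#'   occupancy per variant and arm, `$sims` the two simulations.
#' @export
ddi_scenario <- function(model, perp, regimen = dose_regimen(80),
                         perp_days = seq_len(regimen$n_days),
                         variants = c("t790m_l858r", "l858r")) {
  base <- simulate_regimen(model, regimen)
  mdl_p <- if (is.null(perp)) model else set_perpetrator(model, perp,
                                                         perp_days)
  combo <- simulate_regimen(mdl_p, regimen)
  s_base <- summarize_pk(base)
  s_combo <- summarize_pk(combo)
  eo <- model$cfg$eo
  eo_base <- simulate_eo(eo_drive_profile(base), eo, variants,
                         interval = regimen$interval)
  eo_combo <- simulate_eo(eo_drive_profile(combo), eo, variants,
                          interval = regimen$interval)
  ratios <- tibble::tibble(
    auc_ratio = s_combo$auc_nmol_h_L / s_base$auc_nmol_h_L,
    cmax_ratio = s_combo$cmax_nmol_L / s_base$cmax_nmol_L,
    ctrough_ratio = s_combo$ctrough_nmol_L / s_base$ctrough_nmol_L
  )
  eo_tbl <- dplyr::bind_rows(
    dplyr::mutate(eo_base$trough, arm = "victim_alone"),
    dplyr::mutate(eo_combo$trough, arm = "co_administered")
  )
  structure(list(ratios = ratios,
                 pk = dplyr::bind_rows(
                   dplyr::mutate(s_base, arm = "victim_alone"),
                   dplyr::mutate(s_combo, arm = "co_administered")),
                 eo = eo_tbl,
                 sims = list(base = base, combo = combo)),
            class = "pbpkeo_ddi")
}

#' @export
print.pbpkeo_ddi <- function(x, ...) {
  cat("<pbpkeo_ddi> AUC ratio", signif(x$ratios$auc_ratio, 3),
      "| Cmax ratio", signif(x$ratios$cmax_ratio, 3), "\n")
  invisible(x)
}

#' The two published single-dose DDI study calendars
#'
#' Scenario (a): single 80 mg victim doses on days 1 and 10 with
#' itraconazole 200 mg BID on days 6-18; the ratio compares the 9-day
#' post-dose exposure of the co-administered dose with the first dose.
#' Scenario (b): victim 80 mg OD days 1-29 with rifampicin 600 mg OD days
#' 6-30; the ratio compares the day-29 dosing-interval exposure with the
#' pre-perpetrator day-5 interval.
#'
#' @param model a `pbpkeo_body_model`.
#' @param perps perpetrator fixture list.
#' @return tibble with `scenario`, `auc_ratio`, `cmax_ratio`.
#' @export
ddi_single_dose_scenarios <- function(model, perps = load_perpetrators()) {
  # (a) itraconazole
  reg_a <- dose_regimen(80, days = c(1, 10))
  mdl_a <- set_perpetrator(model, perps$itraconazole, days = 6:18)
  sim_a <- simulate_regimen(mdl_a, reg_a, horizon_h = 19 * 24)
  win <- function(sim, lo, hi) {
    pr <- dplyr::filter(sim$profile, .data$time_h >= lo, .data$time_h <= hi)
    c(auc = trapz(pr$time_h, pr$plasma_nmol_L), cmax = max(pr$plasma_nmol_L))
  }
  d1 <- win(sim_a, 0, 216)
  d10 <- win(sim_a, 216, 432)
  # (b) rifampicin
  reg_b <- dose_regimen(80, n_days = 29)
  mdl_b <- set_perpetrator(model, perps$rifampicin, days = 6:30)
  sim_b <- simulate_regimen(mdl_b, reg_b, horizon_h = 30 * 24)
  d5 <- win(sim_b, 4 * 24, 5 * 24)
  d29 <- win(sim_b, 28 * 24, 29 * 24)
  tibble::tibble(
    scenario = c("itraconazole_single_dose", "rifampicin_steady_state"),
    auc_ratio = c(d10["auc"] / d1["auc"], d29["auc"] / d5["auc"]),
    cmax_ratio = c(d10["cmax"] / d1["cmax"], d29["cmax"] / d5["cmax"])
  )
}
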