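#' Fraction unionized of a monoprotic base
#'
#' Henderson-Hasselbalch single-site form: the log10 ratio of unionized to
#' ionized species equals `ph - pka` for a base, so the unionized fraction
#' is `u / (1 + u)` with `u = 10^(ph - pka)`.
#'
#' @param pka base dissociation constant (unitless).
#' @param ph medium pH.
#' @return fraction unionized, in (0, 1).
#' @examples
#' unionized_fraction(9.5, 7.4) # osimertinib at physiological pH, ~0.0079
#' @export
unionized_fraction <- function(pka, ph) {
  u <- 10^(ph - pka)
  u / (1 + u)
}

#' Intrinsic efflux clearance from a bidirectional transwell assay
#'
#' Converts apparent apical-to-basolateral permeability and the net efflux
#' ratio measured in a transfected cell monolayer into an unbound intrinsic
#' transport clearance per million cells:
#' `CLint,u = 2 * Papp,A-B * (NFR - 1) * SA / (gamma * cells)`,
#' where `gamma` is the unionized fraction at the assay pH.
#'
#' @param papp_ab apical-to-basolateral apparent permeability, 1e-6 cm/s.
#' @param nfr net efflux ratio (>= 1).
#' @param sa filter surface area, cm^2.
#' @param cells cell amount on the filter, million cells.
#' @param assay_ph assay pH (default 7.4).
#' @param pka base pKa used for the unionized fraction (default 9.5).
#' @return intrinsic clearance in uL/min/million cells.
#' @examples
#' # ABCB1: Papp 1.36, NFR 13.4 on a 1.12 cm^2 insert with 3.92e6 cells
#' transporter_clint_from_assay(1.36, 13.4, sa = 1.12, cells = 3.92)
#' @export
transporter_clint_from_assay <- function(papp_ab, nfr, sa, cells,
                                         assay_ph = 7.4, pka = 9.5) {
  stopifnot(papp_ab > 0, sa > 0, cells > 0)
  if (nfr < 1) {
    stop("net efflux ratio < 1: assay implies negative efflux", call. = FALSE)
  }
  gamma <- unionized_fraction(pka, assay_ph)
  # Papp in 1e-6 cm/s: 1e-6 cm3/s = 1e-3 uL/s = 0.06 uL/min
  (2 * papp_ab * (nfr - 1) * sa * 0.06) / (gamma * cells)
}

#' Plasma-protein scale factor for altered albumin
#'
#' Scales the fraction unbound in plasma for a patient whose albumin level
#' differs from the reference at which `fu` was measured:
#' `PPSF = 1 / (fu + (1 - fu) * albumin_f)`. With the physiological
#' orientation (`albumin_f = albumin / albumin_ref`) this is algebraically
#' identical to the standard albumin-dilution relation
#' `fu2 = 1 / (1 + (alb2/alb1) * (1 - fu1) / fu1)`, so hypoalbuminemia
#' raises the unbound fraction. The `as_printed` orientation uses the
#' reciprocal ratio; it inverts that direction and is retained because the
#' published factor-sweep behaviour of this model follows it (see the
#' methods vignette).
#'
#' @param fu fraction unbound measured at the reference albumin, in (0, 1].
#' @param albumin subject albumin level (any unit, consistently with
#'   `albumin_ref`).
#' @param albumin_ref reference albumin level.
#' @param orientation `"physiological"` (albumin/albumin_ref, default) or
#'   `"as_printed"` (albumin_ref/albumin).
#' @return unitless scale factor; `fu * ppsf()` is the adjusted fraction
#'   unbound (clamped to 1 with a warning if the scaling overshoots).
#' @examples
#' ppsf(0.011, albumin = 0.31, albumin_ref = 0.45) # ~1.444
#' 0.011 * ppsf(0.011, 0.31, 0.45)                 # scaled fup ~0.0159
#' @export
ppsf <- function(fu, albumin, albumin_ref,
                 orientation = c("physiological", "as_printed")) {
  stopifnot(fu > 0, fu <= 1, albumin > 0, albumin_ref > 0)
  orientation <- match.arg(orientation)
  albumin_f <- switch(orientation,
    physiological = albumin / albumin_ref,
    as_printed = albumin_ref / albumin
  )
  1 / (fu + (1 - fu) * albumin_f)
}

#' Apply the plasma-protein scale factor to a fraction unbound
#'
#' @inheritParams ppsf
#' @return scaled fraction unbound in (0, 1].
#' @export
scaled_fu <- function(fu, albumin, albumin_ref,
                      orientation = c("physiological", "as_printed")) {
  out <- fu * ppsf(fu, albumin, albumin_ref, match.arg(orientation))
  if (out > 1) {
    warning("scaled fraction unbound > 1; clamped to 1", call. = FALSE)
    out <- 1
  }
  out
}

#' First-order degradation rate constant from a half-life
#'
#' @param halflife half-life in hours (e.g. 27.5 h for EGFR turnover).
#' @return rate constant in 1/h (`ln(2)/halflife`).
#' @examples
#' kdeg_from_halflife(27.5) # ~0.025 1/h
#' @export
kdeg_from_halflife <- function(halflife) {
  stopifnot(halflife > 0)
  log(2) / halflife
}

check_positive <- function(x, nm) {
  bad <- names(x)[!vapply(x, function(v) all(is.finite(v) & v > 0), TRUE)]
  if (length(bad)) {
    stop(sprintf("%s: fields must be positive: %s", nm,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Load the full model configuration
#'
#' Reads the declarative YAML parameterization (drug physicochemistry,
#' absorption, distribution, metabolism, blood-brain-barrier transport,
#' EGFR binding kinetics, physiology, interaction constants and the frozen
#' calibration factors) and validates field presence, units and invariants.
#' The shipped default reproduces the published model input table verbatim.
#'
#' @param path YAML file; default is the packaged osimertinib
#'   parameterization.
#' @return a nested list of class `"pbpkeo_config"`.
#' @export
load_model_config <- function(path = system.file("extdata", "osimertinib.yaml",
                                                 package = "pbpkeo")) {
  cfg <- yaml::read_yaml(path)
  required <- c("compound", "absorption", "distribution", "metabolism",
                "brain_transport", "eo", "interactions", "physiology",
                "calibration")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config missing sections: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cmp <- cfg$compound
  stopifnot(cmp$fu_plasma > 0, cmp$fu_plasma <= 1,
            cmp$blood_plasma_ratio > 0, cmp$solubility_water > 0)
  ab <- cfg$absorption
  check_positive(ab[c("gastric_emptying_time", "effective_permeability",
                      "weibull_t50", "weibull_shape")], "absorption")
  stopifnot(ab$weibull_shape <= 5)
  dist <- cfg$distribution
  stopifnot(dist$kp_scale > 0, dist$k_brt_plasma > 0,
            identical(dist$partition_method, "rodgers_rowland"))
  met <- cfg$metabolism
  enz <- c("CYP1A2", "CYP2A6", "CYP2C9", "CYP2E1", "CYP3A4", "CYP3A5")
  stopifnot(all(enz %in% names(met$cyp_clint)),
            all(unlist(met$cyp_clint) >= 0), met$gfr > 0,
            identical(met$renal_clearance_rule, "gfr_times_fup"))
  bt <- cfg$brain_transport
  stopifnot(bt$abcb1_clint >= 0, bt$bcrp_clint >= 0,
            bt$abcb1_conc >= 0, bt$bcrp_conc >= 0)
  eo <- cfg$eo
  variants <- c("wild_type", "t790m_l858r", "l858r", "c797s")
  stopifnot(all(variants %in% names(eo$kon)),
            all(unlist(eo$kon) >= 0), eo$koff >= 0,
            eo$egfr_t0 > 0, eo$kdeg > 0,
            eo$kon_time_base %in% c("per_hour", "per_second"),
            eo$drive %in% c("brt_total", "interstitial_free"))
  phys <- cfg$physiology
  stopifnot(phys$hematocrit > 0, phys$hematocrit < 1,
            phys$albumin_patient > 0, phys$albumin_healthy_reference > 0,
            phys$body_weight > 0,
            phys$ppsf_orientation %in% c("physiological", "as_printed"))
  structure(cfg, class = "pbpkeo_config")
}

#' @export
print.pbpkeo_config <- function(x, ...) {
  cat("<pbpkeo_config>\n")
  cat("  compound MW:", x$compound$molecular_weight, "g/mol, fup",
      x$compound$fu_plasma, "\n")
  cat("  EO drive:", x$eo$drive, "| kon time base:", x$eo$kon_time_base, "\n")
  cat("  calibration: hepatic_clint_scale =",
      x$calibration$hepatic_clint_scale,
      ", brain_ps =", x$calibration$brain_ps, "L/h\n")
  invisible(x)
}

#' Tidy view of the parameter table
#'
#' Flattens the configuration into one row per scalar parameter with its
#' unit string, for reporting and round-trip checks.
#'
#' @param cfg a `pbpkeo_config`.
#' @return a tibble with columns `section`, `parameter`, `value`, `unit`.
#' @export
parameter_table <- function(cfg = load_model_config()) {
  units <- cfg$units %||% list()
  rows <- purrr::imap(unclass(cfg)[setdiff(names(cfg), "units")],
    function(section, sec_name) {
      flat <- unlist(section)
      num <- suppressWarnings(as.numeric(flat))
      tibble::tibble(
        section = sec_name,
        parameter = names(flat),
        value = num,
        value_chr = as.character(flat),
        unit = purrr::map_chr(names(flat), function(p) {
          u <- units[[paste(sec_name, p, sep = ".")]]
          if (is.null(u)) NA_character_ else u
        })
      )
    })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
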