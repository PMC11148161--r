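#' Mean virtual subject
#'
#' The deterministic reference patient: all variability multipliers at 1,
#' demographics at the configured patient means.
#'
#' @param cfg a `pbpkeo_config`.
#' @return one-row tibble of class usable wherever a subject is expected.
#' @export
mean_subject <- function(cfg = load_model_config()) {
  tibble::tibble(
    id = 0L,
    body_weight = cfg$physiology$body_weight,
    albumin = cfg$physiology$albumin_patient,
    hematocrit = cfg$physiology$hematocrit,
    m_clint_hep = 1, m_peff = 1, m_brain_ps = 1, m_abcb1 = 1
  )
}

#' Whole-liver unbound intrinsic clearance per CYP enzyme
#'
#' Bottom-up scale-up: per-pmol unbound intrinsic clearance x hepatic
#' abundance (pmol/mg microsomal protein) x microsomal protein per gram of
#' liver x liver weight, converted to L/h, times the frozen global hepatic
#' calibration factor.
#'
#' @param cfg a `pbpkeo_config`.
#' @param calibration_factor global scalar on all six enzymes (default: the
#'   frozen value in the config).
#' @return tibble with `enzyme` and `clint_L_h` (unbound, whole liver).
#' @export
hepatic_intrinsic_clearance <- function(cfg = load_model_config(),
                                        calibration_factor =
                                          cfg$calibration$hepatic_clint_scale) {
  enz <- names(cfg$metabolism$cyp_clint)
  clint <- unlist(cfg$metabolism$cyp_clint[enz])
  abund <- unlist(cfg$physiology$enzyme_abundance[enz])
  # uL/min/pmol x pmol/mg x mg/g x g -> uL/min -> L/h (x 60 / 1e6)
  l_h <- clint * abund * cfg$physiology$mppgl *
    cfg$physiology$liver_weight_g * 60 / 1e6 * calibration_factor
  tibble::tibble(enzyme = enz, clint_L_h = unname(l_h))
}

#' Assemble the body model for one subject
#'
#' Computes per-subject volumes, flows, partition coefficients, effective
#' fraction unbound (via the plasma-protein scale factor at the subject's
#' albumin), and all clearance terms, returning the parameter vector and
#' bookkeeping needed by the ODE core. Volumes scale linearly with body
#' weight and flows with weight^0.75 relative to the reference human.
#'
#' @param cfg a `pbpkeo_config`.
#' @param subject one-row subject tibble (see [mean_subject()],
#'   [sample_population()]).
#' @param overrides named list of config overrides applied before assembly
#'   (e.g. `list(brain_transport.abcb1_clint = 146.8)`); names use
#'   `section.field` paths.
#' @return a list of class `"pbpkeo_body_model"`.
#' @export
build_body_model <- function(cfg = load_model_config(),
                             subject = mean_subject(cfg),
                             overrides = list()) {
  for (nm in names(overrides)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg[[path]] <- overrides[[nm]]
  }
  phys <- cfg$physiology
  cmp <- cfg$compound
  stopifnot(nrow(subject) == 1)
  if (abs(cmp$blood_plasma_ratio - 1) > 1e-8) {
    stop("the circulating compartments assume Rbp = 1", call. = FALSE)
  }

  wf_v <- subject$body_weight / phys$body_weight
  wf_q <- wf_v^0.75
  vol <- lapply(phys$organ_volumes, function(v) v * wf_v)
  flow <- lapply(phys$organ_flows, function(q) q * wf_q)
  co <- sum(unlist(flow))
  hct <- subject$hematocrit

  fu <- scaled_fu(cmp$fu_plasma, subject$albumin, phys$albumin_patient,
                  orientation = phys$ppsf_orientation)

  kp <- kp_rodgers_rowland(cmp$log_p, cmp$pka_base_strong, fu,
                           cmp$blood_plasma_ratio, hct,
                           kp_scale = cfg$distribution$kp_scale)
  kp_vec <- stats::setNames(kp$kp, kp$tissue)

  hep <- hepatic_intrinsic_clearance(cfg)
  hep$clint_L_h <- hep$clint_L_h * subject$m_clint_hep
  cl_gut <- cfg$physiology$gut_cyp3a4_pmol *
    cfg$metabolism$cyp_clint$CYP3A4 * 60 / 1e6 *
    cfg$calibration$hepatic_clint_scale * subject$m_clint_hep
  cl_r <- cfg$metabolism$gfr * 60 / 1000 * fu  # mL/min -> L/h, x fup

  # absorption rate constant from effective permeability in a cylindrical
  # absorbing segment: ka = 2 Peff / r
  peff_cm_s <- cfg$absorption$effective_permeability * 1e-4 * subject$m_peff
  ka <- 2 * peff_cm_s * 3600 / cfg$absorption$intestinal_radius_cm *
    cfg$absorption$surface_amplification
  k_ge <- 1 / (cfg$absorption$gastric_emptying_time / 60)

  # brain sub-compartment volumes
  v_br <- vol$brain
  v_bv <- v_br * phys$brain_fractions$vascular
  v_bvp <- v_bv * (1 - hct)
  v_bvc <- v_bv * hct
  v_is <- v_br * phys$brain_fractions$interstitial
  v_ic <- v_br - v_bv - v_is
  q_br <- flow$brain
  kbrt <- cfg$distribution$k_brt_plasma

  # intracellular partition pinned so the passive-equilibrium total
  # brain:plasma ratio equals K_BRT,p
  kic <- (v_br * kbrt - v_bv - v_is * kbrt * fu) / (v_ic * kbrt * fu)
  stopifnot(kic > 0)

  bt <- cfg$brain_transport
  cl_e <- function(clint, mult) clint * mult * bt$brain_cell_count * 60 / 1e6
  cle_abcb1 <- cl_e(bt$abcb1_clint, subject$m_abcb1)
  cle_bcrp <- cl_e(bt$bcrp_clint, 1)
  ps <- cfg$calibration$brain_ps * subject$m_brain_ps

  parms <- c(
    vol$gut, vol$liver, vol$kidney, vol$muscle, vol$adipose, vol$skin,
    vol$heart, vol$spleen, vol$bone, vol$rest, vol$lung,
    vol$arterial, vol$venous, v_bvp, v_bvc, v_is, v_ic,
    kp_vec[c("gut", "liver", "kidney", "muscle", "adipose", "skin",
             "heart", "spleen", "bone", "rest", "lung")],
    flow$gut, flow$liver_arterial, flow$kidney, flow$muscle, flow$adipose,
    flow$skin, flow$heart, flow$spleen, flow$bone, flow$rest,
    q_br * (1 - hct), q_br * hct, co,
    fu, ka, k_ge, cfg$absorption$lumen_loss_rate,
    cfg$absorption$weibull_t50 / 60, cfg$absorption$weibull_shape,
    cl_r, cl_gut, ps, cle_abcb1, cle_bcrp,
    30,                       # cellular exchange permeability, L/h
    kbrt, kic,
    1,                        # blood-cell:plasma ratio (Rbp = 1)
    50,                       # vascular plasma/cell exchange, L/h
    hep$clint_L_h[match(c("CYP1A2", "CYP2A6", "CYP2C9", "CYP2E1",
                          "CYP3A4", "CYP3A5"), hep$enzyme)],
    log(2) / 36,              # induced-enzyme turnover, 36 h half-life
    rep(0, 9),                # interaction terms, filled per scenario
    0, 0, 1, 0, 0,            # perpetrator PK placeholder
    0, 0,                     # dose counts
    rep(0, 128),              # dose calendars
    0                         # victim dose amount
  )
  parms <- unname(parms)
  stopifnot(length(parms) == 209)

  structure(list(cfg = cfg, subject = subject, parms = parms,
                 fu = fu, kp = kp, volumes = vol, flows = flow,
                 brain = list(v_bvp = v_bvp, v_bvc = v_bvc, v_is = v_is,
                              v_ic = v_ic, v_total = v_br, kic = kic,
                              ps = ps, cle = cle_abcb1 + cle_bcrp)),
            class = "pbpkeo_body_model")
}

#' @export
print.pbpkeo_body_model <- function(x, ...) {
  cat("<pbpkeo_body_model>\n")
  cat("  subject weight:", x$subject$body_weight, "kg, fu(effective):",
      signif(x$fu, 4), "\n")
  cat("  brain PS:", signif(x$brain$ps, 4), "L/h, efflux CL:",
      signif(x$brain$cle, 4), "L/h\n")
  invisible(x)
}

# indices into the parameter vector (1-based, mirror of the C layout)
.pi <- list(
  ki_1a2 = 65, ki_2c9 = 66, ki_3a4 = 67,
  emax_1a2 = 68, ec50_1a2 = 69, emax_2c9 = 70, ec50_2c9 = 71,
  emax_3a4 = 72, ec50_3a4 = 73,
  perp_ka = 74, perp_ke = 75, perp_vf = 76, perp_fu = 77, perp_dose = 78,
  n_dose_o = 79, n_dose_p = 80,
  t_dose_o = 81:144, t_dose_p = 145:208, dose_o = 209
)
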