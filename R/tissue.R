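#' Tissue composition table for partition-coefficient prediction
#'
#' Fractional tissue volumes of extracellular water, intracellular water,
#' neutral lipid and neutral phospholipid, plus acidic phospholipid
#' content, for the reference human. These are the published compositions
#' commonly used with tissue-composition partitioning methods; `rest` is a
#' documented average over poorly perfused residual tissues.
#'
#' @return a tibble, one row per tissue.
#' @export
tissue_composition <- function() {
  tibble::tribble(
    ~tissue,   ~f_ew, ~f_iw, ~f_nl,  ~f_np,  ~ap_mg_g,
    "gut",     0.282, 0.475, 0.0487, 0.0163, 2.41,
    "liver",   0.161, 0.573, 0.0348, 0.0252, 4.56,
    "kidney",  0.273, 0.483, 0.0207, 0.0162, 5.03,
    "muscle",  0.118, 0.630, 0.0238, 0.0072, 1.53,
    "adipose", 0.135, 0.017, 0.8530, 0.0016, 0.40,
    "skin",    0.382, 0.291, 0.0284, 0.0111, 1.32,
    "heart",   0.320, 0.456, 0.0115, 0.0166, 2.25,
    "spleen",  0.207, 0.579, 0.0201, 0.0198, 3.18,
    "bone",    0.100, 0.346, 0.0170, 0.0017, 0.67,
    "rest",    0.250, 0.450, 0.0400, 0.0120, 2.00,
    "lung",    0.336, 0.446, 0.0022, 0.0128, 3.91
  )
}

# blood-cell composition used to back out the acidic-phospholipid
# association constant from the measured blood:plasma ratio
bc_composition <- list(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029,
                       ap_mg_g = 0.5, ph = 7.22)

#' Tissue-to-plasma partition coefficients (moderate-to-strong base)
#'
#' Tissue-composition prediction of total tissue:plasma partition
#' coefficients for a monoprotic base with pKa above intracellular pH. The
#' ionized species associates with tissue acidic phospholipids with an
#' affinity back-calculated from the blood-cell partitioning implied by the
#' measured blood:plasma ratio; the neutral species partitions into neutral
#' lipid and phospholipid (vegetable-oil correlation for adipose). Each Kp
#' is multiplied by the empirical `kp_scale`.
#'
#' @param log_p octanol-water log partition coefficient.
#' @param pka basic dissociation constant (must exceed intracellular pH).
#' @param fu fraction unbound in plasma.
#' @param rbp blood:plasma concentration ratio.
#' @param hct hematocrit.
#' @param kp_scale global scalar applied to every organ Kp.
#' @param composition tissue composition tibble (default packaged values).
#' @return tibble with columns `tissue`, `kpu` (unbound-based) and `kp`
#'   (plasma-based, scaled).
#' @export
kp_rodgers_rowland <- function(log_p, pka, fu, rbp, hct,
                               kp_scale = 1,
                               composition = tissue_composition()) {
  stopifnot(pka > 7, fu > 0, fu <= 1, rbp > 0, hct > 0, hct < 1)
  ph_p <- 7.4; ph_iw <- 7.0
  P <- 10^log_p
  Y <- 10^(pka - ph_p)
  X <- 10^(pka - ph_iw)
  Z <- 10^(pka - bc_composition$ph)

  kpu_bc <- (hct - 1 + rbp) / (hct * fu)
  ka_ap <- (kpu_bc -
              (1 + Z) / (1 + Y) * bc_composition$f_iw -
              (P * bc_composition$f_nl + (0.3 * P + 0.7) *
                 bc_composition$f_np) / (1 + Y)) *
    (1 + Y) / (bc_composition$ap_mg_g * Z)
  if (ka_ap < 0) {
    stop("blood-cell data imply negative acidic-phospholipid affinity",
         call. = FALSE)
  }

  p_adipose <- 10^(1.115 * log_p - 1.35)  # vegetable oil:water
  kpu <- purrr::pmap_dbl(composition, function(tissue, f_ew, f_iw, f_nl,
                                               f_np, ap_mg_g) {
    Pt <- if (tissue == "adipose") p_adipose else P
    f_ew +
      (1 + X) / (1 + Y) * f_iw +
      ka_ap * ap_mg_g * X / (1 + Y) +
      (Pt * f_nl + (0.3 * Pt + 0.7) * f_np) / (1 + Y)
  })
  tibble::tibble(tissue = composition$tissue,
                 kpu = kpu,
                 kp = kpu * fu * kp_scale)
}

#' Weibull dissolution profile
#'
#' Cumulative fraction of an oral dose dissolved at time `t` after gastric
#' release: `F(t) = 1 - exp(-ln(2) * (t / t50)^shape)`, so half the dose is
#' dissolved at `t50` by construction.
#'
#' @param t_min minutes since the dose reached the dissolving compartment.
#' @param t50 dissolution time of 50% of the dose, min.
#' @param shape Weibull shape parameter.
#' @return fraction dissolved in `[0, 1)`.
#' @examples
#' dissolution_fraction(15, 15, 0.92) # 0.5 at t50
#' @export
dissolution_fraction <- function(t_min, t50, shape) {
  stopifnot(all(t_min >= 0), t50 > 0, shape > 0)
  1 - exp(-log(2) * (t_min / t50)^shape)
}
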