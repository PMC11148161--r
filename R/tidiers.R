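#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation into long concentration-time records
#'
#' @param x a `pbpkeo_sim`.
#' @param ... unused.
#' @return tibble `time_h`, `compartment`, `concentration_nmol_per_L`.
#' @export
tidy.pbpkeo_sim <- function(x, ...) {
  keep <- c("plasma_nmol_L", "brain_interstitial_free_nmol_L",
            "brain_total_nmol_L")
  out <- tidyr::pivot_longer(x$profile[, c("time_h", keep)], -"time_h",
                             names_to = "compartment",
                             values_to = "concentration_nmol_per_L")
  out$compartment <- sub("_nmol_L$", "", out$compartment)
  out
}

#' One-row exposure summary of a simulation
#'
#' @param x a `pbpkeo_sim`.
#' @param ... unused.
#' @export
glance.pbpkeo_sim <- function(x, ...) {
  s <- summarize_pk(x)
  s$dose_mg <- x$regimen$dose_mg
  s$interval_h <- x$regimen$interval
  s$brain_ctrough_nmol_L <-
    summarize_pk(x, column = "brain_interstitial_free_nmol_L")$ctrough_nmol_L
  s
}

#' @export
tidy.pbpkeo_eo <- function(x, ...) x$occupancy

#' @export
glance.pbpkeo_eo <- function(x, ...) {
  tidyr::pivot_wider(x$trough[, c("variant", "eo_trough_pct")],
                     names_from = "variant", values_from = "eo_trough_pct",
                     names_prefix = "eo_trough_")
}

#' @export
tidy.pbpkeo_sweep <- function(x, ...) x$curve

#' @export
glance.pbpkeo_sweep <- function(x, ...) {
  tidyr::pivot_wider(x$crossings, names_from = "quantity",
                     values_from = c("threshold", "level_at_crossing"))
}

#' Concentration-time plot of a simulation
#'
#' @param object a `pbpkeo_sim`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pbpkeo_sim <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h,
                                  .data$concentration_nmol_per_L,
                                  colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "concentration (nmol/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Occupancy time-course plot
#'
#' @param object a `pbpkeo_eo`.
#' @param ... unused.
#' @export
autoplot.pbpkeo_eo <- function(object, ...) {
  ggplot2::ggplot(object$occupancy,
                  ggplot2::aes(.data$time_h, .data$occupancy_pct,
                               colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 80, linetype = 2) +
    ggplot2::labs(x = "time (h)", y = "EGFR occupancy (%)",
                  colour = "variant") +
    ggplot2::theme_minimal()
}

#' Sweep curve plot with thresholds
#'
#' @param object a `pbpkeo_sweep`.
#' @param ... unused.
#' @export
autoplot.pbpkeo_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curve, -c("factor", "level"))
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste(object$factor, "level"), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
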