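#' Unit helpers
#'
#' Concentrations are carried internally in micromolar and reported
#' externally in nmol/L; amounts are micromoles; doses enter in mg. All
#' mass-to-mole conversion goes through these two helpers so the molecular
#' weight is applied in exactly one place.
#'
#' @param mg dose in milligrams.
#' @param mw molecular weight in g/mol.
#' @return `mg_to_umol()`: micromoles; `umolL_to_nmolL()` /
#'   `nmolL_to_umolL()`: converted concentrations.
#' @examples
#' mg_to_umol(80, 499.6) # an 80 mg oral dose in umol
#' @export
mg_to_umol <- function(mg, mw) 1000 * mg / mw

#' @rdname mg_to_umol
#' @param x concentration value(s).
#' @export
umolL_to_nmolL <- function(x) 1000 * x

#' @rdname mg_to_umol
#' @export
nmolL_to_umolL <- function(x) x / 1000
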