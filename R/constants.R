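#' Physical constants and unit conversions
#'
#' All quantities inside the package are stored in Hartree atomic units
#' (lengths in bohr, energies in hartree, charges in units of e). Files use
#' the conventions of the formats they serve: XYZ coordinates are in
#' angstrom, spectra are written in eV. This table is the single source of
#' conversion factors; every conversion in the package goes through
#' [ang_to_bohr()], [bohr_to_ang()], [hartree_to_ev()] or [ev_to_hartree()].
#'
#' @format A named list with elements `bohr_ang` (bohr in angstrom, CODATA
#'   2018) and `hartree_ev` (hartree in eV, CODATA 2018).
#' @export
units_au <- list(
  bohr_ang   = 0.529177210903,
  hartree_ev = 27.211386245988
)

#' @rdname units_au
#' @param x numeric vector of lengths in angstrom
#' @return numeric vector in bohr
#' @export
ang_to_bohr <- function(x) x / units_au$bohr_ang

#' @rdname units_au
#' @param x numeric vector of lengths in bohr
#' @export
bohr_to_ang <- function(x) x * units_au$bohr_ang

#' @rdname units_au
#' @param x numeric vector of energies in hartree
#' @export
hartree_to_ev <- function(x) x * units_au$hartree_ev

#' @rdname units_au
#' @param x numeric vector of energies in eV
#' @export
ev_to_hartree <- function(x) x / units_au$hartree_ev
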