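# Physical constants. The legacy conversion factors of the semiempirical
# literature are used deliberately: published MNDO/AM1 heats of formation were
# obtained with these values, and reproducing them requires using the same
# constants rather than modern CODATA ones.
EV_PER_HARTREE <- 27.21
KCAL_PER_EV <- 23.061
ANGSTROM_PER_BOHR <- 0.529167
BOHR_PER_ANGSTROM <- 1 / ANGSTROM_PER_BOHR

#' Unit conversion helpers
#'
#' Conversions between the unit systems used internally: coordinates are
#' handled in Angstrom at the user interface and in bohr inside the integral
#' code; matrix elements and energy components are in eV; heats of formation
#' in kcal/mol. The legacy conversion constants of the semiempirical
#' literature (1 hartree = 27.21 eV, 1 eV = 23.061 kcal/mol, a0 = 0.529167 A)
#' are used so that published MNDO/AM1 results are reproduced exactly.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @keywords internal
#' @name units
NULL

#' @rdname units
angstrom_to_bohr <- function(x) x * BOHR_PER_ANGSTROM

#' @rdname units
bohr_to_angstrom <- function(x) x * ANGSTROM_PER_BOHR

#' @rdname units
hartree_to_ev <- function(x) x * EV_PER_HARTREE

#' @rdname units
ev_to_kcal <- function(x) x * KCAL_PER_EV
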