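#' Unit conventions and physical constants
#'
#' All coordinates are in angstrom (A), times in nanoseconds (ns), forces in
#' piconewton (pN) and energies in kcal/mol throughout the package.  This
#' module is the single owner of the conversion constants between those
#' conventions, so no other file hard-codes a unit factor.
#'
#' @section Constants:
#' \describe{
#'   \item{`coulomb_kcal`}{Electrostatic constant, 332.0636 kcal A / (mol e^2),
#'     so that `q1*q2*coulomb_kcal/r` is an energy in kcal/mol for charges in
#'     elementary units and `r` in A.}
#'   \item{`kB_kcal`}{Boltzmann constant, 0.0019872 kcal/(mol K).}
#'   \item{`pNA_kcal`}{1 pN * A expressed in kcal/mol: 0.0143836.  Divides
#'     forces in kcal/(mol A) to give pN and vice versa.}
#' }
#'
#' @return `rc_constants()` returns a named list of the constants above.
#' @examples
#' rc_constants()$coulomb_kcal
#' force_pN_to_kcal(25)     # 25 pN as kcal/(mol A)
#' spring_pN_nm_to_kcal(34.74)
#' @export
rc_constants <- function() {
  list(
    coulomb_kcal = 332.0636,   # kcal A mol^-1 e^-2
    kB_kcal      = 0.0019872,  # kcal mol^-1 K^-1
    pNA_kcal     = 0.0143836   # kcal/mol per pN*A
  )
}

#' @rdname rc_constants
#' @param force_pN force in piconewton.
#' @export
force_pN_to_kcal <- function(force_pN) force_pN * rc_constants()$pNA_kcal

#' @rdname rc_constants
#' @param force_kcal force in kcal/(mol A).
#' @export
force_kcal_to_pN <- function(force_kcal) force_kcal / rc_constants()$pNA_kcal

#' @rdname rc_constants
#' @param k_pN_nm spring stiffness in pN/nm.
#' @export
spring_pN_nm_to_kcal <- function(k_pN_nm) {
  # pN/nm -> pN/A -> kcal/(mol A^2)
  k_pN_nm * 0.1 * rc_constants()$pNA_kcal
}

#' @rdname rc_constants
#' @param temperature_K absolute temperature in kelvin.
#' @export
kBT_kcal <- function(temperature_K) rc_constants()$kB_kcal * temperature_K
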