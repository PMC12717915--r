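#' Physical constants used throughout the package
#'
#' `hc_ev_nm` is the product of Planck's constant and the speed of light in
#' eV.nm, `cm1_to_ev` converts wavenumbers to eV, and `kb_ev_k` is the
#' Boltzmann constant in eV/K. All three are CODATA-consistent and mutually
#' consistent (`cm1_to_ev == hc_ev_nm * 1e-7`).
#'
#' @name constants
#' @keywords internal
NULL

hc_ev_nm <- 1239.8420
cm1_to_ev <- 1.239842e-4
kb_ev_k <- 8.617333262e-5

#' Convert wavelength to photon energy
#'
#' Photon energy in eV for a vacuum wavelength in nm, using
#' \eqn{E = hc/\lambda} with \eqn{hc = 1239.8420} eV.nm, the convention that
#' pairs 678 nm with 1.83 eV and 612 nm with 2.03 eV at two-decimal
#' reporting precision.
#'
#' @param wavelength_nm Wavelength(s) in nm; must be positive.
#' @return Photon energy in eV.
#' @seealso [ev_to_nm()], [energy_shift_mev()]
#' @examples
#' nm_to_ev(678) # 1.8287...
#' @export
nm_to_ev <- function(wavelength_nm) {
  if (!is.numeric(wavelength_nm) || any(!is.finite(wavelength_nm)) ||
      any(wavelength_nm <= 0)) {
    stop("wavelength must be finite and positive (nm)", call. = FALSE)
  }
  hc_ev_nm / wavelength_nm
}

#' Convert photon energy to wavelength
#'
#' Inverse of [nm_to_ev()]: \eqn{\lambda = hc/E}.
#'
#' @param energy_ev Photon energy in eV; must be positive.
#' @return Wavelength in nm.
#' @export
ev_to_nm <- function(energy_ev) {
  if (!is.numeric(energy_ev) || any(!is.finite(energy_ev)) ||
      any(energy_ev <= 0)) {
    stop("energy must be finite and positive (eV)", call. = FALSE)
  }
  hc_ev_nm / energy_ev
}

#' Energy shift between two wavelengths, in meV
#'
#' Returns \eqn{(hc/\lambda_2 - hc/\lambda_1) \cdot 1000}: positive when
#' `lambda2 < lambda1`, i.e. a blue shift. Reproduces shift arithmetic such
#' as 678 nm to 664 nm = 39 meV.
#'
#' @param lambda1_nm Reference wavelength, nm.
#' @param lambda2_nm Shifted wavelength, nm.
#' @return Energy shift in meV (positive = blue shift).
#' @export
energy_shift_mev <- function(lambda1_nm, lambda2_nm) {
  (nm_to_ev(lambda2_nm) - nm_to_ev(lambda1_nm)) * 1000
}

#' Round half away from zero
#'
#' Fixed-tie rounding for reporting: eV values are quoted to 2 decimals and
#' meV shifts to integers, and exact .5 ties go away from zero rather than
#' to even (which base [round()] uses).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
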