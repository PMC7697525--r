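# Internal unit system: lengths in nm, energies in eV, masses in amu,
# angles in rad.  A single audited constant converts squared angular
# frequencies from the internal eV/(amu nm^2) units to SI rad^2 s^-2.

# CODATA: 1 eV = 1.602176634e-19 J (exact); 1 amu = 1.66053906660e-27 kg
.EV_J    <- 1.602176634e-19
.AMU_KG  <- 1.66053906660e-27

# eV / (amu nm^2) -> s^-2
.OMEGA2_SI <- .EV_J / (.AMU_KG * 1e-18)

# hbar^2/m_e in eV nm^2 (Slater-Koster prefactor)
.HBAR2_OVER_ME <- 0.0762

#' Convert an angular frequency to a linear frequency in THz
#'
#' @param omega Angular frequency in rad/s (vectorised, non-negative).
#' @return Frequency \eqn{\nu = \omega / (2\pi \times 10^{12})} in THz.
#' @seealso [thz_to_angular_frequency()], [frequency_to_period()]
#' @examples
#' angular_frequency_to_thz(2 * pi * 1e12)  # 1 THz
#' @export
angular_frequency_to_thz <- function(omega) {
  stopifnot(all(omega >= 0))
  omega / (2 * pi * 1e12)
}

#' Convert a linear frequency in THz to an angular frequency in rad/s
#'
#' Inverse of [angular_frequency_to_thz()].
#'
#' @param nu Frequency in THz.
#' @return Angular frequency in rad/s.
#' @export
thz_to_angular_frequency <- function(nu) {
  stopifnot(all(nu >= 0))
  nu * 2 * pi * 1e12
}

#' Oscillation period in ps from a frequency in THz
#'
#' @param nu Frequency in THz (> 0).
#' @return Period \eqn{\tau = 1/\nu} in ps.
#' @export
frequency_to_period <- function(nu) {
  stopifnot(all(nu > 0))
  1 / nu
}
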