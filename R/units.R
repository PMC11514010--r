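# Physical constants used throughout. All internal rate math is done in
# cm^-1 and seconds; unit conversion happens only at module boundaries.
EV_TO_WAVENUMBER <- 8065.544     # cm^-1 per eV
EV_NM_PRODUCT <- 1239.842        # eV * nm
KB_WAVENUMBER <- 0.695035        # Boltzmann constant, cm^-1 per K
SPEED_OF_LIGHT_CM <- 2.99792458e10  # cm / s
HARTREE_WAVENUMBER <- 219474.6313   # cm^-1 per hartree (a.u. of energy)
STRICKLER_BERG_CONST <- 1.499    # cm^-2 s, denominator of k_r = nu^2 f / 1.499

#' Convert photon energy from electronvolt to wavenumber
#'
#' @param e Energy in eV. Vectorised.
#' @return Wavenumber in cm^-1 (`e * 8065.544`).
#' @examples
#' ev_to_wavenumber(1.67)
#' @export
ev_to_wavenumber <- function(e) {
  if (!is.numeric(e)) abort("`e` must be numeric.")
  e * EV_TO_WAVENUMBER
}

#' Convert photon energy from electronvolt to wavelength
#'
#' @param e Energy in eV, strictly positive. Vectorised.
#' @return Wavelength in nm (`1239.842 / e`). The map is an involution when
#'   the result is re-read as an energy: `ev_to_nm(ev_to_nm(x)) == x`.
#' @examples
#' ev_to_nm(2.36) # ~525 nm, green emission
#' @export
ev_to_nm <- function(e) {
  if (!is.numeric(e)) abort("`e` must be numeric.")
  if (any(!is.finite(e)) || any(e <= 0)) {
    abort("`e` must be finite and > 0 to convert to wavelength.")
  }
  EV_NM_PRODUCT / e
}

#' Convert wavenumber to electronvolt
#'
#' @param w Wavenumber in cm^-1. Vectorised.
#' @return Energy in eV.
#' @export
wavenumber_to_ev <- function(w) {
  if (!is.numeric(w)) abort("`w` must be numeric.")
  w / EV_TO_WAVENUMBER
}

# Round half away from zero (Table-style percent rounding; base round()
# is half-even and would print 22.5 -> 22).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
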