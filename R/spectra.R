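# Spectral rendering -----------------------------------------------------
#
# TD-DFT gives stick spectra: a handful of (excitation energy,
# oscillator strength) pairs. For comparison with measured absorption
# and fluorescence curves the sticks are broadened with unit-area
# Gaussian or Lorentzian line shapes on an energy grid. Broadening is
# done on the energy axis; displaying in nm or cm^-1 relabels the axis
# pointwise without Jacobian reweighting (the common TD-DFT plotting
# convention).

#' Build a stick spectrum
#'
#' @param energy Line positions in eV, > 0.
#' @param weight Line weights (oscillator strengths or intensities), >= 0.
#' @param kind `"absorption"` or `"emission"`.
#' @return A tibble of class `stick_spectrum` with columns `energy`,
#'   `weight` and attribute `kind`. May have zero rows.
#' @export
stick_spectrum <- function(energy, weight, kind = c("absorption", "emission")) {
  kind <- match.arg(kind)
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    abort("stick energies must be finite and > 0 eV.")
  }
  if (any(!is.finite(weight)) || any(weight < 0)) {
    abort("stick weights must be finite and >= 0.")
  }
  s <- tibble(energy = as.numeric(energy), weight = as.numeric(weight))
  structure(s, kind = kind, class = c("stick_spectrum", class(s)))
}

new_spectrum <- function(grid, intensity, kind, axis_unit = "eV") {
  sp <- tibble(axis = grid, intensity = intensity)
  structure(sp, kind = kind, axis_unit = axis_unit,
            class = c("spectrum", class(sp)))
}

#' Broaden a stick spectrum onto an energy grid
#'
#' Each line becomes a unit-area Gaussian or Lorentzian of the given
#' full width at half maximum, scaled by its weight; the curve is the
#' sum. Gaussian broadening conserves total weight (integral of the
#' curve equals the summed weights) to the grid-truncation error; the
#' Lorentzian's heavy tails lose a reported fraction outside the grid.
#'
#' @param s A [stick_spectrum()].
#' @param fwhm Full width at half maximum in eV, > 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param grid Either `NULL` (default: 2000 points spanning the lines
#'   +/- 5 fwhm) or a strictly increasing numeric vector of energies in
#'   eV. The grid must cover every line +/- 3 fwhm.
#' @param n_points Grid size when `grid` is `NULL`.
#' @return A `spectrum` tibble (`axis` in eV, `intensity`), attributes
#'   `kind` and `axis_unit`.
#' @examples
#' s <- stick_spectrum(2.36, 0.87)
#' sp <- broaden(s, fwhm = 0.15)
#' sp$axis[which.max(sp$intensity)] # peak at the line
#' @export
broaden <- function(s, fwhm = 0.15, shape = c("gaussian", "lorentzian"),
                    grid = NULL, n_points = 2000L) {
  shape <- match.arg(shape)
  if (!is.finite(fwhm) || fwhm <= 0) abort("`fwhm` must be > 0 eV.")
  kind <- attr(s, "kind") %||% "absorption"
  if (is.null(grid)) {
    if (nrow(s) == 0L) {
      grid <- seq(0.5, 5, length.out = n_points)
    } else {
      grid <- seq(max(min(s$energy) - 5 * fwhm, 1e-6),
                  max(s$energy) + 5 * fwhm, length.out = n_points)
    }
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing.")
  }
  if (nrow(s) > 0L) {
    uncovered <- s$energy - 3 * fwhm < min(grid) | s$energy + 3 * fwhm > max(grid)
    if (any(uncovered)) {
      abort(paste0(
        "grid does not cover line(s) at ",
        toString(format(s$energy[uncovered], digits = 4)),
        " eV (+/- 3 fwhm)."
      ))
    }
  }
  intensity <- numeric(length(grid))
  if (nrow(s) > 0L) {
    if (shape == "gaussian") {
      sd <- fwhm / (2 * sqrt(2 * log(2)))
      for (i in seq_len(nrow(s))) {
        intensity <- intensity + s$weight[i] * dnorm(grid, s$energy[i], sd)
      }
    } else {
      hwhm <- fwhm / 2
      for (i in seq_len(nrow(s))) {
        intensity <- intensity +
          s$weight[i] * hwhm / (pi * ((grid - s$energy[i])^2 + hwhm^2))
      }
    }
  }
  new_spectrum(grid, intensity, kind = kind, axis_unit = "eV")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Integrated intensity of a spectrum
#'
#' Trapezoidal integral over the axis, in axis units.
#'
#' @param sp A `spectrum`.
#' @return A single number.
#' @export
spectrum_area <- function(sp) {
  ord <- order(sp$axis)
  trapz(sp$axis[ord], sp$intensity[ord])
}

#' Relabel the spectral axis
#'
#' Pointwise unit conversion of the axis (eV <-> nm <-> cm^-1);
#' intensities are carried over unchanged (no Jacobian reweighting), so
#' peak positions map exactly through the unit map. The nm axis is
#' stored in decreasing-energy order (increasing wavelength).
#'
#' @param sp A `spectrum`.
#' @param to Target unit: `"eV"`, `"nm"` or `"cm-1"`.
#' @return A `spectrum` on the new axis.
#' @export
convert_axis <- function(sp, to = c("eV", "nm", "cm-1")) {
  to <- match.arg(to)
  from <- attr(sp, "axis_unit")
  if (identical(from, to)) return(sp)
  ev <- switch(from,
    "eV" = sp$axis,
    "nm" = EV_NM_PRODUCT / sp$axis,
    "cm-1" = wavenumber_to_ev(sp$axis)
  )
  new_axis <- switch(to,
    "eV" = ev,
    "nm" = ev_to_nm(ev),
    "cm-1" = ev_to_wavenumber(ev)
  )
  ord <- order(new_axis)
  new_spectrum(new_axis[ord], sp$intensity[ord],
               kind = attr(sp, "kind"), axis_unit = to)
}

#' Normalize a spectrum
#'
#' @param sp A non-zero `spectrum`.
#' @param mode `"max"` (peak scaled to 1) or `"area"` (trapezoidal
#'   integral scaled to 1). Idempotent.
#' @return The rescaled `spectrum`.
#' @export
normalize_spectrum <- function(sp, mode = c("max", "area")) {
  mode <- match.arg(mode)
  denom <- switch(mode, max = max(sp$intensity), area = spectrum_area(sp))
  if (!is.finite(denom) || denom <= 0) {
    abort("cannot normalize a zero (or negative-area) spectrum.")
  }
  new_spectrum(sp$axis, sp$intensity / denom,
               kind = attr(sp, "kind"), axis_unit = attr(sp, "axis_unit"))
}

#' Plot a broadened spectrum
#'
#' @param object A `spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum
#' @export
autoplot.spectrum <- function(object, ...) {
  unit_lab <- switch(attr(object, "axis_unit"),
    "eV" = "Energy (eV)", "nm" = "Wavelength (nm)",
    "cm-1" = expression(Wavenumber ~ (cm^-1))
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$axis, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = unit_lab, y = "Intensity",
                  title = paste0("Broadened ", attr(object, "kind"),
                                 " spectrum")) +
    ggplot2::theme_minimal()
}
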