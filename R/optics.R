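# Analytic calculators for the instrument-design relations: Raman
# cross-section wavelength scaling, telescope magnification, Gaussian light
# sheet profile and divergence, AOTF tuning, and the Rayleigh resolution
# criterion. Pure functions; no hardware control.

#' Raman scattering cross-section ratio of two excitation wavelengths
#'
#' The Raman cross-section scales as `1/lambda^4`, so the ratio by which
#' scattering at `lambda1` exceeds scattering at `lambda2` (all else equal)
#' is `(lambda2 / lambda1)^4`.
#'
#' @param lambda1_nm,lambda2_nm excitation wavelengths in nm.
#' @return dimensionless ratio.
#' @export
cross_section_ratio <- function(lambda1_nm, lambda2_nm) {
  if (lambda1_nm <= 0 || lambda2_nm <= 0) stop("wavelengths must be positive")
  (lambda2_nm / lambda1_nm)^4
}

#' Keplerian telescope magnification
#'
#' Default convention is the instrument description's printed form
#' `M = f1 / f2` (input over output focal length);
#' `convention = "f2_over_f1"` gives the textbook reciprocal.
#'
#' @param f1_mm,f2_mm focal lengths of input and output lenses, mm.
#' @param convention `"f1_over_f2"` (default) or `"f2_over_f1"`.
#' @return magnification factor.
#' @export
telescope_magnification <- function(f1_mm, f2_mm,
                                    convention = c("f1_over_f2",
                                                   "f2_over_f1")) {
  if (f1_mm <= 0 || f2_mm <= 0) stop("focal lengths must be positive")
  convention <- match.arg(convention)
  if (convention == "f1_over_f2") f1_mm / f2_mm else f2_mm / f1_mm
}

#' Gaussian light-sheet intensity profile
#'
#' `I(x, z) = I0 * exp(-2 x^2 / w0^2) * sinc^2(z / zR)` with
#' `sinc(t) = sin(pi t) / (pi t)` (and 1 at t = 0): Gaussian across the
#' sheet (transverse x), sinc-squared envelope along propagation (z).
#'
#' @param x_um transverse offset, um.
#' @param z_um axial offset along propagation, um.
#' @param I0 peak intensity (arbitrary units).
#' @param w0_um beam waist radius, um.
#' @param zR_um Rayleigh range, um.
#' @return relative intensity.
#' @export
sheet_intensity <- function(x_um, z_um, I0 = 1, w0_um = 8, zR_um = 100) {
  if (w0_um <= 0 || zR_um <= 0) stop("w0 and zR must be positive")
  t <- z_um / zR_um
  s <- ifelse(t == 0, 1, sin(pi * t) / (pi * t))
  I0 * exp(-2 * x_um^2 / w0_um^2) * s^2
}

#' Gaussian beam width at axial distance z
#'
#' `w(z) = w0 * sqrt(1 + (z / zR)^2)`.
#'
#' @param z_um axial distance, um.
#' @param w0_um beam waist radius, um.
#' @param zR_um Rayleigh range, um.
#' @return beam width in um.
#' @export
beam_width <- function(z_um, w0_um = 8, zR_um = 100) {
  if (w0_um <= 0 || zR_um <= 0) stop("w0 and zR must be positive")
  w0_um * sqrt(1 + (z_um / zR_um)^2)
}

#' AOTF passband center wavelength
#'
#' `lambda_c = v * n / f`: acoustic velocity times refractive index over
#' the applied acoustic frequency, in consistent units (e.g. v in m/s and
#' f in MHz gives lambda_c in um).
#'
#' @param acoustic_velocity `v`.
#' @param refractive_index `n`.
#' @param acoustic_frequency `f`, > 0.
#' @return center wavelength in units of `v / f`.
#' @export
aotf_center_wavelength <- function(acoustic_velocity, refractive_index,
                                   acoustic_frequency) {
  if (acoustic_frequency <= 0) stop("acoustic frequency must be positive")
  acoustic_velocity * refractive_index / acoustic_frequency
}

#' Rayleigh-criterion spatial resolution
#'
#' `dr = 0.61 * lambda / NA` with the detection wavelength `lambda`.
#'
#' @param lambda_nm detection wavelength, nm.
#' @param NA_ numerical aperture, > 0.
#' @return resolution in nm.
#' @export
rayleigh_resolution <- function(lambda_nm, NA_) {
  if (any(NA_ <= 0)) stop("NA must be positive")
  0.61 * lambda_nm / NA_
}

#' Laser presets of the two-laser platform
#'
#' @return data.frame with the two excitation lines, their power ranges and
#'   their relative Raman cross-section (normalized to the 660 nm line).
#' @export
laser_presets <- function() {
  data.frame(wavelength_nm = c(532, 660),
             power_max_mw = c(2000, 130),
             cross_section_vs_660 = c(cross_section_ratio(532, 660), 1),
             stringsAsFactors = FALSE)
}

#' Print an optics parameter report
#'
#' @param lambda_nm excitation wavelength, nm.
#' @param NA_ detection numerical aperture.
#' @param f1_mm,f2_mm telescope focal lengths, mm.
#' @param w0_um,zR_um beam waist and Rayleigh range, um.
#' @return the report lines, invisibly.
#' @export
optics_report <- function(lambda_nm = 532, NA_ = 1.2, f1_mm = 25,
                          f2_mm = 50, w0_um = 8, zR_um = 100) {
  lines <- c(
    sprintf("excitation: %g nm", lambda_nm),
    sprintf("telescope magnification (f1/f2): %.3g",
            telescope_magnification(f1_mm, f2_mm)),
    sprintf("beam waist w0: %g um; width at zR: %.3g um", w0_um,
            beam_width(zR_um, w0_um, zR_um)),
    sprintf("Rayleigh resolution at NA %.2f: %.1f nm", NA_,
            rayleigh_resolution(lambda_nm, NA_)),
    sprintf("Raman cross-section vs 660 nm: %.3g",
            cross_section_ratio(lambda_nm, 660)))
  cat(lines, sep = "\n")
  invisible(lines)
}
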