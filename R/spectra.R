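# Raman spectral processing: iterative Savitzky-Golay baseline estimation
# (lower envelope of the fluorescence background), peak quantification,
# band assignment against the C-H stretching band table, and Raman-shift
# bookkeeping for the instrument's excitation/detection presets.

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoother: each point is replaced by the
#' value at the center of a polynomial of order `polyorder` fitted to its
#' `window`-point neighborhood. Edges use reflect padding.
#'
#' @param y numeric vector.
#' @param window odd window length, `> polyorder`, `< length(y)`.
#' @param polyorder polynomial order (default 2).
#' @return smoothed vector, same length. The `window %/% 2` points at each
#'   end are taken from polynomials fitted to the first/last full window,
#'   so polynomial signals (ramps in particular) are reproduced exactly at
#'   the boundaries.
#' @export
savitzky_golay <- function(y, window = 11, polyorder = 2) {
  if (window %% 2 == 0 || window <= polyorder)
    stop("window must be odd and > polyorder")
  n <- length(y)
  if (window >= n) stop("window must be shorter than the signal")
  m <- (window - 1) / 2
  A <- outer(-m:m, 0:polyorder, "^")
  # convolution coefficients = center row of the least-squares hat matrix
  h <- solve(crossprod(A), t(A))[1, ]
  out <- as.numeric(stats::filter(y, rev(h), sides = 2))
  # edges: evaluate the polynomial fitted to the first/last full window
  Af <- outer(0:(window - 1), 0:polyorder, "^")
  cf_head <- qr.solve(Af, y[seq_len(window)])
  out[seq_len(m)] <- drop(Af[seq_len(m), , drop = FALSE] %*% cf_head)
  cf_tail <- qr.solve(Af, y[(n - window + 1):n])
  out[(n - m + 1):n] <- drop(Af[(m + 2):window, , drop = FALSE] %*% cf_tail)
  out
}

#' Baseline correction by iterative Savitzky-Golay lower envelope
#'
#' Repeatedly smooths the running baseline estimate and clamps it to the
#' pointwise minimum of the previous estimate, so peaks are progressively
#' shaved off while the slowly varying fluorescence background is kept —
#' the estimate converges to a smooth lower envelope of the spectrum.
#' `corrected = original - baseline`.
#'
#' @param s a [spectrum()].
#' @param window odd Savitzky-Golay window in points (default 101, wide
#'   against the 20-40 1/cm Raman bands on a 1 1/cm grid). Features wider
#'   than roughly half the window are treated as background and absorbed
#'   into the baseline; widen the window to preserve broad envelopes.
#' @param polyorder polynomial order (default 2).
#' @param iterations maximum number of smooth-and-clamp passes; the loop
#'   exits early once the estimate stops moving (relative change below
#'   `tol`), which it does when the envelope has bridged under every peak.
#' @param tol relative convergence tolerance on the baseline update.
#' @return list with `corrected` and `baseline` (both [spectrum()]s).
#' @export
baseline_correct <- function(s, window = 101, polyorder = 2,
                             iterations = 1000, tol = 1e-8) {
  stopifnot(inherits(s, "spectrum"))
  if (window >= length(s$intensity))
    stop("window must be shorter than the spectrum")
  b <- s$intensity
  scale <- max(abs(b), 1e-12)
  for (i in seq_len(iterations)) {
    b2 <- pmin(b, savitzky_golay(b, window, polyorder))
    if (max(abs(b2 - b)) < tol * scale) { b <- b2; break }
    b <- b2
  }
  list(corrected = spectrum(s$wavenumbers, s$intensity - b,
                            excitation_nm = s$excitation_nm,
                            bands = s$bands),
       baseline = spectrum(s$wavenumbers, b,
                           excitation_nm = s$excitation_nm))
}

band_window <- function(s, band) {
  sel <- s$wavenumbers >= band[1] & s$wavenumbers <= band[2]
  if (!any(sel)) stop("band span [", band[1], ", ", band[2],
                      "] contains no samples")
  sel
}

#' Peak intensity ratio between two bands
#'
#' Ratio of the maximum intensity inside `band_a` to that inside `band_b`
#' (on a baseline-corrected spectrum); `mode = "integral"` uses trapezoidal
#' band areas instead of maxima.
#'
#' @param s a baseline-corrected [spectrum()].
#' @param band_a,band_b `c(low, high)` in 1/cm.
#' @param mode `"max"` (default) or `"integral"`.
#' @return the ratio (dimensionless; scale-invariant).
#' @export
peak_ratio <- function(s, band_a, band_b, mode = c("max", "integral")) {
  stopifnot(inherits(s, "spectrum"))
  mode <- match.arg(mode)
  va <- band_window(s, band_a); vb <- band_window(s, band_b)
  stat <- function(sel) {
    if (mode == "max") max(s$intensity[sel])
    else {
      w <- s$wavenumbers[sel]; y <- s$intensity[sel]
      sum(diff(w) * (y[-1] + y[-length(y)]) / 2)
    }
  }
  stat(va) / stat(vb)
}

#' The C-H stretching band assignment table
#'
#' The vibrational-mode windows used for peak assignment: the broad C-H
#' stretch envelope, the CH2 asymmetric stretch and the CH3 stretch.
#'
#' @return data.frame with columns `low`, `high` (1/cm) and `mode`; read
#'   from the band table shipped in `extdata/band_table.csv`.
#' @export
band_table <- function() {
  read.csv(system.file("extdata", "band_table.csv", package = "lsraman",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Assign spectral peaks to vibrational bands
#'
#' For each band window, locates the intensity argmax of the (baseline-
#' corrected) spectrum within the window; maxima below `noise_floor` are
#' flagged absent.
#'
#' @param s a baseline-corrected [spectrum()].
#' @param table a band table as from [band_table()].
#' @param noise_floor minimum intensity to count as a detected peak.
#' @return data.frame with `mode`, `low`, `high`, `peak_position`,
#'   `intensity`, `present`.
#' @export
assign_bands <- function(s, table = band_table(), noise_floor = 0) {
  stopifnot(inherits(s, "spectrum"))
  out <- table
  out$peak_position <- NA_real_
  out$intensity <- NA_real_
  out$present <- FALSE
  for (i in seq_len(nrow(table))) {
    sel <- s$wavenumbers >= table$low[i] & s$wavenumbers <= table$high[i]
    if (!any(sel)) next
    w <- s$wavenumbers[sel]; y <- s$intensity[sel]
    k <- which.max(y)
    out$peak_position[i] <- w[k]
    out$intensity[i] <- y[k]
    out$present[i] <- y[k] > noise_floor
  }
  out
}

#' Raman shift of a detected wavelength
#'
#' `10^7 * (1/excitation_nm - 1/detected_nm)` in 1/cm. Stokes shifts
#' (detected red of the excitation) are positive; anti-Stokes values are
#' returned negative with a warning.
#'
#' @param excitation_nm excitation wavelength, nm.
#' @param detected_nm detected wavelength, nm.
#' @return Raman shift in 1/cm.
#' @export
raman_shift <- function(excitation_nm, detected_nm) {
  if (excitation_nm <= 0 || detected_nm <= 0)
    stop("wavelengths must be positive")
  shift <- 1e7 * (1 / excitation_nm - 1 / detected_nm)
  if (shift < 0) warning("anti-Stokes shift (detected blue of excitation)")
  shift
}

#' Instrument modality presets
#'
#' Excitation/detection bookkeeping of the two-laser platform: optical
#' power, exposure, AOTF setting and detected wavelength per modality.
#' Useful for config validation and for checking that the Raman presets
#' land in the C-H stretching region.
#'
#' @return data.frame of presets, read from `extdata/modality_presets.csv`.
#' @export
modality_presets <- function() {
  read.csv(system.file("extdata", "modality_presets.csv",
                       package = "lsraman", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Write / read a spectrum as two-column CSV
#' @param s a [spectrum()].
#' @param path CSV path.
#' @return `path` invisibly (write) or a [spectrum()] (read).
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  write.csv(data.frame(wavenumber = s$wavenumbers,
                       intensity = s$intensity), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @param excitation_nm excitation wavelength to attach on read.
#' @export
read_spectrum <- function(path, excitation_nm = 532) {
  d <- read.csv(path)
  spectrum(d$wavenumber, d$intensity, excitation_nm = excitation_nm)
}
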