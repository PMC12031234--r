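#' @useDynLib lsraman, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif median sd setNames
#' @importFrom utils write.csv read.csv
NULL

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Construct a single-channel image slice
#'
#' The basic 2D container of the package: a numeric matrix of intensities
#' plus the physical pixel pitch and a record of whether the values are
#' unit-normalized (in `[0, 1]`, the working range of the whole pipeline —
#' the denoiser's sigmoid output lives there).
#'
#' @param pixels numeric matrix (rows = image rows).
#' @param pixel_pitch physical pixel size at the sample, in micrometres.
#' @param bit_depth `"8"`, `"16"` or `"float"`; records the source container.
#' @param normalized logical; `TRUE` asserts all values lie in `[0, 1]`.
#' @return an `image_slice` object.
#' @export
image_slice <- function(pixels, pixel_pitch = 6.5, bit_depth = "float",
                        normalized = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  bit_depth <- match.arg(as.character(bit_depth), c("8", "16", "float"))
  if (normalized && length(pixels) &&
      (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9))
    stop("normalized slice must have values in [0, 1]")
  structure(
    list(pixels = pixels, pixel_pitch = pixel_pitch,
         bit_depth = bit_depth, normalized = isTRUE(normalized)),
    class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice> %d x %d px, pitch %.3g um, %s-bit, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch, x$bit_depth,
              if (x$normalized) "normalized [0,1]" else "raw"))
  invisible(x)
}

#' @export
dim.image_slice <- function(x) dim(x$pixels)

as_slice_like <- function(template, pixels, normalized = template$normalized) {
  image_slice(pixels, pixel_pitch = template$pixel_pitch,
              bit_depth = template$bit_depth, normalized = normalized)
}

#' Construct a Z-stack of image slices
#'
#' An ordered axial series of equally shaped [image_slice()] objects with a
#' constant Z spacing (10 um on the instrument this package models).
#'
#' @param slices list of `image_slice`, ascending Z, all the same shape and
#'   normalization state.
#' @param z_step axial spacing in micrometres; must be positive.
#' @return an `image_stack` object.
#' @export
image_stack <- function(slices, z_step = 10) {
  if (!length(slices)) stop("stack needs at least one slice")
  if (!all(vapply(slices, inherits, logical(1), "image_slice")))
    stop("all elements must be image_slice objects")
  d0 <- dim(slices[[1]]$pixels)
  n0 <- slices[[1]]$normalized
  for (s in slices) {
    if (!identical(dim(s$pixels), d0)) stop("all slices must share one shape")
    if (!identical(s$normalized, n0))
      stop("all slices must share one normalization state")
  }
  if (!is.numeric(z_step) || z_step <= 0) stop("z_step must be > 0")
  structure(list(slices = slices, z_step = z_step), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  cat(sprintf("<image_stack> %d slices of %d x %d px, z-step %.3g um\n",
              length(x$slices), d[1], d[2], x$z_step))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$slices)

#' Number of slices in a stack
#' @param stack an `image_stack`.
#' @return integer slice count.
#' @export
n_slices <- function(stack) length(stack$slices)

#' Convert a stack to a 3D array (z, row, col)
#' @param stack an `image_stack`.
#' @return numeric array `[n_slices, nrow, ncol]`.
#' @export
stack_to_array <- function(stack) {
  d <- dim(stack$slices[[1]]$pixels)
  arr <- array(0, c(length(stack$slices), d[1], d[2]))
  for (k in seq_along(stack$slices)) arr[k, , ] <- stack$slices[[k]]$pixels
  arr
}

#' Build a stack from a 3D array (z, row, col)
#' @param arr numeric array `[n, rows, cols]`.
#' @param z_step axial spacing in micrometres.
#' @param pixel_pitch pixel size in micrometres.
#' @param normalized logical, passed to [image_slice()].
#' @return an `image_stack`.
#' @export
array_to_stack <- function(arr, z_step = 10, pixel_pitch = 6.5,
                           normalized = TRUE) {
  stopifnot(length(dim(arr)) == 3)
  slices <- lapply(seq_len(dim(arr)[1]), function(k)
    image_slice(arr[k, , , drop = TRUE] + matrix(0, dim(arr)[2], dim(arr)[3]),
                pixel_pitch = pixel_pitch, normalized = normalized))
  image_stack(slices, z_step = z_step)
}

#' Construct a hyperspectral Raman cube
#'
#' @param data numeric array `(y, x, wavenumber)`, non-negative.
#' @param wavenumbers strictly increasing axis in 1/cm, length = third dim.
#' @param excitation_nm excitation laser wavelength in nm.
#' @return a `spectral_cube` object.
#' @export
spectral_cube <- function(data, wavenumbers, excitation_nm = 532) {
  if (length(dim(data)) != 3) stop("cube data must be a 3D array")
  if (length(wavenumbers) != dim(data)[3])
    stop("wavenumber axis length must match third data dimension")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumber axis must be strictly increasing")
  if (min(data) < 0) stop("cube data must be non-negative")
  structure(list(data = data, wavenumbers = as.numeric(wavenumbers),
                 excitation_nm = excitation_nm),
            class = "spectral_cube")
}

#' Construct a Raman spectrum
#'
#' @param wavenumbers strictly increasing Raman shift axis in 1/cm.
#' @param intensity intensities (arbitrary units), same length as the axis.
#' @param excitation_nm excitation wavelength in nm.
#' @param bands optional list recording ground-truth band parameters (used by
#'   the synthetic generator for recovery tests).
#' @return a `spectrum` object.
#' @export
spectrum <- function(wavenumbers, intensity, excitation_nm = 532,
                     bands = NULL) {
  if (length(wavenumbers) != length(intensity))
    stop("axis and intensity must have equal length")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumber axis must be strictly increasing")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensity = as.numeric(intensity),
                 excitation_nm = excitation_nm, bands = bands),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm^-1, excitation %g nm\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$excitation_nm))
  invisible(x)
}
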