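#' Specification of a synthetic spheroid phantom
#'
#' Describes the world the synthetic stacks emulate: a 300-400 um tumor
#' spheroid inside the instrument's 635 um x 635 um field of view, sectioned
#' at 10 um axial steps into a 41-slice Z-stack, corrupted by a smooth
#' additive autofluorescence field and i.i.d. Gaussian noise.
#'
#' @param grid_size pixels per side of the square field of view (>= 16).
#' @param n_slices number of Z planes (default 41, a full instrument stack).
#' @param z_step axial spacing in micrometres (default 10).
#' @param spheroid_diameter diameter in micrometres; `NULL` draws one
#'   uniformly from 300-400 um using `seed`.
#' @param core_intensity,rim_intensity plateau intensities of the spheroid
#'   interior and outer rim, in `[0, 1]`; spheroids image with a brighter
#'   rim because the densely packed outer proliferating zone scatters more.
#' @param base_intensity constant pedestal outside the spheroid (camera
#'   offset plus medium scattering); keeps additive noise away from the
#'   clipping boundary at 0.
#' @param noise_sigma standard deviation of the additive Gaussian noise on
#'   unit-normalized intensities, in `[0, 1)`.
#' @param fluor_amplitude peak amplitude of the smooth autofluorescence
#'   background field.
#' @param fluor_scale spatial correlation length of the background, pixels.
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise at a
#'   photon budget implied by `noise_sigma` at mid-intensity).
#' @param seed integer RNG seed; identical seeds give bit-identical phantoms.
#' @param fov_um physical field of view per side, micrometres.
#' @return a `phantom_spec` object; `pixel_pitch` is derived as
#'   `fov_um / grid_size`.
#' @export
phantom_spec <- function(grid_size = 128, n_slices = 41, z_step = 10,
                         spheroid_diameter = NULL, core_intensity = 0.5,
                         rim_intensity = 0.8, base_intensity = 0.15,
                         noise_sigma = 0.05, fluor_amplitude = 0.2,
                         fluor_scale = 20, noise_model = "gaussian",
                         seed = 1, fov_um = 635) {
  if (grid_size < 16) stop("grid_size must be >= 16")
  if (n_slices < 1) stop("n_slices must be >= 1")
  if (noise_sigma < 0 || noise_sigma >= 1) stop("noise_sigma must be in [0, 1)")
  if (fluor_amplitude < 0) stop("fluor_amplitude must be non-negative")
  if (!is.null(spheroid_diameter)) {
    if (spheroid_diameter <= 0) stop("spheroid_diameter must be positive")
    if (spheroid_diameter > fov_um)
      stop("spheroid_diameter exceeds the field of view")
  }
  for (v in c(core_intensity, rim_intensity, base_intensity))
    if (v < 0 || v > 1) stop("intensities must lie in [0, 1]")
  noise_model <- match.arg(noise_model, c("gaussian", "poisson"))
  structure(list(
    grid_size = as.integer(grid_size), n_slices = as.integer(n_slices),
    z_step = z_step, spheroid_diameter = spheroid_diameter,
    core_intensity = core_intensity, rim_intensity = rim_intensity,
    base_intensity = base_intensity, noise_sigma = noise_sigma,
    fluor_amplitude = fluor_amplitude, fluor_scale = fluor_scale,
    noise_model = noise_model, seed = as.integer(seed), fov_um = fov_um,
    pixel_pitch = fov_um / grid_size), class = "phantom_spec")
}

smoothstep <- function(x) {
  t <- clip01(x)
  t * t * (3 - 2 * t)
}

# Radial intensity profile of one optical section of the sphere:
# plateau core, brighter rim band over the outer 15% of the local radius,
# smooth roll-offs about two pixels wide to avoid aliased hard edges.
slice_profile <- function(dist_um, r_um, core, rim, edge_um) {
  if (r_um <= 0) return(dist_um * 0)
  up <- smoothstep((dist_um - 0.85 * r_um) / edge_um + 0.5)
  dn <- smoothstep((dist_um - r_um) / edge_um + 0.5)
  (core + (rim - core) * up) * (1 - dn)
}

# Smooth random field in [0, amplitude]: seeded white noise blurred with a
# Gaussian kernel of sd `scale` pixels via FFT, then min-max rescaled.
smooth_field <- function(n, scale, amplitude) {
  if (amplitude == 0) return(matrix(0, n, n))
  w <- matrix(rnorm(n * n), n, n)
  f <- c(0:(n %/% 2), -((ceiling(n / 2) - 1):1)) / n
  g <- exp(-2 * pi^2 * scale^2 * outer(f^2, f^2, "+"))
  b <- Re(fft(fft(w) * g, inverse = TRUE)) / n^2
  rng <- range(b)
  if (diff(rng) < .Machine$double.eps) return(matrix(amplitude / 2, n, n))
  (b - rng[1]) / diff(rng) * amplitude
}

#' Generate a synthetic spheroid light-sheet stack
#'
#' Produces the three aligned stacks the rest of the pipeline is tested
#' against: the noise-free ground truth, the autofluorescence background
#' field alone, and the corrupted observation
#' `noisy = clip(clean + background + noise, 0, 1)`.
#'
#' The ground truth is a solid sphere; every Z plane carries the disk whose
#' radius is the sphere's chord at that plane, with a dimmer core and a
#' brighter rim. The background is an independent smooth (large-correlation-
#' length) random field per slice, and the noise is i.i.d. Gaussian per
#' pixel (optionally Poisson shot noise).
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_volume` list with elements `clean`, `noisy`,
#'   `background` (each an [image_stack()]) and `spec`.
#' @export
generate_spheroid_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$grid_size
  diam <- spec$spheroid_diameter
  if (is.null(diam)) diam <- runif(1, 300, 400)
  if (diam > spec$fov_um) stop("spheroid_diameter exceeds the field of view")
  R <- diam / 2
  pp <- spec$pixel_pitch
  ctr <- (n + 1) / 2
  dist_um <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")) * pp
  zc <- (spec$n_slices - 1) / 2 * spec$z_step
  edge <- 2 * pp

  clean <- vector("list", spec$n_slices)
  bg <- vector("list", spec$n_slices)
  noisy <- vector("list", spec$n_slices)
  for (k in seq_len(spec$n_slices)) {
    dz <- (k - 1) * spec$z_step - zc
    rz <- if (abs(dz) < R) sqrt(R^2 - dz^2) else 0
    obj <- slice_profile(dist_um, rz, spec$core_intensity,
                         spec$rim_intensity, edge)
    cl <- pmax(obj, spec$base_intensity)
    b <- smooth_field(n, spec$fluor_scale, spec$fluor_amplitude)
    nz <- if (spec$noise_sigma == 0) {
      matrix(0, n, n)
    } else if (spec$noise_model == "gaussian") {
      matrix(rnorm(n * n, 0, spec$noise_sigma), n, n)
    } else {
      # shot noise calibrated so that variance at intensity 0.5 matches
      # noise_sigma^2: counts ~ Poisson(I * 0.5 / sigma^2)
      lam <- 0.5 / spec$noise_sigma^2
      matrix(rpois(n * n, pmax(cl + b, 0) * lam) / lam, n, n) - (cl + b)
    }
    clean[[k]] <- image_slice(cl, pixel_pitch = pp)
    bg[[k]] <- image_slice(b, pixel_pitch = pp)
    noisy[[k]] <- image_slice(clip01(cl + b + nz), pixel_pitch = pp)
  }
  structure(list(clean = image_stack(clean, spec$z_step),
                 noisy = image_stack(noisy, spec$z_step),
                 background = image_stack(bg, spec$z_step),
                 spec = spec),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %d slices, %d px, sigma %.3g, fluor %.3g\n",
              x$spec$n_slices, x$spec$grid_size, x$spec$noise_sigma,
              x$spec$fluor_amplitude))
  invisible(x)
}

#' The standard evaluation phantom
#'
#' One 128 x 128 slice (or a full stack) with a spheroid filling about 60%
#' of the frame (381 um of the 635 um field), rim 0.8 / core 0.5, additive
#' Gaussian noise sigma 0.05 and smooth background amplitude 0.2, seed 42 —
#' the configuration every quality-gate check in this package runs on.
#'
#' @param n_slices number of Z planes (default 1 for single-slice checks).
#' @param grid_size pixels per side.
#' @param noise_sigma,fluor_amplitude corruption levels.
#' @param seed RNG seed.
#' @return a [phantom_spec()].
#' @export
standard_phantom_spec <- function(n_slices = 1, grid_size = 128,
                                  noise_sigma = 0.05, fluor_amplitude = 0.2,
                                  seed = 42) {
  phantom_spec(grid_size = grid_size, n_slices = n_slices,
               spheroid_diameter = 0.6 * 635, core_intensity = 0.5,
               rim_intensity = 0.8, noise_sigma = noise_sigma,
               fluor_amplitude = fluor_amplitude, seed = seed)
}

#' Generate a synthetic Raman spectrum
#'
#' Sum of Gaussian bands on a polynomial baseline plus Gaussian noise; the
#' generating band parameters are recorded in the result for recovery tests
#' against the baseline-correction and band-assignment routines.
#'
#' @param bands list of `c(center, width, amplitude)` triplets
#'   (center and width in 1/cm); may be empty for a baseline-only spectrum.
#' @param baseline_poly polynomial coefficients (constant first) evaluated
#'   on a unit-scaled axis `(wavenumber - min) / (max - min)`.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param seed RNG seed.
#' @param wavenumbers axis in 1/cm (default 2600-3600, 1/cm steps, covering
#'   the C-H stretching region).
#' @param excitation_nm recorded excitation wavelength.
#' @return a [spectrum()] whose `bands` element holds the ground truth.
#' @export
generate_synthetic_spectrum <- function(bands = list(),
                                        baseline_poly = c(0),
                                        noise_sigma = 0, seed = 1,
                                        wavenumbers = seq(2600, 3600, by = 1),
                                        excitation_nm = 532) {
  for (b in bands) {
    if (length(b) != 3) stop("each band must be c(center, width, amplitude)")
    if (b[2] <= 0) stop("band widths must be positive")
    if (b[3] < 0) stop("band amplitudes must be non-negative")
    if (b[1] < min(wavenumbers) || b[1] > max(wavenumbers))
      stop("band center outside the spectral axis")
  }
  set.seed(seed)
  u <- (wavenumbers - min(wavenumbers)) / diff(range(wavenumbers))
  base <- rep(0, length(wavenumbers))
  for (i in seq_along(baseline_poly)) base <- base + baseline_poly[i] * u^(i - 1)
  intens <- base
  for (b in bands) intens <- intens + b[3] * exp(-(wavenumbers - b[1])^2 / (2 * b[2]^2))
  if (noise_sigma > 0) intens <- intens + rnorm(length(intens), 0, noise_sigma)
  spectrum(wavenumbers, intens, excitation_nm = excitation_nm, bands = bands)
}

#' Write a phantom volume to disk
#'
#' Three multi-page TIFFs (`clean.tiff`, `noisy.tiff`, `background.tiff`)
#' plus a JSON sidecar with the generating specification.
#'
#' @param vol a `phantom_volume`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(vol, dir) {
  stopifnot(inherits(vol, "phantom_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(vol$clean, file.path(dir, "clean.tiff"), bit_depth = "float")
  write_stack(vol$noisy, file.path(dir, "noisy.tiff"), bit_depth = "float")
  write_stack(vol$background, file.path(dir, "background.tiff"),
              bit_depth = "float")
  sp <- vol$spec
  class(sp) <- NULL
  jsonlite::write_json(sp, file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
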