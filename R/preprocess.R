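# Pre- and post-processing chain surrounding the DIP denoiser: background
# subtraction, median filtering, circular ROI, contrast-limited adaptive
# histogram equalization, grayscale morphology, Fourier band-pass. All
# operations preserve shape and the [0,1] range contract; borders use
# reflect padding.

check_slice <- function(x, name = "image") {
  if (!inherits(x, "image_slice")) stop(name, " must be an image_slice")
  invisible(x)
}

#' Subtract a reference background image
#'
#' `clip(image - reference, 0, 1)`; the reference is typically an
#' acquisition without the specimen (autofluorescence plus camera offset).
#'
#' @param image,reference normalized [image_slice()]s of equal shape.
#' @return an `image_slice`.
#' @export
subtract_background <- function(image, reference) {
  check_slice(image); check_slice(reference, "reference")
  if (!identical(dim(image$pixels), dim(reference$pixels)))
    stop("image and reference shapes differ")
  as_slice_like(image, clip01(image$pixels - reference$pixels))
}

#' Median filter
#'
#' Each pixel is replaced by the median of its `kernel x kernel`
#' neighborhood (reflect padding) — suppresses impulsive, high-frequency
#' noise without blurring step edges.
#'
#' @param image an [image_slice()].
#' @param kernel odd window size, >= 1.
#' @return an `image_slice`.
#' @export
median_filter <- function(image, kernel = 3) {
  check_slice(image)
  if (kernel < 1 || kernel %% 2 == 0) stop("kernel must be odd and >= 1")
  if (kernel == 1) return(image)
  as_slice_like(image, median_filter_cpp(image$pixels, as.integer(kernel)))
}

#' Circular region-of-interest mask
#'
#' True where `(r - r0)^2 + (c - c0)^2 <= radius^2`. The default covers a
#' 300-400 um spheroid centered in the 635 um field of view.
#'
#' @param shape `c(rows, cols)`.
#' @param center `c(row, col)` in pixels; default the image center.
#' @param radius pixels; default `0.45 * min(shape)`.
#' @return a logical matrix.
#' @export
circular_roi_mask <- function(shape, center = NULL, radius = NULL) {
  if (is.null(center)) center <- (shape + 1) / 2
  if (is.null(radius)) radius <- 0.45 * min(shape)
  if (radius <= 0) stop("radius must be positive")
  outer((seq_len(shape[1]) - center[1])^2,
        (seq_len(shape[2]) - center[2])^2, "+") <= radius^2
}

# Clipped-histogram CDF mapping for one tile: histogram on `nbins` bins over
# [0,1], counts above clip are redistributed uniformly, then the CDF maps
# bin centers back to [0,1].
clahe_tile_map <- function(vals, nbins, clip_limit) {
  h <- tabulate(pmin(pmax(floor(vals * nbins) + 1, 1), nbins), nbins)
  clip <- max(clip_limit * length(vals), 1)
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / nbins
  cdf <- cumsum(h)
  cdf / cdf[nbins]
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise clipped-histogram equalization with bilinear interpolation of
#' the tile mappings, restricted to a mask: pixels outside `mask` are
#' returned unchanged. Improves local contrast without letting noise
#' amplification run away (the clip limit caps the slope of the transfer
#' function).
#'
#' @param image a normalized [image_slice()].
#' @param mask logical matrix, default all-true.
#' @param clip_limit histogram clip as a fraction of tile pixel count
#'   (> 0; 1 reduces to plain adaptive equalization).
#' @param tile_grid number of tiles per side.
#' @param nbins histogram bins.
#' @return an `image_slice` with values in `[0, 1]`.
#' @export
adaptive_hist_eq <- function(image, mask = NULL, clip_limit = 0.01,
                             tile_grid = 8, nbins = 256) {
  check_slice(image)
  if (clip_limit <= 0) stop("clip_limit must be positive")
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  tg <- max(1, min(tile_grid, H %/% 4, W %/% 4))
  rb <- round(seq(0, H, length.out = tg + 1))
  cb <- round(seq(0, W, length.out = tg + 1))
  maps <- vector("list", tg * tg)
  rc <- cc <- numeric(tg)
  for (i in seq_len(tg)) rc[i] <- (rb[i] + rb[i + 1] + 1) / 2
  for (j in seq_len(tg)) cc[j] <- (cb[j] + cb[j + 1] + 1) / 2
  for (i in seq_len(tg)) for (j in seq_len(tg)) {
    tile <- px[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
    maps[[(j - 1) * tg + i]] <- clahe_tile_map(as.vector(tile), nbins,
                                               clip_limit)
  }
  bin_of <- pmin(pmax(floor(px * nbins) + 1, 1), nbins)
  # tile interpolation weights per row/col
  ridx <- findInterval(seq_len(H), rc)            # tile at/below
  ri0 <- pmax(ridx, 1); ri1 <- pmin(ridx + 1, tg)
  rw <- ifelse(ri1 > ri0, (seq_len(H) - rc[ri0]) / (rc[ri1] - rc[ri0]), 0)
  rw <- pmin(pmax(rw, 0), 1)
  cidx <- findInterval(seq_len(W), cc)
  ci0 <- pmax(cidx, 1); ci1 <- pmin(cidx + 1, tg)
  cw <- ifelse(ci1 > ci0, (seq_len(W) - cc[ci0]) / (cc[ci1] - cc[ci0]), 0)
  cw <- pmin(pmax(cw, 0), 1)
  out <- px
  lookup <- function(ti, tj) {
    m <- maps[[(tj - 1) * tg + ti]]
    matrix(m[bin_of], H, W)
  }
  # bilinear blend of the four neighboring tile mappings, vectorized by
  # unique tile-pair combinations along rows and columns
  v00 <- v01 <- v10 <- v11 <- matrix(0, H, W)
  for (ti in unique(c(ri0, ri1))) for (tj in unique(c(ci0, ci1))) {
    sel_r0 <- ri0 == ti; sel_r1 <- ri1 == ti
    sel_c0 <- ci0 == tj; sel_c1 <- ci1 == tj
    if (!any(sel_r0 | sel_r1) || !any(sel_c0 | sel_c1)) next
    mp <- lookup(ti, tj)
    if (any(sel_r0) && any(sel_c0)) v00[sel_r0, sel_c0] <- mp[sel_r0, sel_c0]
    if (any(sel_r0) && any(sel_c1)) v01[sel_r0, sel_c1] <- mp[sel_r0, sel_c1]
    if (any(sel_r1) && any(sel_c0)) v10[sel_r1, sel_c0] <- mp[sel_r1, sel_c0]
    if (any(sel_r1) && any(sel_c1)) v11[sel_r1, sel_c1] <- mp[sel_r1, sel_c1]
  }
  RW <- matrix(rw, H, W); CW <- matrix(cw, H, W, byrow = TRUE)
  eq <- (1 - RW) * ((1 - CW) * v00 + CW * v01) +
        RW * ((1 - CW) * v10 + CW * v11)
  if (is.null(mask)) out <- eq else out[mask] <- eq[mask]
  as_slice_like(image, clip01(out))
}

#' Grayscale morphological refinement
#'
#' Dilation (neighborhood maximum) or erosion (neighborhood minimum) over a
#' disk structuring element of the given radius.
#'
#' @param image an [image_slice()].
#' @param op `"dilate"` or `"erode"`.
#' @param structuring_radius disk radius in pixels, >= 1.
#' @return an `image_slice`.
#' @export
morph_refine <- function(image, op = c("dilate", "erode"),
                         structuring_radius = 1) {
  check_slice(image)
  op <- match.arg(op)
  if (structuring_radius < 1) stop("structuring_radius must be >= 1")
  out <- morph_filter_cpp(image$pixels, as.integer(structuring_radius),
                          if (op == "dilate") 0L else 1L)
  as_slice_like(image, out)
}

# radial frequency (cycles/image) of each FFT bin for an n-point axis
fft_freq_cycles <- function(n) c(0:(n %/% 2), -((ceiling(n / 2) - 1):1))

#' Fourier band-pass filter
#'
#' Keeps spatial frequencies with radial distance `low_cut <= r <= high_cut`
#' (cycles/image) in the 2D Fourier domain and re-clips the real part to
#' `[0, 1]`. `low_cut = 0` retains the DC term; any positive `low_cut`
#' rejects it (removing smooth, autofluorescence-like components), while a
#' finite `high_cut` suppresses residual high-frequency noise.
#'
#' @param image an [image_slice()].
#' @param low_cut,high_cut cycles per image width, `0 <= low_cut < high_cut`.
#' @return an `image_slice`.
#' @export
bandpass_filter <- function(image, low_cut = 0, high_cut = Inf) {
  check_slice(image)
  if (low_cut < 0 || high_cut <= low_cut)
    stop("need 0 <= low_cut < high_cut")
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  fr <- fft_freq_cycles(H); fc <- fft_freq_cycles(W)
  r <- sqrt(outer(fr^2, fc^2, "+"))
  keep <- (r >= low_cut) & (r <= high_cut)
  out <- Re(fft(fft(px) * keep, inverse = TRUE)) / (H * W)
  as_slice_like(image, clip01(out))
}

#' Generate an additive/subtractive corrupted pair
#'
#' One Gaussian noise draw `n ~ N(0, sigma)` applied with both signs:
#' `plus = clip(image + n)`, `minus = clip(image - n)`. Without clipping the
#' two average back to the input exactly.
#'
#' @param image an [image_slice()].
#' @param sigma noise standard deviation, >= 0.
#' @param seed RNG seed.
#' @return list with elements `plus`, `minus` (image_slices) and `noise`
#'   (the raw draw, a matrix).
#' @export
make_noise_pairs <- function(image, sigma, seed = 1) {
  check_slice(image)
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  n <- matrix(rnorm(length(image$pixels), 0, sigma), nrow(image$pixels))
  list(plus = as_slice_like(image, clip01(image$pixels + n)),
       minus = as_slice_like(image, clip01(image$pixels - n)),
       noise = n)
}
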