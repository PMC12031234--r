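# The four printed validation metrics: PSNR, SSIM, RMSE and Fourier Ring
# Correlation, plus the per-slice QC report over a stack.

pixels_of <- function(x) if (inherits(x, "image_slice")) x$pixels else x

check_pair <- function(a, b) {
  a <- pixels_of(a); b <- pixels_of(b)
  if (!identical(dim(a), dim(b))) stop("image shapes differ")
  list(a = a, b = b)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX^2 / MSE)` in dB. Identical images have zero MSE and are
#' reported as `Inf` (never a large finite stand-in).
#'
#' @param a,b image slices or matrices of equal shape.
#' @param max_value `MAX`, the largest representable pixel value (1 for
#'   unit-normalized data).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_value = 1) {
  p <- check_pair(a, b)
  mse <- mean((p$a - p$b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Root mean squared error
#'
#' @param a,b image slices or matrices of equal shape.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  p <- check_pair(a, b)
  sqrt(mean((p$a - p$b)^2))
}

# separable sliding-window mean with reflect padding, via cumulative sums
box_mean <- function(m, w) {
  r <- w %/% 2
  n1 <- nrow(m); n2 <- ncol(m)
  idx <- function(n) c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1)
  mp <- m[idx(n1), idx(n2), drop = FALSE]
  cs <- apply(mp, 2, cumsum)                      # (n1 + 2r) x (n2 + 2r)
  v <- cs[w:(n1 + 2 * r), , drop = FALSE] -
    rbind(matrix(0, 1, ncol(cs)), cs[seq_len(n1 - 1), , drop = FALSE])
  cs2 <- t(apply(v, 1, cumsum))                   # n1 x (n2 + 2r)
  out <- cs2[, w:(n2 + 2 * r), drop = FALSE] -
    cbind(matrix(0, n1, 1), cs2[, seq_len(n2 - 1), drop = FALSE])
  out / (w * w)
}

#' Structural similarity index
#'
#' Local means, variances and covariance are computed over a sliding
#' uniform window and combined as
#' `((2*mu_x*mu_y + C1) * (2*sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1) * (sigma_x^2 + sigma_y^2 + C2))`,
#' then averaged over the image. `mode = "global"` instead evaluates the
#' same expression once from whole-image statistics (the literal printed
#' form of the index).
#'
#' @param a,b normalized image slices or matrices of equal shape.
#' @param C1,C2 stabilizing constants; defaults `(0.01 * MAX)^2` and
#'   `(0.03 * MAX)^2` with `MAX = 1`.
#' @param window odd sliding-window width (default 7).
#' @param mode `"windowed"` (default) or `"global"`.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(a, b, C1 = 0.01^2, C2 = 0.03^2, window = 7,
                 mode = c("windowed", "global")) {
  p <- check_pair(a, b)
  mode <- match.arg(mode)
  x <- p$a; y <- p$b
  if (mode == "global") {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  if (window > min(dim(x))) stop("window larger than image")
  mx <- box_mean(x, window); my <- box_mean(y, window)
  vx <- box_mean(x * x, window) - mx^2
  vy <- box_mean(y * y, window) - my^2
  cxy <- box_mean(x * y, window) - mx * my
  m <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(m)
}

#' Fourier ring correlation
#'
#' Correlation of the two images' Fourier transforms within concentric
#' frequency shells:
#' `Re(sum(FFT1 * conj(FFT2))) / sqrt(sum(|FFT1|^2) * sum(|FFT2|^2))`
#' per shell. The DC bin is excluded. The scalar summary is the mean over
#' shells whose radius lies below half the Nyquist frequency.
#'
#' @param a,b image slices or matrices of equal (square; reflect-padded
#'   otherwise) shape.
#' @param shell_width width of each radial shell in frequency bins.
#' @return list with `radius` (cycles/image), `correlation` (per shell, in
#'   `[-1, 1]`), `n_bins` (bins per shell) and `mean_frc` (mean over shells
#'   below half-Nyquist).
#' @export
frc <- function(a, b, shell_width = 1) {
  p <- check_pair(a, b)
  x <- p$a; y <- p$b
  if (nrow(x) != ncol(x)) {
    n <- max(dim(x))
    x <- pad_reflect_to(x, n, n)
    y <- pad_reflect_to(y, n, n)
  }
  n <- nrow(x)
  F1 <- fft(x); F2 <- fft(y)
  f <- fft_freq_cycles(n)
  r <- sqrt(outer(f^2, f^2, "+"))
  shell <- floor(r / shell_width)
  shell[1, 1] <- NA  # exclude DC
  num <- Re(F1 * Conj(F2))
  d1 <- Mod(F1)^2
  d2 <- Mod(F2)^2
  sid <- sort(unique(as.vector(shell[!is.na(shell)])))
  corr <- rad <- nb <- numeric(length(sid))
  keepmask <- !is.na(shell)
  for (i in seq_along(sid)) {
    m <- keepmask & shell == sid[i]
    s1 <- sum(d1[m]); s2 <- sum(d2[m])
    nb[i] <- sum(m)
    rad[i] <- (sid[i] + 0.5) * shell_width
    corr[i] <- if (s1 == 0 || s2 == 0) NA_real_
               else sum(num[m]) / sqrt(s1 * s2)
  }
  empty <- is.na(corr)
  if (any(empty)) warning(sum(empty), " empty/degenerate shells skipped")
  half_nyquist <- n / 4  # Nyquist = n/2 cycles/image
  sel <- !empty & rad < half_nyquist
  list(radius = rad, correlation = corr, n_bins = nb,
       mean_frc = mean(corr[sel]))
}

#' Per-slice quality-control curves for a stack pair
#'
#' Computes PSNR, SSIM, RMSE and mean FRC slice-for-slice between two
#' aligned stacks plus their aggregates — the per-slice metric panels
#' reported for full 41-slice reconstructions.
#'
#' @param original,processed aligned [image_stack()]s.
#' @param reference_convention label recording what `original` is
#'   (`"noisy_input"` for the instrument convention of comparing the noisy
#'   acquisition with its enhanced output, `"clean_truth"` for synthetic
#'   ground-truth evaluation).
#' @param max_value PSNR `MAX`.
#' @return a `metric_report`: list with `per_slice` (data.frame), `aggregate`
#'   (named means; PSNR aggregated over finite slices) and
#'   `reference_convention`.
#' @export
qc_curves <- function(original, processed,
                      reference_convention = c("noisy_input", "clean_truth"),
                      max_value = 1) {
  stopifnot(inherits(original, "image_stack"),
            inherits(processed, "image_stack"))
  reference_convention <- match.arg(reference_convention)
  if (length(original$slices) != length(processed$slices))
    stop("slice counts differ")
  n <- length(original$slices)
  per <- data.frame(slice_index = seq_len(n) - 1L, psnr = NA_real_,
                    ssim = NA_real_, rmse = NA_real_, frc_mean = NA_real_)
  for (k in seq_len(n)) {
    a <- original$slices[[k]]; b <- processed$slices[[k]]
    per$psnr[k] <- psnr(a, b, max_value)
    per$ssim[k] <- ssim(a, b)
    per$rmse[k] <- rmse(a, b)
    per$frc_mean[k] <- suppressWarnings(frc(a, b)$mean_frc)
  }
  agg <- c(psnr = mean(per$psnr[is.finite(per$psnr)]),
           ssim = mean(per$ssim), rmse = mean(per$rmse),
           frc_mean = mean(per$frc_mean, na.rm = TRUE))
  structure(list(per_slice = per, aggregate = agg,
                 reference_convention = reference_convention),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d slices vs %s\n", nrow(x$per_slice),
              x$reference_convention))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Write a metric report as CSV
#' @param report a `metric_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  write.csv(report$per_slice, path, row.names = FALSE)
  invisible(path)
}
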