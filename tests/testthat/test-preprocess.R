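test_that("background subtraction clips at zero and passes identities", {
  a <- random_slice(6, 1)
  zero <- image_slice(matrix(0, 6, 6))
  expect_equal(subtract_background(a, a)$pixels, matrix(0, 6, 6))
  expect_equal(subtract_background(a, zero)$pixels, a$pixels)
  lo <- image_slice(matrix(0.3, 4, 4)); hi <- image_slice(matrix(0.5, 4, 4))
  expect_equal(subtract_background(lo, hi)$pixels, matrix(0, 4, 4))
  expect_error(subtract_background(a, image_slice(matrix(0.1, 3, 3))),
               "shapes")
})

test_that("median filter matches a brute-force oracle and kills impulses", {
  # brute force: per-pixel sorted neighborhood median with reflect padding
  brute_median <- function(m, k) {
    r <- k %/% 2
    refl <- function(i, n) {
      while (any(bad <- i < 1 | i > n)) {
        i[i < 1] <- 1 - i[i < 1]
        i[i > n] <- 2 * n + 1 - i[i > n]
      }
      i
    }
    out <- m
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      nb <- m[cbind(rep(refl(i + (-r:r), nrow(m)), k),
                    rep(refl(j + (-r:r), ncol(m)), each = k))]
      out[i, j] <- median(nb)
    }
    out
  }
  for (seed in 1:3) {
    m <- random_slice(7, seed)
    expect_equal(median_filter(m, 3)$pixels, brute_median(m$pixels, 3))
    expect_equal(median_filter(m, 5)$pixels, brute_median(m$pixels, 5))
  }
  const <- image_slice(matrix(0.4, 5, 5))
  expect_equal(median_filter(const, 3)$pixels, const$pixels)
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  expect_equal(median_filter(image_slice(imp), 3)$pixels, matrix(0, 7, 7))
  expect_error(median_filter(const, 4), "odd")
})

test_that("circular ROI mask enumerates correctly", {
  m <- circular_roi_mask(c(9, 9), radius = 1)
  expect_equal(sum(m), 5)                 # center + 4-neighbors
  expect_true(m[5, 5])
  expect_true(all(circular_roi_mask(c(9, 9), radius = 13)))  # >= diagonal
  d <- circular_roi_mask(c(21, 21))       # default radius 0.45 * 21
  expect_true(d[11, 11])
  expect_false(d[1, 1])
  expect_error(circular_roi_mask(c(5, 5), radius = 0), "positive")
})

test_that("adaptive equalization respects range, mask and contrast", {
  const <- image_slice(matrix(0.7, 32, 32))
  out <- adaptive_hist_eq(const)
  expect_equal(sd(out$pixels), 0)
  r <- random_slice(32, 4)
  o <- adaptive_hist_eq(r)
  expect_gte(min(o$pixels), 0); expect_lte(max(o$pixels), 1)
  # low-contrast ramp gains dynamic range
  ramp <- image_slice(matrix(seq(0.4, 0.6, length.out = 32 * 32), 32, 32))
  oe <- adaptive_hist_eq(ramp)
  expect_gt(diff(range(oe$pixels)), diff(range(ramp$pixels)))
  # pixels outside the mask untouched
  mask <- circular_roi_mask(c(32, 32), radius = 8)
  om <- adaptive_hist_eq(r, mask)
  expect_identical(om$pixels[!mask], r$pixels[!mask])
  expect_error(adaptive_hist_eq(r, clip_limit = 0), "positive")
})

test_that("morphology matches neighborhood extrema and order properties", {
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  d <- morph_refine(image_slice(imp), "dilate", 1)
  expect_equal(sum(d$pixels), 5)          # plus-shaped disk of radius 1
  expect_equal(d$pixels[4, 3:5], c(1, 1, 1))
  const <- image_slice(matrix(0.3, 6, 6))
  expect_equal(morph_refine(morph_refine(const, "dilate", 1), "erode",
                            1)$pixels, const$pixels)
  r <- random_slice(7, 5)
  er <- morph_refine(r, "erode", 2)$pixels
  di <- morph_refine(r, "dilate", 2)$pixels
  expect_true(all(er <= r$pixels + 1e-12))
  expect_true(all(r$pixels <= di + 1e-12))
  # brute-force oracle on a disk of radius 2
  brute <- function(m, radius, f) {
    refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
    out <- m
    offs <- subset(expand.grid(di = -radius:radius, dj = -radius:radius),
                   di^2 + dj^2 <= radius^2)
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      out[i, j] <- f(m[cbind(refl(i + offs$di, nrow(m)),
                             refl(j + offs$dj, ncol(m)))])
    out
  }
  expect_equal(di, brute(r$pixels, 2, max))
  expect_equal(er, brute(r$pixels, 2, min))
  expect_error(morph_refine(r, "dilate", 0), "radius")
})

test_that("band-pass filter selects frequencies as advertised", {
  const <- image_slice(matrix(0.5, 16, 16))
  dc_removed <- bandpass_filter(const, low_cut = 0.5, high_cut = 8)
  expect_equal(dc_removed$pixels, matrix(0, 16, 16))  # DC rejected, clipped
  r <- random_slice(16, 6)
  ident <- bandpass_filter(r, 0, 1e6)
  expect_equal(ident$pixels, r$pixels, tolerance = 1e-12)
  # pure tone inside the band survives (up to clipping-free offset)
  n <- 32; f0 <- 5
  tone <- 0.5 + 0.25 * cos(2 * pi * f0 * (0:(n - 1)) / n)
  img <- image_slice(matrix(tone, n, n, byrow = TRUE))
  kept <- bandpass_filter(img, low_cut = 0, high_cut = 10)
  expect_equal(kept$pixels, img$pixels, tolerance = 1e-10)
  cut <- bandpass_filter(img, low_cut = 0, high_cut = 3)
  expect_equal(cut$pixels, matrix(0.5, n, n), tolerance = 1e-10)
  expect_error(bandpass_filter(r, 5, 2), "low_cut")
})

test_that("noise pairs share one draw and cancel without clipping", {
  base <- image_slice(matrix(0.5, 50, 50))
  p <- make_noise_pairs(base, 0.1, seed = 9)
  expect_equal((p$plus$pixels + p$minus$pixels) / 2, base$pixels,
               tolerance = 1e-12)  # 0.5 +- 0.1 never clips
  expect_equal(sd(p$noise), 0.1, tolerance = 0.05)
  z <- make_noise_pairs(base, 0, seed = 1)
  expect_identical(z$plus$pixels, base$pixels)
  expect_identical(z$minus$pixels, base$pixels)
})

test_that("preprocessing preserves shape and [0,1] everywhere", {
  r <- random_slice(16, 8)
  ops <- list(function(x) median_filter(x, 3),
              function(x) adaptive_hist_eq(x),
              function(x) morph_refine(x, "erode", 1),
              function(x) bandpass_filter(x, 0, 6))
  for (op in ops) {
    o <- op(r)
    expect_identical(dim(o$pixels), dim(r$pixels))
    expect_gte(min(o$pixels), 0)
    expect_lte(max(o$pixels), 1)
  }
})
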