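test_that("16-bit multi-page round trip is bit-identical", {
  set.seed(1)
  mats <- lapply(1:41, function(k) matrix(sample(0:65535, 64, TRUE), 8, 8))
  stack <- image_stack(lapply(mats, function(m)
    image_slice(m, bit_depth = "16", normalized = FALSE)), z_step = 10)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_stack(stack, path, bit_depth = "16")
  r <- read_stack(path)
  expect_length(r$slices, 41)
  for (k in c(1, 20, 41))
    expect_identical(r$slices[[k]]$pixels, mats[[k]])
})

test_that("8-bit and float round trips, single page behaves", {
  set.seed(2)
  m8 <- matrix(sample(0:255, 25, TRUE), 5, 5)
  p8 <- withr::local_tempfile(fileext = ".tiff")
  write_stack(image_stack(list(image_slice(m8, bit_depth = "8",
                                           normalized = FALSE))), p8, "8")
  r8 <- read_stack(p8)
  expect_equal(n_slices(r8), 1)
  expect_identical(r8$slices[[1]]$pixels, m8)

  mf <- matrix(runif(25), 5, 5)
  pf <- withr::local_tempfile(fileext = ".tiff")
  write_stack(image_stack(list(image_slice(mf))), pf, "float")
  rf <- read_stack(pf)
  expect_equal(rf$slices[[1]]$pixels, mf, tolerance = 1e-7)
})

test_that("normalization maps full scale to 1.0", {
  m <- matrix(c(0, 1000, 30000, 65535), 2, 2)
  s <- normalize_slice(image_slice(m, bit_depth = "16", normalized = FALSE))
  expect_equal(max(s$pixels), 1.0)
  expect_equal(s$pixels, m / 65535)
  p <- withr::local_tempfile(fileext = ".tiff")
  write_stack(image_stack(list(image_slice(m, bit_depth = "16",
                                           normalized = FALSE))), p, "16")
  expect_equal(max(read_stack(p, normalize = TRUE)$slices[[1]]$pixels), 1.0)
})

test_that("missing files and malformed input raise errors", {
  expect_error(read_stack(file.path(tempdir(), "nope.tiff")), "not found")
  p <- withr::local_tempfile(fileext = ".bin")
  writeBin(as.raw(1:64), p)
  expect_error(read_stack(p), "not a TIFF")
})

test_that("round trip agrees with an independent TIFF implementation", {
  # cross-validation of the hand-rolled codec against Python tifffile,
  # which is part of the supported environment
  py <- Sys.which("python")
  expect_true(nzchar(py))  # python + tifffile ship with the environment
  set.seed(3)
  m <- matrix(sample(0:65535, 15 * 11, TRUE), 15, 11)
  ours <- withr::local_tempfile(fileext = ".tiff")
  write_stack(image_stack(list(image_slice(m, bit_depth = "16",
                                           normalized = FALSE))), ours, "16")
  out <- withr::local_tempfile(fileext = ".txt")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c("import tifffile, numpy as np, sys",
               "a = tifffile.imread(sys.argv[1])",
               "np.savetxt(sys.argv[2], a.astype(int), fmt='%d')"), script)
  st <- system2(py, c(script, ours, out), stderr = TRUE, stdout = TRUE)
  expect_equal(attr(st, "status"), NULL)
  theirs <- as.matrix(read.table(out))
  expect_equal(unname(theirs), unname(m))
  # and read back a file tifffile wrote
  theirs_tiff <- withr::local_tempfile(fileext = ".tiff")
  script2 <- withr::local_tempfile(fileext = ".py")
  writeLines(c("import tifffile, numpy as np, sys",
               "rng = np.random.default_rng(0)",
               "a = rng.integers(0, 65536, (3, 9, 7), dtype=np.uint16)",
               "tifffile.imwrite(sys.argv[1], a, photometric='minisblack')",
               "np.savetxt(sys.argv[2], a.reshape(-1, 7), fmt='%d')"),
             script2)
  system2(py, c(script2, theirs_tiff, out))
  r <- read_stack(theirs_tiff)
  expect_length(r$slices, 3)
  ref <- as.matrix(read.table(out))
  for (k in 1:3)
    expect_equal(unname(r$slices[[k]]$pixels),
                 unname(ref[(k - 1) * 9 + 1:9, ]))
})

test_that("spectral cube round trip preserves data and axes", {
  set.seed(4)
  cube <- spectral_cube(array(runif(5 * 6 * 7), c(5, 6, 7)),
                        wavenumbers = seq(2800, 3400, by = 100),
                        excitation_nm = 532)
  p <- withr::local_tempfile(fileext = ".tiff")
  write_cube(cube, p)
  r <- read_cube(p)
  expect_equal(r$data, cube$data, tolerance = 1e-7)
  expect_equal(r$wavenumbers, cube$wavenumbers)
  expect_equal(r$excitation_nm, 532)
  # single-plane cube reduces to an image
  c1 <- spectral_cube(array(runif(20), c(4, 5, 1)), 3000)
  p1 <- withr::local_tempfile(fileext = ".tiff")
  write_cube(c1, p1)
  r1 <- read_cube(p1)
  expect_equal(dim(r1$data), c(4, 5, 1))
  expect_equal(r1$data[, , 1], c1$data[, , 1], tolerance = 1e-7)
})

test_that("cube constructor enforces its invariants", {
  expect_error(spectral_cube(array(1, c(2, 2, 3)), c(1, 2)), "length")
  expect_error(spectral_cube(array(1, c(2, 2, 2)), c(2, 1)), "increasing")
  expect_error(spectral_cube(array(-1, c(2, 2, 1)), 1), "non-negative")
})
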