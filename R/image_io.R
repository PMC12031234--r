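# Minimal baseline TIFF codec (little-endian, uncompressed, single-channel
# grayscale, 8/16-bit unsigned or 32-bit float, multi-page). No TIFF package
# exists in the supported environment, so the container is implemented here;
# the tests cross-validate round trips against an independent reader.

tiff_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                    `6` = 1, `7` = 1, `8` = 2, `9` = 4, `10` = 8,
                    `11` = 4, `12` = 8)

read_tag_values <- function(con, type, count, raw4, endian) {
  sz <- tiff_type_size[as.character(type)]
  if (is.na(sz)) return(NULL)
  total <- sz * count
  readvals <- function(r) {
    if (type %in% c(3, 8)) readBin(r, "integer", count, size = 2,
                                   signed = type == 8, endian = endian)
    else if (type %in% c(4, 9)) readBin(r, "integer", count, size = 4,
                                        endian = endian)
    else if (type == 11) readBin(r, "double", count, size = 4, endian = endian)
    else if (type == 12) readBin(r, "double", count, size = 8, endian = endian)
    else readBin(r, "integer", count, size = 1, signed = FALSE)
  }
  if (total <= 4) {
    readvals(raw4[seq_len(max(total, 1))])
  } else {
    off <- readBin(raw4, "integer", 1, size = 4, endian = endian)
    here <- seek(con)
    seek(con, off)
    v <- readvals(readBin(con, "raw", total))
    seek(con, here)
    v
  }
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  endian <- if (identical(rawToChar(magic[1:2]), "II")) "little"
            else if (identical(rawToChar(magic[1:2]), "MM")) "big"
            else stop("not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_ent <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = endian)
    tags <- list()
    for (i in seq_len(n_ent)) {
      tag <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = endian)
      type <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                      endian = endian)
      count <- readBin(con, "integer", 1, size = 4, endian = endian)
      raw4 <- readBin(con, "raw", 4)
      tags[[as.character(tag)]] <- read_tag_values(con, type, count, raw4,
                                                   endian)
    }
    ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    W <- g(256); H <- g(257)
    bits <- g(258, 8)[1]
    comp <- g(259, 1)
    spp <- g(277, 1)
    fmt <- g(339, 1)[1]
    offs <- g(273); cnts <- g(279)
    if (is.null(W) || is.null(H) || is.null(offs))
      stop("malformed TIFF page in ", path)
    if (comp != 1) stop("only uncompressed TIFF is supported")
    if (spp != 1) stop("only single-channel TIFF is supported")
    if (is.null(cnts)) cnts <- rep(W * H * bits / 8 / length(offs),
                                   length(offs))
    raw_all <- raw(0)
    for (i in seq_along(offs)) {
      seek(con, offs[i])
      raw_all <- c(raw_all, readBin(con, "raw", cnts[i]))
    }
    npx <- W * H
    vals <- if (fmt == 3 && bits == 32) {
      readBin(raw_all, "double", npx, size = 4, endian = endian)
    } else if (bits == 16) {
      readBin(raw_all, "integer", npx, size = 2, signed = FALSE,
              endian = endian)
    } else if (bits == 8) {
      readBin(raw_all, "integer", npx, size = 1, signed = FALSE)
    } else stop("unsupported TIFF bit depth: ", bits)
    pages[[length(pages) + 1]] <-
      list(pixels = matrix(vals, nrow = H, ncol = W, byrow = TRUE),
           bits = bits, float = fmt == 3)
  }
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  pages
}

write_tiff_pages <- function(mats, path, bit_depth = "16") {
  bit_depth <- match.arg(as.character(bit_depth), c("8", "16", "float"))
  bits <- switch(bit_depth, "8" = 8L, "16" = 16L, "float" = 32L)
  fmt <- if (bit_depth == "float") 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n <- length(mats)
  # layout: header(8) | page strips | IFDs
  strip_bytes <- vapply(mats, function(m) length(m) * bits / 8, numeric(1))
  strip_offs <- 8 + cumsum(c(0, strip_bytes[-n]))
  ifd_size <- 2 + 10 * 12 + 4
  ifd_offs <- 8 + sum(strip_bytes) + (seq_len(n) - 1) * ifd_size
  writeBin(as.integer(ifd_offs[1]), con, size = 4, endian = "little")
  for (m in mats) {
    v <- as.vector(t(m))  # scanline (row-major) order
    if (bit_depth == "float") writeBin(v, con, size = 4, endian = "little")
    else writeBin(as.integer(round(v)), con, size = bits / 8,
                  endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3) {  # SHORT: left-justified in the 4-byte field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_len(n)) {
    H <- nrow(mats[[k]]); W <- ncol(mats[[k]])
    writeBin(10L, con, size = 2, endian = "little")
    entry(256, 4, 1, W)
    entry(257, 4, 1, H)
    entry(258, 3, 1, bits)
    entry(259, 3, 1, 1)       # no compression
    entry(262, 3, 1, 1)       # BlackIsZero
    entry(273, 4, 1, strip_offs[k])
    entry(277, 3, 1, 1)       # one sample per pixel
    entry(278, 4, 1, H)       # one strip per page
    entry(279, 4, 1, strip_bytes[k])
    entry(339, 3, 1, fmt)
    writeBin(as.integer(if (k < n) ifd_offs[k + 1] else 0), con, size = 4,
             endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF Z-stack
#'
#' @param path TIFF file (single-channel grayscale, uncompressed).
#' @param z_step axial spacing to attach, micrometres.
#' @param pixel_pitch pixel size to attach, micrometres.
#' @param normalize if `TRUE`, integer data are divided by the full-scale
#'   value of their bit depth (255 or 65535) to land in `[0, 1]`.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, z_step = 10, pixel_pitch = 6.5,
                       normalize = FALSE) {
  pages <- read_tiff_pages(path)
  d0 <- dim(pages[[1]]$pixels)
  slices <- lapply(pages, function(p) {
    if (!identical(dim(p$pixels), d0))
      stop("TIFF pages have inconsistent shapes")
    px <- p$pixels
    bd <- if (p$float) "float" else as.character(p$bits)
    norm <- p$float
    if (normalize && !p$float) {
      px <- px / (2^p$bits - 1)
      norm <- TRUE
      bd <- "float"
    }
    image_slice(px, pixel_pitch = pixel_pitch, bit_depth = bd,
                normalized = norm)
  })
  image_stack(slices, z_step = z_step)
}

#' Write a Z-stack as a multi-page TIFF
#'
#' Normalized stacks written to an integer bit depth are scaled to full
#' range (x 255 or x 65535) and rounded; `"float"` writes IEEE 32-bit
#' losslessly up to single precision.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @param bit_depth `"8"`, `"16"` (default) or `"float"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bit_depth = "16") {
  stopifnot(inherits(stack, "image_stack"))
  scale <- if (stack$slices[[1]]$normalized && bit_depth != "float")
    2^as.integer(bit_depth) - 1 else 1
  mats <- lapply(stack$slices, function(s) s$pixels * scale)
  write_tiff_pages(mats, path, bit_depth)
  invisible(path)
}

#' Normalize a slice to the unit interval
#'
#' Integer bit depths divide by the container full scale (255 or 65535);
#' float slices are clipped to `[0, 1]`.
#'
#' @param slice an [image_slice()].
#' @return a normalized `image_slice`.
#' @export
normalize_slice <- function(slice) {
  stopifnot(inherits(slice, "image_slice"))
  if (slice$normalized) return(slice)
  px <- if (slice$bit_depth == "float") clip01(slice$pixels)
        else slice$pixels / (2^as.integer(slice$bit_depth) - 1)
  image_slice(px, pixel_pitch = slice$pixel_pitch, bit_depth = "float",
              normalized = TRUE)
}

cube_sidecar <- function(path) paste0(path, ".json")

#' Read a hyperspectral Raman cube
#'
#' The cube is stored as a float TIFF with one page per wavenumber plane and
#' a JSON sidecar (`<path>.json`) carrying the wavenumber axis and the
#' excitation wavelength.
#'
#' @param path TIFF path written by [write_cube()].
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path) {
  pages <- read_tiff_pages(path)
  side <- cube_sidecar(path)
  if (!file.exists(side)) stop("cube sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (length(meta$wavenumbers) != length(pages))
    stop("wavenumber axis length does not match number of spectral planes")
  d <- dim(pages[[1]]$pixels)
  arr <- array(0, c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]$pixels
  spectral_cube(arr, meta$wavenumbers, excitation_nm = meta$excitation_nm)
}

#' Write a hyperspectral Raman cube
#'
#' @param cube a [spectral_cube()].
#' @param path output TIFF; the axis goes to a JSON sidecar `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  mats <- lapply(seq_along(cube$wavenumbers),
                 function(k) cube$data[, , k, drop = TRUE])
  write_tiff_pages(mats, path, "float")
  jsonlite::write_json(list(wavenumbers = cube$wavenumbers,
                            excitation_nm = cube$excitation_nm),
                       cube_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
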