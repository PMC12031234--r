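# 3D reconstruction: Z interpolation, maximum intensity projections and the
# projection renderings (top view, side view, orthogonal triptych).

#' Linear Z interpolation of a stack
#'
#' Inserts `factor - 1` linearly interpolated planes between every pair of
#' neighboring slices; the output has `(n - 1) * factor + 1` slices and
#' `z_step / factor` spacing. Axial interpolation of spherical objects
#' elongates them toward cylinders — use for display, not measurement.
#'
#' @param stack an [image_stack()] with >= 2 slices (>= 1 if `factor == 1`).
#' @param factor integer >= 1; 1 is the identity.
#' @return an `image_stack`.
#' @export
interpolate_z <- function(stack, factor = 1) {
  stopifnot(inherits(stack, "image_stack"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(stack)
  n <- length(stack$slices)
  if (n < 2) stop("need at least 2 slices to interpolate")
  out <- vector("list", (n - 1) * factor + 1)
  t <- 1
  for (k in seq_len(n - 1)) {
    a <- stack$slices[[k]]$pixels; b <- stack$slices[[k + 1]]$pixels
    for (j in 0:(factor - 1)) {
      w <- j / factor
      out[[t]] <- as_slice_like(stack$slices[[k]], (1 - w) * a + w * b)
      t <- t + 1
    }
  }
  out[[t]] <- stack$slices[[n]]
  image_stack(out, z_step = stack$z_step / factor)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum along the chosen axis. `Z` gives the top view
#' (rows x cols); `X` and `Y` give side views whose first dimension is Z —
#' the physical aspect ratio `z_step / pixel_pitch` is attached as
#' attribute `"aspect"` for display scaling.
#'
#' @param stack a non-empty [image_stack()].
#' @param axis `"Z"` (default), `"X"` or `"Y"`.
#' @return an [image_slice()] (projection).
#' @export
max_intensity_projection <- function(stack, axis = c("Z", "X", "Y")) {
  stopifnot(inherits(stack, "image_stack"))
  axis <- match.arg(axis)
  arr <- stack_to_array(stack)
  pp <- stack$slices[[1]]$pixel_pitch
  proj <- switch(axis,
    Z = apply(arr, c(2, 3), max),
    Y = apply(arr, c(1, 3), max),  # Z x cols (view along rows)
    X = apply(arr, c(1, 2), max))  # Z x rows (view along cols)
  s <- image_slice(proj, pixel_pitch = pp,
                   normalized = stack$slices[[1]]$normalized)
  if (axis != "Z") attr(s, "aspect") <- stack$z_step / pp
  s
}

scale_rows <- function(m, factor) {
  if (factor <= 1) return(m)
  m[rep(seq_len(nrow(m)), each = factor), , drop = FALSE]
}

#' Render projection views of a volume
#'
#' Writes the top-view maximum intensity projection, the side-view
#' projection (Z axis stretched to physical proportions by nearest-neighbor
#' row replication) and an orthogonal triptych (top + both side views on
#' one canvas) as 16-bit grayscale TIFFs. Purely presentational;
#' deterministic for fixed input.
#'
#' @param stack a normalized [image_stack()].
#' @param output_dir directory for `mip_top.tiff`, `mip_side_x.tiff`,
#'   `mip_side_y.tiff`, `triptych.tiff`.
#' @return named character vector of the written paths, invisibly.
#' @export
render_volume <- function(stack, output_dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  top <- max_intensity_projection(stack, "Z")
  sx <- max_intensity_projection(stack, "X")
  sy <- max_intensity_projection(stack, "Y")
  fac <- max(1L, as.integer(round(stack$z_step /
                                    stack$slices[[1]]$pixel_pitch)))
  sx_px <- scale_rows(sx$pixels, fac)
  sy_px <- scale_rows(sy$pixels, fac)
  paths <- c(top = file.path(output_dir, "mip_top.tiff"),
             side_x = file.path(output_dir, "mip_side_x.tiff"),
             side_y = file.path(output_dir, "mip_side_y.tiff"),
             triptych = file.path(output_dir, "triptych.tiff"))
  write_tiff_pages(list(top$pixels * 65535), paths["top"], "16")
  write_tiff_pages(list(sx_px * 65535), paths["side_x"], "16")
  write_tiff_pages(list(sy_px * 65535), paths["side_y"], "16")
  gap <- 4
  H <- nrow(top$pixels) + gap + nrow(sx_px)
  W <- ncol(top$pixels) + gap + nrow(stack$slices[[1]]$pixels) # sy cols = rows
  canvas <- matrix(0, H, max(W, ncol(sy_px) + gap + ncol(sx_px)))
  canvas[seq_len(nrow(top$pixels)), seq_len(ncol(top$pixels))] <- top$pixels
  r0 <- nrow(top$pixels) + gap
  canvas[r0 + seq_len(nrow(sx_px)), seq_len(ncol(sx_px))] <- sx_px
  c0 <- ncol(top$pixels) + gap
  canvas[r0 + seq_len(nrow(sy_px)), c0 + seq_len(ncol(sy_px))] <- sy_px
  write_tiff_pages(list(canvas * 65535), paths["triptych"], "16")
  invisible(paths)
}
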