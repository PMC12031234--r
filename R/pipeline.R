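# Config-driven end-to-end runs: phantom (or file) -> preprocessing -> DIP
# per slice -> postprocessing -> metrics -> projections, with a manifest
# that makes every random draw reconstructible. The three ablation variants
# (raw, DIP-only, DIP + pre/post) are expressed through the `enabled`
# switches of the preprocess/postprocess blocks.

#' Default pipeline configuration
#'
#' @param phantom a [phantom_spec()] (or `NULL` when `stack_path` is given).
#' @param stack_path path to a multi-page TIFF to process instead of a
#'   phantom.
#' @param reference_path optional background reference TIFF for file input.
#' @param preprocess_enabled,postprocess_enabled master ablation switches.
#' @param dip DIP settings as a [dip_config()].
#' @param median_kernel median window (odd; 0 or 1 disables).
#' @param roi apply the circular ROI mask to the contrast-equalization step.
#' @param clahe apply contrast-limited adaptive histogram equalization
#'   (off by default: it deliberately remaps intensities, which is wanted
#'   for visualization but not for quantitative comparison against truth).
#' @param morphology `"none"`, `"dilate"` or `"erode"` (postprocess).
#' @param low_cut,high_cut band-pass cutoffs in cycles/image; `NULL`
#'   `high_cut` defaults to 0.45 x image size (gentle high-frequency
#'   noise suppression below Nyquist).
#' @param reference_convention metric reference: `"clean_truth"` (phantom
#'   runs) or `"noisy_input"` (the instrument convention).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = standard_phantom_spec(),
                            stack_path = NULL, reference_path = NULL,
                            preprocess_enabled = TRUE,
                            postprocess_enabled = TRUE,
                            dip = dip_config(seed = 42),
                            median_kernel = 3, roi = FALSE, clahe = FALSE,
                            morphology = "none", low_cut = 0,
                            high_cut = NULL,
                            reference_convention = NULL) {
  if (is.null(reference_convention))
    reference_convention <- if (is.null(stack_path)) "clean_truth"
                            else "noisy_input"
  structure(list(
    input = list(phantom = phantom, stack_path = stack_path,
                 reference_path = reference_path),
    preprocess = list(enabled = preprocess_enabled,
                      background_subtraction = TRUE,
                      median_kernel = median_kernel, roi = roi,
                      clahe = clahe, clahe_clip = 0.01, clahe_tiles = 8),
    dip = dip,
    postprocess = list(enabled = postprocess_enabled, bandpass = TRUE,
                       low_cut = low_cut, high_cut = high_cut,
                       morphology = morphology, morph_radius = 1),
    metrics = list(reference_convention = reference_convention)),
    class = "pipeline_config")
}

apply_preprocess <- function(stack, reference, pp) {
  out <- stack$slices
  for (k in seq_along(out)) {
    s <- out[[k]]
    if (isTRUE(pp$background_subtraction) && !is.null(reference))
      s <- subtract_background(s, reference$slices[[k]])
    if (pp$median_kernel > 1) s <- median_filter(s, pp$median_kernel)
    if (isTRUE(pp$clahe)) {
      mask <- if (isTRUE(pp$roi)) circular_roi_mask(dim(s$pixels)) else NULL
      s <- adaptive_hist_eq(s, mask, clip_limit = pp$clahe_clip,
                            tile_grid = pp$clahe_tiles)
    }
    out[[k]] <- s
  }
  image_stack(out, z_step = stack$z_step)
}

apply_postprocess <- function(stack, pp) {
  n <- nrow(stack$slices[[1]]$pixels)
  hc <- if (is.null(pp$high_cut)) 0.45 * n else pp$high_cut
  out <- stack$slices
  for (k in seq_along(out)) {
    s <- out[[k]]
    if (isTRUE(pp$bandpass)) s <- bandpass_filter(s, pp$low_cut, hc)
    if (pp$morphology %in% c("dilate", "erode"))
      s <- morph_refine(s, pp$morphology, pp$morph_radius)
    out[[k]] <- s
  }
  image_stack(out, z_step = stack$z_step)
}

#' Run the full enhancement pipeline
#'
#' Generates or loads the input stack, applies the preprocessing chain,
#' fits DIP per slice with early stopping, applies postprocessing, computes
#' the per-slice metric report, writes projections, and records a manifest
#' (config, seeds, package version) so the run is exactly reproducible.
#'
#' @param config a [pipeline_config()].
#' @param output_dir run directory; created. `NULL` skips all file output.
#' @param progress print per-slice progress.
#' @return a `pipeline_run` list: `denoised`, `input` (noisy), `reference`
#'   stack used by the metrics, `report` (a `metric_report`), `config`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config, output_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  # --- ingest ---------------------------------------------------------
  if (!is.null(config$input$stack_path)) {
    noisy <- read_stack(config$input$stack_path, normalize = TRUE)
    reference <- if (!is.null(config$input$reference_path))
      read_stack(config$input$reference_path, normalize = TRUE) else NULL
    clean <- NULL
  } else {
    vol <- generate_spheroid_phantom(config$input$phantom)
    noisy <- vol$noisy
    reference <- vol$background
    clean <- vol$clean
  }
  # --- preprocess -----------------------------------------------------
  pre <- if (isTRUE(config$preprocess$enabled))
    apply_preprocess(noisy, reference, config$preprocess) else noisy
  # --- DIP ------------------------------------------------------------
  denoised <- denoise_stack(pre, config$dip, progress = progress)
  dip_results <- attr(denoised, "results")
  # --- postprocess ----------------------------------------------------
  post <- if (isTRUE(config$postprocess$enabled))
    apply_postprocess(denoised, config$postprocess) else denoised
  # --- metrics --------------------------------------------------------
  conv <- config$metrics$reference_convention
  refstack <- if (conv == "clean_truth" && !is.null(clean)) clean else noisy
  report <- qc_curves(refstack, post, reference_convention = conv)
  run <- structure(list(denoised = post, input = noisy,
                        reference = refstack, report = report,
                        dip_results = dip_results, config = config,
                        output_dir = output_dir),
                   class = "pipeline_run")
  # --- outputs --------------------------------------------------------
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_stack(post, file.path(output_dir, "denoised.tiff"),
                bit_depth = "float")
    write_metric_report(report, file.path(output_dir, "metrics.csv"))
    render_volume(post, output_dir)
    traces <- do.call(rbind, lapply(seq_along(dip_results), function(k)
      data.frame(slice = k - 1L,
                 iteration = seq_along(dip_results[[k]]$loss_trace),
                 loss = dip_results[[k]]$loss_trace)))
    write.csv(traces, file.path(output_dir, "loss_traces.csv"),
              row.names = FALSE)
    manifest <- list(
      package = "lsraman",
      version = as.character(utils::packageVersion("lsraman")),
      config = serialize_config(config),
      slice_seeds = config$dip$seed + seq_len(length(noisy$slices)) - 1L,
      aggregate = as.list(report$aggregate))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
  }
  run
}

serialize_config <- function(config) {
  cf <- unclass(config)
  if (!is.null(cf$input$phantom)) cf$input$phantom <- unclass(cf$input$phantom)
  cf$dip <- unclass(cf$dip)
  cf
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file with the same nesting as [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- if (!is.null(j$input$phantom))
    do.call(phantom_spec, j$input$phantom[setdiff(names(j$input$phantom),
                                                  "pixel_pitch")])
  else NULL
  dipc <- if (!is.null(j$dip)) do.call(dip_config, as.list(j$dip))
          else dip_config(seed = 42)
  cfg <- pipeline_config(
    phantom = ph, stack_path = j$input$stack_path,
    reference_path = j$input$reference_path, dip = dipc)
  for (blk in c("preprocess", "postprocess", "metrics"))
    for (nm in names(j[[blk]])) cfg[[blk]][[nm]] <- j[[blk]][[nm]]
  cfg
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d slices, reference %s\n",
              length(x$denoised$slices),
              x$report$reference_convention))
  print(round(x$report$aggregate, 4))
  invisible(x)
}

#' Compare two pipeline runs
#'
#' Side-by-side aggregate PSNR/SSIM/RMSE/FRC of two runs on the same input,
#' with deltas (B - A) — the format of a raw-versus-enhanced evaluation
#' table.
#'
#' @param run_a,run_b `pipeline_run` objects over the same input stack.
#' @return data.frame with one row per metric: `run_a`, `run_b`, `delta`.
#' @export
compare_runs <- function(run_a, run_b) {
  stopifnot(inherits(run_a, "pipeline_run"), inherits(run_b, "pipeline_run"))
  da <- dim(run_a$input$slices[[1]]$pixels)
  db <- dim(run_b$input$slices[[1]]$pixels)
  if (!identical(da, db) ||
      length(run_a$input$slices) != length(run_b$input$slices))
    stop("runs are not over the same input")
  m <- names(run_a$report$aggregate)
  data.frame(metric = m,
             run_a = as.numeric(run_a$report$aggregate[m]),
             run_b = as.numeric(run_b$report$aggregate[m]),
             delta = as.numeric(run_b$report$aggregate[m] -
                                  run_a$report$aggregate[m]))
}
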