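# Deep Image Prior: fit a randomly initialized encoder-decoder CNN (fixed
# random input z) to a single noisy slice by minimizing ||f_theta(z) - Y||^2
# and keep the output at the early-stopping iteration. The network's
# inductive bias fits structure before noise, so stopping on the smoothed-
# loss plateau yields the denoised image without any training data.

#' Configuration of the Deep Image Prior denoiser
#'
#' @param depth encoder/decoder levels (each halves the resolution).
#' @param base_channels feature channels per convolution.
#' @param skip_channels channels carried across each skip connection.
#' @param input_channels channels of the fixed random input `z`.
#' @param input_noise_std standard deviation of the entries of `z`.
#' @param iterations_max optimization budget per slice. Deliberately tight:
#'   the network fits image structure within the first few hundred
#'   iterations and starts reproducing noise texture afterwards, which the
#'   training loss cannot detect (it keeps decreasing); the cap is the
#'   second half of the early-stopping strategy next to the smoothed-loss
#'   plateau rule.
#' @param learning_rate Adam step size.
#' @param window moving-average window (iterations) for the smoothed loss.
#' @param min_delta minimum smoothed-loss improvement over one window.
#' @param patience consecutive below-`min_delta` checks before stopping.
#' @param seed RNG seed for weights and `z`.
#' @return a `dip_config` object.
#' @export
dip_config <- function(depth = 4, base_channels = 16, skip_channels = 4,
                       input_channels = 16, input_noise_std = 0.1,
                       iterations_max = 300, learning_rate = 0.01,
                       window = 50, min_delta = 1e-5, patience = 3,
                       seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (iterations_max < 1) stop("iterations_max must be >= 1")
  if (learning_rate <= 0 || input_noise_std <= 0)
    stop("rates must be positive")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 skip_channels = as.integer(skip_channels),
                 input_channels = as.integer(input_channels),
                 input_noise_std = input_noise_std,
                 iterations_max = as.integer(iterations_max),
                 learning_rate = learning_rate,
                 window = as.integer(window), min_delta = min_delta,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "dip_config")
}

# Shapes of every learnable tensor, in the order the optimizer consumes
# them. Each hidden conv block owns four tensors: kernel (Cout x Cin*k^2),
# bias, and the instance-norm scale/shift (gamma, beta); the 1x1 sigmoid
# head has kernel + bias only. Block order: per encoder level conv(3x3,
# stride 2) + conv(3x3) + skip conv(1x1, absent at the deepest level), then
# per decoder level conv(3x3) x 2 on the upsampled + skip concatenation,
# then the output head.
dip_param_shapes <- function(config) {
  D <- config$depth; C <- config$base_channels; S <- config$skip_channels
  Zc <- config$input_channels
  shapes <- list()
  add <- function(cout, cin, k, norm = TRUE) {
    shapes[[length(shapes) + 1]] <<- list(dim = c(cout, cin * k * k),
                                          init = "randn")
    shapes[[length(shapes) + 1]] <<- list(dim = cout, init = "zeros")
    if (norm) {
      shapes[[length(shapes) + 1]] <<- list(dim = cout, init = "ones")
      shapes[[length(shapes) + 1]] <<- list(dim = cout, init = "zeros")
    }
  }
  for (l in seq_len(D)) {
    add(C, if (l == 1) Zc else C, 3)
    add(C, C, 3)
    if (l < D) add(S, C, 1)  # deepest level feeds the decoder directly
  }
  for (j in seq_len(D)) {
    L <- D - j  # resolution level produced
    add(C, C + if (L >= 1) S else 0, 3)
    add(C, C, 3)
  }
  add(1, C, 1, norm = FALSE)
  shapes
}

#' Number of learnable parameters of a DIP network
#' @param config a [dip_config()].
#' @return integer parameter count.
#' @export
dip_param_count <- function(config) {
  sum(vapply(dip_param_shapes(config), function(s) prod(s$dim), numeric(1)))
}

# He-style kernel initialization; biases and norm shifts start at zero,
# norm scales at one. All random draws come from R's RNG so config$seed
# fixes the network bit-for-bit.
dip_init_weights <- function(config) {
  lapply(dip_param_shapes(config), function(s) {
    switch(s$init,
           randn = matrix(rnorm(prod(s$dim), 0, sqrt(2 / s$dim[2])),
                          s$dim[1], s$dim[2]),
           zeros = numeric(s$dim),
           ones = rep(1, s$dim))
  })
}

dip_make_z <- function(config, H, W) {
  matrix(rnorm(config$input_channels * H * W, 0, config$input_noise_std),
         config$input_channels, H * W)
}

pad_reflect_to <- function(px, Hp, Wp) {
  H <- nrow(px); W <- ncol(px)
  ridx <- c(seq_len(H), rev(seq_len(H)))[((seq_len(Hp) - 1) %% (2 * H)) + 1]
  cidx <- c(seq_len(W), rev(seq_len(W)))[((seq_len(Wp) - 1) %% (2 * W)) + 1]
  px[ridx, cidx, drop = FALSE]
}

#' Build an (untrained) DIP network
#'
#' Materializes the fixed random input `z` and the seeded initial weights
#' for an image of the given shape; spatial dimensions are reflect-padded
#' up to a multiple of `2^depth`.
#'
#' @param config a [dip_config()].
#' @param image_shape `c(rows, cols)`.
#' @return a `dip_network` list with `z`, `weights`, padded shape and a
#'   `forward()`-able state (see [dip_network_forward()]).
#' @export
build_network <- function(config, image_shape) {
  stopifnot(inherits(config, "dip_config"))
  H <- image_shape[1]; W <- image_shape[2]
  m <- 2^config$depth
  Hp <- as.integer(ceiling(H / m) * m)
  Wp <- as.integer(ceiling(W / m) * m)
  if (Hp / m < 1 || Wp / m < 1)
    stop("image too small for the requested depth")
  set.seed(config$seed)
  weights <- dip_init_weights(config)
  z <- dip_make_z(config, Hp, Wp)
  structure(list(config = config, z = z, weights = weights,
                 shape = c(H, W), padded_shape = c(Hp, Wp)),
            class = "dip_network")
}

#' Forward pass of a DIP network
#'
#' @param net a `dip_network` from [build_network()].
#' @return the network output as a matrix of the original (unpadded) shape;
#'   values lie strictly in `(0, 1)` (sigmoid head).
#' @export
dip_network_forward <- function(net) {
  stopifnot(inherits(net, "dip_network"))
  Hp <- net$padded_shape[1]; Wp <- net$padded_shape[2]
  y <- dip_forward_cpp(net$z, Hp, Wp, net$weights,
                       list(depth = net$config$depth,
                            base_channels = net$config$base_channels,
                            skip_channels = net$config$skip_channels))
  matrix(y, Hp, Wp)[seq_len(net$shape[1]), seq_len(net$shape[2]),
                    drop = FALSE]
}

#' Early-stopping decision on a loss trace
#'
#' The smoothed loss is the trailing moving average over `window`
#' iterations. A check at iteration `t` (possible once `t >= 2 * window`)
#' measures the improvement `smoothed[t - window] - smoothed[t]`; when the
#' improvement stays below `min_delta` for `patience` consecutive checks,
#' optimization stops. The iteration to keep is the argmin of the smoothed
#' loss seen so far.
#'
#' @param loss_trace numeric vector of per-iteration losses.
#' @param rule list with `window`, `min_delta`, `patience` (defaults from
#'   [dip_config()]).
#' @return list with `stop` (logical), `stop_iteration` (first iteration at
#'   which the rule fires, `NA` if never) and `keep_iteration` (argmin of
#'   the smoothed loss up to the stop, or over the whole trace).
#' @export
early_stop_check <- function(loss_trace, rule = list(window = 50,
                                                     min_delta = 1e-5,
                                                     patience = 3)) {
  w <- rule$window
  n <- length(loss_trace)
  sm <- rep(NA_real_, n)
  if (n >= w)
    for (t in w:n) sm[t] <- mean(loss_trace[(t - w + 1):t])
  plateau <- 0L
  stop_it <- NA_integer_
  for (t in seq_len(n)) {
    if (t >= 2 * w) {
      impr <- sm[t - w] - sm[t]
      plateau <- if (impr < rule$min_delta) plateau + 1L else 0L
      if (plateau >= rule$patience) { stop_it <- t; break }
    }
  }
  upto <- if (is.na(stop_it)) n else stop_it
  keep <- if (all(is.na(sm[seq_len(upto)]))) upto
          else which.min(sm[seq_len(upto)])
  list(stop = !is.na(stop_it), stop_iteration = stop_it,
       keep_iteration = keep, smoothed = sm)
}

#' Fit the Deep Image Prior to one slice
#'
#' Minimizes the mean squared error between the network output and the
#' (noisy) target with Adam; the fixed input `z` is drawn once from
#' `config$seed` and never updated. Returns the output snapshotted at the
#' iteration with the lowest smoothed loss (the early-stop keep point), the
#' full loss trace, and the stopping diagnostics.
#'
#' @param target a normalized [image_slice()] with no non-finite values.
#' @param config a [dip_config()].
#' @return a `dip_result` with elements `denoised` (image_slice in
#'   `[0, 1]`), `loss_trace`, `smoothed_loss`, `stop_iteration`,
#'   `keep_iteration`, `stopped_early`, `config`.
#' @export
fit_dip <- function(target, config = dip_config()) {
  check_slice(target, "target")
  if (!target$normalized) stop("target must be normalized to [0, 1]")
  if (any(!is.finite(target$pixels))) stop("target contains non-finite values")
  net <- build_network(config, dim(target$pixels))
  Hp <- net$padded_shape[1]; Wp <- net$padded_shape[2]
  tp <- pad_reflect_to(target$pixels, Hp, Wp)
  res <- dip_fit_cpp(as.vector(tp), Hp, Wp, net$z, net$weights,
                     list(depth = config$depth,
                          base_channels = config$base_channels,
                          skip_channels = config$skip_channels,
                          iterations_max = config$iterations_max,
                          learning_rate = config$learning_rate,
                          window = config$window,
                          min_delta = config$min_delta,
                          patience = config$patience))
  den <- matrix(res$output, Hp, Wp)[seq_len(dim(target$pixels)[1]),
                                    seq_len(dim(target$pixels)[2]),
                                    drop = FALSE]
  structure(list(denoised = as_slice_like(target, clip01(den)),
                 loss_trace = res$loss_trace,
                 smoothed_loss = res$smoothed,
                 stop_iteration = res$stop_iteration,
                 keep_iteration = res$keep_iteration,
                 stopped_early = res$stopped_early,
                 config = config),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf(
    "<dip_result> %d iterations (kept %d%s), final loss %.3g\n",
    x$stop_iteration, x$keep_iteration,
    if (x$stopped_early) ", early stop" else "",
    x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Denoise every slice of a stack with DIP
#'
#' Slices are fitted independently; slice `k` uses seed
#' `config$seed + k - 1` so a stack run is reproducible and slices do not
#' share their random input.
#'
#' @param stack a normalized [image_stack()].
#' @param config a [dip_config()].
#' @param progress print a line per slice.
#' @return an `image_stack` of denoised slices (same shape and z-step); the
#'   per-slice `dip_result`s are attached as attribute `"results"`.
#' @export
denoise_stack <- function(stack, config = dip_config(), progress = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  results <- vector("list", length(stack$slices))
  out <- vector("list", length(stack$slices))
  for (k in seq_along(stack$slices)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k - 1L
    r <- tryCatch(fit_dip(stack$slices[[k]], cfg_k), error = function(e)
      stop("DIP failed on slice ", k, ": ", conditionMessage(e)))
    results[[k]] <- r
    out[[k]] <- r$denoised
    if (progress)
      message(sprintf("slice %d/%d: %d iters, loss %.3g", k,
                      length(stack$slices), r$stop_iteration,
                      r$loss_trace[length(r$loss_trace)]))
  }
  res <- image_stack(out, z_step = stack$z_step)
  attr(res, "results") <- results
  res
}
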