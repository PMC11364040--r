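#' Configuration of the 3D U-Net denoiser
#'
#' The denoiser is a volumetric U-Net: a contracting path of
#' conv / LeakyReLU / 2x max-pool blocks, a single conv bottleneck, and
#' an expanding path of 2x upsample / skip-concatenation / two
#' conv-LeakyReLU blocks per level, closed by a single-filter output
#' convolution. It is fully convolutional, so a model trained on patches
#' denoises whole maps of any size.
#'
#' @param depth levels in each path (default 5).
#' @param base_filters filters per convolution (default 16).
#' @param kernel odd convolution kernel edge (default 3).
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @param upsample_mode upsampling interpolation; `"nearest"` is the
#'   implemented mode (cheap and checkerboard-free when followed by
#'   convolutions).
#' @param seed weight-initialization seed.
#' @return A `denoiser_config`.
#' @export
denoiser_config <- function(depth = 5L, base_filters = 16L, kernel = 3L,
                            leaky_slope = 0.01, upsample_mode = "nearest",
                            seed = 42L) {
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  kernel <- as.integer(kernel)
  if (depth < 1L) stop("`depth` must be >= 1")
  if (base_filters < 1L) stop("`base_filters` must be >= 1")
  if (kernel < 1L || kernel %% 2L == 0L) stop("`kernel` must be odd")
  if (!identical(upsample_mode, "nearest"))
    stop("only `upsample_mode = \"nearest\"` is implemented")
  structure(
    list(depth = depth, base_filters = base_filters, kernel = kernel,
         leaky_slope = leaky_slope, upsample_mode = upsample_mode,
         seed = as.integer(seed)),
    class = "denoiser_config")
}

# He-style normal init for one conv layer, drawn from the current RNG
init_conv <- function(k, cin, cout) {
  w <- stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / (cin * k^3)))
  dim(w) <- c(k, k, k, cin, cout)
  list(w = w, b = numeric(cout))
}

# ordered layer plan: list of (name, cin, cout) for every convolution
unet_layer_plan <- function(cfg) {
  f <- cfg$base_filters
  plan <- list()
  for (i in seq_len(cfg$depth))
    plan[[length(plan) + 1L]] <-
      list(name = paste0("enc", i), cin = if (i == 1L) 1L else f, cout = f)
  plan[[length(plan) + 1L]] <- list(name = "bottleneck", cin = f, cout = f)
  for (i in rev(seq_len(cfg$depth))) {
    plan[[length(plan) + 1L]] <-
      list(name = paste0("dec", i, "a"), cin = 2L * f, cout = f)
    plan[[length(plan) + 1L]] <-
      list(name = paste0("dec", i, "b"), cin = f, cout = f)
  }
  plan[[length(plan) + 1L]] <- list(name = "out", cin = f, cout = 1L)
  plan
}

#' Build a denoiser with freshly initialized weights
#'
#' Weight initialization is fully determined by `cfg$seed`: two builds
#' from the same config have bit-identical parameters.
#'
#' @param cfg a [denoiser_config()].
#' @return A `denoiser` object holding the parameter store and config.
#' @examples
#' d <- build_denoiser(denoiser_config(depth = 2, base_filters = 4))
#' count_parameters(d)
#' @export
build_denoiser <- function(cfg = denoiser_config()) {
  plan <- unet_layer_plan(cfg)
  params <- list()
  withr_seed(cfg$seed, {
    for (layer in plan) {
      init <- init_conv(cfg$kernel, layer$cin, layer$cout)
      params[[paste0("w_", layer$name)]] <- init$w
      params[[paste0("b_", layer$name)]] <- init$b
    }
  })
  structure(list(params = params, config = cfg), class = "denoiser")
}

#' Number of trainable parameters
#' @param d a `denoiser`.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(d) {
  sum(vapply(d$params, length, integer(1)))
}

#' @export
print.denoiser <- function(x, ...) {
  cat(sprintf("<denoiser: depth %d, %d base filters, kernel %d^3, %d parameters>\n",
              x$config$depth, x$config$base_filters, x$config$kernel,
              count_parameters(x)))
  invisible(x)
}

leaky_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

leaky_bwd <- function(pre, g, slope) {
  g[pre < 0] <- g[pre < 0] * slope
  g
}

# forward pass on a (nx, ny, nz) array whose axes are multiples of
# 2^depth; returns the output array and, optionally, the cache needed
# for backpropagation
unet_forward <- function(d, x, keep_cache = FALSE) {
  cfg <- d$config
  pr <- d$params
  sl <- cfg$leaky_slope
  dim(x) <- c(dim(x), 1L)
  if (any(dim(x)[1:3] %% (2L^cfg$depth) != 0L))
    stop("input axes must be multiples of 2^depth = ", 2L^cfg$depth)
  cache <- list(x = x)
  h <- x
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    nm <- paste0("enc", i)
    cache[[paste0("in_", nm)]] <- h
    a <- conv3d_fwd(h, pr[[paste0("w_", nm)]], pr[[paste0("b_", nm)]])
    cache[[paste0("pre_", nm)]] <- a
    z <- leaky_fwd(a, sl)
    skips[[i]] <- z
    pooled <- maxpool3d_fwd(z)
    cache[[paste0("pool_", nm)]] <- pooled$argmax
    cache[[paste0("pooldim_", nm)]] <- dim(z)
    h <- pooled$y
  }
  cache$in_bottleneck <- h
  a <- conv3d_fwd(h, pr$w_bottleneck, pr$b_bottleneck)
  cache$pre_bottleneck <- a
  h <- leaky_fwd(a, sl)
  for (i in rev(seq_len(cfg$depth))) {
    up <- upsample3d_fwd(h)
    cache[[paste0("updim_", i)]] <- dim(h)
    skip <- skips[[i]]
    cat_ <- c(up, skip)
    dim(cat_) <- c(dim(up)[1:3], dim(up)[4] + dim(skip)[4])
    for (part in c("a", "b")) {
      nm <- paste0("dec", i, part)
      cache[[paste0("in_", nm)]] <- cat_
      a <- conv3d_fwd(cat_, pr[[paste0("w_", nm)]], pr[[paste0("b_", nm)]])
      cache[[paste0("pre_", nm)]] <- a
      cat_ <- leaky_fwd(a, sl)
    }
    h <- cat_
  }
  cache$in_out <- h
  y <- conv3d_fwd(h, pr$w_out, pr$b_out)
  out <- y
  dim(out) <- dim(y)[1:3]
  if (keep_cache) list(y = out, cache = cache) else list(y = out)
}

# backpropagate d(loss)/d(output) through the cached forward pass;
# returns gradients named like the parameter store
unet_backward <- function(d, cache, gy) {
  cfg <- d$config
  pr <- d$params
  sl <- cfg$leaky_slope
  grads <- list()
  gskips <- vector("list", cfg$depth)
  dim(gy) <- c(dim(gy), 1L)
  bw <- conv3d_bwd(cache$in_out, pr$w_out, gy)
  grads$w_out <- bw$gw; grads$b_out <- bw$gb
  g <- bw$gx
  # decoder, shallowest level first (reverse of the forward order)
  for (i in seq_len(cfg$depth)) {
    for (part in c("b", "a")) {
      nm <- paste0("dec", i, part)
      g <- leaky_bwd(cache[[paste0("pre_", nm)]], g, sl)
      bw <- conv3d_bwd(cache[[paste0("in_", nm)]], pr[[paste0("w_", nm)]], g)
      grads[[paste0("w_", nm)]] <- bw$gw
      grads[[paste0("b_", nm)]] <- bw$gb
      g <- bw$gx
    }
    # split the concatenation gradient: first block of channels is the
    # upsampled path, the rest is the skip connection
    dcat <- dim(g)
    updim <- cache[[paste0("updim_", i)]]
    nup <- updim[4]
    half <- prod(dcat[1:3]) * nup
    gup <- g[seq_len(half)]
    dim(gup) <- c(dcat[1:3], nup)
    gskips[[i]] <- g[-seq_len(half)]
    dim(gskips[[i]]) <- c(dcat[1:3], dcat[4] - nup)
    g <- upsample3d_bwd(gup, updim)
  }
  g <- leaky_bwd(cache$pre_bottleneck, g, sl)
  bw <- conv3d_bwd(cache$in_bottleneck, pr$w_bottleneck, g)
  grads$w_bottleneck <- bw$gw; grads$b_bottleneck <- bw$gb
  g <- bw$gx
  # encoder, deepest level first, accumulating the skip gradients
  for (j in rev(seq_len(cfg$depth))) {
    nm <- paste0("enc", j)
    g <- maxpool3d_bwd(cache[[paste0("pool_", nm)]], g,
                       cache[[paste0("pooldim_", nm)]])
    g <- g + gskips[[j]]
    g <- leaky_bwd(cache[[paste0("pre_", nm)]], g, sl)
    bw <- conv3d_bwd(cache[[paste0("in_", nm)]], pr[[paste0("w_", nm)]], g)
    grads[[paste0("w_", nm)]] <- bw$gw
    grads[[paste0("b_", nm)]] <- bw$gb
    g <- bw$gx
  }
  grads
}

# reflection-padding index vector taking an axis of length n to `target`
reflect_index <- function(n, target) {
  pad <- target - n
  if (pad == 0L) return(seq_len(n))
  if (pad > n - 1L)
    stop("volume too small to reflect-pad: axis of ", n,
         " cannot be padded by ", pad, " voxels")
  c(seq_len(n), seq.int(n - 1L, n - pad))
}

#' Denoise a whole map with a trained model
#'
#' The network is fully convolutional, so maps of any size are accepted:
#' the volume is reflection-padded up to the next multiple of
#' `2^depth` per axis (reflection avoids the dark-border artifacts of
#' zero padding), passed through the network, and cropped back. Voxel
#' size and origin are preserved. Deterministic given fixed weights.
#'
#' @param d a trained (or freshly built) `denoiser`.
#' @param v a [volume_grid()].
#' @return The denoised [volume_grid()] of identical shape.
#' @export
denoise_volume <- function(d, v) {
  stopifnot(inherits(d, "denoiser"), is_volume_grid(v))
  m <- 2L^d$config$depth
  dims <- dim(v$values)
  target <- as.integer(ceiling(dims / m) * m)
  x <- v$values[reflect_index(dims[1], target[1]),
                reflect_index(dims[2], target[2]),
                reflect_index(dims[3], target[3]), drop = FALSE]
  y <- unet_forward(d, x)$y
  out <- y[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
  as_volume_like(out, v)
}

#' Save / load a denoiser checkpoint
#'
#' A checkpoint is a single RDS file carrying the parameter store, the
#' architecture config and optional training metadata, so a model is
#' always reloadable without external context.
#'
#' @param d a `denoiser`.
#' @param path checkpoint file path.
#' @param meta optional list of training metadata to embed.
#' @return `save_checkpoint` returns `path`; `load_checkpoint` the
#'   restored `denoiser` (metadata in attribute `"meta"`).
#' @export
save_checkpoint <- function(d, path, meta = NULL) {
  saveRDS(list(params = d$params, config = d$config, meta = meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  d <- structure(list(params = ck$params, config = ck$config),
                 class = "denoiser")
  attr(d, "meta") <- ck$meta
  d
}
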