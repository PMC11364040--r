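#' Specification for a synthetic half-map set
#'
#' Parameters of the synthetic ground-truth / half-map generator used to
#' exercise the whole toolchain. The generator emulates the statistical
#' structure of deposited half-map pairs: a common density `S`, two maps
#' `M_i = S + N_i` with independent noise whose per-shell power is
#' controlled (optionally to a target spectral SNR), a soft spherical
#' mask, and optionally "denoised-like" maps `D_i = S + B + a N_i` with
#' an injected shared bias field `B`.
#'
#' @param shape cubic side in voxels (default 64).
#' @param voxel_size Angstrom per voxel.
#' @param n_blobs number of Gaussian blobs in the phantom.
#' @param blob_width range (Angstrom) of blob standard deviations.
#' @param amplitude range of blob peak amplitudes.
#' @param noise `"white"` (flat spectrum, scale `noise_sd`) or
#'   `"ssnr"` (per-shell noise power set so the spectral SNR equals
#'   `ssnr`).
#' @param noise_sd white-noise standard deviation.
#' @param ssnr target spectral signal-to-noise ratio; scalar (flat) or
#'   one value per shell.
#' @param bias_ratio target per-shell `var(B) / var(S)` for
#'   [inject_bias()]; `NA` selects the low-pass bias mode instead.
#' @param bias_scale overall bias amplitude in low-pass mode, as
#'   `sqrt(var(B) / var(S))` over the whole map.
#' @param bias_smoothness real-space Gaussian width (Angstrom) of the
#'   low-pass bias field; large values concentrate the bias at low
#'   frequency, mirroring the low-frequency bias typical of learned
#'   sharpening models.
#' @param leftover leftover-noise factor `a` in `D_i = S + B + a N_i`.
#' @param seed integer seed; every random draw of the generator is a
#'   deterministic function of it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(shape = 64L, voxel_size = 1.0, n_blobs = 40L,
                           blob_width = c(2, 6), amplitude = c(0.5, 2),
                           noise = c("white", "ssnr"), noise_sd = 1.0,
                           ssnr = 1.0, bias_ratio = NA_real_,
                           bias_scale = 0.5, bias_smoothness = 8,
                           leftover = 0.5, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(shape >= 8L, voxel_size > 0, n_blobs >= 0L,
            all(blob_width > 0), noise_sd >= 0, all(ssnr > 0),
            bias_scale >= 0, bias_smoothness > 0, leftover >= 0)
  structure(
    list(shape = as.integer(shape), voxel_size = voxel_size,
         n_blobs = as.integer(n_blobs), blob_width = blob_width,
         amplitude = amplitude, noise = noise, noise_sd = noise_sd,
         ssnr = ssnr, bias_ratio = bias_ratio, bias_scale = bias_scale,
         bias_smoothness = bias_smoothness, leftover = leftover,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

# shell index (1-based, unbounded) for every Fourier voxel, incl. corners
# beyond Nyquist -- used to shape noise spectra over the full grid
extended_shell_ids <- function(n) {
  k2 <- fft_freq_index(n)^2
  shell <- as.integer(round(sqrt(outer(outer(k2, k2, `+`), k2, `+`))))
  dim(shell) <- c(n, n, n)
  shell + 1L
}

# per-extended-shell mean Fourier power of a complex FFT array
extended_shell_power <- function(f, ids) {
  s <- rowsum(as.numeric(Re(f * Conj(f))), group = as.vector(ids))
  out <- numeric(max(ids))
  out[as.integer(rownames(s))] <- s[, 1L] / tabulate(ids, nbins = max(ids))
  out
}

#' Generate a Gaussian-blob ground-truth density
#'
#' Sum of `n_blobs` isotropic Gaussian blobs with seeded centres inside
#' the central 2/3 of the box and widths/amplitudes drawn from the
#' configured ranges; a stand-in for a noise-free macromolecular density.
#'
#' @param spec a [synthetic_spec()].
#' @return A [volume_grid()].
#' @export
make_phantom <- function(spec) {
  n <- spec$shape
  if (min(spec$blob_width) / spec$voxel_size < 1)
    stop("blob width below one voxel cannot be represented")
  vals <- array(0, c(n, n, n))
  if (spec$n_blobs > 0L) {
    withr_seed(spec$seed, {
      lo <- n / 6; hi <- n * 5 / 6
      cx <- stats::runif(spec$n_blobs, lo, hi)
      cy <- stats::runif(spec$n_blobs, lo, hi)
      cz <- stats::runif(spec$n_blobs, lo, hi)
      w  <- stats::runif(spec$n_blobs, spec$blob_width[1], spec$blob_width[2]) /
        spec$voxel_size
      a  <- stats::runif(spec$n_blobs, spec$amplitude[1], spec$amplitude[2])
    })
    ax <- seq_len(n)
    for (i in seq_len(spec$n_blobs)) {
      gx <- exp(-(ax - cx[i])^2 / (2 * w[i]^2))
      gy <- exp(-(ax - cy[i])^2 / (2 * w[i]^2))
      gz <- exp(-(ax - cz[i])^2 / (2 * w[i]^2))
      vals <- vals + a[i] * outer(outer(gx, gy), gz)
    }
  }
  out <- volume_grid(vals, voxel_size = spec$voxel_size)
  if (spec$n_blobs > 0L)
    attr(out, "blobs") <- data.frame(x = cx, y = cy, z = cz,
                                     width_voxels = w, amplitude = a)
  out
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# assigning results into the caller's frame
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  eval.parent(substitute(expr))
}

#' Soft spherical mask covering the phantom region
#'
#' A raised-cosine-edged sphere of the given fractional radius, centred
#' in the box.
#'
#' @param shape cubic side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param radius_frac sphere radius as a fraction of the half-side.
#' @param edge_width soft-edge width in voxels (0 for a binary mask).
#' @return A [volume_grid()] with values in `[0, 1]`.
#' @export
make_mask <- function(shape, voxel_size = 1.0, radius_frac = 0.9,
                      edge_width = 3) {
  n <- as.integer(shape)
  c0 <- (n + 1) / 2
  d2 <- (seq_len(n) - c0)^2
  r <- sqrt(outer(outer(d2, d2, `+`), d2, `+`))
  r0 <- radius_frac * n / 2
  if (edge_width > 0) {
    m <- pmin(pmax((r0 - r) / edge_width + 0.5, 0), 1)
    m <- (1 - cos(pi * m)) / 2
  } else {
    m <- (r <= r0) * 1.0
  }
  volume_grid(array(m, c(n, n, n)), voxel_size = voxel_size)
}

# draw one real white-noise field and shape its per-shell Fourier power
# to `target` (indexed by extended shell id); returns the real field
shaped_noise_field <- function(n, target, ids, seed) {
  withr_seed(seed, w <- stats::rnorm(n^3))
  dim(w) <- c(n, n, n)
  fw <- stats::fft(w)
  pw <- extended_shell_power(fw, ids)
  scale <- sqrt(target / pmax(pw, 1e-300))
  fw <- fw * array(scale[ids], dim(ids))
  Re(stats::fft(fw, inverse = TRUE)) / n^3
}

#' Generate a pair of half-maps around a ground truth
#'
#' Adds two independent noise fields to the truth: `M_i = S + N_i`. In
#' `"ssnr"` mode the noise is Fourier-shaped per shell so the realized
#' spectral SNR `var(S, s) / var(N, s)` hits the requested target, which
#' makes the expected half-map FSC equal `ssnr / (1 + ssnr)` per shell.
#' Realized spectra are recorded in the same per-shell mean-power
#' convention as [shell_covariance()].
#'
#' @param truth a [volume_grid()] ground truth (see [make_phantom()]).
#' @param spec a [synthetic_spec()].
#' @return A `synthetic_set`: `truth`, `m1`, `m2`, `mask`, `partition`,
#'   and realized `var_S`, `var_N` per shell.
#' @export
make_half_maps <- function(truth, spec) {
  n <- spec$shape
  stopifnot(identical(dim(truth$values), c(n, n, n)))
  ids <- extended_shell_ids(n)
  p <- build_shell_partition(c(n, n, n), spec$voxel_size)
  ps <- extended_shell_power(stats::fft(truth$values), ids)
  if (spec$noise == "ssnr") {
    q <- rep_len(spec$ssnr, length(ps))
    if (any(ps[seq_len(p$n_shells)] <= 0))
      stop("unreachable SSNR: truth has zero power in some shell")
    target <- ps / q
  } else {
    # flat spectrum: white noise of variance noise_sd^2 has mean Fourier
    # power noise_sd^2 * n^3 in the unnormalized FFT convention
    target <- rep(spec$noise_sd^2 * n^3, length(ps))
  }
  n1 <- shaped_noise_field(n, target, ids, seed = spec$seed + 1001L)
  n2 <- shaped_noise_field(n, target, ids, seed = spec$seed + 2002L)
  if (spec$noise == "white" && spec$noise_sd == 0) n1 <- n2 <- array(0, c(n, n, n))
  m1 <- as_volume_like(truth$values + n1, truth)
  m2 <- as_volume_like(truth$values + n2, truth)
  in_band <- seq_len(p$n_shells)
  var_n1 <- extended_shell_power(stats::fft(n1), ids)[in_band]
  var_n2 <- extended_shell_power(stats::fft(n2), ids)[in_band]
  structure(
    list(truth = truth, m1 = m1, m2 = m2,
         mask = make_mask(n, spec$voxel_size),
         partition = p, spec = spec,
         var_S = ps[in_band], var_N = (var_n1 + var_n2) / 2),
    class = "synthetic_set")
}

#' Inject a shared bias field to form "denoised-like" maps
#'
#' Produces `D_i = S + B + a N_i`, with one shared random bias field `B`
#' (independent of `S` and of both noise fields) and the leftover-noise
#' factor `a` from the spec. With `bias_ratio` set, `B` is Fourier-shaped
#' so that `var(B, s) = bias_ratio * var(S, s)` per shell; otherwise `B`
#' is low-pass-filtered white noise (Gaussian width `bias_smoothness`)
#' scaled so its total variance is `bias_scale^2` times the truth's,
#' concentrating the bias at low frequency.
#'
#' @param set a `synthetic_set` from [make_half_maps()].
#' @param spec the [synthetic_spec()] (defaults to the set's own).
#' @return The set extended with `d1`, `d2`, `bias` and realized `var_B`.
#' @export
inject_bias <- function(set, spec = set$spec) {
  n <- spec$shape
  ids <- extended_shell_ids(n)
  a <- spec$leftover
  if (!is.na(spec$bias_ratio)) {
    if (spec$bias_ratio > 0) {
      ps <- extended_shell_power(stats::fft(set$truth$values), ids)
      b <- shaped_noise_field(n, spec$bias_ratio * ps, ids,
                              seed = spec$seed + 7007L)
    } else {
      b <- array(0, c(n, n, n))
    }
  } else {
    withr_seed(spec$seed + 7007L, w <- stats::rnorm(n^3))
    dim(w) <- c(n, n, n)
    fw <- stats::fft(w)
    freq <- (ids - 1L) / (n * spec$voxel_size)   # 1/Angstrom per voxel
    env <- exp(-2 * pi^2 * spec$bias_smoothness^2 *
                 array(freq, dim(ids))^2)
    b <- Re(stats::fft(fw * env, inverse = TRUE)) / n^3
    b <- b * spec$bias_scale * stats::sd(set$truth$values) /
      max(stats::sd(b), 1e-300)
  }
  noise1 <- set$m1$values - set$truth$values
  noise2 <- set$m2$values - set$truth$values
  set$d1 <- as_volume_like(set$truth$values + b + a * noise1, set$truth)
  set$d2 <- as_volume_like(set$truth$values + b + a * noise2, set$truth)
  set$bias <- as_volume_like(b, set$truth)
  in_band <- seq_len(set$partition$n_shells)
  set$var_B <- extended_shell_power(stats::fft(b), ids)[in_band]
  set
}
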