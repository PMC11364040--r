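# Independent oracles and small generators shared across tests.

# deterministic random volume
rand_volume <- function(n, seed, voxel_size = 1) {
  set.seed(seed)
  volume_grid(array(rnorm(n^3), c(n, n, n)), voxel_size = voxel_size)
}

# naive all-voxel FSC oracle: visits every Fourier voxel in a plain
# triple loop and accumulates per-shell sums, independent of the
# package's shell bookkeeping
oracle_fsc <- function(a, b) {
  n <- dim(a)[1]
  fa <- fft(a)
  fb <- fft(b)
  kidx <- ifelse(0:(n - 1) > n %/% 2, 0:(n - 1) - n, 0:(n - 1))
  ns <- n %/% 2 + 1
  num <- pa <- pb <- numeric(ns)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    s <- round(sqrt(kidx[i]^2 + kidx[j]^2 + kidx[k]^2))
    if (s <= n %/% 2) {
      f1 <- fa[i, j, k]; f2 <- fb[i, j, k]
      num[s + 1] <- num[s + 1] + Re(f1 * Conj(f2))
      pa[s + 1] <- pa[s + 1] + Mod(f1)^2
      pb[s + 1] <- pb[s + 1] + Mod(f2)^2
    }
  }
  num / sqrt(pa * pb)
}

# naive per-shell covariance oracle (same loop, mean Hermitian product)
oracle_shell_cov <- function(a, b) {
  n <- dim(a)[1]
  fa <- fft(a)
  fb <- fft(b)
  kidx <- ifelse(0:(n - 1) > n %/% 2, 0:(n - 1) - n, 0:(n - 1))
  ns <- n %/% 2 + 1
  num <- cnt <- numeric(ns)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    s <- round(sqrt(kidx[i]^2 + kidx[j]^2 + kidx[k]^2))
    if (s <= n %/% 2) {
      num[s + 1] <- num[s + 1] + Re(fa[i, j, k] * Conj(fb[i, j, k]))
      cnt[s + 1] <- cnt[s + 1] + 1
    }
  }
  num / cnt
}

# synthetic half-map set under the spectral-SNR study conditions
ssnr_set <- function(shape = 64, ssnr = 1, seed = 7, ...) {
  spec <- synthetic_spec(shape = shape, noise = "ssnr", ssnr = ssnr,
                         seed = seed, ...)
  make_half_maps(make_phantom(spec), spec)
}

# small white-noise training dataset of matched patch pairs
white_patch_dataset <- function(n_maps = 8, shape = 64, edge = 32,
                                noise_sd = 0.3, seed0 = 100,
                                n_patches = 60) {
  out <- list()
  for (i in seq_len(n_maps)) {
    spec <- synthetic_spec(shape = shape, noise = "white",
                           noise_sd = noise_sd, seed = seed0 + i)
    set <- make_half_maps(make_phantom(spec), spec)
    out <- c(out, tile_patches(set$m1, set$m2, NULL, edge,
                               paste0("map", i)))
  }
  out[seq_len(min(n_patches, length(out)))]
}
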