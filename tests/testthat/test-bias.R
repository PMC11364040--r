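test_that("shell covariance matches definition, bilinearity and oracle", {
  n <- 16
  a <- rand_volume(n, seed = 61)
  b <- rand_volume(n, seed = 62)
  p <- build_shell_partition(c(n, n, n), 1)
  caa <- shell_covariance(a, a, p)
  expect_true(all(caa >= 0))
  neg <- volume_grid(-a$values, 1)
  expect_equal(shell_covariance(a, neg, p)[-1], -caa[-1])
  # naive oracle on the non-DC shells (DC uses real-space covariance)
  expect_equal(shell_covariance(a, b, p)[-1],
               oracle_shell_cov(a$values, b$values)[-1], tolerance = 1e-12)
})

test_that("independent noise fields have near-zero shell covariance", {
  n <- 64
  a <- rand_volume(n, seed = 63)
  b <- rand_volume(n, seed = 64)
  p <- build_shell_partition(c(n, n, n), 1)
  cab <- shell_covariance(a, b, p)
  va <- shell_covariance(a, a, p)
  vb <- shell_covariance(b, b, p)
  big <- p$n_per_shell >= 100
  expect_true(all(abs(cab[big]) <=
                    4 * sqrt(va[big] * vb[big] / p$n_per_shell[big])))
})

test_that("identical half-maps decompose into pure signal", {
  n <- 16
  x <- rand_volume(n, seed = 65)
  p <- build_shell_partition(c(n, n, n), 1)
  d <- decompose_noisy(x, x, p)
  expect_equal(d$var_N, rep(0, p$n_shells))
  expect_equal(d$var_S[-1], shell_covariance(x, x, p)[-1])
})

test_that("decomposition recovers generated signal and noise spectra", {
  # half-maps with var(N) = var(S)/4 per shell (spectral SNR 4)
  set <- ssnr_set(shape = 64, ssnr = 4, seed = 71)
  p <- set$partition
  d <- decompose_noisy(set$m1, set$m2, p)
  big <- which(p$n_per_shell >= 500)
  # per-shell sampling bound on the cross-term noise of cov(M1, M2):
  # var ~ (2 var_S var_N + var_N^2) / n_s
  se_s <- sqrt((2 * set$var_S * set$var_N + set$var_N^2) / p$n_per_shell)
  expect_true(all(abs(d$var_S - set$var_S)[big] <= 4 * se_s[big]))
  expect_true(all(abs(d$var_N - set$var_N)[big] <=
                    4 * set$var_N[big] * sqrt(2 / p$n_per_shell[big])))
  # aggregate ratio over the well-populated band
  expect_equal(mean((d$var_S / d$var_N)[big]), 4, tolerance = 0.1)
})

test_that("pure noise yields signal variance within sampling bounds of 0", {
  n <- 64
  spec <- synthetic_spec(shape = n, noise = "white", noise_sd = 1,
                         n_blobs = 0, seed = 73)
  truth <- make_phantom(spec)
  set <- make_half_maps(truth, spec)
  p <- set$partition
  d <- decompose_noisy(set$m1, set$m2, p)
  big <- p$n_per_shell >= 100
  expect_true(all(abs(d$var_S[big]) <=
                    4 * d$var_N[big] / sqrt(p$n_per_shell[big])))
})

test_that("reconstruction closure: var_S + var_N equals mean half-map power", {
  set <- ssnr_set(shape = 32, ssnr = 1, seed = 75)
  p <- set$partition
  d <- decompose_noisy(set$m1, set$m2, p)
  half_power <- (shell_covariance(set$m1, set$m1, p) +
                   shell_covariance(set$m2, set$m2, p)) / 2
  expect_equal(d$var_S + d$var_N, half_power, tolerance = 1e-12)
})

test_that("identity denoiser gives exactly zero bias and unchanged noise", {
  set <- ssnr_set(shape = 32, ssnr = 1, seed = 77)
  p <- set$partition
  v <- decompose_denoised(set$m1, set$m2, set$m1, set$m2, p)
  expect_equal(v$var_B, rep(0, p$n_shells))
  expect_equal(v$var_Nd, v$var_N)
  r <- ratio_curves(v)
  expect_true(all(r$bias_floored))
  expect_equal(r$snr[-1], (v$var_S_clamped / v$var_N_clamped)[-1])
})

test_that("perfect denoiser gives near-zero bias and leftover noise", {
  spec <- synthetic_spec(shape = 64, noise = "ssnr", ssnr = 1, seed = 79,
                         bias_ratio = 0, leftover = 0)
  set <- inject_bias(make_half_maps(make_phantom(spec), spec))
  p <- set$partition
  expect_equal(set$d1$values, set$truth$values, tolerance = 1e-12)
  v <- decompose_denoised(set$m1, set$m2, set$d1, set$d2, p)
  big <- p$n_per_shell >= 500
  expect_true(all(abs(v$var_B[big]) <=
                    4 * v$var_S[big] / sqrt(p$n_per_shell[big])))
  expect_equal(v$var_Nd, rep(0, p$n_shells), tolerance = 1e-10)
})

test_that("four-covariance combination cancels cross terms by construction", {
  # plug D_i = S + B + a N_i with arbitrary *correlated* S and B draws:
  # the var_B formula must still return <BB> + (a-1)(<BN1> + <BN2>) +
  # (1-a)^2 <N1N2>, i.e. no <SB> or <SS> residue
  n <- 16
  s <- rand_volume(n, seed = 81)
  b <- volume_grid(0.5 * s$values + rand_volume(n, seed = 82)$values, 1)
  n1 <- rand_volume(n, seed = 83)
  n2 <- rand_volume(n, seed = 84)
  a <- 0.3
  p <- build_shell_partition(c(n, n, n), 1)
  m1 <- volume_grid(s$values + n1$values, 1)
  m2 <- volume_grid(s$values + n2$values, 1)
  d1 <- volume_grid(s$values + b$values + a * n1$values, 1)
  d2 <- volume_grid(s$values + b$values + a * n2$values, 1)
  v <- decompose_denoised(m1, m2, d1, d2, p)
  expected <- shell_covariance(b, b, p) +
    (a - 1) * (shell_covariance(b, n1, p) + shell_covariance(b, n2, p)) +
    (1 - a)^2 * shell_covariance(n1, n2, p)
  expect_equal(v$var_B[-1], expected[-1], tolerance = 1e-10)
})

test_that("ratio curves floor clamped denominators and flag them", {
  v <- structure(list(
    var_S = c(0, 2, 2), var_N = c(0, 2, -1), var_B = c(0, 0, 1),
    var_Nd = c(0, 1, 1),
    var_S_clamped = c(0, 2, 2), var_N_clamped = c(0, 2, 0),
    var_B_clamped = c(0, 0, 1), var_Nd_clamped = c(0, 1, 1),
    freq_axis = c(0, 0.1, 0.2), n_per_shell = c(1, 10, 20)),
    class = "variance_spectra")
  r <- ratio_curves(v, floor = 1e-6)
  expect_equal(r$snr[2], 1)
  expect_equal(r$snr[3], 2 / 1e-6)
  expect_true(r$snr_floored[3])
  expect_true(r$bias_floored[2])
  expect_equal(r$signal_to_bias[3], 2)
  expect_error(ratio_curves(v, floor = 0))
})

test_that("shared spectral shrinkage trips the independence flag", {
  set <- ssnr_set(shape = 64, ssnr = 1, seed = 85)
  p <- set$partition
  shrink <- function(m, c0) {
    ids <- crefdenoise:::extended_shell_ids(64)
    cc <- rep(1, max(ids))
    cc[seq(max(ids) %/% 2, max(ids))] <- c0
    f <- fft(m$values) * array(cc[ids], dim(ids))
    volume_grid(Re(fft(f, inverse = TRUE)) / 64^3, m$voxel_size)
  }
  d1 <- shrink(set$m1, 0.4)
  d2 <- shrink(set$m2, 0.4)
  diag <- shrinkage_diagnostic(set$m1, set$m2, d1, d2, p)
  expect_true(diag$violated)
  # an honest denoiser (independent bias model) must not be flagged
  spec2 <- synthetic_spec(shape = 64, noise = "ssnr", ssnr = 1, seed = 85,
                          bias_ratio = 0.25, leftover = 0.5)
  set2 <- inject_bias(make_half_maps(make_phantom(spec2), spec2))
  diag2 <- shrinkage_diagnostic(set2$m1, set2$m2, set2$d1, set2$d2, p)
  expect_false(diag2$violated)
})

test_that("spectra TSV carries all documented columns", {
  set <- ssnr_set(shape = 32, ssnr = 1, seed = 87)
  v <- decompose_denoised(set$m1, set$m2, set$m1, set$m2, set$partition)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_spectra_tsv(v, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_named(df, c("shell", "frequency_invA", "var_S", "var_N", "var_B",
                     "var_Nd", "snr", "signal_to_bias", "flags"))
  expect_equal(df$var_S, v$var_S)
})
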