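test_that("shell partition covers the in-band Fourier grid exactly once", {
  p <- build_shell_partition(c(8, 8, 8), 1)
  expect_equal(p$n_shells, 5L)
  # shell 0 is exactly the DC voxel
  expect_equal(p$n_per_shell[1], 1L)
  expect_equal(which(p$shell_of_voxel == 1L), 1L)
  for (n in c(8L, 16L, 21L)) {
    p <- build_shell_partition(c(n, n, n), 1)
    in_band <- sum(!is.na(p$shell_of_voxel))
    expect_equal(sum(p$n_per_shell), in_band)
    expect_true(all(p$n_per_shell > 0))
    expect_true(all(diff(p$freq_axis) > 0))
  }
})

test_that("frequency axis reaches Nyquist", {
  p <- build_shell_partition(c(32, 32, 32), voxel_size = 1.0)
  expect_equal(p$freq_axis[17], 0.5)
  p2 <- build_shell_partition(c(32, 32, 32), voxel_size = 1.25)
  expect_equal(p2$freq_axis[17], 0.4)
})

test_that("non-cubic shapes are rejected with a geometry error", {
  expect_error(build_shell_partition(c(16, 16, 18), 1), "16 x 16 x 18")
  expect_error(build_shell_partition(c(4, 4, 4), 1), "at least 8")
})

test_that("FSC matches a naive all-voxel oracle", {
  for (n in c(16L, 24L)) {
    a <- rand_volume(n, seed = n)
    b <- rand_volume(n, seed = n + 1L)
    p <- build_shell_partition(c(n, n, n), 1)
    expect_lt(max(abs(compute_fsc(a, b, p)$values -
                        oracle_fsc(a$values, b$values))), 1e-10)
  }
})

test_that("FSC self-correlation, sign and scale behaviour", {
  n <- 16
  a <- rand_volume(n, seed = 3)
  b <- rand_volume(n, seed = 4)
  p <- build_shell_partition(c(n, n, n), 1)
  expect_equal(compute_fsc(a, a, p)$values, rep(1, p$n_shells))
  neg <- volume_grid(-a$values, a$voxel_size)
  expect_equal(compute_fsc(a, neg, p)$values, rep(-1, p$n_shells))
  scaled <- volume_grid(2.5 * a$values, a$voxel_size)
  expect_equal(compute_fsc(a, scaled, p)$values, rep(1, p$n_shells),
               tolerance = 1e-12)
  # symmetry and positive-scale invariance on distinct volumes
  f_ab <- compute_fsc(a, b, p)$values
  expect_equal(f_ab, compute_fsc(b, a, p)$values)
  expect_equal(f_ab, compute_fsc(volume_grid(7 * a$values), b, p)$values,
               tolerance = 1e-12)
})

test_that("independent white noise decorrelates within sampling bounds", {
  n <- 64
  a <- rand_volume(n, seed = 11)
  b <- rand_volume(n, seed = 12)
  p <- build_shell_partition(c(n, n, n), 1)
  f <- compute_fsc(a, b, p)
  big <- p$n_per_shell >= 100
  expect_true(all(abs(f$values[big]) <= 4 / sqrt(p$n_per_shell[big])))
})

test_that("degenerate and mismatched inputs error; dead shells return 0", {
  n <- 16
  a <- rand_volume(n, seed = 5)
  p <- build_shell_partition(c(n, n, n), 1)
  zero <- volume_grid(array(0, c(n, n, n)) + 0, 1)
  expect_error(compute_fsc(zero, zero, p), "zero power")
  b24 <- rand_volume(24, seed = 6)
  expect_error(compute_fsc(a, b24, p), "different shapes")
  # a constant volume has power only in shell 0: other shells are dead
  # and must return the defined sentinel 0, with a warning
  dc <- volume_grid(array(1, c(n, n, n)), 1)
  expect_warning(f <- compute_fsc(dc, dc, p), "zero power")
  expect_equal(f$values[1], 1)
  expect_true(all(f$values[-1] == 0))
})

test_that("integrated FSC sums non-DC shells", {
  mk <- function(v) structure(list(values = v), class = "fsc_curve")
  expect_equal(integrate_fsc(mk(rep(1, 49))), 48)
  expect_equal(integrate_fsc(mk(rep(0, 20))), 0)
  expect_equal(integrate_fsc(mk(rep(0.5, 17))), 8)
  expect_error(integrate_fsc(mk(numeric(1))), "non-DC")
})

test_that("Cref relation endpoints, exact half-power point, clamping", {
  expect_equal(cref_value(1), 1)
  expect_equal(cref_value(0), 0)
  expect_equal(cref_value(1 / 7), 0.5)
  expect_equal(cref_value(-0.3), 0)
  f <- seq(0, 1, by = 0.01)
  expect_true(all(diff(cref_value(f)) >= 0))
})

test_that("Cref loss is zero at the fixed point and linear in offsets", {
  n <- 16
  a <- rand_volume(n, seed = 21)
  p <- build_shell_partition(c(n, n, n), 1)
  # identical half-maps: Cref = 1, FSC_FD(mean, mean) = 1
  expect_equal(cref_loss(NULL, a, a, a, p), 0)
  # an externally supplied Cref offset by 0.1 from a perfect FSC_FD
  cr <- cref_from_fsc_half(compute_fsc(a, a, p))
  cr$values <- cr$values - 0.1
  expect_equal(cref_loss(NULL, a, a, a, p, cref = cr), 0.1)
})

test_that("Cref loss gradient matches finite differences", {
  n <- 8
  ha <- rand_volume(n, seed = 31)
  hb <- rand_volume(n, seed = 32)
  d0 <- rand_volume(n, seed = 33)$values
  p <- build_shell_partition(c(n, n, n), 1)
  L <- cref_loss(NULL, volume_grid(d0), ha, hb, p, grad = TRUE)
  g <- attr(L, "gradient")
  eps <- 1e-6
  set.seed(34)
  for (i in sample(n^3, 8)) {
    dp <- d0; dp[i] <- dp[i] + eps
    dm <- d0; dm[i] <- dm[i] - eps
    fd <- (as.numeric(cref_loss(NULL, volume_grid(dp), ha, hb, p)) -
           as.numeric(cref_loss(NULL, volume_grid(dm), ha, hb, p))) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("Cref loss validates the mean map against the half-maps", {
  n <- 16
  ha <- rand_volume(n, seed = 41)
  hb <- rand_volume(n, seed = 42)
  p <- build_shell_partition(c(n, n, n), 1)
  wrong <- volume_grid(ha$values, 1)   # not the average
  expect_error(cref_loss(wrong, ha, ha, hb, p), "not the average")
  avg <- volume_grid((ha$values + hb$values) / 2, 1)
  expect_silent(cref_loss(avg, ha, ha, hb, p))
})

test_that("curve TSV round-trips through the documented columns", {
  n <- 16
  a <- rand_volume(n, seed = 51)
  b <- rand_volume(n, seed = 52)
  p <- build_shell_partition(c(n, n, n), 1.3)
  crv <- compute_fsc(a, b, p)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curve_tsv(crv, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_named(df, c("shell_index", "frequency_invA", "resolution_A",
                     "value"))
  expect_equal(df$value, crv$values)
  back <- read_curve_tsv(path)
  expect_equal(back$values, crv$values)
  expect_equal(back$freq_axis, crv$freq_axis)
})
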