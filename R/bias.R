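#' Per-shell covariance of two volumes
#'
#' For each frequency shell `s >= 1`, the mean Hermitian product of the
#' two maps' Fourier coefficients,
#' `cov(s) = Re[(1/n_s) sum F_a(r) conj(F_b(r))]`,
#' with no mean subtraction: per-shell means of Fourier coefficients of
#' stationary fields vanish. The DC shell instead reports the
#' mean-subtracted real-space covariance of the two maps, since its
#' single Fourier voxel is just the (squared) map mean.
#'
#' @param a,b [volume_grid()] objects with matching geometry.
#' @param p matching [build_shell_partition()].
#' @return Numeric vector of per-shell covariances (length `p$n_shells`).
#' @examples
#' v <- volume_grid(array(rnorm(16^3), c(16, 16, 16)))
#' p <- build_shell_partition(dim(v$values))
#' all(shell_covariance(v, v, p)[-1] >= 0)
#' @export
shell_covariance <- function(a, b, p) {
  stop_if_geometry_mismatch(a, b)
  check_partition_match(a, p)
  fa <- stats::fft(a$values)
  fb <- stats::fft(b$values)
  cov <- shell_sums(Re(fa * Conj(fb)), p) / pmax(p$n_per_shell, 1L)
  cov[1L] <- stats::cov(as.numeric(a$values), as.numeric(b$values))
  cov
}

#' Signal and noise variance spectra from noisy half-maps
#'
#' With the half-map model `M_i = S + N_i` and independent noise
#' realizations, per shell:
#' `var(S) = cov(M1, M2)` and
#' `var(N) = (cov(M1, M1) + cov(M2, M2)) / 2 - cov(M1, M2)`.
#' Raw (possibly negative, from sampling noise) values are returned; the
#' clamped-at-zero versions used for ratio curves are attached alongside.
#'
#' @param m1,m2 the two half-maps.
#' @param p matching [build_shell_partition()].
#' @param mask optional mask applied to both maps before decomposition.
#' @return List with `var_S`, `var_N` (raw), `var_S_clamped`,
#'   `var_N_clamped`, `freq_axis`, `n_per_shell`.
#' @export
decompose_noisy <- function(m1, m2, p, mask = NULL) {
  m1 <- apply_mask(m1, mask); m2 <- apply_mask(m2, mask)
  c12 <- shell_covariance(m1, m2, p)
  c11 <- shell_covariance(m1, m1, p)
  c22 <- shell_covariance(m2, m2, p)
  var_s <- c12
  var_n <- (c11 + c22) / 2 - c12
  list(var_S = var_s, var_N = var_n,
       var_S_clamped = pmax(var_s, 0), var_N_clamped = pmax(var_n, 0),
       freq_axis = p$freq_axis, n_per_shell = p$n_per_shell)
}

#' Signal / noise / bias / leftover-noise decomposition
#'
#' Decomposes a quartet of maps -- two noisy half-maps `M_i = S + N_i`
#' and their independently denoised versions `D_i = S + B + N_i^d` --
#' into per-shell variance spectra. Assuming the bias `B` is shared
#' between the half-maps while `N`, `N^d` are independent of `S` and of
#' each other:
#' `var(B)  = cov(D1,D2) - cov(D1,M2) - cov(D2,M1) + cov(M1,M2)` and
#' `var(N^d) = (cov(D1,D1) + cov(D2,D2)) / 2 - cov(D1,D2)`;
#' `var(S)` and `var(N)` come from [decompose_noisy()]. The four-term
#' combination for `var(B)` cancels all cross terms exactly, so it does
#' not require `cov(S, B) = 0`.
#'
#' The independence assumptions fail when a denoiser shrinks both
#' half-maps by a shared per-shell factor (signal and noise dampened
#' together); see [shrinkage_diagnostic()] for the detection of that
#' regime.
#'
#' @param m1,m2 noisy half-maps.
#' @param d1,d2 the corresponding denoised half-maps.
#' @param p matching [build_shell_partition()].
#' @param mask optional mask applied to all four maps first.
#' @return A `variance_spectra` object: raw and clamped `var_S`, `var_N`,
#'   `var_B`, `var_Nd`, plus `freq_axis`, `n_per_shell` and an
#'   `assumptions` note.
#' @export
decompose_denoised <- function(m1, m2, d1, d2, p, mask = NULL) {
  m1 <- apply_mask(m1, mask); m2 <- apply_mask(m2, mask)
  d1 <- apply_mask(d1, mask); d2 <- apply_mask(d2, mask)
  noisy <- decompose_noisy(m1, m2, p)
  cd12 <- shell_covariance(d1, d2, p)
  cd11 <- shell_covariance(d1, d1, p)
  cd22 <- shell_covariance(d2, d2, p)
  cd1m2 <- shell_covariance(d1, m2, p)
  cd2m1 <- shell_covariance(d2, m1, p)
  cm12 <- noisy$var_S
  var_b <- cd12 - cd1m2 - cd2m1 + cm12
  var_nd <- (cd11 + cd22) / 2 - cd12
  structure(
    list(var_S = noisy$var_S, var_N = noisy$var_N,
         var_B = var_b, var_Nd = var_nd,
         var_S_clamped = pmax(noisy$var_S, 0),
         var_N_clamped = pmax(noisy$var_N, 0),
         var_B_clamped = pmax(var_b, 0),
         var_Nd_clamped = pmax(var_nd, 0),
         freq_axis = p$freq_axis, n_per_shell = p$n_per_shell,
         assumptions = paste(
           "var(B) and var(N^d) assume B independent of N and N^d,",
           "and S independent of N^d; shared per-shell shrinkage of both",
           "half-maps violates these (see shrinkage_diagnostic).")),
    class = "variance_spectra")
}

#' Signal-to-noise and signal-to-bias ratio curves
#'
#' Elementwise `var(S)/var(N)` and `var(S)/var(B)` on clamped spectra,
#' with the denominator floored at `floor` to keep the curves total;
#' shells whose denominator was floored are flagged.
#'
#' @param v a `variance_spectra` from [decompose_denoised()].
#' @param floor small positive denominator floor.
#' @return List with `snr`, `signal_to_bias`, logical flags
#'   `snr_floored`, `bias_floored`, and `freq_axis`.
#' @export
ratio_curves <- function(v, floor = 1e-12) {
  stopifnot(floor > 0)
  dn <- pmax(v$var_N_clamped, floor)
  db <- pmax(v$var_B_clamped, floor)
  list(snr = v$var_S_clamped / dn,
       signal_to_bias = v$var_S_clamped / db,
       snr_floored = v$var_N_clamped < floor,
       bias_floored = v$var_B_clamped < floor,
       freq_axis = v$freq_axis)
}

#' Detect correlated shrinkage of denoised half-maps
#'
#' If a denoiser multiplies both half-maps by a shared per-shell factor
#' `c(s) < 1` (signal and noise dampened together, as pure spectral
#' filters do), the independence assumptions behind the bias/leftover-
#' noise decomposition break and var(N^d) understates the leftover
#' noise. In that regime the denoised cross-covariance is fully
#' explained by the scaled input cross-covariance:
#' `cov(D1, D2) ~= c1(s) c2(s) cov(M1, M2)` with
#' `c_i(s) = cov(D_i, M_i) / cov(M_i, M_i)`. Shells where that identity
#' holds within `rel_tol` while `c < shrink_below` are flagged.
#'
#' @param m1,m2,d1,d2 the map quartet, as in [decompose_denoised()].
#' @param p matching [build_shell_partition()].
#' @param rel_tol relative agreement required to call a shell "explained
#'   by shrinkage".
#' @param shrink_below only factors below this count as shrinkage.
#' @param min_voxels shells with fewer Fourier voxels are too noisy to
#'   judge and are never flagged.
#' @return List with per-shell `c1`, `c2`, `rel_residual`, logical
#'   `flag`, and `violated` (`TRUE` if any shell is flagged).
#' @export
shrinkage_diagnostic <- function(m1, m2, d1, d2, p,
                                 rel_tol = 0.1, shrink_below = 0.95,
                                 min_voxels = 100L) {
  cm12 <- shell_covariance(m1, m2, p)
  c1 <- shell_covariance(d1, m1, p) / pmax(shell_covariance(m1, m1, p), 1e-300)
  c2 <- shell_covariance(d2, m2, p) / pmax(shell_covariance(m2, m2, p), 1e-300)
  cd12 <- shell_covariance(d1, d2, p)
  pred <- c1 * c2 * cm12
  rel <- abs(cd12 - pred) / pmax(abs(cd12), 1e-300)
  flag <- rel < rel_tol & c1 < shrink_below & c2 < shrink_below &
    p$n_per_shell >= min_voxels
  flag[1L] <- FALSE  # DC shell not informative
  list(c1 = c1, c2 = c2, rel_residual = rel, flag = flag,
       violated = any(flag), freq_axis = p$freq_axis)
}

#' Write variance spectra and ratio curves as TSV
#'
#' Columns: `shell`, `frequency_invA`, `var_S`, `var_N`, `var_B`,
#' `var_Nd`, `snr`, `signal_to_bias`, `flags` (semicolon-joined).
#'
#' @param v a `variance_spectra`.
#' @param path output TSV path.
#' @param floor ratio denominator floor, see [ratio_curves()].
#' @export
write_spectra_tsv <- function(v, path, floor = 1e-12) {
  r <- ratio_curves(v, floor)
  flags <- mapply(function(nf, bf) {
    f <- c(if (nf) "noise_floored", if (bf) "bias_floored")
    if (length(f)) paste(f, collapse = ";") else "."
  }, r$snr_floored, r$bias_floored)
  df <- data.frame(shell = seq_along(v$var_S) - 1L,
                   frequency_invA = v$freq_axis,
                   var_S = v$var_S, var_N = v$var_N,
                   var_B = v$var_B, var_Nd = v$var_Nd,
                   snr = r$snr, signal_to_bias = r$signal_to_bias,
                   flags = flags)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
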