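#' FSC-threshold resolution estimate
#'
#' Scans the curve outward from shell 1 and finds the first pair of
#' consecutive shells straddling the threshold ("first falls below");
#' the crossing frequency is linearly interpolated between the shell
#' centres and returned with its reciprocal resolution in Angstrom. A
#' curve re-rising above the threshold later is ignored. The usual
#' thresholds are 0.143 (half-map gold standard) and 0.5.
#'
#' @param c an `fsc_curve`.
#' @param threshold scalar in (0, 1).
#' @return A `resolution_estimate`: `threshold`, `crossed` (logical),
#'   `frequency` (1/Angstrom), `resolution` (Angstrom). When the curve
#'   never falls below the threshold, `crossed` is `FALSE` and the
#'   Nyquist limit (`2 * voxel_size`) is reported as the sentinel.
#' @examples
#' p <- build_shell_partition(c(64, 64, 64), 1)
#' crv <- structure(list(values = c(rep(1, 11), rep(0, 22)),
#'                       freq_axis = p$freq_axis, voxel_size = 1),
#'                  class = "fsc_curve")
#' fsc_threshold_resolution(crv, 0.5)$resolution  # 64 / 10.5
#' @export
fsc_threshold_resolution <- function(c, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  v <- c$values
  f <- c$freq_axis
  if (length(v) < 2L) stop("curve has fewer than 2 shells")
  est <- function(crossed, freq) {
    structure(list(threshold = threshold, crossed = crossed,
                   frequency = freq, resolution = 1 / freq),
              class = "resolution_estimate")
  }
  if (v[2L] < threshold) return(est(TRUE, f[2L]))
  for (s in seq.int(2L, length(v) - 1L)) {
    if (v[s] >= threshold && v[s + 1L] < threshold) {
      frac <- (v[s] - threshold) / (v[s] - v[s + 1L])
      return(est(TRUE, f[s] + frac * (f[s + 1L] - f[s])))
    }
  }
  # never fell below the threshold: resolution limited by Nyquist
  nyq <- f[length(f)]
  est(FALSE, nyq)
}

#' @export
print.resolution_estimate <- function(x, ...) {
  cat(sprintf("<FSC-%.3g resolution: %.3f A (%.4f 1/A)%s>\n",
              x$threshold, x$resolution, x$frequency,
              if (x$crossed) "" else ", no crossing (Nyquist limit)"))
  invisible(x)
}

#' RMSE between an FSC curve and a Cref curve
#'
#' Root-mean-square difference of the *squared* curves over non-DC
#' shells -- squaring keeps the comparison numerically stable where the
#' curves approach zero. This is the scalar used to judge how closely a
#' denoised map's FSC to the full-dataset map tracks the theoretical
#' noise-free target.
#'
#' @param fsc_fd `fsc_curve` between the half-map average and the
#'   denoised map.
#' @param cref `cref_curve` from the half-map FSC.
#' @return Scalar RMSE of the squared curves.
#' @export
rmse_fsc_to_cref <- function(fsc_fd, cref) {
  if (length(fsc_fd$values) != length(cref$values))
    stop("curve lengths differ: ", length(fsc_fd$values), " vs ",
         length(cref$values))
  d <- fsc_fd$values[-1L]^2 - cref$values[-1L]^2
  sqrt(mean(d^2))
}

#' Change in FSC-threshold resolution after denoising one half-map
#'
#' Convenience wrapper comparing the denoised-vs-noisy half-map pair
#' `(D2, M1)` with the noisy pair `(M1, M2)` at a common threshold
#' (0.5 by default). Negative values mean the denoised pair crosses at
#' higher frequency, i.e. improved resolution. When a mask is supplied,
#' it is applied to every input before each FSC computation (including
#' the denoised map).
#'
#' @param d2 denoised second half-map.
#' @param m1,m2 noisy half-maps.
#' @param p matching [build_shell_partition()].
#' @param mask optional mask.
#' @param threshold FSC threshold.
#' @return List with both `resolution_estimate`s and `change_A`
#'   (denoised minus noisy, Angstrom).
#' @export
fsc_resolution_change <- function(d2, m1, m2, p, mask = NULL,
                                  threshold = 0.5) {
  m1 <- apply_mask(m1, mask); m2 <- apply_mask(m2, mask)
  d2 <- apply_mask(d2, mask)
  noisy <- fsc_threshold_resolution(compute_fsc(m1, m2, p), threshold)
  den <- fsc_threshold_resolution(compute_fsc(d2, m1, p), threshold)
  list(noisy = noisy, denoised = den,
       change_A = den$resolution - noisy$resolution)
}
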