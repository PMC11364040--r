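#' Partition the Fourier grid into concentric frequency shells
#'
#' Assigns every Fourier voxel of a cubic `N^3` grid to the shell whose
#' index is the integer-rounded centred radius `round(|k|)` (in index
#' units). Shells run from 0 (the DC component) to `floor(N / 2)` (the
#' Nyquist shell); voxels beyond the Nyquist radius (the corners of the
#' Fourier cube) belong to no shell and are ignored by all shell
#' statistics. Shell `s` sits at spatial frequency `s / (N * voxel_size)`
#' cycles per Angstrom.
#'
#' @param shape integer length-3 voxel shape; must be cubic with side
#'   `N >= 8`.
#' @param voxel_size voxel edge in Angstrom.
#' @return A `shell_partition`: list with `shape`, `n_shells`,
#'   `shell_of_voxel` (integer array, 1-based shell id, `NA` beyond
#'   Nyquist), `n_per_shell`, `freq_axis` (1/Angstrom) and `voxel_size`.
#' @examples
#' p <- build_shell_partition(c(32, 32, 32), voxel_size = 1.0)
#' p$freq_axis[17]  # Nyquist: 0.5 cycles/Angstrom
#' @export
build_shell_partition <- function(shape, voxel_size = 1) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  n <- require_cubic(shape)
  if (n < 8L) stop("shell partition requires a side of at least 8 voxels")
  k <- fft_freq_index(n)
  k2 <- k^2
  r2 <- outer(outer(k2, k2, `+`), k2, `+`)
  shell <- as.integer(round(sqrt(r2)))
  n_shells <- n %/% 2L + 1L
  id <- ifelse(shell <= n %/% 2L, shell + 1L, NA_integer_)
  dim(id) <- c(n, n, n)
  counts <- tabulate(id, nbins = n_shells)
  structure(
    list(shape = c(n, n, n),
         n_shells = n_shells,
         shell_of_voxel = id,
         n_per_shell = counts,
         freq_axis = (seq_len(n_shells) - 1) / (n * voxel_size),
         voxel_size = as.numeric(voxel_size)),
    class = "shell_partition")
}

# centred frequency index along one axis for an unshifted FFT layout
fft_freq_index <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k > n %/% 2L, k - n, k)
}

# per-shell sums of a real-valued quantity on the Fourier grid
shell_sums <- function(x, p) {
  in_band <- !is.na(p$shell_of_voxel)
  s <- rowsum(as.numeric(x[in_band]),
              group = p$shell_of_voxel[in_band], reorder = TRUE)
  out <- numeric(p$n_shells)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

check_partition_match <- function(v, p) {
  if (!identical(dim(v$values), p$shape))
    stop("volume shape ", paste(dim(v$values), collapse = "x"),
         " does not match shell partition shape ",
         paste(p$shape, collapse = "x"))
  invisible(TRUE)
}

new_fsc_curve <- function(values, p, clamp = c(-1, 1)) {
  structure(
    list(values = pmin(pmax(values, clamp[1]), clamp[2]),
         freq_axis = p$freq_axis,
         n_per_shell = p$n_per_shell,
         voxel_size = p$voxel_size),
    class = "fsc_curve")
}

#' Fourier shell correlation between two volumes
#'
#' Per shell `s`, the normalized cross-correlation of the Fourier
#' coefficients of the two maps:
#' `FSC(s) = Re[sum F1 conj(F2)] / sqrt(sum |F1|^2 * sum |F2|^2)`,
#' the standard cryo-EM similarity curve. Values are clamped to
#' `[-1, 1]`; a shell in which either map has zero power gets the defined
#' value 0 (with a warning) so that curves stay total.
#'
#' @param a,b [volume_grid()] objects with identical geometry.
#' @param p a [build_shell_partition()] matching their shape.
#' @return An `fsc_curve`: `values`, `freq_axis`, `n_per_shell`.
#' @examples
#' v <- volume_grid(array(rnorm(16^3), c(16, 16, 16)))
#' p <- build_shell_partition(dim(v$values), v$voxel_size)
#' all(compute_fsc(v, v, p)$values == 1)
#' @export
compute_fsc <- function(a, b, p) {
  stop_if_geometry_mismatch(a, b)
  check_partition_match(a, p)
  fa <- stats::fft(a$values)
  fb <- stats::fft(b$values)
  num <- shell_sums(Re(fa * Conj(fb)), p)
  pa <- shell_sums(Re(fa * Conj(fa)), p)
  pb <- shell_sums(Re(fb * Conj(fb)), p)
  dead <- pa <= 0 | pb <= 0
  if (all(dead))
    stop("degenerate input: both volumes have zero power in every shell")
  if (any(dead))
    warning(sum(dead), " shell(s) with zero power; FSC set to 0 there")
  vals <- numeric(p$n_shells)
  vals[!dead] <- num[!dead] / sqrt(pa[!dead] * pb[!dead])
  new_fsc_curve(vals, p)
}

#' Integrated FSC score
#'
#' Sum of per-shell FSC values over shells 1 to Nyquist. The DC shell is
#' excluded: standardized maps have near-zero mean, which makes shell 0
#' numerically meaningless.
#'
#' @param c an `fsc_curve` (or `cref_curve`).
#' @return Scalar sum over non-DC shells.
#' @export
integrate_fsc <- function(c) {
  if (length(c$values) < 2L) stop("curve has no non-DC shells")
  sum(c$values[-1L])
}

#' Cref curve from a half-map FSC curve
#'
#' The Rosenthal-Henderson relation between the half-map FSC and the
#' expected correlation of the full-dataset map with a noise-free map:
#' `Cref = sqrt(2 F / (1 + F))`. The half-map FSC is clamped to `[0, 1]`
#' first; negative half-map correlations carry no signal and map to
#' `Cref = 0`.
#'
#' @param fsc_half an `fsc_curve` from the two half-maps.
#' @return A `cref_curve` with values in `[0, 1]` on the same frequency
#'   axis.
#' @examples
#' cref_value(1)    # 1: perfect half-map agreement
#' cref_value(1/7)  # 0.5: the gold-standard 0.143 threshold
#' @export
cref_from_fsc_half <- function(fsc_half) {
  structure(
    list(values = cref_value(fsc_half$values),
         freq_axis = fsc_half$freq_axis,
         n_per_shell = fsc_half$n_per_shell,
         voxel_size = fsc_half$voxel_size),
    class = "cref_curve")
}

#' @rdname cref_from_fsc_half
#' @param f numeric vector of half-map FSC values.
#' @export
cref_value <- function(f) {
  f <- pmin(pmax(f, 0), 1)
  sqrt(2 * f / (1 + f))
}

#' Cref training loss
#'
#' The self-supervised objective of the denoiser: the mean absolute
#' difference, over non-DC shells, between the Cref curve predicted from
#' the half-map FSC and `FSC_FD`, the FSC between the half-map average
#' (the denoiser input) and the denoised map. Zero loss means the
#' denoised map relates to the full-dataset map exactly as a noise-free
#' map should; `FSC_FD` above Cref indicates residual noise, below Cref
#' a loss of signal.
#'
#' @param mean_map the half-map average, as fed to the denoiser. If
#'   `NULL`, recomputed from `half_a` and `half_b`; if supplied it must
#'   equal that average to numerical tolerance.
#' @param denoised the denoiser output volume.
#' @param half_a,half_b the two half-maps.
#' @param p matching [build_shell_partition()].
#' @param cref optional externally supplied `cref_curve` (e.g. from a
#'   whole-map FSC); by default Cref is computed from `half_a`/`half_b`
#'   on this grid.
#' @param grad if `TRUE`, attach the analytic gradient of the loss with
#'   respect to every voxel of `denoised` as attribute `"gradient"`
#'   (a 3D array); this is the gradient used in network training.
#' @return Scalar loss (with optional `"gradient"` attribute).
#' @export
cref_loss <- function(mean_map, denoised, half_a, half_b, p,
                      cref = NULL, grad = FALSE) {
  stop_if_geometry_mismatch(half_a, half_b, "half-maps")
  stop_if_geometry_mismatch(half_a, denoised, "half-map and denoised map")
  check_partition_match(half_a, p)
  avg <- (half_a$values + half_b$values) / 2
  if (is.null(mean_map)) {
    mean_map <- as_volume_like(avg, half_a)
  } else {
    stop_if_geometry_mismatch(mean_map, half_a, "mean map and half-maps")
    tol <- 1e-4 * max(stats::sd(avg), 1e-12)
    if (max(abs(mean_map$values - avg)) > tol)
      stop("`mean_map` is not the average of the two half-maps")
  }
  if (is.null(cref)) {
    cref <- cref_from_fsc_half(compute_fsc(half_a, half_b, p))
  } else if (length(cref$values) != p$n_shells) {
    stop("supplied Cref curve length does not match the shell partition")
  }

  fm <- stats::fft(mean_map$values)
  fd <- stats::fft(denoised$values)
  num <- shell_sums(Re(fm * Conj(fd)), p)
  pm <- shell_sums(Re(fm * Conj(fm)), p)
  pd <- shell_sums(Re(fd * Conj(fd)), p)
  if (all(pm <= 0) || all(pd <= 0))
    stop("degenerate input: a volume has zero power in every shell")
  dead <- pm <= 0 | pd <= 0
  fsc_fd <- numeric(p$n_shells)
  fsc_fd[!dead] <- num[!dead] / sqrt(pm[!dead] * pd[!dead])
  keep <- seq.int(2L, p$n_shells)          # DC excluded
  diff <- cref$values[keep] - pmin(pmax(fsc_fd[keep], -1), 1)
  loss <- mean(abs(diff))

  if (grad) {
    ns <- length(keep)
    # dL/dFSC_FD(s), 0 for DC and for zero-power shells
    dfsc <- numeric(p$n_shells)
    dfsc[keep] <- -sign(diff) / ns
    dfsc[dead] <- 0
    # Wirtinger gradient wrt conj(F_d(r)), accumulated per shell:
    #   G = dL/dFSC * 0.5 * (F_m / sqrt(Pm Pd) - FSC * F_d / Pd)
    id <- p$shell_of_voxel
    coef_m <- coef_d <- numeric(p$n_shells)
    ok <- !dead
    coef_m[ok] <- dfsc[ok] * 0.5 / sqrt(pm[ok] * pd[ok])
    coef_d[ok] <- -dfsc[ok] * 0.5 * fsc_fd[ok] / pd[ok]
    am <- array(0, p$shape); ad <- array(0, p$shape)
    in_band <- !is.na(id)
    am[in_band] <- coef_m[id[in_band]]
    ad[in_band] <- coef_d[id[in_band]]
    g <- 2 * Re(stats::fft(am * fm + ad * fd, inverse = TRUE))
    attr(loss, "gradient") <- g
  }
  loss
}

#' Write a per-shell curve as a tab-separated table
#'
#' Columns: `shell_index` (0-based), `frequency_invA`, `resolution_A`
#' (reciprocal frequency; `Inf` at DC), `value`.
#'
#' @param curve an `fsc_curve` or `cref_curve`.
#' @param path output file path.
#' @export
write_curve_tsv <- function(curve, path) {
  freq <- curve$freq_axis
  df <- data.frame(
    shell_index = seq_along(curve$values) - 1L,
    frequency_invA = freq,
    resolution_A = ifelse(freq > 0, 1 / freq, Inf),
    value = curve$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a curve written by [write_curve_tsv()]
#' @param path TSV path.
#' @param voxel_size voxel size to record on the curve (Angstrom).
#' @return An `fsc_curve`.
#' @export
read_curve_tsv <- function(path, voxel_size = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(
    list(values = df$value, freq_axis = df$frequency_invA,
         n_per_shell = rep(NA_integer_, nrow(df)),
         voxel_size = voxel_size),
    class = "fsc_curve")
}
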