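#' Read an MRC/CCP4 density map
#'
#' A native reader for the MRC2014 format as used by EMDB depositions.
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16);
#' values are returned as doubles. Axis order is normalized to the
#' canonical X-fastest convention using the `mapc`/`mapr`/`maps` header
#' words (a note is emitted when a permutation was applied), and the
#' voxel size is taken as `cella / (mx, my, mz)`. Anisotropic voxel
#' sizes beyond 0.1% tolerance trigger a warning and the mean is used.
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [volume_grid()]; the raw header fields are attached as
#'   attribute `"mrc_header"`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  dims <- ri(3)            # nc, nr, ns
  mode <- ri(1)
  nstart <- ri(3)
  m <- ri(3)               # mx, my, mz (sampling grid)
  cella <- rf(3)
  cellb <- rf(3)
  axes <- ri(3)            # mapc, mapr, maps
  dstats <- rf(3)          # dmin, dmax, dmean
  ispg <- ri(1); nsymbt <- ri(1)
  extra <- ri(25)
  origin <- rf(3)
  map_id <- readBin(con, "raw", 4)
  machst <- readBin(con, "raw", 4)
  rms <- rf(1)
  nlabl <- ri(1)
  labels <- readBin(con, "raw", 800)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  nvox <- prod(dims)
  if (any(dims < 1)) stop("corrupt MRC header: non-positive dimensions")
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2L,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", nvox, size = 2L,
                             signed = FALSE, endian = "little")),
    stop("unsupported MRC mode: ", mode))
  if (length(vals) < nvox)
    stop("truncated MRC file: expected ", nvox, " voxels, read ",
         length(vals))
  dim(vals) <- dims
  if (!identical(axes, c(1L, 2L, 3L))) {
    if (!setequal(axes, 1:3)) stop("invalid mapc/mapr/maps: ",
                                   paste(axes, collapse = ","))
    vals <- aperm(vals, match(1:3, axes))
    message("read_mrc: permuted axis order (",
            paste(axes, collapse = ","), ") normalized to (1,2,3)")
  }
  vsz <- cella / m
  if (any(!is.finite(vsz)) || any(vsz <= 0))
    stop("corrupt MRC header: non-positive voxel size")
  if (diff(range(vsz)) > 1e-3 * mean(vsz)) {
    warning(sprintf(
      "anisotropic voxel sizes (%.4g, %.4g, %.4g); using the mean",
      vsz[1], vsz[2], vsz[3]))
  }
  v <- volume_grid(vals, voxel_size = mean(vsz), origin = origin)
  attr(v, "mrc_header") <- list(mode = mode, dims = dims, nstart = nstart,
                                m = m, cella = cella, axes = axes,
                                dmin = dstats[1], dmax = dstats[2],
                                dmean = dstats[3], rms = rms,
                                origin = origin)
  v
}

#' Write a volume as a mode-2 (float32) MRC map
#'
#' Writes a canonical-axis-order MRC2014 file with the volume's voxel
#' size and origin, and header min/max/mean/rms statistics recomputed
#' from the data.
#'
#' @param v a [volume_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(v, path) {
  stopifnot(is_volume_grid(v))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  d <- dim(v$values)
  wi(d)                                   # nc, nr, ns
  wi(2L)                                  # mode 2: float32
  wi(c(0L, 0L, 0L))                       # nstart
  wi(d)                                   # mx, my, mz
  wf(d * v$voxel_size)                    # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1L, 2L, 3L))                       # mapc, mapr, maps
  wf(c(min(v$values), max(v$values), mean(v$values)))
  wi(c(1L, 0L))                           # ispg, nsymbt
  wi(integer(25))                         # extra
  wf(v$origin)                            # origin (MRC2014)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(v$values)))     # rms
  wi(1L)                                  # nlabl
  lab <- charToRaw(sprintf("%-80s", "crefdenoise"))
  writeBin(c(lab, raw(800 - length(lab))), con)
  writeBin(as.numeric(v$values), con, size = 4L, endian = "little")
  invisible(path)
}
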