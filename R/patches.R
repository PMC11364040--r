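#' Mask and standardize a map
#'
#' Multiplies the map by the mask (when given) and rescales it to mean 0
#' and standard deviation 1. By default the statistics are computed over
#' all voxels of the masked volume -- masking first, then standardizing,
#' which keeps solvent zeros in the statistics the way whole-map
#' preprocessing does; `stats_in_mask = TRUE` restricts the statistics
#' to voxels with positive mask weight instead.
#'
#' @param v a [volume_grid()].
#' @param mask optional mask [volume_grid()] on the same grid.
#' @param stats_in_mask compute mean/sd inside the mask only.
#' @return The standardized [volume_grid()] with attributes
#'   `"standardize_mean"` and `"standardize_sd"` recording the applied
#'   statistics.
#' @export
standardize <- function(v, mask = NULL, stats_in_mask = FALSE) {
  mv <- apply_mask(v, mask)
  x <- mv$values
  sel <- if (stats_in_mask && !is.null(mask)) mask$values > 0 else TRUE
  mu <- mean(x[sel])
  sd_ <- stats::sd(as.numeric(x[sel]))
  if (!is.finite(sd_) || sd_ <= 1e-12)
    stop("degenerate input: zero variance after masking")
  out <- as_volume_like((x - mu) / sd_, v)
  attr(out, "standardize_mean") <- mu
  attr(out, "standardize_sd") <- sd_
  out
}

# 0-based window offsets along one axis: a non-overlapping grid from the
# origin, with a final shifted-to-fit window flush with the boundary
axis_offsets <- function(n, edge) {
  if (edge > n) stop("patch edge ", edge, " exceeds axis length ", n)
  unique(c(seq.int(0L, n - edge, by = edge), n - edge))
}

#' Cut a pair of half-maps into matched cubic patches
#'
#' Tiles both half-maps with an identical non-overlapping grid of
#' `edge^3` windows starting at the origin; a final partial window on an
#' axis is shifted back to end flush with the boundary (full-size,
#' possibly overlapping its neighbour). Windows whose mask content is
#' identically zero -- patches lying completely outside the masked
#' region -- are dropped.
#'
#' @param m1,m2 half-map [volume_grid()]s with shared geometry.
#' @param mask mask [volume_grid()] on the same grid (`NULL` keeps every
#'   window).
#' @param edge cubic patch edge in voxels.
#' @param source_id identifier recorded on every patch pair.
#' @return List of `patch_pair` objects, each with `p1`, `p2` (3D
#'   arrays), 0-based `offset`, `edge` and `source_id`.
#' @export
tile_patches <- function(m1, m2, mask = NULL, edge = 96L,
                         source_id = "map") {
  stop_if_geometry_mismatch(m1, m2, "half-maps")
  if (!is.null(mask)) stop_if_geometry_mismatch(m1, mask, "map and mask")
  d <- dim(m1$values)
  edge <- as.integer(edge)
  offs <- expand.grid(x = axis_offsets(d[1], edge),
                      y = axis_offsets(d[2], edge),
                      z = axis_offsets(d[3], edge))
  pairs <- vector("list", nrow(offs))
  kept <- 0L
  for (i in seq_len(nrow(offs))) {
    ix <- offs$x[i] + seq_len(edge)
    iy <- offs$y[i] + seq_len(edge)
    iz <- offs$z[i] + seq_len(edge)
    if (!is.null(mask) && all(mask$values[ix, iy, iz] == 0)) next
    kept <- kept + 1L
    pairs[[kept]] <- structure(
      list(p1 = m1$values[ix, iy, iz], p2 = m2$values[ix, iy, iz],
           offset = c(offs$x[i], offs$y[i], offs$z[i]),
           edge = edge, source_id = source_id,
           voxel_size = m1$voxel_size),
      class = "patch_pair")
  }
  pairs[seq_len(kept)]
}

#' Split map identifiers into train and test sets
#'
#' A seeded shuffle split at the map level, so no source map contributes
#' patches to both sides (patch-level splitting would leak shared signal
#' between train and test).
#'
#' @param entries character vector of source-map identifiers.
#' @param test_fraction fraction of maps assigned to the test side.
#' @param seed integer shuffle seed.
#' @return List with `train_ids` and `test_ids` (disjoint, covering all
#'   entries).
#' @export
split_by_map <- function(entries, test_fraction = 0.1, seed = 1L) {
  if (length(entries) < 2L) stop("need at least 2 entries to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)")
  if (anyDuplicated(entries)) stop("duplicate source ids in `entries`")
  withr_seed(seed, perm <- sample(length(entries)))
  n_test <- max(1L, round(test_fraction * length(entries)))
  shuffled <- entries[perm]
  list(test_ids = sort(shuffled[seq_len(n_test)]),
       train_ids = sort(shuffled[-seq_len(n_test)]))
}

#' Prepare a patch dataset from standardized half-maps
#'
#' The full preparation pipeline for one entry: mask, standardize each
#' half-map (whole-map statistics, before tiling), then tile into
#' matched patches.
#'
#' @inheritParams tile_patches
#' @param stats_in_mask see [standardize()].
#' @return List of `patch_pair`s.
#' @export
prepare_entry <- function(m1, m2, mask = NULL, edge = 96L,
                          source_id = "map", stats_in_mask = FALSE) {
  s1 <- standardize(m1, mask, stats_in_mask)
  s2 <- standardize(m2, mask, stats_in_mask)
  tile_patches(s1, s2, mask, edge, source_id)
}
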