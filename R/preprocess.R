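#' Box-filter downsampling by a factor of two
#'
#' Replaces each disjoint 2x2x2 block of voxels by its mean, halving the
#' resolution along every axis and reducing the voxel count by a factor of
#' eight (for even dimensions). Output spacing is doubled; trailing
#' rows/columns/slabs of odd dimensions are dropped.
#'
#' @param vol A [grey_volume()] with all dimensions at least 2.
#' @return The resampled [grey_volume()].
#' @export
resample_box2 <- function(vol) {
  stopifnot(inherits(vol, "grey_volume"))
  d <- dim(vol$data)
  if (any(d < 2)) stop("all dimensions must be >= 2 to resample")
  nd <- d %/% 2L
  a <- vol$data[seq_len(2L * nd[1]), seq_len(2L * nd[2]), seq_len(2L * nd[3]),
                drop = FALSE]
  # pairwise means along each axis in turn
  a <- (a[seq(1, 2 * nd[1], 2), , , drop = FALSE] +
        a[seq(2, 2 * nd[1], 2), , , drop = FALSE]) / 2
  a <- (a[, seq(1, 2 * nd[2], 2), , drop = FALSE] +
        a[, seq(2, 2 * nd[2], 2), , drop = FALSE]) / 2
  a <- (a[, , seq(1, 2 * nd[3], 2), drop = FALSE] +
        a[, , seq(2, 2 * nd[3], 2), drop = FALSE]) / 2
  # block centre of the first 2x2x2 block sits half a (new) voxel past the
  # old first voxel centre
  grey_volume(a, spacing = 2 * vol$spacing,
              origin = vol$origin + vol$spacing / 2)
}

#' Slice-wise unsharp masking
#'
#' Sharpens each x-y plane independently: `out = in + g * (in - lowpass(in))`
#' where the lowpass is a `kernel_size` x `kernel_size` uniform mean with edge
#' replication and the gain is `g = sharpness / (1 - sharpness)` (or plainly
#' `g = sharpness` with `gain = "plain"` — the vendor formulation is
#' unpublished, so both conventions are offered). Output is clipped to the
#' input value range so the sharpening cannot create out-of-range intensities.
#'
#' @param vol A [grey_volume()].
#' @param kernel_size Odd box-kernel side length in voxels, >= 3.
#' @param sharpness Sharpening strength in \[0, 1).
#' @param gain Gain convention, `"ratio"` (default) or `"plain"`.
#' @return The filtered [grey_volume()].
#' @export
unsharp_mask <- function(vol, kernel_size = 5L, sharpness = 0.6,
                         gain = c("ratio", "plain")) {
  stopifnot(inherits(vol, "grey_volume"))
  gain <- match.arg(gain)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 3L || kernel_size %% 2L == 0L)
    stop("kernel_size must be an odd integer >= 3")
  if (sharpness < 0 || sharpness >= 1) stop("sharpness must be in [0, 1)")
  if (sharpness == 0) return(vol)
  g <- if (gain == "ratio") sharpness / (1 - sharpness) else sharpness

  d <- dim(vol$data)
  box <- rep(1 / kernel_size, kernel_size)
  # separable box filter within each slice: x then y, never z
  low <- .convolve_axis(vol$data, d, box, 1L)
  low <- .convolve_axis(low, d, box, 2L)
  out <- vol$data + g * (vol$data - low)
  rng <- range(vol$data)
  out[out < rng[1]] <- rng[1]
  out[out > rng[2]] <- rng[2]
  grey_volume(out, spacing = vol$spacing, origin = vol$origin)
}

#' Crop a volume to a voxel-index box
#'
#' Extracts the half-open index box `[x0, x1) x [y0, y1) x [z0, z1)`
#' (0-based, matching the on-disk voxel indexing) and shifts the origin so
#' physical coordinates of retained voxels are unchanged.
#'
#' @param vol A [grey_volume()] or [label_volume()].
#' @param box Integer vector `c(x0, x1, y0, y1, z0, z1)`, 0-based half-open.
#' @return The cropped volume of the same class.
#' @export
crop_roi <- function(vol, box) {
  stopifnot(inherits(vol, "ct_volume"), length(box) == 6)
  box <- as.integer(box)
  d <- dim(vol$data)
  lo <- box[c(1, 3, 5)]; hi <- box[c(2, 4, 6)]
  if (any(lo < 0) || any(hi > d)) stop("crop box out of bounds")
  if (any(hi <= lo)) stop("crop box is empty")
  a <- vol$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                drop = FALSE]
  origin <- vol$origin + lo * vol$spacing
  if (inherits(vol, "label_volume"))
    label_volume(a, spacing = vol$spacing, origin = origin)
  else grey_volume(a, spacing = vol$spacing, origin = origin)
}
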