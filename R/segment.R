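#' Three-class histogram thresholds (multi-level Otsu)
#'
#' Finds the two grey thresholds separating background/marrow, bone and
#' implant by maximizing the three-class between-class variance over a
#' 256-bin histogram of the volume, the classic multi-level extension of
#' Otsu's criterion. When a plateau of bin pairs is equally optimal (well
#' separated spike histograms), the midpoint of the plateau is returned for
#' each threshold.
#'
#' @param vol A [grey_volume()] with at least 3 distinct values.
#' @param n_bins Number of histogram bins spanning the data range.
#' @return A list with `t_bone` (background|bone boundary) and `t_implant`
#'   (bone|implant boundary), `t_bone < t_implant`, in grey units.
#' @export
detect_thresholds <- function(vol, n_bins = 256L) {
  stopifnot(inherits(vol, "grey_volume"))
  v <- as.numeric(vol$data)
  rng <- range(v)
  if (length(unique(v)) < 3)
    stop("degenerate histogram: need at least 3 distinct grey values")
  n_bins <- as.integer(n_bins)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          n_bins), n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  p <- counts / sum(counts)
  P <- cumsum(p)                 # class mass up to bin t
  S <- cumsum(p * centers)       # first moment up to bin t

  # between-class variance of the split (1..t1 | t1+1..t2 | t2+1..n) equals
  # sum_k S_k^2 / w_k up to a constant; scan t1, vectorize over t2
  best <- -Inf
  best_pairs <- matrix(integer(0), ncol = 2)
  Pn <- P[n_bins]; Sn <- S[n_bins]
  for (t1 in 1:(n_bins - 2L)) {
    w1 <- P[t1]; s1 <- S[t1]
    if (w1 <= 0) next
    t2 <- (t1 + 1L):(n_bins - 1L)
    w2 <- P[t2] - w1; s2 <- S[t2] - s1
    w3 <- Pn - P[t2]; s3 <- Sn - S[t2]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    crit <- rep(-Inf, length(t2))
    crit[ok] <- s1^2 / w1 + s2[ok]^2 / w2[ok] + s3[ok]^2 / w3[ok]
    m <- max(crit)
    if (m > best + 1e-12) {
      best <- m
      best_pairs <- cbind(t1, t2[crit >= m - 1e-12])
    } else if (m >= best - 1e-12) {
      best_pairs <- rbind(best_pairs, cbind(t1, t2[crit >= m - 1e-12]))
    }
  }
  if (!is.finite(best)) stop("could not place two thresholds in the histogram")
  # midpoint of the optimal plateau, mapped to the bin's upper edge
  mid <- function(idx) edges[1] + (min(idx) + max(idx)) / 2 *
    (rng[2] - rng[1]) / n_bins
  list(t_bone = mid(best_pairs[, 1]), t_implant = mid(best_pairs[, 2]))
}

#' Label materials by grey thresholds
#'
#' Voxels at or below `t_bone` become background/marrow, voxels in
#' `(t_bone, t_implant]` bone, voxels above `t_implant` implant. A voxel
#' exactly at a threshold goes to the lower class.
#'
#' @param vol A [grey_volume()].
#' @param thr Threshold pair from [detect_thresholds()] (or a list with
#'   `t_bone` and `t_implant`, `t_bone < t_implant`).
#' @return A [label_volume()] on the same grid.
#' @export
segment_materials <- function(vol, thr) {
  stopifnot(inherits(vol, "grey_volume"))
  if (!(thr$t_bone < thr$t_implant)) stop("thresholds must satisfy t_bone < t_implant")
  lab <- array(LBL_BACKGROUND, dim = dim(vol$data))
  lab[vol$data > thr$t_bone] <- LBL_BONE
  lab[vol$data > thr$t_implant] <- LBL_IMPLANT
  label_volume(lab, spacing = vol$spacing, origin = vol$origin)
}

#' Clean up segmentation errors at the implant-bone transition
#'
#' Blur, noise and the bright metal halo tend to deposit thin films and
#' speckles of spurious "bone" against the implant. Two corrections are
#' applied: (1) a bounded geodesic opening of the bone mask (Euclidean-ball
#' erosion followed by a limited geodesic dilation within the original
#' mask), restricted to a 3-voxel collar around the implant: bone truly
#' apposed to the shell is regrown from the bulk behind it, while thin
#' films with marrow behind them stay removed; (2) removal of bone islands
#' (26-connected components) smaller than `min_island` voxels anywhere in the
#' volume. Implant and excluded labels are never modified; removed bone
#' becomes background/marrow.
#'
#' @param labels A [label_volume()].
#' @param opening_radius Ball radius (voxels) of the opening.
#' @param min_island Minimum bone component size (voxels) to survive.
#' @param collar Collar width (voxels) around the implant within which the
#'   opening acts.
#' @return The cleaned [label_volume()].
#' @export
clean_interface <- function(labels, opening_radius = 1, min_island = 27L,
                            collar = 3) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$data)
  bone <- labels$data == LBL_BONE
  imp <- labels$data == LBL_IMPLANT

  if (opening_radius > 0 && any(imp)) {
    collar_mask <- .morph_ball_3d(imp, d, collar, 1L) & !imp
    # bounded geodesic opening: ball erosion, then (radius + 1) unit
    # geodesic dilations inside the original bone mask. True contact sits at
    # most a staircase notch away from the eroded core and is restored;
    # halo/blur films against the shell have marrow behind them, hence no
    # core to grow back from, and stay removed.
    opened <- .morph_ball_3d(bone, d, opening_radius, 0L)
    for (it in seq_len(ceiling(opening_radius) + 1L))
      opened <- .morph_ball_3d(opened, d, 1, 1L) & bone
    bone <- (bone & !collar_mask) | (opened & collar_mask)
  }
  if (min_island > 1 && any(bone)) {
    cc <- .cc_label_3d(bone, d, 26L)
    sz <- tabulate(cc[cc > 0L])
    bone <- bone & array(sz[pmax(cc, 1L)] >= min_island & cc > 0L, dim = d)
  }
  out <- labels$data
  out[out == LBL_BONE] <- LBL_BACKGROUND
  out[bone] <- LBL_BONE
  out[imp] <- LBL_IMPLANT          # opening may not eat implant-overlap, keep invariant explicit
  label_volume(out, spacing = labels$spacing, origin = labels$origin)
}

#' Exclude implant shell regions outside the bone
#'
#' Implants seated too proud of the bone expose part of their shell to soft
#' tissue/air; that shell must not count as "possible" contact. All
#' non-implant voxels on the far side of a cutting plane are relabelled
#' `excluded`, which downstream removes the adjacent shell faces from the
#' pBIC (with the pVA denominator corrected accordingly).
#'
#' With `plane = "auto"` the plane is placed perpendicular to the implant
#' axis (z) at the bottom of the topmost run of slices whose perimeter
#' coverage falls below `coverage_threshold`. Coverage of a slice is the
#' fraction of angular bins around the implant cross-section that contain
#' bone within an `annulus_width`-voxel ring — embedded levels score high
#' even across thin marrow gaps, exposed-in-air levels score zero.
#'
#' @param labels A [label_volume()].
#' @param plane `"auto"`, or a list with `point` (µm, length 3) and `normal`
#'   (length 3, pointing towards the excluded side).
#' @param coverage_threshold Fraction of covered angular bins below which a
#'   slice counts as outside the bone.
#' @param annulus_width Ring width (voxels) searched for bone.
#' @param n_angular_bins Angular resolution of the coverage estimate.
#' @return The [label_volume()] with excluded voxels set to label 3, and an
#'   attribute `exclusion` describing the plane used (or `NULL` if nothing
#'   was excluded).
#' @export
exclude_outside_bone <- function(labels, plane = "auto",
                                 coverage_threshold = 0.5,
                                 annulus_width = 5, n_angular_bins = 72L) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$data)

  if (identical(plane, "auto")) {
    cov <- perimeter_bone_coverage(labels, annulus_width, n_angular_bins)
    below <- which(!is.na(cov) & cov < coverage_threshold)
    imp_slices <- which(!is.na(cov))
    if (length(below) == 0) {
      attr(labels, "exclusion") <- NULL
      return(labels)
    }
    # contiguous run of uncovered slices reaching the implant top
    top <- max(imp_slices)
    run <- below[below > max(setdiff(imp_slices, below), 0)]
    if (length(run) == 0 || max(run) != top) {
      attr(labels, "exclusion") <- NULL
      return(labels)
    }
    z_star <- min(run)
    out <- labels$data
    sel <- slice_index_array(d, 3) >= z_star & out != LBL_IMPLANT
    out[sel] <- LBL_EXCLUDED
    res <- label_volume(out, spacing = labels$spacing, origin = labels$origin)
    attr(res, "exclusion") <- list(mode = "auto", z_slice = z_star,
                                   coverage = cov)
    return(res)
  }

  stopifnot(is.list(plane), length(plane$point) == 3, length(plane$normal) == 3)
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  xs <- axis_coords(labels, 1); ys <- axis_coords(labels, 2)
  zs <- axis_coords(labels, 3)
  sd_x <- (xs - plane$point[1]) * nrm[1]
  sd_y <- (ys - plane$point[2]) * nrm[2]
  sd_z <- (zs - plane$point[3]) * nrm[3]
  sdist <- outer(outer(sd_x, sd_y, "+"), sd_z, "+")
  sel <- sdist > 0 & labels$data != LBL_IMPLANT
  if (all(sdist > 0)) stop("plane would exclude the entire volume")
  out <- labels$data
  out[sel] <- LBL_EXCLUDED
  res <- label_volume(out, spacing = labels$spacing, origin = labels$origin)
  attr(res, "exclusion") <- if (any(sel))
    list(mode = "plane", point = plane$point, normal = nrm) else NULL
  res
}

# Per-slice fraction of angular bins around the implant cross-section that
# contain bone within an annulus of the given width. NA for slices without
# implant.
perimeter_bone_coverage <- function(labels, annulus_width = 5,
                                    n_angular_bins = 72L) {
  d <- dim(labels$data)
  cov <- rep(NA_real_, d[3])
  for (k in seq_len(d[3])) {
    sl <- labels$data[, , k]
    imp <- sl == LBL_IMPLANT
    if (!any(imp)) next
    slab <- array(imp, dim = c(d[1], d[2], 1L))
    ring <- .morph_ball_3d(slab, c(d[1], d[2], 1L), annulus_width, 1L)[, , 1] & !imp
    if (!any(ring)) { cov[k] <- 0; next }
    ij <- which(ring, arr.ind = TRUE)
    cimp <- colMeans(which(imp, arr.ind = TRUE))
    ang <- atan2(ij[, 2] - cimp[2], ij[, 1] - cimp[1])
    bin <- pmin(floor((ang + pi) / (2 * pi) * n_angular_bins) + 1L,
                n_angular_bins)
    has_ring <- unique(bin)
    has_bone <- unique(bin[sl[ring] == LBL_BONE])
    cov[k] <- length(has_bone) / length(has_ring)
  }
  cov
}
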