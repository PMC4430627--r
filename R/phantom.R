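#' Acquisition geometry of a micro-CT scan
#'
#' Describes the rotation protocol and magnification of a cone-beam micro-CT
#' acquisition, enough to reproduce the projection-count and voxel-size
#' arithmetic of a scan report.
#'
#' @param rotation_total Total specimen rotation in degrees (> 0).
#' @param step Rotation step in degrees; must divide `rotation_total`.
#' @param frames_per_step Number of 2D images averaged/acquired per step.
#' @param magnification Geometric magnification (source-detector over
#'   source-object distance), dimensionless.
#' @param detector_pitch Detector pixel pitch in micrometres. The default of
#'   50 µm is inferred from published magnification/voxel-size pairs (it is
#'   the unique pitch reproducing them to two decimals), not a vendor datum.
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(rotation_total = 360, step = 0.75,
                                 frames_per_step = 3, magnification = 11.5,
                                 detector_pitch = 50) {
  if (rotation_total <= 0) stop("rotation_total must be > 0")
  if (step <= 0) stop("step must be > 0")
  k <- rotation_total / step
  if (abs(k - round(k)) > 1e-9) stop("step must divide rotation_total")
  if (frames_per_step < 1) stop("frames_per_step must be >= 1")
  if (magnification <= 0) stop("magnification must be > 0")
  if (detector_pitch <= 0) stop("detector_pitch must be > 0")
  structure(list(rotation_total = rotation_total, step = step,
                 frames_per_step = as.integer(frames_per_step),
                 magnification = magnification,
                 detector_pitch = detector_pitch),
            class = "acquisition_geometry")
}

#' Number of 2D projections acquired in one scan
#'
#' `(rotation_total / step) * frames_per_step`, e.g. a full 360° rotation in
#' 0.75° steps with 3 frames per step yields 1440 projections.
#'
#' @param geometry An [acquisition_geometry()].
#' @return Integer projection count.
#' @export
projection_count <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  as.integer(round(geometry$rotation_total / geometry$step) *
               geometry$frames_per_step)
}

#' Nominal reconstructed voxel size
#'
#' Detector pixel pitch divided by geometric magnification, rounded to two
#' decimals (the precision at which scan reports quote voxel size).
#'
#' @inheritParams projection_count
#' @return Voxel edge length in micrometres.
#' @export
nominal_voxel_size <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  round(geometry$detector_pitch / geometry$magnification, 2)
}

#' Specification of a synthetic bone-implant phantom
#'
#' Describes a conical titanium-like implant embedded in a bone block, with
#' the contact geometry, grey-value mapping and acquisition artifacts to
#' simulate. All lengths in micrometres, grey values in arbitrary units.
#'
#' @param implant_max_diameter Maximum (top) implant diameter, µm.
#' @param implant_length Implant length along its axis, µm.
#' @param implant_taper_angle Cone half-angle in degrees (radius shrinks
#'   towards the bottom).
#' @param voxel_size Isotropic voxel edge, µm. Must keep the implant at least
#'   20 voxels across.
#' @param contact_mode One of `"full"`, `"none"`, `"sector"`, `"trabecular"`.
#' @param contact_fraction For sector mode: fraction of the shell
#'   circumference in bone contact, in \[0, 1\].
#' @param bone_volume_fraction,correlation_length For trabecular mode: target
#'   BV/TV of the random bone field and its smoothing length (µm).
#' @param grey_means Grey values of (background/marrow, bone, implant); must
#'   be strictly increasing.
#' @param noise_sigma Additive Gaussian noise SD, grey units.
#' @param blur_sigma Gaussian PSF sigma, µm (`NULL` = one voxel).
#' @param halo_amplitude,halo_decay Additive bright halo around the implant
#'   (metal halation / beam-hardening stand-in): amplitude in grey units,
#'   exponential decay length in µm.
#' @param exposed_top If `TRUE`, the top part of the implant protrudes from
#'   the bone block into background (adverse positioning).
#' @param exposed_fraction Fraction of the implant length exposed when
#'   `exposed_top` is set.
#' @param lateral_margin Bone thickness around the implant's maximum radius, µm.
#' @param axial_margin Volume padding below/above the implant, µm.
#' @param gap_voxels Width (voxels) of the marrow gap separating bone from the
#'   shell where no contact is intended; at least 3.
#' @param rng_seed Integer seed; the phantom is bit-reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(implant_max_diameter = 3000, implant_length = 3000,
                         implant_taper_angle = 5, voxel_size = 50,
                         contact_mode = c("full", "none", "sector", "trabecular"),
                         contact_fraction = 0.5,
                         bone_volume_fraction = 0.35, correlation_length = 200,
                         grey_means = c(50, 120, 230),
                         noise_sigma = 8, blur_sigma = NULL,
                         halo_amplitude = 25, halo_decay = 40,
                         exposed_top = FALSE, exposed_fraction = 1 / 3,
                         lateral_margin = 1000, axial_margin = 300,
                         gap_voxels = 4, rng_seed = 1L) {
  contact_mode <- match.arg(contact_mode)
  if (is.null(blur_sigma)) blur_sigma <- voxel_size
  if (!(length(grey_means) == 3 && all(diff(grey_means) > 0)))
    stop("grey_means must be strictly increasing (background < bone < implant)")
  if (contact_fraction < 0 || contact_fraction > 1)
    stop("contact_fraction must be in [0, 1]")
  if (implant_max_diameter / voxel_size < 20)
    stop("voxel_size too coarse: implant must span at least 20 voxels")
  if (implant_taper_angle < 0 ||
      tan(implant_taper_angle * pi / 180) * implant_length >=
        implant_max_diameter / 2)
    stop("taper angle would close the cone before its full length")
  if (gap_voxels < 3) stop("gap_voxels must be at least 3")
  if (bone_volume_fraction <= 0 || bone_volume_fraction >= 1)
    stop("bone_volume_fraction must be in (0, 1)")
  structure(list(
    implant_max_diameter = implant_max_diameter,
    implant_length = implant_length,
    implant_taper_angle = implant_taper_angle, voxel_size = voxel_size,
    contact_mode = contact_mode, contact_fraction = contact_fraction,
    bone_volume_fraction = bone_volume_fraction,
    correlation_length = correlation_length,
    grey_means = as.numeric(grey_means), noise_sigma = noise_sigma,
    blur_sigma = blur_sigma, halo_amplitude = halo_amplitude,
    halo_decay = halo_decay, exposed_top = isTRUE(exposed_top),
    exposed_fraction = exposed_fraction, lateral_margin = lateral_margin,
    axial_margin = axial_margin, gap_voxels = gap_voxels,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
}

# Implant radius (µm) at height z (µm above the implant bottom).
implant_radius_at <- function(spec, z_above_bottom) {
  r_top <- spec$implant_max_diameter / 2
  r_top - (spec$implant_length - z_above_bottom) *
    tan(spec$implant_taper_angle * pi / 180)
}

#' Generate a synthetic micro-CT phantom
#'
#' Builds a conical implant on the z axis embedded in bone, renders clean
#' material labels, then a grey volume with (in order) an additive bright halo
#' decaying away from the implant surface, Gaussian blur and Gaussian noise.
#' The true shell contact fraction is counted on the clean label adjacency
#' (implant shell faces touching bone over all shell faces, end caps
#' excluded) before any degradation.
#'
#' @param spec A [phantom_spec()].
#' @param vol_dim Optional explicit volume dimensions (voxels); the implant
#'   must fit or an error is raised. Default sizes the volume from the implant
#'   plus margins.
#' @return A list with elements `grey` ([grey_volume()]), `labels`
#'   ([label_volume()]), `true_contact_fraction`, and `meta` (the spec plus
#'   seed, for provenance).
#' @export
generate_phantom <- function(spec, vol_dim = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$voxel_size
  r_top <- spec$implant_max_diameter / 2

  if (is.null(vol_dim)) {
    nxy <- ceiling((spec$implant_max_diameter + 2 * spec$lateral_margin) / s)
    nz <- ceiling((spec$implant_length + 2 * spec$axial_margin) / s)
    vol_dim <- c(nxy, nxy, nz)
  }
  nx <- vol_dim[1]; ny <- vol_dim[2]; nz <- vol_dim[3]
  if (nx * s < spec$implant_max_diameter + 2 * s ||
      ny * s < spec$implant_max_diameter + 2 * s ||
      nz * s < spec$implant_length + 2 * s)
    stop("implant does not fit in the requested volume")

  # voxel-centre coordinates, implant axis through the lateral centre
  x <- (seq_len(nx) - 1) * s; y <- (seq_len(ny) - 1) * s
  z <- (seq_len(nz) - 1) * s
  cx <- (nx - 1) * s / 2; cy <- (ny - 1) * s / 2
  z_bot <- min(spec$axial_margin, (nz * s - spec$implant_length) / 2)
  z_top <- z_bot + spec$implant_length

  dx <- x - cx
  dy <- y - cy
  rho2 <- outer(dx^2, dy^2, "+")        # nx x ny squared radial distance
  rho <- sqrt(rho2)
  azim <- atan2(rep(dy, each = nx), rep(dx, times = ny))
  dim(azim) <- c(nx, ny)

  in_span <- z >= z_bot & z <= z_top
  r_at_z <- ifelse(in_span, implant_radius_at(spec, z - z_bot), -Inf)

  labels <- array(LBL_BACKGROUND, dim = c(nx, ny, nz))
  implant <- array(FALSE, dim = c(nx, ny, nz))
  for (k in seq_len(nz))
    if (in_span[k]) implant[, , k] <- rho <= r_at_z[k]

  bone_top <- if (spec$exposed_top)
    z_top - spec$exposed_fraction * spec$implant_length else z_top
  bone_span <- z <= bone_top
  gap_um <- spec$gap_voxels * s

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$rng_seed)

  if (spec$contact_mode == "trabecular") {
    field <- array(stats::rnorm(nx * ny * nz), dim = c(nx, ny, nz))
    field <- gaussian_blur_3d(field, spec$correlation_length / s)
    thr <- stats::quantile(field, 1 - spec$bone_volume_fraction)
    bone_field <- field > thr
  }

  # The marrow gap that keeps bone off the shell outside the contact region
  # must also extend one gap-width below the implant bottom: otherwise the
  # bone floor under the implant reaches the lowest lateral shell voxels
  # through the imaging blur and violates the stated contact geometry.
  r_bot <- implant_radius_at(spec, 0)
  below_ring <- z < z_bot & z >= z_bot - gap_um
  wedge <- abs(azim) <= pi * spec$contact_fraction
  for (k in seq_len(nz)) {
    if (!bone_span[k]) next
    ring_k <- if (below_ring[k]) rho > r_bot & rho <= r_bot + gap_um
    else matrix(FALSE, nx, ny)
    slice_bone <- switch(spec$contact_mode,
      full = !implant[, , k],
      none = if (in_span[k]) rho > r_at_z[k] + gap_um else
        !implant[, , k] & !ring_k,
      sector = {
        if (in_span[k]) {
          (rho > r_at_z[k] & wedge) | (rho > r_at_z[k] + gap_um & !wedge)
        } else !implant[, , k] & !(ring_k & !wedge)
      },
      trabecular = bone_field[, , k] & !implant[, , k])
    lk <- labels[, , k]
    lk[slice_bone] <- LBL_BONE
    labels[, , k] <- lk
  }
  labels[implant] <- LBL_IMPLANT

  tcf <- shell_contact_fraction(labels)

  # grey rendering: means -> halo -> blur -> noise
  grey <- array(spec$grey_means[1], dim = c(nx, ny, nz))
  grey[labels == LBL_BONE] <- spec$grey_means[2]
  grey[labels == LBL_IMPLANT] <- spec$grey_means[3]

  if (spec$halo_amplitude > 0) {
    for (k in seq_len(nz)) {
      d <- if (in_span[k]) {
        pmax(rho - r_at_z[k], 0)
      } else if (z[k] > z_top) {
        sqrt(pmax(rho - r_top, 0)^2 + (z[k] - z_top)^2)
      } else {
        r_b <- implant_radius_at(spec, 0)
        sqrt(pmax(rho - r_b, 0)^2 + (z_bot - z[k])^2)
      }
      halo <- spec$halo_amplitude * exp(-d / spec$halo_decay)
      gk <- grey[, , k]
      sel <- !implant[, , k]
      gk[sel] <- gk[sel] + halo[sel]
      grey[, , k] <- gk
    }
  }
  if (spec$blur_sigma > 0) grey <- gaussian_blur_3d(grey, spec$blur_sigma / s)
  if (spec$noise_sigma > 0)
    grey <- grey + array(stats::rnorm(length(grey), sd = spec$noise_sigma),
                         dim = dim(grey))

  list(grey = grey_volume(grey, spacing = s),
       labels = label_volume(labels, spacing = s),
       true_contact_fraction = tcf,
       meta = list(spec = unclass(spec), seed = spec$rng_seed,
                   implant_z_range_um = c(z_bot, z_top)))
}

# Separable Gaussian blur, sigma in voxels, edge replication.
gaussian_blur_3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) arr <- .convolve_axis(arr, d, k, ax)
  arr
}

# Shell contact fraction counted directly on label adjacency (6-neighbour
# shifts); end-cap faces (z faces within one voxel of the implant z extremes,
# outward-facing) are not part of the shell. Kept independent of the FaceSet
# machinery so the two can cross-check each other.
shell_contact_fraction <- function(labels_arr) {
  if (inherits(labels_arr, "label_volume")) labels_arr <- labels_arr$data
  d <- dim(labels_arr)
  imp <- labels_arr == LBL_IMPLANT
  if (!any(imp)) stop("no implant voxels in label volume")
  kz <- which(apply(imp, 3, any))
  zmin <- min(kz); zmax <- max(kz)

  n_bone <- 0; n_shell <- 0
  for (axis in 1:3) for (dir in c(-1L, 1L)) {
    nb <- shift_array(labels_arr, axis, dir, fill = NA_integer_)
    face <- imp & !is.na(nb) & nb != LBL_IMPLANT
    if (axis == 3) {
      # drop end-cap faces at the implant's extreme slices (+/- 1 voxel)
      kidx <- slice_index_array(d, 3)
      if (dir == -1L) face <- face & !(kidx <= zmin + 1L)
      else face <- face & !(kidx >= zmax - 1L)
    }
    n_bone <- n_bone + sum(face & nb == LBL_BONE, na.rm = TRUE)
    n_shell <- n_shell + sum(face & (nb == LBL_BONE | nb == LBL_BACKGROUND),
                             na.rm = TRUE)
  }
  if (n_shell == 0) return(NA_real_)
  n_bone / n_shell
}

# Array of the index along `axis`, same dim as the volume.
slice_index_array <- function(d, axis) {
  idx <- slice.index(array(0L, dim = d), axis)
  idx
}

# Shift an array by one voxel along an axis; vacated voxels get `fill`.
# dir = +1 brings the neighbour at position i+1 to position i.
shift_array <- function(a, axis, dir, fill = NA) {
  d <- dim(a)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (n < 2) return(out)
  src <- vector("list", 3); dst <- vector("list", 3)
  for (ax in 1:3) src[[ax]] <- dst[[ax]] <- seq_len(d[ax])
  if (dir == 1L) { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  else { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
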