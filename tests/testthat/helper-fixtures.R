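# Shared fixtures and independent oracles, built in code at test time.

# Small, fast sector phantom (30-voxel implant diameter unless overridden).
quick_phantom <- function(mode = "sector", f = 0.5, voxel = 100,
                          seed = 11L, ...) {
  generate_phantom(phantom_spec(contact_mode = mode, contact_fraction = f,
                                voxel_size = voxel, rng_seed = seed, ...))
}

# Label volume of an axis-aligned right circular cylinder (implant label),
# radius and height in voxels, embedded in background.
cylinder_labels <- function(radius_vox, height_vox, spacing = 10,
                            pad = 3L, fill = 0L) {
  n <- 2L * (radius_vox + pad) + 1L
  ctr <- radius_vox + pad + 1L
  disc <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
                function(i, j) i^2 + j^2 <= radius_vox^2)
  arr <- array(fill, dim = c(n, n, height_vox + 2L * pad))
  for (k in seq_len(height_vox) + pad) arr[, , k][disc] <- 2L
  label_volume(arr, spacing = spacing)
}

# Independent brute-force oracle: number of 6-neighbour transitions between
# labels a and b in a raw label array (counts each a|b face once), written
# against the grid directly, not via the face machinery.
count_transitions <- function(arr, a, b) {
  d <- dim(arr)
  n <- 0L
  for (axis in 1:3) {
    idx1 <- lapply(d, seq_len); idx2 <- idx1
    idx1[[axis]] <- seq_len(d[axis] - 1L)
    idx2[[axis]] <- seq_len(d[axis] - 1L) + 1L
    lo <- arr[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE]
    hi <- arr[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE]
    n <- n + sum((lo == a & hi == b) | (lo == b & hi == a))
  }
  n
}

# Random small label grid containing all of background, bone, implant.
random_label_grid <- function(dim3 = c(9L, 8L, 7L)) {
  repeat {
    arr <- array(sample(0:2, prod(dim3), replace = TRUE,
                        prob = c(0.5, 0.3, 0.2)), dim = dim3)
    if (all(0:2 %in% arr)) return(label_volume(arr, spacing = 5))
  }
}
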