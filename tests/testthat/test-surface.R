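test_that("boundary faces of simple blocks are counted exactly", {
  arr <- array(0L, dim = c(5, 5, 5)); arr[3, 3, 3] <- 2L
  lab <- label_volume(arr, spacing = 4)
  fs <- extract_boundary_faces(lab, 2L)
  expect_identical(nrow(fs), 6L)
  expect_equal(area_of(fs), 6 * 16)

  arr2 <- array(0L, dim = c(6, 6, 6)); arr2[3:4, 3:4, 3:4] <- 2L
  fs2 <- extract_boundary_faces(label_volume(arr2, 4), 2L)
  expect_identical(nrow(fs2), 24L)
  expect_error(extract_boundary_faces(label_volume(arr, 4), 1L), "absent")
})

test_that("interface faces isolate exactly the touching label pairs", {
  arr <- array(0L, dim = c(4, 3, 3))
  arr[2, 2, 2] <- 2L; arr[3, 2, 2] <- 1L
  lab <- label_volume(arr, spacing = 2)
  expect_identical(nrow(interface_faces(lab, 2L, 1L)), 1L)

  arr[3, 2, 2] <- 0L; arr[4, 2, 2] <- 1L  # separated by marrow
  expect_identical(nrow(interface_faces(label_volume(arr, 2), 2L, 1L)), 0L)
})

test_that("fully embedded implant: bone interface equals whole boundary", {
  arr <- array(1L, dim = c(7, 7, 7)); arr[3:5, 3:5, 3:5] <- 2L
  lab <- label_volume(arr, spacing = 1)
  whole <- extract_boundary_faces(lab, 2L)
  bone_if <- interface_faces(lab, 2L, 1L)
  expect_identical(nrow(bone_if), nrow(whole) - sum(is.na(whole$nb)))
  expect_identical(sum(is.na(whole$nb)), 0L)  # implant not at volume border
})

test_that("digitized cylinder shows the 4/pi staircase area ratio", {
  r <- 40; h <- 20
  lab <- cylinder_labels(r, h, spacing = 10)
  analytic <- 2 * pi * (r * 10) * (h * 10)
  ratio <- aliasing_report(lab, analytic)
  expect_lt(abs(ratio - 4 / pi), 0.03)
})

test_that("shell classification removes exactly the cylinder end disks", {
  r <- 12; h <- 10
  lab <- cylinder_labels(r, h, spacing = 10)
  all_faces <- extract_boundary_faces(lab, 2L)
  shell <- classify_shell(all_faces, lab)
  # no retained z-faces at the extreme slices, lateral faces untouched
  expect_identical(sum(shell$axis == 3), 0L)  # constant cross-section
  expect_identical(sum(shell$axis != 3), sum(all_faces$axis != 3))
  n_disc <- sum(lab$data[, , 4] == 2L)
  expect_identical(nrow(all_faces) - nrow(shell), 2L * n_disc)
})

test_that("conical shell area ratio is stable across resolution", {
  spec50 <- phantom_spec(contact_mode = "none", voxel_size = 50,
                         noise_sigma = 0, blur_sigma = 0, halo_amplitude = 0,
                         lateral_margin = 300)
  spec25 <- phantom_spec(contact_mode = "none", voxel_size = 25,
                         noise_sigma = 0, blur_sigma = 0, halo_amplitude = 0,
                         lateral_margin = 300)
  ph50 <- generate_phantom(spec50); ph25 <- generate_phantom(spec25)
  r1 <- 1500; half <- 5 * pi / 180
  r0 <- r1 - 3000 * tan(half)
  slant <- 3000 / cos(half)
  analytic <- pi * (r0 + r1) * slant
  rat50 <- aliasing_report(ph50$labels, analytic)
  rat25 <- aliasing_report(ph25$labels, analytic)
  expect_gt(rat50, 1); expect_gt(rat25, 1)
  expect_lt(abs(rat50 - rat25) / rat25, 0.02)
})

test_that("area is additive and scales with spacing squared", {
  lab <- random_label_grid()
  fs <- extract_boundary_faces(lab, 2L)
  part1 <- fs[fs$axis == 1, , drop = FALSE]
  part2 <- fs[fs$axis != 1, , drop = FALSE]
  class(part1) <- class(part2) <- class(fs)
  attr(part1, "spacing") <- attr(part2, "spacing") <- attr(fs, "spacing")
  expect_equal(area_of(part1) + area_of(part2), area_of(fs))
  expect_equal(area_of(fs), nrow(fs) * 25)
})

test_that("pVA hits the exact bounds for full and no contact", {
  full <- quick_phantom("full")
  res <- compute_bic3d(full$labels)
  expect_equal(res$pVA, 100)
  expect_equal(res$eBIC_area, res$pBIC_area)
  expect_identical(res$triangle_count_pBIC, 2L * as.integer(res$pBIC_area /
                                                              full$labels$spacing^2))
  none <- quick_phantom("none")
  expect_equal(compute_bic3d(none$labels)$pVA, 0)
})

test_that("sector phantom pVA matches the constructed contact fraction", {
  ph <- generate_phantom(phantom_spec(contact_mode = "sector",
                                      contact_fraction = 0.5,
                                      voxel_size = 50, rng_seed = 2))
  res <- compute_bic3d(ph$labels)
  expect_lt(abs(res$pVA - 50), 2)
  expect_lte(res$eBIC_area, res$pBIC_area)
  expect_gte(res$pVA, 0); expect_lte(res$pVA, 100)
})

test_that("excluded shell faces leave the pBIC and land in excluded_area", {
  ph <- quick_phantom("full", exposed_top = TRUE, seed = 13)
  before <- compute_bic3d(ph$labels)
  lab <- exclude_outside_bone(ph$labels, plane = "auto")
  after <- compute_bic3d(lab)
  expect_gt(after$excluded_area, 0)
  expect_lt(after$pBIC_area, before$pBIC_area)
  # exposed (non-contact) shell removed from the denominator raises pVA
  expect_gt(after$pVA, before$pVA)
  all_excluded <- label_volume(array(c(2L, 3L), dim = c(2, 1, 1)), 1)
  expect_error(compute_bic3d(all_excluded), "pBIC")
})

test_that("mesh export round-trips face counts and areas", {
  arr <- array(0L, dim = c(3, 3, 3)); arr[2, 2, 2] <- 2L
  lab <- label_volume(arr, spacing = 4)
  fs <- extract_boundary_faces(lab, 2L)
  for (ext in c("stl", "ply")) {
    path <- tempfile(fileext = paste0(".", ext))
    export_surface(fs, path)
    back <- read_surface(path)
    expect_identical(dim(back$triangles)[1], 12L)
    expect_equal(back$area, area_of(fs))
  }
  # empty face set gives a valid zero-triangle file
  empty <- fs[0, , drop = FALSE]
  class(empty) <- class(fs)
  attr(empty, "spacing") <- attr(fs, "spacing")
  p0 <- tempfile(fileext = ".stl")
  export_surface(empty, p0)
  expect_identical(dim(read_surface(p0)$triangles)[1], 0L)
})

test_that("face counts agree with a brute-force transition count", {
  set.seed(99)
  for (rep in 1:5) {
    lab <- random_label_grid()
    for (pair in list(c(2L, 1L), c(2L, 0L), c(1L, 0L))) {
      expect_identical(nrow(interface_faces(lab, pair[1], pair[2])),
                       count_transitions(lab$data, pair[1], pair[2]))
    }
  }
})
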