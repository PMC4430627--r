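test_that("three-class thresholds separate well-separated trimodal data", {
  set.seed(10)
  v <- grey_volume(array(c(rnorm(4000, 50, 5), rnorm(3000, 120, 6),
                           rnorm(3000, 220, 8)), dim = c(10, 10, 100)),
                   spacing = 1)
  thr <- detect_thresholds(v)
  expect_gt(thr$t_bone, 50); expect_lt(thr$t_bone, 120)
  expect_gt(thr$t_implant, 120); expect_lt(thr$t_implant, 220)
})

test_that("spike histograms give plateau-midpoint thresholds", {
  v <- grey_volume(array(rep(c(0, 100, 200), each = 9), dim = c(3, 3, 3)),
                   spacing = 1)
  thr <- detect_thresholds(v)
  bw <- 200 / 256
  expect_lt(abs(thr$t_bone - 50), 2 * bw)
  expect_lt(abs(thr$t_implant - 150), 2 * bw)
  expect_error(detect_thresholds(grey_volume(array(c(1, 2), dim = c(2, 1, 1)),
                                             1)), "degenerate")
})

test_that("noise-free phantoms are recovered exactly from their histogram", {
  ph <- quick_phantom(noise_sigma = 0, blur_sigma = 0, halo_amplitude = 0)
  lab <- segment_materials(ph$grey, detect_thresholds(ph$grey))
  expect_identical(lab$data, ph$labels$data)
})

test_that("threshold boundary values fall to the lower class", {
  v <- grey_volume(array(c(10, 50, 70, 120, 130), dim = c(5, 1, 1)), 1)
  lab <- segment_materials(v, list(t_bone = 50, t_implant = 120))
  expect_identical(as.integer(lab$data), c(0L, 0L, 1L, 1L, 2L))
  expect_true(all(segment_materials(
    grey_volume(array(c(1, 2, 3), dim = c(3, 1, 1)), 1),
    list(t_bone = 50, t_implant = 120))$data == 0L))
})

test_that("segmentation error stays below 1% at quarter-gap noise", {
  # smallest inter-class grey gap is 70 (120 - 50); noise sigma 8 < 70/4
  ph <- quick_phantom(noise_sigma = 8, blur_sigma = 0, halo_amplitude = 0,
                      seed = 21)
  lab <- segment_materials(ph$grey, detect_thresholds(ph$grey))
  expect_lt(mean(lab$data != ph$labels$data), 0.01)
})

test_that("interface cleanup removes speckles but not the implant or bulk bone", {
  ph <- quick_phantom("none", noise_sigma = 0, blur_sigma = 0,
                      halo_amplitude = 0)
  lab <- ph$labels
  # inject 10 isolated one-voxel bone speckles against the implant shell
  shell_bg <- which(lab$data == 0L &
                      shift_array(lab$data, 1, 1, fill = NA_integer_) == 2L)
  set.seed(7)
  pick <- sample(shell_bg, 10)
  lab$data[pick] <- 1L
  cleaned <- clean_interface(lab)
  expect_identical(cleaned$data[pick], rep(0L, 10))
  expect_identical(which(cleaned$data == 2L), which(ph$labels$data == 2L))
  # everything else unchanged
  expect_identical(cleaned$data[-pick], ph$labels$data[-pick])
})

test_that("cleanup of a solid contact phantom changes few voxels", {
  ph <- quick_phantom("full", noise_sigma = 0, blur_sigma = 0,
                      halo_amplitude = 0)
  cleaned <- clean_interface(ph$labels)
  changed <- sum(cleaned$data != ph$labels$data)
  imp <- ph$labels$data == 2L
  collar_vol <- sum(.morph_ball_3d(imp, dim(ph$labels$data), 3, 1L) & !imp)
  expect_lte(changed, collar_vol)
})

test_that("plane exclusion is monotone and no-op for a plane above the volume", {
  ph <- quick_phantom(f = 0.5)
  lab <- ph$labels
  far <- exclude_outside_bone(lab, plane = list(point = c(0, 0, 1e6),
                                                normal = c(0, 0, 1)))
  expect_identical(far$data, lab$data)

  p1 <- exclude_outside_bone(lab, plane = list(point = c(0, 0, 2800),
                                               normal = c(0, 0, 1)))
  p2 <- exclude_outside_bone(lab, plane = list(point = c(0, 0, 2300),
                                               normal = c(0, 0, 1)))
  # moving the plane further out never un-excludes a voxel
  expect_true(all(which(p1$data == 3L) %in% which(p2$data == 3L)))
  expect_error(exclude_outside_bone(lab, plane = list(point = c(0, 0, -1e6),
                                                      normal = c(0, 0, 1))),
               "entire volume")
})

test_that("auto exclusion finds the exposed implant top and only that", {
  emb <- quick_phantom("full")
  auto_emb <- exclude_outside_bone(emb$labels, plane = "auto")
  expect_identical(auto_emb$data, emb$labels$data)

  exp_ph <- quick_phantom("full", exposed_top = TRUE, seed = 31)
  auto <- exclude_outside_bone(exp_ph$labels, plane = "auto")
  excl_z <- range(which(apply(auto$data == 3L, 3, any)))
  s <- exp_ph$labels$spacing
  z_bone_top <- exp_ph$meta$implant_z_range_um[2] -
    exp_ph$meta$spec$exposed_fraction * exp_ph$meta$spec$implant_length
  expected_slice <- z_bone_top / s + 1
  expect_lt(abs(excl_z[1] - expected_slice), 2.5)
  expect_identical(excl_z[2], dim(auto$data)[3])
  # implant voxels never relabelled
  expect_identical(which(auto$data == 2L), which(exp_ph$labels$data == 2L))
})
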