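test_that("projection count follows rotation protocol arithmetic", {
  expect_identical(projection_count(acquisition_geometry(360, 0.75, 3)), 1440L)
  expect_identical(projection_count(acquisition_geometry(360, 1, 1)), 360L)
  expect_identical(projection_count(acquisition_geometry(180, 0.5, 2)), 720L)
  expect_error(acquisition_geometry(360, 0.7, 3), "divide")
  expect_error(acquisition_geometry(step = 0), "step")
})

test_that("nominal voxel size is pitch over magnification", {
  expect_equal(nominal_voxel_size(acquisition_geometry(magnification = 12.5)),
               4.00)
  expect_equal(nominal_voxel_size(acquisition_geometry(magnification = 11.5)),
               4.35)
  expect_equal(nominal_voxel_size(acquisition_geometry(magnification = 10)),
               5.00)
  expect_error(acquisition_geometry(magnification = 0), "magnification")
})

test_that("a 50 um detector pitch reproduces every published pair, uniquely on a 1 um grid", {
  # magnification / voxel-size pairs quoted by a scanner report at 2 decimals
  mags <- c(11.50, 12.50, 12.00, 10.75, 11.22, 11.36, 12.50, 11.50, 11.50,
            11.50, 11.75, 11.50, 11.50, 11.50, 10.53)
  vox <- c(4.35, 4.00, 4.17, 4.65, 4.46, 4.40, 4.00, 4.35, 4.35,
           4.35, 4.26, 4.35, 4.35, 4.35, 4.75)
  fits <- vapply(1:200, function(pitch)
    all(abs(round(pitch / mags, 2) - vox) < 0.005), logical(1))
  expect_identical(which(fits), 50L)
})

test_that("full and none contact modes hit the exact fraction bounds", {
  expect_equal(quick_phantom("full")$true_contact_fraction, 1.0)
  expect_equal(quick_phantom("none")$true_contact_fraction, 0.0)
})

test_that("sector phantoms realize the requested contact fraction", {
  ph <- generate_phantom(phantom_spec(contact_mode = "sector",
                                      contact_fraction = 0.5,
                                      voxel_size = 50, rng_seed = 3))
  expect_gt(sum(ph$labels$data == 2), 0)
  expect_lt(abs(ph$true_contact_fraction - 0.5), 0.02)
})

test_that("phantoms are bit-reproducible from the seed", {
  a <- quick_phantom(seed = 42L)
  b <- quick_phantom(seed = 42L)
  expect_identical(a$grey$data, b$grey$data)
  expect_identical(a$labels$data, b$labels$data)
  c <- quick_phantom(seed = 43L)
  expect_false(identical(a$grey$data, c$grey$data))
})

test_that("artifact-free phantoms have exactly three grey values", {
  ph <- quick_phantom(noise_sigma = 0, blur_sigma = 0, halo_amplitude = 0)
  expect_identical(sort(unique(as.numeric(ph$grey$data))), c(50, 120, 230))
})

test_that("sector contact fraction converges with resolution", {
  fractions <- c(0.3, 0.45, 0.6)
  err_at <- function(voxel) mean(vapply(fractions, function(f) {
    ph <- generate_phantom(phantom_spec(contact_mode = "sector",
                                        contact_fraction = f,
                                        voxel_size = voxel,
                                        lateral_margin = 300, rng_seed = 5))
    abs(ph$true_contact_fraction - f)
  }, numeric(1)))
  expect_lt(err_at(50), err_at(100))
})

test_that("trabecular phantoms hit the requested bone volume fraction", {
  ph <- quick_phantom("trabecular", bone_volume_fraction = 0.35, seed = 9)
  lab <- ph$labels$data
  # BV/TV inside the bone-bearing region (below the implant top)
  bvtv <- mean(lab[, , 1:30] == 1)
  expect_lt(abs(bvtv - 0.35), 0.08)
  expect_gt(ph$true_contact_fraction, 0)
  expect_lt(ph$true_contact_fraction, 1)
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(voxel_size = 200), "20 voxels")
  expect_error(phantom_spec(grey_means = c(120, 50, 230)), "increasing")
  expect_error(phantom_spec(contact_fraction = 1.2), "contact_fraction")
  expect_error(generate_phantom(phantom_spec(), vol_dim = c(30, 30, 30)),
               "fit")
})
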