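# SUV conversion, resampling, smoothing and thresholding.

tiny_scan <- function(vox, spacing = 5, W = 70000, D = 3.7e8, t = 0,
                      thalf = 109.77) {
  pet_scan(vox, spacing = spacing, weight_g = W, dose_bq = D,
           elapsed_min = t, halflife_min = thalf)
}

test_that("SUV conversion follows the decay-corrected dose-per-mass form", {
  vox <- array(5000, c(2, 2, 2))
  # no elapsed decay: SUV = C * W / D
  s0 <- convert_to_suv(tiny_scan(vox, t = 0))
  expect_equal(s0$voxels, vox * 70000 / 3.7e8)
  # one half-life doubles SUV: 2 * 5000 * 70000 / 3.7e8
  s1 <- convert_to_suv(tiny_scan(vox, t = 109.77))
  expect_equal(s1$voxels[1], 2 * 5000 * 70000 / 3.7e8, tolerance = 1e-12)
  expect_equal(s1$voxels[1], 1.8919, tolerance = 1e-4)
  # zero activity maps to zero SUV
  expect_true(all(convert_to_suv(tiny_scan(array(0, c(2, 2, 2))))$voxels == 0))
})

test_that("SUV conversion matches the scalar oracle on random tuples", {
  set.seed(11)
  for (i in 1:50) {
    C <- runif(1, 0, 5e4)
    W <- runif(1, 2e4, 1.2e5)
    D <- runif(1, 5e7, 5e8)
    t <- runif(1, 0, 180)
    s <- convert_to_suv(tiny_scan(array(C, c(1, 1, 1)), W = W, D = D, t = t))
    expect_equal(s$voxels[1], oracle_suv(C, W, D, t, 109.77),
                 tolerance = 1e-12)
  }
})

test_that("SUV conversion is linear in C, inversely linear in D, and a
           half-life of elapsed time doubles it", {
  set.seed(12)
  vox <- array(runif(27, 0, 1000), c(3, 3, 3))
  base <- convert_to_suv(tiny_scan(vox, t = 30))
  expect_equal(convert_to_suv(tiny_scan(2 * vox, t = 30))$voxels,
               2 * base$voxels)
  expect_equal(convert_to_suv(tiny_scan(vox, t = 30, D = 2 * 3.7e8))$voxels,
               base$voxels / 2)
  expect_equal(convert_to_suv(tiny_scan(vox, t = 30 + 109.77))$voxels,
               2 * base$voxels, tolerance = 1e-12)
})

test_that("invalid acquisition metadata is rejected", {
  vox <- array(1, c(2, 2, 2))
  expect_error(tiny_scan(vox, W = 0), "invalid metadata")
  expect_error(tiny_scan(vox, D = -1), "invalid metadata")
  expect_error(tiny_scan(vox, t = -5), "invalid metadata")
  expect_error(pet_scan(array(-1, c(2, 2, 2)), 5, weight_g = 1, dose_bq = 1,
                        elapsed_min = 0), "finite")
})

test_that("isotropic resampling preserves constants, identity grids and
           linear fields", {
  const <- suv_volume(array(4.2, c(8, 10, 6)), spacing = c(4, 3, 6))
  rs <- resample_isotropic(const, 5)
  expect_true(all(abs(rs$voxels - 4.2) < 1e-9))
  expect_equal(rs$spacing, c(5, 5, 5))

  same <- suv_volume(array(runif(8 * 10 * 6), c(8, 10, 6)), spacing = 5)
  expect_identical(resample_isotropic(same, 5)$voxels, same$voxels)

  # linear-in-position field is reproduced exactly away from boundaries
  d <- c(12, 12, 12)
  sp <- c(2, 3, 4)
  co <- arrayInd(seq_len(prod(d)), d)
  lin <- array(10 + 0.5 * (co[, 1] - 1) * sp[1] + 0.25 * (co[, 2] - 1) * sp[2] +
                 0.1 * (co[, 3] - 1) * sp[3], d)
  rs <- resample_isotropic(suv_volume(lin, sp), 2.5)
  dn <- dim(rs$voxels)
  cn <- arrayInd(seq_len(prod(dn)), dn)
  expected <- 10 + 0.5 * (cn[, 1] - 1) * 2.5 + 0.25 * (cn[, 2] - 1) * 2.5 +
    0.1 * (cn[, 3] - 1) * 2.5
  interior <- cn[, 1] %in% 3:(dn[1] - 2) & cn[, 2] %in% 3:(dn[2] - 2) &
    cn[, 3] %in% 3:(dn[3] - 2)
  expect_lt(max(abs(rs$voxels[interior] - expected[interior])), 1e-6)
})

test_that("Gaussian smoothing preserves constants and the impulse response
           is the normalised separable kernel", {
  const <- suv_volume(array(2.5, c(10, 10, 10)), spacing = 5)
  expect_equal(gaussian_smooth(const, 1)$voxels, const$voxels,
               tolerance = 1e-12)

  d <- c(21, 21, 21)
  imp <- array(0, d)
  imp[11, 11, 11] <- 1
  sm <- gaussian_smooth(suv_volume(imp, 5), sigma_vox = 1, truncate = 4)$voxels
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  k <- petrad:::gaussian_kernel_1d(1, 4)
  r <- (length(k) - 1) / 2
  expect_equal(sm[11 + (-r:r), 11, 11], k * k[r + 1]^2, tolerance = 1e-12)
  expect_error(gaussian_smooth(const, sigma_vox = 0), "sigma_vox")
})

test_that("smoothing conserves interior mass and reduces noise variance by
           the kernel energy", {
  set.seed(21)
  d <- c(48, 48, 48)
  noise <- array(rnorm(prod(d)), d)
  blob <- array(0, d)
  blob[20:28, 20:28, 20:28] <- 7
  sm <- petrad:::smooth3d(blob, 1)
  expect_equal(sum(sm), sum(blob), tolerance = 1e-3 * sum(blob))

  smn <- petrad:::smooth3d(noise, 1)
  k <- petrad:::gaussian_kernel_1d(1, 4)
  kernel_energy <- sum(k^2)^3
  inner <- smn[6:43, 6:43, 6:43]
  expect_equal(var(as.vector(inner)), kernel_energy, tolerance = 0.05)
})

test_that("smoothing commutes with translation in the interior", {
  set.seed(22)
  d <- c(24, 24, 24)
  arr <- array(0, d)
  arr[8:14, 8:14, 8:14] <- runif(343, 1, 5)
  sm <- petrad:::smooth3d(arr, 1)
  shifted <- petrad:::shift3d(arr, c(2L, 1L, 3L), 0)
  sm_shift <- petrad:::smooth3d(shifted, 1)
  reference <- petrad:::shift3d(sm, c(2L, 1L, 3L), 0)
  inner <- 7:18
  expect_equal(sm_shift[inner, inner, inner], reference[inner, inner, inner],
               tolerance = 1e-10)
})

test_that("SUV thresholding is inclusive at the threshold and monotone", {
  vox <- array(c(2.9, 3, 3.1, 0, 5, 1, 2, 3), c(2, 2, 2))
  v <- suv_volume(vox, 5)
  m <- threshold_suv(v, 3)
  expect_identical(m$voxels, vox >= 3)
  expect_equal(sum(m$voxels), 4)  # 3, 3.1, 5, 3
  expect_true(all(threshold_suv(v, 4)$voxels <= m$voxels))
  low <- suv_volume(array(1, c(3, 3, 3)), 5)
  expect_equal(sum(threshold_suv(low, 3)$voxels), 0)
})

test_that("the full chain recovers a uniform SUV-5 organ's volume within 10%", {
  d <- c(40, 40, 40)
  mask <- make_sphere_mask(d, c(20, 20, 20), 8.2)
  suv_true <- array(1, d)
  suv_true[mask] <- 5
  W <- 60000; D <- 3.3e8; t <- 60
  activity <- suv_true * 2^(-t / 109.77) * D / W
  scan <- pet_scan(activity, spacing = 5, weight_g = W, dose_bq = D,
                   elapsed_min = t)
  pre <- preprocess_pet(scan)
  expect_lt(abs(sum(pre$mask$voxels) - sum(mask)) / sum(mask), 0.10)
})
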