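# Radiomics features: discretization, first-order, shape, texture.

test_that("discretization bins equal-width over the region range", {
  expect_equal(discretize(c(3, 4, 5, 6), 2)$gray_levels, c(1L, 1L, 2L, 2L))
  expect_equal(discretize(rep(4, 10), 8)$gray_levels, rep(1L, 10))
  expect_error(discretize(c(1, 2), 1), "n_levels")
  d <- discretize(seq(0, 10, length.out = 33), 32)
  expect_equal(range(d$gray_levels), c(1L, 32L))
  expect_true(all(diff(d$bin_edges) > 0))
})

test_that("first-order features match hand arithmetic and the histogram
           entropy oracle", {
  # two-sample case
  f <- first_order_features(c(2, 4))
  expect_equal(unname(f["mean"]), 3)
  expect_equal(unname(f["rms"]), sqrt(10))
  expect_equal(unname(f["energy"]), 20)
  expect_equal(unname(f["range"]), 2)
  expect_equal(unname(f["mad"]), 1)
  expect_equal(unname(f["median"]), 3)

  # constant region conventions
  n <- 17
  fc <- first_order_features(rep(4, n))
  expect_equal(unname(fc[c("mean", "variance", "energy", "entropy",
                           "uniformity", "skewness", "kurtosis")]),
               c(4, 0, 16 * n, 0, 1, 0, 0))

  # entropy against an independent histogram implementation
  set.seed(41)
  for (i in 1:10) {
    v <- runif(sample(5:200, 1), 0, 10)
    expect_equal(unname(first_order_features(v)["entropy"]),
                 oracle_entropy(v, 32), tolerance = 1e-9)
  }
})

test_that("all 14 first-order features match the brute-force oracle", {
  set.seed(42)
  for (i in 1:20) {
    v <- runif(sample(4:150, 1), 1, 9)
    got <- first_order_features(v)
    want <- oracle_first_order(v)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
})

test_that("first-order scale properties hold", {
  set.seed(43)
  v <- runif(60, 2, 7)
  f1 <- first_order_features(v)
  f2 <- first_order_features(2 * v)
  lin <- c("maximum", "mean", "mad", "median", "minimum", "range", "rms", "sd")
  expect_equal(unname(f2[lin]), unname(2 * f1[lin]), tolerance = 1e-10)
  expect_equal(unname(f2[c("variance", "energy")]),
               unname(4 * f1[c("variance", "energy")]), tolerance = 1e-10)
  inv <- c("skewness", "kurtosis", "uniformity", "entropy")
  expect_equal(unname(f2[inv]), unname(f1[inv]), tolerance = 1e-10)
})

test_that("shape indices are exact in closed form (cube oracle) and
           consistent (compactness2 = sphericity^3)", {
  a <- 40  # mm
  idx <- shape_indices(a^3, 6 * a^2)
  expect_equal(unname(idx["compactness2"]), pi / 6, tolerance = 1e-12)
  expect_equal(unname(idx["sphericity"]), (pi / 6)^(1 / 3), tolerance = 1e-12)
  # sphere in closed form: sphericity and disproportion 1, compactness1 = 1/(6 pi)
  r <- 17
  sph <- shape_indices(4 / 3 * pi * r^3, 4 * pi * r^2)
  expect_equal(unname(sph["sphericity"]), 1, tolerance = 1e-12)
  expect_equal(unname(sph["spherical_disproportion"]), 1, tolerance = 1e-12)
  expect_equal(unname(sph["compactness1"]), 1 / (6 * pi), tolerance = 1e-12)
  set.seed(44)
  for (i in 1:10) {
    v <- runif(1, 10, 1e5)
    s <- runif(1, 50, 5e3)
    ix <- shape_indices(v, s)
    expect_equal(unname(ix["compactness2"]), unname(ix["sphericity"]^3),
                 tolerance = 1e-6)
  }
})

test_that("a digitized sphere has near-unit sphericity and a 1000-voxel
           region at 5 mm spacing has volume 125 mL", {
  dims <- c(27, 27, 27)
  mask <- make_sphere_mask(dims, c(14, 14, 14), 10)
  suv_arr <- array(1, dims)
  suv_arr[mask] <- 5
  reg <- make_region(mask, suv_arr, spacing = 1)
  sf <- shape_features(reg)
  expect_gt(sf[["sphericity"]], 0.95)
  expect_lt(sf[["sphericity"]], 1.05)
  expect_gt(sf[["spherical_disproportion"]], 0.95)
  expect_lt(sf[["spherical_disproportion"]], 1.05)
  expect_equal(sf[["max_diameter_3d"]], 20, tolerance = 0.1)

  cube <- array(FALSE, c(14, 14, 14))
  cube[3:12, 3:12, 3:12] <- TRUE
  regc <- make_region(cube, array(5, c(14, 14, 14)), spacing = 5)
  expect_equal(regc$volume_ml, 1000 * 0.125)  # 1000 voxels, 0.125 mL each
  expect_equal(shape_features(regc)[["volume_ml"]], 125)
})

test_that("centroid features sit at 0.5 for a centred symmetric region and
           shift by the normalised offset under translation", {
  dims <- c(21, 21, 21)
  mask <- make_sphere_mask(dims, c(11, 11, 11), 5)
  suv_arr <- array(2, dims)
  reg <- make_region(mask, suv_arr, spacing = 5)
  sf <- shape_features(reg)
  expect_equal(unname(sf[c("centroid_x", "centroid_y", "centroid_z")]),
               c(0.5, 0.5, 0.5), tolerance = 1e-12)

  mask2 <- make_sphere_mask(dims, c(13, 11, 11), 5)
  sf2 <- shape_features(make_region(mask2, suv_arr, spacing = 5))
  expect_equal(sf2[["centroid_x"]] - sf[["centroid_x"]], 2 / 20,
               tolerance = 1e-12)
  # translation leaves the size/shape block unchanged
  fixed <- c("volume_ml", "surface_area", "sphericity", "compactness2",
             "max_diameter_3d")
  expect_equal(sf2[fixed], sf[fixed], tolerance = 1e-9)
})

test_that("the principal axis follows the elongation and has non-negative Z", {
  dims <- c(31, 15, 15)
  co <- arrayInd(seq_len(prod(dims)), dims)
  elong <- array(((co[, 1] - 16) / 12)^2 + ((co[, 2] - 8) / 4)^2 +
                   ((co[, 3] - 8) / 4)^2 <= 1, dims)
  sf <- shape_features(make_region(elong, array(3, dims), spacing = 5))
  ax <- sf[c("major_axis_x", "major_axis_y", "major_axis_z")]
  expect_equal(abs(unname(ax[1])), 1, tolerance = 1e-6)
  expect_gte(sf[["major_axis_z"]], 0)
  expect_equal(sqrt(sum(ax^2)), 1, tolerance = 1e-9)
})

test_that("texture features collapse correctly on a constant region", {
  dims <- c(5, 5, 5)
  mask <- array(TRUE, dims)
  reg <- make_region(mask, array(4, dims), spacing = 1)
  disc <- discretize(reg, 32)
  expect_warning(tex <- texture_features(disc), "correlation")
  expect_equal(tex[["glcm_contrast"]], 0)
  expect_equal(tex[["glcm_energy"]], 1)
  expect_equal(tex[["glcm_correlation"]], 0)
  # run percentage: 13 directions of straight runs through a full 5^3 cube
  counts <- oracle_glrlm_counts(disc$level_array, disc$n_levels)
  expect_equal(tex[["glrlm_rp"]], sum(counts) / (13 * 125))
})

test_that("a two-level alternating line pattern gives pure off-diagonal
           GLCM mass with contrast 1 along its direction", {
  dims <- c(8, 1, 1)
  suv_arr <- array(rep(c(2, 4), 4), dims)
  reg <- make_region(array(TRUE, dims), suv_arr, spacing = 1)
  disc <- discretize(reg, 2)
  tex <- texture_features(disc, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(tex[["glcm_contrast"]], 1)
  expect_equal(tex[["glcm_max_probability"]], 0.5)
  expect_equal(tex[["glcm_energy"]], 0.5)
})

test_that("GLCM and GLRLM features match brute-force enumeration oracles on
           small random regions", {
  set.seed(45)
  for (i in 1:8) {
    reg <- random_small_region()
    disc <- discretize(reg, sample(3:8, 1))
    tex <- texture_features(disc)
    gc <- oracle_glcm_counts(disc$level_array, disc$n_levels)
    want_glcm <- oracle_glcm_features(gc)
    expect_equal(tex[names(want_glcm)], want_glcm, tolerance = 1e-9)
    gr <- oracle_glrlm_counts(disc$level_array, disc$n_levels)
    want_glrlm <- oracle_glrlm_features(gr, length(disc$gray_levels), 13)
    expect_equal(tex[names(want_glrlm)], want_glrlm, tolerance = 1e-9)
  }
})

test_that("feature vectors have the frozen names and finite values", {
  set.seed(46)
  reg <- random_small_region(c(7, 7, 7))
  f28 <- compute_features(reg, "core28")
  f62 <- compute_features(reg, "full62")
  expect_named(f28, pet_feature_names("core28"))
  expect_named(f62, pet_feature_names("full62"))
  expect_length(f28, 28)
  expect_length(f62, 62)
  expect_true(all(is.finite(f62)))
  expect_equal(f62[pet_feature_names("core28")], f28)
})
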