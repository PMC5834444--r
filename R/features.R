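# Radiomics features per segmented region: 14 first-order SUV statistics,
# 14 shape descriptors (8 standard + 6 spatial), 34 texture statistics
# (23 GLCM + 11 GLRLM).

FIRST_ORDER_NAMES <- c(
  "energy", "entropy", "kurtosis", "maximum", "mean", "mad", "median",
  "minimum", "range", "rms", "skewness", "sd", "uniformity", "variance")

SHAPE_NAMES <- c(
  "volume_ml", "surface_area", "surface_to_volume", "sphericity",
  "spherical_disproportion", "compactness1", "compactness2",
  "max_diameter_3d", "centroid_x", "centroid_y", "centroid_z",
  "major_axis_x", "major_axis_y", "major_axis_z")

GLCM_NAMES <- paste0("glcm_", c(
  "autocorrelation", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_entropy",
  "difference_variance", "dissimilarity", "energy", "entropy",
  "homogeneity1", "homogeneity2", "imc1", "imc2", "idmn", "idn",
  "inverse_variance", "max_probability", "sum_average", "sum_entropy",
  "sum_variance", "variance"))

GLRLM_NAMES <- paste0("glrlm_", c(
  "sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge", "srhge",
  "lrlge", "lrhge"))

TEXTURE_NAMES <- c(GLCM_NAMES, GLRLM_NAMES)

#' Radiomics feature names in their frozen output order
#'
#' @param feature_set `"core28"` (14 first-order + 14 shape) or `"full62"`
#'   (core set plus 34 texture features).
#' @return Character vector of feature names.
#' @export
pet_feature_names <- function(feature_set = c("core28", "full62")) {
  feature_set <- match.arg(feature_set)
  base <- c(FIRST_ORDER_NAMES, SHAPE_NAMES)
  if (feature_set == "full62") c(base, TEXTURE_NAMES) else base
}

# the 13 unique 3-D direction offsets at distance 1 (first non-zero positive)
DIRS13 <- matrix(c(
  1, 0, 0,   0, 1, 0,   0, 0, 1,
  1, 1, 0,   1, -1, 0,  1, 0, 1,   1, 0, -1,
  0, 1, 1,   0, 1, -1,
  1, 1, 1,   1, 1, -1,  1, -1, 1,  1, -1, -1), ncol = 3, byrow = TRUE)

#' Discretize a region's SUV samples into equal-width gray levels
#'
#' Equal-width bins spanning the region's own SUV range; a constant region
#' maps every voxel to level 1. The levels substrate is used by entropy,
#' uniformity and all texture features.
#'
#' @param region a `pet_region` (or a bare numeric vector of SUV samples).
#' @param n_levels number of gray levels (>= 2; default 32).
#' @return An object of class `discretized_region` with `gray_levels`
#'   (integer per region voxel), `n_levels`, `bin_edges`, and, when built
#'   from a region, `level_array` (levels placed in the region bounding box,
#'   0 outside the region).
#' @export
discretize <- function(region, n_levels = 32) {
  if (!is.finite(n_levels) || n_levels < 2)
    stop("n_levels must be >= 2", call. = FALSE)
  n_levels <- as.integer(n_levels)
  values <- if (inherits(region, "pet_region")) region$suv_values else as.numeric(region)
  if (length(values) == 0L) stop("region must be non-empty", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) {
    lev <- rep(1L, length(values))
    edges <- seq(lo, lo + 1, length.out = n_levels + 1L)
  } else {
    width <- (hi - lo) / n_levels
    lev <- pmin(n_levels, as.integer(floor((values - lo) / width)) + 1L)
    edges <- seq(lo, hi, length.out = n_levels + 1L)
  }
  out <- list(gray_levels = lev, n_levels = n_levels, bin_edges = edges)
  if (inherits(region, "pet_region")) {
    bb <- region$bbox
    dsub <- bb[2, ] - bb[1, ] + 1L
    arr <- array(0L, dsub)
    co <- arrayInd(region$voxel_idx, region$dim)
    co <- sweep(co, 2, bb[1, ] - 1L)
    arr[cbind(co[, 1], co[, 2], co[, 3])] <- lev
    out$level_array <- arr
  }
  structure(out, class = "discretized_region")
}

#' First-order SUV features
#'
#' The 14 intensity-histogram statistics of a region's (smoothed) SUV
#' samples: energy, entropy, kurtosis, maximum, mean, mean absolute
#' deviation, median, minimum, range, root mean square, skewness, standard
#' deviation, uniformity and variance. Entropy (base 2) and uniformity are
#' computed on the discretized gray levels; moments use the population
#' (n-denominator) convention and kurtosis is excess kurtosis (Gaussian
#' gives 0). Constant regions take skewness = kurtosis = 0, entropy = 0 and
#' uniformity = 1.
#'
#' @param region a `pet_region`.
#' @param disc optional [discretize()] result (recomputed with `n_levels`
#'   when missing).
#' @param n_levels gray levels for the entropy/uniformity histogram.
#' @return Named numeric vector of the 14 features.
#' @export
first_order_features <- function(region, disc = NULL, n_levels = 32) {
  v <- if (inherits(region, "pet_region")) region$suv_values else as.numeric(region)
  if (length(v) == 0L) stop("region must be non-empty", call. = FALSE)
  if (is.null(disc)) disc <- discretize(v, n_levels)
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  p <- tabulate(disc$gray_levels, nbins = disc$n_levels) / n
  p <- p[p > 0]
  c(energy = sum(v^2),
    entropy = -sum(p * log2(p)),
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    maximum = max(v),
    mean = m,
    mad = mean(abs(v - m)),
    median = median(v),
    minimum = min(v),
    range = max(v) - min(v),
    rms = sqrt(mean(v^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    sd = sqrt(m2),
    uniformity = sum(p^2),
    variance = m2)
}

#' Shape indices from volume and surface area
#'
#' Closed-form indices comparing a region's surface area to that of the
#' volume-equivalent sphere: sphericity `pi^(1/3) (6V)^(2/3) / A`, spherical
#' disproportion `A / (4 pi R^2)` with `R` the volume-equivalent radius,
#' compactness 1 `V / (sqrt(pi) A^(3/2))` and compactness 2
#' `36 pi V^2 / A^3` (= sphericity cubed).
#'
#' @param volume_mm3 region volume in mm^3.
#' @param area_mm2 region surface area in mm^2.
#' @return Named numeric vector: `sphericity`, `spherical_disproportion`,
#'   `compactness1`, `compactness2`, `surface_to_volume`.
#' @export
shape_indices <- function(volume_mm3, area_mm2) {
  r_eq <- (3 * volume_mm3 / (4 * pi))^(1 / 3)
  c(sphericity = pi^(1 / 3) * (6 * volume_mm3)^(2 / 3) / area_mm2,
    spherical_disproportion = area_mm2 / (4 * pi * r_eq^2),
    compactness1 = volume_mm3 / (sqrt(pi) * area_mm2^1.5),
    compactness2 = 36 * pi * volume_mm3^2 / area_mm2^3,
    surface_to_volume = area_mm2 / volume_mm3)
}

# Surface area of a voxel region by the coarea estimator: the binary mask is
# Gaussian-smoothed and the integral of the gradient magnitude of the
# resulting indicator field equals the interface area (exact for planar
# interfaces, relative error ~ (sigma/R)^2 for curvature radius R).
surface_area_coarea <- function(mask, spacing_mm, sigma_vox = 1) {
  pad <- as.integer(ceiling(4 * sigma_vox)) + 2L
  d <- dim(mask)
  big <- array(0, d + 2L * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  f <- smooth3d(big, sigma_vox)
  gx <- (shift3d(f, c(-1L, 0L, 0L), 0) - shift3d(f, c(1L, 0L, 0L), 0)) / 2
  gy <- (shift3d(f, c(0L, -1L, 0L), 0) - shift3d(f, c(0L, 1L, 0L), 0)) / 2
  gz <- (shift3d(f, c(0L, 0L, -1L), 0) - shift3d(f, c(0L, 0L, 1L), 0)) / 2
  sum(sqrt(gx^2 + gy^2 + gz^2)) * spacing_mm^2
}

# deterministic Fibonacci-sphere direction set for diameter pruning
fib_directions <- function(n = 200) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

max_diameter_3d <- function(surface_coords_mm) {
  n <- nrow(surface_coords_mm)
  if (n <= 1L) return(0)
  if (n > 400L) {
    proj <- surface_coords_mm %*% t(fib_directions(200))
    cand <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
    surface_coords_mm <- surface_coords_mm[cand, , drop = FALSE]
  }
  .max_pair_dist(surface_coords_mm)
}

#' Shape features of a segmented region
#'
#' The 8 standard 3-D shape descriptors (volume in mL, surface area,
#' surface-to-volume ratio, sphericity, spherical disproportion,
#' compactness 1 and 2, maximum 3-D diameter) plus 6 spatial descriptors:
#' the SUV-weighted centroid normalised to `[0, 1]` within the scan bounding
#' box, and the unit principal axis of the voxel-coordinate covariance
#' (sign fixed to a non-negative Z component). Surface area uses the coarea
#' estimator on the smoothed region mask; the maximum diameter is the
#' largest pairwise distance between surface-voxel centres.
#'
#' A single-voxel region falls back to the exact voxel cube (area `6 h^2`,
#' diameter `h sqrt(3)`).
#'
#' @param region a `pet_region` (carries its scan grid geometry).
#' @return Named numeric vector of the 14 shape features.
#' @export
shape_features <- function(region) {
  if (!inherits(region, "pet_region")) stop("region must be a pet_region", call. = FALSE)
  h <- region$spacing[1]
  if (!is_isotropic(region$spacing))
    stop("shape features require isotropic spacing", call. = FALSE)
  n <- length(region$voxel_idx)
  vol_mm3 <- n * h^3
  co <- arrayInd(region$voxel_idx, region$dim)   # voxel indices
  bb <- region$bbox
  dsub <- bb[2, ] - bb[1, ] + 1L
  msub <- array(FALSE, dsub)
  cos_ <- sweep(co, 2, bb[1, ] - 1L)
  msub[cbind(cos_[, 1], cos_[, 2], cos_[, 3])] <- TRUE

  if (n == 1L) {
    area <- 6 * h^2
    maxd <- sqrt(3) * h
  } else {
    area <- surface_area_coarea(msub, h)
    # surface voxels: any of the 6 neighbours outside the region
    interior <- array(TRUE, dsub)
    for (a in 1:3) for (s in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L)
      d[a] <- s
      interior <- interior & shift3d(msub, d, FALSE)
    }
    surf <- msub & !interior
    sco <- which(surf, arr.ind = TRUE)
    maxd <- max_diameter_3d(sco * h)
  }
  idx_shape <- shape_indices(vol_mm3, area)

  # SUV-weighted centroid, normalised to the scan bounding box
  w <- region$suv_values / sum(region$suv_values)
  cen_idx <- colSums(co * w)                     # index units
  extent <- region$dim - 1L
  if (any(extent == 0L))
    stop("scan bounding box has a zero-extent axis", call. = FALSE)
  cen_rel <- (cen_idx - 1) / extent

  # principal axis of the voxel-coordinate covariance
  if (n >= 2L) {
    cc <- sweep(co, 2, colMeans(co))
    ev <- eigen(crossprod(cc) / n, symmetric = TRUE)
    ax <- ev$vectors[, 1]
  } else {
    ax <- c(0, 0, 1)
  }
  flip <- if (ax[3] != 0) ax[3] < 0 else if (ax[2] != 0) ax[2] < 0 else ax[1] < 0
  if (flip) ax <- -ax

  out <- c(vol_mm3 / 1000, area, idx_shape[["surface_to_volume"]],
           idx_shape[["sphericity"]], idx_shape[["spherical_disproportion"]],
           idx_shape[["compactness1"]], idx_shape[["compactness2"]],
           maxd, cen_rel, ax)
  names(out) <- SHAPE_NAMES
  out
}

# --- texture matrices -------------------------------------------------------

# symmetric GLCM counts pooled over the given directions
glcm_matrix <- function(level_array, n_levels, directions = DIRS13) {
  K <- n_levels
  counts <- matrix(0, K, K)
  for (i in seq_len(nrow(directions))) {
    d <- directions[i, ]
    nb <- shift3d(level_array, d, 0L)
    ok <- level_array > 0L & nb > 0L
    if (!any(ok)) next
    a <- level_array[ok]
    b <- nb[ok]
    tab <- tabulate((a - 1L) * K + b, nbins = K * K)
    cm <- matrix(tab, K, K, byrow = TRUE)
    counts <- counts + cm + t(cm)
  }
  counts
}

glcm_features <- function(p, warn_degenerate = TRUE) {
  K <- nrow(p)
  i <- matrix(seq_len(K), K, K)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(K) * px)
  var_x <- sum((seq_len(K) - mu_x)^2 * px)
  sd_x <- sqrt(var_x)
  plog <- function(q) ifelse(q > 0, log2(q), 0)

  # diagonal (i - j) and cross-diagonal (i + j) marginals
  kd <- 0:(K - 1)
  p_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * K)
  p_sum <- vapply(ks, function(k) sum(p[(i + j) == k]), numeric(1))

  hxy <- -sum(p * plog(p))
  pxy <- outer(px, px)
  hxy1 <- -sum(p * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))
  hx <- -sum(px * plog(px))

  if (sd_x <= 0 && warn_degenerate)
    warning("constant gray levels: GLCM correlation undefined, reported as 0",
            call. = FALSE)
  correlation <- if (sd_x > 0) (sum(i * j * p) - mu_x^2) / var_x else 0
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  mu_diff <- sum(kd * p_diff)
  sa <- sum(ks * p_sum)

  c(autocorrelation = sum(i * j * p),
    cluster_prominence = sum((i + j - 2 * mu_x)^4 * p),
    cluster_shade = sum((i + j - 2 * mu_x)^3 * p),
    cluster_tendency = sum((i + j - 2 * mu_x)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = correlation,
    difference_entropy = -sum(p_diff * plog(p_diff)),
    difference_variance = sum((kd - mu_diff)^2 * p_diff),
    dissimilarity = sum(abs(i - j) * p),
    energy = sum(p^2),
    entropy = hxy,
    homogeneity1 = sum(p / (1 + abs(i - j))),
    homogeneity2 = sum(p / (1 + (i - j)^2)),
    imc1 = imc1,
    imc2 = imc2,
    idmn = sum(p / (1 + (i - j)^2 / K^2)),
    idn = sum(p / (1 + abs(i - j) / K)),
    inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    max_probability = max(p),
    sum_average = sa,
    sum_entropy = -sum(p_sum * plog(p_sum)),
    sum_variance = sum((ks - sa)^2 * p_sum),
    variance = sum((i - mu_x)^2 * p))
}

# run-length counts (levels x run length) pooled over the given directions
glrlm_matrix <- function(level_array, n_levels, directions = DIRS13) {
  d <- dim(level_array)
  idx <- which(level_array > 0L)
  co <- arrayInd(idx, d)
  lev <- level_array[idx]
  maxlen <- max(d)
  counts <- matrix(0, n_levels, maxlen)
  for (k in seq_len(nrow(directions))) {
    dd <- directions[k, ]
    t_pos <- as.vector(co %*% dd)
    # cross product with the direction identifies the line
    key1 <- co[, 2] * dd[3] - co[, 3] * dd[2]
    key2 <- co[, 3] * dd[1] - co[, 1] * dd[3]
    key3 <- co[, 1] * dd[2] - co[, 2] * dd[1]
    ord <- order(key1, key2, key3, t_pos)
    k1 <- key1[ord]; k2 <- key2[ord]; k3 <- key3[ord]
    tp <- t_pos[ord]; lv <- lev[ord]
    nv <- length(ord)
    step <- sum(dd^2)
    newrun <- c(TRUE, k1[-1] != k1[-nv] | k2[-1] != k2[-nv] |
                  k3[-1] != k3[-nv] | lv[-1] != lv[-nv] |
                  (tp[-1] - tp[-nv]) != step)
    runid <- cumsum(newrun)
    rlen <- tabulate(runid)
    rlev <- lv[newrun]
    tab <- tabulate((rlev - 1L) * maxlen + rlen, nbins = n_levels * maxlen)
    counts <- counts + matrix(tab, n_levels, maxlen, byrow = TRUE)
  }
  counts
}

glrlm_features <- function(r, n_voxels, n_dirs) {
  nr <- sum(r)
  iG <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))
  jL <- matrix(seq_len(ncol(r)), nrow(r), ncol(r), byrow = TRUE)
  c(sre = sum(r / jL^2) / nr,
    lre = sum(r * jL^2) / nr,
    gln = sum(rowSums(r)^2) / nr,
    rln = sum(colSums(r)^2) / nr,
    rp = nr / (n_dirs * n_voxels),
    lgre = sum(r / iG^2) / nr,
    hgre = sum(r * iG^2) / nr,
    srlge = sum(r / (iG^2 * jL^2)) / nr,
    srhge = sum(r * iG^2 / jL^2) / nr,
    lrlge = sum(r * jL^2 / iG^2) / nr,
    lrhge = sum(r * iG^2 * jL^2) / nr)
}

#' Texture features from a discretized region
#'
#' 23 gray-level co-occurrence (GLCM) and 11 gray-level run-length (GLRLM)
#' statistics. Both matrices are built symmetric at voxel distance 1 over
#' the 13 unique 3-D directions and pooled before the statistics are taken.
#' A constant region collapses to a single-level matrix: contrast-type
#' features are 0, GLCM energy is 1 and correlation (undefined) is reported
#' as 0 with a warning.
#'
#' @param disc a [discretize()] result built from a `pet_region` (so that
#'   the spatial level array is available).
#' @param directions optional integer matrix of direction offsets (rows
#'   `(dx, dy, dz)`); defaults to the 13 unique 3-D directions.
#' @return Named numeric vector of the 34 texture features.
#' @export
texture_features <- function(disc, directions = NULL) {
  if (!inherits(disc, "discretized_region") || is.null(disc$level_array))
    stop("disc must be discretized from a pet_region", call. = FALSE)
  if (length(disc$gray_levels) < 2L)
    stop("texture features require >= 2 voxels", call. = FALSE)
  if (is.null(directions)) directions <- DIRS13
  K <- disc$n_levels
  counts <- glcm_matrix(disc$level_array, K, directions)
  if (sum(counts) == 0) counts <- matrix(1, 1, 1)  # isolated voxels only
  gl <- glcm_features(counts / sum(counts))
  rl_counts <- glrlm_matrix(disc$level_array, K, directions)
  rl <- glrlm_features(rl_counts, length(disc$gray_levels),
                             nrow(directions))
  out <- c(gl, rl)
  names(out) <- TEXTURE_NAMES
  out
}


#' Compute the radiomics feature vector for one region
#'
#' @param region a `pet_region`.
#' @param feature_set `"core28"` or `"full62"`.
#' @param n_levels gray levels for discretization (default 32).
#' @return Named numeric vector in the frozen [pet_feature_names()] order.
#' @export
compute_features <- function(region, feature_set = c("core28", "full62"),
                             n_levels = 32) {
  feature_set <- match.arg(feature_set)
  disc <- discretize(region, n_levels)
  out <- c(first_order_features(region, disc), shape_features(region))
  if (feature_set == "full62") {
    tex <- if (length(region$voxel_idx) >= 2L) {
      texture_features(disc)
    } else {
      z <- rep(0, length(TEXTURE_NAMES))
      names(z) <- TEXTURE_NAMES
      z
    }
    out <- c(out, tex)
  }
  out[pet_feature_names(feature_set)]
}

#' Feature table for a list of regions
#'
#' @param regions list of `pet_region` objects.
#' @inheritParams compute_features
#' @return data.frame, one row per region, `region_id` first then the
#'   features in frozen order.
#' @export
features_table <- function(regions, feature_set = c("core28", "full62"),
                           n_levels = 32) {
  feature_set <- match.arg(feature_set)
  nm <- pet_feature_names(feature_set)
  if (length(regions) == 0L) {
    df <- as.data.frame(matrix(numeric(), 0, length(nm) + 1))
    names(df) <- c("region_id", nm)
    return(df)
  }
  mat <- t(vapply(regions, compute_features, numeric(length(nm)),
                  feature_set = feature_set, n_levels = n_levels))
  df <- data.frame(region_id = vapply(regions, `[[`, integer(1), "id"), mat)
  names(df) <- c("region_id", nm)
  df
}
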