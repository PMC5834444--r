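# Preprocessing: SUV conversion, isotropic resampling, Gaussian smoothing,
# SUV thresholding.

#' Convert a PET activity image to standard uptake values
#'
#' SUV(x) = C(x) / 2^(-t / T1/2) * W / D: the measured activity concentration
#' is decay-corrected back to injection time and normalised by injected dose
#' per body mass. With activity in Bq/mL and weight in grams the result
#' carries g/mL, the standard body-weight SUV convention.
#'
#' @param scan a [pet_scan()].
#' @return A [suv_volume()] on the same grid as `scan`.
#' @export
convert_to_suv <- function(scan) {
  if (!inherits(scan, "pet_scan")) stop("scan must be a pet_scan", call. = FALSE)
  decay <- 2^(-scan$elapsed_min / scan$halflife_min)
  suv <- scan$voxels / decay * (scan$weight_g / scan$dose_bq)
  suv_volume(suv, spacing = scan$spacing, origin = scan$origin)
}

# Keys cubic-convolution kernel, a = -1/2 (reproduces polynomials up to
# degree 2 exactly in the interior).
keys_weights <- function(u) {
  # u in [0,1): offsets -1, 0, 1, 2 from the floor sample
  s <- abs(outer(u, c(-1, 0, 1, 2), "-"))
  a <- -0.5
  w <- ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
              ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
  w
}

# Cubic interpolation of a 3-D array along one axis to positions `pos`
# (in source index units, 1-based). Replicate boundary handling.
resample_axis <- function(arr, axis, pos) {
  d <- dim(arr)
  n <- d[axis]
  f <- floor(pos)
  u <- pos - f
  w <- keys_weights(u)                       # length(pos) x 4
  idx <- outer(f, c(-1, 0, 1, 2), "+")       # length(pos) x 4
  idx <- pmin(pmax(idx, 1L), n)
  newd <- d
  newd[axis] <- length(pos)
  out <- array(0, newd)
  for (m in seq_len(4L)) {
    take <- idx[, m]
    slab <- switch(axis,
                   arr[take, , , drop = FALSE],
                   arr[, take, , drop = FALSE],
                   arr[, , take, drop = FALSE])
    wm <- w[, m]
    wfull <- switch(axis,
                    array(wm, newd),
                    aperm(array(wm, newd[c(2, 1, 3)]), c(2, 1, 3)),
                    aperm(array(wm, newd[c(3, 1, 2)]), c(2, 3, 1)))
    out <- out + wfull * slab
  }
  out
}

#' Resample a volume to an isotropic grid
#'
#' Cubic (Keys) interpolation along each axis in turn, to a cubic voxel of
#' side `target_mm` (default 5 mm). The first voxel centre is kept at the
#' original origin and the grid length is chosen so the physical extent is
#' preserved to within one voxel. Interpolation overshoot below zero is
#' clamped to 0. A volume already at the target spacing is returned
#' unchanged.
#'
#' @param x a [suv_volume()] or [pet_scan()].
#' @param target_mm isotropic voxel size in mm (> 0).
#' @return Object of the same class as `x` on the isotropic grid.
#' @export
resample_isotropic <- function(x, target_mm = 5) {
  if (!is.finite(target_mm) || target_mm <= 0)
    stop("target_mm must be > 0", call. = FALSE)
  if (!inherits(x, c("suv_volume", "pet_scan")))
    stop("x must be a suv_volume or pet_scan", call. = FALSE)
  if (is.null(x$spacing)) stop("spacing metadata missing", call. = FALSE)
  sp <- x$spacing
  if (all(abs(sp - target_mm) <= 1e-9)) return(x)
  arr <- x$voxels
  for (axis in 1:3) {
    n_old <- dim(arr)[axis]
    n_new <- max(1L, as.integer(floor((n_old - 1) * sp[axis] / target_mm + 1e-9)) + 1L)
    pos <- ((seq_len(n_new) - 1) * target_mm) / sp[axis] + 1
    arr <- resample_axis(arr, axis, pos)
  }
  arr[arr < 0] <- 0
  x$voxels <- arr
  x$spacing <- rep(target_mm, 3)
  x
}

gaussian_kernel_1d <- function(sigma_vox, truncate = 4) {
  if (!is.finite(sigma_vox) || sigma_vox <= 0)
    stop("sigma_vox must be > 0", call. = FALSE)
  if (!is.finite(truncate) || truncate < 2)
    stop("truncate must be >= 2", call. = FALSE)
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable correlation with a symmetric 1-D kernel along `axis`,
# replicate-padded (constants are preserved exactly).
filter_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (off in -r:r) {
    take <- pmin(pmax(base + off, 1L), n)
    slab <- switch(axis,
                   arr[take, , , drop = FALSE],
                   arr[, take, , drop = FALSE],
                   arr[, , take, drop = FALSE])
    out <- out + k[off + r + 1L] * slab
  }
  out
}

smooth3d <- function(arr, sigma_vox, truncate = 4) {
  k <- gaussian_kernel_1d(sigma_vox, truncate)
  for (axis in 1:3) arr <- filter_axis(arr, k, axis)
  arr
}

#' Gaussian smoothing of an isotropic SUV volume
#'
#' Convolution with a normalised, separable, isotropic 3-D Gaussian of width
#' `sigma_vox` voxels (support truncated at `truncate` sigma, boundary
#' replicated). Used for noise reduction before thresholding so that organ
#' interiors present a near-uniform SUV.
#'
#' @param vol a [suv_volume()] with isotropic spacing.
#' @param sigma_vox kernel width in voxels (> 0); default 1 voxel (5 mm at
#'   the default grid).
#' @param truncate kernel support radius in units of sigma (>= 2).
#' @return A smoothed [suv_volume()].
#' @export
gaussian_smooth <- function(vol, sigma_vox = 1, truncate = 4) {
  if (!inherits(vol, "suv_volume")) stop("vol must be a suv_volume", call. = FALSE)
  if (!is_isotropic(vol$spacing))
    stop("gaussian_smooth requires an isotropic volume; resample first",
         call. = FALSE)
  vol$voxels <- smooth3d(vol$voxels, sigma_vox, truncate)
  vol
}

#' Threshold a smoothed SUV volume into a high-uptake mask
#'
#' The mask is true exactly where SUV >= `thr` (inclusive); the default
#' threshold is SUV 3, the value used to isolate FDG-avid tissue.
#'
#' @param vol a [suv_volume()] (normally the smoothed volume).
#' @param thr SUV threshold (> 0); default 3.
#' @return A [binary_mask()] on the grid of `vol`.
#' @export
threshold_suv <- function(vol, thr = 3) {
  if (!inherits(vol, "suv_volume")) stop("vol must be a suv_volume", call. = FALSE)
  if (!is.finite(thr) || thr <= 0) stop("thr must be > 0", call. = FALSE)
  binary_mask(vol$voxels >= thr, spacing = vol$spacing, origin = vol$origin)
}

#' Full preprocessing chain
#'
#' [convert_to_suv()], [resample_isotropic()], [gaussian_smooth()] and
#' [threshold_suv()] applied in that order.
#'
#' @param scan a [pet_scan()].
#' @param target_mm isotropic voxel size in mm.
#' @param sigma_vox Gaussian width in voxels.
#' @param truncate Gaussian support radius in sigma.
#' @param threshold SUV threshold.
#' @return A list with elements `suv` (resampled SUV volume), `smoothed`
#'   (smoothed SUV volume) and `mask` (high-uptake [binary_mask()]).
#' @export
preprocess_pet <- function(scan, target_mm = 5, sigma_vox = 1, truncate = 4,
                           threshold = 3) {
  suv <- resample_isotropic(convert_to_suv(scan), target_mm)
  smoothed <- gaussian_smooth(suv, sigma_vox = sigma_vox, truncate = truncate)
  list(suv = suv, smoothed = smoothed,
       mask = threshold_suv(smoothed, thr = threshold))
}
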