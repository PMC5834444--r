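#' @useDynLib petrad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rpois rlnorm sd var t.test lm coef predict quantile
#' @importFrom utils head write.csv
NULL

F18_HALFLIFE_MIN <- 109.77

as_spacing3 <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 1 or 3 positive finite values (mm)", call. = FALSE)
  spacing
}

check_volume_array <- function(voxels, what = "voxels") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop(what, " must be a 3-D array", call. = FALSE)
  invisible(voxels)
}

#' PET activity scan
#'
#' Container for a raw 3-D PET activity volume (Bq/mL) together with the
#' acquisition metadata needed for SUV conversion: body weight, injected dose,
#' injection-to-scan delay and radionuclide half-life.
#'
#' @param voxels 3-D numeric array of activity concentration in Bq/mL
#'   (finite, non-negative).
#' @param spacing voxel size in mm; scalar or length-3 `(dx, dy, dz)`.
#' @param origin physical coordinates (mm) of the centre of voxel `[1,1,1]`.
#' @param weight_g patient body weight in grams (> 0).
#' @param dose_bq injected dose in Bq (> 0).
#' @param elapsed_min minutes from injection to scan (>= 0).
#' @param halflife_min radionuclide half-life in minutes; defaults to F-18
#'   (109.77 min).
#' @return An object of class `pet_scan`.
#' @export
pet_scan <- function(voxels, spacing, origin = c(0, 0, 0),
                     weight_g, dose_bq, elapsed_min,
                     halflife_min = F18_HALFLIFE_MIN) {
  check_volume_array(voxels)
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("activity voxels must be finite and >= 0", call. = FALSE)
  spacing <- as_spacing3(spacing)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have 3 components", call. = FALSE)
  if (!is.finite(weight_g) || weight_g <= 0 ||
      !is.finite(dose_bq) || dose_bq <= 0 ||
      !is.finite(halflife_min) || halflife_min <= 0)
    stop("invalid metadata: weight_g, dose_bq and halflife_min must be > 0",
         call. = FALSE)
  if (!is.finite(elapsed_min) || elapsed_min < 0)
    stop("invalid metadata: elapsed_min must be >= 0", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 weight_g = weight_g, dose_bq = dose_bq,
                 elapsed_min = elapsed_min, halflife_min = halflife_min),
            class = "pet_scan")
}

#' @export
print.pet_scan <- function(x, ...) {
  cat("<pet_scan> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = "x"), " mm\n",
      "  weight ", x$weight_g / 1000, " kg, dose ",
      signif(x$dose_bq / 1e6, 4), " MBq, t = ", x$elapsed_min,
      " min, T1/2 = ", x$halflife_min, " min\n", sep = "")
  invisible(x)
}

#' SUV volume
#'
#' A 3-D standard-uptake-value image (g/mL) with voxel spacing and origin.
#' After [resample_isotropic()] the spacing is equal on all three axes, which
#' the smoothing and segmentation stages require.
#'
#' @param voxels 3-D numeric array of SUV (finite, non-negative).
#' @param spacing voxel size in mm; scalar or length-3.
#' @param origin physical coordinates (mm) of voxel `[1,1,1]`.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  check_volume_array(voxels)
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("SUV voxels must be finite and >= 0", call. = FALSE)
  structure(list(voxels = voxels, spacing = as_spacing3(spacing),
                 origin = as.numeric(origin)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, SUV range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

is_isotropic <- function(spacing, tol = 1e-8) {
  diff(range(spacing)) <= tol * max(spacing)
}

#' Binary high-uptake mask
#'
#' Logical 3-D mask on the same grid as its source SUV volume.
#'
#' @param voxels 3-D logical array.
#' @param spacing,origin grid geometry, matching the source volume.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  check_volume_array(voxels)
  if (!is.logical(voxels)) stop("mask voxels must be logical", call. = FALSE)
  structure(list(voxels = voxels, spacing = as_spacing3(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " foreground\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-8))
}

#' Read a PET NIfTI volume with acquisition metadata
#'
#' Thin wrapper over [RNifti::readNifti()]; metadata is supplied explicitly
#' (NIfTI headers do not carry dose information). Weight is taken in kg and
#' dose in MBq at this I/O layer and converted to the g / Bq units the SUV
#' formula uses.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param weight_kg body weight in kg.
#' @param dose_mbq injected dose in MBq.
#' @param elapsed_min injection-to-scan time in minutes.
#' @param halflife_min radionuclide half-life in minutes.
#' @return A [pet_scan()].
#' @export
read_pet_nifti <- function(path, weight_kg, dose_mbq, elapsed_min,
                           halflife_min = F18_HALFLIFE_MIN) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  pix <- RNifti::pixdim(img)
  pet_scan(vox, spacing = pix[seq_len(3)],
           weight_g = weight_kg * 1000, dose_bq = dose_mbq * 1e6,
           elapsed_min = elapsed_min, halflife_min = halflife_min)
}

#' Write a volume or mask as NIfTI
#'
#' @param x a `suv_volume`, `binary_mask`, `region_label_map` or bare 3-D array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing voxel size in mm (taken from `x` when it carries one).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, spacing = NULL) {
  if (is.list(x) && !is.null(x$voxels)) {
    spacing <- x$spacing
    x <- x$voxels
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  arr <- if (is.logical(x) || is.integer(x)) array(as.integer(x), dim(x)) else x
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- as_spacing3(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
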