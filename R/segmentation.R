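# Watershed partitioning of the high-uptake mask into candidate tissue
# regions, morphological closing, and region extraction.

#' Labelled region map
#'
#' Integer 3-D array with 0 = background and 1..K = region ids, plus grid
#' geometry.
#'
#' @param voxels 3-D integer array of labels.
#' @param spacing,origin grid geometry.
#' @return An object of class `region_label_map`.
#' @export
region_label_map <- function(voxels, spacing, origin = c(0, 0, 0)) {
  check_volume_array(voxels)
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = as_spacing3(spacing),
                 origin = as.numeric(origin)),
            class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  k <- max(0L, x$voxels)
  cat("<region_label_map> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", k, " regions\n", sep = "")
  invisible(x)
}

# bounding box (2 x 3 index matrix) of TRUE voxels / a linear index set
bbox_of <- function(idx, dims) {
  coords <- arrayInd(idx, dims)
  rbind(lo = apply(coords, 2, min), hi = apply(coords, 2, max))
}

# shift a 3-D array by (dx,dy,dz), padding with `fill`
shift3d <- function(arr, d, fill) {
  dm <- dim(arr)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= 0) {
      dst[[a]] <- seq_len(dm[a] - d[a]) + d[a]
      src[[a]] <- seq_len(dm[a] - d[a])
    } else {
      dst[[a]] <- seq_len(dm[a] + d[a])
      src[[a]] <- seq_len(dm[a] + d[a]) - d[a]
    }
    if (length(dst[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

max_filter6 <- function(arr) {
  out <- arr
  for (a in 1:3) for (s in c(-1L, 1L)) {
    d <- c(0L, 0L, 0L)
    d[a] <- s
    out <- pmax(out, shift3d(arr, d, -Inf))
  }
  out
}

# Grayscale reconstruction of (f - h) under f by iterated geodesic dilation
# (6-connected); returns the reconstruction. f uses -Inf outside the domain.
reconstruct_minus_h <- function(f, h) {
  rec <- f - h
  repeat {
    nxt <- pmin(f, max_filter6(rec))
    if (identical(nxt, rec)) return(rec)
    rec <- nxt
  }
}

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

dilate_ball <- function(m, offs) {
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) out <- out | shift3d(m, offs[i, ], FALSE)
  out
}

erode_ball <- function(m, offs) {
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offs))) out <- out & shift3d(m, offs[i, ], FALSE)
  out
}

#' Watershed partitioning of the high-uptake mask
#'
#' Each 26-connected component of the mask is partitioned by a marker-based
#' watershed on the inverted smoothed SUV landscape: markers are the h-maxima
#' of the smoothed SUV inside the component (peaks standing at least `h` SUV
#' above their saddle, computed by grayscale reconstruction), and the flood
#' claims voxels in order of descending SUV through 6-connected steps, ties
#' broken towards the smaller linear voxel index. Touching organs with
#' distinct SUV peaks are thereby split; a component with a single marker is
#' returned whole.
#'
#' @param mask a [binary_mask()] of high-uptake voxels.
#' @param suv the smoothed [suv_volume()] on the same grid.
#' @param h h-maxima depth in SUV units (default 1.0).
#' @return A [region_label_map()]; every true mask voxel belongs to exactly
#'   one region. An empty mask gives an empty label map.
#' @export
watershed_regions <- function(mask, suv, h = 1.0) {
  if (!inherits(mask, "binary_mask")) stop("mask must be a binary_mask", call. = FALSE)
  if (!inherits(suv, "suv_volume")) stop("suv must be a suv_volume", call. = FALSE)
  if (!same_grid(mask, suv)) stop("mask and suv grids differ", call. = FALSE)
  dims <- dim(mask$voxels)
  out <- array(0L, dims)
  if (!any(mask$voxels))
    return(region_label_map(out, mask$spacing, mask$origin))

  comp <- .cc_label(as.logical(mask$voxels), as.integer(dims), 26L)
  ncomp <- attr(comp, "max_label")
  comp <- array(comp, dims)
  next_label <- 0L
  for (ci in seq_len(ncomp)) {
    idx <- which(comp == ci)
    bb <- bbox_of(idx, dims)
    sub <- list(bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3])
    cm <- comp[sub[[1]], sub[[2]], sub[[3]], drop = FALSE] == ci
    dim(cm) <- lengths(sub)
    f <- array(-Inf, dim(cm))
    f[cm] <- suv$voxels[sub[[1]], sub[[2]], sub[[3]]][cm]
    rec <- reconstruct_minus_h(f, h)
    markers_mask <- cm & (f - rec >= h - 1e-7)
    mk <- .cc_label(as.logical(markers_mask), as.integer(dim(cm)), 26L)
    nmk <- attr(mk, "max_label")
    if (nmk <= 1L) {
      next_label <- next_label + 1L
      lab_sub <- array(0L, dim(cm))
      lab_sub[cm] <- next_label
    } else {
      mk <- as.integer(mk) + ifelse(as.integer(mk) > 0L, next_label, 0L)
      lab <- .watershed_flood(as.numeric(f), as.logical(cm),
                              as.integer(mk), as.integer(dim(cm)))
      lab_sub <- array(lab, dim(cm))
      next_label <- next_label + nmk
    }
    cur <- out[sub[[1]], sub[[2]], sub[[3]]]
    cur[cm] <- lab_sub[cm]
    out[sub[[1]], sub[[2]], sub[[3]]] <- cur
  }
  region_label_map(out, mask$spacing, mask$origin)
}

#' Morphological closing of labelled regions
#'
#' Each region is closed independently with a ball structuring element of the
#' given voxel radius: interior cavities up to the element size are filled
#' and no voxel of any region is ever removed. Voxels claimed by the closing
#' of more than one region are resolved in favour of the region with the
#' higher mean SUV (when `suv` is supplied; otherwise the lower region id).
#'
#' @param labels a [region_label_map()].
#' @param radius_vox structuring-element radius in voxels (>= 0).
#' @param suv optional smoothed [suv_volume()] used for conflict resolution.
#' @return A [region_label_map()].
#' @export
close_regions <- function(labels, radius_vox = 1, suv = NULL) {
  if (!inherits(labels, "region_label_map"))
    stop("labels must be a region_label_map", call. = FALSE)
  if (radius_vox < 0) stop("radius_vox must be >= 0", call. = FALSE)
  r <- as.integer(radius_vox)
  arr <- labels$voxels
  ids <- sort(unique(arr[arr > 0L]))
  if (r == 0L || length(ids) == 0L) return(labels)
  dims <- dim(arr)
  offs <- ball_offsets(r)

  mean_suv <- vapply(ids, function(id) {
    if (is.null(suv)) -as.numeric(id) else mean(suv$voxels[arr == id])
  }, numeric(1))
  order_ids <- ids[order(-mean_suv, ids)]

  out <- arr
  for (id in order_ids) {
    idx <- which(arr == id)
    bb <- bbox_of(idx, dims)
    lo <- pmax(bb[1, ] - 2L * r, 1L)
    hi <- pmin(bb[2, ] + 2L * r, dims)
    sub <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    m <- arr[sub[[1]], sub[[2]], sub[[3]], drop = FALSE] == id
    dim(m) <- lengths(sub)
    closed <- erode_ball(dilate_ball(m, offs), offs) | m
    added <- closed & !m
    if (!any(added)) next
    cur <- out[sub[[1]], sub[[2]], sub[[3]]]
    take <- added & (cur == 0L)
    cur[take] <- id
    out[sub[[1]], sub[[2]], sub[[3]]] <- cur
  }
  region_label_map(out, labels$spacing, labels$origin)
}

#' Extract per-region objects from a label map
#'
#' One region per surviving label, sorted by descending physical volume;
#' regions smaller than `min_volume_ml` are dropped (default 4 mL, the
#' detection floor below which small lesions are not reliably identified).
#' SUV samples are attached from the smoothed volume.
#'
#' @param labels a [region_label_map()].
#' @param suv the smoothed [suv_volume()] on the same grid.
#' @param min_volume_ml minimum region volume in mL (>= 0).
#' @return A list of `pet_region` objects (possibly empty), ids renumbered
#'   1..K in volume order.
#' @export
extract_regions <- function(labels, suv, min_volume_ml = 4) {
  if (!inherits(labels, "region_label_map"))
    stop("labels must be a region_label_map", call. = FALSE)
  if (min_volume_ml < 0) stop("min_volume_ml must be >= 0", call. = FALSE)
  arr <- labels$voxels
  dims <- dim(arr)
  voxvol_ml <- prod(labels$spacing) / 1000
  fg <- which(arr > 0L)
  if (length(fg) == 0L) return(list())
  by_label <- split(fg, arr[fg])
  vols <- lengths(by_label) * voxvol_ml
  keep <- vols >= min_volume_ml
  by_label <- by_label[keep]
  vols <- vols[keep]
  if (length(by_label) == 0L) return(list())
  ord <- order(-vols)
  regions <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    idx <- by_label[[ord[i]]]
    regions[[i]] <- structure(list(
      id = i,
      voxel_idx = as.integer(idx),
      dim = dims,
      spacing = labels$spacing,
      origin = labels$origin,
      suv_values = suv$voxels[idx],
      volume_ml = unname(vols[ord[i]]),
      bbox = bbox_of(idx, dims)
    ), class = "pet_region")
  }
  regions
}

#' @export
print.pet_region <- function(x, ...) {
  cat("<pet_region ", x$id, "> ", length(x$voxel_idx), " voxels, ",
      signif(x$volume_ml, 4), " mL, mean SUV ",
      signif(mean(x$suv_values), 4), "\n", sep = "")
  invisible(x)
}

# logical mask of a region on its full grid
region_mask <- function(region) {
  m <- array(FALSE, region$dim)
  m[region$voxel_idx] <- TRUE
  m
}

#' Summary table of segmented regions
#'
#' @param regions list of `pet_region` objects.
#' @return A data.frame with id, voxel count, volume (mL), physical centroid
#'   (mm) and mean/max SUV per region.
#' @export
region_table <- function(regions) {
  if (length(regions) == 0L)
    return(data.frame(id = integer(), n_voxels = integer(),
                      volume_ml = numeric(), centroid_x_mm = numeric(),
                      centroid_y_mm = numeric(), centroid_z_mm = numeric(),
                      mean_suv = numeric(), max_suv = numeric()))
  rows <- lapply(regions, function(r) {
    co <- arrayInd(r$voxel_idx, r$dim)
    cen <- r$origin + (colMeans(co) - 1) * r$spacing
    data.frame(id = r$id, n_voxels = length(r$voxel_idx),
               volume_ml = r$volume_ml,
               centroid_x_mm = cen[1], centroid_y_mm = cen[2],
               centroid_z_mm = cen[3],
               mean_suv = mean(r$suv_values), max_suv = max(r$suv_values))
  })
  do.call(rbind, rows)
}
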