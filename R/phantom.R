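# Synthetic whole-body FDG-PET phantom: ellipsoidal high-uptake organs and
# tumors with ground-truth labels, so the whole pipeline is testable
# without patient data.

default_organ_table <- function() {
  data.frame(
    class = c("brain", "heart", "kidney_left", "kidney_right", "bladder"),
    volume_mean_ml = c(1468.37, 197.59, 30.70, 31.20, 118.94),
    volume_sd_ml = c(266.15, 125.63, 22.61, 22.85, 153.07),
    suv_mean = c(6.0, 5.5, 5.5, 5.5, 6.0),
    suv_sd = c(0.5, 0.5, 0.5, 0.5, 0.75),
    anchor_x = c(0.50, 0.42, 0.64, 0.36, 0.50),
    anchor_y = c(0.50, 0.45, 0.32, 0.32, 0.42),
    anchor_z = c(0.90, 0.64, 0.47, 0.47, 0.18),
    presence_prob = c(1.00, 0.48, 0.91, 0.86, 1.00),
    axis_x = c(1.00, 1.00, 0.62, 0.62, 1.00),
    axis_y = c(0.85, 0.85, 0.62, 0.62, 1.00),
    axis_z = c(0.78, 0.75, 1.30, 1.30, 0.90),
    partial_mode = c("none", "apex_only", "collecting_system",
                     "collecting_system", "none"),
    partial_prob = c(0, 0.25, 0.25, 0.25, 0),
    stringsAsFactors = FALSE)
}

#' Phantom specification
#'
#' Parameters of the synthetic whole-body scan generator. Defaults encode a
#' torso-scale 5 mm isotropic grid; per-organ volume statistics (mean, SD
#' in mL), ellipsoid axis ratios, anatomical anchors (relative position in
#' the body box), presence probabilities and partial-uptake modes; a
#' truncated log-normal tumor volume distribution with a Poisson tumor
#' count; background SUV level; additive Gaussian activity noise; and
#' dosing realism (5.55 MBq/kg, 60 min uptake, F-18 half-life).
#'
#' @param grid voxel grid dimensions `(nx, ny, nz)`.
#' @param spacing_mm isotropic voxel size in mm.
#' @param organs organ parameter table in the layout of the default
#'   (columns class, volume/suv moments, anchors, presence, axis ratios,
#'   partial modes).
#' @param tumor_volume_mean_ml,tumor_volume_sd_ml log-normal tumor volume
#'   moments in mL.
#' @param tumor_suv_mean,tumor_suv_sd tumor SUV distribution.
#' @param tumor_rate Poisson mean of the per-scan tumor count (truncated
#'   at `tumor_max`; the default gives P(>= 1 tumor) = 0.75).
#' @param tumor_max maximum tumors per scan.
#' @param background_suv uniform body background SUV.
#' @param noise_sd additive Gaussian noise SD on the SUV scale.
#' @param min_volume_ml floor applied to drawn structure volumes (organs;
#'   tumors use `tumor_min_volume_ml`).
#' @param tumor_min_volume_ml truncation floor of tumor volumes in mL.
#' @param min_gap_mm minimum surface-to-surface clearance enforced between
#'   placed structures (bounding-sphere test).
#' @param weight_mean_kg,weight_sd_kg body-weight distribution (clamped to
#'   25-100 kg).
#' @param dose_mbq_per_kg injected dose per body mass.
#' @param elapsed_min injection-to-scan delay.
#' @param halflife_min radionuclide half-life.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(140, 70, 340), spacing_mm = 5,
                         organs = default_organ_table(),
                         tumor_volume_mean_ml = 193.90,
                         tumor_volume_sd_ml = 394.46,
                         tumor_suv_mean = 6.0, tumor_suv_sd = 1.0,
                         tumor_rate = 1.386, tumor_max = 4,
                         background_suv = 1.0, noise_sd = 0.1,
                         min_volume_ml = 8, tumor_min_volume_ml = 1,
                         min_gap_mm = 20,
                         weight_mean_kg = 54, weight_sd_kg = 15,
                         dose_mbq_per_kg = 5.55, elapsed_min = 60,
                         halflife_min = F18_HALFLIFE_MIN) {
  stopifnot(length(grid) == 3L, all(grid >= 8), spacing_mm > 0,
            all(organs$volume_mean_ml > 0),
            all(organs$presence_prob >= 0 & organs$presence_prob <= 1),
            background_suv >= 0, noise_sd >= 0)
  structure(list(grid = as.integer(grid), spacing_mm = spacing_mm,
                 organs = organs,
                 tumor_volume_mean_ml = tumor_volume_mean_ml,
                 tumor_volume_sd_ml = tumor_volume_sd_ml,
                 tumor_suv_mean = tumor_suv_mean, tumor_suv_sd = tumor_suv_sd,
                 tumor_rate = tumor_rate, tumor_max = as.integer(tumor_max),
                 background_suv = background_suv, noise_sd = noise_sd,
                 min_volume_ml = min_volume_ml,
                 tumor_min_volume_ml = tumor_min_volume_ml,
                 min_gap_mm = min_gap_mm,
                 weight_mean_kg = weight_mean_kg, weight_sd_kg = weight_sd_kg,
                 dose_mbq_per_kg = dose_mbq_per_kg,
                 elapsed_min = elapsed_min, halflife_min = halflife_min),
            class = "phantom_spec")
}

# log-normal draw with the given arithmetic mean/SD, redrawn until inside
# [lo, hi]
rlnorm_meansd <- function(mean, sd, lo, hi = Inf) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  s2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - s2 / 2
  for (i in seq_len(200L)) {
    v <- rlnorm(1, mu, sqrt(s2))
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

rnorm_trunc <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  for (i in seq_len(200L)) {
    v <- rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

# semi-axes (mm) of an ellipsoid with the target volume and axis ratios
semi_axes_mm <- function(volume_ml, ratios) {
  s <- (3 * volume_ml * 1000 / (4 * pi * prod(ratios)))^(1 / 3)
  s * ratios
}

#' Draw a phantom scan manifest (no voxelisation)
#'
#' Performs all random draws for one scan — organ presence, volumes, SUVs,
#' partial-uptake modes, placement jitter, tumor count/volumes/positions,
#' body weight — and solves placement, without rendering the voxel volume.
#' [generate_scan()] renders a manifest into an actual scan; having the
#' draws separately keeps distributional checks (presence rates, volume
#' statistics over many scans) cheap.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return A list with `structures` (one row per placed structure: class,
#'   mode, volume_ml, suv, centre in voxel units, semi-axes in mm) and
#'   `meta` (weight, dose, timing, seed).
#' @export
draw_phantom_manifest <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer(seed))
  g <- spec$grid
  h <- spec$spacing_mm
  org <- spec$organs

  rows <- list()
  placed <- list()  # centres (mm) + bounding radius for the clearance test
  fits <- function(cen_vox, ax_mm) {
    all(cen_vox - ax_mm / h >= 2) && all(cen_vox + ax_mm / h <= g - 1)
  }
  clear_of_others <- function(cen_vox, ax_mm) {
    if (length(placed) == 0L) return(TRUE)
    for (p in placed) {
      d <- sqrt(sum(((cen_vox - p$cen) * h)^2))
      if (d < max(ax_mm) + p$rad + spec$min_gap_mm) return(FALSE)
    }
    TRUE
  }

  for (i in seq_len(nrow(org))) {
    present <- runif(1) < org$presence_prob[i]
    vol <- rlnorm_meansd(org$volume_mean_ml[i], org$volume_sd_ml[i],
                         spec$min_volume_ml)
    suv <- rnorm_trunc(org$suv_mean[i], org$suv_sd[i], 4.2,
                       org$suv_mean[i] + 3 * org$suv_sd[i])
    mode <- "full"
    if (org$partial_mode[i] != "none" && runif(1) < org$partial_prob[i])
      mode <- org$partial_mode[i]
    ax <- semi_axes_mm(vol, c(org$axis_x[i], org$axis_y[i], org$axis_z[i]))
    ok <- FALSE
    cen <- NULL
    for (try in seq_len(50L)) {
      jit <- runif(3, -0.02, 0.02)
      cen <- (c(org$anchor_x[i], org$anchor_y[i], org$anchor_z[i]) + jit) *
        (g - 1) + 1
      if (fits(cen, ax) && clear_of_others(cen, ax)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("phantom placement failed for ", org$class[i], " (seed ", seed,
           ")", call. = FALSE)
    if (!present) next
    placed[[length(placed) + 1L]] <- list(cen = cen, rad = max(ax))
    rows[[length(rows) + 1L]] <- data.frame(
      structure = org$class[i], class = org$class[i], mode = mode,
      volume_ml = vol, suv = suv,
      cx = cen[1], cy = cen[2], cz = cen[3],
      ax_mm = ax[1], ay_mm = ax[2], az_mm = ax[3])
  }

  n_tumors <- min(rpois(1, spec$tumor_rate), spec$tumor_max)
  if (n_tumors > 0) for (ti in seq_len(n_tumors)) {
    ok <- FALSE
    for (try in seq_len(400L)) {
      vol <- rlnorm_meansd(spec$tumor_volume_mean_ml, spec$tumor_volume_sd_ml,
                           spec$tumor_min_volume_ml, 1500)
      ratios <- runif(3, 0.7, 1.4)
      ax <- semi_axes_mm(vol, ratios)
      cen <- c(runif(1, 0.12, 0.88), runif(1, 0.15, 0.85),
               runif(1, 0.05, 0.80)) * (g - 1) + 1
      if (fits(cen, ax) && clear_of_others(cen, ax)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("phantom placement failed for tumor (seed ", seed, ")",
                  call. = FALSE)
    suv <- rnorm_trunc(spec$tumor_suv_mean, spec$tumor_suv_sd, 4.2,
                       spec$tumor_suv_mean + 3 * spec$tumor_suv_sd)
    placed[[length(placed) + 1L]] <- list(cen = cen, rad = max(ax))
    rows[[length(rows) + 1L]] <- data.frame(
      structure = paste0("tumor_", ti), class = "tumor", mode = "full",
      volume_ml = vol, suv = suv, cx = cen[1], cy = cen[2], cz = cen[3],
      ax_mm = ax[1], ay_mm = ax[2], az_mm = ax[3])
  }

  weight_kg <- rnorm_trunc(spec$weight_mean_kg, spec$weight_sd_kg, 25, 100)
  structures <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(), class = character(),
               mode = character(), volume_ml = numeric(), suv = numeric(),
               cx = numeric(), cy = numeric(), cz = numeric(),
               ax_mm = numeric(), ay_mm = numeric(), az_mm = numeric())
  list(structures = structures,
       meta = list(weight_g = weight_kg * 1000,
                   dose_bq = spec$dose_mbq_per_kg * weight_kg * 1e6,
                   elapsed_min = spec$elapsed_min,
                   halflife_min = spec$halflife_min, seed = as.integer(seed)))
}

# voxel linear indices of an ellipsoid on the grid
ellipsoid_indices <- function(grid, spacing, centre_vox, semi_axes_mm) {
  r_vox <- semi_axes_mm / spacing
  lo <- pmax(1L, as.integer(floor(centre_vox - r_vox)))
  hi <- pmin(grid, as.integer(ceiling(centre_vox + r_vox)))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - centre_vox[1]) / r_vox[1])^2
  dy2 <- ((ys - centre_vox[2]) / r_vox[2])^2
  dz2 <- ((zs - centre_vox[3]) / r_vox[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  w <- which(inside, arr.ind = TRUE)
  if (nrow(w) == 0L) return(integer())
  ix <- xs[w[, 1]]; iy <- ys[w[, 2]]; iz <- zs[w[, 3]]
  as.integer(ix + grid[1] * ((iy - 1) + grid[2] * (iz - 1)))
}

#' Restrict an organ mask to its partial-uptake sub-volume
#'
#' Emulates the partial tissue-uptake patterns seen clinically: `full`
#' keeps the whole organ; `apex_only` keeps the inferior third of the organ
#' (left-ventricular-apex-style uptake); `collecting_system` keeps a
#' central co-ellipsoid at 0.6 of the organ's half-extents (renal
#' collecting-system uptake, ~22% of the organ volume); `absent` removes
#' all uptake.
#'
#' @param mask logical 3-D organ mask.
#' @param mode one of `"full"`, `"apex_only"`, `"collecting_system"`,
#'   `"absent"`.
#' @return Logical 3-D array of the active sub-volume (a subset of `mask`).
#' @export
apply_partial_uptake <- function(mask, mode) {
  if (!mode %in% c("full", "apex_only", "collecting_system", "absent"))
    stop("unknown partial-uptake mode: ", mode, call. = FALSE)
  if (mode == "full") return(mask)
  if (mode == "absent") return(array(FALSE, dim(mask)))
  co <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dim(mask))
  if (nrow(co) == 0L) return(out)
  if (mode == "apex_only") {
    zcut <- stats::quantile(co[, 3], 1 / 3, type = 1)
    keep <- co[, 3] <= zcut
  } else {
    cen <- colMeans(co)
    half <- pmax(apply(abs(sweep(co, 2, cen)), 2, max), 0.5)
    d2 <- rowSums(sweep(sweep(co, 2, cen), 2, half, "/")^2)
    keep <- d2 <= 0.6^2
    if (!any(keep)) keep <- d2 <= min(d2) + 1e-9
  }
  out[co[keep, , drop = FALSE]] <- TRUE
  out
}

#' Generate one synthetic whole-body PET scan
#'
#' Renders a [draw_phantom_manifest()] draw into a voxel volume: organs are
#' placed at their anatomically ordered anchors (brain superior; heart
#' mid-thorax left of midline; kidneys paired and posterior; bladder
#' inferior midline; tumors at random non-organ sites), each structure's
#' activity is set so the smoothed SUV interior matches its drawn SUV,
#' Gaussian voxel noise is added, and the field is back-converted to Bq/mL
#' consistent with the drawn weight/dose/timing so that [convert_to_suv()]
#' recovers the intended SUV field.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same spec and seed reproduce the scan
#'   bit-identically.
#' @return An object of class `phantom_scan`: `scan` (a [pet_scan()]),
#'   `truth_labels` (a [region_label_map()] of the active uptake regions),
#'   `truth` (data.frame: label, class, mode, drawn/realised/active
#'   volumes, SUV) and `manifest`.
#' @export
generate_scan <- function(spec, seed) {
  man <- draw_phantom_manifest(spec, seed)
  g <- spec$grid
  h <- spec$spacing_mm
  suv_field <- array(spec$background_suv, g)
  labels <- array(0L, g)
  st <- man$structures
  truth_rows <- list()
  for (i in seq_len(nrow(st))) {
    idx <- ellipsoid_indices(g, h, c(st$cx[i], st$cy[i], st$cz[i]),
                             c(st$ax_mm[i], st$ay_mm[i], st$az_mm[i]))
    if (length(idx) == 0L) next
    m <- array(FALSE, g)
    m[idx] <- TRUE
    active <- apply_partial_uptake(m, st$mode[i])
    aidx <- which(active)
    lab <- length(truth_rows) + 1L
    suv_field[aidx] <- st$suv[i]
    labels[aidx] <- lab
    truth_rows[[lab]] <- data.frame(
      label = lab, class = st$class[i], structure = st$structure[i],
      mode = st$mode[i], volume_ml = st$volume_ml[i],
      realized_volume_ml = length(idx) * h^3 / 1000,
      active_volume_ml = length(aidx) * h^3 / 1000, suv = st$suv[i])
  }
  suv_field <- suv_field + array(rnorm(prod(g), 0, spec$noise_sd), g)
  suv_field[suv_field < 0] <- 0
  meta <- man$meta
  decay <- 2^(-meta$elapsed_min / meta$halflife_min)
  activity <- suv_field * decay * meta$dose_bq / meta$weight_g
  scan <- pet_scan(activity, spacing = h, weight_g = meta$weight_g,
                   dose_bq = meta$dose_bq, elapsed_min = meta$elapsed_min,
                   halflife_min = meta$halflife_min)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(label = integer(), class = character(),
               structure = character(), mode = character(),
               volume_ml = numeric(), realized_volume_ml = numeric(),
               active_volume_ml = numeric(), suv = numeric())
  structure(list(scan = scan,
                 truth_labels = region_label_map(labels, h),
                 truth = truth, manifest = man, seed = as.integer(seed)),
            class = "phantom_scan")
}

#' @export
print.phantom_scan <- function(x, ...) {
  cat("<phantom_scan> seed ", x$seed, ", ", nrow(x$truth),
      " uptake regions: ", paste(x$truth$class, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Generate an independent cohort of phantom scans
#'
#' Per-scan seeds are derived from the master seed, so cohorts built from
#' different master seeds are independent and any cohort is reproducible
#' from its master seed.
#'
#' @param spec a [phantom_spec()].
#' @param n_scans number of scans (>= 1).
#' @param seed master seed.
#' @return A list with `scans` (list of [generate_scan()] results) and
#'   `truth` (cohort-level table: scan_id plus the per-scan truth rows).
#' @export
generate_cohort <- function(spec, n_scans, seed) {
  stopifnot(n_scans >= 1)
  set.seed(as.integer(seed))
  scan_seeds <- sample.int(.Machine$integer.max - 1L, n_scans)
  scans <- lapply(seq_len(n_scans), function(i) generate_scan(spec, scan_seeds[i]))
  truth <- do.call(rbind, lapply(seq_len(n_scans), function(i) {
    tr <- scans[[i]]$truth
    if (nrow(tr) == 0L) return(NULL)
    cbind(scan_id = i, tr)
  }))
  list(scans = scans, truth = truth, seed = as.integer(seed),
       scan_seeds = scan_seeds)
}
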