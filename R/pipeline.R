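# End-to-end orchestration: preprocess -> watershed -> closing -> region
# extraction -> features, plus truth matching for phantom cohorts.

#' Segment the high-uptake tissue of a PET scan
#'
#' Runs the full segmentation chain: SUV conversion, isotropic resampling,
#' Gaussian smoothing, SUV thresholding, marker-based watershed,
#' morphological closing and minimum-size filtering. A user-supplied label
#' map can replace the automatic watershed (manual override for scans with
#' abnormal uptake, e.g. super-scans).
#'
#' @param scan a [pet_scan()].
#' @param target_mm isotropic voxel size (mm).
#' @param sigma_vox Gaussian smoothing width in voxels.
#' @param threshold SUV threshold.
#' @param h_maxima watershed marker depth in SUV units.
#' @param closing_radius morphological closing radius in voxels.
#' @param min_volume_ml minimum region volume (mL).
#' @param manual_labels optional [region_label_map()] (or integer array)
#'   replacing the automatic segmentation.
#' @return An object of class `pet_segmentation`: the resampled `suv`,
#'   `smoothed` volume, high-uptake `mask`, final `labels` map and the
#'   extracted `regions` list.
#' @export
segment_pet <- function(scan, target_mm = 5, sigma_vox = 1, threshold = 3,
                        h_maxima = 1.0, closing_radius = 1,
                        min_volume_ml = 4, manual_labels = NULL) {
  pre <- preprocess_pet(scan, target_mm = target_mm, sigma_vox = sigma_vox,
                        threshold = threshold)
  if (is.null(manual_labels)) {
    labels <- watershed_regions(pre$mask, pre$smoothed, h = h_maxima)
    labels <- close_regions(labels, radius_vox = closing_radius,
                            suv = pre$smoothed)
  } else {
    labels <- if (inherits(manual_labels, "region_label_map")) manual_labels
      else region_label_map(manual_labels, pre$smoothed$spacing,
                            pre$smoothed$origin)
  }
  regions <- extract_regions(labels, pre$smoothed,
                             min_volume_ml = min_volume_ml)
  structure(list(suv = pre$suv, smoothed = pre$smoothed, mask = pre$mask,
                 labels = labels, regions = regions),
            class = "pet_segmentation")
}

#' @export
print.pet_segmentation <- function(x, ...) {
  cat("<pet_segmentation> ", length(x$regions), " regions\n", sep = "")
  print(region_table(x$regions))
  invisible(x)
}

#' Match segmented regions to phantom ground truth
#'
#' Each ground-truth uptake region is matched to the segmented region with
#' the largest voxel overlap; Dice and the other voxelwise metrics are
#' reported per truth region, and each segmented region is assigned the
#' truth class with which it overlaps most (its training/evaluation
#' label).
#'
#' @param seg a [segment_pet()] result.
#' @param phantom the [generate_scan()] result it was computed from.
#' @return A list with `truth_match` (one row per truth region: class,
#'   mode, matched region id, dice, truth/auto volumes) and
#'   `region_labels` (one row per segmented region: region id, majority
#'   truth class or NA, overlap fraction).
#' @export
match_truth <- function(seg, phantom) {
  tl <- phantom$truth_labels$voxels
  truth <- phantom$truth
  regions <- seg$regions
  nreg <- length(regions)
  voxvol <- prod(phantom$truth_labels$spacing) / 1000

  overlap <- matrix(0L, nrow(truth), max(1L, nreg))
  reg_sizes <- integer(max(1L, nreg))
  for (j in seq_len(nreg)) {
    tv <- tl[regions[[j]]$voxel_idx]
    reg_sizes[j] <- length(regions[[j]]$voxel_idx)
    tab <- tabulate(tv[tv > 0L], nbins = nrow(truth))
    if (nrow(truth) > 0L) overlap[, j] <- tab
  }
  truth_sizes <- round(truth$active_volume_ml / voxvol)

  truth_match <- NULL
  if (nrow(truth) > 0L) {
    truth_match <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      if (nreg > 0L && any(overlap[i, ] > 0L)) {
        j <- which.max(overlap[i, ])
        inter <- overlap[i, j]
        dice <- 2 * inter / (truth_sizes[i] + reg_sizes[j])
        data.frame(label = truth$label[i], class = truth$class[i],
                   mode = truth$mode[i], region_id = j, dice = dice,
                   truth_volume_ml = truth$active_volume_ml[i],
                   auto_volume_ml = reg_sizes[j] * voxvol)
      } else {
        data.frame(label = truth$label[i], class = truth$class[i],
                   mode = truth$mode[i], region_id = NA_integer_, dice = 0,
                   truth_volume_ml = truth$active_volume_ml[i],
                   auto_volume_ml = NA_real_)
      }
    }))
  }
  region_labels <- NULL
  if (nreg > 0L) {
    region_labels <- do.call(rbind, lapply(seq_len(nreg), function(j) {
      if (nrow(truth) > 0L && any(overlap[, j] > 0L)) {
        i <- which.max(overlap[, j])
        data.frame(region_id = j, class = truth$class[i],
                   mode = truth$mode[i],
                   overlap_fraction = overlap[i, j] / reg_sizes[j])
      } else {
        data.frame(region_id = j, class = NA_character_,
                   mode = NA_character_, overlap_fraction = 0)
      }
    }))
  }
  list(truth_match = truth_match, region_labels = region_labels)
}

#' Segment and featurise a whole phantom cohort
#'
#' Runs the full pipeline on every scan of a [generate_cohort()] result and
#' assembles the labelled feature table used for classifier training and
#' evaluation, together with per-truth-region Dice and the auto-vs-truth
#' tumor volume pairs.
#'
#' @param cohort a [generate_cohort()] result.
#' @param feature_set `"core28"` or `"full62"` (the full-62 table contains
#'   the core-28 columns, so one computation serves both).
#' @param n_levels discretization levels for texture/entropy features.
#' @param ... further arguments passed to [segment_pet()].
#' @return A list with `features` (data.frame: scan_id, region_id, label,
#'   mode, feature columns), `dice` (per truth region), `seg_metrics`
#'   (per-scan voxelwise metrics of the union segmentation against the
#'   union truth mask) and `regions_per_scan`.
#' @export
process_cohort <- function(cohort, feature_set = "full62", n_levels = 32,
                           ...) {
  feat_rows <- list()
  dice_rows <- list()
  seg_rows <- list()
  nreg <- integer(length(cohort$scans))
  for (i in seq_along(cohort$scans)) {
    ph <- cohort$scans[[i]]
    seg <- segment_pet(ph$scan, ...)
    mt <- match_truth(seg, ph)
    nreg[i] <- length(seg$regions)
    pred_mask <- array(FALSE, dim(seg$labels$voxels))
    for (r in seg$regions) pred_mask[r$voxel_idx] <- TRUE
    sm <- suppressWarnings(
      segmentation_metrics(pred_mask, ph$truth_labels$voxels > 0L))
    seg_rows[[i]] <- cbind(scan_id = i, as.data.frame(as.list(sm)))
    if (!is.null(mt$truth_match))
      dice_rows[[i]] <- cbind(scan_id = i, mt$truth_match)
    if (length(seg$regions) > 0L) {
      ft <- features_table(seg$regions, feature_set = feature_set,
                           n_levels = n_levels)
      ft <- cbind(scan_id = i,
                  label = mt$region_labels$class,
                  mode = mt$region_labels$mode, ft)
      feat_rows[[i]] <- ft
    }
  }
  list(features = do.call(rbind, feat_rows),
       dice = do.call(rbind, dice_rows),
       seg_metrics = do.call(rbind, seg_rows),
       regions_per_scan = nreg)
}

feature_columns <- function(df, feature_set = "core28") {
  df[pet_feature_names(feature_set)]
}

#' Train-on-one-cohort / test-on-the-other experiment
#'
#' Reproduces the two-cohort protocol on synthetic phantoms: a random
#' forest is trained on the labelled regions of cohort A and evaluated,
#' with the per-scan sole-occurrence constraint, on cohort B.
#'
#' @param train_set,test_set [process_cohort()] results.
#' @param feature_set `"core28"` or `"full62"`.
#' @param n_trees ensemble size (the texture variant conventionally
#'   doubles it).
#' @param seed RNG seed for training.
#' @return A list with `model` and the [evaluate_holdout()] `evaluation`.
#' @export
cross_cohort_experiment <- function(train_set, test_set,
                                    feature_set = "core28", n_trees = 50,
                                    seed = 1) {
  tr <- train_set$features
  te <- test_set$features
  tr <- tr[!is.na(tr$label), ]
  te <- te[!is.na(te$label), ]
  model <- train_forest(feature_columns(tr, feature_set), tr$label,
                        n_trees = n_trees, seed = seed)
  evaluation <- evaluate_holdout(model, feature_columns(te, feature_set),
                                 te$label, scan = te$scan_id)
  list(model = model, evaluation = evaluation)
}
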