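# Segmentation quality metrics, auto-vs-reference volume concordance and
# per-feature class discrimination.

#' Voxelwise segmentation performance metrics
#'
#' Sensitivity, specificity, precision, accuracy, Dice similarity
#' coefficient and Jaccard index from the voxelwise TP/FP/FN/TN counts of a
#' predicted versus reference mask. Specificity is computed over the full
#' scan field of view (background-inclusive denominator). Conventions for
#' degenerate inputs: both masks empty gives 1 for every metric; an empty
#' reference with a non-empty prediction gives sensitivity 0 with a
#' warning.
#'
#' @param pred,truth [binary_mask()] objects (or bare logical arrays) on
#'   the same grid.
#' @return Named numeric vector: sensitivity, specificity, precision,
#'   accuracy, dice, jaccard.
#' @export
segmentation_metrics <- function(pred, truth) {
  p <- if (inherits(pred, "binary_mask")) pred$voxels else pred
  t_ <- if (inherits(truth, "binary_mask")) truth$voxels else truth
  if (!identical(dim(p), dim(t_))) stop("pred and truth grids differ", call. = FALSE)
  tp <- sum(p & t_)
  fp <- sum(p & !t_)
  fn <- sum(!p & t_)
  tn <- sum(!p & !t_)
  if (tp + fn == 0L && fp == 0L)
    return(c(sensitivity = 1, specificity = 1, precision = 1, accuracy = 1,
             dice = 1, jaccard = 1))
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("empty reference mask: sensitivity undefined, reported as 0",
            call. = FALSE)
    0
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  c(sensitivity = sens,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 1,
    precision = prec,
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0)
}

#' Concordance of automatic versus reference volumes
#'
#' Ordinary least-squares fit of automatic volumes on reference volumes;
#' the slope, intercept (mL) and R-squared quantify how faithfully
#' automatic segmentation recovers reference volumes.
#'
#' @param auto_ml,ref_ml numeric vectors of equal length (>= 3), volumes
#'   in mL.
#' @return An object of class `concordance_fit` with `slope`, `intercept`,
#'   `r_squared` and `n`.
#' @export
volume_concordance <- function(auto_ml, ref_ml) {
  auto_ml <- as.numeric(auto_ml)
  ref_ml <- as.numeric(ref_ml)
  if (length(auto_ml) != length(ref_ml) || length(auto_ml) < 3L)
    stop("need equal-length volume vectors with n >= 3", call. = FALSE)
  if (var(ref_ml) == 0) stop("reference volumes have zero variance", call. = FALSE)
  fit <- lm(auto_ml ~ ref_ml)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = length(auto_ml)),
            class = "concordance_fit")
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat("<concordance_fit> auto = ", signif(x$slope, 4), " * ref ",
      ifelse(x$intercept < 0, "- ", "+ "), signif(abs(x$intercept), 4),
      " mL,  R^2 = ", signif(x$r_squared, 4), "  (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

welch_or_pooled_t <- function(a, b, var_equal = FALSE) {
  # degenerate convention: zero variance in both groups
  if (var(a) == 0 && var(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf * sign(mean(a) - mean(b)),
                p.value = p, degenerate = TRUE))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       degenerate = FALSE)
}

#' Per-feature, per-class-pair discrimination tests
#'
#' Two-sample t-tests (Welch by default) of every feature for every pair of
#' tissue classes, plus a ranked table of the most discriminating features
#' per tissue. A feature is ranked for a tissue by its worst p-value over
#' that tissue's pairwise comparisons, so the top features separate the
#' tissue from every other class. Degenerate zero-variance comparisons take
#' p = 0 when the means differ and p = 1 when they are equal (logged
#' convention).
#'
#' @param features data.frame of numeric feature columns (a `region_id` /
#'   `scan_id` column is ignored).
#' @param classes tissue class per row; every class needs >= 2 rows.
#' @param var_equal use the pooled-variance (classical Student) test
#'   instead of Welch.
#' @param top_n features to keep per tissue in the ranked table.
#' @param p_adjust multiple-testing correction applied across all tests;
#'   `"none"` (the default, matching the convention of reporting raw
#'   per-test p-values) or `"BH"` (Benjamini-Hochberg).
#' @return An object of class `feature_discrimination`: `tests` (long
#'   data.frame: feature, class_a, class_b, statistic, p_value, and
#'   p_adjusted when a correction is requested) and `top_features`
#'   (tissue, rank, feature, worst_p).
#' @export
feature_discrimination <- function(features, classes, var_equal = FALSE,
                                   top_n = 5, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  feats <- drop_id_cols(features)
  classes <- as.character(classes)
  if (nrow(feats) != length(classes))
    stop("feature/class length mismatch", call. = FALSE)
  tab <- table(classes)
  if (any(tab < 2L))
    stop("every class needs >= 2 samples", call. = FALSE)
  cls <- names(tab)
  pairs <- utils::combn(cls, 2)
  rows <- vector("list", ncol(pairs) * ncol(feats))
  k <- 0L
  for (fn in names(feats)) {
    for (pi in seq_len(ncol(pairs))) {
      a <- feats[[fn]][classes == pairs[1, pi]]
      b <- feats[[fn]][classes == pairs[2, pi]]
      ht <- welch_or_pooled_t(a, b, var_equal)
      k <- k + 1L
      rows[[k]] <- data.frame(feature = fn, class_a = pairs[1, pi],
                              class_b = pairs[2, pi],
                              statistic = ht$statistic,
                              p_value = ht$p.value)
    }
  }
  tests <- do.call(rbind, rows)
  if (p_adjust == "BH")
    tests$p_adjusted <- stats::p.adjust(tests$p_value, method = "BH")
  top <- do.call(rbind, lapply(cls, function(tis) {
    sub <- tests[tests$class_a == tis | tests$class_b == tis, ]
    worst <- tapply(sub$p_value, sub$feature, max)
    ord <- order(worst)[seq_len(min(top_n, length(worst)))]
    data.frame(tissue = tis, rank = seq_along(ord),
               feature = names(worst)[ord], worst_p = unname(worst[ord]))
  }))
  structure(list(tests = tests, top_features = top), class = "feature_discrimination")
}

#' @export
print.feature_discrimination <- function(x, ...) {
  cat("<feature_discrimination> ", nrow(x$tests), " tests\n", sep = "")
  print(x$top_features, row.names = FALSE)
  invisible(x)
}
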