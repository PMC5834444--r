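# Random-forest tissue classification with the per-scan sole-occurrence
# constraint: each normal tissue label may be used at most once per scan,
# tumor any number of times.

#' The six tissue classes
#'
#' @return Character vector: brain, heart, kidney_left, kidney_right,
#'   bladder, tumor.
#' @export
tissue_classes <- function() {
  c("brain", "heart", "kidney_left", "kidney_right", "bladder", "tumor")
}

NORMAL_TISSUES <- c("brain", "heart", "kidney_left", "kidney_right", "bladder")

#' Train the random-forest tissue classifier
#'
#' An ensemble of CART trees grown on bootstrap resamples with sqrt(p)
#' candidate features per split (Gini criterion, unlimited depth). Features
#' enter unscaled and equally weighted; class priors are uniform in the
#' sense that no rebalancing or per-class weighting is applied. The default
#' ensemble size is 50 trees (doubled when the 34 texture features are
#' added).
#'
#' @param features data.frame of numeric feature columns, one row per
#'   region (a `region_id` column, if present, is dropped).
#' @param labels tissue class per row (character or factor drawn from
#'   [tissue_classes()]).
#' @param n_trees ensemble size (>= 1); default 50.
#' @param seed integer RNG seed for the bootstrap/feature sampling.
#' @return An object of class `tissue_forest` carrying the fitted ensemble,
#'   the frozen feature-name list and the out-of-bag error.
#' @export
train_forest <- function(features, labels, n_trees = 50, seed = 1) {
  features <- drop_id_cols(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stop("feature/label length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training data must contain >= 2 classes", call. = FALSE)
  if (!all(labels %in% tissue_classes()))
    stop("unknown tissue labels: ",
         paste(setdiff(labels, tissue_classes()), collapse = ", "),
         call. = FALSE)
  if (anyNA(features) || any(!vapply(features, is.numeric, logical(1))))
    stop("features must be numeric with no missing values", call. = FALSE)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  y <- factor(labels, levels = intersect(tissue_classes(), unique(labels)))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = features, y = y, ntree = as.integer(n_trees),
    mtry = max(1L, floor(sqrt(ncol(features)))),
    replace = TRUE, sampsize = nrow(features))
  structure(list(forest = fit,
                 n_trees = as.integer(n_trees),
                 feature_names = colnames(features),
                 classes = levels(y),
                 oob_error = unname(fit$err.rate[n_trees, "OOB"]),
                 seed = as.integer(seed)),
            class = "tissue_forest")
}

drop_id_cols <- function(features) {
  features <- as.data.frame(features)
  features[setdiff(names(features), c("region_id", "scan_id", "label"))]
}

#' @export
print.tissue_forest <- function(x, ...) {
  cat("<tissue_forest> ", x$n_trees, " trees, ",
      length(x$feature_names), " features, classes: ",
      paste(x$classes, collapse = ", "), "\n  OOB error ",
      signif(x$oob_error, 3), "\n", sep = "")
  invisible(x)
}

#' Save / load a fitted tissue forest
#'
#' The bundle stores the fitted ensemble together with the frozen
#' feature-name list and a format version; loading verifies both, so a
#' model cannot silently be applied to a mismatched feature table.
#'
#' @param model a [train_forest()] fit.
#' @param path file path for the model bundle.
#' @return `save_forest()` returns `path` invisibly; `load_forest()`
#'   returns the restored `tissue_forest`.
#' @export
save_forest <- function(model, path) {
  if (!inherits(model, "tissue_forest")) stop("model must be a tissue_forest", call. = FALSE)
  saveRDS(list(format = "petrad_tissue_forest", format_version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  bundle <- readRDS(path)
  if (!is.list(bundle) || !identical(bundle$format, "petrad_tissue_forest"))
    stop("not a petrad tissue-forest bundle: ", path, call. = FALSE)
  if (!identical(bundle$format_version, 1L))
    stop("unsupported bundle version: ", bundle$format_version, call. = FALSE)
  model <- bundle$model
  if (!inherits(model, "tissue_forest") || is.null(model$feature_names))
    stop("corrupt tissue-forest bundle", call. = FALSE)
  model
}

#' Per-region class probabilities
#'
#' The probability of each class is the fraction of trees voting for it;
#' rows sum to 1. Columns cover all six [tissue_classes()]; classes absent
#' from training receive probability 0.
#'
#' @param model a [train_forest()] fit.
#' @param features data.frame whose feature columns match the model's
#'   frozen feature-name list.
#' @return Numeric matrix, regions x 6 classes.
#' @export
predict_probabilities <- function(model, features) {
  if (!inherits(model, "tissue_forest")) stop("model must be a tissue_forest", call. = FALSE)
  features <- drop_id_cols(features)
  missing_cols <- setdiff(model$feature_names, names(features))
  extra <- setdiff(names(features), model$feature_names)
  if (length(missing_cols) || length(extra))
    stop("feature columns do not match the model (missing: ",
         paste(missing_cols, collapse = ","), "; unknown: ",
         paste(extra, collapse = ","), ")", call. = FALSE)
  features <- features[model$feature_names]
  p <- predict(model$forest, newdata = features, type = "prob")
  out <- matrix(0, nrow(features), length(tissue_classes()),
                dimnames = list(NULL, tissue_classes()))
  out[, colnames(p)] <- p
  out
}

#' @export
predict.tissue_forest <- function(object, newdata, ...) {
  predict_probabilities(object, newdata)
}

# exact maximisation of sum(log(p + eps)) over labelings in which each
# normal-tissue class is used at most once: dynamic programme over the
# 2^5 subsets of already-used normal classes, regions in row order.
solve_unique_assignment <- function(logp) {
  n <- nrow(logp)
  classes <- tissue_classes()
  tumor_col <- match("tumor", classes)
  normal_cols <- match(NORMAL_TISSUES, classes)
  nstate <- 2L^length(normal_cols)
  NEG <- -Inf
  val <- rep(NEG, nstate)
  val[1] <- 0
  choice <- matrix(NA_integer_, n, nstate)  # class chosen to REACH state after region r
  prev <- matrix(NA_integer_, n, nstate)
  for (r in seq_len(n)) {
    nv <- rep(NEG, nstate)
    nc <- rep(NA_integer_, nstate)
    np <- rep(NA_integer_, nstate)
    for (s in seq_len(nstate)) {
      if (val[s] == NEG) next
      used <- bitwAnd(s - 1L, bitwShiftL(1L, seq_along(normal_cols) - 1L)) > 0L
      # tumor: state unchanged
      cand <- val[s] + logp[r, tumor_col]
      if (cand > nv[s]) {
        nv[s] <- cand
        nc[s] <- tumor_col
        np[s] <- s
      }
      for (k in seq_along(normal_cols)) {
        if (used[k]) next
        s2 <- s + bitwShiftL(1L, k - 1L)
        cand <- val[s] + logp[r, normal_cols[k]]
        if (cand > nv[s2]) {
          nv[s2] <- cand
          nc[s2] <- normal_cols[k]
          np[s2] <- s
        }
      }
    }
    val <- nv
    choice[r, ] <- nc
    prev[r, ] <- np
  }
  s <- which.max(val)
  objective <- val[s]
  labels <- integer(n)
  for (r in rev(seq_len(n))) {
    labels[r] <- choice[r, s]
    s <- prev[r, s]
  }
  list(labels = classes[labels], objective = objective)
}

#' Assign tissue labels under the sole-occurrence constraint
#'
#' Chooses the labeling that maximises the summed log-probability
#' `sum(log(p + 1e-9))` subject to each of the five normal-tissue classes
#' being used at most once per scan; tumor (primary site and metastases)
#' may label any number of regions. Solved exactly by dynamic programming
#' over used-class subsets; an all-tumor labeling is always feasible.
#'
#' @param prob_matrix regions x 6 probability matrix with columns named as
#'   [tissue_classes()] (rows summing to 1).
#' @param region_ids optional region identifiers (defaults to row numbers).
#' @return An object of class `tissue_assignment` with `labels`,
#'   `prob_matrix`, `region_ids` and the attained `objective`.
#' @export
assign_with_uniqueness <- function(prob_matrix, region_ids = NULL) {
  prob_matrix <- as.matrix(prob_matrix)
  if (is.null(colnames(prob_matrix)) ||
      !setequal(colnames(prob_matrix), tissue_classes()))
    stop("prob_matrix columns must be the six tissue classes", call. = FALSE)
  prob_matrix <- prob_matrix[, tissue_classes(), drop = FALSE]
  if (any(prob_matrix < -1e-9) ||
      any(abs(rowSums(prob_matrix) - 1) > 1e-6))
    stop("prob_matrix rows must be probabilities summing to 1", call. = FALSE)
  if (is.null(region_ids)) region_ids <- seq_len(nrow(prob_matrix))
  sol <- solve_unique_assignment(log(prob_matrix + 1e-9))
  structure(list(region_ids = region_ids,
                 prob_matrix = prob_matrix,
                 labels = sol$labels,
                 objective = sol$objective),
            class = "tissue_assignment")
}

#' @export
print.tissue_assignment <- function(x, ...) {
  cat("<tissue_assignment> ", length(x$labels), " regions, objective ",
      signif(x$objective, 6), "\n", sep = "")
  print(data.frame(region = x$region_ids, label = x$labels,
                   probability = x$prob_matrix[cbind(seq_along(x$labels),
                                                     x$labels)]))
  invisible(x)
}

#' Classify regions scan by scan
#'
#' Applies [predict_probabilities()] and then the sole-occurrence
#' constraint within each scan.
#'
#' @param model a [train_forest()] fit.
#' @param features feature data.frame.
#' @param scan factor/vector of scan ids grouping the rows; `NULL` treats
#'   all rows as one scan.
#' @return Character vector of labels, one per row of `features`.
#' @export
classify_regions <- function(model, features, scan = NULL) {
  prob <- predict_probabilities(model, features)
  if (is.null(scan)) scan <- rep(1L, nrow(prob))
  labels <- character(nrow(prob))
  for (s in unique(scan)) {
    rows <- which(scan == s)
    labels[rows] <- assign_with_uniqueness(prob[rows, , drop = FALSE])$labels
  }
  labels
}

#' Hold-out evaluation of the tissue classifier
#'
#' Classifies a hold-out cohort (with the per-scan constraint when scan ids
#' are given) and tabulates correctly-classified / total counts overall and
#' per tissue, the shape in which cross-cohort classification performance
#' is conventionally reported.
#'
#' @param model a [train_forest()] fit.
#' @param features hold-out feature data.frame.
#' @param truth_labels true tissue class per row.
#' @param scan optional scan ids for the constrained assignment.
#' @return An object of class `tissue_holdout`: data.frame `per_class`
#'   (class, correct, total, accuracy), `overall` counts, and the predicted
#'   labels.
#' @export
evaluate_holdout <- function(model, features, truth_labels, scan = NULL) {
  truth_labels <- as.character(truth_labels)
  if (length(truth_labels) == 0L) stop("empty test set", call. = FALSE)
  if (nrow(as.data.frame(features)) != length(truth_labels))
    stop("feature/label length mismatch", call. = FALSE)
  pred <- classify_regions(model, features, scan)
  per_class <- do.call(rbind, lapply(tissue_classes(), function(cl) {
    tot <- sum(truth_labels == cl)
    ok <- sum(truth_labels == cl & pred == cl)
    data.frame(class = cl, correct = ok, total = tot,
               accuracy = if (tot > 0) ok / tot else NA_real_)
  }))
  structure(list(per_class = per_class,
                 overall = c(correct = sum(pred == truth_labels),
                             total = length(truth_labels)),
                 predicted = pred, truth = truth_labels),
            class = "tissue_holdout")
}

#' @export
print.tissue_holdout <- function(x, ...) {
  ov <- x$overall
  cat("Hold-out classification: ", ov["correct"], "/", ov["total"], " (",
      sprintf("%.1f%%", 100 * ov["correct"] / ov["total"]), ")\n", sep = "")
  for (i in seq_len(nrow(x$per_class))) {
    row <- x$per_class[i, ]
    if (row$total == 0) next
    cat(sprintf("  %-13s %3d/%3d (%.1f%%)\n", row$class, row$correct,
                row$total, 100 * row$accuracy))
  }
  invisible(x)
}
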