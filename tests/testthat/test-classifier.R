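# Random-forest training, probability prediction, constrained assignment.

sim_features <- function(n_per_class, classes, shift = 3) {
  rows <- lapply(seq_along(classes), function(k) {
    data.frame(f1 = rnorm(n_per_class, k * shift),
               f2 = rnorm(n_per_class, -k * shift),
               f3 = rnorm(n_per_class))
  })
  list(x = do.call(rbind, rows),
       y = rep(classes, each = n_per_class))
}

random_prob_matrix <- function(n) {
  p <- matrix(rexp(n * 6), n, 6)
  p <- p / rowSums(p)
  colnames(p) <- tissue_classes()
  p
}

test_that("well-separated classes give near-zero OOB error; permuted labels
           give chance-level OOB error", {
  set.seed(51)
  sim <- sim_features(100, c("brain", "tumor"), shift = 6)
  fit <- train_forest(sim$x, sim$y, n_trees = 50, seed = 1)
  expect_lte(fit$oob_error, 0.05)

  simp <- sim_features(125, c("brain", "heart", "bladder", "tumor"),
                       shift = 0)  # no signal at all
  fit2 <- train_forest(simp$x, sample(simp$y), n_trees = 50, seed = 1)
  expect_lt(abs(fit2$oob_error - 0.75), 0.1)
})

test_that("training is deterministic under a fixed seed and validates input", {
  set.seed(52)
  sim <- sim_features(40, c("heart", "tumor"))
  probe <- sim_features(10, c("heart", "tumor"))$x
  a <- train_forest(sim$x, sim$y, seed = 9)
  b <- train_forest(sim$x, sim$y, seed = 9)
  expect_identical(predict_probabilities(a, probe),
                   predict_probabilities(b, probe))
  expect_error(train_forest(sim$x, rep("tumor", nrow(sim$x))), "2 classes")
  expect_error(train_forest(sim$x, sim$y[-1]), "mismatch")
  bad <- sim$x
  bad$f1[1] <- NA
  expect_error(train_forest(bad, sim$y), "missing")
})

test_that("predicted probabilities are tree-vote fractions summing to 1", {
  set.seed(53)
  sim <- sim_features(50, c("brain", "bladder", "tumor"))
  fit <- train_forest(sim$x, sim$y, n_trees = 50, seed = 2)
  probe <- sim_features(20, c("brain", "bladder", "tumor"))$x
  p <- predict_probabilities(fit, probe)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_equal(colnames(p), tissue_classes())
  expect_true(all(p[, c("heart", "kidney_left", "kidney_right")] == 0))
  # vote granularity: multiples of 1/50
  expect_true(all(abs(p * 50 - round(p * 50)) < 1e-9))

  one <- train_forest(sim$x, sim$y, n_trees = 1, seed = 2)
  p1 <- predict_probabilities(one, probe)
  expect_true(all(p1 %in% c(0, 1)))
  expect_equal(rowSums(p1), rep(1, nrow(p1)))

  expect_error(predict_probabilities(fit, probe[, 1:2]), "missing")
  expect_error(predict_probabilities(fit, cbind(probe, junk = 1)), "unknown")
})

test_that("a heavily represented exemplar is recovered with high
           probability", {
  set.seed(54)
  x <- data.frame(f1 = c(rep(0, 60) + rnorm(60, 0, 1e-3),
                         rnorm(60, 8)),
                  f2 = c(rep(5, 60) + rnorm(60, 0, 1e-3),
                         rnorm(60, -4)))
  y <- rep(c("bladder", "tumor"), each = 60)
  fit <- train_forest(x, y, n_trees = 50, seed = 3)
  p <- predict_probabilities(fit, data.frame(f1 = 0, f2 = 5))
  expect_gte(p[1, "bladder"], 0.9)
})

test_that("constrained assignment resolves argmax collisions optimally", {
  # constraint inactive: distinct argmaxes
  p <- diag(6) * 0.7 + 0.05
  colnames(p) <- tissue_classes()
  a <- assign_with_uniqueness(p)
  expect_equal(a$labels, tissue_classes())

  # two regions both prefer brain; the weaker one must move to its best
  # feasible alternative (tumor)
  p2 <- rbind(c(0.90, 0.02, 0.02, 0.02, 0.02, 0.02),
              c(0.60, 0.02, 0.02, 0.02, 0.04, 0.30))
  colnames(p2) <- tissue_classes()
  a2 <- assign_with_uniqueness(p2)
  expect_equal(a2$labels, c("brain", "tumor"))

  # tumor is unconstrained
  p3 <- matrix(rep(c(0.01, 0.01, 0.01, 0.01, 0.01, 0.95), 3), 3,
               byrow = TRUE)
  colnames(p3) <- tissue_classes()
  expect_equal(assign_with_uniqueness(p3)$labels, rep("tumor", 3))
})

test_that("constrained assignment matches exhaustive enumeration on random
           probability matrices", {
  set.seed(55)
  for (i in 1:60) {
    n <- sample(1:6, 1)
    p <- random_prob_matrix(n)
    got <- assign_with_uniqueness(p)
    want <- oracle_assignment(p)
    expect_equal(got$labels, want$labels)
    expect_equal(got$objective, want$objective, tolerance = 1e-9)
  }
})

test_that("the sole-occurrence invariant holds on fuzzed inputs and the
           constrained objective dominates feasible greedy labelings", {
  set.seed(56)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    p <- random_prob_matrix(n)
    a <- assign_with_uniqueness(p)
    normals <- a$labels[a$labels != "tumor"]
    expect_equal(anyDuplicated(normals), 0)
    greedy <- tissue_classes()[apply(p, 1, which.max)]
    greedy_normals <- greedy[greedy != "tumor"]
    if (anyDuplicated(greedy_normals) == 0) {
      greedy_obj <- sum(log(p[cbind(seq_len(n), match(greedy, colnames(p)))] +
                              1e-9))
      expect_gte(a$objective, greedy_obj - 1e-12)
    }
  }
})

test_that("a saved forest bundle round-trips and is version-checked", {
  set.seed(58)
  sim <- sim_features(30, c("brain", "tumor"), shift = 5)
  fit <- train_forest(sim$x, sim$y, seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_forest(fit, path)
  back <- load_forest(path)
  expect_identical(back$feature_names, fit$feature_names)
  probe <- sim_features(5, c("brain", "tumor"))$x
  expect_identical(predict_probabilities(back, probe),
                   predict_probabilities(fit, probe))
  saveRDS(list(format = "something_else"), path)
  expect_error(load_forest(path), "bundle")
})

test_that("hold-out evaluation counts per-class and overall accuracy", {
  set.seed(57)
  sim <- sim_features(30, c("brain", "heart", "tumor"), shift = 6)
  fit <- train_forest(sim$x, sim$y, seed = 4)
  ev <- evaluate_holdout(fit, sim$x, sim$y)
  expect_equal(unname(ev$overall["total"]), 90)
  expect_equal(sum(ev$per_class$total), 90)
  # perfect predictions count 100% everywhere; injected confusions count
  truth <- sim$y
  pred_perfect <- truth
  k <- 7
  truth_k <- truth
  truth_k[seq_len(k)] <- "bladder"   # k known mismatches
  ev2 <- evaluate_holdout(fit, sim$x, truth_k)
  expect_lte(ev2$overall["correct"], 90 - k + sum(ev2$per_class$correct
                                                  [ev2$per_class$class == "bladder"]))
  expect_error(evaluate_holdout(fit, sim$x[0, ], character(0)), "empty")
})
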