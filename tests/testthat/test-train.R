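test_that("holdout split is disjoint, exhaustive, stratified, reproducible", {
  set.seed(1)
  lab <- sample(0:4, 1000, replace = TRUE)
  sp <- holdout_split(lab, 0.2, seed = 7)
  expect_length(intersect(sp$train, sp$valid), 0)
  expect_setequal(c(sp$train, sp$valid), seq_along(lab))
  sp2 <- holdout_split(lab, 0.2, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp, holdout_split(lab, 0.2, seed = 8)))
  # 7 balanced classes of 50 at fraction 0.2 -> exactly 10 each in validation
  lab7 <- rep(0:6, each = 50)
  sp7 <- holdout_split(lab7, 0.2, seed = 1)
  expect_equal(unname(tabulate(lab7[sp7$valid] + 1L, 7)), rep(10L, 7L))
  expect_error(holdout_split(c(0, 0, 1), 0.2), "fewer than 2")
  expect_error(holdout_split(lab7, 1.2), "fraction")
})

test_that("plateau schedule decays exactly once after patience is exhausted", {
  st <- list(best = Inf, wait = 0L, lr = 0.001)
  losses <- c(1.0, 0.5, 0.6, 0.7, 0.65)   # 3 consecutive non-improving epochs
  for (l in losses)
    st <- ngndgnet:::plateau_update(st, l, patience = 2L, factor = 0.5)
  expect_equal(st$lr, 0.0005)             # exactly one decay event
  # k decay events give lr0 * factor^k exactly
  st <- list(best = Inf, wait = 0L, lr = 0.001)
  st <- ngndgnet:::plateau_update(st, 1, 2L, 0.5)
  for (i in 1:8) st <- ngndgnet:::plateau_update(st, 2, 2L, 0.5)
  expect_identical(st$lr, 0.001 * 0.5^4)
})

test_that("metrics report: perfect predictions, rank AUC, brute-force tallies", {
  # all correct -> accuracy 1, unit precision/recall, diagonal confusion
  probs <- diag(3)[c(1, 2, 3, 1, 2), ]
  r <- metrics_report(c(0L, 1L, 2L, 0L, 1L), probs)
  expect_equal(r$accuracy, 1)
  expect_equal(r$per_class$precision, rep(1, 3))
  expect_equal(r$per_class$recall, rep(1, 3))
  expect_true(all(r$confusion[upper.tri(r$confusion)] == 0))
  # perfectly separated 2-class scores -> AUC 1; reversed -> 0
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(c(0.1, 0.9), c(TRUE, FALSE)), 0)
  expect_equal(auc_rank(c(0.5, 0.5), c(TRUE, FALSE)), 0.5)  # tie -> midrank
  # hand-built 3-class list of 9 items vs exhaustive tally
  truth <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  pred <- c(0, 1, 0, 1, 1, 2, 2, 2, 0)
  cm <- confusion_matrix(truth, pred, 3)
  tally <- matrix(0L, 3, 3)
  for (i in 1:9) tally[truth[i] + 1, pred[i] + 1] <- tally[truth[i] + 1, pred[i] + 1] + 1L
  expect_equal(unclass(cm), tally, ignore_attr = TRUE)
  expect_equal(sum(cm), 9)
})

test_that("metrics conservation: micro precision = micro recall = accuracy; ovr counts", {
  set.seed(30)
  N <- 60; C <- 4
  probs <- matrix(rexp(N * C), N, C); probs <- probs / rowSums(probs)
  truth <- sample(0:(C - 1), N, replace = TRUE)
  r <- metrics_report(truth, probs)
  expect_equal(sum(r$confusion), N)
  expect_equal(r$micro_precision, r$accuracy)
  expect_equal(r$micro_recall, r$accuracy)
  # one-vs-rest expansion sums to N*C
  expect_equal(sum(r$per_class$tp + r$per_class$tn +
                     r$per_class$fp + r$per_class$fn), N * C)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- rnorm(80)
  pos <- rbinom(80, 1, plogis(scores))   # informative but noisy
  if (length(unique(pos)) < 2) pos[1:2] <- c(0, 1)
  ours <- auc_rank(scores, pos == 1)
  theirs <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("AUC for a class absent from the labels is excluded with a note", {
  probs <- matrix(c(0.7, 0.2, 0.1,
                    0.1, 0.8, 0.1,
                    0.6, 0.3, 0.1), 3, 3, byrow = TRUE)
  expect_message(r <- metrics_report(c(0L, 1L, 0L), probs), "undefined")
  expect_true(is.na(r$per_class$auc[3]))
  expect_false(is.na(r$macro_auc))
})

test_that("a short seeded fit is reproducible and learns the synthetic classes", {
  ds <- generate_lesions(synth_config(n_per_class = rep(12L, 7L), seed = 2))
  spec <- cnn_spec()
  cfg <- train_config(max_epochs = 3L, batch_size = 32L,
                      validation_fraction = 0.25, seed = 5L)
  fit1 <- ngndg_cnn(ds$images, ds$labels, spec, cfg, class_names = ds$classes)
  expect_s3_class(fit1, "ngndg_cnn")
  expect_equal(nrow(fit1$history), 3L)
  expect_true(all(c("train_loss", "valid_loss", "train_accuracy",
                    "valid_accuracy", "train_precision", "train_recall",
                    "train_auc", "valid_auc", "lr") %in% names(fit1$history)))
  # loss decreases over the short run
  expect_lt(fit1$history$train_loss[3], fit1$history$train_loss[1])
  # identical seed -> bitwise-identical history
  fit2 <- ngndg_cnn(ds$images, ds$labels, spec, cfg, class_names = ds$classes)
  expect_identical(fit1$history, fit2$history)
  # predict method: probabilities and classes
  p <- predict(fit1, ds$images[1:3, , , ])
  expect_equal(dim(p), c(3L, 7L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  cl <- predict(fit1, ds$images[1:3, , , ], type = "class")
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), ds$classes)
  # evaluation report is well-formed
  r <- suppressMessages(evaluate_cnn(fit1, ds$images, ds$labels))
  expect_s3_class(r, "metrics_report")
  expect_equal(sum(r$confusion), 84)
})

test_that("inverse-frequency class weighting reweights the loss but trains cleanly", {
  ds <- generate_lesions(synth_config(n_per_class = c(30L, 6L, 6L, 6L, 6L,
                                                      6L, 6L), seed = 4))
  cfg <- train_config(max_epochs = 2L, batch_size = 32L,
                      class_weights = "inverse", validation_fraction = 0.25,
                      seed = 6L)
  fit <- ngndg_cnn(ds$images, ds$labels, cnn_spec(), cfg,
                   class_names = ds$classes)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_equal(nrow(fit$history), 2L)
})

test_that("fitting rejects inconsistent inputs", {
  ds <- generate_lesions(synth_config(n_per_class = rep(3L, 7L), seed = 8))
  expect_error(ngndg_cnn(ds$images, ds$labels[-1]), "disagree")
  expect_error(ngndg_cnn(ds$images, rep(9L, 21)), "labels")
})
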