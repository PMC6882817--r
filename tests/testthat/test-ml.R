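# SVM extension of regulation labels.

test_that("feature construction yields the 13 documented features", {
  net <- metabolic_network(c("A", "B", "C"), list(
    reaction("R1", c(A = -1, B = -1, C = 1), 0, 10, gpr = "g1"),
    reaction("EX_A", c(A = 1), -10, 10)))
  expr <- matrix(1, 2, 4, dimnames = list(net$rxn_id, NULL))
  flux <- matrix(2, 2, 4, dimnames = list(net$rxn_id, NULL))
  ft <- build_features(net, expr, flux)
  expect_equal(ncol(ft), 13)
  expect_equal(ft["R1", "reversible"], 0)
  expect_equal(ft["R1", "n_metabolites"], 3)
  expect_equal(ft["R1", "n_substrates"], 2)
  expect_equal(ft["R1", "n_products"], 1)
  expect_equal(ft["EX_A", "reversible"], 1)
  expect_equal(ft["EX_A", "n_metabolites"], 1)
  # deterministic pathway indexing
  ft2 <- build_features(net, expr, flux)
  expect_identical(ft$pathway_index, ft2$pathway_index)
})

test_that("separable features train to perfect accuracy and duplicates
           predict identically", {
  set.seed(1)
  sim <- simulate_feature_table(n = 120, noise_sd = 0.05, seed = 4)
  clf <- train_classifiers(sim$features, sim$labels, seed = 1)
  # training accuracy on a cleanly separable class
  sc <- fluxtier:::decision_scores(clf$models[["TR-high"]],
                                   as.matrix(sim$features))
  expect_equal(unname(sc > 0), unname(sim$labels == "TR-high"))
  dup <- sim$features[c(1, 1, 2, 2), ]
  pred <- predict_unassigned(clf, dup)
  expect_identical(pred$labels[[1]], pred$labels[[2]])
  expect_identical(pred$labels[[3]], pred$labels[[4]])
})

test_that("classes below the positive minimum are skipped with a
           warning", {
  sim <- simulate_feature_table(n = 60, seed = 5)
  labs <- sim$labels
  labs[labs == "TL-down"] <- "TR-low"
  labs[which(labs == "TR-high")[-(1:3)]] <- "TR-low"  # 3 positives left
  w <- capture_warnings(clf <- train_classifiers(sim$features, labs,
                                                 seed = 1))
  expect_true(any(grepl("skipped", w)))
  expect_true("TR-high" %in% clf$skipped)
  expect_null(clf$models[["TR-high"]])
})

test_that("cross-validation scores a perfectly informative feature at
           AUC 1 and errors when folds exceed positives", {
  set.seed(2)
  n <- 80
  labs <- rep(c("TR-high", "none"), each = n / 2)
  ft <- data.frame(matrix(stats::rnorm(n * 12), n, 12))
  ft$signal <- ifelse(labs == "TR-high", 1, 0) + stats::rnorm(n, 0, 0.01)
  cv <- suppressWarnings(
    cross_validate(ft, labs, k = 5, seed = 1, classes = "TR-high"))
  expect_equal(cv$auc[cv$class == "TR-high"], 1)
  labs2 <- c(rep("TR-high", 3), rep("none", n - 3))
  expect_error(
    cross_validate(ft, labs2, k = 5, seed = 1, classes = "TR-high",
                   min_positive = 2),
    "exceeds positive count")
})

test_that("standardization is learned from the training rows only", {
  sim <- simulate_feature_table(n = 60, seed = 6)
  x_tr <- as.matrix(sim$features)
  y <- factor(ifelse(sim$labels == "TR-high", "pos", "neg"),
              levels = c("pos", "neg"))
  m <- fluxtier:::fit_one_svm(x_tr, y)
  expect_equal(unname(m$x.scale$`scaled:center`), unname(colMeans(x_tr)))
  # scoring a wild held-out outlier does not alter the stored scaling
  outlier <- x_tr[1, , drop = FALSE] * 1e3
  invisible(fluxtier:::decision_scores(m, outlier))
  expect_equal(unname(m$x.scale$`scaled:center`), unname(colMeans(x_tr)))
})

test_that("exactly-one-positive gating assigns predicted labels", {
  sim <- simulate_feature_table(n = 150, noise_sd = 0.05, seed = 7)
  clf <- train_classifiers(sim$features, sim$labels, seed = 1)
  pred <- predict_unassigned(clf, sim$features)
  one <- pred$n_positive == 1
  expect_true(all(!is.na(pred$labels[one])))
  expect_true(all(is.na(pred$labels[!one])))
  # labels assigned by a single firing classifier match that classifier
  hits <- pred$labels[one]
  for (cl in unique(hits)) {
    idx <- which(one)[hits == cl]
    sc <- fluxtier:::decision_scores(clf$models[[cl]],
                                     as.matrix(sim$features[idx, ]))
    expect_true(all(sc > 0))
  }
})
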