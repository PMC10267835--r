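test_that("hyperparameter grid enumerates 54 combinations", {
  g <- hyperparameter_grid()
  expect_equal(nrow(g), 54)
  expect_setequal(unique(g$kernel_size), c(3, 5, 7))
  expect_setequal(unique(g$epochs), c(50, 100))
})

test_that("disjoint-support classes are learned near-perfectly", {
  d <- gaussian_feature_data(n_per_class = 120, T = 32, mu1 = 5, mu2 = 50,
                             sd = 2, seed = 1)
  clf <- train_classifier(d$features, d$labels,
                          spec = model_spec(epochs = 20), seed = 3)
  expect_gte(clf$test_accuracy, 0.99)
  # argmax of the probability matrix is the returned label
  pred <- predict(clf, d$features)
  probs <- attr(pred, "probs")
  expect_equal(as.character(pred$label),
               colnames(probs)[max.col(probs)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
})

test_that("identically distributed classes stay at chance level", {
  d <- gaussian_feature_data(n_per_class = 150, T = 32, mu1 = 20, mu2 = 20,
                             sd = 4, seed = 5)
  clf <- train_classifier(d$features, d$labels,
                          spec = model_spec(epochs = 15), seed = 2)
  n_test <- sum(clf$test_confusion)
  ci <- 1.96 * sqrt(0.25 / n_test)
  expect_lt(abs(clf$test_accuracy - 0.5), ci + 0.05)
})

test_that("training is reproducible under a fixed seed", {
  d <- gaussian_feature_data(n_per_class = 60, T = 24, mu1 = 10, mu2 = 14,
                             sd = 3, seed = 9)
  c1 <- train_classifier(d$features, d$labels,
                         spec = model_spec(epochs = 8), seed = 11)
  c2 <- train_classifier(d$features, d$labels,
                         spec = model_spec(epochs = 8), seed = 11)
  expect_identical(c1$params, c2$params)
  p1 <- predict(c1, d$features); p2 <- predict(c2, d$features)
  expect_identical(p1$confidence, p2$confidence)
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- gaussian_feature_data(30, 24, 10, 20, 2, seed = 4)
  one_class <- factor(rep("A", length(d$labels)))
  expect_error(train_classifier(d$features, one_class, spec = model_spec()),
               "two classes")
  expect_error(nctmux:::nn_init(model_spec(kernel_size = 7), 5, 5, 2, 1),
               "shorter than kernel")
  clf <- train_classifier(d$features, d$labels,
                          spec = model_spec(epochs = 5), seed = 1)
  short <- gaussian_feature_data(10, 16, 10, 20, 2, seed = 2)
  expect_error(predict(clf, short$features), "does not match")
})

test_that("single-branch ablations are constructible and trainable", {
  d <- gaussian_feature_data(n_per_class = 80, T = 32, mu1 = 8, mu2 = 30,
                             sd = 2, seed = 6)
  for (br in c("intensity", "frequency")) {
    clf <- train_classifier(d$features, d$labels,
                            spec = model_spec(epochs = 15, branches = br),
                            seed = 4)
    expect_s3_class(clf, "nct_classifier")
    expect_true(clf$test_accuracy >= 0 && clf$test_accuracy <= 1)
  }
  # intensity-only easily solves a mean-shift problem
  clf_i <- train_classifier(d$features, d$labels,
                            spec = model_spec(epochs = 15,
                                              branches = "intensity"),
                            seed = 4)
  expect_gte(clf_i$test_accuracy, 0.95)
})

test_that("evaluation produces coherent confusion and discard curves", {
  d <- gaussian_feature_data(n_per_class = 100, T = 32, mu1 = 5, mu2 = 60,
                             sd = 2, seed = 8)
  clf <- train_classifier(d$features, d$labels,
                          spec = model_spec(epochs = 20), seed = 5)
  ev <- evaluate_classifier(clf, d$features, d$labels)
  # near-perfect predictions concentrate the confusion mass on the diagonal
  expect_gte(sum(diag(ev$confusion)) / sum(ev$confusion), 0.99)
  expect_equal(ev$discard_curve$discard_fraction[1], 0)
  expect_true(all(ev$discard_curve$accuracy >= 0 &
                    ev$discard_curve$accuracy <= 1))
  # confidence_filter(keep = 1) keeps every non-excluded spot
  pred <- predict(clf, d$features)
  expect_equal(sort(confidence_filter(pred, keep = 1)),
               seq_along(d$labels))
})

test_that("classifier checkpoints round-trip through disk", {
  d <- gaussian_feature_data(40, 24, 5, 25, 2, seed = 3)
  clf <- train_classifier(d$features, d$labels,
                          spec = model_spec(epochs = 5), seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, path)
  back <- load_classifier(path)
  expect_identical(back$params, clf$params)
  manifest <- jsonlite::read_json(sub("\\.rds$", ".json", path))
  expect_equal(unlist(manifest$classes), clf$classes)
})
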