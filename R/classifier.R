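# User-facing classifier: model specification, hyperparameter search,
# training protocol (80:20 split, 3-fold CV random search), prediction
# with confidence, and evaluation.

#' Classifier model specification
#'
#' Two parallel conv1d + max-pool branches (shared kernel size and filter
#' count) over the normalized intensity trace and its autocorrelation,
#' concatenated into one dense ReLU layer and a softmax output.
#'
#' @param kernel_size Convolution kernel length (grid: 3, 5, 7).
#' @param n_kernels Filters per branch (grid: 16, 32, 64).
#' @param batch_size Minibatch size (grid: 16, 32, 64).
#' @param epochs Training epochs (grid: 50, 100).
#' @param dense_units Width of the fully connected layer (200).
#' @param l1,l2 Elastic-net strengths on the weights.
#' @param lr Adam learning rate.
#' @param pool_size Max-pooling window.
#' @param branches `"both"` (default), or the ablations `"intensity"` /
#'   `"frequency"` that keep a single branch.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kernel_size = 5L, n_kernels = 32L, batch_size = 32L,
                       epochs = 50L, dense_units = 200L, l1 = 1e-5,
                       l2 = 1e-5, lr = 1e-3, pool_size = 2L,
                       branches = c("both", "intensity", "frequency")) {
  branches <- match.arg(branches)
  structure(list(kernel_size = as.integer(kernel_size),
                 n_kernels = as.integer(n_kernels),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 dense_units = as.integer(dense_units),
                 l1 = l1, l2 = l2, lr = lr,
                 pool_size = as.integer(pool_size), branches = branches),
            class = "model_spec")
}

#' The hyperparameter search grid
#'
#' @return A data.frame of all 54 combinations of kernel size (3/5/7),
#'   filter count (16/32/64), batch size (16/32/64) and epochs (50/100).
#' @export
hyperparameter_grid <- function() {
  expand.grid(kernel_size = c(3L, 5L, 7L), n_kernels = c(16L, 32L, 64L),
              batch_size = c(16L, 32L, 64L), epochs = c(50L, 100L))
}

stratified_split <- function(y, fraction, seed) {
  with_seed(seed, {
    test <- unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, max(1L, round(length(ix) * fraction)))))
    sort(unname(test))
  })
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (ix in split(seq_along(y), y)) {
      fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
    }
    fold
  })
}

fs_inputs <- function(features) {
  stopifnot(inherits(features, "feature_set"))
  list(Xi = features$intensity, Xg = features$acf)
}

#' Train the dual-input classifier
#'
#' Implements the training protocol: the data are split 80:20 into a
#' training pool and a withheld test set; hyperparameters are chosen by
#' random search over [hyperparameter_grid()] maximizing mean 3-fold
#' cross-validated accuracy on the training pool; the selected model is
#' retrained on the full pool and evaluated once on the withheld split.
#' Pass an explicit `spec` to skip the search.
#'
#' @param features A [build_features()] / [bind_features()] result.
#' @param labels Class labels (factor or coercible), one per spot.
#' @param spec A [model_spec()] to use directly, or `NULL` to search.
#' @param search_budget Number of random-search draws (without
#'   replacement) from the 54-cell grid.
#' @param cv_folds Cross-validation folds for the search.
#' @param cv_epoch_cap Optional cap on epochs during CV scoring only (the
#'   final refit uses the chosen epochs).
#' @param test_fraction Withheld fraction (default 0.2).
#' @param seed Master seed (splits, init, batching).
#' @param verbose Print search progress.
#' @return An object of class `nct_classifier` with the fitted weights,
#'   chosen `spec`, class levels, stored normalization extrema, withheld
#'   `test_accuracy` / `test_confusion`, and the search table.
#' @export
train_classifier <- function(features, labels, spec = NULL,
                             search_budget = 15L, cv_folds = 3L,
                             cv_epoch_cap = NULL, test_fraction = 0.2,
                             seed = 1L, verbose = FALSE) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stopf("training needs at least two classes")
  if (any(table(labels) < 2L)) stopf("every class needs >= 2 examples")
  inp <- fs_inputs(features)
  n_classes <- nlevels(labels)
  y <- as.integer(labels)

  test_idx <- stratified_split(y, test_fraction, child_seed(seed, 1L))
  train_idx <- setdiff(seq_along(y), test_idx)

  search_tab <- NULL
  if (is.null(spec)) {
    grid <- hyperparameter_grid()
    draws <- with_seed(child_seed(seed, 2L),
                       sample.int(nrow(grid), min(search_budget, nrow(grid))))
    fold <- stratified_folds(y[train_idx], cv_folds, child_seed(seed, 3L))
    score <- numeric(length(draws))
    for (d in seq_along(draws)) {
      sp <- do.call(model_spec, as.list(grid[draws[d], ]))
      acc <- numeric(cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- train_idx[fold != f]; va <- train_idx[fold == f]
        fit <- nn_train(inp$Xi[tr, , drop = FALSE],
                        inp$Xg[tr, , drop = FALSE], y[tr], sp, n_classes,
                        seed = child_seed(seed, 100L + 10L * d + f),
                        epochs = min(sp$epochs, cv_epoch_cap %||% sp$epochs))
        pr <- nn_predict_probs(fit, sp, inp$Xi[va, , drop = FALSE],
                               inp$Xg[va, , drop = FALSE])
        acc[f] <- mean(max.col(pr) == y[va])
      }
      score[d] <- mean(acc)
      if (verbose)
        message(sprintf("draw %d/%d: k=%d nk=%d bs=%d ep=%d -> cv acc %.3f",
                        d, length(draws), sp$kernel_size, sp$n_kernels,
                        sp$batch_size, sp$epochs, score[d]))
    }
    search_tab <- cbind(grid[draws, ], cv_accuracy = score)
    spec <- do.call(model_spec, as.list(grid[draws[which.max(score)], ]))
  }

  fit <- nn_train(inp$Xi[train_idx, , drop = FALSE],
                  inp$Xg[train_idx, , drop = FALSE], y[train_idx], spec,
                  n_classes, seed = child_seed(seed, 4L))
  pr <- nn_predict_probs(fit, spec, inp$Xi[test_idx, , drop = FALSE],
                         inp$Xg[test_idx, , drop = FALSE])
  pred <- max.col(pr)
  clf <- structure(list(params = fit$params, dims = fit$dims, spec = spec,
                        classes = levels(labels),
                        T_i = ncol(inp$Xi), T_g = ncol(inp$Xg),
                        extrema = features$extrema, seed = seed,
                        history = fit$history, search = search_tab,
                        test_accuracy = mean(pred == y[test_idx]),
                        test_confusion = table(
                          truth = labels[test_idx],
                          predicted = factor(levels(labels)[pred],
                                             levels = levels(labels)))),
                   class = "nct_classifier")
  clf
}

#' @export
print.nct_classifier <- function(x, ...) {
  cat(sprintf(paste0("<nct_classifier> %d classes (%s), k=%d, %d kernels; ",
                     "withheld accuracy %.3f\n"),
              length(x$classes), paste(x$classes, collapse = "/"),
              x$spec$kernel_size, x$spec$n_kernels, x$test_accuracy))
  invisible(x)
}

#' Predict labels and confidences
#'
#' @param object An [train_classifier()] result.
#' @param features A `feature_set` with the training trace length.
#' @param ... Unused.
#' @return A data.frame with `label` and `confidence` (the winning softmax
#'   probability); the full probability matrix is in `attr(, "probs")`.
#'   Deterministic given the fitted weights.
#' @export
predict.nct_classifier <- function(object, features, ...) {
  inp <- fs_inputs(features)
  if (ncol(inp$Xi) != object$T_i || ncol(inp$Xg) != object$T_g)
    stopf("feature length (%d, %d) does not match training length (%d, %d)",
          ncol(inp$Xi), ncol(inp$Xg), object$T_i, object$T_g)
  pr <- nn_predict_probs(object, object$spec, inp$Xi, inp$Xg)
  colnames(pr) <- object$classes
  out <- data.frame(
    label = factor(object$classes[max.col(pr)], levels = object$classes),
    confidence = pr[cbind(seq_len(nrow(pr)), max.col(pr))])
  attr(out, "probs") <- pr
  out
}

#' Evaluate a classifier on labeled data
#'
#' @param clf An [train_classifier()] result.
#' @param features A `feature_set`.
#' @param labels True labels.
#' @param exclude_class Optional class name(s) (e.g. the non-translating
#'   noise class) excluded from the accuracy numerator/denominator, as in
#'   reporting accuracy "disregarding blank trajectories".
#' @return A list: `accuracy`, `confusion` (full table),
#'   `accuracy_excluding` (when `exclude_class` given), and
#'   `discard_curve`, a data.frame of accuracy vs the fraction of
#'   lowest-confidence (non-excluded) spots discarded.
#' @export
evaluate_classifier <- function(clf, features, labels,
                                exclude_class = NULL) {
  labels <- factor(labels, levels = clf$classes)
  pred <- predict(clf, features)
  confusion <- table(truth = labels, predicted = pred$label)
  acc <- mean(pred$label == labels)
  keep <- !(as.character(labels) %in% exclude_class) &
    !(as.character(pred$label) %in% exclude_class)
  acc_ex <- if (is.null(exclude_class)) NULL else
    mean(pred$label[keep] == labels[keep])
  fracs <- seq(0, 0.9, by = 0.1)
  curve <- vapply(fracs, function(d) {
    sel <- which(!(as.character(pred$label) %in% exclude_class))
    ord <- sel[order(pred$confidence[sel], decreasing = TRUE)]
    kept <- ord[seq_len(max(1L, floor(length(ord) * (1 - d))))]
    mean(pred$label[kept] == labels[kept])
  }, numeric(1))
  list(accuracy = acc, confusion = confusion, accuracy_excluding = acc_ex,
       discard_curve = data.frame(discard_fraction = fracs,
                                  accuracy = curve))
}

#' Keep only the most confident predictions
#'
#' @param pred A [predict.nct_classifier()] result.
#' @param keep Fraction of spots to keep (by descending confidence);
#'   `keep = 1` is a no-op.
#' @param exclude_class Class name(s) never counted or kept (noise spots).
#' @return Integer indices of the kept spots.
#' @export
confidence_filter <- function(pred, keep = 0.5, exclude_class = NULL) {
  sel <- which(!(as.character(pred$label) %in% exclude_class))
  ord <- sel[order(pred$confidence[sel], decreasing = TRUE)]
  ord[seq_len(max(1L, floor(length(ord) * keep)))]
}

#' Save / load a trained classifier
#'
#' Weights go to an RDS checkpoint; a JSON manifest (spec, classes, seed,
#' normalization extrema, withheld accuracy) is written alongside.
#'
#' @param clf An `nct_classifier`.
#' @param path Checkpoint path (`.rds`); the manifest gets `.json`.
#' @return The path, invisibly (`load_classifier`: the classifier).
#' @export
save_classifier <- function(clf, path) {
  saveRDS(clf, path)
  write_manifest(paste0(sub("\\.rds$", "", path), ".json"),
                 classes = clf$classes, spec = unclass(clf$spec),
                 seed = clf$seed, extrema = clf$extrema,
                 test_accuracy = clf$test_accuracy)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(path)
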