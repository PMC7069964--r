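# Benchmark classifiers: k-nearest neighbours (Euclidean, k up to 30),
# random forest (maximum depth one third of the input dimension, varying
# tree count) and RBF-kernel SVM (grids over the L2-regularization cost
# and kernel width). Hyper-parameters are selected by mean AUC over
# stratified 10-fold cross-validation of the training set.

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  folds
}

benchmark_grid <- function(kind, input_dim) {
  switch(kind,
    knn = data.frame(k = 1:30),
    rf = data.frame(num_trees = c(100L, 300L, 500L),
                    max_depth = ceiling(input_dim / 3)),
    svm = expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = c(0.005, 0.01, 0.05, 0.1, 0.5))
  )
}

fit_predict_benchmark <- function(kind, params, x_train, y_train, x_test,
                                  seed) {
  y_factor <- factor(y_train, levels = c(0, 1))
  if (kind == "knn") {
    local_seed(seed, {
      pred <- class::knn(train = x_train, test = x_test, cl = y_factor,
                         k = params$k, prob = TRUE)
    })
    vote <- attr(pred, "prob")
    ifelse(pred == "1", vote, 1 - vote)
  } else if (kind == "rf") {
    df <- data.frame(y = y_factor, x_train, check.names = FALSE)
    fit <- ranger::ranger(y ~ ., data = df, probability = TRUE,
                          num.trees = params$num_trees,
                          max.depth = params$max_depth,
                          seed = seed, num.threads = 1L)
    stats::predict(fit, data.frame(x_test, check.names = FALSE),
                   num.threads = 1L)$predictions[, "1"]
  } else if (kind == "svm") {
    local_seed(seed, {
      fit <- e1071::svm(x_train, y_factor, kernel = "radial",
                        cost = params$cost, gamma = params$gamma,
                        probability = TRUE)
      pr <- stats::predict(fit, x_test, probability = TRUE)
    })
    attr(pr, "probabilities")[, "1"]
  } else {
    stopf("unknown benchmark kind '%s'", kind)
  }
}

#' Train a benchmark classifier with cross-validated tuning
#'
#' Runs a hyper-parameter grid search by stratified `cv_folds`-fold
#' cross-validation on the training data, selecting the setting with the
#' highest mean validation AUC (ties toward the simpler, earlier grid
#' entry), then refits on all training data.
#'
#' @param kind `"knn"`, `"rf"` or `"svm"`.
#' @param features training features (`feature_block` or matrix).
#' @param labels binary outcome (1 = death).
#' @param cv_folds number of folds (default 10).
#' @param seed seed for folding and stochastic fits.
#' @param grid optional data.frame overriding the default grid.
#' @return object of class `prognet_benchmark` with the selected
#'   parameters, the CV table, and (for rf/svm) the refitted model; KNN
#'   stores its training data, being a lazy learner.
#' @export
train_benchmark <- function(kind = c("knn", "rf", "svm"), features, labels,
                            cv_folds = 10L, seed = 1L, grid = NULL) {
  kind <- match.arg(kind)
  x <- as_feature_matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(x)) stopf("labels and features differ in length")
  if (length(unique(y)) < 2L) stopf("training labels contain a single class")
  if (nrow(x) < cv_folds) stopf("fewer samples than folds")
  if (is.null(grid)) grid <- benchmark_grid(kind, ncol(x))

  folds <- local_seed(seed, stratified_folds(y, cv_folds))
  cv_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      te <- folds == f
      scores <- fit_predict_benchmark(kind, grid[gi, , drop = FALSE],
                                      x[!te, , drop = FALSE], y[!te],
                                      x[te, , drop = FALSE],
                                      seed = seed + f)
      aucs[f] <- roc_and_auc(scores, y[te])$auc
    }
    cv_auc[gi] <- mean(aucs)
  }
  best <- which.max(cv_auc) # first (simplest) grid row wins ties
  params <- grid[best, , drop = FALSE]

  final_model <- NULL
  if (kind == "rf") {
    df <- data.frame(y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
    final_model <- ranger::ranger(y ~ ., data = df, probability = TRUE,
                                  num.trees = params$num_trees,
                                  max.depth = params$max_depth,
                                  seed = seed, num.threads = 1L)
  } else if (kind == "svm") {
    final_model <- local_seed(seed, {
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = params$cost, gamma = params$gamma,
                 probability = TRUE)
    })
  }
  structure(
    list(kind = kind, params = params, seed = seed,
         cv_table = cbind(grid, cv_auc = cv_auc),
         model = final_model,
         train_x = if (kind == "knn") x else NULL,
         train_y = if (kind == "knn") y else NULL),
    class = "prognet_benchmark"
  )
}

#' @export
predict_risk.prognet_benchmark <- function(model, features, ...) {
  x <- as_feature_matrix(features)
  p <- if (model$kind == "knn") {
    fit_predict_benchmark("knn", model$params, model$train_x,
                          model$train_y, x, seed = model$seed)
  } else if (model$kind == "rf") {
    stats::predict(model$model, data.frame(x, check.names = FALSE),
                   num.threads = 1L)$predictions[, "1"]
  } else {
    pr <- stats::predict(model$model, x, probability = TRUE)
    attr(pr, "probabilities")[, "1"]
  }
  stats::setNames(as.numeric(p), rownames(x))
}

#' @export
print.prognet_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark classifier: %s (%s); best CV AUC %.4f\n",
              toupper(x$kind),
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "),
              max(x$cv_table$cv_auc)))
  invisible(x)
}
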