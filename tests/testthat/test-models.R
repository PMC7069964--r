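# Neural networks (unimodal + bimodal) and benchmark classifiers.

test_that("network architecture matches the documented design", {
  spec <- bimodal_spec()
  expect_equal(spec$merged_width, 58L)      # 40 + 18

  micro <- build_network(branch_spec(15))
  # 15*40+40 + 3*(40*40+40) + 40+1
  expect_equal(n_params(micro), 5601L)

  bi <- build_network(spec)
  expect_equal(nrow(bi$post[[1]]$W), 58L)
  expect_lt(n_params(bi), 20000L)           # desk-scale model

  expect_error(branch_spec(0), "positive")
  expect_error(branch_spec(5, hidden_widths = integer(0)), "non-empty")
})

test_that("an all-zero network outputs probability one half", {
  m <- build_network(branch_spec(4, hidden_widths = c(8, 8)))
  m$layers <- lapply(m$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  p <- predict_risk(m, matrix(rnorm(20), 5, 4))
  expect_equal(unname(p), rep(0.5, 5))
})

test_that("training fits a linearly separable toy problem", {
  set.seed(1)
  n <- 60
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- as.integer(X[, 1] + X[, 2] > 0)
  m <- build_network(branch_spec(2, hidden_widths = c(8, 8), seed = 2))
  fit <- train_unimodal(m, X, y, X, y,
                        train_spec(max_epochs = 100, early_stop_patience = 100,
                                   seed = 3))
  acc <- mean(classify_at(predict_risk(fit, X)) == y)
  expect_equal(acc, 1)
  expect_equal(fit$best_epoch,
               fit$history$epoch[which.min(fit$history$val_loss)])
})

test_that("training is deterministic given the seeds", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, plogis(X[, 1]))
  while (length(unique(y)) < 2) y <- rbinom(50, 1, 0.5)
  ts <- train_spec(max_epochs = 10, early_stop_patience = 10, seed = 5)
  f1 <- train_unimodal(build_network(branch_spec(4, c(6, 6), seed = 4)),
                       X, y, X, y, ts)
  f2 <- train_unimodal(build_network(branch_spec(4, c(6, 6), seed = 4)),
                       X, y, X, y, ts)
  expect_identical(f1$layers, f2$layers)
  expect_identical(f1$history, f2$history)
  expect_error(train_unimodal(build_network(branch_spec(4, c(6, 6))),
                              X, rep(1, 50), X, y, ts), "single class")
})

test_that("label-permuted training yields chance-level validation AUC", {
  set.seed(12)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.5)
  aucs <- vapply(1:8, function(s) {
    yp <- sample(y)
    tr <- 1:80
    va <- 81:120
    f <- train_unimodal(build_network(branch_spec(5, c(8, 8), seed = s)),
                        X[tr, ], yp[tr], X[va, ], yp[va],
                        train_spec(max_epochs = 30, early_stop_patience = 30,
                                   seed = s))
    roc_and_auc(predict_risk(f, X[va, ]), yp[va])$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("bimodal initialization reproduces the pre-trained branches exactly", {
  set.seed(3)
  n <- 40
  Xm <- matrix(rnorm(n * 6), n, 6)
  Xc <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, 0.5)
  while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
  ts <- train_spec(max_epochs = 5, early_stop_patience = 5, seed = 2)
  m1 <- train_unimodal(build_network(branch_spec(6, c(10, 10), seed = 1)),
                       Xm, y, Xm, y, ts)
  m2 <- train_unimodal(build_network(branch_spec(3, c(4, 4), seed = 2)),
                       Xc, y, Xc, y, ts)
  # zero fine-tuning epochs: branch weights must equal the unimodal weights
  bi0 <- train_bimodal(m1, m2, Xm, Xc, y, Xm, Xc, y,
                       train_spec(max_epochs = 0, early_stop_patience = 0,
                                  seed = 3),
                       post_merge_widths = c(8), seed = 11)
  expect_identical(bi0$micro, m1$layers[1:2])
  expect_identical(bi0$clin, m2$layers[1:2])
  expect_equal(bi0$best_epoch, 0L)
  expect_error(train_bimodal(m1, m2, Xc, Xm, y, Xc, Xm, y), "dimensions")
})

test_that("prediction is deterministic, batched consistently and bounded", {
  set.seed(6)
  m <- build_network(branch_spec(3, c(5, 5), seed = 9))
  X <- matrix(rnorm(60), 20, 3)
  p_batch <- predict_risk(m, X)
  p_single <- vapply(seq_len(20), function(i) {
    predict_risk(m, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(unname(p_batch), unname(p_single), tolerance = 1e-6)
  expect_true(all(p_batch > 0 & p_batch < 1))
  # a duplicated sample gets an identical probability
  X2 <- rbind(X, X[1, ])
  expect_equal(unname(predict_risk(m, X2))[21], unname(p_batch)[1])
})

test_that("benchmark tuning respects the documented constraints", {
  set.seed(44)
  n <- 80
  X <- cbind(matrix(rnorm(n * 15), n, 15))
  colnames(X) <- paste0("f", 1:15)
  y <- as.integer(X[, 1] > 0)
  rf <- train_benchmark("rf", X, y, cv_folds = 5, seed = 2)
  expect_equal(unique(rf$cv_table$max_depth), 5)  # ceil(15 / 3)
  expect_true(rf$params$num_trees %in% c(100, 300, 500))

  # KNN grid spans 1..30 and selection is reproducible
  knn1 <- train_benchmark("knn", X, y, cv_folds = 5, seed = 3)
  knn2 <- train_benchmark("knn", X, y, cv_folds = 5, seed = 3)
  expect_identical(knn1$params, knn2$params)
  expect_equal(range(knn1$cv_table$k), c(1, 30))
  expect_true(all(predict_risk(knn1, X) >= 0 & predict_risk(knn1, X) <= 1))

  expect_error(train_benchmark("rf", X, rep(1L, n), seed = 1), "single class")
})

test_that("KNN picks a small k when only local structure is informative", {
  set.seed(10)
  # XOR-like checkerboard: 1-NN succeeds, 30-NN near chance
  n <- 100
  X <- cbind(runif(n), runif(n))
  y <- as.integer(xor(X[, 1] > 0.5, X[, 2] > 0.5))
  knn <- train_benchmark("knn", X, y, cv_folds = 5, seed = 1)
  expect_lt(knn$params$k, 15)
})

test_that("SVM benchmark trains and separates an easy problem", {
  set.seed(13)
  n <- 60
  X <- cbind(rnorm(n, mean = rep(c(0, 3), each = n / 2)), rnorm(n))
  colnames(X) <- c("a", "b")
  y <- rep(c(0L, 1L), each = n / 2)
  svm <- train_benchmark("svm", X, y, cv_folds = 5, seed = 4,
                         grid = expand.grid(cost = c(1, 10),
                                            gamma = c(0.05, 0.5)))
  auc <- roc_and_auc(predict_risk(svm, X), y)$auc
  expect_gt(auc, 0.9)
})
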