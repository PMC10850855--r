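# SVM training pipeline: data preparation, splitting, grid search,
# Nystroem approximation, final model, persistence.

# two well-separated Gaussian blobs in the 26-feature space
make_blobs <- function(n_good, n_bad, sep = 6, sd = 1) {
  p <- length(feature_names())
  X <- rbind(matrix(rnorm(n_good * p, 0, sd), n_good),
             matrix(rnorm(n_bad * p, sep, sd), n_bad))
  colnames(X) <- feature_names()
  list(X = X, y = c(rep(1L, n_good), rep(0L, n_bad)))
}

blob_table <- function(n_good, n_bad, ...) {
  b <- make_blobs(n_good, n_bad, ...)
  df <- tibble::as_tibble(as.data.frame(b$X))
  df$label <- as.numeric(b$y)
  df
}

test_that("train_config validates its arguments", {
  expect_s3_class(train_config(), "train_config")
  expect_equal(train_config()$C_grid, c(100, 1000, 10000))
  expect_equal(train_config()$gamma_grid, c(0.001, 0.01, 0.1))
  expect_error(train_config(test_fraction = 0), class = "cellcurator_validation_error")
  expect_error(train_config(folds = 1), class = "cellcurator_validation_error")
  expect_error(train_config(C_grid = numeric(0)), class = "cellcurator_validation_error")
})

test_that("prepare_training_data concatenates, drops incomplete rows, checks labels", {
  set.seed(301)
  t1 <- blob_table(5, 5); t2 <- blob_table(3, 3)
  t2$cell_length[1] <- NA
  t2$label[2] <- NA
  prep <- prepare_training_data(list(t1, t2))
  expect_equal(nrow(prep$X), 14L)
  expect_equal(prep$n_dropped, 2L)
  expect_equal(sum(prep$proportions), 1)
  expect_error(prepare_training_data(t1[, -3]), class = "cellcurator_validation_error")
  all_good <- blob_table(4, 1); all_good$label <- 1
  expect_error(prepare_training_data(all_good), class = "cellcurator_validation_error")
  t3 <- blob_table(2, 2); t3$label <- c(1, 0, 2, 1)
  expect_error(prepare_training_data(t3), class = "cellcurator_validation_error")
})

test_that("splitting is stratified, deterministic and exhaustive", {
  set.seed(307)
  b <- make_blobs(63, 37)
  sp <- split_data(b$X, b$y, train_config(seed = 5))
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), 100L)
  # 50-50 split of each class; round() halves go to the even count
  expect_equal(sum(sp$test$y == 1L), 32L)
  expect_equal(sum(sp$test$y == 0L), 18L)
  expect_equal(abs(sum(sp$train$y == 1L) - sum(sp$test$y == 1L)) <= 2, TRUE)
  sp2 <- split_data(b$X, b$y, train_config(seed = 5))
  expect_identical(sp$train$X, sp2$train$X)
  sp3 <- split_data(b$X, b$y, train_config(seed = 6))
  expect_false(identical(sp$train$X, sp3$train$X))
  expect_error(split_data(b$X, rep(1L, 100)), class = "cellcurator_validation_error")
})

test_that("correlation matrix matches stats::cor and warns on constants", {
  set.seed(311)
  X <- make_blobs(20, 20)$X
  cc <- correlation_matrix(X)
  expect_equal(cc, cor(X))
  expect_equal(diag(cc), rep(1, 26), ignore_attr = TRUE)
  Xc <- X; Xc[, 2] <- 3.3
  expect_warning(cc2 <- correlation_matrix(Xc), "constant")
  expect_true(all(is.na(cc2[2, -2])))
  expect_error(correlation_matrix(X[1:2, ]), class = "cellcurator_validation_error")
})

test_that("grid search covers the full grid and nails separable data", {
  set.seed(313)
  b <- make_blobs(60, 40)
  gs <- grid_search(b, train_config(seed = 2))
  expect_equal(nrow(gs$cv_table), 3L + 9L)
  expect_equal(sum(gs$cv_table$kernel == "linear"), 3L)
  expect_equal(sum(is.na(gs$cv_table$gamma)), 3L)
  expect_equal(gs$best$accuracy, 1)
  # deterministic tie-break: all-perfect grid picks linear with smallest C
  expect_equal(gs$best$kernel, "linear")
  expect_equal(gs$best$C, 100)
  gs2 <- grid_search(b, train_config(seed = 2))
  expect_identical(gs$cv_table, gs2$cv_table)
})

test_that("grid search honours a restricted kernel list", {
  set.seed(317)
  b <- make_blobs(30, 30)
  gs <- grid_search(b, train_config(kernels = "rbf", seed = 3))
  expect_equal(nrow(gs$cv_table), 9L)
  expect_true(all(gs$cv_table$kernel == "rbf"))
})

test_that("the final model separates the classes with the documented sign convention", {
  set.seed(331)
  b <- make_blobs(40, 40)
  gs <- grid_search(b, train_config(seed = 4))
  m <- fit_final(b, gs$best, train_config(seed = 4))
  expect_s3_class(m, "curation_model")
  pr <- predict_curation(m, b$X)
  expect_equal(pr$labels, b$y)
  expect_true(all(pr$scores[b$y == 1L] > 0))
  expect_true(all(pr$scores[b$y == 0L] < 0))
  expect_output(print(m), "curation_model")
  m2 <- fit_final(b, gs$best, train_config(seed = 4))
  expect_identical(m$rule, m2$rule)
})

test_that("the sign convention holds for an RBF model too", {
  set.seed(337)
  b <- make_blobs(25, 40, sep = 4)
  m <- fit_final(b, list(kernel = "rbf", C = 1000, gamma = 0.01),
                 train_config(seed = 7))
  pr <- predict_curation(m, b$X)
  expect_gt(mean(pr$labels == b$y), 0.95)
  expect_gt(mean(pr$scores[b$y == 1L]), 0)
  expect_lt(mean(pr$scores[b$y == 0L]), 0)
})

test_that("the full-rank Nystroem map reproduces the RBF kernel matrix", {
  set.seed(347)
  b <- make_blobs(120, 80, sep = 3)
  Z <- cellcurator:::apply_scaler(cellcurator:::fit_scaler(b$X), b$X)
  gamma <- 0.01
  ny <- cellcurator:::nystrom_fit(Z, 200L, gamma)  # all points as landmarks
  Phi <- cellcurator:::nystrom_transform(ny, Z)
  K <- cellcurator:::rbf_kernel(Z, Z, gamma)
  expect_lt(max(abs(tcrossprod(Phi) - K)), 1e-6)
  # low-rank map still approximates well on smooth data
  set.seed(347)
  ny2 <- cellcurator:::nystrom_fit(Z, 80L, gamma)
  Phi2 <- cellcurator:::nystrom_transform(ny2, Z)
  expect_lt(max(abs(tcrossprod(Phi2) - K)), 0.1)
})

test_that("Nystroem-trained and exact RBF models agree in their decisions", {
  set.seed(349)
  b <- make_blobs(120, 80, sep = 3)
  best <- list(kernel = "rbf", C = 1000, gamma = 0.01)
  exact <- fit_final(b, best, train_config(use_nystrom = FALSE, seed = 11))
  approx <- fit_final(b, best, train_config(use_nystrom = TRUE,
                                            nystrom_components = 200L, seed = 11))
  expect_false(is.null(approx$nystrom))
  expect_null(exact$nystrom)
  se <- predict_curation(exact, b$X)
  sa <- predict_curation(approx, b$X)
  # identical kernel, independently solved duals: scores match to the
  # solver tolerance and every label agrees
  expect_lt(max(abs(se$scores - sa$scores)), 0.01)
  expect_identical(se$labels, sa$labels)
})

test_that("the Nystroem path switches in automatically above the threshold", {
  cfg <- train_config()
  expect_false(cellcurator:::nystrom_active(cfg, 5000L))
  expect_true(cellcurator:::nystrom_active(cfg, 5001L))
  expect_true(cellcurator:::nystrom_active(train_config(use_nystrom = TRUE), 10L))
})

test_that("balanced class weights are inversely proportional to class counts", {
  w <- cellcurator:::class_weights_arg(train_config(class_weight = "balanced"),
                                       c(rep(0L, 30), rep(1L, 10)))
  expect_equal(unname(w["0"] / w["1"]), 1 / 3)
  expect_null(cellcurator:::class_weights_arg(train_config(), c(0L, 1L)))
})

test_that("prediction enforces the feature manifest", {
  set.seed(349)
  b <- make_blobs(20, 20)
  m <- fit_final(b, list(kernel = "linear", C = 100), train_config(seed = 8))
  scrambled <- b$X[, rev(colnames(b$X))]
  expect_error(predict_curation(m, scrambled), class = "cellcurator_validation_error")
  df <- as.data.frame(b$X)[, 1:10]
  expect_error(predict_curation(m, df), class = "cellcurator_validation_error")
  withna <- b$X; withna[3, 5] <- NA
  expect_error(predict_curation(m, withna), class = "cellcurator_validation_error")
  # data-frame input with extra columns and different order is reconciled
  df2 <- as.data.frame(b$X)[, sample(26)]
  df2$frame <- 0L
  pr <- predict_curation(m, df2)
  expect_equal(pr$labels, predict_curation(m, b$X)$labels)
})

test_that("model archives round-trip predictions bit-identically", {
  set.seed(353)
  b <- make_blobs(30, 30, sep = 3)
  for (best in list(list(kernel = "linear", C = 1000),
                    list(kernel = "rbf", C = 100, gamma = 0.1))) {
    m <- fit_final(b, best, train_config(seed = 9))
    f <- withr::local_tempfile(fileext = ".json")
    save_model(m, f)
    m2 <- load_model(f)
    expect_identical(predict_curation(m2, b$X)$scores,
                     predict_curation(m, b$X)$scores)
  }
})

test_that("corrupt or truncated model files raise a format error", {
  expect_error(load_model(file.path(tempdir(), "missing.json")),
               class = "cellcurator_input_error")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("]", f)
  expect_error(load_model(f), class = "cellcurator_format_error")
  set.seed(359)
  b <- make_blobs(10, 10)
  m <- fit_final(b, list(kernel = "linear", C = 100), train_config(seed = 10))
  save_model(m, f)
  txt <- readLines(f)
  writeLines(substr(paste(txt, collapse = ""), 1, 200), f)
  expect_error(load_model(f), class = "cellcurator_format_error")
})
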