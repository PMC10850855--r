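# Training, validation and deployment of the detection-curation SVM:
# NaN removal, stratified splitting, 5-fold grid-search cross-validation
# over linear/RBF kernels (with an optional Nystroem low-rank kernel
# approximation for large training sets), ROC/AUC, confusion-matrix
# metrics, per-feature bias ratios, and a self-describing model archive.

#' Training configuration
#'
#' Defaults: 50-50 train-test split, 5-fold
#' CV over linear and RBF kernels with C in \{100, 1000, 10000\} and
#' gamma in \{0.001, 0.01, 0.1\}, and the Nystroem approximation switched
#' in automatically above 5000 training points.
#'
#' @param test_fraction Fraction of rows held out for testing.
#' @param kernels Subset of `c("linear", "rbf")`.
#' @param C_grid,gamma_grid Hyperparameter grids.
#' @param folds Cross-validation folds.
#' @param use_nystrom `NA` = auto (enabled when `n_train >
#'   nystrom_threshold`); `TRUE`/`FALSE` force.
#' @param nystrom_components Number of landmark points (capped at
#'   `n_train`).
#' @param nystrom_threshold Training-set size above which the RBF kernel
#'   is approximated.
#' @param class_weight `NULL`, `"balanced"`, or a named vector of weights
#'   for classes `"0"` and `"1"` (cost-sensitive training).
#' @param seed Seed for splitting, fold assignment and landmark sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(test_fraction = 0.5,
                         kernels = c("linear", "rbf"),
                         C_grid = c(100, 1000, 10000),
                         gamma_grid = c(0.001, 0.01, 0.1),
                         folds = 5L,
                         use_nystrom = NA,
                         nystrom_components = 1000L,
                         nystrom_threshold = 5000L,
                         class_weight = NULL,
                         seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_validation("test_fraction must lie strictly between 0 and 1")
  }
  kernels <- match.arg(kernels, c("linear", "rbf"), several.ok = TRUE)
  if (folds < 2L) stop_validation("folds must be at least 2")
  if (!length(C_grid) || !length(gamma_grid)) stop_validation("hyperparameter grids must be non-empty")
  structure(list(test_fraction = test_fraction, kernels = kernels,
                 C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 folds = as.integer(folds), use_nystrom = use_nystrom,
                 nystrom_components = as.integer(nystrom_components),
                 nystrom_threshold = as.integer(nystrom_threshold),
                 class_weight = class_weight, seed = as.integer(seed)),
            class = "train_config")
}

# -- data preparation -------------------------------------------------------

#' Assemble a training matrix from labeled feature tables
#'
#' Tables are concatenated; rows with any missing feature value or a
#' missing label (ambiguous "question" verdicts) are dropped.
#'
#' @param labeled_tables A labeled feature tibble, or a list of them; each
#'   needs the 26 feature columns and a `label` column in \{1, 0, `NA`\}.
#' @return List with `X` (numeric matrix, 26 columns), `y` (integer 0/1),
#'   `n_dropped`, and `proportions` (fraction good / bad).
#' @export
prepare_training_data <- function(labeled_tables) {
  if (is.data.frame(labeled_tables)) labeled_tables <- list(labeled_tables)
  fnames <- feature_names()
  for (tb in labeled_tables) {
    missing_cols <- setdiff(c(fnames, "label"), names(tb))
    if (length(missing_cols)) {
      stop_validation(sprintf("labeled table lacks column(s): %s",
                              paste(missing_cols, collapse = ", ")))
    }
  }
  df <- do.call(rbind, lapply(labeled_tables, function(tb) {
    as.data.frame(tb)[, c(fnames, "label"), drop = FALSE]
  }))
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop_validation("no complete labeled rows remain after NaN removal")
  y <- as.integer(df$label)
  if (!all(y %in% c(0L, 1L))) stop_validation("labels must be 0 or 1 after filtering")
  for (cls in c(0L, 1L)) {
    if (!any(y == cls)) {
      stop_validation(sprintf("class %d absent from the labeled data", cls))
    }
  }
  X <- as.matrix(df[, fnames, drop = FALSE])
  list(X = X, y = y, n_dropped = n_dropped,
       proportions = c(good = mean(y == 1L), bad = mean(y == 0L)))
}

#' Stratified train/test split
#'
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param config A [train_config()]; `test_fraction` and `seed` are used.
#' @return List with `train` and `test` (each `list(X, y)`) and
#'   `proportions` (class fractions per partition).
#' @export
split_data <- function(X, y, config = train_config()) {
  if (length(unique(y)) < 2L) stop_validation("both classes must be present before splitting")
  set.seed(config$seed)
  test_idx <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    n_test <- round(length(idx) * config$test_fraction)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  parts <- list(train = list(X = X[train_idx, , drop = FALSE], y = y[train_idx]),
                test = list(X = X[test_idx, , drop = FALSE], y = y[test_idx]))
  for (p in names(parts)) {
    if (length(unique(parts[[p]]$y)) < 2L) {
      stop_validation(sprintf("the %s partition lost a class; adjust test_fraction", p))
    }
  }
  parts$proportions <- rbind(
    train = c(good = mean(parts$train$y == 1L), bad = mean(parts$train$y == 0L)),
    test = c(good = mean(parts$test$y == 1L), bad = mean(parts$test$y == 0L)))
  parts
}

#' Pearson correlation matrix of the feature columns
#'
#' @param X Feature matrix (>= 3 rows). Constant columns yield missing
#'   correlations with a warning.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(X) {
  if (nrow(X) < 3L) stop_validation("need at least 3 rows for correlations")
  const <- apply(X, 2L, function(v) var(v) < 1e-24)
  if (any(const)) {
    warn(sprintf("constant feature(s) yield undefined correlations: %s",
                 paste(colnames(X)[const], collapse = ", ")))
  }
  cc <- suppressWarnings(cor(X))
  diag(cc) <- 1
  cc
}

# -- kernel machinery -------------------------------------------------------

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}
apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$mean), 2L, scaler$sd, "/")
}

# Nystroem feature map: landmarks L, K_mm = U D U', map = U_k D_k^{-1/2};
# transform(X) = rbf(X, L) %*% map, so transform(X) transform(X)' approximates
# (at full rank: equals) the RBF kernel matrix.
nystrom_fit <- function(Xs, components, gamma) {
  m <- min(components, nrow(Xs))
  idx <- sample(nrow(Xs), m)
  landmarks <- Xs[idx, , drop = FALSE]
  Kmm <- rbf_kernel(landmarks, landmarks, gamma)
  eig <- eigen(Kmm, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-12
  map <- eig$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eig$values[keep]), sum(keep))
  list(landmarks = landmarks, map = map, gamma = gamma)
}
nystrom_transform <- function(ny, Xs) {
  rbf_kernel(Xs, ny$landmarks, ny$gamma) %*% ny$map
}

class_weights_arg <- function(config, y) {
  cw <- config$class_weight
  if (is.null(cw)) return(NULL)
  if (identical(cw, "balanced")) {
    tab <- table(factor(y, levels = c(0L, 1L)))
    w <- length(y) / (2 * as.numeric(tab))
    names(w) <- names(tab)
    return(w)
  }
  cw
}

# fit an svm in the (already standardized / mapped) model input space and
# extract a self-contained decision rule with positive score == good (1)
fit_svm_raw <- function(Z, y, kernel, C, gamma = NULL, weights = NULL) {
  yf <- factor(y, levels = c(1L, 0L))
  args <- list(x = Z, y = yf, scale = FALSE, cost = C,
               kernel = if (kernel == "rbf") "radial" else "linear")
  if (kernel == "rbf") args$gamma <- gamma
  if (!is.null(weights)) {
    w <- weights
    names(w) <- as.character(names(w))
    args$class.weights <- w[levels(yf)[levels(yf) %in% names(w)]]
  }
  m <- do.call(e1071::svm, args)
  sv <- as.matrix(m$SV)
  coefs <- as.numeric(m$coefs)
  rho <- as.numeric(m$rho)
  # libsvm orients decision values toward its first internal label
  positive_class <- m$levels[m$labels[1L]]
  if (!identical(positive_class, "1")) {
    coefs <- -coefs
    rho <- -rho
  }
  list(sv = sv, coefs = coefs, rho = rho, kernel = kernel, C = C, gamma = gamma)
}

decision_values <- function(rule, Z) {
  K <- if (rule$kernel == "rbf") {
    rbf_kernel(Z, rule$sv, rule$gamma)
  } else {
    tcrossprod(Z, rule$sv)
  }
  as.numeric(K %*% rule$coefs - rule$rho)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

nystrom_active <- function(config, n_train) {
  if (is.na(config$use_nystrom)) n_train > config$nystrom_threshold
  else isTRUE(config$use_nystrom)
}

#' Grid-search cross-validation over the hyperparameter grids
#'
#' Evaluates the linear kernel over the C grid and the RBF kernel over the
#' C x gamma grid by stratified k-fold CV accuracy on features
#' standardized within each fold. When the Nystroem path is active (forced
#' or `n_train > nystrom_threshold`), the RBF kernel is replaced by a
#' Nystroem feature map followed by a linear SVM. The winning setting is
#' the accuracy argmax with deterministic tie-breaking (smaller C, then
#' smaller gamma, linear before RBF).
#'
#' @param train List `(X, y)` as produced by [split_data()].
#' @param config A [train_config()].
#' @return List with `best` (kernel, C, gamma, accuracy) and `cv_table`
#'   (one row per grid setting).
#' @export
grid_search <- function(train, config = train_config()) {
  X <- train$X; y <- train$y
  set.seed(config$seed)
  fold <- stratified_folds(y, config$folds)
  for (f in seq_len(config$folds)) {
    if (length(unique(y[fold != f])) < 2L || !any(fold == f)) {
      stop_validation("a CV fold lacks both classes; use fewer folds or more data")
    }
  }
  use_ny <- nystrom_active(config, nrow(X))
  grid <- expand_grid_settings(config)
  weights <- class_weights_arg(config, y)

  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(config$folds)) {
      tr <- fold != f; te <- fold == f
      scaler <- fit_scaler(X[tr, , drop = FALSE])
      Ztr <- apply_scaler(scaler, X[tr, , drop = FALSE])
      Zte <- apply_scaler(scaler, X[te, , drop = FALSE])
      if (grid$kernel[g] == "rbf" && use_ny) {
        ny <- nystrom_fit(Ztr, config$nystrom_components, grid$gamma[g])
        rule <- fit_svm_raw(nystrom_transform(ny, Ztr), y[tr], "linear",
                            grid$C[g], weights = weights)
        pred <- as.integer(decision_values(rule, nystrom_transform(ny, Zte)) > 0)
      } else {
        rule <- fit_svm_raw(Ztr, y[tr], grid$kernel[g], grid$C[g],
                            gamma = grid$gamma[g], weights = weights)
        pred <- as.integer(decision_values(rule, Zte) > 0)
      }
      correct <- correct + sum(pred == y[te])
    }
    acc[g] <- correct / length(y)
  }
  cv_table <- tibble::tibble(kernel = grid$kernel, C = grid$C,
                             gamma = grid$gamma, accuracy = acc)
  ord <- order(-acc, grid$C, ifelse(is.na(grid$gamma), -Inf, grid$gamma),
               match(grid$kernel, c("linear", "rbf")))
  best <- cv_table[ord[1L], ]
  list(best = as.list(best), cv_table = cv_table)
}

expand_grid_settings <- function(config) {
  rows <- list()
  if ("linear" %in% config$kernels) {
    rows[[length(rows) + 1L]] <- data.frame(kernel = "linear", C = config$C_grid,
                                            gamma = NA_real_)
  }
  if ("rbf" %in% config$kernels) {
    gg <- expand.grid(C = config$C_grid, gamma = config$gamma_grid)
    rows[[length(rows) + 1L]] <- data.frame(kernel = "rbf", C = gg$C, gamma = gg$gamma)
  }
  do.call(rbind, rows)
}

#' Fit the final curation model
#'
#' Standardizer and (if applicable) Nystroem map are fit on the full
#' training set, then the SVM is refit at the selected hyperparameters.
#'
#' @param train List `(X, y)`.
#' @param best Winning setting from [grid_search()] (`kernel`, `C`,
#'   `gamma`, optionally `accuracy`).
#' @param config A [train_config()].
#' @return A `curation_model`: feature manifest, standardizer, optional
#'   Nystroem map, decision rule, and training metadata.
#' @export
fit_final <- function(train, best, config = train_config()) {
  X <- train$X; y <- train$y
  set.seed(config$seed)
  scaler <- fit_scaler(X)
  Z <- apply_scaler(scaler, X)
  use_ny <- nystrom_active(config, nrow(X)) && best$kernel == "rbf"
  ny <- NULL
  if (use_ny) {
    ny <- nystrom_fit(Z, config$nystrom_components, best$gamma)
    rule <- fit_svm_raw(nystrom_transform(ny, Z), y, "linear", best$C,
                        weights = class_weights_arg(config, y))
  } else {
    rule <- fit_svm_raw(Z, y, best$kernel, best$C, gamma = best$gamma,
                        weights = class_weights_arg(config, y))
  }
  structure(list(schema = "cellcurator/model/1",
                 feature_names = feature_names(),
                 scaler = scaler, nystrom = ny, rule = rule,
                 metadata = list(
                   n_train = nrow(X),
                   proportions = c(good = mean(y == 1L), bad = mean(y == 0L)),
                   cv_accuracy = if (!is.null(best$accuracy)) best$accuracy else NA_real_,
                   kernel = best$kernel, C = best$C,
                   gamma = if (is.null(best$gamma)) NA_real_ else best$gamma,
                   nystrom = use_ny, seed = config$seed)),
            class = "curation_model")
}

#' Classify feature rows with a curation model
#'
#' @param model A `curation_model`.
#' @param X Numeric matrix or data frame whose feature columns match the
#'   model's manifest (same names, same order).
#' @return List with `labels` (1 = good detection, 0 = bad) and `scores`
#'   (signed decision values; positive means good).
#' @export
predict_curation <- function(model, X) {
  if (is.data.frame(X)) {
    miss <- setdiff(model$feature_names, names(X))
    if (length(miss)) {
      stop_validation(sprintf("input lacks feature column(s): %s",
                              paste(miss, collapse = ", ")))
    }
    X <- as.matrix(as.data.frame(X)[, model$feature_names, drop = FALSE])
  }
  if (!identical(colnames(X), model$feature_names)) {
    stop_validation("feature names/order differ from the model manifest")
  }
  bad_rows <- which(!stats::complete.cases(X))
  if (length(bad_rows)) {
    stop_validation(sprintf("missing feature values in row(s): %s",
                            paste(head(bad_rows, 10L), collapse = ", ")))
  }
  Z <- apply_scaler(model$scaler, X)
  if (!is.null(model$nystrom)) Z <- nystrom_transform(model$nystrom, Z)
  scores <- decision_values(model$rule, Z)
  list(labels = as.integer(scores > 0), scores = scores)
}

#' @export
print.curation_model <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<curation_model> %s kernel, C = %g%s, trained on %d cells (CV accuracy %.3f)%s\n",
              md$kernel, md$C,
              if (!is.na(md$gamma)) sprintf(", gamma = %g", md$gamma) else "",
              md$n_train, md$cv_accuracy,
              if (isTRUE(md$nystrom)) " [Nystroem]" else ""))
  invisible(x)
}
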