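#' Min-max feature scaling
#'
#' Fits the affine map sending each training column's minimum to 0 and
#' maximum to 1, and applies it to the training rows and (optionally)
#' held-out rows, which may land outside [0, 1].  Constant training columns
#' map to 0 with a warning.  Scaling is always fitted on the training split
#' only, so no information leaks from held-out rows.
#'
#' @param train_features numeric matrix/data frame of training rows.
#' @param apply_features optional rows to transform with the fitted ranges.
#' @return list with `train`, `applied` (or NULL), and `ranges` (2 x p:
#'   min/max per column).
#' @export
minmax_rescale <- function(train_features, apply_features = NULL) {
  X <- as.matrix(train_features)
  if (!nrow(X)) stop("empty training set")
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    warning("constant training column(s) mapped to 0: ",
            paste(colnames(X)[span == 0], collapse = ", "))
    span[span == 0] <- 1
  }
  scl <- function(M) sweep(sweep(as.matrix(M), 2, rng[1, ]), 2, span, `/`)
  list(train = scl(X),
       applied = if (is.null(apply_features)) NULL else scl(apply_features),
       ranges = rng)
}

#' Invert a min-max scaling
#' @param scaled scaled matrix; @param ranges the `ranges` element from
#'   [minmax_rescale()].
#' @return matrix on the original scale.
#' @export
minmax_invert <- function(scaled, ranges) {
  span <- ranges[2, ] - ranges[1, ]
  span[span == 0] <- 1
  sweep(sweep(as.matrix(scaled), 2, span, `*`), 2, ranges[1, ], `+`)
}

#' Train/test split and cross-validation folds
#'
#' Uniform random split without replacement with `n_train =
#' floor(train_frac * n)` (116 rows give 81 train / 35 test), and a k-fold
#' partition of the training set with fold sizes differing by at most one.
#'
#' @param n number of rows (or a data frame, whose rows are counted).
#' @param train_frac training fraction; default 0.7.
#' @param k number of folds; default 10.
#' @param seed RNG seed; the split is a deterministic function of it.
#' @return list with `train`, `test` (row indices) and `folds` (list of k
#'   index vectors partitioning `train`).
#' @export
split_and_folds <- function(n, train_frac = 0.7, k = 10, seed = 1) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  stopifnot(n >= 2, train_frac > 0, train_frac < 1)
  n_train <- floor(train_frac * n)
  if (k > n_train) stop("k = ", k, " folds exceed the ", n_train,
                        " training rows")
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  test <- setdiff(seq_len(n), train)
  fold_id <- sample(rep(seq_len(k), length.out = n_train))
  folds <- lapply(seq_len(k), function(j) train[fold_id == j])
  list(train = train, test = test, folds = folds)
}

#' Pearson correlation feature filter
#'
#' Retains features whose absolute sample Pearson correlation with the
#' target exceeds the threshold.  Zero-variance features have r defined as
#' 0 (and are never retained).
#'
#' @param dataset `vt_dataset` (or data frame with the feature columns).
#' @param target `"SV"` or `"ampTens"` (any numeric column).
#' @param threshold default 0.5.
#' @param features candidate feature names; default the 12 electrical
#'   features.
#' @return character vector of retained names, attribute `r` holding all
#'   correlations.
#' @export
pearson_filter <- function(dataset, target, threshold = 0.5,
                           features = feature_names()) {
  stopifnot(nrow(dataset) >= 3)
  y <- dataset[[target]]
  r <- vapply(features, function(f) {
    x <- dataset[[f]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }, numeric(1))
  out <- features[abs(r) > threshold]
  attr(out, "r") <- r
  out
}

#' Regression model specification
#'
#' @param family `"SVR"` or `"ANN"`.
#' @param kernel SVR kernel: `"linear"`, `"polynomial"` or `"rbf"`.
#' @param C SVR regularization parameter (default 100).
#' @param gamma SVR kernel coefficient; default `1/n_features` at fit time.
#' @param degree polynomial kernel degree (default 3).
#' @param n_hidden_layers ANN depth (1-4), 6 neurons per layer.
#' @param n_neurons neurons per hidden layer.
#' @param epochs,lr,patience,init_range ANN training controls (full-batch
#'   Adam on MSE, ReLU hidden / linear output, uniform init).
#' @param target `"SV"` or `"ampTens"`.
#' @return `regression_spec` object.
#' @export
regression_spec <- function(family = c("SVR", "ANN"),
                            kernel = c("linear", "polynomial", "rbf"),
                            C = 100, gamma = NULL, degree = 3,
                            n_hidden_layers = 3, n_neurons = 6,
                            epochs = 2000, lr = 1e-3, patience = 200,
                            init_range = 0.05, target = "SV") {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  stopifnot(C > 0, n_hidden_layers >= 1, n_hidden_layers <= 4)
  structure(list(family = family, kernel = kernel, C = C, gamma = gamma,
                 degree = degree, n_hidden_layers = n_hidden_layers,
                 n_neurons = n_neurons, epochs = epochs, lr = lr,
                 patience = patience, init_range = init_range,
                 target = target),
            class = "regression_spec")
}

#' Fit a regression model
#'
#' @param spec `regression_spec`.
#' @param X scaled feature matrix (training rows).
#' @param y response vector (scaled target).
#' @param seed seed for the ANN initialization (ignored for SVR).
#' @return `vt_model`: list with `spec`, the fitted object, and for ANN the
#'   recorded final training MSE and convergence flag.
#' @export
fit_model <- function(spec, X, y, seed = NULL) {
  X <- as.matrix(X)
  if (spec$family == "SVR") {
    gamma <- if (is.null(spec$gamma)) 1 / ncol(X) else spec$gamma
    kern <- switch(spec$kernel, linear = "linear",
                   polynomial = "polynomial", rbf = "radial")
    fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = kern,
                      cost = spec$C, gamma = gamma, degree = spec$degree,
                      scale = FALSE)
    out <- list(spec = spec, fit = fit)
  } else {
    fit <- mlp_fit(X, y, hidden = rep(spec$n_neurons, spec$n_hidden_layers),
                   epochs = spec$epochs, lr = spec$lr,
                   init_range = spec$init_range, patience = spec$patience,
                   seed = seed)
    out <- list(spec = spec, fit = fit, final_mse = fit$final_mse,
                converged = fit$converged)
  }
  class(out) <- "vt_model"
  out
}

#' @export
predict.vt_model <- function(object, newdata, ...) {
  as.numeric(predict(object$fit, as.matrix(newdata)))
}

#' Coefficient of determination and mean squared error
#'
#' `R^2 = 1 - SS_res/SS_tot` with `SS_tot` about the evaluation-set mean;
#' MSE is the mean squared residual.  With zero target variance R^2 is
#' undefined and returned as `NA`.
#'
#' @param predictor `vt_model` (or anything with a `predict` method), or a
#'   numeric vector of predictions.
#' @param X evaluation features (ignored when predictions are supplied).
#' @param y observed target.
#' @return named vector `c(R2, MSE)`.
#' @export
evaluate_model <- function(predictor, X = NULL, y) {
  pred <- if (is.numeric(predictor)) predictor else predict(predictor, X)
  stopifnot(length(pred) == length(y), length(y) >= 2)
  resid <- y - pred
  mse <- mean(resid^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(resid^2) / sstot
  c(R2 = r2, MSE = mse)
}

.default_model_specs <- function(include_ann4 = FALSE, epochs = 2000) {
  specs <- list(
    `SVR-linear` = regression_spec("SVR", kernel = "linear"),
    `SVR-poly` = regression_spec("SVR", kernel = "polynomial"),
    `SVR-rbf` = regression_spec("SVR", kernel = "rbf"),
    `ANN-1` = regression_spec("ANN", n_hidden_layers = 1, epochs = epochs),
    `ANN-2` = regression_spec("ANN", n_hidden_layers = 2, epochs = epochs),
    `ANN-3` = regression_spec("ANN", n_hidden_layers = 3, epochs = epochs))
  if (include_ann4)
    specs$`ANN-4` <- regression_spec("ANN", n_hidden_layers = 4,
                                     epochs = epochs)
  specs
}

#' Benchmark all regression models on a dataset
#'
#' Reproduces the full model comparison: min-max scaling fitted on the
#' training split (features and targets), SVR with linear/polynomial/RBF
#' kernels (C = 100, gamma = 1/n_features), ANN with 1-3 (optionally 4)
#' hidden layers of 6 ReLU neurons, a shared 70/30 split, optional 10-fold
#' cross-validation on the training split, and train/test R^2 and MSE per
#' model and target.  MSE is reported on the scaled target (comparable
#' across targets) and on the raw scale (`MSE_raw`).
#'
#' @param dataset `vt_dataset`.
#' @param seed split/initialization seed.
#' @param targets default `c("SV", "ampTens")`.
#' @param features feature subset; default all 12.
#' @param include_ann4 add the 4-hidden-layer ANN.
#' @param cv run 10-fold CV on the training split (columns `cv_R2`,
#'   `cv_MSE`).
#' @param epochs ANN epoch budget.
#' @return `bench_report` data frame: model, target, train/test R^2 and
#'   MSE, raw-scale test MSE, and CV metrics when requested.
#' @export
benchmark_all <- function(dataset, seed = 1, targets = c("SV", "ampTens"),
                          features = feature_names(), include_ann4 = FALSE,
                          cv = TRUE, epochs = 2000) {
  sp <- split_and_folds(nrow(dataset), 0.7, 10, seed = seed)
  specs <- .default_model_specs(include_ann4, epochs)
  rows <- list()
  for (tg in targets) {
    Xall <- as.matrix(dataset[, features])
    yall <- dataset[[tg]]
    sc <- minmax_rescale(Xall[sp$train, , drop = FALSE],
                         Xall[sp$test, , drop = FALSE])
    ysc <- minmax_rescale(matrix(yall[sp$train]), matrix(yall[sp$test]))
    ytr <- ysc$train[, 1]; yte <- ysc$applied[, 1]
    yspan <- ysc$ranges[2, 1] - ysc$ranges[1, 1]
    for (mn in names(specs)) {
      spec <- specs[[mn]]; spec$target <- tg
      mseed <- seed + 1000 * match(mn, names(specs))
      cvm <- c(R2 = NA_real_, MSE = NA_real_)
      if (cv) {
        cvs <- sapply(seq_along(sp$folds), function(j) {
          hold <- match(sp$folds[[j]], sp$train)
          m <- fit_model(spec, sc$train[-hold, , drop = FALSE], ytr[-hold],
                         seed = mseed + j)
          evaluate_model(m, sc$train[hold, , drop = FALSE], ytr[hold])
        })
        cvm <- rowMeans(cvs)
      }
      m <- fit_model(spec, sc$train, ytr, seed = mseed)
      tr <- evaluate_model(m, sc$train, ytr)
      te <- evaluate_model(m, sc$applied, yte)
      rows[[length(rows) + 1]] <- data.frame(
        model = mn, target = tg,
        train_R2 = tr[["R2"]], train_MSE = tr[["MSE"]],
        test_R2 = te[["R2"]], test_MSE = te[["MSE"]],
        test_MSE_raw = te[["MSE"]] * yspan^2,
        cv_R2 = cvm[["R2"]], cv_MSE = cvm[["MSE"]])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "n") <- nrow(dataset)
  class(out) <- c("bench_report", class(out))
  out
}

#' Bar chart of test MSE per model and target
#'
#' @param report `bench_report`.
#' @param metric column to plot; default `"test_MSE"`.
#' @return invisibly, the plotted matrix.
#' @export
plot_bench <- function(report, metric = "test_MSE") {
  tg <- unique(report$target)
  mods <- unique(report$model)
  m <- sapply(tg, function(t) report[report$target == t, metric])
  rownames(m) <- mods
  graphics::barplot(t(m), beside = TRUE, legend.text = tg,
                    ylab = metric, las = 2,
                    main = "Prediction error by regression model")
  invisible(m)
}
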