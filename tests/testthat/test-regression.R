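test_that("min-max scaling maps train extremes to [0,1] and inverts exactly", {
  sc <- minmax_rescale(matrix(c(2, 4, 6)), matrix(8))
  expect_equal(as.numeric(sc$train), c(0, 0.5, 1))
  expect_equal(as.numeric(sc$applied), 1.5)  # held-out rows may exceed 1
  X <- matrix(rnorm(60), 20, 3)
  sc2 <- minmax_rescale(X)
  expect_equal(minmax_invert(sc2$train, sc2$ranges), X, tolerance = 1e-12)
  expect_warning(minmax_rescale(cbind(1:5, rep(2, 5))), "constant")
  expect_error(minmax_rescale(matrix(numeric(0), 0, 2)), "empty")
})

test_that("the 70/30 split and 10 folds partition the data reproducibly", {
  sp <- split_and_folds(116, seed = 4)
  expect_length(sp$train, 81)
  expect_length(sp$test, 35)
  expect_setequal(c(sp$train, sp$test), 1:116)
  all_folds <- unlist(sp$folds)
  expect_setequal(all_folds, sp$train)
  expect_equal(anyDuplicated(all_folds), 0)
  sizes <- lengths(sp$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(sp, split_and_folds(116, seed = 4))
  expect_false(identical(sp$train, split_and_folds(116, seed = 5)$train))
  expect_error(split_and_folds(12, k = 10), "folds exceed")
})

test_that("the Pearson filter retains exactly the linearly related features", {
  set.seed(2)
  n <- 10000
  d <- data.frame(matrix(rnorm(n * 12), n))
  names(d) <- feature_names()
  d$SV <- 2 * d$APD                   # exact linear relation
  d$DF_mean <- rep(1, n)              # zero variance
  ret <- pearson_filter(d, "SV")
  expect_true("APD" %in% ret)
  r <- attr(ret, "r")
  expect_equal(unname(r["APD"]), 1)
  expect_equal(unname(r["DF_mean"]), 0)
  # independent noise features are dropped (|r| < 0.05 at n = 10000)
  expect_true(all(abs(r[setdiff(names(r), "APD")]) < 0.05))
  expect_length(pearson_filter(d, "SV", threshold = 1.0), 0)
})

test_that("R^2 and MSE agree with hand arithmetic", {
  m <- evaluate_model(c(1, 2, 3, 5), y = c(1, 2, 3, 4))
  expect_equal(m[["MSE"]], 0.25)
  expect_equal(m[["R2"]], 0.8)
  expect_equal(evaluate_model(c(1, 2, 3), y = c(1, 2, 3)),
               c(R2 = 1, MSE = 0))
  # constant mean predictor scores R^2 = 0
  expect_equal(evaluate_model(rep(2, 4), y = c(1, 2, 2, 3))[["R2"]], 0)
  # zero target variance: undefined
  expect_true(is.na(evaluate_model(c(1, 1), y = c(1, 1))[["R2"]]))
})

test_that("linear SVR recovers a noiseless linear map", {
  set.seed(1)
  X <- matrix(runif(400), 200, 2)
  y <- 3 * X[, 1] - 2 * X[, 2]
  sp <- split_and_folds(200, seed = 1)
  m <- fit_model(regression_spec("SVR", kernel = "linear"),
                 X[sp$train, ], y[sp$train])
  expect_gte(evaluate_model(m, X[sp$test, ], y[sp$test])[["R2"]], 0.99)
  expect_true(is.finite(predict(m, X[1, , drop = FALSE])))
})

test_that("a 3-layer network beats linear SVR on a nonlinear response", {
  set.seed(3)
  n <- 1000
  X <- matrix(runif(n * 3), n, 3)
  y <- sin(2 * pi * X[, 1]) * sin(2 * pi * X[, 2]) + 0.5 * X[, 3]
  sp <- split_and_folds(n, seed = 3)
  lin <- fit_model(regression_spec("SVR", kernel = "linear"),
                   X[sp$train, ], y[sp$train])
  ann <- fit_model(regression_spec("ANN", n_hidden_layers = 3, epochs = 4000),
                   X[sp$train, ], y[sp$train], seed = 3)
  mse_lin <- evaluate_model(lin, X[sp$test, ], y[sp$test])[["MSE"]]
  mse_ann <- evaluate_model(ann, X[sp$test, ], y[sp$test])[["MSE"]]
  expect_lt(mse_ann, mse_lin)
  expect_true(is.finite(ann$final_mse))
})

test_that("the benchmark report has the full model x target x metric grid", {
  d <- emulate_feature_table(200, seed = 21)
  r <- benchmark_all(d, seed = 21, cv = FALSE, epochs = 500)
  expect_equal(nrow(r), 12)  # 6 models x 2 targets
  expect_true(all(c("train_R2", "train_MSE", "test_R2", "test_MSE") %in%
                    names(r)))
  expect_true(all(is.finite(r$test_MSE)))
  expect_true(all(r$train_MSE >= 0))
  expect_true(all(r$train_R2 <= 1))
  # deterministic given the seed
  r2 <- benchmark_all(d, seed = 21, cv = FALSE, epochs = 500)
  expect_equal(r$test_MSE, r2$test_MSE)
  # ANN-4 is optional
  r3 <- benchmark_all(d, seed = 21, targets = "SV", cv = FALSE, epochs = 200,
                      include_ann4 = TRUE)
  expect_true("ANN-4" %in% r3$model)
})

test_that("cross-validation folds feed model selection metrics", {
  d <- emulate_feature_table(150, seed = 31)
  r <- benchmark_all(d, seed = 31, targets = "SV", cv = TRUE, epochs = 200)
  expect_true(all(is.finite(r$cv_MSE)))
  expect_true(all(r$cv_MSE >= 0))
})
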