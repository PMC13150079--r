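test_that("feature matrix keeps one row per unique formula", {
  fx <- noiseless_pair(n = 400, seed = 0)
  db <- compute_descriptors(fx$before$assignments)
  da <- compute_descriptors(fx$after$assignments)
  fm <- build_feature_matrix(db, da, fx$partition)
  expect_identical(nrow(fm), nrow(fx$partition$fates))
  expect_false(anyDuplicated(fm$formula) > 0)
  expect_identical(as.vector(table(fm$fate)[c("Disappeared", "Resistant",
                                              "Product")]),
                   unname(fx$partition$counts[c("n_disappeared",
                                                "n_resistant",
                                                "n_product")]))
  expect_false(anyNA(fm[attr(fm, "feature_cols")]))
  # feature columns are on descriptor scale
  glucose_like <- fm[fm$formula == fm$formula[which.max(fm$o_c)][1], ]
  expect_true(glucose_like$o_c <= 1.2)
  # descriptors must be computed upstream
  expect_error(
    build_feature_matrix(fx$before$assignments, fx$after$assignments,
                         fx$partition),
    "compute_descriptors"
  )
})

test_that("a single separating feature yields near-perfect CV accuracy", {
  fm <- separable_features(n_per_class = 100, seed = 1)
  fit <- train_and_evaluate(fm, folds = 5, seed = 0)
  expect_gte(fit$accuracy, 0.99)
  # refitting with the same seed reproduces the accuracy exactly
  fit2 <- train_and_evaluate(fm, folds = 5, seed = 0)
  expect_identical(fit$accuracy, fit2$accuracy)
})

test_that("permuted labels drop accuracy to the multinomial chance level", {
  set.seed(3)
  n_per <- 400
  fm <- data.frame(
    formula = paste0("F", 1:(3 * n_per)),
    fate = factor(rep(c("Disappeared", "Resistant", "Product"),
                      each = n_per)),
    f1 = rnorm(3 * n_per), f2 = rnorm(3 * n_per), f3 = rnorm(3 * n_per)
  )
  attr(fm, "feature_cols") <- c("f1", "f2", "f3")
  fm$fate <- sample(fm$fate)
  fit <- train_and_evaluate(fm, folds = 5, seed = 0, nrounds = 100)
  band <- 3 * sqrt((1 / 3) * (2 / 3) / nrow(fm))
  expect_lt(abs(fit$accuracy - 1 / 3), band)
  expect_lt(abs(fit$balanced_accuracy - 1 / 3), band + 0.01)
})

test_that("degenerate label structures raise explicit errors", {
  fm <- separable_features(30, seed = 2)
  one <- fm[fm$fate == "Resistant", ]
  attr(one, "feature_cols") <- c("sep", "noise")
  expect_error(train_and_evaluate(one), "two fate classes")
  few <- fm[c(1:30, 31:34, 61:90), ]  # 4 Resistant rows < 5 folds
  attr(few, "feature_cols") <- c("sep", "noise")
  expect_error(train_and_evaluate(few, folds = 5), "at least")
})

test_that("attribution recovers a planted single-predictor model", {
  cfg <- generator_config(
    n_formulas = 800, seed = 0,
    fate_coefficients = c(intercept = 0, n_c = 8, mz = 0, s_c = 0, o_c = 0)
  )
  pair <- generate_sample_pair(config = cfg)
  fm <- truth_features(pair)
  fit <- train_and_evaluate(fm, folds = 5, seed = 0)
  att <- feature_attribution(fit)
  expect_identical(att$method, "shap")
  expect_identical(att$ranking[1], "n_c")
  # additive contributions are reported per class for every feature
  expect_identical(rownames(att$per_class), att$ranking)
  expect_identical(ncol(att$per_class), nlevels(fm$fate))

  # the top feature survives a permutation of the feature columns
  fc <- attr(fm, "feature_cols")
  fm2 <- fm[c("formula", "fate", rev(fc))]
  attr(fm2, "feature_cols") <- rev(fc)
  fit2 <- train_and_evaluate(fm2, folds = 5, seed = 0)
  expect_identical(feature_attribution(fit2)$ranking[1], "n_c")
})

test_that("permutation importance is exactly zero for a constant feature", {
  fm <- separable_features(60, seed = 4)
  fm$flat <- 1
  attr(fm, "feature_cols") <- c("sep", "noise", "flat")
  fit <- train_and_evaluate(fm, folds = 5, seed = 0, nrounds = 50)
  imp <- domfate:::permutation_importance(fit, fm, n_perm = 3)
  expect_identical(imp$overall[["flat"]], 0)
  expect_gt(imp$overall[["sep"]], 0.5)
})

test_that("exact SHAP attributions sum to the prediction margins", {
  fm <- separable_features(60, seed = 5)
  fit <- train_and_evaluate(fm, folds = 5, seed = 0, nrounds = 50)
  x <- as.matrix(fm[attr(fm, "feature_cols")])
  contrib <- predict(fit$model, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  margin <- predict(fit$model, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
  expect_equal(apply(contrib, c(1, 2), sum), margin,
               tolerance = 1e-6, ignore_attr = TRUE)
})
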