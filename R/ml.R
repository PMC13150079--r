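#' Build the descriptor feature matrix for fate prediction
#'
#' Collects exactly one row per unique neutral formula in Before union After,
#' with the molecular descriptor features and the fate label from the
#' partition.  Formulas appearing in both samples (Resistant) contribute a
#' single row.
#'
#' @param before,after descriptor tables for the two samples: data frames
#'   containing a `formula` column and the descriptor columns produced by
#'   [compute_descriptors()].
#' @param partition a [classify_fate()] result.
#' @return data frame with `formula`, `fate` (factor) and the feature
#'   columns `mz`, `o_c`, `h_c`, `n_c`, `s_c`, `dbe`, `dbe_o_c`, `nosc`,
#'   `ai_mod` plus one 0/1 indicator per observed heteroatom class; the
#'   feature column names are stored in `attr(x, "feature_cols")`.
#' @export
build_feature_matrix <- function(before, after, partition) {
  stopifnot(inherits(partition, "fate_partition"))
  need <- c("formula", "mz_theor", "o_c", "h_c", "n_c", "s_c", "dbe",
            "dbe_o_c", "nosc", "ai_mod", "heteroatom_class")
  for (nm in c("before", "after")) {
    x <- get(nm)
    if (!all(need %in% names(x))) {
      stop("sample `", nm, "` lacks descriptor columns; run ",
           "compute_descriptors() before build_feature_matrix()")
    }
  }
  lookup <- rbind(before[need], after[need])
  lookup <- lookup[!duplicated(lookup$formula), , drop = FALSE]
  f <- partition$fates
  idx <- match(f$formula, lookup$formula)
  if (anyNA(idx)) {
    stop("formulas in the partition lack descriptors (pipeline ordering bug)")
  }
  d <- lookup[idx, , drop = FALSE]
  out <- data.frame(formula = f$formula,
                    fate = factor(f$fate),
                    mz = d$mz_theor, o_c = d$o_c, h_c = d$h_c, n_c = d$n_c,
                    s_c = d$s_c, dbe = d$dbe, dbe_o_c = d$dbe_o_c,
                    nosc = d$nosc, ai_mod = d$ai_mod)
  classes <- sort(unique(d$heteroatom_class))
  for (cl in classes) {
    out[[paste0("class_", cl)]] <- as.numeric(d$heteroatom_class == cl)
  }
  rownames(out) <- NULL
  attr(out, "feature_cols") <- setdiff(names(out), c("formula", "fate"))
  out
}

feature_cols_of <- function(features) {
  fc <- attr(features, "feature_cols")
  if (is.null(fc)) fc <- setdiff(names(features), c("formula", "fate"))
  fc
}

# Balanced instance weights: each class contributes equal total weight.
balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  as.numeric(w[as.character(y)])
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

xgb_params <- function(n_class) {
  list(objective = "multi:softprob", num_class = n_class, eta = 0.1,
       max_depth = 5, min_child_weight = 1, subsample = 1,
       colsample_bytree = 1, tree_method = "exact", nthread = 1)
}

train_gbt <- function(x, y, w, nrounds) {
  d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, weight = w)
  xgboost::xgb.train(params = xgb_params(nlevels(y)), data = d,
                     nrounds = nrounds, verbose = 0)
}

predict_backend <- function(model, backend, x, levels) {
  if (backend == "gbt") {
    p <- predict(model, xgboost::xgb.DMatrix(x))
    factor(levels[max.col(p)], levels = levels)
  } else {
    predict(model, data = as.data.frame(x))$predictions
  }
}

#' Cross-validated fate classification from molecular descriptors
#'
#' Trains a multi-class classifier (gradient-boosted trees by default, or a
#' random forest) to predict molecular fate from descriptors, with
#' stratified k-fold cross-validation, balanced class weights and a fixed
#' seed.  A final model is refit on all rows for feature attribution.
#'
#' @param features a [build_feature_matrix()] result.
#' @param folds number of CV folds (default 5); every class must have at
#'   least `folds` members.
#' @param seed integer seed controlling fold assignment (tree growth is
#'   deterministic for the default configuration).
#' @param model `"gbt"` (xgboost) or `"rf"` (ranger, if installed).
#' @param nrounds boosting rounds for the gbt backend.
#' @return object of class `"dom_ml"`: `accuracy` (overall CV),
#'   `balanced_accuracy` (mean per-class recall, the natural chance-level
#'   statistic under class-weight balancing: 1/|classes| for a
#'   label-independent classifier whatever the class imbalance),
#'   `per_class_accuracy`, `confusion`, `predictions` (per-row CV
#'   prediction), the refit `model`, `backend`, `feature_cols`, `folds`,
#'   `seed`.
#' @export
train_and_evaluate <- function(features, folds = 5, seed = 0L,
                               model = c("gbt", "rf"), nrounds = 200) {
  backend <- match.arg(model)
  fc <- feature_cols_of(features)
  y <- droplevels(factor(features$fate))
  if (nlevels(y) < 2L) {
    stop("at least two fate classes are required to train a classifier")
  }
  if (any(table(y) < folds)) {
    stop("every class needs at least `folds` members")
  }
  x <- as.matrix(features[fc])
  if (anyNA(x)) stop("feature matrix contains missing values")
  set.seed(as.integer(seed))
  fold <- stratified_folds(y, folds)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    w <- balanced_weights(y[tr])
    fit <- if (backend == "gbt") {
      train_gbt(x[tr, , drop = FALSE], y[tr], w, nrounds)
    } else {
      fit_ranger(x[tr, , drop = FALSE], y[tr], w, seed)
    }
    pred[!tr] <- predict_backend(fit, backend, x[!tr, , drop = FALSE],
                                 levels(y))
  }
  final <- if (backend == "gbt") {
    train_gbt(x, y, balanced_weights(y), nrounds)
  } else {
    fit_ranger(x, y, balanced_weights(y), seed)
  }
  confusion <- table(truth = y, predicted = pred)
  per_class <- diag(confusion) / rowSums(confusion)
  structure(
    list(accuracy = mean(pred == y),
         balanced_accuracy = mean(per_class),
         per_class_accuracy = per_class,
         confusion = confusion,
         predictions = data.frame(formula = features$formula, fate = y,
                                  predicted = pred),
         model = final, backend = backend, feature_cols = fc,
         folds = folds, seed = seed, nrounds = nrounds,
         features = features),
    class = "dom_ml"
  )
}

fit_ranger <- function(x, y, w, seed) {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop("the random-forest backend requires the `ranger` package")
  }
  d <- as.data.frame(x)
  d$.fate <- y
  ranger::ranger(dependent.variable.name = ".fate", data = d,
                 case.weights = w, num.threads = 1, seed = seed)
}

#' @export
print.dom_ml <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy (%s backend): %.3f (balanced %.3f)\n",
              x$folds, x$backend, x$accuracy, x$balanced_accuracy))
  cat("Per-class accuracy:\n")
  print(round(x$per_class_accuracy, 3))
  invisible(x)
}

#' Per-feature attribution of fate predictions
#'
#' For the gradient-boosting backend, computes exact additive tree (SHAP)
#' attributions per prediction and class and summarizes them as the mean
#' absolute attribution per feature (overall and per class); the per-row
#' attributions sum to the margin deviation from the model bias.  For
#' backends without an exact tree-path method, falls back to permutation
#' importance (mean accuracy drop over permutations of one feature column)
#' with a warning; the `method` field records which route was used.
#'
#' @param fit a [train_and_evaluate()] result.
#' @param features feature matrix to attribute (defaults to the training
#'   matrix).
#' @param n_perm permutations per feature for the fallback route.
#' @return object of class `"dom_attribution"`: `method` (`"shap"` or
#'   `"permutation"`), `mean_abs` (named vector over all features, sorted
#'   decreasing), `per_class` (feature-by-class matrix), `ranking`.
#' @export
feature_attribution <- function(fit, features = NULL, n_perm = 5L) {
  stopifnot(inherits(fit, "dom_ml"))
  if (is.null(features)) features <- fit$features
  fc <- fit$feature_cols
  x <- as.matrix(features[fc])
  if (fit$backend == "gbt") {
    contrib <- predict(fit$model, xgboost::xgb.DMatrix(x),
                       predcontrib = TRUE)
    # [n, class, feature+BIAS]
    per_class <- apply(abs(contrib[, , fc, drop = FALSE]), c(3, 2), mean)
    colnames(per_class) <- levels(fit$predictions$fate)
    mean_abs <- rowMeans(per_class)
    method <- "shap"
  } else {
    warning("exact tree attribution unavailable for backend '", fit$backend,
            "'; falling back to permutation importance")
    imp <- permutation_importance(fit, features, n_perm)
    per_class <- imp$per_class
    mean_abs <- imp$overall
    method <- "permutation"
  }
  ord <- order(mean_abs, decreasing = TRUE)
  structure(list(method = method, mean_abs = mean_abs[ord],
                 per_class = per_class[ord, , drop = FALSE],
                 ranking = names(mean_abs)[ord]),
            class = "dom_attribution")
}

permutation_importance <- function(fit, features, n_perm = 5L) {
  fc <- fit$feature_cols
  x <- as.matrix(features[fc])
  y <- factor(features$fate)
  base_pred <- predict_backend(fit$model, fit$backend, x, levels(y))
  base_acc <- mean(base_pred == y)
  classes <- levels(y)
  overall <- stats::setNames(numeric(length(fc)), fc)
  per_class <- matrix(0, length(fc), length(classes),
                      dimnames = list(fc, classes))
  for (j in seq_along(fc)) {
    drops <- numeric(n_perm)
    cls_drops <- matrix(0, n_perm, length(classes))
    for (r in seq_len(n_perm)) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      pred <- predict_backend(fit$model, fit$backend, xp, levels(y))
      drops[r] <- base_acc - mean(pred == y)
      for (ci in seq_along(classes)) {
        sel <- y == classes[ci]
        cls_drops[r, ci] <- mean(base_pred[sel] == y[sel]) -
          mean(pred[sel] == y[sel])
      }
    }
    overall[j] <- mean(drops)
    per_class[j, ] <- colMeans(cls_drops)
  }
  list(overall = overall, per_class = per_class)
}

#' @export
print.dom_attribution <- function(x, ...) {
  cat("Feature attribution (", x$method, "), mean |attribution|:\n",
      sep = "")
  print(round(x$mean_abs, 4))
  invisible(x)
}
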