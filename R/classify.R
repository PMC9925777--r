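#' Feature panels for classification
#'
#' `panel10` uses ten H0-quadrant-2 statistics: number of points, persistent
#' entropy, mean/median/standard deviation of births and deaths, the 25th
#' percentile of births and the 75th percentile of deaths. `panel20` adds
#' the same ten from H1 quadrant 1. Interquartile ranges, the 25th death
#' percentile and the radius-thresholded counts are excluded by construction
#' (each is a function of included features or was dropped for weaker group
#' separation).
#'
#' @param name `"panel10"` or `"panel20"`.
#' @return Character vector of panel column names.
#' @export
feature_panel <- function(name = c("panel10", "panel20")) {
  name <- match.arg(name)
  ten <- function(prefix)
    paste0(prefix, c("n_points", "entropy", "birth_mean", "birth_median",
                     "birth_sd", "death_mean", "death_median", "death_sd",
                     "birth_q25", "death_q75"))
  if (name == "panel10") ten("H0Q2_") else c(ten("H0Q2_"), ten("H1Q1_"))
}

scale_train_test <- function(train, test) {
  mu <- colMeans(train)
  sg <- apply(train, 2, sd)
  sg[sg == 0 | is.na(sg)] <- 1
  list(train = scale(train, center = mu, scale = sg),
       test = scale(test, center = mu, scale = sg))
}

binary_metrics <- function(truth, pred, positive = "KO") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  acc <- mean(pred == truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

stratified_folds <- function(strata, folds) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

#' Repeated stratified cross-validated RBF-SVC evaluation
#'
#' Trains a support vector classifier with a radial basis function kernel
#' (`C = 3` by default) to distinguish test (KO) from control (WT) patches
#' from their persistence-statistic panels, under repeated stratified k-fold
#' cross-validation. Folds are stratified on genotype crossed with sex (when
#' present) so every fold contains patches from each category; features are
#' standardised with training-fold parameters only; metrics take KO as the
#' positive class, are computed on the pooled out-of-fold predictions of
#' each repeat, and are averaged over repeats.
#'
#' @param panels Data frame with a `genotype` column (`"KO"`/`"WT"`),
#'   optionally `sex`, and the feature columns. Rows with missing feature
#'   values are dropped (count reported via message).
#' @param features `"panel10"`, `"panel20"`, or a character vector of
#'   column names.
#' @param C SVC cost parameter (default 3).
#' @param folds Number of CV folds (default 10).
#' @param repeats Number of full CV repetitions (default 100).
#' @param seed Integer seed.
#' @return List of class `classifier_report`: `metrics` (means over
#'   repeats), `per_repeat` (matrix), and the evaluation settings.
#' @export
evaluate_classifier <- function(panels, features = "panel10", C = 3,
                                folds = 10L, repeats = 100L, seed = 1L) {
  if (length(features) == 1L && features %in% c("panel10", "panel20")) {
    feature_set <- features
    features <- feature_panel(features)
  } else feature_set <- "custom"
  missing_cols <- setdiff(features, names(panels))
  if (length(missing_cols))
    stop("unseen feature names: ", paste(missing_cols, collapse = ", "))
  stopifnot("genotype" %in% names(panels))
  X <- as.matrix(panels[, features, drop = FALSE])
  keep <- stats::complete.cases(X)
  if (any(!keep))
    message(sum(!keep), " patch(es) dropped for missing panel values")
  X <- X[keep, , drop = FALSE]
  y <- factor(panels$genotype[keep], levels = c("WT", "KO"))
  strata <- if ("sex" %in% names(panels))
    interaction(y, panels$sex[keep], drop = TRUE) else y
  if (any(table(y) < folds))
    stop("a class has fewer than ", folds,
         " patches; use fewer folds or more data")
  set.seed(seed)
  per_repeat <- matrix(NA_real_, repeats, 4,
                       dimnames = list(NULL, c("accuracy", "precision",
                                               "recall", "f1")))
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(strata, folds)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (k in seq_len(folds)) {
      te <- fold == k
      sc <- scale_train_test(X[!te, , drop = FALSE], X[te, , drop = FALSE])
      fit <- e1071::svm(x = sc$train, y = y[!te], kernel = "radial",
                        cost = C, scale = FALSE)
      pred[te] <- predict(fit, sc$test)
    }
    per_repeat[r, ] <- binary_metrics(y, pred, positive = "KO")
  }
  structure(list(metrics = colMeans(per_repeat), per_repeat = per_repeat,
                 feature_set = feature_set, features = features, C = C,
                 folds = folds, repeats = repeats, seed = seed,
                 n_patches = length(y)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("RBF-SVC (C = ", x$C, ", ", x$folds, "-fold x ", x$repeats,
      " repeats, ", x$feature_set, ", n = ", x$n_patches, "):\n", sep = "")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Fit on one panel table and predict another
#'
#' Single-split entry point: standardises with training parameters, fits the
#' RBF-SVC and returns predicted classes and decision values for the test
#' panels.
#'
#' @param train,test Panel data frames; `train` must have a `genotype`
#'   column covering both classes.
#' @inheritParams evaluate_classifier
#' @return Data frame with `predicted` and `decision_value` per test row.
#' @export
fit_predict <- function(train, test, features = "panel10", C = 3) {
  if (length(features) == 1L && features %in% c("panel10", "panel20"))
    features <- feature_panel(features)
  missing_cols <- setdiff(features, union(names(train), names(test)))
  if (length(missing_cols))
    stop("unseen feature names: ", paste(missing_cols, collapse = ", "))
  y <- factor(train$genotype, levels = c("WT", "KO"))
  if (nlevels(droplevels(y)) < 2L) stop("training data must cover both classes")
  Xtr <- as.matrix(train[, features, drop = FALSE])
  Xte <- as.matrix(test[, features, drop = FALSE])
  sc <- scale_train_test(Xtr, Xte)
  fit <- e1071::svm(x = sc$train, y = y, kernel = "radial", cost = C,
                    scale = FALSE)
  pr <- predict(fit, sc$test, decision.values = TRUE)
  data.frame(predicted = as.character(pr),
             decision_value = as.numeric(attr(pr, "decision.values")))
}
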