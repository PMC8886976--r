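# The pathogenicity classifier: a random forest with out-of-bag (OOB)
# bookkeeping, bundled with its train-fitted imputer and scaler so that
# predict-time preprocessing is identical to training. The pathogenicity
# score of a CNV is the forest's probability for the pathogenic class.

MODEL_VERSION <- 1L

#' @noRd
as_binary_labels <- function(labels, positive = NULL) {
  lv <- unique(as.character(labels))
  if (is.null(positive)) {
    positive <- if ("pathogenic" %in% lv) "pathogenic" else sort(lv, decreasing = TRUE)[1L]
  }
  as.integer(as.character(labels) == positive)
}

#' Train the random-forest pathogenicity classifier
#'
#' Fits the train-mean imputer and the [0, 1] scaler on the supplied training
#' table, then grows a random forest (Gini CART trees, `mtry` features per
#' split, per-class stratified bootstrap) with OOB scoring enabled. Fully
#' reproducible under `seed`. An optional hyperparameter grid is evaluated by
#' stratified cross-validated AUC on the training data only.
#'
#' @param features training feature table (metadata columns id / chrom /
#'   start / end / svtype / label are ignored) or numeric matrix.
#' @param labels class labels; `"pathogenic"` is the positive class when
#'   present, otherwise the lexicographically larger label.
#' @param svtype optional variant type tag (DEL/DUP) stored in the model;
#'   [predict.tadcnv_model()] refuses data of a different type.
#' @param n_trees number of trees (default 500).
#' @param mtry features sampled per split; default `floor(sqrt(p))`.
#' @param min_node minimum samples per leaf (default 1).
#' @param max_depth maximum tree depth; 0 (default) means unlimited.
#' @param seed integer seed.
#' @param positive positive-class label (defaults to `"pathogenic"`).
#' @param tune_grid optional data.frame with columns among `mtry`,
#'   `min_node`, `max_depth`; each row is scored by 5-fold CV AUC on the
#'   training set and the best row's settings are used. Off by default.
#' @return object of class `tadcnv_model`.
#' @export
train_model <- function(features, labels, svtype = NULL, n_trees = 500,
                        mtry = NULL, min_node = 1, max_depth = 0,
                        seed = 1L, positive = NULL, tune_grid = NULL) {
  y <- as_binary_labels(labels, positive)
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  imputer <- fit_imputer(features)
  xi <- apply_imputer(imputer, features)
  scaler <- fit_scaler(xi)
  x <- apply_scaler(scaler, xi)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))

  if (!is.null(tune_grid)) {
    scores <- vapply(seq_len(nrow(tune_grid)), function(i) {
      g <- tune_grid[i, , drop = FALSE]
      cv <- cross_validate(features, labels, k = 5, seed = seed,
                           n_trees = n_trees,
                           mtry = if ("mtry" %in% names(g)) g$mtry else mtry,
                           min_node = if ("min_node" %in% names(g)) g$min_node else min_node,
                           max_depth = if ("max_depth" %in% names(g)) g$max_depth else max_depth,
                           positive = positive)
      mean(cv$auc)
    }, numeric(1))
    best <- which.max(scores)
    g <- tune_grid[best, , drop = FALSE]
    if ("mtry" %in% names(g)) mtry <- g$mtry
    if ("min_node" %in% names(g)) min_node <- g$min_node
    if ("max_depth" %in% names(g)) max_depth <- g$max_depth
  }

  fit <- with_seed(seed, rf_build(x, y, as.integer(n_trees), as.integer(mtry),
                                  as.integer(min_node), as.integer(max_depth),
                                  TRUE))
  oob <- rf_predict_oob_mat(fit$trees, fit$inbag, x)
  model <- structure(list(
    imputer = imputer,
    scaler = scaler,
    forest = fit$trees,
    inbag = fit$inbag,
    feature_names = colnames(x),
    svtype = svtype,
    training_seed = seed,
    params = list(n_trees = n_trees, mtry = mtry, min_node = min_node,
                  max_depth = max_depth),
    positive = if (is.null(positive)) {
      if ("pathogenic" %in% unique(as.character(labels))) "pathogenic"
      else sort(unique(as.character(labels)), decreasing = TRUE)[1L]
    } else positive,
    train_x = x,
    train_y = y,
    oob_scores = oob,
    version = MODEL_VERSION
  ), class = "tadcnv_model")
  model$oob_accuracy <- oob_accuracy(model)
  model
}

#' @export
print.tadcnv_model <- function(x, ...) {
  cat(sprintf("tadcnv_model (%s): %d trees, mtry %d, %d features, OOB accuracy %.3f\n",
              if (is.null(x$svtype)) "untyped" else x$svtype,
              x$params$n_trees, x$params$mtry, length(x$feature_names),
              x$oob_accuracy))
  invisible(x)
}

#' Predict pathogenicity scores
#'
#' Applies the stored imputer and scaler, then the forest. Scores are the
#' fraction-weighted probability of the pathogenic class, in `[0, 1]`.
#' Feature columns are matched by name; a missing column is an error naming
#' it.
#'
#' @param object a `tadcnv_model`.
#' @param newdata feature table or numeric matrix.
#' @param svtype optional variant type of `newdata`; an svtype-mismatched
#'   model is refused.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict.tadcnv_model <- function(object, newdata, svtype = NULL, ...) {
  if (!is.null(svtype) && !is.null(object$svtype) && svtype != object$svtype) {
    stop(sprintf("model was trained on %s but data is %s", object$svtype, svtype))
  }
  x <- apply_scaler(object$scaler, apply_imputer(object$imputer, newdata))
  rf_predict_mat(object$forest, x)
}

#' Out-of-bag accuracy of a trained model
#'
#' Accuracy of OOB predictions (score > 0.5 called pathogenic) against the
#' training labels. When `x` is supplied (a matrix on the model's
#' preprocessed scale, e.g. with permuted columns), OOB predictions are
#' recomputed on it; otherwise the stored training matrix is used.
#'
#' @param model a `tadcnv_model`.
#' @param x optional preprocessed matrix aligned with the training rows.
#' @return OOB accuracy in `[0, 1]`.
#' @export
oob_accuracy <- function(model, x = NULL) {
  stopifnot(inherits(model, "tadcnv_model"))
  oob <- if (is.null(x)) model$oob_scores else {
    rf_predict_oob_mat(model$forest, model$inbag, x)
  }
  ok <- !is.na(oob)
  mean((oob[ok] > 0.5) == (model$train_y[ok] == 1L))
}

#' Stratified k-fold cross-validated ROC-AUC
#'
#' Splits the rows into `k` stratified folds; for each fold the imputer,
#' scaler and forest are fitted on the remaining folds only (no information
#' leakage) and the held-out fold is scored. Each sample is tested exactly
#' once.
#'
#' @param features feature table or matrix.
#' @param labels class labels (each class needs >= k members).
#' @param k number of folds (default 5).
#' @param seed integer seed (fold assignment and tree growing).
#' @param ... hyperparameters passed to [train_model()].
#' @return list with `auc` (per-fold ROC-AUC), `folds` (fold id per row),
#'   `scores` (out-of-fold score per row) and `prep` (per-fold fitted
#'   imputer/scaler parameters, exposed so leakage can be audited).
#' @export
cross_validate <- function(features, labels, k = 5, seed = 1L, ...) {
  stopifnot(k >= 2)
  y <- as.character(labels)
  tab <- table(y)
  if (any(tab < k)) stop(sprintf("every class needs at least k=%d members", k))
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  m <- if (is.matrix(features)) features else feature_matrix(features)
  scores <- numeric(length(y))
  auc <- numeric(k)
  prep <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- train_model(m[tr, , drop = FALSE], y[tr], seed = seed + f, ...)
    scores[!tr] <- predict(fit, m[!tr, , drop = FALSE])
    auc[f] <- roc_auc(scores[!tr], y[!tr], positive = fit$positive)
    prep[[f]] <- list(imputer = fit$imputer, scaler = fit$scaler)
  }
  list(auc = auc, folds = folds, scores = scores, prep = prep)
}

#' ROC-AUC (Mann--Whitney with half credit for ties)
#'
#' Equals the probability that a randomly drawn positive outscores a
#' randomly drawn negative, ties counted 1/2.
#'
#' @param scores numeric scores.
#' @param labels class labels.
#' @param positive positive-class label (defaults to `"pathogenic"` when
#'   present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores) # average ranks implement the tie = 1/2 convention
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged F1 at a hard score threshold
#'
#' Scores strictly greater than `threshold` are called pathogenic (a score of
#' exactly 0.5 is non-pathogenic at the default). The macro F1 is the
#' unweighted mean of the per-class F1 scores; a class with an undefined F1
#' (no predictions and no members) contributes 0 with a warning.
#'
#' @param scores numeric scores.
#' @param labels class labels.
#' @param threshold decision threshold (default 0.5, strict).
#' @param positive positive-class label.
#' @return macro-averaged F1 in `[0, 1]`.
#' @export
macro_f1 <- function(scores, labels, threshold = 0.5, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  pred <- as.integer(scores > threshold)
  f1_for <- function(cls) {
    tp <- sum(pred == cls & y == cls)
    fp <- sum(pred == cls & y != cls)
    fn <- sum(pred != cls & y == cls)
    if (2 * tp + fp + fn == 0) {
      warning(sprintf("class %d has no members and no predictions; F1 set to 0", cls))
      return(0)
    }
    2 * tp / (2 * tp + fp + fn)
  }
  (f1_for(1L) + f1_for(0L)) / 2
}

#' Calibration curve
#'
#' Bins scores into `n_bins` equal-width bins on `[0, 1]` and reports, per
#' non-empty bin, the mean predicted score and the observed fraction of
#' positives.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels class labels.
#' @param n_bins number of bins (default 10).
#' @param positive positive-class label.
#' @return data.table with columns bin, mean_predicted, fraction_positive, n.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10, positive = NULL) {
  stopifnot(n_bins >= 1)
  y <- as_binary_labels(labels, positive)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- findInterval(scores, edges, rightmost.closed = TRUE, all.inside = TRUE)
  dt <- data.table::data.table(bin = bin, score = scores, y = y)
  out <- dt[, .(mean_predicted = mean(score), fraction_positive = mean(y),
                n = .N), by = bin]
  out[order(bin)]
}

#' Serialize a trained model to a single file
#'
#' @param model a `tadcnv_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tadcnv_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a serialized model
#'
#' @param path file written by [save_model()].
#' @return a `tadcnv_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tadcnv_model")) stop("not a tadcnv model file")
  if (is.null(model$version) || model$version > MODEL_VERSION) {
    stop("model was written by a newer package version")
  }
  model
}
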