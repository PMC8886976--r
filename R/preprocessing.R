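# Train/test splitting, imputation and scaling with strict train-only
# fitting. Both the imputer and the scaler are fitted on training rows only
# and then applied unchanged to any other table, so no information can leak
# from held-out data into the preprocessing parameters.

#' @noRd
feature_matrix <- function(x) {
  x <- data.table::as.data.table(x)
  meta <- intersect(c("id", "chrom", "start", "end", "svtype", "label"), names(x))
  cols <- setdiff(names(x), meta)
  as.matrix(x[, cols, with = FALSE])
}

#' Stratified train/test split
#'
#' Splits rows into train and test sets preserving the label distribution:
#' within each class, `round(test_fraction * n_class)` rows are sampled into
#' the test set. Class proportions in each part are therefore within one
#' sample of the global proportion. Reproducible under `seed`.
#'
#' @param labels vector of class labels (two or more classes, each with at
#'   least 2 members).
#' @param test_fraction fraction of rows held out (default 0.3).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.3, seed = 1L) {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  tab <- table(labels)
  if (any(tab < 2L)) stop("every class needs at least 2 members")
  test <- integer(0)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_test <- round(test_fraction * length(idx))
      if (n_test > 0L) test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Fit a train-mean imputer
#'
#' Records the per-feature mean over non-missing training values. A feature
#' with no non-missing training value is an error naming the feature.
#'
#' @param train numeric matrix or feature data.frame (metadata columns id /
#'   chrom / start / end / svtype / label are ignored).
#' @return object of class `mean_imputer`.
#' @export
fit_imputer <- function(train) {
  m <- if (is.matrix(train)) train else feature_matrix(train)
  means <- colMeans(m, na.rm = TRUE)
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na)) {
    stop(sprintf("feature(s) with no non-missing training value: %s",
                 paste(colnames(m)[all_na], collapse = ", ")))
  }
  structure(list(means = means), class = "mean_imputer")
}

#' Apply a fitted imputer
#'
#' Replaces missing values by the stored training means; non-missing values
#' are unchanged.
#'
#' @param imputer a `mean_imputer`.
#' @param x matrix or feature data.frame with the same feature columns.
#' @return numeric matrix without missing values.
#' @export
apply_imputer <- function(imputer, x) {
  stopifnot(inherits(imputer, "mean_imputer"))
  m <- if (is.matrix(x)) x else feature_matrix(x)
  miss <- setdiff(names(imputer$means), colnames(m))
  if (length(miss) > 0L) {
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  }
  m <- m[, names(imputer$means), drop = FALSE]
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- imputer$means[j]
  }
  m
}

#' Fit a [0, 1] min--max scaler
#'
#' Records the per-feature training minimum and maximum. The transform is
#' `x -> (x - min) / (max - min)`; constant training columns map to 0.
#'
#' @param train numeric matrix (imputed) or feature data.frame.
#' @return object of class `minmax_scaler`.
#' @export
fit_scaler <- function(train) {
  m <- if (is.matrix(train)) train else feature_matrix(train)
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max)),
            class = "minmax_scaler")
}

#' Apply a fitted scaler
#'
#' Training columns map onto `[0, 1]`; values from other tables may fall
#' outside `[0, 1]` and are deliberately not clipped, preserving ordering.
#'
#' @param scaler a `minmax_scaler`.
#' @param x matrix or feature data.frame.
#' @return scaled numeric matrix.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  m <- if (is.matrix(x)) x else feature_matrix(x)
  miss <- setdiff(names(scaler$min), colnames(m))
  if (length(miss) > 0L) {
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  }
  m <- m[, names(scaler$min), drop = FALSE]
  rng <- scaler$max - scaler$min
  for (j in seq_len(ncol(m))) {
    m[, j] <- if (rng[j] == 0) 0 else (m[, j] - scaler$min[j]) / rng[j]
  }
  m
}

#' Fit imputer and scaler on a training table and apply to several tables
#'
#' Convenience wrapper enforcing the no-leakage discipline: both transforms
#' are fitted on `train` only and applied to `train` and every table in
#' `...`.
#'
#' @param train training feature table or matrix.
#' @param ... further tables to transform with the train-fitted parameters.
#' @return list with `imputer`, `scaler`, `train` (transformed matrix) and
#'   `others` (list of transformed matrices).
#' @export
fit_preprocessing <- function(train, ...) {
  imputer <- fit_imputer(train)
  tr <- apply_imputer(imputer, train)
  scaler <- fit_scaler(tr)
  others <- lapply(list(...), function(x) apply_scaler(scaler, apply_imputer(imputer, x)))
  list(imputer = imputer, scaler = scaler,
       train = apply_scaler(scaler, tr), others = others)
}
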