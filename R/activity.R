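# Random-forest activity classification and its evaluation harness:
# repeated 7:3 hold-out and the growing-database protocol, with the
# accuracy / precision / recall / F1 metric suite over a 4x4 confusion
# matrix (rows = truth, columns = predicted).

#' Train the random-forest activity classifier
#'
#' Fits a random forest on a labelled `FeatureTable`. Defaults follow
#' standard forest practice: 500 trees, unlimited depth, sqrt(p) candidate
#' features per split. Deterministic given `seed`.
#'
#' @param features a labelled `FeatureTable` (integer `label` column,
#'   codes 1-4).
#' @param seed integer RNG seed.
#' @param n_trees number of trees.
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @return object of class `activity_model`.
#' @export
train_activity_model <- function(features, seed = 1L, n_trees = 500L,
                                 mtry = NULL) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  x <- features[feature_names(features)]
  y <- features$label
  if (anyNA(x) || any(!vapply(x, function(col) all(is.finite(col)), logical(1))))
    stop("features contain non-finite values")
  if (length(unique(y)) < 2L)
    stop("cannot fit a classifier on a single class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = x, y = factor(y, levels = 1:4),
    ntree = n_trees, mtry = mtry
  )
  structure(list(fit = fit, feature_names = names(x), seed = seed,
                 n_trees = n_trees, classes = 1:4),
            class = "activity_model")
}

#' Predict activity codes for new windows
#'
#' Majority vote over the trees; exact vote ties break to the lowest
#' activity code so predictions are reproducible.
#'
#' @param model an `activity_model`.
#' @param features a `FeatureTable` (label column ignored if present).
#' @return integer vector of activity codes (1-4), one per row.
#' @export
predict_activity <- function(model, features) {
  stopifnot(inherits(model, "activity_model"))
  have <- feature_names(features)
  missing_f <- setdiff(model$feature_names, have)
  extra_f <- setdiff(have, model$feature_names)
  if (length(missing_f) || length(extra_f))
    stop("feature schema mismatch; missing: [",
         paste(missing_f, collapse = ", "), "], extra: [",
         paste(extra_f, collapse = ", "), "]")
  if (nrow(features) == 0L) return(integer(0))
  votes <- stats::predict(model$fit, features[model$feature_names],
                          type = "vote", norm.votes = FALSE)
  as.integer(max.col(votes, ties.method = "first"))
}

#' Per-class metrics and accuracy from a confusion matrix
#'
#' Rows are truth, columns predictions. `precision = M[c,c]/colsum`,
#' `recall = M[c,c]/rowsum`, `f1 = 2PR/(P+R)`, `accuracy = trace/total`.
#' Zero denominators yield 0 with a warning.
#'
#' @param confusion 4x4 non-negative count matrix.
#' @return list with `accuracy`, `per_class` data.frame (activity,
#'   precision, recall, f1) and the confusion matrix.
#' @export
summarize_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop("confusion matrix must hold non-negative counts")
  if (sum(confusion) == 0) stop("confusion matrix is all zero")
  safe_div <- function(num, den) {
    if (any(den == 0))
      warning("zero denominator in per-class metrics; reporting 0")
    ifelse(den > 0, num / pmax(den, 1), 0)
  }
  d <- diag(confusion)
  precision <- safe_div(d, colSums(confusion))
  recall <- safe_div(d, rowSums(confusion))
  f1 <- f1_score(precision, recall)
  k <- nrow(confusion)
  list(
    accuracy = sum(d) / sum(confusion),
    per_class = data.frame(
      activity = if (k == 4L) ACTIVITY_NAMES else as.character(seq_len(k)),
      precision = unname(precision), recall = unname(recall),
      f1 = unname(f1)
    ),
    confusion = confusion
  )
}

#' F1 score
#'
#' Harmonic mean of precision and recall, defined as 0 when both are 0.
#'
#' @param precision,recall numeric vectors in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

confusion_counts <- function(truth, pred, k = 4L) {
  tab <- table(factor(truth, levels = seq_len(k)),
               factor(pred, levels = seq_len(k)))
  m <- matrix(as.integer(tab), k, k,
              dimnames = list(truth = seq_len(k), predicted = seq_len(k)))
  m
}

# Stratified train/test split: per class, a random `ratio` share goes to
# training. Resampled (bounded retries) if either side misses a class.
stratified_split <- function(y, ratio, max_retry = 20L) {
  classes <- sort(unique(y))
  for (attempt in seq_len(max_retry)) {
    train_idx <- unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(length(idx) * ratio)))
    }), use.names = FALSE)
    test_idx <- setdiff(seq_along(y), train_idx)
    if (all(classes %in% y[train_idx]) && all(classes %in% y[test_idx]))
      return(list(train = train_idx, test = test_idx))
    message("degenerate split (a class missing); resampling")
  }
  stop("could not produce a split containing every class on both sides")
}

#' Repeated hold-out evaluation
#'
#' Random stratified `ratio` (default 7:3) train/test splits, repeated
#' `repeats` times with re-division each time. Confusion counts are pooled
#' across repeats; per-class metrics come from the pooled confusion, and
#' the per-repeat accuracies are kept alongside their mean.
#'
#' @param features labelled `FeatureTable`.
#' @param ratio training share of rows.
#' @param repeats number of re-splits.
#' @param seed integer RNG seed.
#' @param n_trees forest size per repeat.
#' @return an `EvalReport` list: `protocol`, `accuracy` (pooled),
#'   `mean_repeat_accuracy`, `repeats` (vector), `per_class`, `confusion`.
#' @export
evaluate_holdout <- function(features, ratio = 0.7, repeats = 10L,
                             seed = 1L, n_trees = 500L) {
  stopifnot("label" %in% names(features))
  set.seed(seed)
  pooled <- matrix(0L, 4L, 4L)
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    sp <- stratified_split(features$label, ratio)
    model <- train_activity_model(features[sp$train, , drop = FALSE],
                                  seed = sample.int(2^30, 1L),
                                  n_trees = n_trees)
    pred <- predict_activity(model, features[sp$test, , drop = FALSE])
    cm <- confusion_counts(features$label[sp$test], pred)
    pooled <- pooled + cm
    acc[r] <- sum(diag(cm)) / sum(cm)
  }
  s <- summarize_metrics(pooled)
  structure(list(protocol = "holdout_7_3_x10", accuracy = s$accuracy,
                 mean_repeat_accuracy = mean(acc), repeats = acc,
                 per_class = s$per_class, confusion = s$confusion),
            class = "EvalReport")
}

#' Growing-database evaluation
#'
#' For k = 1..n-1 trains on the pooled feature tables of subjects 1..k and
#' predicts all remaining subjects, reporting pooled metrics per database.
#' Subject order is input order.
#'
#' @param per_subject_features list of labelled `FeatureTable`s (>= 2).
#' @param seed integer RNG seed.
#' @param n_trees forest size per database.
#' @return list of `EvalReport`s of length `n - 1` (protocol
#'   `"growing_db"`, element `k_train` recording the database size).
#' @export
evaluate_growing_db <- function(per_subject_features, seed = 1L,
                                n_trees = 500L) {
  n <- length(per_subject_features)
  stopifnot(n >= 2L)
  schema <- feature_names(per_subject_features[[1]])
  for (ft in per_subject_features[-1])
    if (!identical(feature_names(ft), schema))
      stop("subject feature tables have mismatching schemas")
  lapply(seq_len(n - 1L), function(k) {
    train <- do.call(rbind, lapply(per_subject_features[seq_len(k)],
                                   as.data.frame))
    test <- do.call(rbind, lapply(per_subject_features[(k + 1L):n],
                                  as.data.frame))
    model <- train_activity_model(train, seed = seed + k, n_trees = n_trees)
    pred <- predict_activity(model, test)
    s <- summarize_metrics(confusion_counts(test$label, pred))
    structure(list(protocol = "growing_db", k_train = k,
                   accuracy = s$accuracy,
                   mean_repeat_accuracy = s$accuracy, repeats = s$accuracy,
                   per_class = s$per_class, confusion = s$confusion),
              class = "EvalReport")
  })
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("<EvalReport> protocol %s: accuracy %.4f\n",
              x$protocol, x$accuracy))
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-15s P %.4f  R %.4f  F1 %.4f\n", pc$activity[i],
                pc$precision[i], pc$recall[i], pc$f1[i]))
  invisible(x)
}
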