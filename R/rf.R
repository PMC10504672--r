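#' Train the artifact classifier
#'
#' Trains the main random forest on the 26 features plus two fallback models:
#' one without the allelic-imbalance feature and one without both the
#' allelic-imbalance and replication-timing features, so variants for which
#' those cannot be determined can still be scored. Rows with an undefined
#' allelic-imbalance p-value or replication timing are excluded from training;
#' the majority class is subsampled to a 1:1 balance before fitting. All three
#' models are trained on the identical rows, differing only in the dropped
#' columns.
#'
#' @param features Tibble of feature columns (see [extract_features()]).
#' @param labels Factor or character vector, `"true_somatic"`/`"artifact"`.
#' @param seed Integer seed (subsampling and forest growth).
#' @param ntree Trees per forest.
#' @param mtry Variables considered per split.
#' @return An `rf_bundle`: models `full`, `no_ai`, `no_ai_no_rt`, the training
#'   rows and labels, and metadata.
#' @export
train_rf <- function(features, labels, seed = 1L, ntree = 500, mtry = 4) {
  labels <- factor(as.character(labels),
                   levels = c("true_somatic", "artifact"))
  if (any(is.na(labels))) abort("labels must be true_somatic or artifact")
  keep <- !is.na(features$ai_log_p) & !is.na(features$replication_timing)
  keep_idx <- which(keep)
  n_input <- nrow(features)
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  counts <- table(labels)
  if (any(counts == 0L)) abort("both classes must be present after exclusions")

  set.seed(seed)
  n_min <- min(counts)
  idx <- unlist(lapply(levels(labels), function(cl) {
    i <- which(labels == cl)
    if (length(i) > n_min) sample(i, n_min) else i
  }))
  idx <- sort(idx)
  x <- as.data.frame(features[idx, , drop = FALSE])
  y <- droplevels(labels[idx])

  fit <- function(drop_cols, seed_offset) {
    set.seed(seed + seed_offset)
    randomForest::randomForest(
      x = x[, setdiff(names(x), drop_cols), drop = FALSE], y = y,
      ntree = ntree, mtry = mtry, importance = TRUE)
  }
  bundle <- list(
    full = fit(character(), 0L),
    no_ai = fit("ai_log_p", 1L),
    no_ai_no_rt = fit(c("ai_log_p", "replication_timing"), 2L),
    training = list(x = x, y = y,
                    input_index = keep_idx[idx],
                    n_input = n_input),
    meta = list(seed = seed, ntree = ntree, mtry = mtry,
                class_counts = as.list(table(y)),
                n_excluded_undefined = sum(!keep),
                feature_names = names(x),
                schema_version = 1L)
  )
  class(bundle) <- "rf_bundle"
  bundle
}

#' @export
print.rf_bundle <- function(x, ...) {
  cat("<rf_bundle>", x$meta$ntree, "trees, mtry", x$meta$mtry, "\n")
  cat("training rows:", length(x$training$y), "per class:",
      paste(unlist(x$meta$class_counts), collapse = "/"), "\n")
  cat("OOB balanced accuracy (full model):",
      round(oob_balanced_accuracy(x$full), 3), "\n")
  invisible(x)
}

oob_balanced_accuracy <- function(model) {
  pred <- model$predicted
  y <- model$y
  tpr <- mean(pred[y == "true_somatic"] == "true_somatic")
  tnr <- mean(pred[y == "artifact"] == "artifact")
  (tpr + tnr) / 2
}

#' Balanced accuracy of a 2x2 classification
#'
#' `(TPR + TNR) / 2`, the mean of sensitivity on the positive class and
#' specificity on the negative class.
#'
#' @param truth,predicted Vectors of class labels.
#' @param positive The positive-class label.
#' @return Numeric scalar.
#' @export
balanced_accuracy <- function(truth, predicted, positive = "true_somatic") {
  tpr <- mean(predicted[truth == positive] == positive)
  tnr <- mean(predicted[truth != positive] != positive)
  (tpr + tnr) / 2
}

#' Artifact probability of candidate variants
#'
#' Scores feature rows with the appropriate model of the bundle: the full
#' model when all features are defined, the model without allelic imbalance
#' when only the AI p-value is undefined, and the model without AI and
#' replication timing when both are. The probability is the fraction of trees
#' voting "artifact"; higher means more artifact-like.
#'
#' @param bundle An [train_rf()] bundle.
#' @param features Feature tibble.
#' @return Tibble `p_artifact`, `model_used`.
#' @export
artifact_probability <- function(bundle, features) {
  stopifnot(inherits(bundle, "rf_bundle"))
  missing_cols <- setdiff(bundle$meta$feature_names, names(features))
  if (length(missing_cols)) {
    abort(paste0("feature schema mismatch; missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(features)
  route <- ifelse(!is.na(x$ai_log_p) & !is.na(x$replication_timing), "full",
                  ifelse(!is.na(x$replication_timing), "no_ai", "no_ai_no_rt"))
  p <- rep(NA_real_, nrow(x))
  for (m in unique(route)) {
    i <- which(route == m)
    cols <- setdiff(bundle$meta$feature_names, switch(
      m, full = character(), no_ai = "ai_log_p",
      no_ai_no_rt = c("ai_log_p", "replication_timing")))
    p[i] <- predict(bundle[[m]], newdata = x[i, cols, drop = FALSE],
                    type = "prob")[, "artifact"]
  }
  tibble(p_artifact = p, model_used = route)
}

#' Out-of-bag artifact probability for the rows a bundle was trained from
#'
#' When the cutoff is calibrated on the same sample the forest was trained on
#' (the self-test setting of simulations), plain re-prediction of training
#' rows is biased toward 0/1 because most trees saw each row in-bag.
#' Out-of-bag votes give the unbiased probability for those rows; rows that
#' did not enter training (undefined features or subsampled out) are scored
#' normally, since they are already out of the training set.
#'
#' @param bundle An [train_rf()] bundle.
#' @param features The same feature tibble `train_rf()` was called with.
#' @return Tibble `p_artifact`, `model_used` (`"full_oob"` for OOB rows).
#' @export
oob_probability <- function(bundle, features) {
  stopifnot(inherits(bundle, "rf_bundle"))
  if (nrow(features) != bundle$training$n_input) {
    abort("features do not match the bundle's training input")
  }
  out <- artifact_probability(bundle, features)
  votes <- bundle$full$votes[, "artifact"]
  out$p_artifact[bundle$training$input_index] <- as.numeric(votes)
  out$model_used[bundle$training$input_index] <- "full_oob"
  out
}

#' Feature importance and ablation curve
#'
#' Ranks features by mean decrease in Gini impurity from the full model, then
#' retrains while consecutively removing the least important feature and
#' records the out-of-bag balanced accuracy at each feature count.
#'
#' @param bundle An [train_rf()] bundle (training rows are stored inside).
#' @param min_features Stop after reaching this many features.
#' @return List with `importance` (tibble `feature`, `mean_decrease_gini`,
#'   sorted decreasing) and `ablation` (tibble `n_features`,
#'   `balanced_accuracy`).
#' @export
importance_and_ablation <- function(bundle, min_features = 1L) {
  stopifnot(inherits(bundle, "rf_bundle"))
  imp <- randomForest::importance(bundle$full, type = 2)
  imp_tb <- tibble(feature = rownames(imp),
                   mean_decrease_gini = imp[, 1L]) |>
    arrange(dplyr::desc(.data$mean_decrease_gini))
  order_drop <- rev(imp_tb$feature)   # least important dropped first
  x <- bundle$training$x
  y <- bundle$training$y
  ks <- seq(ncol(x), min_features)
  res <- purrr::map_dbl(ks, function(k) {
    keep_feats <- setdiff(names(x), order_drop[seq_len(ncol(x) - k)])
    set.seed(bundle$meta$seed + k)
    m <- randomForest::randomForest(
      x = x[, keep_feats, drop = FALSE], y = y,
      ntree = bundle$meta$ntree, mtry = min(bundle$meta$mtry, k))
    oob_balanced_accuracy(m)
  })
  list(importance = imp_tb,
       ablation = tibble(n_features = ks, balanced_accuracy = res))
}

#' Save / load a model bundle
#'
#' The bundle is serialized to a single versioned file. [load_rf_bundle()]
#' refuses files whose schema version does not match the current one.
#'
#' @param bundle An `rf_bundle`.
#' @param path File path.
#' @export
save_rf_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "rf_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_rf_bundle
#' @export
load_rf_bundle <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "rf_bundle") || !identical(b$meta$schema_version, 1L)) {
    abort("not a compatible rf_bundle file")
  }
  b
}

#' @export
tidy.rf_bundle <- function(x, ...) {
  imp <- randomForest::importance(x$full, type = 2)
  tibble(term = rownames(imp), mean_decrease_gini = imp[, 1L]) |>
    arrange(dplyr::desc(.data$mean_decrease_gini))
}

#' @export
glance.rf_bundle <- function(x, ...) {
  tibble(
    n_train = length(x$training$y),
    n_true = sum(x$training$y == "true_somatic"),
    n_artifact = sum(x$training$y == "artifact"),
    ntree = x$meta$ntree,
    mtry = x$meta$mtry,
    oob_balanced_accuracy = oob_balanced_accuracy(x$full)
  )
}
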