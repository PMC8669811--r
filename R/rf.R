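#' Random-forest classifier configuration
#'
#' Defaults mirror the classical WEKA RandomForest settings: 100 trees,
#' `floor(log2(d)) + 1` candidate features per split for `d` features, and
#' unlimited tree depth. The number of candidate features per split can
#' alternatively follow the `sqrt` rule or be a fixed integer.
#'
#' @param n_trees Number of trees (>= 1).
#' @param mtry Features tried per split: `"log2"` (default,
#'   `floor(log2(d)) + 1`), `"sqrt"` (`floor(sqrt(d))`), or a positive
#'   integer.
#' @param max_depth Maximum tree depth; `NULL` (default) = unlimited.
#' @param seed Integer seed; recorded in every trained model.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100, mtry = "log2", max_depth = NULL,
                      seed = 1) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1) abort("n_trees must be >= 1")
  if (is.character(mtry)) {
    mtry <- match.arg(mtry, c("log2", "sqrt"))
  } else {
    mtry <- as.integer(mtry)
    if (is.na(mtry) || mtry < 1) abort("integer mtry must be >= 1")
  }
  structure(
    list(n_trees = n_trees, mtry = mtry,
         max_depth = if (!is.null(max_depth)) as.integer(max_depth),
         seed = as.integer(seed)),
    class = "rf_config"
  )
}

resolve_mtry <- function(mtry, d) {
  m <- switch(as.character(mtry),
    log2 = floor(log2(d)) + 1,
    sqrt = max(1, floor(sqrt(d))),
    as.integer(mtry)
  )
  as.integer(min(m, d))
}

#' Train a random-forest peptide classifier
#'
#' Fits a probability forest on a labelled feature tibble. Training is
#' deterministic given the data and `config$seed`. The model stores the
#' training feature names and rejects prediction input whose feature
#' columns differ in name or order.
#'
#' @param features A labelled feature tibble (both classes present, no NAs).
#' @param config An [rf_config()].
#' @param encoders Optional character vector recording which sequence
#'   encoders produced `features`; stored so [cmd_predict()] can re-encode
#'   raw FASTA input consistently.
#' @return An object of class `aip_rf`.
#' @export
train_rf <- function(features, config = rf_config(), encoders = NULL) {
  stopifnot(inherits(config, "rf_config"))
  if (!"label" %in% names(features)) abort("features must carry a 'label' column")
  y <- check_binary_label(features$label)
  if (length(unique(y)) < 2) {
    abort("training data contains a single class; need both positives and negatives")
  }
  m <- feature_matrix(features)
  if (anyNA(m)) abort("features contain NA values")
  fit <- ranger::ranger(
    x = m,
    y = factor(y, levels = c(0, 1)),
    num.trees = config$n_trees,
    mtry = resolve_mtry(config$mtry, ncol(m)),
    max.depth = config$max_depth %||% 0,
    probability = TRUE,
    seed = config$seed,
    num.threads = 1,
    verbose = FALSE
  )
  structure(
    list(
      fit = fit,
      feature_names = colnames(m),
      config = config,
      encoders = encoders,
      n_pos = sum(y == 1),
      n_neg = sum(y == 0),
      trained_at = format(Sys.time(), tz = "UTC")
    ),
    class = "aip_rf"
  )
}

#' @export
print.aip_rf <- function(x, ...) {
  cat("Random-forest peptide classifier\n")
  cat(sprintf("  %d features, %d trees, mtry rule '%s', seed %d\n",
              length(x$feature_names), x$config$n_trees,
              as.character(x$config$mtry), x$config$seed))
  cat(sprintf("  trained on %d positives / %d negatives\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Predict peptide classes with a trained model
#'
#' Scores are the positive-class vote fraction of the forest, in \[0, 1\];
#' the hard label is `score >= 0.5` (a score of exactly 0.5 is called
#' positive).
#'
#' @param object An `aip_rf` model.
#' @param features A feature tibble whose feature columns match the
#'   training columns exactly (names and order).
#' @param ... Unused.
#' @return A tibble: `sample_id`, `score`, `label`.
#' @export
predict.aip_rf <- function(object, features, ...) {
  fn <- feature_names(features)
  if (!identical(fn, object$feature_names)) {
    diff_at <- which(fn[seq_len(min(length(fn), length(object$feature_names)))] !=
                       object$feature_names[seq_len(min(length(fn), length(object$feature_names)))])
    msg <- if (length(diff_at) > 0) {
      paste0("first differing feature: got '", fn[diff_at[1]], "', expected '",
             object$feature_names[diff_at[1]], "' (position ", diff_at[1], ")")
    } else {
      paste0("got ", length(fn), " features, expected ",
             length(object$feature_names))
    }
    abort(paste0("feature columns do not match the training features; ", msg))
  }
  m <- feature_matrix(features)
  p <- predict(object$fit, data = m, num.threads = 1)$predictions[, "1"]
  tibble(
    sample_id = features$sample_id,
    score = unname(p),
    label = as.integer(p >= 0.5)
  )
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to exactly one test fold, stratified by class:
#' within each class, samples are shuffled (seeded) and dealt round-robin,
#' so per-fold class proportions differ from the global ones by at most one
#' sample.
#'
#' @param labels Binary 0/1 vector.
#' @param folds Number of folds (>= 2, and at most the smallest class size).
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..folds`, one per sample.
#' @export
make_folds <- function(labels, folds = 5, seed = 1) {
  labels <- check_binary_label(labels)
  folds <- as.integer(folds)
  if (folds < 2) abort("need at least 2 folds")
  if (folds > min(table(labels))) {
    abort(paste0("folds = ", folds, " exceeds the smallest class size (",
                 min(table(labels)), ")"))
  }
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Cross-validate a random-forest classifier
#'
#' Runs stratified k-fold cross-validation: for each fold, trains on the
#' remaining folds and scores the held-out samples. Out-of-fold scores are
#' pooled into a single headline evaluation report; per-fold reports are
#' retained (the mean and standard deviation across folds often differ
#' slightly from the pooled values, so both views are kept).
#'
#' @param features A labelled feature tibble.
#' @param config An [rf_config()] for the per-fold models.
#' @param folds Number of folds (default 5).
#' @param cv_seed Seed for the fold assignment.
#' @return A list of class `aip_cv`: `pooled` (an `aip_eval`), `per_fold`
#'   (list of `aip_eval`), `fold_assignment`, `scores` (tibble of pooled
#'   out-of-fold scores), `folds`.
#' @export
cross_validate <- function(features, config = rf_config(), folds = 5,
                           cv_seed = 1) {
  if (!"label" %in% names(features)) abort("features must carry a 'label' column")
  y <- check_binary_label(features$label)
  assignment <- make_folds(y, folds = folds, seed = cv_seed)
  scores <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- assignment == f
    model <- train_rf(features[!test, , drop = FALSE], config = config)
    pred <- predict(model, features[test, , drop = FALSE])
    scores[test] <- pred$score
    per_fold[[f]] <- eval_report(y[test], pred$score)
  }
  structure(
    list(
      pooled = eval_report(y, scores),
      per_fold = per_fold,
      fold_assignment = assignment,
      scores = tibble(sample_id = features$sample_id, label = y,
                      fold = assignment, score = scores),
      folds = folds
    ),
    class = "aip_cv"
  )
}

#' @export
print.aip_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (pooled out-of-fold metrics)\n", x$folds))
  print(x$pooled)
  invisible(x)
}

#' @describeIn cross_validate pooled metrics plus across-fold mean and sd of
#'   the AUC.
#' @param x An `aip_cv` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.aip_cv <- function(x, ...) {
  fold_auc <- vapply(x$per_fold, function(r) r$auc, numeric(1))
  dplyr::bind_cols(
    glance(x$pooled)[, c("sn", "sp", "acc", "mcc", "auc")],
    tibble(fold_auc_mean = mean(fold_auc), fold_auc_sd = stats::sd(fold_auc),
           folds = x$folds)
  )
}

#' @describeIn cross_validate per-fold summary metrics, one row per fold.
#' @exportS3Method generics::tidy
tidy.aip_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(x$per_fold, glance), .id = "fold")
}

#' Save / load a trained model
#'
#' The fitted forest is serialized as an RDS blob next to a human-readable
#' JSON sidecar recording a schema tag, the configuration, the encoder set
#' and the training feature names. Loading verifies the schema tag.
#'
#' @param model An `aip_rf` model.
#' @param path Path for the model blob; the sidecar is written to
#'   `<path>.json`.
#' @return `path` invisibly for the saver; an `aip_rf` for the loader.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aip_rf"))
  saveRDS(model, path)
  sidecar <- list(
    schema = "aipforest-model-v1",
    n_trees = model$config$n_trees,
    mtry = as.character(model$config$mtry),
    seed = model$config$seed,
    encoders = model$encoders,
    n_pos = model$n_pos,
    n_neg = model$n_neg,
    trained_at = model$trained_at,
    n_features = length(model$feature_names),
    feature_names = model$feature_names
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path)
    if (!identical(sidecar$schema, "aipforest-model-v1")) {
      abort(paste0("unrecognised model schema: ", sidecar$schema %||% "<missing>"))
    }
  }
  model <- readRDS(path)
  if (!inherits(model, "aip_rf")) abort("file does not contain an aipforest model")
  model
}
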