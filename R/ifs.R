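#' Incremental feature selection (IFS)
#'
#' Starting from an empty set, adds features in ranked order (in batches of
#' `step`) and cross-validates a random forest on each leading subset; the
#' subset maximising the chosen objective is selected. The full performance
#' curve is kept so before/after-selection comparisons can be plotted.
#'
#' Subset sizes are `step, 2*step, ...` up to `max_size` (or the full
#' feature count); when the cap is not hit, the full feature set is always
#' included as the last curve point, so the selected subset can never score
#' below the unselected feature set on the same folds. Ties on the
#' objective are broken towards the smaller subset.
#'
#' The same seeded fold partition is reused for every subset size, so curve
#' points differ only in the features used. To keep the curve an honest
#' estimate, the ANOVA ranking used to evaluate each subset size is
#' recomputed inside every training fold (nested selection): ranking on the
#' full data and then cross-validating the leading features would leak test
#' information into the ranking and inflate the curve well above chance
#' even for label-independent features. The full-data `ranking` determines
#' only which features are finally reported and used for the deployed
#' model.
#'
#' @param features A labelled feature tibble.
#' @param ranking A ranking tibble from [anova_scores()] covering exactly
#'   the feature columns of `features`.
#' @param objective Metric maximised over the curve: one of `"auc"`
#'   (default), `"acc"`, `"mcc"`, `"sn"`, `"sp"`.
#' @param step Number of features added per curve point (>= 1).
#' @param max_size Optional cap on the largest subset evaluated.
#' @param config An [rf_config()] for the per-subset models.
#' @param folds,cv_seed Cross-validation settings (see [cross_validate()]).
#' @return An object of class `aip_ifs`: `ranking`, `curve` (tibble with
#'   `size` and the summary metrics per subset), `optimal_size`,
#'   `optimal_features`, `objective`, `reports` (per-size `aip_cv` pooled
#'   reports) and `cv` (the `aip_cv` of the optimal subset).
#' @export
incremental_select <- function(features, ranking = anova_scores(features),
                               objective = c("auc", "acc", "mcc", "sn", "sp"),
                               step = 1, max_size = NULL,
                               config = rf_config(), folds = 5, cv_seed = 1) {
  objective <- match.arg(objective)
  step <- as.integer(step)
  if (is.na(step) || step < 1) abort("step must be >= 1")
  fn <- feature_names(features)
  if (!setequal(ranking$feature, fn)) {
    abort("ranking does not match the feature columns of the input")
  }
  ranked <- ranking$feature[order(ranking$rank)]
  p <- length(ranked)
  cap <- min(max_size %||% p, p)
  sizes <- seq(step, cap, by = step)
  if (length(sizes) == 0 || sizes[length(sizes)] < cap) sizes <- c(sizes, cap)

  y <- check_binary_label(features$label)
  assignment <- make_folds(y, folds = folds, seed = cv_seed)
  # out-of-fold score matrix: one column per subset size
  scores <- matrix(NA_real_, nrow = length(y), ncol = length(sizes))
  for (f in seq_len(folds)) {
    test <- assignment == f
    train <- features[!test, , drop = FALSE]
    fold_ranking <- anova_scores(train)
    fold_ranked <- fold_ranking$feature[order(fold_ranking$rank)]
    for (i in seq_along(sizes)) {
      cols <- c("sample_id", "label", fold_ranked[seq_len(sizes[i])])
      model <- train_rf(train[, cols], config = config)
      scores[test, i] <- predict(model, features[test, cols])$score
    }
  }
  reports <- lapply(seq_along(sizes), function(i) eval_report(y, scores[, i]))
  curve <- dplyr::bind_cols(
    tibble(size = sizes),
    dplyr::bind_rows(lapply(reports, function(r) {
      glance(r)[, c("sn", "sp", "acc", "mcc", "auc")]
    }))
  )
  best <- which.max(curve[[objective]])  # which.max takes the first maximum
  best_cv <- structure(
    list(
      pooled = reports[[best]],
      per_fold = lapply(seq_len(folds), function(f) {
        eval_report(y[assignment == f], scores[assignment == f, best])
      }),
      fold_assignment = assignment,
      scores = tibble(sample_id = features$sample_id, label = y,
                      fold = assignment, score = scores[, best]),
      folds = folds
    ),
    class = "aip_cv"
  )
  structure(
    list(
      ranking = ranking,
      curve = curve,
      optimal_size = sizes[best],
      optimal_features = ranked[seq_len(sizes[best])],
      objective = objective,
      reports = reports,
      cv = best_cv
    ),
    class = "aip_ifs"
  )
}

#' @export
print.aip_ifs <- function(x, ...) {
  cat("Incremental feature selection\n")
  cat(sprintf("  %d curve points, objective '%s'\n", nrow(x$curve), x$objective))
  cat(sprintf("  optimal subset: %d features, %s = %.3f\n",
              x$optimal_size, toupper(x$objective),
              x$curve[[x$objective]][x$curve$size == x$optimal_size][1]))
  invisible(x)
}

#' @describeIn incremental_select the IFS performance curve as a tibble.
#' @param x,object An `aip_ifs` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.aip_ifs <- function(x, ...) {
  x$curve
}

#' @describeIn incremental_select one-row summary (optimal size and its
#'   metrics).
#' @exportS3Method generics::glance
glance.aip_ifs <- function(x, ...) {
  dplyr::bind_cols(
    tibble(optimal_size = x$optimal_size, objective = x$objective,
           n_features = nrow(x$ranking)),
    x$curve[x$curve$size == x$optimal_size,
            c("sn", "sp", "acc", "mcc", "auc")][1, ]
  )
}

#' @describeIn incremental_select IFS curve plot (objective vs subset size).
#' @exportS3Method ggplot2::autoplot
autoplot.aip_ifs <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, -"size",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimal_size,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Number of leading ranked features",
                  y = "Cross-validated value", colour = NULL,
                  title = sprintf("IFS curve (optimal size = %d by %s)",
                                  object$optimal_size,
                                  toupper(object$objective)))
}

#' Serialize a selection result to JSON (plus a TSV of the curve)
#'
#' @param selection An `aip_ifs` object.
#' @param path Output JSON path; the curve is also written to
#'   `<path without extension>_curve.tsv`.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "aip_ifs"))
  payload <- list(
    objective = selection$objective,
    optimal_size = selection$optimal_size,
    optimal_features = selection$optimal_features,
    ranking = as.data.frame(selection$ranking),
    curve = as.data.frame(selection$curve)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  readr::write_tsv(selection$curve,
                   paste0(sub("\\.json$", "", path), "_curve.tsv"))
  invisible(path)
}

#' Fit the full identification pipeline
#'
#' Runs the two-step feature selection (ANOVA ranking then incremental
#' selection under cross-validated AUC) and trains the final random forest
#' on the optimal feature subset. With `select = FALSE` the selection step
#' is skipped and the model is trained and cross-validated on all features.
#'
#' @param features A labelled feature tibble.
#' @param select Run feature selection? Default `TRUE`.
#' @param encoders Optional encoder names recorded in the model (see
#'   [train_rf()]).
#' @inheritParams incremental_select
#' @return A list of class `aip_fit`: `model` (the trained `aip_rf` on the
#'   selected features), `selection` (`aip_ifs` or `NULL`), `cv` (the
#'   `aip_cv` of the selected subset — the pipeline's headline
#'   cross-validation report).
#' @export
aip_fit <- function(features, select = TRUE, step = 1, max_size = NULL,
                    objective = "auc", config = rf_config(), folds = 5,
                    cv_seed = 1, encoders = NULL) {
  if (select) {
    sel <- incremental_select(features, objective = objective, step = step,
                              max_size = max_size, config = config,
                              folds = folds, cv_seed = cv_seed)
    keep <- c("sample_id", "label", sel$optimal_features)
    model <- train_rf(features[, keep], config = config, encoders = encoders)
    out <- list(model = model, selection = sel, cv = sel$cv)
  } else {
    cv <- cross_validate(features, config = config, folds = folds,
                         cv_seed = cv_seed)
    model <- train_rf(features, config = config, encoders = encoders)
    out <- list(model = model, selection = NULL, cv = cv)
  }
  structure(out, class = "aip_fit")
}

#' @export
print.aip_fit <- function(x, ...) {
  cat("aipforest pipeline fit\n")
  if (!is.null(x$selection)) {
    cat(sprintf("  selection: %d of %d features kept\n",
                x$selection$optimal_size, nrow(x$selection$ranking)))
  } else {
    cat("  selection: none (all features)\n")
  }
  print(x$cv)
  invisible(x)
}

#' @describeIn aip_fit one-row summary of the pipeline's pooled
#'   cross-validation metrics and selected subset size.
#' @param x An `aip_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.aip_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      n_features = length(x$model$feature_names),
      selected = !is.null(x$selection)
    ),
    glance(x$cv)
  )
}
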