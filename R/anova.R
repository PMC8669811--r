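#' ANOVA F-score feature ranking
#'
#' Scores every feature by the ratio of between-group to within-group
#' variance,
#' \deqn{S(t) = S_B^2(t) / S_W^2(t),}
#' with
#' \deqn{S_B^2(t) = \frac{1}{K-1} \sum_i m_i (\bar{x}_i - \bar{x})^2, \qquad
#'       S_W^2(t) = \frac{1}{N-K} \sum_i \sum_j (x_{ij} - \bar{x}_i)^2,}
#' where `K` is the number of groups (2 for binary labels), `m_i` the group
#' sizes, `N` the total sample count, `x̄_i` the group means and `x̄` the
#' grand mean. This is exactly the one-way ANOVA F statistic. Features are
#' ranked by descending score; ties keep the original column order.
#'
#' A feature with zero within-group variance but non-zero between-group
#' variance separates the groups perfectly; it receives `Inf` and ranks
#' ahead of all finite scores. A feature with zero variance both between
#' and within groups scores 0.
#'
#' @param features A labelled feature tibble (must contain a `label` column
#'   with both classes present and at least 2 samples per class).
#' @return A tibble with columns `feature`, `score` and `rank` (1 = best),
#'   ordered by rank.
#' @examples
#' f <- tibble::tibble(sample_id = as.character(1:4), label = c(0L, 0L, 1L, 1L),
#'                     x = c(0, 2, 4, 6))
#' anova_scores(f)$score  # F = 8
#' @export
anova_scores <- function(features) {
  if (!"label" %in% names(features)) abort("features must carry a 'label' column")
  y <- check_binary_label(features$label)
  if (length(unique(y)) < 2) abort("both classes must be present to rank features")
  m <- feature_matrix(features)
  n <- nrow(m)
  k <- length(unique(y))
  if (min(table(y)) < 2) abort("need at least 2 samples per class")
  if (n - k < 1) abort("need at least 3 samples (N - K must be >= 1)")

  groups <- split(seq_len(n), y)
  sizes <- lengths(groups)
  group_means <- do.call(cbind, lapply(groups, function(i) {
    colMeans(m[i, , drop = FALSE])
  }))
  grand <- colMeans(m)
  sb <- rowSums(sweep(sweep(group_means, 1, grand)^2, 2, sizes, `*`)) / (k - 1)
  within_ss <- Reduce(`+`, lapply(seq_along(groups), function(g) {
    colSums(sweep(m[groups[[g]], , drop = FALSE], 2, group_means[, g])^2)
  }))
  sw <- within_ss / (n - k)

  score <- ifelse(sw > 0, sb / sw, ifelse(sb > 0, Inf, 0))
  ord <- order(-score, seq_along(score))
  tibble(
    feature = colnames(m)[ord],
    score = unname(score[ord]),
    rank = seq_along(ord)
  )
}
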