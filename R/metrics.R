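#' One-vs-rest confusion counts per class
#'
#' Single-label tasks (`rule = "argmax"`) count the argmax prediction against
#' the true class; multi-label tasks (`rule = "threshold"`) threshold each
#' class score at `threshold`. Counts satisfy tp + tn + fp + fn = number of
#' samples for every class.
#'
#' @param scores N x K score matrix (column names become class labels).
#' @param targets N x K binary target matrix.
#' @param rule `"argmax"` or `"threshold"`.
#' @param threshold Score threshold for the multi-label rule.
#' @return Tibble with columns `class`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(scores, targets, rule = c("argmax", "threshold"),
                      threshold = 0.5) {
  rule <- match.arg(rule)
  scores <- as.matrix(scores)
  targets <- as.matrix(targets)
  if (nrow(scores) == 0) abort("cannot compute confusion counts on empty input")
  if (!all(dim(scores) == dim(targets))) abort("scores and targets must have equal dimensions")
  classes <- colnames(scores) %||% paste0("class_", seq_len(ncol(scores)))
  pred <- if (rule == "argmax") {
    p <- matrix(0, nrow(scores), ncol(scores))
    p[cbind(seq_len(nrow(scores)), max.col(scores, ties.method = "first"))] <- 1
    p
  } else {
    (scores > threshold) * 1
  }
  tibble(
    class = classes,
    tp = as.integer(colSums(pred == 1 & targets == 1)),
    tn = as.integer(colSums(pred == 0 & targets == 0)),
    fp = as.integer(colSums(pred == 1 & targets == 0)),
    fn = as.integer(colSums(pred == 0 & targets == 1))
  )
}

#' Derive accuracy, precision, recall and F1 from confusion counts
#'
#' Zero-division policy: precision (tp + fp = 0), recall (tp + fn = 0) or F1
#' (precision + recall = 0) return 0 and the row is flagged in `degenerate`.
#'
#' @param counts Tibble with `class`, `tp`, `tn`, `fp`, `fn` (from
#'   [confusion()] or printed tables).
#' @return The counts with added `precision`, `recall`, `accuracy`, `f1`,
#'   `degenerate` columns.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  counts |>
    mutate(
      precision = safe_div(.data$tp, .data$tp + .data$fp),
      recall = safe_div(.data$tp, .data$tp + .data$fn),
      accuracy = safe_div(.data$tp + .data$tn, .data$tp + .data$tn + .data$fp + .data$fn),
      f1 = safe_div(2 * .data$precision * .data$recall, .data$precision + .data$recall),
      degenerate = (.data$tp + .data$fp == 0) | (.data$tp + .data$fn == 0) |
        (.data$precision + .data$recall == 0)
    )
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from midranks, which equals the fraction
#' of (positive, negative) pairs ordered correctly with half credit for ties.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1), both values present.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("scores and labels must have equal length")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1)")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined when only one class is present in the labels")
  }
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full per-class metrics report with macro-average AUC
#'
#' @inheritParams confusion
#' @return Tibble with one row per class (confusion counts, derived metrics,
#'   one-vs-rest `auc`; `auc` is `NA` for classes absent from `targets`) plus
#'   one `macro` row whose `auc` is the unweighted mean of the defined
#'   per-class AUCs.
#' @export
metrics_report <- function(scores, targets, rule = c("argmax", "threshold"),
                           threshold = 0.5) {
  rule <- match.arg(rule)
  per_class <- classification_metrics(confusion(scores, targets, rule, threshold))
  scores <- as.matrix(scores)
  targets <- as.matrix(targets)
  per_class$auc <- vapply(seq_len(ncol(scores)), function(k) {
    if (length(unique(targets[, k])) < 2) {
      return(NA_real_)
    }
    auc_rank(scores[, k], targets[, k])
  }, numeric(1))
  macro <- tibble(
    class = "macro", tp = NA_integer_, tn = NA_integer_, fp = NA_integer_,
    fn = NA_integer_, precision = mean(per_class$precision),
    recall = mean(per_class$recall), accuracy = mean(per_class$accuracy),
    f1 = mean(per_class$f1), degenerate = any(per_class$degenerate),
    auc = mean(per_class$auc, na.rm = TRUE)
  )
  dplyr::bind_rows(per_class, macro)
}
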