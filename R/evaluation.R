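#' Stratified train/dev/test split
#'
#' Splits per class: a ceiling-rounded `test_frac` share of each class goes
#' to the test set; of the remainder, a ceiling-rounded `dev_frac` share goes
#' to the development set; the rest is training. Shuffling is within class
#' under the seed, so partitions are reproducible, disjoint and exhaustive,
#' and each preserves the natural class imbalance up to rounding.
#'
#' @param corpus A labeled `tweet_corpus`.
#' @param test_frac,dev_frac Held-out fractions in `(0, 1)`.
#' @param seed Integer seed.
#' @return The corpus with an added `split` factor column
#'   (`train`/`dev`/`test`).
#' @export
stratified_split <- function(corpus, test_frac = 0.2, dev_frac = 0.2,
                             seed = 1) {
  stopifnot(test_frac > 0, test_frac < 1, dev_frac > 0, dev_frac < 1)
  split <- rep(NA_character_, nrow(corpus))
  withr::with_seed(seed, {
    for (cls in unique(corpus$label)) {
      idx <- which(corpus$label == cls)
      n <- length(idx)
      n_test <- ceiling(n * test_frac)
      n_dev <- ceiling((n - n_test) * dev_frac)
      if (n - n_test - n_dev < 1 || n_test < 1 || n_dev < 1) {
        stop("class '", cls, "' too small to populate all partitions",
             call. = FALSE)
      }
      shuffled <- sample(idx)
      split[shuffled[seq_len(n_test)]] <- "test"
      split[shuffled[n_test + seq_len(n_dev)]] <- "dev"
      split[shuffled[(n_test + n_dev + 1):n]] <- "train"
    }
  })
  corpus$split <- factor(split, levels = c("train", "dev", "test"))
  corpus
}

#' @rdname stratified_split
#' @param counts Named integer vector of per-class counts.
#' @return `split_sizes()`: a tibble of per-class train/dev/test sizes under
#'   the same ceiling-rounding rule.
#' @export
split_sizes <- function(counts, test_frac = 0.2, dev_frac = 0.2) {
  n_test <- ceiling(counts * test_frac)
  rem <- counts - n_test
  n_dev <- ceiling(rem * dev_frac)
  tibble::tibble(class = names(counts), total = as.integer(counts),
                 train = as.integer(rem - n_dev), dev = as.integer(n_dev),
                 test = as.integer(n_test))
}

#' Confusion matrix
#'
#' K-by-K integer counts with actual classes as rows and predicted classes
#' as columns, in the fixed canonical class order.
#'
#' @param actual,predicted Label vectors of equal length.
#' @param classes Class order; defaults to the canonical order restricted to
#'   observed classes.
#' @return A matrix of class `confusion_matrix`.
#' @export
confusion <- function(actual, predicted, classes = NULL) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  classes <- classes %||% class_levels(c(actual, predicted))
  m <- table(factor(actual, levels = classes),
             factor(predicted, levels = classes))
  m <- unclass(m)
  dimnames(m) <- list(actual = classes, predicted = classes)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @rdname confusion
#' @param m A K-by-K matrix (rows actual, columns predicted) to tag as a
#'   confusion matrix, e.g. counts copied from a printed table.
#' @export
as_confusion <- function(m, classes = rownames(m)) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  classes <- classes %||% paste0("class", seq_len(nrow(m)))
  dimnames(m) <- list(actual = classes, predicted = classes)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest metrics from a confusion matrix: `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`, `F1 = 2 * recall * precision / (recall +
#' precision)`. A metric whose denominator is zero (e.g. precision for a
#' never-predicted class) is reported as 0 and flagged in the `undefined`
#' column rather than returned as NaN.
#'
#' @param cm A `confusion_matrix`.
#' @return A tibble with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `support`, `undefined`.
#' @export
#' @examples
#' cm <- as_confusion(rbind(c(163, 12, 64), c(18, 109, 113), c(81, 68, 3974)),
#'                    classes = tweet_classes())
#' metrics_from_confusion(cm)
metrics_from_confusion <- function(cm) {
  tp <- diag(cm)
  row_sum <- rowSums(cm)
  col_sum <- colSums(cm)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, col_sum)
  recall <- safe_div(tp, row_sum)
  f1 <- safe_div(2 * recall * precision, recall + precision)
  tibble::tibble(
    class = rownames(cm),
    precision = unname(precision),
    recall = unname(recall),
    f1 = unname(f1),
    support = as.integer(unname(row_sum)),
    undefined = unname(col_sum == 0 | row_sum == 0)
  )
}

#' @rdname metrics_from_confusion
#' @param tp,fp,fn True-positive, false-positive and false-negative counts
#'   for a single positive class.
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * recall * precision / (recall + precision)
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

#' Display rounding
#'
#' Round half up to two decimals, the convention used in the reported
#' tables; raw values are kept in machine output.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
#' @examples
#' round_display(0.625)
round_display <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Two-class collapse evaluation
#'
#' Collapses `defect` and `possible_defect` into a single `positive` class
#' (against `negative`) in both the actual and predicted labels, and scores
#' the positive class. Note that collapsing predictions from a 3-class model
#' differs from retraining a 2-class model; this operation evaluates
#' whatever 2- or 3-class prediction set it is given.
#'
#' @param actual,predicted Label vectors (3-class labels are collapsed;
#'   already-binary `positive`/`negative` labels pass through).
#' @return A list with `confusion` (2x2) and `metrics` (positive class).
#' @export
collapse_two_class <- function(actual, predicted) {
  collapse <- function(x) {
    x <- as.character(x)
    ifelse(x %in% c("defect", "possible_defect", "positive"),
           "positive", "negative")
  }
  cm <- confusion(collapse(actual), collapse(predicted),
                  classes = c("positive", "negative"))
  metrics <- metrics_from_confusion(cm)
  list(confusion = cm, metrics = metrics[metrics$class == "positive", ])
}

#' Precision-recall curve and area under it
#'
#' Sweeps thresholds over the unique scores in descending order; at each
#' threshold an instance is predicted positive iff its score is at least the
#' threshold. The area is the trapezoid rule over recall, anchored at
#' recall 0 with the first point's precision. The curve (and hence the area)
#' is invariant under strictly monotone transformations of the scores.
#'
#' @param actual Label vector.
#' @param scores Numeric scores for the positive class (higher = more
#'   positive), e.g. calibrated SVM probabilities.
#' @param positive The positive class label.
#' @return `pr_curve()`: a tibble of class `bd_pr_curve` with columns
#'   `threshold`, `recall`, `precision`; `auc_pr()`: a number.
#' @export
pr_curve <- function(actual, scores, positive = "defect") {
  y <- as.character(actual) == positive
  stopifnot(length(y) == length(scores), any(y))
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_tie]; fp <- fp[last_of_tie]
  out <- tibble::tibble(
    threshold = s[last_of_tie],
    recall = tp / sum(y),
    precision = tp / (tp + fp)
  )
  class(out) <- unique(c("bd_pr_curve", class(out)))
  attr(out, "positive") <- positive
  out
}

#' @rdname pr_curve
#' @param curve A tibble from [pr_curve()].
#' @export
auc_pr <- function(curve) {
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  sum(diff(r) * (head(p, -1) + p[-1]) / 2)
}
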