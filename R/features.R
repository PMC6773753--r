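#' Feature matrices
#'
#' A `feature_matrix` wraps a sparse instances-by-features matrix (counts or
#' numeric lengths) whose columns are namespaced feature names (`ngram:`,
#' `cluster:`, `len:`) in deterministic lexicographic order, together with
#' the per-column min-max scaling bounds once fitted (on training data only).
#'
#' @param m A sparse `dgCMatrix` with column names.
#' @param bounds Optional scaling-bounds tibble (`feature`, `min`, `max`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(m, bounds = NULL) {
  m <- methods::as(m, "CsparseMatrix")
  if (is.null(colnames(m))) stop("feature matrix must have column names", call. = FALSE)
  ord <- order(colnames(m), method = "radix")
  structure(list(m = m[, ord, drop = FALSE], bounds = bounds),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$m)

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$m), " x ", ncol(x$m),
      if (!is.null(x$bounds)) " (scaled)" else " (unscaled)", "\n", sep = "")
  invisible(x)
}

#' @rdname feature_matrix
#' @param x A `feature_matrix`.
#' @export
scaling_bounds <- function(x) x$bounds

#' Fit an n-gram vocabulary
#'
#' The vocabulary is every contiguous 1-, 2- and 3-gram (by default) observed
#' in the training token lists; no document-frequency pruning is applied
#' unless `min_df > 1`. Tokens within an n-gram are joined by `_`.
#'
#' @param tokens A list of character token vectors.
#' @param n Integer vector of n-gram orders.
#' @param min_df Minimum number of documents a feature must occur in.
#' @return Character vector of n-gram names, sorted.
#' @export
#' @examples
#' fit_ngrams(list(c("a", "b", "c")))
fit_ngrams <- function(tokens, n = 1:3, min_df = 1) {
  if (length(tokens) == 0) stop("empty corpus", call. = FALSE)
  per_doc <- purrr::map(tokens, function(t) unique(token_ngrams(t, n)))
  tab <- table(unlist(per_doc))
  sort(names(tab)[tab >= min_df], method = "radix")
}

token_ngrams <- function(t, n) {
  out <- character(0)
  for (k in n) {
    if (length(t) >= k) {
      if (k == 1) {
        out <- c(out, t)
      } else {
        idx <- seq_len(length(t) - k + 1)
        grams <- t[idx]
        for (j in seq_len(k - 1)) grams <- paste(grams, t[idx + j], sep = "_")
        out <- c(out, grams)
      }
    }
  }
  out
}

# Sparse count matrix over a fixed vocabulary; unseen grams are dropped
# (transform never adds columns).
ngram_counts <- function(tokens, vocab, n = 1:3) {
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  idx <- seq_along(vocab)
  names(idx) <- vocab
  for (d in seq_along(tokens)) {
    grams <- token_ngrams(tokens[[d]], n)
    grams <- grams[grams %in% vocab]
    if (length(grams) == 0) next
    tab <- table(grams)
    ii <- c(ii, rep(d, length(tab)))
    jj <- c(jj, unname(idx[names(tab)]))
    xx <- c(xx, as.integer(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(tokens), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Word-cluster indicator counts
#'
#' Maps each token to its hierarchical cluster path and counts path
#' occurrences per instance. Unknown words (including placeholder tokens,
#' which appear in no public cluster table) contribute nothing. The column
#' set is the full set of paths in the table, so transforms are stable.
#'
#' @param tokens A list of character token vectors.
#' @param cluster_table A tibble from [read_clusters()].
#' @return Sparse count matrix with one column per cluster path.
#' @export
cluster_features <- function(tokens, cluster_table) {
  paths <- sort(unique(cluster_table$cluster), method = "radix")
  lookup <- setNames(cluster_table$cluster, cluster_table$word)
  pidx <- setNames(seq_along(paths), paths)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_along(tokens)) {
    t <- tolower(tokens[[d]])
    t <- t[!grepl("^_[a-z]+_$", t)]
    hit <- lookup[t]
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) next
    tab <- table(hit)
    ii <- c(ii, rep(d, length(tab)))
    jj <- c(jj, unname(pidx[names(tab)]))
    xx <- c(xx, as.integer(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(tokens), length(paths)),
                       dimnames = list(NULL, paths))
}

#' Tweet length features
#'
#' Length of the raw tweet in characters and in words (tokens).
#'
#' @param text Character vector of raw texts.
#' @param tokens List of token vectors (same length as `text`).
#' @return A two-column matrix (`chars`, `words`).
#' @export
#' @examples
#' length_features("ab cd", list(c("ab", "cd")))
length_features <- function(text, tokens) {
  cbind(chars = nchar(text), words = lengths(tokens))
}

#' Build the combined feature matrix
#'
#' Assembles n-gram, word-cluster and length feature blocks (each toggleable)
#' into one sparse matrix with namespaced, lexicographically ordered columns.
#' Fitting the vocabulary and transforming new data share this function: pass
#' the training vocabulary via `vocab` to transform held-out data without
#' adding columns.
#'
#' @param corpus A corpus that has been through [classic_normalize()] (needs
#'   `classic_tokens`; `text` is used for lengths).
#' @param vocab N-gram vocabulary from [fit_ngrams()]; `NULL` fits it from
#'   `corpus`.
#' @param cluster_table Optional cluster table; enables `cluster:` features.
#' @param n N-gram orders.
#' @param use_ngrams,use_clusters,use_lengths Feature-group toggles.
#' @param binary Use presence/absence instead of counts for n-grams.
#' @param min_df Minimum document frequency when fitting the vocabulary.
#' @return A `feature_matrix` (unscaled).
#' @export
build_features <- function(corpus, vocab = NULL, cluster_table = NULL,
                           n = 1:3, use_ngrams = TRUE,
                           use_clusters = !is.null(cluster_table),
                           use_lengths = TRUE, binary = FALSE, min_df = 1) {
  stopifnot("classic_tokens" %in% names(corpus))
  tokens <- corpus$classic_tokens
  blocks <- list()
  if (use_ngrams) {
    if (is.null(vocab)) vocab <- fit_ngrams(tokens, n = n, min_df = min_df)
    ng <- ngram_counts(tokens, vocab, n = n)
    if (binary) ng@x <- rep(1, length(ng@x))
    colnames(ng) <- paste0("ngram:", colnames(ng))
    blocks <- c(blocks, list(ng))
  }
  if (use_clusters) {
    if (is.null(cluster_table)) stop("use_clusters = TRUE needs a cluster_table", call. = FALSE)
    cl <- cluster_features(tokens, cluster_table)
    colnames(cl) <- paste0("cluster:", colnames(cl))
    blocks <- c(blocks, list(cl))
  }
  if (use_lengths) {
    lf <- Matrix::Matrix(length_features(corpus$text, tokens), sparse = TRUE)
    colnames(lf) <- c("len:chars", "len:words")
    blocks <- c(blocks, list(lf))
  }
  if (length(blocks) == 0) stop("no feature groups enabled", call. = FALSE)
  feature_matrix(do.call(cbind, blocks))
}

#' Min-max feature scaling
#'
#' `scale_fit_transform()` fits per-column (min, max) bounds on the training
#' matrix and rescales it to `[0, 1]`; `scale_transform()` applies fitted
#' bounds to another matrix, clipping out-of-range values to `[0, 1]`.
#' Zero-range (constant) columns scale to 0, keeping SVM inputs bounded.
#'
#' @param fm A `feature_matrix`.
#' @param bounds A scaling-bounds tibble (from a fitted matrix via
#'   [scaling_bounds()]).
#' @return A scaled `feature_matrix` carrying its bounds.
#' @export
scale_fit_transform <- function(fm) {
  m <- fm$m
  cmin <- sparse_col_min(m)
  cmax <- sparse_col_max(m)
  bounds <- tibble::tibble(feature = colnames(m), min = cmin, max = cmax)
  scale_transform(fm, bounds)
}

#' @rdname scale_fit_transform
#' @export
scale_transform <- function(fm, bounds) {
  m <- fm$m
  if (!identical(colnames(m), bounds$feature)) {
    bounds <- bounds[match(colnames(m), bounds$feature), ]
    if (anyNA(bounds$feature)) stop("scaling bounds do not cover all columns", call. = FALSE)
  }
  rng <- bounds$max - bounds$min
  m <- methods::as(m, "CsparseMatrix")
  p <- m@p
  nz_col <- rep(seq_len(ncol(m)), diff(p))
  x <- m@x
  r <- rng[nz_col]
  scaled <- ifelse(r == 0, 0, (x - bounds$min[nz_col]) / r)
  # structural zeros stay 0: exact when min == 0, and equal to the clipped
  # value when min > 0 (since (0 - min)/range < 0 clips to 0)
  m@x <- pmin(pmax(scaled, 0), 1)
  m <- Matrix::drop0(m)
  structure(list(m = m, bounds = bounds), class = "feature_matrix")
}

sparse_col_min <- function(m) {
  p <- m@p
  nnz <- diff(p)
  mins <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    vals <- m@x[seq_len(nnz[j]) + p[j]]
    mins[j] <- if (nnz[j] < nrow(m)) min(0, vals) else min(vals)
  }
  mins
}

sparse_col_max <- function(m) {
  p <- m@p
  nnz <- diff(p)
  maxs <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    vals <- m@x[seq_len(nnz[j]) + p[j]]
    maxs[j] <- if (nnz[j] < nrow(m)) max(0, vals) else max(vals)
  }
  maxs
}

#' Information-gain feature ranking
#'
#' Ranks features by the reduction in label entropy from observing the
#' feature's presence/absence: `IG(f) = H(label) - sum_v p(f=v) H(label|f=v)`
#' with the feature binarized. Entropy is in bits. Ties are broken by feature
#' name so the ranking is deterministic.
#'
#' @param fm A `feature_matrix` (or sparse matrix).
#' @param labels Class labels, one per row.
#' @return A tibble (`feature`, `ig`) in descending `ig` order.
#' @export
information_gain <- function(fm, labels) {
  m <- if (inherits(fm, "feature_matrix")) fm$m else fm
  labels <- factor(labels)
  n <- nrow(m)
  stopifnot(length(labels) == n)
  bin <- m
  bin@x <- rep(1, length(bin@x))
  y <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(labels),
                            x = 1, dims = c(n, nlevels(labels)))
  present <- as.matrix(Matrix::crossprod(bin, y))   # features x classes
  class_tot <- as.numeric(table(labels))
  absent <- matrix(class_tot, nrow = nrow(present), ncol = length(class_tot),
                   byrow = TRUE) - present
  h <- function(counts) {
    tot <- rowSums(counts)
    p <- counts / ifelse(tot == 0, 1, tot)
    -rowSums(ifelse(p > 0, p * log2(p), 0))
  }
  h_label <- {
    p <- class_tot / n
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  n_present <- rowSums(present)
  ig <- h_label - (n_present / n) * h(present) -
    ((n - n_present) / n) * h(absent)
  out <- tibble::tibble(feature = colnames(m), ig = pmax(unname(ig), 0))
  out[order(-out$ig, out$feature, method = "radix"), ]
}
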