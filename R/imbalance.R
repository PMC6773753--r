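#' Levenshtein-ratio lexical similarity
#'
#' `LR = (lensum - lendist) / lensum`, where `lensum` is the sum of the two
#' string lengths and `lendist` their Levenshtein distance (minimal number of
#' insertions, deletions or substitutions). The ratio lies in `[0, 1]`: 0 for
#' completely dissimilar strings, 1 for identical strings. It is symmetric in
#' its arguments. Two empty strings are undefined by the formula and return 1
#' by convention (identical strings).
#'
#' `levenshtein_ratio()` is elementwise over recycled vectors;
#' `lr_matrix()` returns the full cross-similarity matrix.
#'
#' @param a,b Character vectors.
#' @return Numeric similarity in `[0, 1]`.
#' @export
#' @examples
#' levenshtein_ratio("kitten", "sitting")  # (13 - 3) / 13
levenshtein_ratio <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  la <- nchar(a); lb <- nchar(b)
  d <- vapply(seq_len(n), function(i) adist(a[i], b[i])[1, 1], numeric(1))
  lensum <- la + lb
  ifelse(lensum == 0, 1, (lensum - d) / lensum)
}

#' @rdname levenshtein_ratio
#' @export
lr_matrix <- function(a, b) {
  d <- adist(a, b)
  lensum <- outer(nchar(a), nchar(b), "+")
  out <- (lensum - d) / ifelse(lensum == 0, 1, lensum)
  out[lensum == 0] <- 1
  out
}

#' Sampling plans
#'
#' Describes one of the five data-level class-imbalance strategies (or
#' `none`): `similarity_all` (method 1: drop majority tweets lexically
#' similar to earlier majority tweets), `similarity_fn` (method 2: drop
#' majority tweets similar to minority development tweets misclassified as
#' majority), `random_under` (method 3: random majority under-sampling to a
#' target corpus size), `oversample_replacement` (method 4: whole-set
#' minority duplication), and `smote` (method 5: synthetic minority
#' interpolation in feature space).
#'
#' @param method One of `"similarity_all"`, `"similarity_fn"`,
#'   `"random_under"`, `"oversample_replacement"`, `"smote"`, `"none"`.
#' @param k Levenshtein-ratio threshold in `(0, 1)`; required for the two
#'   similarity methods.
#' @param target_size Total corpus size after sampling; required for
#'   `random_under`.
#' @param seed Integer RNG seed for the stochastic methods.
#' @return A named list of class `sampling_plan`.
#' @export
sampling_plan <- function(method = c("none", "similarity_all", "similarity_fn",
                                     "random_under", "oversample_replacement",
                                     "smote"),
                          k = NA_real_, target_size = NA_integer_,
                          seed = NULL) {
  method <- match.arg(method)
  if (method %in% c("similarity_all", "similarity_fn")) {
    stopifnot(!is.na(k), k > 0, k < 1)
  } else if (!is.na(k)) {
    stop("k is only meaningful for the similarity methods", call. = FALSE)
  }
  if (method == "random_under") {
    # NA is allowed: the comparison harness fills in the size produced by
    # the preceding similarity plan (its control)
    stopifnot(is.na(target_size) || target_size > 0)
  } else if (!is.na(target_size)) {
    stop("target_size is only meaningful for random_under", call. = FALSE)
  }
  structure(list(method = method, k = k,
                 target_size = as.integer(target_size), seed = seed),
            class = "sampling_plan")
}

# Text used for similarity: classic-normalized if available (near-duplicates
# differing only in usernames/URLs collapse), else raw.
sim_text <- function(corpus) {
  if ("classic_text" %in% names(corpus)) corpus$classic_text else corpus$text
}

#' Similarity under-sampling of the majority class (method 1)
#'
#' Scans majority-class tweets in corpus order and removes a tweet iff its
#' Levenshtein ratio to any *retained earlier* majority tweet exceeds `k`
#' (keep-first rule; corpus order is the tie-break). Near-duplicate clusters
#' -- repeated fundraisers, news headlines, advertisements -- collapse to
#' their first occurrence, reducing imbalance without losing linguistic
#' information about the majority class. Minority classes are untouched.
#'
#' Similarity is computed on classic-normalized text when present (see
#' [classic_normalize()]). An exact length-difference prefilter skips pairs
#' whose length gap alone forces `LR <= k`.
#'
#' @param corpus A labeled `tweet_corpus` (optionally with `classic_text`).
#' @param k Levenshtein-ratio threshold in `(0, 1)`.
#' @param majority The majority class label.
#' @return The under-sampled corpus, original order preserved.
#' @export
undersample_similarity_all <- function(corpus, k, majority = "non_defect") {
  stopifnot(k > 0, k < 1)
  texts <- sim_text(corpus)
  maj <- which(corpus$label == majority)
  keep <- rep(TRUE, nrow(corpus))
  ret_text <- character(0)
  ret_len <- integer(0)
  for (i in maj) {
    t <- texts[i]
    l <- nchar(t)
    # LR > k needs lendist < lensum (1 - k); lendist >= |l1 - l2|
    cand <- which(abs(ret_len - l) < (ret_len + l) * (1 - k))
    drop_it <- FALSE
    if (length(cand) > 0) {
      d <- drop(adist(t, ret_text[cand]))
      lensum <- l + ret_len[cand]
      lr <- ifelse(lensum == 0, 1, (lensum - d) / lensum)
      drop_it <- any(lr > k)
    }
    if (drop_it) {
      keep[i] <- FALSE
    } else {
      ret_text <- c(ret_text, t)
      ret_len <- c(ret_len, l)
    }
  }
  corpus[keep, , drop = FALSE]
}

#' Similarity under-sampling against misclassified anchors (method 2)
#'
#' Removes majority-class tweets whose maximum Levenshtein ratio to any
#' anchor string exceeds `k`. Anchors are intended to be development-set
#' minority tweets that a preliminary classifier misclassified as the
#' majority class (see [misclassified_anchors()]), so this strategically
#' trims majority tweets near the linguistic boundary of the minority
#' classes. An empty anchor list leaves the corpus unchanged.
#'
#' @inheritParams undersample_similarity_all
#' @param anchors Character vector of anchor strings (normalized the same
#'   way as the corpus similarity text).
#' @export
undersample_similarity_fn <- function(corpus, anchors, k,
                                      majority = "non_defect") {
  stopifnot(k > 0, k < 1)
  if (length(anchors) == 0) return(corpus)
  texts <- sim_text(corpus)
  maj <- corpus$label == majority
  if (!any(maj)) return(corpus)
  lr <- lr_matrix(texts[maj], anchors)
  drop_it <- apply(lr, 1, max) > k
  keep <- rep(TRUE, nrow(corpus))
  keep[which(maj)[drop_it]] <- FALSE
  corpus[keep, , drop = FALSE]
}

#' Random under-sampling of the majority class (method 3)
#'
#' Uniformly samples the majority class without replacement so that the total
#' corpus size equals `target_size` (typically the size produced by one of
#' the similarity methods, for a controlled comparison). Minority classes are
#' untouched; corpus order is preserved among kept rows.
#'
#' @inheritParams undersample_similarity_all
#' @param target_size Total corpus size after sampling.
#' @param seed Integer seed (uses the current RNG state when `NULL`).
#' @export
undersample_random <- function(corpus, target_size, seed = NULL,
                               majority = "non_defect") {
  if (is.na(target_size)) stop("target_size must be a number", call. = FALSE)
  maj <- which(corpus$label == majority)
  n_min <- nrow(corpus) - length(maj)
  n_keep_maj <- target_size - n_min
  if (n_keep_maj < 0) {
    stop("target_size smaller than the minority total (", n_min, ")",
         call. = FALSE)
  }
  if (n_keep_maj > length(maj)) {
    stop("target_size exceeds corpus size", call. = FALSE)
  }
  pick <- function() sort(sample(maj, n_keep_maj))
  kept_maj <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  keep <- rep(TRUE, nrow(corpus))
  keep[setdiff(maj, kept_maj)] <- FALSE
  corpus[keep, , drop = FALSE]
}

#' Minority over-sampling with replacement (method 4)
#'
#' Duplicates each minority class as a whole `m` times, with
#' `m = floor(majority_count / class_count)`, so each minority class ends up
#' nearly equal to the majority class. The majority class is unchanged; the
#' final row order is shuffled.
#'
#' @inheritParams undersample_random
#' @export
oversample_replacement <- function(corpus, seed = NULL,
                                   majority = "non_defect") {
  counts <- table(corpus$label)
  n_major <- as.integer(counts[majority])
  pieces <- list(corpus[corpus$label == majority, , drop = FALSE])
  for (cls in setdiff(names(counts), majority)) {
    rows <- corpus[corpus$label == cls, , drop = FALSE]
    m <- max(1L, n_major %/% nrow(rows))
    pieces <- c(pieces, rep(list(rows), m))
  }
  out <- dplyr::bind_rows(pieces)
  shuffle <- function() sample.int(nrow(out))
  ord <- if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
  out[ord, , drop = FALSE]
}

#' SMOTE over-sampling in feature space (method 5)
#'
#' Creates synthetic minority instances by interpolation: each synthetic row
#' is `x + u (x_nn - x)` with `u ~ Uniform(0, 1)` and `x_nn` one of the
#' `k_neighbors` nearest neighbors of `x` within its own class (Euclidean
#' distance). Each minority class is brought up to the majority count, so
#' classes end up nearly balanced. Majority rows are unchanged. All sparse
#' arithmetic, so large n-gram spaces stay cheap.
#'
#' @param fm A `feature_matrix` of the training instances.
#' @param labels Class labels, one per row of `fm`.
#' @param k_neighbors Number of nearest neighbors to interpolate towards.
#' @param seed Integer seed (uses the current RNG state when `NULL`).
#' @param majority The majority class label.
#' @return A list with elements `features` (a `feature_matrix` containing the
#'   original rows followed by the synthetic rows) and `labels`.
#' @export
smote_oversample <- function(fm, labels, k_neighbors = 5, seed = NULL,
                             majority = "non_defect") {
  run <- function() smote_impl(fm, labels, k_neighbors, majority)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

smote_impl <- function(fm, labels, k_neighbors, majority) {
  m <- fm$m
  labels <- as.character(labels)
  counts <- table(labels)
  n_major <- as.integer(counts[majority])
  syn_blocks <- list()
  syn_labels <- character(0)
  for (cls in setdiff(names(counts), majority)) {
    idx <- which(labels == cls)
    n_c <- length(idx)
    if (n_c < k_neighbors + 1) {
      stop("class '", cls, "' has fewer than k_neighbors + 1 = ",
           k_neighbors + 1, " instances", call. = FALSE)
    }
    n_syn <- n_major - n_c
    if (n_syn <= 0) next
    xs <- m[idx, , drop = FALSE]
    # squared Euclidean distances via the sparse Gram matrix
    g <- as.matrix(Matrix::tcrossprod(xs))
    rs <- Matrix::diag(g)
    d2 <- outer(rs, rs, "+") - 2 * g
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k_neighbors)]))
    base <- sample.int(n_c, n_syn, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    xb <- xs[base, , drop = FALSE]
    xn <- xs[pick, , drop = FALSE]
    syn <- xb + Matrix::Diagonal(x = u) %*% (xn - xb)
    syn_blocks <- c(syn_blocks, list(syn))
    syn_labels <- c(syn_labels, rep(cls, n_syn))
  }
  out_m <- if (length(syn_blocks) > 0) {
    do.call(rbind, c(list(m), syn_blocks))
  } else {
    m
  }
  list(features = structure(list(m = methods::as(out_m, "CsparseMatrix"),
                                 bounds = fm$bounds),
                            class = "feature_matrix"),
       labels = c(labels, syn_labels))
}
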