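# Shared fixtures and independent oracles, all built in code.

make_corpus <- function(texts, labels = NA_character_) {
  tweet_corpus(seq_along(texts), paste0("u", seq_along(texts)), texts, labels)
}

fixture_lexicon <- function() {
  bd_lexicon(c("spina bifida", "down syndrome", "gastroschisis", "club foot",
               "hydrocephalus", "craniosynostosis", "trisomy 18"),
             variants = list(hydrocephalus = "hydrocephalis"))
}

# Brute-force recursive edit distance (insert/delete/substitute), the
# independent oracle for the Levenshtein ratio. Exponential; small strings
# only.
recursive_edit_dist <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- as.integer(substring(a, 1, 1) != substring(b, 1, 1))
  min(recursive_edit_dist(substring(a, 2), b) + 1,
      recursive_edit_dist(a, substring(b, 2)) + 1,
      recursive_edit_dist(substring(a, 2), substring(b, 2)) + cost)
}

recursive_lr <- function(a, b) {
  lensum <- nchar(a) + nchar(b)
  if (lensum == 0) return(1)
  (lensum - recursive_edit_dist(a, b)) / lensum
}

# All strings of the given length over the alphabet, as integer matrices
# (one row per string, one column per position).
enumerate_strings <- function(max_len, n_letters = 3) {
  out <- list(matrix(integer(0), nrow = 1, ncol = 0))
  for (l in seq_len(max_len)) {
    prev <- out[[l]]
    out[[l + 1]] <- cbind(prev[rep(seq_len(nrow(prev)), each = n_letters), ,
                               drop = FALSE],
                          rep(seq_len(n_letters), nrow(prev)))
  }
  out  # index by length + 1
}

chars_of <- function(m, alphabet = c("a", "b", "c")) {
  apply(m, 1, function(r) paste(alphabet[r], collapse = ""))
}

# Levenshtein-ratio DP oracle vectorized across all pairs of two string
# groups (rows of integer matrices A and B). Independent of utils::adist.
dp_lr_group <- function(A, B) {
  na <- nrow(A); nb <- nrow(B); la <- ncol(A); lb <- ncol(B)
  np <- na * nb
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  prev <- matrix(rep(0:lb, each = np), nrow = np)
  for (i in seq_len(la)) {
    cur <- matrix(0L, np, lb + 1)
    cur[, 1] <- i
    ai <- A[ia, i]
    for (j in seq_len(lb)) {
      cost <- as.integer(ai != B[ib, j])
      cur[, j + 1] <- pmin(prev[, j + 1] + 1L, cur[, j] + 1L, prev[, j] + cost)
    }
    prev <- cur
  }
  d <- prev[, lb + 1]
  lensum <- la + lb
  if (lensum == 0) rep(1, np) else (lensum - d) / lensum
}

# Per-instance metric counting, the independent oracle for
# metrics_from_confusion.
count_metrics <- function(actual, predicted, classes) {
  out <- lapply(classes, function(cls) {
    tp <- sum(actual == cls & predicted == cls)
    fp <- sum(actual != cls & predicted == cls)
    fn <- sum(actual == cls & predicted != cls)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  })
  do.call(rbind, out)
}

default_resources <- function(spec) {
  bd_resources(spec$lexicon, clusters = generate_cluster_table(spec),
               name_lexicon = generate_names(spec))
}
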