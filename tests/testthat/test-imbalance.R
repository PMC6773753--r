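test_that("the Levenshtein ratio follows its closed form", {
  expect_equal(levenshtein_ratio("abc", "abc"), 1)
  expect_equal(levenshtein_ratio("kitten", "sitting"), 10 / 13)
  expect_equal(levenshtein_ratio("", "a"), 0)
  expect_equal(levenshtein_ratio("", ""), 1)  # documented convention
  # symmetry
  a <- c("abba", "cab", "b", "abcabc")
  b <- c("bab", "abc", "", "cba")
  expect_equal(levenshtein_ratio(a, b), levenshtein_ratio(b, a))
})

test_that("the ratio agrees with a brute-force recursive oracle", {
  withr::with_seed(71, {
    alphabet <- c("a", "b", "c")
    rand_str <- function() {
      paste(sample(alphabet, sample(0:5, 1), replace = TRUE), collapse = "")
    }
    for (i in 1:40) {
      x <- rand_str(); y <- rand_str()
      expect_equal(levenshtein_ratio(x, y), recursive_lr(x, y),
                   info = paste(x, y))
    }
  })
  expect_equal(levenshtein_ratio("abc", "cba"), recursive_lr("abc", "cba"))
})

test_that("similarity under-sampling keeps the first of each duplicate cluster", {
  corpus <- make_corpus(
    c("totally original minority tweet",
      "breaking news story about defects",
      "breaking news story about defects",
      "completely different headline here"),
    labels = c("defect", "non_defect", "non_defect", "non_defect"))
  out <- undersample_similarity_all(corpus, k = 0.9)
  expect_equal(out$tweet_id, c("1", "2", "4"))
  # all-distinct majority at high k: nothing removed
  distinct <- make_corpus(c("alpha bravo", "charlie delta", "echo foxtrot"),
                          labels = "non_defect")
  expect_equal(nrow(undersample_similarity_all(distinct, k = 0.99)), 3)
  # five near-duplicates of one headline collapse to one at k = 0.8
  dups <- c("state opens new defect clinic today",
            "state opens new defect clinic today!",
            "state opens new defect clinic today!!",
            "state opens a new defect clinic today",
            "state opens new defect clinic  today")
  lr <- lr_matrix(dups, dups[1])
  expect_true(all(lr > 0.8))
  out <- undersample_similarity_all(make_corpus(dups, "non_defect"), k = 0.8)
  expect_equal(nrow(out), 1)
  expect_equal(out$text, dups[1])
})

test_that("larger k removes a subset of what smaller k removes", {
  spec <- generator_spec(n_tweets = 300, seed = 41, frac_near_duplicate = 0.3)
  corpus <- classic_normalize(generate_tweets(spec),
                              build_patterns(spec$lexicon))
  lo <- undersample_similarity_all(corpus, k = 0.7)
  hi <- undersample_similarity_all(corpus, k = 0.95)
  removed_lo <- setdiff(corpus$tweet_id, lo$tweet_id)
  removed_hi <- setdiff(corpus$tweet_id, hi$tweet_id)
  expect_gt(length(removed_lo), 0)
  expect_true(all(removed_hi %in% removed_lo))
})

test_that("anchor-based under-sampling removes only near-anchor majority tweets", {
  corpus <- make_corpus(
    c("ambiguous minority sounding tweet",
      "ambiguous minority sounding tweets",   # near the anchor
      "completely unrelated headline text"),
    labels = c("possible_defect", "non_defect", "non_defect"))
  anchors <- "ambiguous minority sounding tweet"
  out <- undersample_similarity_fn(corpus, anchors, k = 0.7)
  expect_equal(out$tweet_id, c("1", "3"))
  # anchor equal to a majority tweet: removed at any k < 1
  eq <- make_corpus(c("exact anchor text"), "non_defect")
  expect_equal(nrow(undersample_similarity_fn(eq, "exact anchor text",
                                              k = 0.95)), 0)
  # empty anchor list leaves the corpus unchanged
  expect_equal(undersample_similarity_fn(corpus, character(0), k = 0.5),
               corpus)
})

test_that("random under-sampling is reproducible and preserves minorities", {
  spec <- generator_spec(n_tweets = 200, seed = 17)
  corpus <- generate_tweets(spec)
  n_min <- sum(corpus$label != "non_defect")
  out1 <- undersample_random(corpus, target_size = 100, seed = 5)
  out2 <- undersample_random(corpus, target_size = 100, seed = 5)
  expect_identical(out1, out2)
  expect_equal(nrow(out1), 100)
  expect_equal(sum(out1$label != "non_defect"), n_min)
  expect_identical(undersample_random(corpus, nrow(corpus), seed = 1),
                   corpus)
  expect_error(undersample_random(corpus, n_min - 1, seed = 1),
               "minority")
})

test_that("replacement over-sampling multiplies whole minority sets", {
  corpus <- make_corpus(
    c(sprintf("minority tweet number %s", letters[1:5]),
      sprintf("majority tweet number %s", seq_len(50))),
    labels = c(rep("defect", 5), rep("non_defect", 50)))
  out <- oversample_replacement(corpus, seed = 2)
  counts <- table(out$label)
  expect_equal(unname(counts["defect"]), 50)      # m = 10
  expect_equal(unname(counts["non_defect"]), 50)  # majority unchanged
  # floor rule: 7 vs 50 gives 49, "nearly equal"
  corpus7 <- make_corpus(
    c(sprintf("minority tweet number %s", letters[1:7]),
      sprintf("majority tweet number %s", seq_len(50))),
    labels = c(rep("possible_defect", 7), rep("non_defect", 50)))
  out7 <- oversample_replacement(corpus7, seed = 2)
  expect_equal(unname(table(out7$label)["possible_defect"]), 49)
  # each minority tweet appears exactly m times
  expect_true(all(table(out$text[out$label == "defect"]) == 10))
})

test_that("SMOTE interpolates inside the minority bounding box", {
  withr::with_seed(8, {
    x_min <- matrix(runif(12 * 4), 12, 4)
    x_maj <- matrix(runif(40 * 4) + 2, 40, 4)
  })
  m <- Matrix::Matrix(rbind(x_min, x_maj), sparse = TRUE)
  colnames(m) <- paste0("f", 1:4)
  fm <- feature_matrix(m)
  labels <- c(rep("defect", 12), rep("non_defect", 40))
  out <- smote_oversample(fm, labels, seed = 3)
  expect_equal(sum(out$labels == "defect"), 40)
  expect_equal(sum(out$labels == "non_defect"), 40)
  # original rows (in particular the majority) are unchanged
  expect_equal(as.matrix(out$features$m[seq_len(52), ]),
               as.matrix(fm$m[, colnames(out$features$m)]),
               ignore_attr = TRUE)
  syn <- as.matrix(out$features$m[out$labels == "defect", ])[-seq_len(12), ]
  box <- as.matrix(fm$m[seq_len(12), colnames(out$features$m)])
  for (j in seq_len(ncol(syn))) {
    expect_true(all(syn[, j] >= min(box[, j]) - 1e-12))
    expect_true(all(syn[, j] <= max(box[, j]) + 1e-12))
  }
})

test_that("SMOTE with identical minority points reproduces them exactly", {
  m <- Matrix::Matrix(rbind(matrix(0.5, 7, 3), matrix(0, 20, 3)),
                      sparse = TRUE)
  colnames(m) <- paste0("f", 1:3)
  labels <- c(rep("defect", 7), rep("non_defect", 20))
  out <- smote_oversample(feature_matrix(m), labels, seed = 1)
  syn <- as.matrix(out$features$m[28:40, ])
  expect_true(all(abs(syn - 0.5) < 1e-12))
  # too-small class refused
  small <- c(rep("defect", 4), rep("non_defect", 23))
  expect_error(smote_oversample(feature_matrix(m), small, seed = 1),
               "fewer than")
})

test_that("all under-sampling methods preserve the minority multiset", {
  spec <- generator_spec(n_tweets = 250, seed = 29, frac_near_duplicate = 0.25)
  corpus <- classic_normalize(generate_tweets(spec),
                              build_patterns(spec$lexicon))
  minority <- sort(corpus$text[corpus$label != "non_defect"])
  for (out in list(undersample_similarity_all(corpus, k = 0.8),
                   undersample_similarity_fn(corpus, corpus$classic_text[1],
                                             k = 0.8),
                   undersample_random(corpus, 150, seed = 4))) {
    expect_equal(sort(out$text[out$label != "non_defect"]), minority)
    expect_true(all(out$tweet_id %in% corpus$tweet_id))
  }
})
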