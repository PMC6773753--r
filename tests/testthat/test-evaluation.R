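test_that("ceiling-rounded stratified split sizes match the bookkeeping", {
  sizes <- split_sizes(c(defect = 1192, possible_defect = 1196,
                         non_defect = 20611))
  expect_equal(sizes$test, c(239, 240, 4123))
  expect_equal(sum(sizes$test), 4602)
  expect_equal(sizes$dev, c(191, 192, 3298))
  expect_equal(sum(sizes$dev), 3681)
  expect_equal(sum(sizes$train), 14716)
  expect_equal(split_sizes(c(a = 10, b = 10, c = 10))$test, c(2, 2, 2))
})

test_that("stratified splits are seeded, disjoint and exhaustive", {
  corpus <- generate_tweets(generator_spec(n_tweets = 400, seed = 3))
  s1 <- stratified_split(corpus, seed = 9)
  s2 <- stratified_split(corpus, seed = 9)
  expect_identical(s1$split, s2$split)
  expect_false(identical(s1$split, stratified_split(corpus, seed = 10)$split))
  expect_false(anyNA(s1$split))
  # per-class sizes follow the ceiling rule
  for (cls in tweet_classes()) {
    n <- sum(corpus$label == cls)
    n_test <- sum(s1$label == cls & s1$split == "test")
    expect_equal(n_test, ceiling(0.2 * n))
    n_dev <- sum(s1$label == cls & s1$split == "dev")
    expect_equal(n_dev, ceiling(0.2 * (n - n_test)))
  }
  tiny <- make_corpus(c("one tweet", "two tweet"), c("defect", "defect"))
  expect_error(stratified_split(tiny, seed = 1), "too small")
})

test_that("confusion matrices count correctly and ignore instance order", {
  actual <- c("defect", "possible_defect", "non_defect")
  perfect <- confusion(actual, actual)
  expect_equal(unname(diag(perfect)), c(1, 1, 1))
  expect_equal(sum(perfect), 3)
  wrong <- confusion(actual, c("possible_defect", "non_defect", "defect"))
  expect_equal(unname(diag(wrong)), c(0, 0, 0))
  withr::with_seed(4, {
    a <- sample(tweet_classes(), 60, replace = TRUE)
    p <- sample(tweet_classes(), 60, replace = TRUE)
    ord <- sample(60)
  })
  expect_equal(confusion(a, p), confusion(a[ord], p[ord]))
})

test_that("metrics match per-instance counting on random prediction sets", {
  expect_equal(metrics_from_confusion(as_confusion(diag(3)))$f1, rep(1, 3))
  withr::with_seed(21, {
    for (rep in 1:40) {
      n <- sample(5:50, 1)
      a <- sample(tweet_classes(), n, replace = TRUE)
      p <- sample(tweet_classes(), n, replace = TRUE)
      got <- metrics_from_confusion(confusion(a, p, classes = tweet_classes()))
      want <- count_metrics(a, p, tweet_classes())
      expect_equal(got$precision, unname(want[, "precision"]))
      expect_equal(got$recall, unname(want[, "recall"]))
      expect_equal(got$f1, unname(want[, "f1"]))
    }
  })
})

test_that("degenerate all-one-class predictions flag undefined metrics", {
  a <- c("defect", "defect", "non_defect")
  p <- rep("defect", 3)
  m <- metrics_from_confusion(confusion(a, p, classes = tweet_classes()))
  expect_equal(m$recall[m$class == "defect"], 1)
  expect_equal(m$recall[m$class == "non_defect"], 0)
  expect_true(m$undefined[m$class == "possible_defect"])
  expect_equal(m$precision[m$class == "possible_defect"], 0)
})

test_that("two-class collapse pools the minority classes", {
  a <- c("defect", "possible_defect", "non_defect", "non_defect")
  p <- rep("defect", 4)
  out <- collapse_two_class(a, p)
  expect_equal(out$metrics$recall, 1)  # all positives predicted positive
  expect_equal(out$metrics$precision, 0.5)
  expect_equal(sum(out$confusion), 4)
})

test_that("PR curves and AUC behave at the boundaries and under rank maps", {
  actual <- c(rep("defect", 5), rep("non_defect", 15))
  perfect <- seq(1, 0.05, length.out = 20)
  curve <- pr_curve(actual, perfect, positive = "defect")
  expect_equal(auc_pr(curve), 1)
  expect_equal(curve$precision[curve$recall == 1][1], 1)
  # precision at full recall equals prevalence for any scores
  withr::with_seed(6, scores <- runif(20))
  c2 <- pr_curve(actual, scores, positive = "defect")
  expect_equal(min(c2$precision[c2$recall == 1]), 0.25, tolerance = 1e-12)
  # strictly monotone transform leaves curve and AUC unchanged
  c3 <- pr_curve(actual, qlogis(scores / 2 + 0.25), positive = "defect")
  expect_equal(c3$recall, c2$recall)
  expect_equal(c3$precision, c2$precision)
  expect_equal(auc_pr(c3), auc_pr(c2))
})

test_that("random scores give PR-AUC near the positive prevalence", {
  withr::with_seed(77, {
    actual <- sample(c("defect", "non_defect"), 2000, replace = TRUE,
                     prob = c(0.3, 0.7))
    scores <- runif(2000)
  })
  curve <- pr_curve(actual, scores, positive = "defect")
  expect_equal(auc_pr(curve), mean(actual == "defect"), tolerance = 0.05)
})

test_that("ablation reproduces the standard run and ignores empty groups", {
  spec <- generator_spec(n_tweets = 350, seed = 47)
  corpus <- generate_tweets(spec)
  res <- default_resources(spec)
  sp <- stratified_split(corpus, seed = 5)
  train <- sp[sp$split == "train", ]
  test <- sp[sp$split == "test", ]
  tab <- ablation(train, test, res, classifier = "svm", seed = 5,
                  subsets = list(all = c("ngrams", "clusters", "lengths"),
                                 wo_clusters = c("ngrams", "lengths")))
  std <- evaluate_pipeline(train_pipeline(train, res, classifier = "svm",
                                          seed = 5), test)
  all_rows <- tab[tab$subset == "all", c("precision", "recall", "f1")]
  expect_equal(as.data.frame(all_rows),
               as.data.frame(std$metrics[, c("precision", "recall", "f1")]))

  # a cluster table whose words never occur yields an all-zero group whose
  # removal changes nothing
  ghost <- tibble::tibble(word = c("zzzz", "qqqq"),
                          cluster = c("0001", "0010"), count = c(1L, 1L))
  res_ghost <- bd_resources(spec$lexicon, clusters = ghost,
                            name_lexicon = generate_names(spec))
  tab2 <- ablation(train, test, res_ghost, classifier = "svm", seed = 5,
                   subsets = list(all = c("ngrams", "clusters", "lengths"),
                                  wo_clusters = c("ngrams", "lengths")))
  expect_equal(
    as.data.frame(tab2[tab2$subset == "all", c("precision", "recall", "f1")]),
    as.data.frame(tab2[tab2$subset == "wo_clusters",
                       c("precision", "recall", "f1")]))
})

test_that("the sampling comparison harness evaluates every plan on one test set", {
  spec <- generator_spec(n_tweets = 350, seed = 53, frac_near_duplicate = 0.3)
  corpus <- generate_tweets(spec)
  res <- default_resources(spec)
  sp <- stratified_split(corpus, seed = 3)
  train <- sp[sp$split == "train", ]
  test <- sp[sp$split == "test", ]
  plans <- list(sampling_plan("none"),
                sampling_plan("similarity_all", k = 0.85),
                sampling_plan("random_under", seed = 1),  # size from above
                sampling_plan("oversample_replacement", seed = 1),
                sampling_plan("smote", seed = 1))
  tab <- sampling_comparison(train, test, res, plans, classifiers = "svm",
                             seed = 3)
  expect_equal(nrow(tab), 5 * 3)
  base <- evaluate_pipeline(train_pipeline(train, res, classifier = "svm",
                                           seed = 3), test)
  none_rows <- tab[tab$plan == "none", ]
  expect_equal(none_rows$f1, base$metrics$f1)
  # the random control adopted the similarity plan's resulting size
  sim_size <- unique(tab$train_size[tab$plan == "similarity_all"])
  expect_equal(unique(tab$train_size[tab$plan == "random_under"]), sim_size)
  expect_lt(sim_size, nrow(train))
  # over-sampling grows the training set, under-sampling shrinks it
  expect_gt(unique(tab$train_size[tab$plan == "oversample_replacement"]),
            nrow(train))
  expect_gt(unique(tab$train_size[tab$plan == "smote"]), nrow(train))
})
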