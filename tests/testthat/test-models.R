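sparse_fm <- function(m, scaled = FALSE) {
  sm <- Matrix::Matrix(m, sparse = TRUE)
  fm <- feature_matrix(sm)
  if (scaled) fm <- scale_fit_transform(fm)
  fm
}

test_that("multinomial NB posteriors match hand-computed Bayes arithmetic", {
  # class x docs: (2,0) and (1,1); class y doc: (0,2); add-one smoothing
  m <- rbind(c(2, 0), c(1, 1), c(0, 2))
  colnames(m) <- c("fa", "fb")
  fm <- sparse_fm(m)
  fit <- train_nb(fm, c("x", "x", "y"), laplace = 1)
  # oracle: theta_x = (3+1, 1+1)/(4+2); theta_y = (0+1, 2+1)/(2+2)
  th_x <- c(4, 2) / 6
  th_y <- c(1, 3) / 4
  prior <- c(x = 2 / 3, y = 1 / 3)
  query <- rbind(c(3, 1))
  colnames(query) <- c("fa", "fb")
  lx <- log(prior["x"]) + 3 * log(th_x[1]) + 1 * log(th_x[2])
  ly <- log(prior["y"]) + 3 * log(th_y[1]) + 1 * log(th_y[2])
  oracle <- exp(c(lx, ly)) / sum(exp(c(lx, ly)))
  p <- predict(fit, sparse_fm(query), type = "prob")
  expect_equal(as.numeric(p), unname(oracle), tolerance = 1e-12)
  expect_equal(as.character(predict(fit, sparse_fm(query))), "x")
})

test_that("NB degenerate and separable cases behave", {
  m <- rbind(c(1, 0), c(2, 0))
  colnames(m) <- c("fa", "fb")
  fit <- train_nb(sparse_fm(m), c("defect", "defect"))
  p <- predict(fit, sparse_fm(m), type = "prob")
  expect_true(all(p[, "defect"] == 1))
  # two perfectly separated one-feature classes
  m2 <- rbind(c(5, 0), c(0, 5))
  colnames(m2) <- c("fa", "fb")
  fit2 <- train_nb(sparse_fm(m2), c("defect", "non_defect"))
  expect_equal(as.character(predict(fit2, sparse_fm(m2))),
               c("defect", "non_defect"))
  neg <- rbind(c(-1, 0))
  colnames(neg) <- c("fa", "fb")
  expect_error(train_nb(sparse_fm(neg), "defect"), "non-negative")
})

test_that("the SVM refuses unscaled features and separates a toy problem", {
  m <- cbind(f = c(0.1, 0.2, 0.8, 0.9))
  fm <- sparse_fm(m)
  expect_error(train_svm(fm, c("a", "a", "b", "b")), "scaled")
  fm <- scale_fit_transform(fm)
  fit <- train_svm(fm, c("defect", "defect", "non_defect", "non_defect"))
  expect_equal(as.character(predict(fit, fm)),
               c("defect", "defect", "non_defect", "non_defect"))
  pr <- predict(fit, fm, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("raising the minority weight never lowers minority training recall", {
  withr::with_seed(12, {
    maj <- cbind(f1 = runif(40, 0, 0.6), f2 = runif(40, 0, 0.6))
    mino <- cbind(f1 = runif(8, 0.4, 1), f2 = runif(8, 0.4, 1))
  })
  fm <- scale_fit_transform(sparse_fm(rbind(maj, mino)))
  labels <- c(rep("non_defect", 40), rep("defect", 8))
  recalls <- vapply(c(1, 2, 4, 8, 16), function(w) {
    fit <- train_svm(fm, labels,
                     class_weights = c(non_defect = 1, defect = w))
    pred <- predict(fit, fm)
    mean(pred[labels == "defect"] == "defect")
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("model predictions are order-invariant and survive persistence", {
  spec <- generator_spec(n_tweets = 300, seed = 19)
  corpus <- generate_tweets(spec)
  res <- default_resources(spec)
  sp <- stratified_split(corpus, seed = 2)
  train <- sp[sp$split == "train", ]
  test <- sp[sp$split == "test", ]
  for (clf in c("nb", "svm")) {
    fit <- train_pipeline(train, res, classifier = clf, seed = 2)
    p1 <- predict(fit, test)
    p2 <- predict(fit, test[rev(seq_len(nrow(test))), ])
    expect_identical(as.character(p1), rev(as.character(p2)))
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(fit, path)
    expect_identical(as.character(predict(load_model(path), test)),
                     as.character(p1))
  }
})

test_that("the LSTM is seed-deterministic and fits a two-pattern toy language", {
  toks <- c(rep(list(c("good", "baby", "news")), 10),
            rep(list(c("sad", "story", "here")), 10))
  labs <- rep(c("defect", "non_defect"), each = 10)
  emb <- random_embeddings(c("good", "baby", "news", "sad", "story", "here"),
                           dim = 8, seed = 2)
  m1 <- train_lstm(toks, labs, emb, units = 16, max_len = 6, epochs = 15,
                   seed = 3)
  m2 <- train_lstm(toks, labs, emb, units = 16, max_len = 6, epochs = 15,
                   seed = 3)
  expect_identical(m1$par, m2$par)
  expect_equal(mean(as.character(predict(m1, toks)) == labs), 1)
  pr <- predict(m1, toks, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 20), tolerance = 1e-12)
  # persistence within floating tolerance
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m1, path)
  expect_equal(predict(load_model(path), toks, type = "prob"), pr,
               tolerance = 1e-12)
  # over-long sequences are truncated with a report
  long <- list(rep("good", 10))
  expect_message(predict(m1, long), "truncated")
})

test_that("pipeline SVM beats the majority baseline on synthetic data", {
  spec <- generator_spec(n_tweets = 600, seed = 37)
  corpus <- generate_tweets(spec)
  res <- default_resources(spec)
  sp <- stratified_split(corpus, seed = 7)
  fit <- train_pipeline(sp[sp$split == "train", ], res, classifier = "svm",
                        seed = 7)
  ev <- evaluate_pipeline(fit, sp[sp$split == "test", ])
  macro <- mean(ev$metrics$f1)
  # majority-class baseline: F1 only on non_defect
  base <- confusion(sp$label[sp$split == "test"],
                    rep("non_defect", sum(sp$split == "test")),
                    classes = tweet_classes())
  macro_base <- mean(metrics_from_confusion(base)$f1)
  expect_gt(macro, macro_base)
})
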