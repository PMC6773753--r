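#' Bundle the external resources a pipeline needs
#'
#' Collects the birth-defect lexicon (compiled to retrieval patterns), the
#' word-cluster table, the given-names lexicon, the deixis wordlists and,
#' for the sequence model, a word-embedding table.
#'
#' @param lexicon A `bd_lexicon`.
#' @param clusters Optional cluster table from [read_clusters()].
#' @param name_lexicon Optional names tibble from [read_names()].
#' @param wordlists Deixis wordlists, see [deixis_wordlists()].
#' @param embeddings Optional embedding matrix (words as row names).
#' @return A list of class `bd_resources`.
#' @export
bd_resources <- function(lexicon, clusters = NULL, name_lexicon = NULL,
                         wordlists = deixis_wordlists(), embeddings = NULL) {
  structure(list(lexicon = lexicon, patterns = build_patterns(lexicon),
                 clusters = clusters, name_lexicon = name_lexicon,
                 wordlists = wordlists, embeddings = embeddings),
            class = "bd_resources")
}

#' Train a full classification pipeline
#'
#' Runs the whole training side of the system on a labeled corpus:
#' classic-track normalization (or the embedding track for the LSTM), the
#' chosen data-level sampling plan, feature extraction, scaling (SVM), and
#' classifier training. The fitted object carries every fitted component
#' (vocabulary, scaling bounds, resources, plan, seed), so
#' [predict.bd_pipeline()] works on raw corpora.
#'
#' @param train A labeled `tweet_corpus`.
#' @param resources A `bd_resources` bundle.
#' @param classifier `"svm"`, `"nb"` or `"lstm"`.
#' @param plan A [sampling_plan()].
#' @param anchors Anchor strings for the `similarity_fn` plan (see
#'   [misclassified_anchors()]).
#' @param use_ngrams,use_clusters,use_lengths Feature-group toggles.
#' @param n N-gram orders.
#' @param cost SVM cost parameter.
#' @param binary Binary instead of count n-gram features.
#' @param min_df Minimum document frequency for n-grams.
#' @param seed Integer seed; per-stage substreams are derived from it.
#' @param lstm A list of overrides for [train_lstm()] arguments.
#' @return A fitted object of class `bd_pipeline`.
#' @export
train_pipeline <- function(train, resources,
                           classifier = c("svm", "nb", "lstm"),
                           plan = sampling_plan("none"), anchors = NULL,
                           use_ngrams = TRUE,
                           use_clusters = !is.null(resources$clusters),
                           use_lengths = TRUE, n = 1:3, cost = 100,
                           binary = FALSE, min_df = 1, seed = 1,
                           lstm = list()) {
  classifier <- match.arg(classifier)
  plan_seed <- plan$seed %||% seed
  if (classifier == "lstm") {
    train <- apply_corpus_plan(classic_normalize(
      train, resources$patterns, resources$name_lexicon,
      resources$wordlists), plan, anchors, plan_seed)
    if (plan$method == "smote") {
      stop("SMOTE operates in feature space and is not applicable to the LSTM",
           call. = FALSE)
    }
    train <- embed_normalize(train)
    if (is.null(resources$embeddings)) {
      stop("the LSTM needs an embedding table in the resources", call. = FALSE)
    }
    args <- modifyList(list(tokens = train$embed_tokens, labels = train$label,
                            embeddings = resources$embeddings, seed = seed),
                       lstm)
    model <- do.call(train_lstm, args)
    return(new_pipeline(classifier, model, resources, plan, seed,
                        train_size = nrow(train)))
  }

  train <- classic_normalize(train, resources$patterns,
                             resources$name_lexicon, resources$wordlists)
  train <- apply_corpus_plan(train, plan, anchors, plan_seed)
  vocab <- if (use_ngrams) {
    fit_ngrams(train$classic_tokens, n = n, min_df = min_df)
  }
  fm <- build_features(train, vocab = vocab,
                       cluster_table = resources$clusters, n = n,
                       use_ngrams = use_ngrams, use_clusters = use_clusters,
                       use_lengths = use_lengths, binary = binary)
  labels <- train$label
  if (classifier == "svm") fm <- scale_fit_transform(fm)
  if (plan$method == "smote") {
    sm <- smote_oversample(fm, labels, seed = plan_seed)
    fm <- sm$features
    labels <- sm$labels
  }
  model <- switch(classifier,
                  svm = train_svm(fm, labels, cost = cost),
                  nb = train_nb(fm, labels))
  new_pipeline(classifier, model, resources, plan, seed,
               train_size = length(labels), vocab = vocab,
               bounds = scaling_bounds(fm),
               feature_opts = list(use_ngrams = use_ngrams,
                                   use_clusters = use_clusters,
                                   use_lengths = use_lengths, n = n,
                                   binary = binary))
}

new_pipeline <- function(classifier, model, resources, plan, seed, train_size,
                         vocab = NULL, bounds = NULL, feature_opts = NULL) {
  structure(list(classifier = classifier, model = model,
                 resources = resources, plan = plan, seed = seed,
                 train_size = train_size, vocab = vocab, bounds = bounds,
                 feature_opts = feature_opts, classes = model$classes),
            class = "bd_pipeline")
}

# Corpus-level sampling (methods 1-4); SMOTE is applied in feature space.
apply_corpus_plan <- function(corpus, plan, anchors, seed) {
  switch(plan$method,
         none = ,
         smote = corpus,
         similarity_all = undersample_similarity_all(corpus, plan$k),
         similarity_fn = {
           if (is.null(anchors)) {
             stop("the similarity_fn plan needs misclassified dev-set anchors",
                  call. = FALSE)
           }
           undersample_similarity_fn(corpus, anchors, plan$k)
         },
         random_under = undersample_random(corpus, plan$target_size,
                                           seed = seed),
         oversample_replacement = oversample_replacement(corpus, seed = seed))
}

pipeline_features <- function(object, corpus) {
  corpus <- classic_normalize(corpus, object$resources$patterns,
                              object$resources$name_lexicon,
                              object$resources$wordlists)
  fo <- object$feature_opts
  fm <- build_features(corpus, vocab = object$vocab,
                       cluster_table = object$resources$clusters, n = fo$n,
                       use_ngrams = fo$use_ngrams,
                       use_clusters = fo$use_clusters,
                       use_lengths = fo$use_lengths, binary = fo$binary)
  if (!is.null(object$bounds)) fm <- scale_transform(fm, object$bounds)
  fm
}

#' @export
predict.bd_pipeline <- function(object, corpus, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  if (object$classifier == "lstm") {
    corpus <- embed_normalize(corpus)
    return(predict(object$model, corpus$embed_tokens, type = type))
  }
  predict(object$model, pipeline_features(object, corpus), type = type)
}

#' @export
print.bd_pipeline <- function(x, ...) {
  cat("<bd_pipeline> ", x$classifier, ", trained on ", x$train_size,
      " instances (plan: ", x$plan$method, ")\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted pipeline on a held-out corpus
#'
#' Predicts labels and class probabilities for every tweet, and derives the
#' confusion matrix and per-class precision/recall/F1.
#'
#' @param object A fitted `bd_pipeline`.
#' @param test A labeled `tweet_corpus`.
#' @return A list of class `bd_evaluation`: `predictions` (tibble with
#'   `tweet_id`, `actual`, `predicted` and one probability column per
#'   class), `confusion`, `metrics`.
#' @export
evaluate_pipeline <- function(object, test) {
  pred <- predict(object, test, type = "class")
  prob <- predict(object, test, type = "prob")
  predictions <- tibble::tibble(tweet_id = test$tweet_id,
                                actual = test$label,
                                predicted = as.character(pred))
  for (cls in colnames(prob)) predictions[[paste0("p_", cls)]] <- prob[, cls]
  cm <- confusion(predictions$actual, predictions$predicted,
                  classes = object$classes)
  structure(list(predictions = predictions, confusion = cm,
                 metrics = metrics_from_confusion(cm),
                 classifier = object$classifier),
            class = "bd_evaluation")
}

#' @export
print.bd_evaluation <- function(x, ...) {
  cat("<bd_evaluation> ", x$classifier, ", n = ",
      nrow(x$predictions), "\n", sep = "")
  m <- x$metrics
  m$precision <- round_display(m$precision)
  m$recall <- round_display(m$recall)
  m$f1 <- round_display(m$f1)
  print(m)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bd_evaluation <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.bd_evaluation <- function(x, ...) {
  acc <- sum(diag(x$confusion)) / sum(x$confusion)
  tibble::tibble(n = nrow(x$predictions), accuracy = acc,
                 macro_f1 = mean(x$metrics$f1))
}

#' Development-set anchors for boundary under-sampling
#'
#' Returns the classic-normalized texts of minority-class development tweets
#' that a preliminary pipeline misclassified as the majority class. These
#' are the anchors consumed by [undersample_similarity_fn()].
#'
#' @param object A fitted `bd_pipeline`.
#' @param dev A labeled development `tweet_corpus`.
#' @param majority The majority class label.
#' @return Character vector of anchor strings.
#' @export
misclassified_anchors <- function(object, dev, majority = "non_defect") {
  pred <- as.character(predict(object, dev, type = "class"))
  dev <- classic_normalize(dev, object$resources$patterns,
                           object$resources$name_lexicon,
                           object$resources$wordlists)
  dev$classic_text[dev$label != majority & pred == majority]
}

#' Feature-ablation study
#'
#' Retrains and evaluates the pipeline for each feature subset: all groups,
#' each group left out, n-grams only, and clusters only. The test set is
#' identical across rows.
#'
#' @param train,test Labeled corpora.
#' @param resources A `bd_resources` bundle.
#' @param subsets Named list of feature-group subsets (character vectors
#'   over `"ngrams"`, `"clusters"`, `"lengths"`).
#' @param classifier Classifier to ablate (default SVM).
#' @param ... Further arguments to [train_pipeline()].
#' @return A tibble: `subset`, `class`, `precision`, `recall`, `f1`.
#' @export
ablation <- function(train, test, resources, subsets = NULL,
                     classifier = "svm", ...) {
  subsets <- subsets %||% list(
    all = c("ngrams", "clusters", "lengths"),
    wo_ngrams = c("clusters", "lengths"),
    wo_clusters = c("ngrams", "lengths"),
    wo_lengths = c("ngrams", "clusters"),
    ngrams_only = "ngrams",
    clusters_only = "clusters"
  )
  rows <- purrr::imap(subsets, function(groups, nm) {
    fit <- train_pipeline(train, resources, classifier = classifier,
                          use_ngrams = "ngrams" %in% groups,
                          use_clusters = "clusters" %in% groups,
                          use_lengths = "lengths" %in% groups, ...)
    ev <- evaluate_pipeline(fit, test)
    dplyr::mutate(ev$metrics, subset = nm, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Compare data-level sampling strategies
#'
#' Trains one pipeline per (classifier, sampling plan) pair and evaluates
#' all of them on the same test set, reporting the resulting training size
#' and per-class F1. A `random_under` plan with no `target_size` is treated
#' as the control for the most recent similarity plan in the list and
#' automatically uses that plan's resulting training size.
#'
#' @param train,test Labeled corpora.
#' @param resources A `bd_resources` bundle.
#' @param plans List of [sampling_plan()] objects.
#' @param classifiers Character vector over `"nb"`, `"svm"`, `"lstm"`.
#' @param anchors Anchors for `similarity_fn` plans.
#' @param ... Further arguments to [train_pipeline()].
#' @return A tibble with one row per (classifier, plan, class).
#' @export
sampling_comparison <- function(train, test, resources, plans,
                                classifiers = c("nb", "svm"), anchors = NULL,
                                ...) {
  out <- list()
  for (clf in classifiers) {
    last_sim_size <- NA_integer_
    for (plan in plans) {
      if (plan$method %in% c("similarity_all", "similarity_fn")) {
        # record the size this plan produces, for the random control
        last_sim_size <- nrow(apply_corpus_plan(
          classic_normalize(train, resources$patterns,
                            resources$name_lexicon, resources$wordlists),
          plan, anchors, plan$seed %||% 1L))
      }
      if (plan$method == "random_under" && is.na(plan$target_size)) {
        if (is.na(last_sim_size)) {
          stop("random_under control has no target_size and no preceding ",
               "similarity plan", call. = FALSE)
        }
        plan <- sampling_plan("random_under", target_size = last_sim_size,
                              seed = plan$seed)
      }
      if (plan$method == "smote" && clf == "lstm") next
      fit <- train_pipeline(train, resources, classifier = clf, plan = plan,
                            anchors = anchors, ...)
      ev <- evaluate_pipeline(fit, test)
      m <- ev$metrics
      plan_method <- plan$method
      plan_k <- plan$k
      out <- c(out, list(tibble::tibble(
        classifier = clf, plan = plan_method,
        k = plan_k, train_size = fit$train_size,
        class = m$class, precision = m$precision, recall = m$recall,
        f1 = m$f1)))
    }
  }
  dplyr::bind_rows(out)
}
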