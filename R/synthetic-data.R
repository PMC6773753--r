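# Seeded generator of synthetic labeled tweet corpora. The generated corpora
# reproduce the statistical and linguistic structure the classifiers exploit
# -- the ~5%/5%/90% class imbalance, possessive+child references with a
# lexicon term in the "defect" class, ambiguous names/pronouns and hedging in
# "possible defect", reported speech / fundraisers / near-duplicate headlines
# in "non-defect", plus usernames, URLs, hashtag-fused references and
# (optionally) retweets -- so every pipeline stage is testable offline.
# Templates are data (a bundled TSV), not code.

#' Synthetic birth-defect lexicon
#'
#' A small lexicon of common birth-defect terms with planted misspelling
#' variants, used by the synthetic generator and for offline tests in place
#' of the full several-hundred-term social-media lexicon.
#'
#' @param extra Additional terms to include.
#' @return A `bd_lexicon` tibble.
#' @export
synthetic_lexicon <- function(extra = c("spina bifida", "cleft palate",
                                        "craniosynostosis",
                                        "hypoplastic left heart syndrome")) {
  base <- read_lexicon(
    system.file("extdata", "birth_defect_terms.txt", package = "bdcohort"),
    system.file("extdata", "birth_defect_variants.tsv", package = "bdcohort"))
  if (length(extra) > 0) {
    base <- dplyr::bind_rows(base,
                             tibble::tibble(term = tolower(extra),
                                            variants = rep(list(character()),
                                                           length(extra))))
    base <- base[!duplicated(base$term), ]
    class(base) <- unique(c("bd_lexicon", class(base)))
  }
  base
}

#' Specification for the synthetic corpus generator
#'
#' All knobs of the generator: the corpus size, the class proportions
#' (default the natural ~5.2%/5.2%/89.6% imbalance), the seed, one fraction
#' per error-analysis phenomenon, decoration rates, and label noise.
#'
#' @param n_tweets Number of tweets.
#' @param class_props Proportions for defect/possible_defect/non_defect;
#'   must sum to 1. Counts are allocated by largest-remainder rounding.
#' @param seed Integer seed; the same spec generates a byte-identical corpus.
#' @param frac_implicit_relation Fraction of `defect` tweets that imply
#'   rather than state the having-relation.
#' @param frac_hashtag_fused Fraction of `defect` tweets whose child/defect
#'   reference is fused into hashtags.
#' @param frac_modifier_interrupted Fraction of `defect` tweets with a
#'   modifier interrupting the possessive pattern ("my unborn daughter").
#' @param frac_name_deixis Fraction of `possible_defect` tweets whose
#'   referent is a bare personal name.
#' @param frac_reported_speech,frac_fundraiser Fractions of `non_defect`
#'   tweets that relay someone else's statement / solicit donations.
#' @param frac_near_duplicate Fraction of `non_defect` tweets drawn from
#'   small clusters of near-identical headlines (what similarity
#'   under-sampling removes).
#' @param rate_username,rate_url,rate_hashtag,rate_retweet Decoration rates.
#'   Retweets default to 0 because the labeled corpus emulates data that has
#'   already passed the retrieval post-filters.
#' @param label_noise Probability of replacing a label with a random other
#'   class (default 0).
#' @param lexicon The `bd_lexicon` whose terms are embedded.
#' @param templates_path Override for the bundled template file.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_tweets = 1000,
                           class_props = c(defect = 0.052,
                                           possible_defect = 0.052,
                                           non_defect = 0.896),
                           seed = 1,
                           frac_implicit_relation = 0.2,
                           frac_hashtag_fused = 0.15,
                           frac_modifier_interrupted = 0.1,
                           frac_name_deixis = 0.5,
                           frac_reported_speech = 0.3,
                           frac_fundraiser = 0.2,
                           frac_near_duplicate = 0.2,
                           rate_username = 0.1, rate_url = 0.1,
                           rate_hashtag = 0.15, rate_retweet = 0,
                           label_noise = 0,
                           lexicon = synthetic_lexicon(),
                           templates_path = NULL) {
  stopifnot(n_tweets >= 3, abs(sum(class_props) - 1) < 1e-8)
  fr <- c(frac_implicit_relation, frac_hashtag_fused,
          frac_modifier_interrupted, frac_name_deixis, frac_reported_speech,
          frac_fundraiser, frac_near_duplicate, rate_username, rate_url,
          rate_hashtag, rate_retweet, label_noise)
  stopifnot(all(fr >= 0), all(fr <= 1))
  if (frac_implicit_relation + frac_hashtag_fused + frac_modifier_interrupted > 1) {
    stop("defect phenomenon fractions exceed 1", call. = FALSE)
  }
  if (frac_reported_speech + frac_fundraiser + frac_near_duplicate > 1) {
    stop("non-defect phenomenon fractions exceed 1", call. = FALSE)
  }
  structure(list(n_tweets = as.integer(n_tweets), class_props = class_props,
                 seed = as.integer(seed),
                 frac_implicit_relation = frac_implicit_relation,
                 frac_hashtag_fused = frac_hashtag_fused,
                 frac_modifier_interrupted = frac_modifier_interrupted,
                 frac_name_deixis = frac_name_deixis,
                 frac_reported_speech = frac_reported_speech,
                 frac_fundraiser = frac_fundraiser,
                 frac_near_duplicate = frac_near_duplicate,
                 rate_username = rate_username, rate_url = rate_url,
                 rate_hashtag = rate_hashtag, rate_retweet = rate_retweet,
                 label_noise = label_noise, lexicon = lexicon,
                 templates_path = templates_path),
            class = "generator_spec")
}

read_templates <- function(spec) {
  path <- spec$templates_path %||%
    system.file("extdata", "synthetic_templates.tsv", package = "bdcohort")
  tpl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("class", "phenomenon", "template") %in% names(tpl)))
  tibble::as_tibble(tpl)
}

name_pool <- function() {
  read_names(system.file("extdata", "synthetic_names.txt",
                         package = "bdcohort"))$name
}

# Largest-remainder allocation of n into proportions (ties by order).
largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic labeled tweet corpus
#'
#' @param spec A [generator_spec()].
#' @return A `tweet_corpus` tibble with `n_tweets` rows.
#' @export
#' @examples
#' corpus <- generate_tweets(generator_spec(n_tweets = 200, seed = 7))
#' class_counts(corpus)
generate_tweets <- function(spec) {
  if (nrow(spec$lexicon) == 0) stop("lexicon is empty", call. = FALSE)
  templates <- read_templates(spec)
  withr::with_seed(spec$seed, generate_impl(spec, templates))
}

generate_impl <- function(spec, templates) {
  counts <- largest_remainder(spec$n_tweets, spec$class_props)
  names(counts) <- names(spec$class_props)
  names_p <- name_pool()
  handles <- paste0("@", sample(names_p), sample(10:99, length(names_p),
                                                 replace = TRUE))
  terms <- spec$lexicon$term

  # near-duplicate headline clusters: a few fixed filled headlines that the
  # near_duplicate phenomenon copies with small perturbations
  headline_tpl <- templates$template[templates$class == "non_defect" &
                                       templates$phenomenon == "headline"]
  n_dup <- round(spec$frac_near_duplicate * counts["non_defect"])
  n_clusters <- max(1, ceiling(n_dup / 8))
  cluster_headlines <- vapply(seq_len(n_clusters), function(i) {
    fill_template(sample(headline_tpl, 1), sample(terms, 1), spec$lexicon,
                  names_p, handles, use_variant = FALSE)
  }, character(1))

  rows <- list()
  for (cls in names(counts)) {
    n_c <- counts[[cls]]
    if (n_c == 0) next
    phen <- sample_phenomena(spec, cls, n_c)
    texts <- character(n_c)
    for (i in seq_len(n_c)) {
      if (phen[i] == "near_duplicate") {
        base <- sample(cluster_headlines, 1)
        perturb <- sample(c("", "!", " please share", " via our page"), 1,
                          prob = c(0.6, 0.2, 0.1, 0.1))
        texts[i] <- paste0(base, perturb)
      } else {
        pool <- templates$template[templates$class == cls &
                                     templates$phenomenon == phen[i]]
        term <- sample(terms, 1)
        texts[i] <- fill_template(sample(pool, 1), term, spec$lexicon,
                                  names_p, handles,
                                  use_variant = runif(1) < 0.15)
      }
      texts[i] <- decorate(texts[i], spec, handles)
    }
    rows[[cls]] <- tibble::tibble(text = texts, label = cls)
  }
  out <- dplyr::bind_rows(rows)
  out <- out[sample.int(nrow(out)), ]
  if (spec$label_noise > 0) {
    flip <- runif(nrow(out)) < spec$label_noise
    out$label[flip] <- vapply(out$label[flip], function(l) {
      sample(setdiff(TWEET_CLASSES, l), 1)
    }, character(1))
  }
  tweet_corpus(
    tweet_id = sprintf("t%06d", seq_len(nrow(out))),
    user_id = paste0("u", sample(ceiling(nrow(out) / 2), nrow(out),
                                 replace = TRUE)),
    text = out$text, label = out$label,
    provenance = paste0("synthetic(seed=", spec$seed, ")")
  )
}

sample_phenomena <- function(spec, cls, n) {
  probs <- switch(cls,
    defect = c(hashtag_fused = spec$frac_hashtag_fused,
               modifier_interrupted = spec$frac_modifier_interrupted,
               implicit = spec$frac_implicit_relation,
               plain = 1 - spec$frac_hashtag_fused -
                 spec$frac_modifier_interrupted - spec$frac_implicit_relation),
    possible_defect = c(name_deixis = spec$frac_name_deixis,
                        pronoun = (1 - spec$frac_name_deixis) / 3,
                        hedge = (1 - spec$frac_name_deixis) / 3,
                        no_referent = (1 - spec$frac_name_deixis) / 3),
    non_defect = c(reported_speech = spec$frac_reported_speech,
                   fundraiser = spec$frac_fundraiser,
                   near_duplicate = spec$frac_near_duplicate,
                   headline = (1 - spec$frac_reported_speech -
                                 spec$frac_fundraiser -
                                 spec$frac_near_duplicate) / 2,
                   info = (1 - spec$frac_reported_speech -
                             spec$frac_fundraiser -
                             spec$frac_near_duplicate) / 2))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

fill_template <- function(tpl, term, lexicon, names_p, handles,
                          use_variant = FALSE) {
  v <- lexicon$variants[[match(term, lexicon$term)]]
  surface <- if (use_variant && length(v) > 0) sample(v, 1) else term
  txt <- tpl
  txt <- stringr::str_replace_all(txt, stringr::fixed("{term}"), surface)
  txt <- stringr::str_replace_all(txt, stringr::fixed("{hterm}"),
                                  paste0("#", gsub(" ", "", surface)))
  txt <- stringr::str_replace_all(txt, stringr::fixed("{fpp}"),
                                  sample(c("my", "our"), 1))
  txt <- stringr::str_replace_all(
    txt, stringr::fixed("{childword}"),
    sample(c("son", "daughter", "baby", "kid", "child"), 1))
  txt <- stringr::str_replace_all(txt, stringr::fixed("{tp}"),
                                  sample(c("she", "he"), 1))
  txt <- stringr::str_replace_all(txt, stringr::fixed("{name}"),
                                  str_capitalize(sample(names_p, 1)))
  txt <- stringr::str_replace_all(
    txt, stringr::fixed("{emo}"),
    sample(c("blessed", "proud", "grateful", "thankful", "strong", "brave"), 1))
  txt <- stringr::str_replace_all(txt, stringr::fixed("{hfused}"),
                                  paste0("#lovemy", sample(c("girl", "boy"), 1)))
  txt <- stringr::str_replace_all(txt, stringr::fixed("{user}"),
                                  sample(handles, 1))
  txt <- stringr::str_replace_all(txt, stringr::fixed("{url}"), random_url())
  str_capitalize(txt)
}

str_capitalize <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

random_url <- function() {
  paste0("http://t.co/", paste(sample(c(letters, 0:9), 6, replace = TRUE),
                               collapse = ""))
}

decorate <- function(text, spec, handles) {
  if (runif(1) < spec$rate_username) {
    text <- paste0(sample(handles, 1), " ", text)
  }
  if (runif(1) < spec$rate_url && !grepl("http://", text, fixed = TRUE)) {
    text <- paste0(text, " ", random_url())
  }
  if (runif(1) < spec$rate_hashtag) {
    text <- paste0(text, " #",
                   sample(c("awareness", "blessed", "family", "love"), 1))
  }
  if (runif(1) < spec$rate_retweet) {
    text <- paste0("RT ", sample(handles, 1), ": ", text)
  }
  text
}

#' Synthetic cluster table and name lexicon
#'
#' Fixture counterparts of the external word-cluster and given-name
#' resources, consistent with the vocabulary the generator emits: every
#' non-placeholder template word, slot filler, name and lexicon word has a
#' cluster path, and each planted misspelling variant maps to its canonical
#' word's path.
#'
#' @param spec A [generator_spec()].
#' @return `generate_cluster_table()`: a tibble (`word`, `cluster`,
#'   `count`); `generate_names()`: a tibble (`name`).
#' @export
generate_cluster_table <- function(spec = generator_spec()) {
  templates <- read_templates(spec)
  tpl_words <- unlist(stringr::str_split(
    stringr::str_replace_all(templates$template, "\\{[a-z]+\\}", " "), "\\s+"))
  fillers <- c("my", "our", "son", "daughter", "baby", "kid", "child", "she",
               "he", "blessed", "proud", "grateful", "thankful", "strong",
               "brave", "lovemygirl", "lovemyboy", "awareness", "family",
               "love", "please", "share", "via", "page")
  term_words <- unlist(stringr::str_split(spec$lexicon$term, "\\s+"))
  vocab <- unique(tolower(c(tpl_words, fillers, term_words, name_pool())))
  vocab <- vocab[nzchar(vocab) & grepl("^[a-z]+$", vocab)]
  if (length(vocab) == 0) stop("empty vocabulary", call. = FALSE)
  path_of <- function(i) {
    paste(rev(as.integer(intToBits(i))[1:12]), collapse = "")
  }
  tab <- tibble::tibble(word = vocab,
                        cluster = vapply(seq_along(vocab), path_of, ""),
                        count = 1000L - seq_along(vocab))
  # planted misspellings share the canonical word's path, word by word;
  # variants that do not align with the term get paths of their own
  extra <- list()
  n_extra_paths <- 0L
  for (i in seq_len(nrow(spec$lexicon))) {
    tw <- strsplit(spec$lexicon$term[i], " ", fixed = TRUE)[[1]]
    for (v in spec$lexicon$variants[[i]]) {
      vw <- strsplit(v, " ", fixed = TRUE)[[1]]
      aligned <- length(vw) == length(tw)
      for (j in seq_along(vw)) {
        if (vw[j] %in% tab$word) next
        cl <- if (aligned && tw[j] %in% tab$word) {
          tab$cluster[match(tw[j], tab$word)]
        } else {
          n_extra_paths <- n_extra_paths + 1L
          path_of(length(vocab) + n_extra_paths)
        }
        extra[[length(extra) + 1]] <- tibble::tibble(word = vw[j],
                                                     cluster = cl, count = 5L)
      }
    }
  }
  out <- dplyr::bind_rows(c(list(tab), extra))
  out[!duplicated(out$word), ]
}

#' @rdname generate_cluster_table
#' @export
generate_names <- function(spec = generator_spec()) {
  tibble::tibble(name = name_pool())
}
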