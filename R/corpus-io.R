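#' Build a labeled tweet corpus
#'
#' A corpus is an ordinary tibble with columns `tweet_id`, `user_id`, `text`
#' and `label`, one row per tweet, in stable (file) order. `label` is one of
#' [tweet_classes()] or `NA` for unlabeled data. All pipeline functions accept
#' and return this shape so that steps chain with the pipe.
#'
#' @param tweet_id,user_id Opaque identifier strings.
#' @param text Raw tweet text (never normalized in place; both preprocessing
#'   tracks read from it).
#' @param label Class labels, one of [tweet_classes()] (case-insensitive) or
#'   `NA`.
#' @param provenance Free-text source tag stored as an attribute.
#' @return A tibble of class `tweet_corpus`.
#' @export
#' @examples
#' tweet_corpus("1", "u1", "my daughter has gastroschisis", "defect")
tweet_corpus <- function(tweet_id, user_id, text, label = NA_character_,
                         provenance = "in-memory") {
  out <- tibble::tibble(
    tweet_id = as.character(tweet_id),
    user_id = as.character(user_id),
    text = as.character(text),
    label = normalize_labels(label, n = length(text))
  )
  as_tweet_corpus(out, provenance = provenance)
}

#' @rdname tweet_corpus
#' @param x A data frame with at least `tweet_id`, `user_id`, `text`, `label`.
#' @export
as_tweet_corpus <- function(x, provenance = attr(x, "provenance") %||% "unknown") {
  needed <- c("tweet_id", "user_id", "text", "label")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("corpus is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(x)
  out$tweet_id <- as.character(out$tweet_id)
  out$user_id <- as.character(out$user_id)
  out$text <- as.character(out$text)
  out$label <- normalize_labels(out$label, n = nrow(out))
  if (any(!nzchar(trimws(out$text)))) {
    stop("corpus text must be non-empty after whitespace stripping", call. = FALSE)
  }
  attr(out, "provenance") <- provenance
  class(out) <- unique(c("tweet_corpus", class(out)))
  out
}

# Case-fold labels to the canonical lowercase names; warn on case variants,
# error on anything unrecognized. NA passes through (unlabeled data).
normalize_labels <- function(label, n) {
  if (length(label) == 1 && n > 1) label <- rep(label, n)
  label <- as.character(label)
  folded <- tolower(trimws(label))
  folded[folded %in% c("", "na")] <- NA_character_
  bad <- !is.na(folded) & !folded %in% TWEET_CLASSES
  if (any(bad)) {
    stop("unknown label string(s): ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  refolded <- !is.na(folded) & folded != label
  if (any(refolded)) {
    warning(sum(refolded), " label(s) case-folded to canonical form",
            call. = FALSE)
  }
  folded
}

#' Read and write tweet corpora
#'
#' Corpora are stored as delimited UTF-8 text with a header row naming the
#' four columns `tweet_id`, `user_id`, `text`, `label` (tab-separated by
#' default, so tweets with internal commas are safe). Labels are case-folded
#' on read. Malformed rows -- empty text, or missing fields -- are counted and
#' reported in the load summary (see [load_summary()]), never silently
#' dropped.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return `read_corpus()`: a `tweet_corpus` tibble with a `load_summary`
#'   attribute; `write_corpus()`: `path`, invisibly.
#' @export
read_corpus <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = delim, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  needed <- c("tweet_id", "user_id", "text", "label")
  if (!all(needed %in% names(raw))) {
    stop("corpus header must name columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) stop("corpus file is empty: ", path, call. = FALSE)
  raw <- raw[needed]
  bad_text <- is.na(raw$text) | !nzchar(trimws(raw$text))
  kept <- raw[!bad_text, , drop = FALSE]
  if (nrow(kept) == 0) stop("no well-formed rows in: ", path, call. = FALSE)
  out <- as_tweet_corpus(kept, provenance = path)
  counts <- table(factor(out$label, levels = TWEET_CLASSES), useNA = "ifany")
  attr(out, "load_summary") <- tibble::tibble(
    rows_read = nrow(raw),
    rows_kept = nrow(kept),
    rows_malformed = sum(bad_text),
    defect = unname(counts["defect"]),
    possible_defect = unname(counts["possible_defect"]),
    non_defect = unname(counts["non_defect"])
  )
  if (any(bad_text)) {
    message(sum(bad_text), " malformed row(s) (empty text) rejected; see load_summary()")
  }
  out
}

#' @rdname read_corpus
#' @param corpus A `tweet_corpus` tibble.
#' @export
write_corpus <- function(corpus, path, delim = "\t") {
  corpus <- as_tweet_corpus(corpus)
  df <- as.data.frame(corpus[c("tweet_id", "user_id", "text", "label")])
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = delim, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname read_corpus
#' @export
load_summary <- function(corpus) attr(corpus, "load_summary")

#' Per-class tweet counts
#'
#' @param corpus A `tweet_corpus` tibble.
#' @return A tibble with one row per class plus the total.
#' @export
class_counts <- function(corpus) {
  counts <- table(factor(corpus$label, levels = TWEET_CLASSES))
  tibble::tibble(
    class = c(TWEET_CLASSES, "total"),
    n = c(as.integer(counts), nrow(corpus))
  )
}

#' Read a birth-defect term lexicon
#'
#' The term file lists one lowercase term per line (single- or multi-word);
#' the optional variants file maps terms to lexical variants (misspellings,
#' inflections), one `term<TAB>variant` pair per line. Variant lines without
#' a tab are kept as standalone extra patterns. Terms are lowercased and
#' deduplicated, preserving first-occurrence order.
#'
#' @param term_path Path to the term file.
#' @param variants_path Optional path to the variants file.
#' @return A tibble of class `bd_lexicon` with columns `term` and `variants`
#'   (a list column of character vectors, possibly empty).
#' @export
read_lexicon <- function(term_path, variants_path = NULL) {
  lines <- read_utf8_lines(term_path)
  terms <- unique(tolower(trimws(lines)))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) stop("empty lexicon: ", term_path, call. = FALSE)
  variants <- rep(list(character()), length(terms))
  names(variants) <- terms
  if (!is.null(variants_path)) {
    vlines <- read_utf8_lines(variants_path)
    vlines <- vlines[nzchar(trimws(vlines))]
    for (line in vlines) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2) {
        key <- tolower(trimws(parts[1]))
        val <- tolower(trimws(parts[2]))
        if (!key %in% terms) {
          terms <- c(terms, key)
          variants[[key]] <- character()
        }
        variants[[key]] <- unique(c(variants[[key]], val))
      } else {
        solo <- tolower(trimws(parts[1]))
        if (!solo %in% terms) {
          terms <- c(terms, solo)
          variants[[solo]] <- character()
        }
      }
    }
  }
  out <- tibble::tibble(term = terms, variants = unname(variants[terms]))
  class(out) <- unique(c("bd_lexicon", class(out)))
  out
}

#' @rdname read_lexicon
#' @param terms Character vector of terms.
#' @param variants Optional named list mapping terms to variant vectors.
#' @export
bd_lexicon <- function(terms, variants = list()) {
  terms <- unique(tolower(trimws(terms)))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) stop("empty lexicon", call. = FALSE)
  vlist <- purrr::map(terms, function(t) {
    v <- variants[[t]] %||% character()
    unique(tolower(trimws(v)))
  })
  out <- tibble::tibble(term = terms, variants = vlist)
  class(out) <- unique(c("bd_lexicon", class(out)))
  out
}

#' Read a word-cluster table
#'
#' Hierarchical word clusters as distributed for Twitter text: a TSV with
#' columns cluster-path (a bit-string label), word, and an optional count.
#' Words appearing in similar collocate contexts (including misspellings)
#' share a path, so the classifier can generalize over them. Lookup is
#' case-normalized; duplicate words keep their first row.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `word`, `cluster`, `count`.
#' @export
read_clusters <- function(path) {
  lines <- read_utf8_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty cluster table: ", path, call. = FALSE)
  parts <- stringr::str_split_fixed(lines, "\t", 3)
  out <- tibble::tibble(
    word = tolower(parts[, 2]),
    cluster = parts[, 1],
    count = suppressWarnings(as.integer(parts[, 3]))
  )
  out[!duplicated(out$word), ]
}

#' Read a given-names lexicon
#'
#' One name per line; lowercased and deduplicated. Used to normalize
#' personal names (a hallmark of the ambiguous-referent class) to a
#' placeholder during preprocessing.
#'
#' @param path Path to the file.
#' @return A tibble with a single `name` column.
#' @export
read_names <- function(path) {
  lines <- read_utf8_lines(path)
  nm <- unique(tolower(trimws(lines)))
  nm <- nm[nzchar(nm)]
  if (length(nm) == 0) stop("empty name lexicon: ", path, call. = FALSE)
  tibble::tibble(name = nm)
}

read_utf8_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Run configuration
#'
#' A flat key-value configuration for a full pipeline run: input paths, split
#' fractions, the RNG seed (recorded in all outputs; every stochastic stage
#' derives its stream deterministically from it), the sampling plan, the
#' classifier and its hyperparameters, and feature toggles.
#'
#' @param ... Overrides of the defaults, as `name = value` pairs.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    corpus = NULL, lexicon = NULL, variants = NULL, clusters = NULL,
    names = NULL,
    test_frac = 0.2, dev_frac = 0.2, seed = 1L,
    sampling = "none", sampling_k = NA_real_, sampling_target = NA_integer_,
    classifier = "svm", svm_cost = 100, ngram_n = c(1L, 2L, 3L),
    use_ngrams = TRUE, use_clusters = TRUE, use_lengths = TRUE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, overrides)
  stopifnot(cfg$test_frac > 0, cfg$test_frac < 1,
            cfg$dev_frac > 0, cfg$dev_frac < 1)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML key-value file.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  do.call(run_config, yaml::read_yaml(path))
}
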