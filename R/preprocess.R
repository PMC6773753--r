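#' Deixis wordlists for the classic track
#'
#' The default word sets normalized to `_fppron_` (first-person possessives),
#' `_child_` (references to a child) and `_tppron_` (third-person pronouns).
#' The sets include simple plurals so that normalization is stable under
#' stemming (a stemmed plural never re-matches a set member on a second
#' pass). All three are configurable.
#'
#' @param fppron,child,tppron Character vectors overriding the defaults.
#' @return A named list with elements `fppron`, `child`, `tppron`.
#' @export
deixis_wordlists <- function(fppron = c("my", "our", "ours"),
                             child = c("son", "sons", "daughter", "daughters",
                                       "child", "children", "baby", "babies",
                                       "kid", "kids"),
                             tppron = c("she", "he", "her", "him", "his", "hers")) {
  list(fppron = fppron, child = child, tppron = tppron)
}

#' Classic-track text normalization
#'
#' The normalization track feeding the sparse-feature (NB/SVM) models. The
#' pipeline, in order: (1) usernames (`@...`) and URLs become `_username_` /
#' `_url_`; (2) spans matched by the birth-defect lexicon patterns become
#' `_malformation_` (so the model cannot overfit to specific defects);
#' (3) whole-word given names become `_name_` (skipped inside hashtag-fused
#' tokens, which are modeled as single tokens); (4) deixis words become
#' `_fppron_` / `_child_` / `_tppron_`; (5) lowercasing; (6) removal of
#' non-alphabetic characters (apostrophes deleted, everything else replaced
#' by a space; placeholder underscores are preserved); (7) Porter stemming of
#' non-placeholder tokens; whitespace tokenization.
#'
#' `classic_normalize()` is the data-frame interface: it adds a
#' `classic_tokens` list column and a `classic_text` column (tokens joined by
#' a single space, used e.g. for Levenshtein-ratio similarity) to the corpus.
#' `classic_tokenize()` works on a character vector.
#'
#' @param corpus A `tweet_corpus` tibble.
#' @param text Character vector of raw tweet texts.
#' @param patterns Optional `bd_patterns` tibble from [build_patterns()];
#'   `NULL` disables `_malformation_` normalization.
#' @param name_lexicon Optional tibble from [read_names()] (or a character
#'   vector of names); `NULL` disables `_name_` normalization.
#' @param wordlists Deixis wordlists, see [deixis_wordlists()].
#' @param stem Stem non-placeholder tokens (default `TRUE`).
#' @return `classic_tokenize()`: a list of character token vectors;
#'   `classic_normalize()`: the corpus with `classic_tokens` and
#'   `classic_text` columns added.
#' @export
#' @examples
#' classic_tokenize("My son has spina bifida",
#'                  patterns = build_patterns(bd_lexicon("spina bifida")))
classic_tokenize <- function(text, patterns = NULL, name_lexicon = NULL,
                             wordlists = deixis_wordlists(), stem = TRUE) {
  text <- stringi::stri_trans_nfc(as.character(text))
  text <- stringr::str_replace_all(
    text, stringr::regex("\\b(?:https?://|www\\.)\\S+", ignore_case = TRUE),
    " _url_ ")
  text <- stringr::str_replace_all(text, "@\\w+", " _username_ ")
  if (!is.null(patterns) && nrow(patterns) > 0) {
    combined <- paste0("(?:", paste(patterns$pattern, collapse = "|"), ")")
    text <- stringr::str_replace_all(
      text, stringr::regex(combined, ignore_case = TRUE), " _malformation_ ")
  }
  nm <- name_vector(name_lexicon)
  if (length(nm) > 0) {
    text <- replace_wordset(text, nm, "_name_", skip_hashtag = TRUE,
                            possessive = TRUE)
  }
  text <- replace_wordset(text, wordlists$fppron, "_fppron_")
  text <- replace_wordset(text, wordlists$child, "_child_")
  text <- replace_wordset(text, wordlists$tppron, "_tppron_")
  text <- tolower(text)
  text <- stringr::str_replace_all(text, "['’]", "")
  text <- stringr::str_replace_all(text, "[^a-z_ ]", " ")
  toks <- stringr::str_split(trimws(text), "\\s+")
  toks <- purrr::map(toks, function(t) t[nzchar(t)])
  if (stem) toks <- purrr::map(toks, stem_token)
  toks
}

#' @rdname classic_tokenize
#' @export
classic_normalize <- function(corpus, patterns = NULL, name_lexicon = NULL,
                              wordlists = deixis_wordlists(), stem = TRUE) {
  toks <- classic_tokenize(corpus$text, patterns = patterns,
                           name_lexicon = name_lexicon,
                           wordlists = wordlists, stem = stem)
  corpus$classic_tokens <- toks
  corpus$classic_text <- vapply(toks, paste, character(1), collapse = " ")
  corpus
}

name_vector <- function(name_lexicon) {
  if (is.null(name_lexicon)) return(character(0))
  if (is.data.frame(name_lexicon)) return(name_lexicon$name)
  as.character(name_lexicon)
}

# Whole-word, case-insensitive replacement of a word set by a placeholder.
# skip_hashtag blocks matches immediately after '#' (hashtag-fused tokens
# stay single tokens); possessive additionally consumes a trailing 's.
replace_wordset <- function(text, words, placeholder, skip_hashtag = FALSE,
                            possessive = FALSE) {
  words <- words[nzchar(words)]
  if (length(words) == 0) return(text)
  esc <- vapply(words, escape_regex, character(1))
  rx <- paste0(if (skip_hashtag) "(?<!#)", "(?<![\\w])(?:",
               paste(esc, collapse = "|"), ")",
               if (possessive) "(?:['’]s)?", "(?![\\w])")
  stringr::str_replace_all(text, stringr::regex(rx, ignore_case = TRUE),
                           paste0(" ", placeholder, " "))
}

#' Embedding-track text normalization
#'
#' The normalization track feeding the sequence (LSTM) model, matching the
#' preprocessing used when training public tweet word vectors. In order:
#' usernames become `<USER>` and URLs `<URL>`; spaces are inserted around
#' slash characters; numbers become `<NUMBER>`; repetitions of the same
#' punctuation mark after the first are replaced by `<REPEAT>`; letters
#' repeated more than three times are trimmed to three and the word is marked
#' with `<ELONG>`; hashtag characters are replaced by `<HASHTAG>`; finally
#' the text is tokenized (punctuation split into its own tokens) and
#' lowercased, marker tokens excepted.
#'
#' @inheritParams classic_tokenize
#' @return `embed_tokenize()`: a list of character token vectors;
#'   `embed_normalize()`: the corpus with an `embed_tokens` list column.
#' @export
#' @examples
#' embed_tokenize("sooooo sad!!! #hlhs")
embed_tokenize <- function(text) {
  text <- stringi::stri_trans_nfc(as.character(text))
  text <- stringr::str_replace_all(
    text, stringr::regex("\\b(?:https?://|www\\.)\\S+", ignore_case = TRUE),
    " <URL> ")
  text <- stringr::str_replace_all(text, "@\\w+", " <USER> ")
  text <- stringr::str_replace_all(text, "/", " / ")
  text <- stringr::str_replace_all(
    text, "(?<![A-Za-z0-9_])[-+]?[.,]?\\d+(?:[.,:]\\d+)*", " <NUMBER> ")
  text <- stringr::str_replace_all(text, "([!?.:;,])\\1+", "\\1 <REPEAT> ")
  text <- stringr::str_replace_all(
    text, "\\b(\\w*?([A-Za-z])\\2{3,}\\w*)\\b", "\\1 <ELONG> ")
  text <- stringr::str_replace_all(text, "([A-Za-z])\\1{3,}", "\\1\\1\\1")
  text <- stringr::str_replace_all(text, "#", " <HASHTAG> ")
  text <- stringr::str_replace_all(text, "([!?.,;:\"()\\[\\]{}&*+=~|^%$])",
                                   " \\1 ")
  toks <- stringr::str_split(trimws(text), "\\s+")
  purrr::map(toks, function(t) {
    t <- t[nzchar(t)]
    marker <- grepl("^<[A-Z]+>$", t)
    t[!marker] <- tolower(t[!marker])
    t
  })
}

#' @rdname embed_tokenize
#' @export
embed_normalize <- function(corpus) {
  corpus$embed_tokens <- embed_tokenize(corpus$text)
  corpus
}
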