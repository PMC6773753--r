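#' Compile lexicon terms into retrieval patterns
#'
#' Builds one word-boundary-anchored, case-insensitive matcher per lexicon
#' term, folding in that term's lexical variants. Multi-word terms tolerate
#' internal whitespace/hyphen variation ("club foot", "club-foot",
#' "Club  Foot"), and a hashtag-collapsed form is matched after a `#`
#' ("#clubfoot"). An optional trailing "s" absorbs simple plurals.
#'
#' @param lexicon A `bd_lexicon` tibble from [read_lexicon()] or
#'   [bd_lexicon()].
#' @return A tibble of class `bd_patterns` with columns `term` (source term)
#'   and `pattern` (regex string).
#' @export
#' @examples
#' lex <- bd_lexicon(c("club foot", "hydrocephalus"))
#' pat <- build_patterns(lex)
#' retrieve(tweet_corpus("1", "u", "My #clubfoot cutie"), pat)
build_patterns <- function(lexicon) {
  if (nrow(lexicon) == 0) stop("empty lexicon", call. = FALSE)
  pattern <- purrr::map2_chr(lexicon$term, lexicon$variants, term_pattern)
  out <- tibble::tibble(term = lexicon$term, pattern = pattern)
  class(out) <- unique(c("bd_patterns", class(out)))
  out
}

# One regex per term: an alternation over the term and its variants, each as
# a word-bounded form with [\s-]+ between words, plus (for multi-word forms)
# a collapsed form valid only immediately after '#'.
term_pattern <- function(term, variants) {
  forms <- unique(c(term, variants))
  forms <- forms[nzchar(forms)]
  alts <- character(0)
  for (f in forms) {
    words <- strsplit(f, "[\\s-]+", perl = TRUE)[[1]]
    words <- words[nzchar(words)]
    if (length(words) == 0) next
    esc <- vapply(words, escape_regex, character(1))
    alts <- c(alts, paste0("\\b", paste(esc, collapse = "[\\s\\-]+"), "s?\\b"))
    if (length(words) > 1) {
      alts <- c(alts, paste0("(?<=#)", paste(esc, collapse = ""), "s?\\b"))
    }
  }
  if (length(alts) == 0) {
    stop("term compiles to an empty pattern: '", term, "'", call. = FALSE)
  }
  paste0("(?:", paste(alts, collapse = "|"), ")")
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Locate lexicon matches in texts
#'
#' Matching is case-insensitive on NFC-normalized text. Offsets are 0-based,
#' end-exclusive character positions into the normalized text.
#'
#' @param patterns A `bd_patterns` tibble from [build_patterns()].
#' @param texts Character vector.
#' @return A list (one element per text) of tibbles with columns `start`,
#'   `end`, `term`.
#' @export
match_spans <- function(patterns, texts) {
  texts <- stringi::stri_trans_nfc(texts)
  per_text <- rep(list(NULL), length(texts))
  for (i in seq_len(nrow(patterns))) {
    rx <- stringr::regex(patterns$pattern[i], ignore_case = TRUE)
    locs <- stringr::str_locate_all(texts, rx)
    for (j in seq_along(texts)) {
      m <- locs[[j]]
      if (nrow(m) > 0) {
        per_text[[j]] <- rbind(
          per_text[[j]],
          data.frame(start = m[, 1] - 1L, end = m[, 2],
                     term = patterns$term[i], stringsAsFactors = FALSE)
        )
      }
    }
  }
  purrr::map(per_text, function(d) {
    if (is.null(d)) {
      tibble::tibble(start = integer(), end = integer(), term = character())
    } else {
      tibble::as_tibble(d[order(d$start, d$end), ])
    }
  })
}

#' Retrieve tweets that mention a birth defect
#'
#' A tweet is returned iff (i) some lexicon pattern matches its text, (ii) it
#' is not a retweet (text starting with "RT @" after left-stripping, or a
#' truthy `is_retweet` column when present), and (iii) no matched span
#' overlaps a username token (whitespace-delimited token starting with `@`)
#' or a URL token (token starting with `http://`, `https://` or `www.`).
#' The result is deterministic and independent of tweet order.
#'
#' @param corpus A `tweet_corpus` tibble.
#' @param patterns A `bd_patterns` tibble.
#' @return The matching subset of `corpus` with an added `matches` list
#'   column of span tibbles (`start`, `end`, `term`; 0-based end-exclusive).
#' @export
retrieve <- function(corpus, patterns) {
  corpus <- as_tweet_corpus(corpus)
  spans <- match_spans(patterns, corpus$text)
  n_hit <- vapply(spans, nrow, integer(1))
  is_rt <- grepl("^rt @", trimws(tolower(corpus$text)))
  if ("is_retweet" %in% names(corpus)) {
    is_rt <- is_rt | isTRUE_vec(corpus$is_retweet)
  }
  clean <- vapply(seq_len(nrow(corpus)), function(j) {
    if (n_hit[j] == 0) return(FALSE)
    !spans_overlap_tokens(spans[[j]], corpus$text[j])
  }, logical(1))
  keep <- n_hit > 0 & !is_rt & clean
  out <- corpus[keep, , drop = FALSE]
  out$matches <- spans[keep]
  out
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | tolower(as.character(x)) %in% c("true", "1"))

# TRUE if any matched span overlaps a username or URL token (char ranges,
# 0-based end-exclusive on NFC text).
spans_overlap_tokens <- function(span_df, text) {
  if (nrow(span_df) == 0) return(FALSE)
  text <- stringi::stri_trans_nfc(text)
  toks <- stringr::str_locate_all(text, "\\S+")[[1]]
  if (nrow(toks) == 0) return(FALSE)
  tok_str <- stringr::str_sub(text, toks[, 1], toks[, 2])
  bad <- grepl("^@.|^https?://|^www\\.", tok_str, ignore.case = TRUE)
  if (!any(bad)) return(FALSE)
  bs <- toks[bad, 1, drop = TRUE] - 1L
  be <- toks[bad, 2, drop = TRUE]
  for (i in seq_len(nrow(span_df))) {
    if (any(span_df$start[i] < be & span_df$end[i] > bs)) return(TRUE)
  }
  FALSE
}
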