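# Porter stemmer (the classic suffix-stripping algorithm), implemented in
# full: steps 1a-1c, 2, 3, 4, 5a-5b with longest-match rule selection per
# step and the m-measure/vowel/double-consonant/cvc conditions.

#' Stem tokens with the Porter algorithm
#'
#' `porter_stem()` stems lowercase words; `stem_token()` is the pipeline
#' wrapper that leaves placeholder tokens (`_username_`, `_malformation_`,
#' ...) and empty strings unchanged.
#'
#' @param word Character vector of lowercase tokens.
#' @return Character vector of stems.
#' @export
#' @examples
#' porter_stem(c("running", "relational", "was"))
#' stem_token(c("_fppron_", "has"))
porter_stem <- function(word) {
  vapply(word, porter_one, character(1), USE.NAMES = FALSE)
}

#' @rdname porter_stem
#' @export
stem_token <- function(word) {
  keep <- grepl("^_[a-z]+_$", word) | !nzchar(word)
  out <- word
  out[!keep] <- porter_stem(word[!keep])
  out
}

porter_one <- function(w) {
  if (is.na(w) || nchar(w) <= 2) return(w)
  w <- p_step1a(w)
  w <- p_step1b(w)
  w <- p_step1c(w)
  w <- p_step2(w)
  w <- p_step3(w)
  w <- p_step4(w)
  w <- p_step5(w)
  w
}

# consonant test at position i (1-based): not a vowel; 'y' is a consonant
# only at the start or after a vowel.
p_cons <- function(ch, i) {
  c <- ch[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1) return(TRUE)
    return(!p_cons(ch, i - 1))
  }
  TRUE
}

p_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

# m: the number of VC sequences in [C](VC){m}[V]
p_measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  ch <- p_chars(stem)
  cls <- vapply(seq_along(ch), function(i) p_cons(ch, i), logical(1))
  runs <- rle(cls)$values  # TRUE = consonant run, FALSE = vowel run
  m <- 0L
  for (i in seq_along(runs)) {
    if (i > 1 && runs[i] && !runs[i - 1]) m <- m + 1L
  }
  m
}

p_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  ch <- p_chars(stem)
  any(!vapply(seq_along(ch), function(i) p_cons(ch, i), logical(1)))
}

p_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2) return(FALSE)
  ch <- p_chars(w)
  ch[n] == ch[n - 1] && p_cons(ch, n)
}

# *o: stem ends consonant-vowel-consonant, final consonant not w, x or y
p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  ch <- p_chars(w)
  p_cons(ch, n - 2) && !p_cons(ch, n - 1) && p_cons(ch, n) &&
    !ch[n] %in% c("w", "x", "y")
}

p_ends <- function(w, suffix) {
  n <- nchar(w); s <- nchar(suffix)
  n > s && substring(w, n - s + 1, n) == suffix
}

p_stem_of <- function(w, suffix) substring(w, 1, nchar(w) - nchar(suffix))

p_step1a <- function(w) {
  if (p_ends(w, "sses")) return(paste0(p_stem_of(w, "sses"), "ss"))
  if (p_ends(w, "ies")) return(paste0(p_stem_of(w, "ies"), "i"))
  if (p_ends(w, "ss")) return(w)
  if (p_ends(w, "s")) return(p_stem_of(w, "s"))
  w
}

p_step1b <- function(w) {
  if (p_ends(w, "eed")) {
    if (p_measure(p_stem_of(w, "eed")) > 0) return(p_stem_of(w, "d"))
    return(w)
  }
  fired <- FALSE
  if (p_ends(w, "ed") && p_has_vowel(p_stem_of(w, "ed"))) {
    w <- p_stem_of(w, "ed"); fired <- TRUE
  } else if (p_ends(w, "ing") && p_has_vowel(p_stem_of(w, "ing"))) {
    w <- p_stem_of(w, "ing"); fired <- TRUE
  }
  if (fired) {
    if (p_ends(w, "at") || p_ends(w, "bl") || p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (p_double_cons(w) &&
               !substring(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substring(w, 1, nchar(w) - 1)
    } else if (p_measure(w) == 1 && p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

p_step1c <- function(w) {
  if (p_ends(w, "y") && p_has_vowel(p_stem_of(w, "y"))) {
    return(paste0(p_stem_of(w, "y"), "i"))
  }
  w
}

P_STEP2 <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
)

P_STEP3 <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
  ful = "", ness = ""
)

P_STEP4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")

p_rule_table <- function(w, rules, min_m) {
  sufs <- names(rules)
  match_len <- vapply(sufs, function(s) if (p_ends(w, s)) nchar(s) else 0L,
                      integer(1))
  if (all(match_len == 0)) return(w)
  s <- sufs[which.max(match_len)]  # longest matching suffix decides
  stem <- p_stem_of(w, s)
  if (p_measure(stem) > min_m - 1) return(paste0(stem, rules[[s]]))
  w
}

p_step2 <- function(w) p_rule_table(w, P_STEP2, min_m = 1)
p_step3 <- function(w) p_rule_table(w, P_STEP3, min_m = 1)

p_step4 <- function(w) {
  match_len <- vapply(P_STEP4, function(s) if (p_ends(w, s)) nchar(s) else 0L,
                      integer(1))
  if (all(match_len == 0)) return(w)
  s <- P_STEP4[which.max(match_len)]
  stem <- p_stem_of(w, s)
  if (p_measure(stem) > 1) {
    if (s == "ion" && !substring(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
      return(w)
    }
    return(stem)
  }
  w
}

p_step5 <- function(w) {
  # 5a
  if (p_ends(w, "e")) {
    stem <- p_stem_of(w, "e")
    m <- p_measure(stem)
    if (m > 1 || (m == 1 && !p_cvc(stem))) w <- stem
  }
  # 5b
  if (p_measure(w) > 1 && p_double_cons(w) &&
      substring(w, nchar(w), nchar(w)) == "l") {
    w <- substring(w, 1, nchar(w) - 1)
  }
  w
}
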