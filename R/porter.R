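# Porter (1980) stemming algorithm.
#
# Implemented from the published rule tables. Words of length <= 2 are
# returned unchanged, as in the original. Only lower-case ASCII letters are
# stemmed; tokens containing digits or hyphens are passed through untouched
# (biomedical compounds such as "hpv-positive" or "p16" are meaningful as-is).

# consonant test at position i (1-based) of letter vector w
.pt_is_cons <- function(w, i) {
  ch <- w[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_is_cons(w, i - 1L))
  }
  TRUE
}

# measure m: number of VC sequences in the stem
.pt_measure <- function(w) {
  n <- length(w)
  if (n == 0L) return(0L)
  pat <- vapply(seq_len(n), function(i) .pt_is_cons(w, i), logical(1))
  m <- 0L
  prev_v <- FALSE
  for (i in seq_len(n)) {
    if (pat[i]) {
      if (prev_v) m <- m + 1L
      prev_v <- FALSE
    } else {
      prev_v <- TRUE
    }
  }
  m
}

.pt_has_vowel <- function(w) {
  n <- length(w)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) .pt_is_cons(w, i), logical(1)))
}

.pt_ends_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[n] == w[n - 1L] && .pt_is_cons(w, n)
}

# *o condition: stem ends cvc where the final c is not w, x or y
.pt_ends_cvc <- function(w) {
  n <- length(w)
  if (n < 3L) return(FALSE)
  .pt_is_cons(w, n) && !.pt_is_cons(w, n - 1L) && .pt_is_cons(w, n - 2L) &&
    !(w[n] %in% c("w", "x", "y"))
}

.pt_ends_with <- function(w, suf) {
  s <- strsplit(suf, "", fixed = TRUE)[[1]]
  n <- length(w); k <- length(s)
  n >= k && all(w[(n - k + 1L):n] == s)
}

.pt_stem_part <- function(w, suf) {
  w[seq_len(length(w) - nchar(suf))]
}

.pt_replace <- function(w, suf, rep) {
  c(.pt_stem_part(w, suf), strsplit(rep, "", fixed = TRUE)[[1]])
}

# rule list application for steps 2-4: first matching suffix wins
.pt_rule_step <- function(w, rules, cond) {
  for (r in rules) {
    suf <- r[[1]]
    if (.pt_ends_with(w, suf)) {
      stem <- .pt_stem_part(w, suf)
      if (cond(stem, w)) {
        return(c(stem, strsplit(r[[2]], "", fixed = TRUE)[[1]]))
      }
      return(w)  # longest match found but condition failed: stop
    }
  }
  w
}

.pt_step1a <- function(w) {
  if (.pt_ends_with(w, "sses")) return(.pt_replace(w, "sses", "ss"))
  if (.pt_ends_with(w, "ies"))  return(.pt_replace(w, "ies", "i"))
  if (.pt_ends_with(w, "ss"))   return(w)
  if (.pt_ends_with(w, "s"))    return(.pt_stem_part(w, "s"))
  w
}

.pt_step1b <- function(w) {
  if (.pt_ends_with(w, "eed")) {
    stem <- .pt_stem_part(w, "eed")
    if (.pt_measure(stem) > 0L) return(.pt_replace(w, "eed", "ee"))
    return(w)
  }
  hit <- FALSE
  if (.pt_ends_with(w, "ed") && .pt_has_vowel(.pt_stem_part(w, "ed"))) {
    w <- .pt_stem_part(w, "ed"); hit <- TRUE
  } else if (.pt_ends_with(w, "ing") && .pt_has_vowel(.pt_stem_part(w, "ing"))) {
    w <- .pt_stem_part(w, "ing"); hit <- TRUE
  }
  if (hit) {
    if (.pt_ends_with(w, "at") || .pt_ends_with(w, "bl") || .pt_ends_with(w, "iz")) {
      w <- c(w, "e")
    } else if (.pt_ends_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      w <- w[-length(w)]
    } else if (.pt_measure(w) == 1L && .pt_ends_cvc(w)) {
      w <- c(w, "e")
    }
  }
  w
}

.pt_step1c <- function(w) {
  if (.pt_ends_with(w, "y") && .pt_has_vowel(.pt_stem_part(w, "y"))) {
    return(.pt_replace(w, "y", "i"))
  }
  w
}

.pt_step2_rules <- list(
  list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
  list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
  list("alli", "al"), list("entli", "ent"), list("eli", "e"),
  list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
  list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
  list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
  list("iviti", "ive"), list("biliti", "ble")
)

.pt_step3_rules <- list(
  list("icate", "ic"), list("ative", ""), list("alize", "al"),
  list("iciti", "ic"), list("ical", "ic"), list("ful", ""),
  list("ness", "")
)

.pt_step4_sufs <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.pt_step4 <- function(w) {
  # longest matching suffix wins; removal requires m(stem) > 1
  best <- ""
  for (suf in .pt_step4_sufs) {
    if (.pt_ends_with(w, suf) && nchar(suf) > nchar(best)) best <- suf
  }
  if (best == "") return(w)
  stem <- .pt_stem_part(w, best)
  if (best == "ion" && !(length(stem) > 0L && stem[length(stem)] %in% c("s", "t"))) {
    return(w)
  }
  if (.pt_measure(stem) > 1L) return(stem)
  w
}

.pt_step5a <- function(w) {
  if (.pt_ends_with(w, "e")) {
    stem <- .pt_stem_part(w, "e")
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_ends_cvc(stem))) return(stem)
  }
  w
}

.pt_step5b <- function(w) {
  if (.pt_measure(w) > 1L && .pt_ends_double_cons(w) && w[length(w)] == "l") {
    return(w[-length(w)])
  }
  w
}

.pt_stem_one <- function(token) {
  if (nchar(token) <= 2L || grepl("[^a-z]", token)) return(token)
  w <- strsplit(token, "", fixed = TRUE)[[1]]
  w <- .pt_step1a(w)
  w <- .pt_step1b(w)
  w <- .pt_step1c(w)
  w <- .pt_rule_step(w, .pt_step2_rules, function(stem, w) .pt_measure(stem) > 0L)
  w <- .pt_rule_step(w, .pt_step3_rules, function(stem, w) .pt_measure(stem) > 0L)
  w <- .pt_step4(w)
  w <- .pt_step5a(w)
  w <- .pt_step5b(w)
  paste(w, collapse = "")
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the Porter (1980) suffix-stripping
#' algorithm. Tokens of length two or less, and tokens containing characters
#' other than lower-case letters (digits, hyphens), are returned unchanged so
#' that biomedical compounds and symbols survive intact.
#'
#' @param tokens character vector of lower-case tokens.
#' @return character vector of stems, same length as `tokens`.
#' @examples
#' porter_stem(c("staging", "relational", "hpv", "caresses"))
#' @export
porter_stem <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  uq <- unique(tokens)
  stems <- vapply(uq, .pt_stem_one, character(1), USE.NAMES = FALSE)
  stems[match(tokens, uq)]
}
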