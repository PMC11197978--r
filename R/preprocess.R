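# Text preprocessing: cleaning, stemming, collocation merging, vocabulary
# pruning. The end product is an lda_tokens object: per-document integer
# token-id sequences over a pruned vocabulary, the input the Gibbs sampler
# consumes.

#' Clean raw text
#'
#' Lower-cases, replaces every character outside `[a-z0-9 -]` with a space,
#' and collapses runs of whitespace. Hyphens are retained inside tokens
#' ("hpv-positive"); all other punctuation and non-ASCII characters are
#' treated as noise.
#'
#' @param text character vector.
#' @return character vector of cleaned text.
#' @examples
#' clean_text("HPV-positive OPC (n=37)!")
#' @export
clean_text <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9 -]", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Default English stopword list
#'
#' The fixed stopword list shipped with the package (one word per line under
#' `extdata/stopwords_en.txt`). Shipping a versioned list keeps runs
#' reproducible; user lists may be appended via the `stopwords` argument of
#' [tokenize_corpus()].
#'
#' @return character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "topiclit")
  readLines(path, warn = FALSE)
}

# split cleaned text into tokens
.split_tokens <- function(text) {
  out <- strsplit(text, " ", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

#' Merge scored bigram collocations
#'
#' Adjacent token pairs (a, b) whose corpus count reaches `min_count` and
#' whose score `(count(a,b) - min_count) * V / (count(a) * count(b))` reaches
#' `threshold` (V = current vocabulary size) are merged into a single token
#' `"a_b"` in one greedy left-to-right pass per document.
#'
#' @param doc_tokens list of character vectors (one per document).
#' @param min_count minimum corpus count for a candidate pair.
#' @param threshold minimum collocation score; `Inf` disables merging.
#' @return list of character vectors with merged bigrams.
#' @export
detect_phrases <- function(doc_tokens, min_count = 5, threshold = 10) {
  if (!is.finite(threshold)) return(doc_tokens)
  uni <- table(unlist(doc_tokens, use.names = FALSE))
  V <- length(uni)
  if (V == 0L) return(doc_tokens)
  pair_keys <- unlist(lapply(doc_tokens, function(tk) {
    n <- length(tk)
    if (n < 2L) return(character(0))
    paste(tk[-n], tk[-1], sep = "\r")
  }), use.names = FALSE)
  if (length(pair_keys) == 0L) return(doc_tokens)
  pc <- table(pair_keys)
  ab <- strsplit(names(pc), "\r", fixed = TRUE)
  a <- vapply(ab, `[`, character(1), 1L)
  b <- vapply(ab, `[`, character(1), 2L)
  cnt <- as.numeric(pc)
  score <- (cnt - min_count) * V / (as.numeric(uni[a]) * as.numeric(uni[b]))
  merge_set <- names(pc)[cnt >= min_count & score >= threshold]
  if (length(merge_set) == 0L) return(doc_tokens)
  merge_set <- as.environment(setNames(as.list(rep(TRUE, length(merge_set))),
                                       merge_set))
  lapply(doc_tokens, function(tk) {
    n <- length(tk)
    if (n < 2L) return(tk)
    out <- character(0)
    i <- 1L
    while (i <= n) {
      if (i < n && !is.null(merge_set[[paste(tk[i], tk[i + 1L], sep = "\r")]])) {
        out <- c(out, paste(tk[i], tk[i + 1L], sep = "_"))
        i <- i + 2L
      } else {
        out <- c(out, tk[i])
        i <- i + 1L
      }
    }
    out
  })
}

#' Prune the vocabulary by stopwords and document frequency
#'
#' Drops stopwords, terms appearing in fewer than `min_df` documents, and
#' terms appearing in more than `max_df_frac * M` documents; re-indexes the
#' surviving vocabulary (alphabetical order); documents emptied by pruning
#' are removed with a message. Pruning an already-pruned corpus with the same
#' parameters is a no-op.
#'
#' @param doc_tokens list of character vectors.
#' @param stopwords character vector of terms always removed.
#' @param min_df minimum document frequency (inclusive), `>= 1`.
#' @param max_df_frac maximum document frequency as a fraction of the corpus.
#' @param doc_meta optional data.frame of per-document metadata (doc_id,
#'   year) filtered alongside the documents.
#' @param quiet suppress the emptied-document message.
#' @return list with `doc_tokens` (integer-id lists), `vocab`, `doc_meta`,
#'   `dropped_docs` (indices removed).
#' @export
prune_vocab <- function(doc_tokens, stopwords = character(0), min_df = 5,
                        max_df_frac = 0.5, doc_meta = NULL, quiet = FALSE) {
  stopifnot(min_df >= 1, max_df_frac > 0, max_df_frac <= 1)
  M <- length(doc_tokens)
  df <- table(unlist(lapply(doc_tokens, unique), use.names = FALSE))
  keep_terms <- names(df)[as.integer(df) >= min_df &
                          as.integer(df) <= max_df_frac * M]
  keep_terms <- setdiff(keep_terms, stopwords)
  vocab <- sort(keep_terms)
  ids <- lapply(doc_tokens, function(tk) {
    m <- match(tk, vocab)
    m[!is.na(m)]
  })
  empty <- which(lengths(ids) == 0L)
  if (length(empty) == M) stop("pruning emptied every document")
  if (length(empty) > 0L) {
    if (!quiet) message("removing ", length(empty), " document(s) emptied by pruning")
    ids <- ids[-empty]
    if (!is.null(doc_meta)) doc_meta <- doc_meta[-empty, , drop = FALSE]
  }
  list(doc_tokens = ids, vocab = vocab, doc_meta = doc_meta,
       dropped_docs = empty)
}

#' Tokenize a corpus for topic modeling
#'
#' Runs the full preprocessing chain: [clean_text()], token splitting,
#' optional Porter stemming, optional bigram collocation merging, and
#' stopword/document-frequency pruning. Returns the token container used by
#' [lda_gibbs()].
#'
#' @param corpus a [lit_corpus()].
#' @param stem apply the Porter stemmer.
#' @param stopwords stopword list; defaults to the shipped English list.
#'   Stopwords are stemmed too when `stem = TRUE` so that pruning operates in
#'   stem space.
#' @param phrase_min_count,phrase_threshold collocation parameters for
#'   [detect_phrases()]; `phrase_threshold = Inf` disables phrase merging.
#' @param min_df,max_df_frac vocabulary pruning thresholds (documents).
#' @param quiet suppress messages.
#' @return an object of class `lda_tokens`: list with `doc_tokens`
#'   (per-document integer vectors, ids into `vocab`), `vocab`, `doc_id`,
#'   `year`, `V`, `n_tokens`.
#' @export
tokenize_corpus <- function(corpus, stem = TRUE,
                            stopwords = default_stopwords(),
                            phrase_min_count = 5, phrase_threshold = 10,
                            min_df = 5, max_df_frac = 0.5, quiet = FALSE) {
  toks <- .split_tokens(clean_text(corpus$docs$text))
  if (stem) {
    all_tok <- unlist(toks, use.names = FALSE)
    stemmed <- porter_stem(all_tok)
    toks <- utils::relist(stemmed, toks)
    stopwords <- unique(c(stopwords, porter_stem(stopwords)))
  }
  toks <- detect_phrases(toks, min_count = phrase_min_count,
                         threshold = phrase_threshold)
  meta <- corpus$docs[, c("doc_id", "year")]
  pr <- prune_vocab(toks, stopwords = stopwords, min_df = min_df,
                    max_df_frac = max_df_frac, doc_meta = meta, quiet = quiet)
  new_lda_tokens(pr$doc_tokens, pr$vocab, pr$doc_meta$doc_id, pr$doc_meta$year)
}

# internal constructor shared with the synthetic generator
new_lda_tokens <- function(doc_tokens, vocab, doc_id, year) {
  doc_tokens <- lapply(doc_tokens, as.integer)
  structure(
    list(doc_tokens = doc_tokens, vocab = vocab,
         doc_id = as.character(doc_id), year = as.integer(year),
         V = length(vocab), n_tokens = lengths(doc_tokens)),
    class = "lda_tokens"
  )
}

#' @export
print.lda_tokens <- function(x, ...) {
  cat("Tokenized corpus: ", length(x$doc_tokens), " documents, ",
      sum(x$n_tokens), " tokens, vocabulary ", x$V, "\n", sep = "")
  invisible(x)
}
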