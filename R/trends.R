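# MeSH-style term and gene-symbol trend analyses.
#
# Documents are pooled by dominant topic; subject tags are counted per
# document (a heading listed twice still counts once, MeSH lists are sets);
# filters follow the conventions: topic-term filter strict (> min_count),
# annual filter inclusive (>= min_count), gene filter inclusive
# (>= min_total). "Significant differences across topics" is a chi-square
# goodness-of-fit of a term's per-topic counts against the documents-per-
# topic margin.

#' Dominant topic of every document
#'
#' `argmax_k theta[j, k]`, ties broken toward the lower topic index.
#'
#' @param model a fitted `lda_gibbs` model.
#' @return integer vector of topic indices, named by document id.
#' @export
dominant_topics <- function(model) {
  out <- max.col(model$theta, ties.method = "first")
  names(out) <- model$doc_id
  out
}

# chi-square goodness-of-fit p-value of counts against margin proportions
.topic_assoc_p <- function(counts, margin) {
  use <- margin > 0
  if (sum(counts[use]) == 0) return(1)
  suppressWarnings(
    stats::chisq.test(counts[use], p = margin[use] / sum(margin[use]))$p.value
  )
}

#' Topic-by-term count matrix with frequency and association filters
#'
#' Counts, for every subject tag, the number of documents carrying it within
#' each dominant-topic pool. Retains tags whose total count exceeds
#' `min_count` (strictly) and whose topic distribution differs significantly
#' (chi-square, `p < alpha_level`) from the documents-per-topic margin.
#'
#' @param corpus a [lit_corpus()] (supplies the tags).
#' @param assignments per-document dominant topics, as from
#'   [dominant_topics()]; must cover every document.
#' @param min_count strict lower bound on a tag's total document count.
#' @param alpha_level significance level of the association test.
#' @return an object of class `term_topic_matrix`: list with `counts`
#'   (retained terms x topics integer matrix), `all_counts` (pre-filter
#'   matrix), `p_values` (named, pre-filter), `filters` (record of
#'   thresholds).
#' @export
topic_term_matrix <- function(corpus, assignments, min_count = 5,
                              alpha_level = 0.05) {
  M <- corpus_size(corpus)
  if (length(assignments) != M) stop("assignments must cover all documents")
  K <- max(assignments)
  terms <- sort(unique(unlist(corpus$tags, use.names = FALSE)))
  counts <- matrix(0L, length(terms), K,
                   dimnames = list(terms, paste0("T", seq_len(K))))
  for (j in seq_len(M)) {
    tg <- corpus$tags[[j]]
    if (length(tg) > 0L) {
      counts[tg, assignments[j]] <- counts[tg, assignments[j]] + 1L
    }
  }
  margin <- tabulate(assignments, nbins = K)
  pvals <- apply(counts, 1L, .topic_assoc_p, margin = margin)
  keep <- rowSums(counts) > min_count & pvals < alpha_level
  structure(
    list(counts = counts[keep, , drop = FALSE],
         all_counts = counts, p_values = pvals,
         filters = list(min_count = min_count, rule = "strict >",
                        test = "chi-square vs topic margin",
                        alpha_level = alpha_level)),
    class = "term_topic_matrix"
  )
}

#' @export
print.term_topic_matrix <- function(x, ...) {
  cat("Topic-term matrix: ", nrow(x$counts), " of ", nrow(x$all_counts),
      " terms retained (total > ", x$filters$min_count,
      ", association p < ", x$filters$alpha_level, ")\n", sep = "")
  invisible(x)
}

#' High-frequency terms per year
#'
#' Document counts per (term, year); a term is reported for a year only when
#' its count that year reaches `min_count` (inclusive).
#'
#' @param corpus a [lit_corpus()].
#' @param min_count inclusive per-year threshold.
#' @return data.frame with columns `term`, `year`, `count`, sorted by year
#'   then decreasing count; attribute `"full_counts"` holds the unfiltered
#'   term x year matrix.
#' @export
annual_terms <- function(corpus, min_count = 6) {
  tag_year <- data.frame(
    term = unlist(corpus$tags, use.names = FALSE),
    year = rep(corpus$docs$year, lengths(corpus$tags)),
    stringsAsFactors = FALSE
  )
  if (nrow(tag_year) == 0L) {
    out <- data.frame(term = character(0), year = integer(0),
                      count = integer(0))
    attr(out, "full_counts") <- matrix(0L, 0, 0)
    return(out)
  }
  tab <- table(tag_year$term, tag_year$year)
  long <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(long) <- c("term", "year", "count")
  long$year <- as.integer(long$year)
  long <- long[long$count >= min_count, , drop = FALSE]
  long <- long[order(long$year, -long$count, long$term), , drop = FALSE]
  rownames(long) <- NULL
  attr(long, "full_counts") <- unclass(tab)
  long
}

#' First emergence year of every term
#'
#' Tracks, independently of frequency, the first corpus year in which each
#' tag appears. Terms first seen in the corpus's earliest year are flagged
#' left-censored: they may well have existed before the observation window.
#' Reporting starts at `start_year`.
#'
#' @param corpus a [lit_corpus()].
#' @param start_year first year to report; defaults to the corpus minimum.
#' @return data.frame with columns `term`, `first_year`, `left_censored`,
#'   sorted by first_year then term; attribute `"annual_counts"` holds the
#'   full term x year document-count matrix.
#' @export
term_emergence <- function(corpus, start_year = min(corpus$docs$year)) {
  yrs <- corpus$docs$year
  if (start_year < min(yrs) || start_year > max(yrs)) {
    stop("start_year outside corpus year range")
  }
  tag_year <- data.frame(
    term = unlist(corpus$tags, use.names = FALSE),
    year = rep(yrs, lengths(corpus$tags)),
    stringsAsFactors = FALSE
  )
  if (nrow(tag_year) == 0L) {
    out <- data.frame(term = character(0), first_year = integer(0),
                      left_censored = logical(0))
    attr(out, "annual_counts") <- matrix(0L, 0, 0)
    return(out)
  }
  first <- tapply(tag_year$year, tag_year$term, min)
  out <- data.frame(term = names(first),
                    first_year = as.integer(first),
                    left_censored = as.integer(first) == min(yrs),
                    stringsAsFactors = FALSE)
  out <- out[out$first_year >= start_year, , drop = FALSE]
  out <- out[order(out$first_year, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "annual_counts") <- unclass(table(tag_year$term, tag_year$year))
  out
}

# case-sensitive whole-token split of raw text
.raw_tokens <- function(text) {
  strsplit(text, "[^A-Za-z0-9-]+")
}

#' Extract gene mentions by lexicon matching with a TF-IDF filter
#'
#' Case-sensitive whole-token matching of gene symbols against the raw
#' (uncleaned) text. A matched symbol is counted only if its corpus TF-IDF
#' weight, `total term frequency * ln(M / document frequency)`, reaches
#' `tfidf_min`. The default `tfidf_min = 0` is a pass-through except for
#' symbols present in every document (their IDF is 0, so any positive
#' threshold excludes them).
#'
#' @param corpus a [lit_corpus()].
#' @param lexicon character vector of gene symbols (non-empty).
#' @param tfidf_min minimum corpus TF-IDF weight for a symbol to be counted.
#' @return an object of class `gene_counts`: list with `counts` (documents x
#'   genes mention matrix, only genes surviving the filter), `totals`,
#'   `tfidf` (named weights of all matched genes), `doc_id`.
#' @export
extract_genes <- function(corpus, lexicon, tfidf_min = 0) {
  if (length(lexicon) == 0L) stop("gene lexicon is empty")
  lexicon <- unique(as.character(lexicon))
  toks <- .raw_tokens(corpus$docs$text)
  M <- corpus_size(corpus)
  counts <- matrix(0L, M, length(lexicon),
                   dimnames = list(corpus$docs$doc_id, lexicon))
  for (j in seq_len(M)) {
    hit <- toks[[j]][toks[[j]] %in% lexicon]
    if (length(hit) > 0L) {
      t <- table(hit)
      counts[j, names(t)] <- as.integer(t)
    }
  }
  tf <- colSums(counts)
  df <- colSums(counts > 0L)
  present <- tf > 0L
  tfidf <- ifelse(present, tf * log(M / pmax(df, 1L)), 0)
  keep <- present & tfidf >= tfidf_min
  structure(
    list(counts = counts[, keep, drop = FALSE],
         totals = tf[keep], tfidf = tfidf[present],
         doc_id = corpus$docs$doc_id),
    class = "gene_counts"
  )
}

#' @export
print.gene_counts <- function(x, ...) {
  cat("Gene mentions: ", ncol(x$counts), " symbols, ",
      sum(x$totals), " mentions across ", nrow(x$counts),
      " documents\n", sep = "")
  invisible(x)
}

#' Gene frequency, topic association and emergence trends
#'
#' Retains genes mentioned at least `min_total` times (inclusive) whose
#' distribution over dominant topics differs significantly from the topic
#' margin (same chi-square test as [topic_term_matrix()]); tabulates counts
#' per year (mentions by default, or distinct documents), counts per topic,
#' and each retained gene's first year of appearance.
#'
#' @param genes a `gene_counts` object from [extract_genes()].
#' @param years per-document years, aligned with the gene count rows.
#' @param assignments per-document dominant topics.
#' @param min_total inclusive total-count threshold.
#' @param alpha_level significance level of the association test.
#' @param count_mode `"mentions"` counts every occurrence; `"documents"`
#'   counts each document once.
#' @return list with `gene_year` (genes x years), `gene_topic` (genes x
#'   topics), `first_year` (named integer vector), `new_by_year` (list:
#'   year -> genes first seen that year), `p_values`, `filters`.
#' @export
gene_trends <- function(genes, years, assignments, min_total = 2,
                        alpha_level = 0.05,
                        count_mode = c("mentions", "documents")) {
  count_mode <- match.arg(count_mode)
  counts <- genes$counts
  if (nrow(counts) != length(years) || nrow(counts) != length(assignments)) {
    stop("years and assignments must align with the gene count rows")
  }
  if (count_mode == "documents") counts <- (counts > 0L) + 0L
  K <- max(assignments)
  gene_topic <- t(rowsum(counts, group = assignments))
  full_topic <- matrix(0L, ncol(counts), K,
                       dimnames = list(colnames(counts), paste0("T", 1:K)))
  full_topic[, as.integer(colnames(gene_topic))] <- gene_topic
  margin <- tabulate(assignments, nbins = K)
  pvals <- apply(full_topic, 1L, .topic_assoc_p, margin = margin)
  keep <- colSums(counts) >= min_total & pvals < alpha_level
  kept <- colnames(counts)[keep]
  gene_year <- t(rowsum(counts[, keep, drop = FALSE], group = years))
  first_year <- vapply(kept, function(g) {
    yrs_g <- years[counts[, g] > 0L]
    as.integer(min(yrs_g))
  }, integer(1))
  new_by_year <- split(names(first_year), first_year)
  list(gene_year = gene_year,
       gene_topic = full_topic[keep, , drop = FALSE],
       first_year = first_year, new_by_year = new_by_year,
       p_values = pvals,
       filters = list(min_total = min_total, rule = "inclusive >=",
                      alpha_level = alpha_level, count_mode = count_mode))
}
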