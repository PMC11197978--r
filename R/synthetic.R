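# Synthetic corpus generation from a known LDA process.
#
# Every downstream stage is validated against corpora whose topic-word rows
# (phi), document mixtures (theta), token assignments (z), tag-topic and
# gene-topic maps are known exactly. Junk topics can be planted for the
# significance-ranking benchmarks: a "uniform" topic emits every vocabulary
# word with probability 1/V; a "vacuous" topic emits the expected word
# marginal of the non-junk topics.

#' Specification of a synthetic LDA corpus
#'
#' @param K_true number of topics, including planted junk topics.
#' @param V vocabulary size, `>= K_true`.
#' @param M number of documents.
#' @param alpha document-topic Dirichlet concentration (symmetric).
#' @param beta topic-word Dirichlet concentration used to draw the non-junk
#'   topic rows (symmetric); ignored for rows supplied via `phi`.
#' @param doc_length_mean expected tokens per document; lengths are Poisson
#'   draws truncated at a minimum of 5 so no document is degenerate.
#' @param years inclusive integer year range; document years are uniform
#'   over it unless skewed.
#' @param junk_plants character vector, each `"uniform"` or `"vacuous"`;
#'   planted topics occupy the last indices.
#' @param tag_lexicon_size number of distinct subject tags.
#' @param tags_per_doc_mean expected tags per document (Poisson).
#' @param tag_enrichment probability that a document's tag is drawn from its
#'   dominant topic's preferred tags rather than from the whole lexicon.
#' @param gene_lexicon character vector of gene symbols to embed (may be
#'   empty).
#' @param gene_rate expected gene mentions per document (Poisson).
#' @param skew_topic optional topic index whose documents are pushed into
#'   `skew_years` (year skew is off by default).
#' @param skew_years integer years used for `skew_topic` documents.
#' @param phi optional fixed `K_true x V` row-stochastic matrix for the
#'   non-junk rows (used by [separated_spec()]).
#' @param seed integer seed; generation is byte-reproducible.
#' @return a list of class `corpus_spec`.
#' @export
corpus_spec <- function(K_true, V, M, alpha = 0.1, beta = 0.05,
                        doc_length_mean = 60, years = 2013:2022,
                        junk_plants = character(0),
                        tag_lexicon_size = 40, tags_per_doc_mean = 3,
                        tag_enrichment = 0.8,
                        gene_lexicon = character(0), gene_rate = 0,
                        skew_topic = NULL, skew_years = NULL,
                        phi = NULL, seed = 1L) {
  if (K_true < 1L) stop("K_true must be >= 1")
  if (V < K_true) stop("V must be >= K_true")
  if (M < 1L) stop("M must be >= 1")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (tag_enrichment < 0 || tag_enrichment > 1) {
    stop("tag_enrichment must lie in [0, 1]")
  }
  junk_plants <- as.character(junk_plants)
  if (!all(junk_plants %in% c("uniform", "vacuous"))) {
    stop("junk_plants entries must be 'uniform' or 'vacuous'")
  }
  if (length(junk_plants) >= K_true) {
    stop("need at least one non-junk topic")
  }
  if (!is.null(phi)) {
    stopifnot(nrow(phi) == K_true, ncol(phi) == V)
  }
  structure(
    list(K_true = as.integer(K_true), V = as.integer(V), M = as.integer(M),
         alpha = alpha, beta = beta, doc_length_mean = doc_length_mean,
         years = as.integer(years), junk_plants = junk_plants,
         tag_lexicon_size = as.integer(tag_lexicon_size),
         tags_per_doc_mean = tags_per_doc_mean,
         tag_enrichment = tag_enrichment,
         gene_lexicon = as.character(gene_lexicon), gene_rate = gene_rate,
         skew_topic = skew_topic, skew_years = skew_years,
         phi = phi, seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Maximally separated synthetic specification
#'
#' Topics with disjoint support: topic k is uniform over its own block of
#' `V / K` vocabulary words, so any two topic rows have cosine similarity 0
#' and each row's KL divergence from the uniform distribution over V is
#' exactly `ln(K)`. This is the most recoverable fixture and anchors the
#' parameter-recovery and K-selection validations.
#'
#' @param K number of topics.
#' @param V vocabulary size; must be divisible by K.
#' @param M number of documents.
#' @param doc_length_mean expected tokens per document.
#' @param alpha document-topic concentration.
#' @param seed integer seed.
#' @return a `corpus_spec` whose `phi` is the block-uniform matrix.
#' @export
separated_spec <- function(K, V, M = 400, doc_length_mean = 60,
                           alpha = 0.1, seed = 1L) {
  if (V %% K != 0L) stop("V must be divisible by K")
  block <- V / K
  phi <- matrix(0, K, V)
  for (k in seq_len(K)) {
    phi[k, ((k - 1L) * block + 1L):(k * block)] <- 1 / block
  }
  corpus_spec(K_true = K, V = V, M = M, alpha = alpha,
              doc_length_mean = doc_length_mean, phi = phi, seed = seed)
}

# Poisson truncated below at min_len (resampling)
.rpois_trunc <- function(n, lambda, min_len = 5L) {
  x <- stats::rpois(n, lambda)
  while (any(x < min_len)) {
    idx <- x < min_len
    x[idx] <- stats::rpois(sum(idx), lambda)
  }
  x
}

.rdirichlet <- function(n, alpha_vec) {
  g <- matrix(stats::rgamma(n * length(alpha_vec), shape = alpha_vec),
              n, length(alpha_vec), byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic corpus with known ground truth
#'
#' Samples documents by the standard LDA generative process: for document j,
#' `theta_j ~ Dirichlet(alpha)`; for each of `N_j ~ Poisson(doc_length_mean)`
#' (truncated at 5) tokens, `z ~ Categorical(theta_j)` and
#' `w ~ Categorical(phi_z)`. Planted junk rows are fixed as described in
#' [corpus_spec()]. Document years are uniform over the year range; subject
#' tags are drawn from the dominant topic's preferred tags with probability
#' `tag_enrichment`; gene mentions are appended to the text as literal
#' upper-case symbols drawn from the dominant topic's genes.
#'
#' @param spec a [corpus_spec()].
#' @return list with `corpus` (a [lit_corpus()]), `tokens` (the exact
#'   `lda_tokens` over the full vocabulary, bypassing text round-trip), and
#'   `truth` (list: `phi_true`, `theta_true`, `z_true`, `junk_ids`,
#'   `tag_topic_map`, `gene_topic_map`, `dominant_true`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, .generate_corpus_impl(spec))
}

.generate_corpus_impl <- function(spec) {
  K <- spec$K_true; V <- spec$V; M <- spec$M
  n_junk <- length(spec$junk_plants)
  junk_ids <- if (n_junk > 0L) (K - n_junk + 1L):K else integer(0)
  real_ids <- setdiff(seq_len(K), junk_ids)

  phi <- if (!is.null(spec$phi)) spec$phi else
    .rdirichlet(K, rep(spec$beta, V))
  for (i in seq_along(junk_ids)) {
    kind <- spec$junk_plants[i]
    k <- junk_ids[i]
    if (kind == "uniform") {
      phi[k, ] <- 1 / V
    } else {
      phi[k, ] <- colMeans(phi[real_ids, , drop = FALSE])
    }
  }

  theta <- .rdirichlet(M, rep(spec$alpha, K))
  dominant <- max.col(theta, ties.method = "first")
  lens <- .rpois_trunc(M, spec$doc_length_mean)

  # token-level draws, grouped by topic for speed
  z_true <- vector("list", M)
  w <- vector("list", M)
  doc_of_tok <- rep(seq_len(M), lens)
  z_flat <- integer(length(doc_of_tok))
  pos <- 1L
  for (j in seq_len(M)) {
    zj <- sample.int(K, lens[j], replace = TRUE, prob = theta[j, ])
    z_true[[j]] <- zj
    z_flat[pos:(pos + lens[j] - 1L)] <- zj
    pos <- pos + lens[j]
  }
  w_flat <- integer(length(z_flat))
  for (k in seq_len(K)) {
    idx <- which(z_flat == k)
    if (length(idx) > 0L) {
      w_flat[idx] <- sample.int(V, length(idx), replace = TRUE,
                                prob = phi[k, ])
    }
  }
  w <- split(w_flat, doc_of_tok)

  years <- sample(spec$years, M, replace = TRUE)
  if (!is.null(spec$skew_topic)) {
    sk <- dominant == spec$skew_topic
    years[sk] <- sample(as.integer(spec$skew_years), sum(sk), replace = TRUE)
  }

  vocab <- sprintf("wv%04d", seq_len(V))

  # topic-enriched tags
  tag_lex <- sprintf("tag%03d", seq_len(spec$tag_lexicon_size))
  tag_topic_map <- setNames(rep(seq_len(K), length.out = length(tag_lex)),
                            tag_lex)
  tags <- vector("list", M)
  for (j in seq_len(M)) {
    n_tags <- stats::rpois(1, spec$tags_per_doc_mean)
    if (n_tags == 0L || length(tag_lex) == 0L) {
      tags[[j]] <- character(0)
      next
    }
    own <- tag_lex[tag_topic_map == dominant[j]]
    pick <- vapply(seq_len(n_tags), function(i) {
      if (length(own) > 0L && stats::runif(1) < spec$tag_enrichment) {
        sample(own, 1L)
      } else {
        sample(tag_lex, 1L)
      }
    }, character(1))
    tags[[j]] <- unique(pick)
  }

  # gene mentions, appended as literal upper-case symbols
  gene_topic_map <- if (length(spec$gene_lexicon) > 0L) {
    setNames(rep(seq_len(K), length.out = length(spec$gene_lexicon)),
             spec$gene_lexicon)
  } else {
    integer(0)
  }
  gene_suffix <- character(M)
  if (length(spec$gene_lexicon) > 0L && spec$gene_rate > 0) {
    for (j in seq_len(M)) {
      n_g <- stats::rpois(1, spec$gene_rate)
      if (n_g == 0L) next
      own <- spec$gene_lexicon[gene_topic_map == dominant[j]]
      pool <- if (length(own) > 0L) own else spec$gene_lexicon
      gene_suffix[j] <- paste(sample(pool, n_g, replace = TRUE),
                              collapse = " ")
    }
  }

  text <- vapply(seq_len(M), function(j) {
    body <- paste(vocab[w[[j]]], collapse = " ")
    if (nzchar(gene_suffix[j])) paste(body, gene_suffix[j]) else body
  }, character(1))

  doc_id <- sprintf("S%05d", seq_len(M))
  corpus <- lit_corpus(doc_id, years, text, tags,
                       provenance = "synthetic LDA generator")
  tokens <- new_lda_tokens(w, vocab, doc_id, years)
  list(
    corpus = corpus,
    tokens = tokens,
    truth = list(phi_true = phi, theta_true = theta, z_true = z_true,
                 junk_ids = junk_ids, tag_topic_map = tag_topic_map,
                 gene_topic_map = gene_topic_map, dominant_true = dominant)
  )
}

#' Write the ground-truth sidecar of a generated corpus
#'
#' JSON sidecar with phi, theta, junk ids and the tag/gene topic maps, next
#' to the tabular corpus written by [write_corpus_table()].
#'
#' @param generated output of [generate_corpus()].
#' @param path output JSON path.
#' @export
write_truth_sidecar <- function(generated, path) {
  tr <- generated$truth
  jsonlite::write_json(
    list(phi_true = tr$phi_true, theta_true = tr$theta_true,
         junk_ids = tr$junk_ids, tag_topic_map = as.list(tr$tag_topic_map),
         gene_topic_map = as.list(tr$gene_topic_map)),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(NULL)
}

#' Greedy topic matching by total-variation distance
#'
#' Matches estimated topic-word rows to reference rows: repeatedly pairs the
#' globally closest (estimated, reference) rows by total-variation distance
#' `0.5 * sum |p - q|` until all are matched.
#'
#' @param phi_est,phi_ref row-stochastic matrices with equal dimensions.
#' @return list with `perm` (perm[i] = reference row matched to estimated
#'   row i) and `tv` (per-pair total-variation distances, in estimated-row
#'   order).
#' @export
match_topics <- function(phi_est, phi_ref) {
  stopifnot(nrow(phi_est) == nrow(phi_ref), ncol(phi_est) == ncol(phi_ref))
  K <- nrow(phi_est)
  d <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      d[i, j] <- 0.5 * sum(abs(phi_est[i, ] - phi_ref[j, ]))
    }
  }
  perm <- integer(K)
  tv <- numeric(K)
  dd <- d
  for (step in seq_len(K)) {
    idx <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    perm[idx[1]] <- idx[2]
    tv[idx[1]] <- d[idx[1], idx[2]]
    dd[idx[1], ] <- Inf
    dd[, idx[2]] <- Inf
  }
  list(perm = perm, tv = tv)
}
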