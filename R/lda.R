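# Latent Dirichlet allocation by collapsed Gibbs sampling.
#
# Model: each document j draws a topic mixture theta_j ~ Dirichlet(alpha);
# each token draws a topic z ~ Categorical(theta_j) and a word
# w ~ Categorical(phi_z), with phi_k ~ Dirichlet(beta) over the vocabulary.
# Inference collapses phi and theta analytically and samples the token-level
# assignments z; point estimates are posterior means given the final state:
#   phi[k, w]  = (n_kw + beta) / (n_k  + V beta)
#   theta[j, k] = (n_jk + alpha) / (N_j + K alpha)

#' Fit LDA by collapsed Gibbs sampling
#'
#' @param tokens an `lda_tokens` object from [tokenize_corpus()] or
#'   [generate_corpus()].
#' @param K number of topics, `>= 1`.
#' @param alpha symmetric document-topic concentration; default `50 / K`.
#' @param beta symmetric topic-word concentration; default `0.1`.
#' @param n_iter total Gibbs sweeps over all tokens; must exceed `burn_in`.
#' @param burn_in sweeps discarded before the log-likelihood trace and
#'   posterior occupancy accumulators start.
#' @param seed integer seed; runs are exactly reproducible for a fixed seed.
#' @param n_starts number of independently initialized chains; the chain
#'   with the highest final complete-data log likelihood is kept. Collapsed
#'   Gibbs can lock into a merged-topic mode it never escapes; a few
#'   restarts make recovery reliable. Chain s uses seed `seed + (s-1)*7919`.
#' @param sample_every if positive, store a full assignment snapshot every
#'   `sample_every` post-burn-in sweeps (only sensible for tiny corpora).
#' @return an object of class `lda_gibbs` with components `K`, `alpha`,
#'   `beta`, `phi` (K x V, rows sum to 1), `theta` (M x K), `z` (1-based
#'   token assignments), count tables `nkw`/`njk`, `loglik_trace` (one
#'   complete-data log likelihood per post-burn-in sweep), `z_marginal`
#'   (per-token posterior topic occupancy frequencies), `vocab`, `doc_id`,
#'   `doc_lengths`, and the call parameters.
#' @seealso [select_k()], [tsr()], [lda_exact_posterior()]
#' @export
lda_gibbs <- function(tokens, K, alpha = 50 / K, beta = 0.1,
                      n_iter = 500, burn_in = 250, seed = 1L,
                      n_starts = 1L, sample_every = 0L) {
  stopifnot(inherits(tokens, "lda_tokens"))
  if (K < 1L) stop("K must be >= 1")
  if (n_iter <= 0L) stop("n_iter must be positive")
  if (burn_in < 0L || n_iter <= burn_in) stop("need n_iter > burn_in >= 0")
  if (n_starts < 1L) stop("n_starts must be >= 1")
  total_tokens <- sum(tokens$n_tokens)
  if (total_tokens == 0L) stop("corpus has no tokens")
  if (K > total_tokens) stop("K exceeds the total token count")
  V <- tokens$V
  docs0 <- lapply(tokens$doc_tokens, function(x) x - 1L)  # 0-based for C++

  res <- NULL
  seed_used <- seed
  best_ll <- -Inf
  for (s in seq_len(n_starts)) {
    seed_s <- as.integer(seed + (s - 1L) * 7919L)
    res_s <- with_seed(seed_s, .gibbs_lda_cpp(docs0, V, as.integer(K),
                                              alpha, beta,
                                              as.integer(n_iter),
                                              as.integer(burn_in),
                                              as.integer(sample_every)))
    ll_s <- res_s$loglik_trace[length(res_s$loglik_trace)]
    if (ll_s > best_ll) {
      res <- res_s
      best_ll <- ll_s
      seed_used <- seed_s
    }
  }

  nkw <- res$nkw
  njk <- res$njk
  phi <- (nkw + beta) / (rowSums(nkw) + V * beta)
  theta <- (njk + alpha) / (tokens$n_tokens + K * alpha)
  colnames(phi) <- tokens$vocab
  rownames(theta) <- tokens$doc_id
  structure(
    list(K = as.integer(K), alpha = alpha, beta = beta,
         phi = phi, theta = theta,
         z = lapply(res$z, function(x) x + 1L),
         nkw = nkw, njk = njk,
         loglik_trace = res$loglik_trace,
         z_marginal = res$z_marginal,
         z_samples = if (sample_every > 0L)
           lapply(res$z_samples, function(x) x + 1L) else NULL,
         vocab = tokens$vocab, doc_id = tokens$doc_id,
         year = tokens$year,
         doc_lengths = tokens$n_tokens,
         n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         seed = as.integer(seed), seed_used = seed_used,
         n_starts = as.integer(n_starts)),
    class = c("lda_gibbs", "lda_model")
  )
}

#' Wrap externally specified topic-word and document-topic matrices
#'
#' Builds the minimal model object that the significance-ranking functions
#' ([tsr()], [temporal_tsr()], [dominant_topics()]) operate on, from any
#' row-stochastic `phi` and `theta` — a model fitted by other software, or a
#' synthetic generator's ground truth.
#'
#' @param phi K x V row-stochastic topic-word matrix.
#' @param theta M x K row-stochastic document-topic matrix.
#' @param tokens an `lda_tokens` object supplying vocabulary, document ids
#'   and years (dimensions must agree with `phi` and `theta`).
#' @return an object of class `lda_model`.
#' @export
lda_model <- function(phi, theta, tokens) {
  stopifnot(inherits(tokens, "lda_tokens"))
  phi <- as.matrix(phi); theta <- as.matrix(theta)
  if (ncol(phi) != tokens$V) stop("phi columns must match the vocabulary")
  if (nrow(theta) != length(tokens$doc_tokens)) {
    stop("theta rows must match the document count")
  }
  if (ncol(theta) != nrow(phi)) stop("phi and theta disagree on K")
  if (max(abs(rowSums(phi) - 1)) > 1e-6 ||
      max(abs(rowSums(theta) - 1)) > 1e-6) {
    stop("phi and theta rows must sum to 1")
  }
  colnames(phi) <- tokens$vocab
  rownames(theta) <- tokens$doc_id
  structure(
    list(K = nrow(phi), phi = phi, theta = theta,
         vocab = tokens$vocab, doc_id = tokens$doc_id, year = tokens$year,
         doc_lengths = tokens$n_tokens),
    class = "lda_model"
  )
}

#' Complete-data log likelihood of a fitted model
#'
#' Computes `log P(W | Z, beta) + log P(Z | alpha)` from the current count
#' tables via the collapsed Dirichlet-multinomial closed form (ratios of
#' log-gamma terms). Agrees with the last entry of `loglik_trace` (which the
#' sampler computes incrementally in C++) to numerical precision.
#'
#' @param object a fitted `lda_gibbs` model.
#' @param ... unused.
#' @return an object of class `logLik`.
#' @export
logLik.lda_gibbs <- function(object, ...) {
  K <- object$K; V <- length(object$vocab)
  alpha <- object$alpha; beta <- object$beta
  nkw <- object$nkw; njk <- object$njk
  ll <- K * (lgamma(V * beta) - V * lgamma(beta)) +
    nrow(njk) * (lgamma(K * alpha) - K * lgamma(alpha)) +
    sum(lgamma(nkw + beta)) - sum(lgamma(rowSums(nkw) + V * beta)) +
    sum(lgamma(njk + alpha)) - sum(lgamma(rowSums(njk) + K * alpha))
  structure(ll, df = K * (V - 1) + length(object$doc_lengths) * (K - 1),
            class = "logLik")
}

#' @export
print.lda_gibbs <- function(x, ...) {
  cat("LDA (collapsed Gibbs): K = ", x$K, ", ", nrow(x$theta),
      " documents, vocabulary ", length(x$vocab), "\n", sep = "")
  cat("  alpha = ", format(x$alpha, digits = 4),
      ", beta = ", format(x$beta, digits = 4),
      ", sweeps = ", x$n_iter, " (burn-in ", x$burn_in, "), seed = ",
      x$seed, "\n", sep = "")
  cat("  final complete-data logLik = ",
      format(x$loglik_trace[length(x$loglik_trace)], digits = 8), "\n",
      sep = "")
  invisible(x)
}

#' Summarize a fitted LDA model
#'
#' @param object a fitted `lda_gibbs` model.
#' @param n_words how many top words to show per topic.
#' @param ... unused.
#' @return invisibly, a data.frame of top words per topic with their
#'   probabilities.
#' @export
summary.lda_gibbs <- function(object, n_words = 8, ...) {
  print(object)
  mass <- colSums(object$theta * object$doc_lengths) /
    sum(object$doc_lengths)
  out <- do.call(rbind, lapply(seq_len(object$K), function(k) {
    ord <- order(object$phi[k, ], decreasing = TRUE)[seq_len(n_words)]
    data.frame(topic = k, token_share = mass[k],
               top_words = paste(object$vocab[ord], collapse = " "),
               stringsAsFactors = FALSE)
  }))
  cat("\nTop words per topic:\n")
  for (k in seq_len(object$K)) {
    cat(sprintf("  T%-2d (%.3f): %s\n", k, out$token_share[k],
                out$top_words[k]))
  }
  invisible(out)
}

#' @export
coef.lda_gibbs <- function(object, ...) object$phi

#' Dominant-topic prediction for documents
#'
#' Returns each document's dominant topic, `argmax_k theta[j, k]`, with ties
#' broken toward the lower topic index.
#'
#' @param object a fitted `lda_gibbs` model.
#' @param ... unused.
#' @return integer vector of topic indices (1-based), named by document id.
#' @export
predict.lda_gibbs <- function(object, ...) {
  dominant_topics(object)
}

#' @export
plot.lda_gibbs <- function(x, ...) {
  it <- x$burn_in + seq_along(x$loglik_trace)
  plot(it, x$loglik_trace, type = "l", xlab = "Gibbs sweep",
       ylab = "complete-data log likelihood",
       main = sprintf("LDA sampler trace (K = %d)", x$K), ...)
  invisible(x)
}

#' Exact LDA posterior by exhaustive enumeration
#'
#' Brute-force reference for validating the Gibbs sampler on tiny corpora:
#' sums the collapsed joint P(Z, W | alpha, beta) over all K^T assignments
#' (T = total tokens) and returns exact per-token posterior topic marginals
#' and pairwise same-topic probabilities. Only feasible for `K^T` up to a
#' few million.
#'
#' @param tokens an `lda_tokens` object with at most ~12 tokens in total.
#' @param K,alpha,beta model hyperparameters.
#' @return list with `marginal` (T x K matrix of P(z_t = k | W), tokens in
#'   document order), `same_topic` (T x T matrix of P(z_s = z_t | W)), and
#'   `log_evidence` (log P(W)).
#' @export
lda_exact_posterior <- function(tokens, K, alpha, beta) {
  stopifnot(inherits(tokens, "lda_tokens"))
  words <- unlist(tokens$doc_tokens, use.names = FALSE)
  docs <- rep(seq_along(tokens$doc_tokens), lengths(tokens$doc_tokens))
  T <- length(words)
  if (T == 0L) stop("empty corpus")
  if (K^T > 2^22) stop("enumeration infeasible: K^T too large")
  V <- tokens$V
  M <- length(tokens$doc_tokens)
  Nj <- tokens$n_tokens

  n_states <- K^T
  logw <- numeric(n_states)
  marg <- matrix(0, T, K)
  same <- matrix(0, T, T)
  z <- integer(T)
  const <- K * (lgamma(V * beta) - V * lgamma(beta)) +
    M * (lgamma(K * alpha) - K * lgamma(alpha)) -
    sum(lgamma(Nj + K * alpha))
  assign_ll <- function(z) {
    nkw <- matrix(0L, K, V)
    njk <- matrix(0L, M, K)
    for (t in seq_len(T)) {
      nkw[z[t], words[t]] <- nkw[z[t], words[t]] + 1L
      njk[docs[t], z[t]] <- njk[docs[t], z[t]] + 1L
    }
    const + sum(lgamma(nkw + beta)) - sum(lgamma(rowSums(nkw) + V * beta)) +
      sum(lgamma(njk + alpha))
  }
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  logw <- apply(states, 1L, assign_ll)
  lz <- max(logw) + log(sum(exp(logw - max(logw))))
  wts <- exp(logw - lz)
  for (k in seq_len(K)) marg[, k] <- colSums(wts * (states == k))
  for (s in seq_len(T)) {
    eq <- states == states[, s]
    same[s, ] <- colSums(wts * eq)
  }
  list(marginal = marg, same_topic = same, log_evidence = lz)
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
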