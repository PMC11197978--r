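# Topic-number selection metrics.
#
# Four standard statistics over a grid of candidate K: Arun2010 and
# CaoJuan2009 are minimized, Deveaud2014 and Griffiths2004 maximized. The
# final K remains a human decision; select_k() reports per-metric optima and
# a consensus note but never auto-commits a K.

.EPS <- 1e-12

.kl_vec <- function(p, q) {
  # KL divergence with 0 * log 0 = 0 and epsilon-smoothed denominator
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (q[nz] + .EPS)))
}

#' Cao-Juan 2009 topic-density metric (minimize)
#'
#' Mean cosine similarity over all K(K-1)/2 pairs of topic-word rows; lower
#' values mean better-separated topics.
#'
#' @param model a fitted `lda_gibbs` model (or any list with a row-stochastic
#'   `phi` and `K >= 2`).
#' @return scalar in `[0, 1]` for nonnegative phi.
#' @export
metric_caojuan2009 <- function(model) {
  phi <- model$phi
  K <- nrow(phi)
  if (K < 2L) stop("CaoJuan2009 requires K >= 2")
  nrm <- sqrt(rowSums(phi^2))
  cosmat <- (phi %*% t(phi)) / outer(nrm, nrm)
  mean(cosmat[upper.tri(cosmat)])
}

#' Deveaud 2014 topic-divergence metric (maximize)
#'
#' Mean over topic pairs of the symmetrized KL divergence
#' `0.5 * (KL(p||q) + KL(q||p))` between smoothed topic-word rows.
#'
#' @inheritParams metric_caojuan2009
#' @return nonnegative scalar.
#' @export
metric_deveaud2014 <- function(model) {
  phi <- model$phi
  K <- nrow(phi)
  if (K < 2L) stop("Deveaud2014 requires K >= 2")
  tot <- 0
  for (a in seq_len(K - 1L)) {
    for (b in seq(a + 1L, K)) {
      tot <- tot + 0.5 * (.kl_vec(phi[a, ], phi[b, ]) +
                          .kl_vec(phi[b, ], phi[a, ]))
    }
  }
  tot / (K * (K - 1L) / 2)
}

#' Arun 2010 divergence metric (minimize)
#'
#' Symmetric KL divergence `KL(c1||c2) + KL(c2||c1)` between (i) the
#' L1-normalized singular values of the topic-word matrix phi and (ii) the
#' L1-normalized topic-mass vector `doc_lengths %*% theta`, both sorted in
#' decreasing order and epsilon-smoothed before logs.
#'
#' @param model a fitted `lda_gibbs` model.
#' @param doc_lengths per-document token counts; defaults to the lengths
#'   stored in the model.
#' @return nonnegative scalar; 0 when K = 1.
#' @export
metric_arun2010 <- function(model, doc_lengths = model$doc_lengths) {
  phi <- model$phi
  theta <- model$theta
  c1 <- svd(phi, nu = 0, nv = 0)$d
  c1 <- sort(c1 / sum(c1), decreasing = TRUE)
  c2 <- as.numeric(doc_lengths %*% theta)
  c2 <- sort(c2 / sum(c2), decreasing = TRUE)
  .kl_vec(c1, c2) + .kl_vec(c2, c1)
}

#' Griffiths 2004 harmonic-mean marginal likelihood (maximize)
#'
#' Harmonic-mean estimator of `log P(W | K)` from post-burn-in complete-data
#' log-likelihood samples, computed in log space:
#' `-(logsumexp(-l) - log S)`.
#'
#' @param loglik_samples numeric vector of log-likelihood samples (for a
#'   fitted model, its `loglik_trace`).
#' @return scalar estimate of `log P(W | K)`; never exceeds the sample
#'   maximum.
#' @export
metric_griffiths2004 <- function(loglik_samples) {
  if (length(loglik_samples) == 0L) stop("no log-likelihood samples")
  x <- -loglik_samples
  m <- max(x)
  -(m + log(sum(exp(x - m))) - log(length(x)))
}

#' Sweep candidate topic numbers and score each with four metrics
#'
#' Fits one model per candidate K (each fit seeded `seed + K` so that a
#' change in one fit's draw count never perturbs another) and evaluates
#' Arun2010, CaoJuan2009 (both minimized), Deveaud2014 and Griffiths2004
#' (both maximized).
#'
#' @param tokens an `lda_tokens` object.
#' @param k_grid integer vector of candidate topic counts, all `>= 2`.
#' @param alpha document-topic concentration; `NULL` means `50 / K` per fit.
#' @param beta topic-word concentration.
#' @param n_iter,burn_in Gibbs sweep counts per fit.
#' @param n_starts restarts per fit (best chain kept, see [lda_gibbs()]).
#' @param seed base seed.
#' @return an object of class `lda_selection`: data.frame `report` with
#'   columns k, arun2010, caojuan2009, deveaud2014, griffiths2004; list
#'   `recommended` with each metric's optimal k and a `consensus` note
#'   (median of the four per-metric optima); the fitted models are not kept.
#' @export
select_k <- function(tokens, k_grid, alpha = NULL, beta = 0.1,
                     n_iter = 300, burn_in = 150, n_starts = 1L, seed = 1L) {
  if (length(k_grid) == 0L) stop("k_grid is empty")
  if (any(k_grid < 2L)) stop("k_grid values must be >= 2")
  k_grid <- as.integer(k_grid)
  rows <- lapply(k_grid, function(K) {
    a <- if (is.null(alpha)) 50 / K else alpha
    fit <- lda_gibbs(tokens, K = K, alpha = a, beta = beta,
                     n_iter = n_iter, burn_in = burn_in,
                     n_starts = n_starts, seed = seed + K)
    data.frame(k = K,
               arun2010 = metric_arun2010(fit),
               caojuan2009 = metric_caojuan2009(fit),
               deveaud2014 = metric_deveaud2014(fit),
               griffiths2004 = metric_griffiths2004(fit$loglik_trace))
  })
  report <- do.call(rbind, rows)
  rec <- list(
    arun2010 = report$k[which.min(report$arun2010)],
    caojuan2009 = report$k[which.min(report$caojuan2009)],
    deveaud2014 = report$k[which.max(report$deveaud2014)],
    griffiths2004 = report$k[which.max(report$griffiths2004)]
  )
  rec$consensus <- as.integer(round(stats::median(unlist(rec))))
  structure(list(report = report, recommended = rec, seed = seed),
            class = "lda_selection")
}

#' @export
print.lda_selection <- function(x, ...) {
  cat("Topic-number selection over K = {",
      paste(x$report$k, collapse = ", "), "}\n", sep = "")
  print(x$report, row.names = FALSE, digits = 6)
  r <- x$recommended
  cat("optima: Arun2010 -> ", r$arun2010, " (min), CaoJuan2009 -> ",
      r$caojuan2009, " (min), Deveaud2014 -> ", r$deveaud2014,
      " (max), Griffiths2004 -> ", r$griffiths2004, " (max)\n", sep = "")
  cat("consensus (median of optima): K = ", r$consensus,
      " -- final choice is left to the analyst\n", sep = "")
  invisible(x)
}

#' @export
plot.lda_selection <- function(x, ...) {
  rep <- x$report
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(rep$k, rep$arun2010, type = "b", xlab = "K", ylab = "Arun2010 (min)")
  plot(rep$k, rep$caojuan2009, type = "b", xlab = "K",
       ylab = "CaoJuan2009 (min)")
  plot(rep$k, rep$deveaud2014, type = "b", xlab = "K",
       ylab = "Deveaud2014 (max)")
  plot(rep$k, rep$griffiths2004, type = "b", xlab = "K",
       ylab = "Griffiths2004 (max)")
  invisible(x)
}
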