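# Collapsed Gibbs sampler: closed forms, determinism, count consistency,
# agreement with exhaustive enumeration on tiny corpora.

test_that("K = 1 reduces to closed-form counts", {
  tk <- make_tokens(list(c(1L, 2L, 2L), c(3L, 1L)), c("a", "b", "c"))
  f <- lda_gibbs(tk, K = 1, alpha = 1, beta = 0.5, n_iter = 10, burn_in = 5,
                 seed = 1)
  expect_equal(as.numeric(f$theta), c(1, 1))
  counts <- c(2, 2, 1)
  expect_equal(as.numeric(f$phi),
               (counts + 0.5) / (5 + 3 * 0.5), tolerance = 1e-12)
})

test_that("a two-token one-word corpus has zero complete-data log likelihood", {
  tk <- make_tokens(list(c(1L, 1L)), "w")
  f <- lda_gibbs(tk, K = 1, alpha = 1, beta = 1, n_iter = 5, burn_in = 1,
                 seed = 1)
  expect_equal(as.numeric(logLik(f)), 0, tolerance = 1e-12)
})

test_that("fitting is deterministic for a fixed seed", {
  sp <- corpus_spec(K_true = 3, V = 30, M = 30, doc_length_mean = 15, seed = 4)
  g <- generate_corpus(sp)
  f1 <- lda_gibbs(g$tokens, K = 3, alpha = 0.2, beta = 0.05, n_iter = 50,
                  burn_in = 25, seed = 11)
  f2 <- lda_gibbs(g$tokens, K = 3, alpha = 0.2, beta = 0.05, n_iter = 50,
                  burn_in = 25, seed = 11)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  f3 <- lda_gibbs(g$tokens, K = 3, alpha = 0.2, beta = 0.05, n_iter = 50,
                  burn_in = 25, seed = 12)
  expect_false(identical(f1$z, f3$z))
})

test_that("count tables are exactly consistent with the assignments", {
  sp <- corpus_spec(K_true = 3, V = 25, M = 40, doc_length_mean = 12, seed = 6)
  g <- generate_corpus(sp)
  f <- lda_gibbs(g$tokens, K = 4, alpha = 0.3, beta = 0.1, n_iter = 30,
                 burn_in = 10, seed = 2)
  nkw <- matrix(0L, 4, 25)
  njk <- matrix(0L, 40, 4)
  for (j in seq_along(f$z)) {
    w <- g$tokens$doc_tokens[[j]]
    for (t in seq_along(w)) {
      k <- f$z[[j]][t]
      nkw[k, w[t]] <- nkw[k, w[t]] + 1L
      njk[j, k] <- njk[j, k] + 1L
    }
  }
  expect_identical(nkw, f$nkw)
  expect_identical(njk, f$njk)
  # posterior-mean estimates follow from the counts
  expect_equal(f$phi, (nkw + 0.1) / (rowSums(nkw) + 25 * 0.1),
               ignore_attr = TRUE)
  expect_equal(f$theta, (njk + 0.3) / (lengths(f$z) + 4 * 0.3),
               ignore_attr = TRUE)
  expect_true(all(f$phi > 0) && all(f$theta > 0))
  expect_equal(unname(rowSums(f$phi)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(rowSums(f$theta)), rep(1, 40), tolerance = 1e-9)
})

test_that("the R log-likelihood matches the sampler's incremental trace", {
  sp <- corpus_spec(K_true = 2, V = 20, M = 15, doc_length_mean = 10, seed = 8)
  g <- generate_corpus(sp)
  f <- lda_gibbs(g$tokens, K = 3, alpha = 0.5, beta = 0.2, n_iter = 40,
                 burn_in = 20, seed = 3)
  expect_equal(as.numeric(logLik(f)),
               f$loglik_trace[length(f$loglik_trace)], tolerance = 1e-9)
})

test_that("the log likelihood is invariant to topic relabeling", {
  sp <- corpus_spec(K_true = 2, V = 20, M = 15, doc_length_mean = 10, seed = 9)
  g <- generate_corpus(sp)
  f <- lda_gibbs(g$tokens, K = 3, alpha = 0.5, beta = 0.2, n_iter = 40,
                 burn_in = 20, seed = 3)
  perm <- c(3L, 1L, 2L)
  g2 <- f
  g2$nkw <- f$nkw[perm, , drop = FALSE]
  g2$njk <- f$njk[, perm, drop = FALSE]
  expect_equal(as.numeric(logLik(g2)), as.numeric(logLik(f)),
               tolerance = 1e-9)
})

test_that("documents with disjoint vocabularies separate into pure topics", {
  tk <- make_tokens(list(rep(c(1L, 2L), 3), rep(c(3L, 4L), 3)),
                    c("a", "b", "c", "d"))
  f <- lda_gibbs(tk, K = 2, alpha = 0.1, beta = 0.1, n_iter = 200,
                 burn_in = 100, seed = 42)
  expect_gte(max(f$theta[1, ]), 0.9)
  expect_gte(max(f$theta[2, ]), 0.9)
})

test_that("Gibbs marginals agree with exhaustive posterior enumeration", {
  # 10 tokens over two documents; 2^10 assignment states enumerated exactly
  tk <- make_tokens(list(c(1L, 1L, 2L, 3L, 1L), c(4L, 4L, 3L, 4L, 2L)),
                    c("a", "b", "c", "d"))
  ex <- lda_exact_posterior(tk, K = 2, alpha = 0.5, beta = 0.5)
  # symmetric priors: exact per-token marginals are uniform by label symmetry
  expect_equal(ex$marginal, matrix(0.5, 10, 2), tolerance = 1e-9)

  f <- lda_gibbs(tk, K = 2, alpha = 0.5, beta = 0.5, n_iter = 5500,
                 burn_in = 500, seed = 17, sample_every = 1)
  occ <- do.call(rbind, f$z_marginal)
  expect_lt(max(abs(occ - ex$marginal)), 0.05)

  # label-invariant check: pairwise same-topic posterior probabilities
  zs <- do.call(rbind, f$z_samples)
  same_est <- matrix(NA_real_, 10, 10)
  for (s in 1:10) for (t in 1:10) same_est[s, t] <- mean(zs[, s] == zs[, t])
  expect_lt(max(abs(same_est - ex$same_topic)), 0.05)
})

test_that("multi-start keeps the chain with the best final log likelihood", {
  sp <- recovery_fixture_spec(3)  # a seed whose single-chain fit mode-locks
  g <- generate_corpus(sp)
  single <- lda_gibbs(g$tokens, 5, alpha = 0.1, beta = 0.01, n_iter = 150,
                      burn_in = 75, seed = 3)
  multi <- lda_gibbs(g$tokens, 5, alpha = 0.1, beta = 0.01, n_iter = 150,
                     burn_in = 75, seed = 3, n_starts = 3)
  expect_gte(multi$loglik_trace[length(multi$loglik_trace)],
             single$loglik_trace[length(single$loglik_trace)])
  expect_true(multi$seed_used %in% (3 + (0:2) * 7919))
})

test_that("degenerate fit requests are rejected", {
  tk <- make_tokens(list(c(1L, 2L)), c("a", "b"))
  expect_error(lda_gibbs(tk, K = 0, n_iter = 10, burn_in = 1), "K must be")
  expect_error(lda_gibbs(tk, K = 1, n_iter = 0, burn_in = 0), "positive")
  expect_error(lda_gibbs(tk, K = 1, n_iter = 5, burn_in = 5), "burn_in")
  expect_error(lda_gibbs(tk, K = 3, n_iter = 5, burn_in = 1),
               "exceeds the total token count")
})

test_that("external matrices wrap into a scoreable model", {
  tk <- make_tokens(list(c(1L, 2L), c(2L, 3L)), c("a", "b", "c"))
  phi <- rbind(c(0.6, 0.3, 0.1), c(0.1, 0.3, 0.6))
  theta <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  m <- lda_model(phi, theta, tk)
  expect_s3_class(m, "lda_model")
  expect_equal(dominant_topics(m), c(d01 = 1L, d02 = 2L))
  expect_error(lda_model(phi[, 1:2], theta, tk), "vocabulary")
  expect_error(lda_model(phi * 2, theta, tk), "sum to 1")
})
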