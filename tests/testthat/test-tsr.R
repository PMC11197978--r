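# Topic significance ranking: distances, standardizations, the combination
# chain against an independent oracle, junk suppression, temporal ranking.

test_that("probability distances reproduce hand-computed values", {
  p <- c(0.5, 0.5); q <- c(0.75, 0.25)
  # 0.5 ln(0.5/0.75) + 0.5 ln(0.5/0.25) = 0.143841
  expect_equal(prob_distance(p, q, "KL"), 0.1438410, tolerance = 1e-6)
  # self-distances vanish
  r <- c(0.2, 0.3, 0.5)
  expect_equal(prob_distance(r, r, "KL"), 0, tolerance = 1e-9)
  expect_equal(prob_distance(r, r, "COS"), 0, tolerance = 1e-12)
  expect_equal(prob_distance(r, r, "COR"), 0, tolerance = 1e-12)
  # orthogonal point masses: maximal cosine dissimilarity, correlation -1
  expect_equal(prob_distance(c(1, 0), c(0, 1), "COS"), 1)
  expect_equal(prob_distance(c(1, 0), c(0, 1), "COR"), 2)
  # zero-variance policy: correlation treated as 0, distance 1
  expect_equal(prob_distance(c(0.5, 0.5), c(0.9, 0.1), "COR"), 1)
  expect_error(prob_distance(c(1, 0), c(0.5, 0.25, 0.25), "KL"), "length")
  expect_error(prob_distance(c(1.5, -0.5), c(0.5, 0.5), "KL"), "negative")
  expect_error(prob_distance(c(0.4, 0.4), c(0.5, 0.5), "KL"), "sum to 1")
})

test_that("total-sum standardization follows the printed form", {
  expect_equal(standardize_total(c(1, 1)), c(0.5, 0.5))
  expect_equal(standardize_total(c(3, 1)), c(0.75, 0.75))
  expect_equal(standardize_total(5), 0)  # single topic: empty j != k sum
  expect_equal(standardize_total(c(3, 1), mode = "share"), c(0.75, 0.25))
  expect_warning(z <- standardize_total(c(0, 0)), "zero")
  expect_equal(z, c(0, 0))
  expect_error(standardize_total(c(-1, 2)), "nonnegative")
})

test_that("range standardization maps into [0, 1] with a constant-vector policy", {
  expect_equal(standardize_range(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(standardize_range(rep(3.3, 4)), rep(0.5, 4))
  set.seed(2)
  for (i in 1:5) {
    x <- rexp(7)
    out <- standardize_range(x)
    expect_true(all(out >= 0 & out <= 1))
    expect_equal(order(out), order(x))
  }
})

test_that("intra-criterion scores average the three metrics", {
  m <- cbind(KL = c(0, 1), COR = c(0.5, 1), COS = c(1, 1))
  expect_equal(intra_criterion_score(m), c(0.5, 1))
  expect_equal(intra_criterion_score(3 * m), 3 * intra_criterion_score(m))
  expect_error(intra_criterion_score(m[, 1:2]), "KL, COR, COS")
})

test_that("the weighted combination has the stated algebraic structure", {
  K <- 4
  for (s in c(0.3, 1.7)) {
    for (t in c(0.2, 0.9)) {
      S1 <- matrix(s, K, 3, dimnames = list(NULL, c("u", "v", "b")))
      S2 <- matrix(t, K, 3, dimnames = list(NULL, c("u", "v", "b")))
      res <- tsr_combine(S1, S2)
      expect_equal(res$S_hat, rep(s^2, K), tolerance = 1e-12)
      expect_equal(res$psi_hat, rep(t, K), tolerance = 1e-12)
      expect_equal(res$tsr, rep(t * s^2, K), tolerance = 1e-12)
    }
  }
  # zero background score annihilates the combined score
  S1 <- cbind(u = c(1, 1), v = c(1, 1), b = c(0, 1))
  S2 <- cbind(u = c(1, 1), v = c(1, 1), b = c(1, 1))
  res <- tsr_combine(S1, S2)
  expect_equal(res$S_hat[1], 0)
  expect_equal(res$rank, c(2L, 1L))
  # ties break toward the lower topic index
  S1[1, "b"] <- 1
  expect_equal(tsr_combine(S1, S2)$rank, c(1L, 2L))
  expect_error(tsr_weights(psi_u = 0.7, psi_v = 0.5), "psi_u")
  expect_error(tsr_weights(Psi_u = 0.5, Psi_v = 0.5, Psi_b = 0.5), "Psi_u")
})

test_that("the full chain matches an independent brute-force evaluation", {
  set.seed(10)
  for (rep in 1:5) {
    raw <- array(rexp(3 * 3 * 3), dim = c(3, 3, 3),
                 dimnames = list(NULL, c("KL", "COR", "COS"),
                                 c("u", "v", "b")))
    res <- topiclit:::.tsr_chain(raw, tsr_weights(), "printed")
    expect_equal(res$tsr, oracle_tsr_chain(raw), tolerance = 1e-9)
  }
  # non-default weights exercise the same chain
  w <- tsr_weights(psi_u = 0.3, psi_v = 0.7, Psi_u = 0.2, Psi_v = 0.2,
                   Psi_b = 0.6)
  raw <- array(rexp(27), dim = c(3, 3, 3),
               dimnames = list(NULL, c("KL", "COR", "COS"), c("u", "v", "b")))
  expect_equal(topiclit:::.tsr_chain(raw, w, "printed")$tsr,
               oracle_tsr_chain(raw, 0.3, 0.7, 0.2, 0.2, 0.6),
               tolerance = 1e-9)
})

test_that("benchmarks are the uniform, corpus-marginal and background laws", {
  tk <- make_tokens(list(c(1L, 1L, 2L), c(3L, 1L), c(2L, 2L), c(1L, 4L)),
                    c("a", "b", "c", "d"))
  f <- lda_gibbs(tk, K = 2, alpha = 0.5, beta = 0.5, n_iter = 20,
                 burn_in = 10, seed = 1)
  b <- tsr_benchmarks(f, tk)
  expect_equal(b$w_uniform, rep(0.25, 4))
  # token counts by hand: a 4, b 3, c 1, d 1 of 9
  expect_equal(b$w_vacuous, c(4, 3, 1, 1) / 9)
  expect_equal(b$d_bground, rep(0.25, 4))

  one <- make_tokens(list(rep(1L, 6)), "w")
  f1 <- lda_gibbs(one, K = 1, alpha = 1, beta = 1, n_iter = 5, burn_in = 1,
                  seed = 1)
  expect_equal(tsr_benchmarks(f1, one)$w_vacuous, 1)
})

test_that("a topic equal to a junk benchmark has null distance to it", {
  tk <- make_tokens(list(c(1L, 2L, 3L), c(2L, 3L, 4L)), letters[1:4])
  phi <- rbind(rep(0.25, 4), c(0.7, 0.1, 0.1, 0.1))
  theta <- rbind(c(0.5, 0.5), c(0.4, 0.6))
  m <- lda_model(phi, theta, tk)
  res <- tsr(m, tk)
  expect_lt(abs(res$raw[1, "KL", "u"]), 1e-6)
  expect_lt(res$raw[1, "COS", "u"], 1e-9)
  # uniform row has zero variance: correlation policy gives distance 1
  expect_equal(res$raw[1, "COR", "u"], 1)
  # the concentrated topic is farther from uniform on every other metric
  expect_gt(res$raw[2, "KL", "u"], res$raw[1, "KL", "u"])
  expect_gt(res$raw[2, "COS", "u"], res$raw[1, "COS", "u"])
})

test_that("reordering topics permutes the table without changing rank sets", {
  sp <- corpus_spec(K_true = 4, V = 40, M = 60, doc_length_mean = 20,
                    seed = 14)
  g <- generate_corpus(sp)
  m <- truth_model(g)
  r1 <- tsr(m, g$tokens)
  perm <- c(3L, 1L, 4L, 2L)
  mp <- lda_model(g$truth$phi_true[perm, ],
                  g$truth$theta_true[, perm], g$tokens)
  r2 <- tsr(mp, g$tokens)
  expect_equal(r2$table$tsr, r1$table$tsr[perm], tolerance = 1e-12)
  expect_setequal(r2$table$rank, r1$table$rank)
})

test_that("planted junk topics fall to the bottom ranks across seeds", {
  hits <- 0L
  for (seed in 1:5) {
    g <- generate_corpus(junk_fixture_spec(seed))
    res <- tsr(truth_model(g), g$tokens)
    hits <- hits + all(res$table$rank[g$truth$junk_ids] >= 5L)
  }
  expect_gte(hits, 4L)
})

test_that("temporal ranking reduces to the global ranking for one period", {
  sp <- corpus_spec(K_true = 3, V = 30, M = 80, doc_length_mean = 20,
                    years = 2013:2022, seed = 23)
  g <- generate_corpus(sp)
  m <- truth_model(g)
  glob <- tsr(m, g$tokens)
  tem <- temporal_tsr(m, g$tokens, periods = list(2013:2022))
  expect_equal(unname(tem$rank_matrix[, 1]), glob$table$rank)
  expect_equal(unname(tem$tsr_matrix[, 1]), glob$table$tsr, tolerance = 1e-12)

  expect_error(temporal_tsr(m, g$tokens, periods = list(2013:2016, 2016:2022)),
               "disjoint")
  expect_error(temporal_tsr(m, g$tokens, periods = list(2013:2015)),
               "do not cover")
  expect_error(temporal_tsr(m, g$tokens,
                            periods = list(2013:2022, 2030:2031)),
               "empty period")
})

test_that("a topic surging in a period converges toward that period's background", {
  # when a topic comes to dominate a period's documents, its document
  # distribution there approaches the uniform background benchmark, so its
  # background distance shrinks and its distance-based significance falls
  sp <- corpus_spec(K_true = 4, V = 60, M = 400, doc_length_mean = 30,
                    years = 2013:2022, skew_topic = 2,
                    skew_years = 2019:2022, seed = 29)
  g <- generate_corpus(sp)
  f <- lda_gibbs(g$tokens, K = 4, alpha = 0.1, beta = 0.01, n_iter = 200,
                 burn_in = 100, seed = 30, n_starts = 3)
  est2 <- which(match_topics(f$phi, g$truth$phi_true)$perm == 2)
  tem <- temporal_tsr(f, g$tokens)
  expect_equal(colnames(tem$rank_matrix),
               c("2013-2015", "2016-2018", "2019-2022"))
  expect_lt(tem$tables[[3]]$raw[est2, "KL", "b"],
            tem$tables[[1]]$raw[est2, "KL", "b"])
  expect_gt(tem$rank_matrix[est2, 3], tem$rank_matrix[est2, 1])
})
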