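# Term/gene trend analyses: threshold semantics, association filtering,
# emergence, lexicon matching.

test_that("dominant topics follow argmax with lower-index tie break", {
  tk <- make_tokens(list(c(1L, 2L), c(1L, 2L), c(1L, 2L)), c("a", "b"))
  m <- lda_model(rbind(c(0.5, 0.5), c(0.5, 0.5)),
                 rbind(c(0.7, 0.3), c(0.5, 0.5), c(0.2, 0.8)), tk)
  expect_equal(unname(dominant_topics(m)), c(1L, 1L, 2L))
})

test_that("fitted dominant topics recover near-pure generative labels", {
  sp <- corpus_spec(K_true = 3, V = 60, M = 150, alpha = 0.02, beta = 0.05,
                    doc_length_mean = 40, seed = 41)
  g <- generate_corpus(sp)
  f <- lda_gibbs(g$tokens, K = 3, alpha = 0.02, beta = 0.01, n_iter = 150,
                 burn_in = 75, seed = 8, n_starts = 3)
  mt <- match_topics(f$phi, g$truth$phi_true)
  est <- mt$perm[dominant_topics(f)]
  # per-document majority vote of the true token assignments
  maj <- vapply(g$truth$z_true, function(z)
    as.integer(names(which.max(table(z)))), integer(1))
  expect_gte(mean(est == maj), 0.95)
})

test_that("the topic-term filter is strictly greater-than and association-tested", {
  # 30 docs: topics 1..3 get 10 docs each
  assignments <- rep(1:3, each = 10)
  tags <- rep(list(character(0)), 30)
  # "focal": 6 docs, all in topic 1 -> kept (6 > 5, concentrated)
  for (j in 1:6) tags[[j]] <- c(tags[[j]], "focal")
  # "borderline": exactly 5 docs, concentrated -> dropped (5 > 5 is false)
  for (j in 1:5) tags[[j]] <- c(tags[[j]], "borderline")
  # "flat": 9 docs spread evenly with the margin -> dropped by the test
  for (j in c(1:3, 11:13, 21:23)) tags[[j]] <- c(tags[[j]], "flat")
  corp <- make_corpus(sprintf("d%02d", 1:30), rep(2015L, 30),
                      rep("tumor text", 30), tags)
  ttm <- topic_term_matrix(corp, assignments, min_count = 5,
                           alpha_level = 0.05)
  expect_identical(rownames(ttm$counts), "focal")
  expect_equal(unname(ttm$counts["focal", ]), c(6L, 0L, 0L))
  # the unfiltered matrix still carries every term's counts
  expect_equal(unname(ttm$all_counts["flat", ]), c(3L, 3L, 3L))
  expect_equal(sum(ttm$all_counts["borderline", ]), 5L)
  # retained totals match the per-term document counts
  expect_equal(rowSums(ttm$counts),
               c(focal = 6L))
})

test_that("annual term reporting is inclusive at the threshold", {
  years <- c(rep(2015L, 10), rep(2016L, 10))
  tags <- rep(list(character(0)), 20)
  for (j in 1:6) tags[[j]] <- "six2015"       # 6 in 2015 -> retained
  for (j in 1:5) tags[[j]] <- c(tags[[j]], "five")  # 5 in 2015 only
  for (j in 11:15) tags[[j]] <- "five"        # and 5 in 2016 -> never shown
  corp <- make_corpus(sprintf("d%02d", 1:20), years, rep("t x", 20), tags)
  out <- annual_terms(corp, min_count = 6)
  expect_equal(out$term, "six2015")
  expect_equal(out$year, 2015L)
  expect_equal(out$count, 6L)
  full <- attr(out, "full_counts")
  expect_equal(full["five", "2015"], 5L)
  expect_equal(full["five", "2016"], 5L)
})

test_that("emergence records first years with left-censoring, independent of order", {
  ids <- sprintf("d%d", 1:6)
  years <- c(2013L, 2015L, 2015L, 2017L, 2019L, 2013L)
  tags <- list("early", "mid", c("mid", "late"), "late", "late", "early")
  corp <- make_corpus(ids, years, rep("x y", 6), tags)
  em <- term_emergence(corp)
  expect_equal(em$first_year[em$term == "mid"], 2015L)
  expect_equal(em$first_year[em$term == "late"], 2015L)
  expect_true(em$left_censored[em$term == "early"])
  expect_false(any(em$left_censored[em$term != "early"]))

  # reporting window drops terms that emerged before start_year
  em2 <- term_emergence(corp, start_year = 2016L)
  expect_equal(em2$term, character(0))
  expect_error(term_emergence(corp, start_year = 2010L), "range")

  # document order is irrelevant
  perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
  corp2 <- make_corpus(ids[perm], years[perm], rep("x y", 6), tags[perm])
  em3 <- term_emergence(corp2)
  expect_identical(em3, em)
})

test_that("gene extraction matches whole tokens case-sensitively with TF-IDF gating", {
  corp <- make_corpus(
    c("a", "b", "c"), rep(2015L, 3),
    c("TP53 and EGFR were mutated; TP53 again",
      "tp53 lowercase is not a symbol, EGFR is",
      "EGFR everywhere here"))
  lex <- c("TP53", "EGFR", "KRAS")
  g <- extract_genes(corp, lex)
  expect_setequal(colnames(g$counts), c("TP53", "EGFR"))
  expect_equal(unname(g$counts[, "TP53"]), c(2L, 0L, 0L))
  expect_equal(unname(g$counts[, "EGFR"]), c(1L, 1L, 1L))
  expect_equal(unname(g$totals["TP53"]), 2L)

  # EGFR sits in every document: IDF = ln(1) = 0, so any positive
  # threshold excludes it while TP53 (tf 2, df 1) survives
  g2 <- extract_genes(corp, lex, tfidf_min = 1e-6)
  expect_identical(colnames(g2$counts), "TP53")
  expect_equal(unname(g2$tfidf["TP53"]), 2 * log(3), tolerance = 1e-12)

  # infinite threshold empties the result
  expect_equal(ncol(extract_genes(corp, lex, tfidf_min = Inf)$counts), 0L)
  expect_error(extract_genes(corp, character(0)), "empty")
})

test_that("gene trends keep topic-associated genes at an inclusive threshold", {
  # 36 documents over 12 topics (3 docs each); GENEA mentioned twice in one
  # topic-1 document: with 12 topics a fully concentrated pair is already
  # significant (chi-square 22 on 11 df, p = 0.024). GENEB appears once
  # (below the inclusive total threshold); GENEC is spread with the margin.
  texts <- rep("background words only", 36)
  texts[1] <- "GENEA found GENEA again"
  texts[11] <- "GENEB once"
  texts[c(2, 14, 26)] <- "GENEC present"
  corp <- make_corpus(sprintf("d%02d", 1:36),
                      c(rep(2014L, 18), rep(2021L, 18)), texts)
  assignments <- rep(1:12, each = 3)
  genes <- extract_genes(corp, c("GENEA", "GENEB", "GENEC"))
  tr <- gene_trends(genes, corp$docs$year, assignments, min_total = 2,
                    alpha_level = 0.05)
  expect_identical(rownames(tr$gene_topic), "GENEA")
  expect_equal(unname(tr$gene_topic["GENEA", ]), c(2L, rep(0L, 11)))
  expect_equal(unname(tr$first_year["GENEA"]), 2014L)
  expect_equal(tr$new_by_year, list("2014" = "GENEA"))
  expect_equal(unname(tr$gene_year["GENEA", ]), c(2L, 0L))

  # document mode counts each document once
  tr2 <- gene_trends(genes, corp$docs$year, assignments, min_total = 1,
                     alpha_level = 1, count_mode = "documents")
  expect_equal(unname(tr2$gene_topic["GENEA", 1]), 1L)
})

test_that("genes injected only in the final year surface as new that year", {
  sp <- corpus_spec(K_true = 2, V = 30, M = 120, doc_length_mean = 12,
                    years = 2020:2021, gene_lexicon = c("CD69", "LAG3"),
                    gene_rate = 0.8, seed = 55)
  g <- generate_corpus(sp)
  corp <- g$corpus
  # rewrite years so every CD69 mention happens in 2021
  has_cd69 <- grepl("\\bCD69\\b", corp$docs$text)
  corp$docs$year[has_cd69] <- 2021L
  genes <- extract_genes(corp, c("CD69", "LAG3"))
  tr <- gene_trends(genes, corp$docs$year, g$truth$dominant_true,
                    min_total = 2, alpha_level = 1)
  expect_equal(unname(tr$first_year["CD69"]), 2021L)
  expect_true("CD69" %in% tr$new_by_year[["2021"]])
})
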