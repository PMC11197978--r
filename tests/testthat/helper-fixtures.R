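# Shared fixtures and independent oracles, built in code at test time.

# token container from explicit id lists
make_tokens <- function(doc_tokens, vocab, years = NULL, ids = NULL) {
  M <- length(doc_tokens)
  if (is.null(years)) years <- rep(2015L, M)
  if (is.null(ids)) ids <- sprintf("d%02d", seq_len(M))
  topiclit:::new_lda_tokens(doc_tokens, vocab, ids, years)
}

# corpus with explicit fields
make_corpus <- function(ids, years, texts, tags = NULL) {
  lit_corpus(ids, years, texts, tags)
}

# MEDLINE flat-file fixture: three records, the second lacking a PMID,
# with continuation lines, qualifiers, asterisks and an unknown tag
write_medline_fixture <- function(path) {
  writeLines(c(
    "PMID- 1001",
    "DP  - 2015 Mar-Apr",
    "TI  - Radiotherapy outcomes in oropharyngeal",
    "      carcinoma",
    "AB  - A retrospective cohort with extended follow",
    "      up.",
    "MH  - Humans",
    "MH  - *Prognosis/methods",
    "MH  - Carcinoma, Squamous Cell/radiotherapy",
    "XX  - some unknown field",
    "",
    "DP  - 2016",
    "TI  - No identifier here",
    "AB  - Should be rejected.",
    "",
    "PMID- 1003",
    "DP  - 2019 Jan",
    "TI  - HPV status and staging",
    "AB  - Observational data.",
    "MH  - Humans; Papillomaviridae"
  ), path)
  path
}

# Independent evaluation of the four-phase significance chain, written as
# literal arithmetic (no shared code with the package internals). raw is a
# K x 3 x 3 array [topic, metric, criterion]; returns the per-topic score.
oracle_tsr_chain <- function(raw, psi_u = 0.5, psi_v = 0.5,
                             Psi_u = 1 / 3, Psi_v = 1 / 3, Psi_b = 1 / 3) {
  K <- dim(raw)[1]
  s1 <- s2 <- array(NA_real_, dim(raw))
  for (m in 1:3) {
    for (cr in 1:3) {
      x <- raw[, m, cr]
      tot <- sum(x)
      for (k in 1:K) s1[k, m, cr] <- x[k] * sum(x[-k]) / tot
      lo <- min(x); hi <- max(x)
      s2[, m, cr] <- if (hi == lo) rep(0.5, K) else (x - lo) / (hi - lo)
    }
  }
  S1 <- apply(s1, c(1, 3), mean)  # K x criterion (u, v, b)
  S2 <- apply(s2, c(1, 3), mean)
  S_hat <- S1[, 3] * (psi_u * S1[, 1] + psi_v * S1[, 2])
  psi_hat <- Psi_u * S2[, 1] + Psi_v * S2[, 2] + Psi_b * S2[, 3]
  psi_hat * S_hat
}

# study-condition fixtures used by the validation suite
junk_fixture_spec <- function(seed) {
  corpus_spec(K_true = 6, V = 150, M = 300, alpha = 0.1, beta = 0.05,
              doc_length_mean = 80, years = 2013:2022,
              junk_plants = c("uniform", "vacuous"), seed = seed)
}

recovery_fixture_spec <- function(seed) {
  separated_spec(5, 200, M = 400, doc_length_mean = 60, alpha = 0.1,
                 seed = seed)
}

# ground-truth model wrapped for significance scoring
truth_model <- function(generated) {
  lda_model(generated$truth$phi_true, generated$truth$theta_true,
            generated$tokens)
}
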