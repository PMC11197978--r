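# topiclit

Topic modeling and topic significance ranking for biomedical literature
corpora.

Bibliometric studies of a clinical field (the motivating case is
oropharyngeal-cancer research) typically face thousands of titles and
abstracts whose latent themes, their relative importance, and their movement
over time are what the analyst actually wants. `topiclit` provides that
analysis chain as a tested R package:

* **LDA by collapsed Gibbs sampling.** Each document j mixes K topics
  (θ_j ~ Dir(α)); each topic k is a distribution over the vocabulary
  (φ_k ~ Dir(β)); each token draws a topic z ~ Cat(θ_j) and a word
  w ~ Cat(φ_z). The sampler integrates φ and θ out and resamples token
  assignments from

      p(z = k | ·) ∝ (n_kw + β) / (n_k + Vβ) · (n_jk + α),

  with posterior-mean estimates φ̂ and θ̂ read off the final counts.
  Optional multi-start keeps the chain with the best complete-data log
  likelihood.
* **Topic-number selection** with the four standard metrics — Arun2010 and
  CaoJuan2009 (minimized), Deveaud2014 and Griffiths2004's harmonic-mean
  marginal likelihood (maximized) — over a user grid; the final K stays a
  human decision.
* **Topic significance ranking (TSR).** Every fitted topic is scored by its
  distance (KL divergence, 1 − Pearson correlation, cosine dissimilarity)
  from three junk benchmarks: the uniform word distribution (W-Uniform), the
  empirical corpus word marginal (W-Vacuous), and the uniform background
  distribution over documents (D-BGround). Distances are standardized two
  ways across topics (a total-sum recalibration x(T−x)/T and a min–max
  rescaling), averaged within criteria, and combined across criteria with a
  four-phase weighted combination

      Ŝ_k = S1_k^b (Ψ′_u S1_k^u + Ψ′_v S1_k^v),
      Ψ̂_k = Ψ_u S2_k^u + Ψ_v S2_k^v + Ψ_b S2_k^b,
      TSR_k = Ψ̂_k · Ŝ_k,

  so topics resembling junk sink to the bottom ranks. A temporal variant
  re-scores fixed topics inside year periods (default 2013–2015, 2016–2018,
  2019–2022).
* **Term and gene trend tables.** MeSH-style tags are pooled by each
  document's dominant topic into a topic–term matrix (terms kept when their
  total count is strictly above 5 and their topic distribution differs from
  the topic margin by chi-square), tabulated per year (kept at ≥ 6 per
  year), and tracked for first emergence. Gene symbols are
  lexicon-matched case-sensitively in the raw text, gated by a corpus
  TF-IDF weight, and kept at ≥ 2 total mentions with the same association
  test.
* **A synthetic-corpus generator** that draws corpora from a known LDA
  process — with year labels, topic-enriched tags, embedded gene symbols,
  and optional planted junk topics (uniform and corpus-marginal) — so every
  stage above is validated against ground truth.

## Worked example

Generate a 300-document corpus from a known 6-topic process in which topics
5 and 6 are planted junk (uniform and corpus-marginal word distributions),
then rank the generative model's topics:

```r
library(topiclit)

spec <- corpus_spec(K_true = 6, V = 150, M = 300, alpha = 0.1, beta = 0.05,
                    doc_length_mean = 80, junk_plants = c("uniform", "vacuous"),
                    seed = 1)
gen <- generate_corpus(spec)
model <- lda_model(gen$truth$phi_true, gen$truth$theta_true, gen$tokens)
tsr(model, gen$tokens)
#> Topic significance ranking (printed total standardization)
#>  topic   S_hat psi_hat     tsr rank
#>      1 0.68543 0.70648 0.48424    1
#>      2 0.65549 0.69078 0.45280    2
#>      4 0.64511 0.69458 0.44808    3
#>      3 0.61965 0.54534 0.33792    4
#>      5 0.36036 0.60276 0.21721    5
#>      6 0.31929 0.39161 0.12504    6
```

Both planted junk topics fall to the bottom two ranks: their proximity to
the uniform/marginal benchmarks collapses the background-weighted score
`S_hat`, and `psi_hat` (the range-standardized weight) pushes them further
down. `tsr` on a fitted `lda_gibbs` object works identically.

Fitting itself recovers planted structure. On a corpus whose five topics
have disjoint vocabulary support:

```r
sep <- generate_corpus(separated_spec(5, 200, M = 400, doc_length_mean = 60,
                                      alpha = 0.1, seed = 11))
fit <- lda_gibbs(sep$tokens, K = 5, alpha = 0.1, beta = 0.01,
                 n_iter = 200, burn_in = 100, seed = 42, n_starts = 3)
fit
#> LDA (collapsed Gibbs): K = 5, 400 documents, vocabulary 200
#>   alpha = 0.1, beta = 0.01, sweeps = 200 (burn-in 100), seed = 42
#>   final complete-data logLik = -104029.35
mean(match_topics(coef(fit), sep$truth$phi_true)$tv)
#> [1] 0.03390702
```

A mean total-variation distance of 0.034 between estimated and true
topic-word rows means each recovered topic places ~97% of its mass exactly
as the generator did.

The whole chain — read or generate a corpus, preprocess (cleaning, Porter
stemming, bigram collocations, stopword and document-frequency pruning),
optional K sweep, fit, global and per-period TSR, term/gene tables, TSV +
manifest output — runs from one configuration via `run_pipeline()`;
`demo_run(seed)` executes it end to end on a synthetic corpus and reports a
junk-suppression check. MEDLINE flat files are read with `read_medline()`,
delimited tables with `read_corpus_table()`.

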