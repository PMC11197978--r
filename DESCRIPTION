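Package: topiclit
Title: Topic Modeling and Topic Significance Ranking for Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining topic structure from collections of article
    titles and abstracts. Fits latent Dirichlet allocation by collapsed Gibbs
    sampling, selects the number of topics with four standard metrics
    (Arun 2010, Cao-Juan 2009, Deveaud 2014, Griffiths 2004), ranks fitted
    topics against junk benchmarks (uniform, corpus-marginal and background
    distributions) with a four-phase weighted-combination significance score,
    tracks topic significance across year periods, and tabulates MeSH-style
    term and gene-symbol trends (frequency, topic association, first
    emergence). Includes a synthetic-corpus generator with known ground truth
    for end-to-end validation, a MEDLINE flat-file reader, and a Porter
    stemmer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
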