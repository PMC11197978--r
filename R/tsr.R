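# Topic Significance Ranking (TSR).
#
# Fitted topics are scored by their distance from three junk benchmarks:
#   W-Uniform  - uniform distribution over the vocabulary (word space);
#   W-Vacuous  - the empirical corpus word marginal (word space);
#   D-BGround  - uniform distribution over documents (document space), the
#                reference for each topic's normalized document distribution.
# Distances (KL divergence, 1 - Pearson correlation, cosine dissimilarity)
# are standardized two ways, averaged within criteria, and combined across
# criteria with a four-phase weighted-combination strategy into a single
# TSR score per topic; larger distance from junk means greater significance,
# so rank 1 is the most significant topic.

#' TSR weight set
#'
#' Inner weights `psi_u`, `psi_v` mix the uniformity and vacuousness scores
#' inside the background-weighted combination (they must sum to 1); outer
#' weights `Psi_u`, `Psi_v`, `Psi_b` mix the range-standardized criterion
#' scores (they must sum to 1). Equal weighting is the neutral default.
#'
#' @param psi_u,psi_v inner weights, `psi_u + psi_v = 1`.
#' @param Psi_u,Psi_v,Psi_b outer weights summing to 1.
#' @return a list of class `tsr_weights`.
#' @export
tsr_weights <- function(psi_u = 0.5, psi_v = 0.5,
                        Psi_u = 1 / 3, Psi_v = 1 / 3, Psi_b = 1 / 3) {
  w <- list(psi_u = psi_u, psi_v = psi_v,
            Psi_u = Psi_u, Psi_v = Psi_v, Psi_b = Psi_b)
  if (any(unlist(w) < 0)) stop("TSR weights must be nonnegative")
  if (abs(psi_u + psi_v - 1) > 1e-9) stop("psi_u + psi_v must equal 1")
  if (abs(Psi_u + Psi_v + Psi_b - 1) > 1e-9) {
    stop("Psi_u + Psi_v + Psi_b must equal 1")
  }
  structure(w, class = "tsr_weights")
}

#' Junk benchmarks for a fitted model
#'
#' @param model a fitted `lda_gibbs` model.
#' @param tokens the `lda_tokens` the model was fitted on (supplies the
#'   empirical word marginal).
#' @return list with `w_uniform` (length V), `w_vacuous` (length V, token
#'   counts normalized), `d_bground` (length M, uniform over documents).
#' @export
tsr_benchmarks <- function(model, tokens) {
  V <- length(model$vocab)
  M <- nrow(model$theta)
  counts <- tabulate(unlist(tokens$doc_tokens, use.names = FALSE), nbins = V)
  list(
    w_uniform = rep(1 / V, V),
    w_vacuous = counts / sum(counts),
    d_bground = rep(1 / M, M)
  )
}

#' Distance between two probability vectors
#'
#' Three metrics: `"KL"` is `sum(p * log(p / (q + 1e-12)))` with
#' `0 * log 0 = 0`; `"COR"` is `1 - Pearson correlation` (range 0..2), with
#' the convention that a zero-variance vector has correlation 0, hence
#' distance 1; `"COS"` is `1 - cosine similarity`.
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1 (within
#'   1e-6).
#' @param metric one of `"KL"`, `"COR"`, `"COS"`.
#' @return scalar distance.
#' @export
prob_distance <- function(p, q, metric = c("KL", "COR", "COS")) {
  metric <- match.arg(metric)
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("negative entries are not probabilities")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("p and q must each sum to 1")
  }
  switch(metric,
    KL = {
      nz <- p > 0
      sum(p[nz] * log(p[nz] / (q[nz] + 1e-12)))
    },
    COR = {
      if (stats::sd(p) == 0 || stats::sd(q) == 0) return(1)
      1 - stats::cor(p, q)
    },
    COS = 1 - sum(p * q) / sqrt(sum(p^2) * sum(q^2))
  )
}

#' Total-sum standardization of per-topic scores
#'
#' Recalibrates each topic's score against the total over topics:
#' `out_k = x_k * (T - x_k) / T` with `T = sum(x)` (mode `"printed"`, the
#' default). Mode `"share"` is the plain proportional alternative `x_k / T`,
#' provided for sensitivity analysis.
#'
#' @param x nonnegative per-topic scores.
#' @param mode `"printed"` or `"share"`.
#' @return standardized scores; all zero (with a warning) when `T = 0`.
#' @export
standardize_total <- function(x, mode = c("printed", "share")) {
  mode <- match.arg(mode)
  x[x < 0 & x > -1e-9] <- 0  # floating-point cancellation in near-zero distances
  if (any(x < 0)) stop("scores must be nonnegative")
  T <- sum(x)
  if (T == 0) {
    warning("all scores zero: total standardization returns zeros")
    return(rep(0, length(x)))
  }
  switch(mode,
    printed = x * (T - x) / T,
    share = x / T
  )
}

#' Range standardization of per-topic scores
#'
#' `(x - min) / (max - min)`, mapped into `[0, 1]`; a constant vector maps
#' to 0.5 everywhere (no topic is distinguished).
#'
#' @param x numeric per-topic scores.
#' @return standardized scores in `[0, 1]`.
#' @export
standardize_range <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Intra-criterion weighted linear combination
#'
#' Averages the three distance-metric scores within one criterion:
#' `S_k = (C_k^KL + C_k^COR + C_k^COS) / 3`.
#'
#' @param std_scores K x 3 matrix with columns named `KL`, `COR`, `COS`.
#' @return per-topic score vector.
#' @export
intra_criterion_score <- function(std_scores) {
  need <- c("KL", "COR", "COS")
  if (!all(need %in% colnames(std_scores))) {
    stop("std_scores must have columns KL, COR, COS")
  }
  rowMeans(std_scores[, need, drop = FALSE])
}

#' Inter-criterion weighted combination and final TSR score
#'
#' Combines total-standardized criterion scores `S1` and range-standardized
#' scores `S2` into the final per-topic significance:
#' `S_hat_k = S1_k^b * (psi_u * S1_k^u + psi_v * S1_k^v)`,
#' `psi_hat_k = Psi_u * S2_k^u + Psi_v * S2_k^v + Psi_b * S2_k^b`,
#' `TSR_k = psi_hat_k * S_hat_k`. Ranking is by decreasing TSR, ties broken
#' toward the lower topic index.
#'
#' @param S1,S2 K x 3 matrices with columns named `u`, `v`, `b`.
#' @param weights a [tsr_weights()] object.
#' @return list with `S_hat`, `psi_hat`, `tsr`, `rank`.
#' @export
tsr_combine <- function(S1, S2, weights = tsr_weights()) {
  if (!inherits(weights, "tsr_weights")) weights <- do.call(tsr_weights, weights)
  for (m in list(S1, S2)) {
    if (!all(c("u", "v", "b") %in% colnames(m))) {
      stop("S1 and S2 must have columns u, v, b")
    }
  }
  S_hat <- S1[, "b"] * (weights$psi_u * S1[, "u"] + weights$psi_v * S1[, "v"])
  psi_hat <- weights$Psi_u * S2[, "u"] + weights$Psi_v * S2[, "v"] +
    weights$Psi_b * S2[, "b"]
  tsr <- psi_hat * S_hat
  ord <- order(-tsr, seq_along(tsr))
  rank <- integer(length(tsr))
  rank[ord] <- seq_along(tsr)
  list(S_hat = unname(S_hat), psi_hat = unname(psi_hat),
       tsr = unname(tsr), rank = rank)
}

.TSR_METRICS <- c("KL", "COR", "COS")
.TSR_CRITERIA <- c("u", "v", "b")

# raw distance array: K topics x 3 metrics x 3 criteria
.tsr_raw <- function(phi, theta, bench) {
  K <- nrow(phi)
  raw <- array(NA_real_, dim = c(K, 3, 3),
               dimnames = list(NULL, .TSR_METRICS, .TSR_CRITERIA))
  theta_cols <- sweep(theta, 2, colSums(theta), "/")
  for (k in seq_len(K)) {
    for (m in .TSR_METRICS) {
      raw[k, m, "u"] <- prob_distance(phi[k, ], bench$w_uniform, m)
      raw[k, m, "v"] <- prob_distance(phi[k, ], bench$w_vacuous, m)
      raw[k, m, "b"] <- prob_distance(theta_cols[, k], bench$d_bground, m)
    }
  }
  raw
}

# Eq. 2 -> Eq. 7 chain on a raw distance array
.tsr_chain <- function(raw, weights, total_mode) {
  K <- dim(raw)[1]
  S1 <- S2 <- matrix(NA_real_, K, 3, dimnames = list(NULL, .TSR_CRITERIA))
  for (cr in .TSR_CRITERIA) {
    mat <- matrix(raw[, , cr], nrow = K,
                  dimnames = list(NULL, .TSR_METRICS))
    std1 <- vapply(.TSR_METRICS,
                   function(m) standardize_total(mat[, m], mode = total_mode),
                   numeric(K))
    std2 <- vapply(.TSR_METRICS,
                   function(m) standardize_range(mat[, m]), numeric(K))
    if (K == 1L) { std1 <- t(std1); std2 <- t(std2) }
    S1[, cr] <- intra_criterion_score(std1)
    S2[, cr] <- intra_criterion_score(std2)
  }
  comb <- tsr_combine(S1, S2, weights)
  c(list(raw = raw, S1 = S1, S2 = S2), comb)
}

#' Rank topics by significance against junk benchmarks
#'
#' Full four-phase pipeline: raw distances of every topic to the three junk
#' benchmarks under three metrics; total-sum and range standardizations
#' across topics; intra-criterion averaging; inter-criterion weighted
#' combination into the final TSR score and rank (1 = most significant).
#'
#' @param model a fitted `lda_gibbs` model.
#' @param tokens the `lda_tokens` the model was fitted on.
#' @param weights a [tsr_weights()] object.
#' @param total_mode passed to [standardize_total()].
#' @return an object of class `tsr_table`: list with `table` (data.frame:
#'   topic, S1/S2 criterion scores, S_hat, psi_hat, tsr, rank), `raw`
#'   (K x metric x criterion distances), `weights`, `total_mode`.
#' @export
tsr <- function(model, tokens, weights = tsr_weights(),
                total_mode = c("printed", "share")) {
  total_mode <- match.arg(total_mode)
  bench <- tsr_benchmarks(model, tokens)
  res <- .tsr_chain(.tsr_raw(model$phi, model$theta, bench),
                    weights, total_mode)
  tab <- data.frame(
    topic = seq_len(model$K),
    S1_u = res$S1[, "u"], S1_v = res$S1[, "v"], S1_b = res$S1[, "b"],
    S2_u = res$S2[, "u"], S2_v = res$S2[, "v"], S2_b = res$S2[, "b"],
    S_hat = res$S_hat, psi_hat = res$psi_hat,
    tsr = res$tsr, rank = res$rank
  )
  structure(list(table = tab, raw = res$raw, weights = weights,
                 total_mode = total_mode),
            class = "tsr_table")
}

#' @export
print.tsr_table <- function(x, ...) {
  cat("Topic significance ranking (", x$total_mode,
      " total standardization)\n", sep = "")
  tab <- x$table[order(x$table$rank), c("topic", "S_hat", "psi_hat",
                                        "tsr", "rank")]
  print(tab, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Topic significance across year periods
#'
#' Keeps the globally fitted topics fixed and re-runs the TSR scoring inside
#' each year period: theta rows are restricted to the period's documents,
#' the vacuous and background benchmarks are recomputed on the period
#' sub-corpus, and the full chain is re-applied. The output includes the
#' topic-by-period rank matrix used to draw significance trajectories.
#'
#' @param model a fitted `lda_gibbs` model (carries per-document years).
#' @param tokens the `lda_tokens` the model was fitted on.
#' @param periods list of integer year vectors; must be disjoint and cover
#'   every document year. Default: 2013-2015, 2016-2018, 2019-2022.
#' @param weights a [tsr_weights()] object.
#' @param total_mode passed to [standardize_total()].
#' @return an object of class `tsr_temporal`: list with `periods` (labels),
#'   `tables` (one `tsr_table` per period), `rank_matrix` (K x periods),
#'   `tsr_matrix` (K x periods).
#' @export
temporal_tsr <- function(model, tokens,
                         periods = list(2013:2015, 2016:2018, 2019:2022),
                         weights = tsr_weights(),
                         total_mode = c("printed", "share")) {
  total_mode <- match.arg(total_mode)
  yrs <- model$year
  if (is.null(yrs)) stop("model carries no document years")
  all_period_years <- unlist(periods)
  if (anyDuplicated(all_period_years)) stop("periods must be disjoint")
  uncovered <- setdiff(unique(yrs), all_period_years)
  if (length(uncovered) > 0L) {
    stop("periods do not cover corpus years: ",
         paste(sort(uncovered), collapse = ", "))
  }
  labels <- vapply(periods, function(p) paste0(min(p), "-", max(p)),
                   character(1))
  tables <- vector("list", length(periods))
  K <- model$K
  rank_matrix <- tsr_matrix <- matrix(NA_real_, K, length(periods),
                                      dimnames = list(paste0("T", seq_len(K)),
                                                      labels))
  for (i in seq_along(periods)) {
    sel <- which(yrs %in% periods[[i]])
    if (length(sel) == 0L) stop("empty period: ", labels[i])
    counts <- tabulate(unlist(tokens$doc_tokens[sel], use.names = FALSE),
                       nbins = tokens$V)
    bench <- list(w_uniform = rep(1 / tokens$V, tokens$V),
                  w_vacuous = counts / sum(counts),
                  d_bground = rep(1 / length(sel), length(sel)))
    res <- .tsr_chain(.tsr_raw(model$phi,
                               model$theta[sel, , drop = FALSE], bench),
                      weights, total_mode)
    tab <- data.frame(topic = seq_len(K), S_hat = res$S_hat,
                      psi_hat = res$psi_hat, tsr = res$tsr, rank = res$rank)
    tables[[i]] <- structure(list(table = tab, raw = res$raw,
                                  weights = weights, total_mode = total_mode),
                             class = "tsr_table")
    rank_matrix[, i] <- res$rank
    tsr_matrix[, i] <- res$tsr
  }
  structure(list(periods = labels, tables = tables,
                 rank_matrix = rank_matrix, tsr_matrix = tsr_matrix),
            class = "tsr_temporal")
}

#' @export
print.tsr_temporal <- function(x, ...) {
  cat("Temporal topic significance over ", length(x$periods),
      " periods (rank 1 = most significant):\n", sep = "")
  print(x$rank_matrix)
  invisible(x)
}
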