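# Candidate locus detection: posterior over the number K of mutated cells,
# with the subset-sum likelihood computed by dynamic programming.

#' Configuration for candidate locus detection
#'
#' @param lambda prior probability of a mutation at a locus, in (0, 1).
#' @param min_mutated_cells minimum number of distinct cells with alternative
#'   support required to retain a locus (single-cell hits are
#'   indistinguishable from sequencing errors).
#' @param cutoff posterior-odds decision cutoff; a locus is flagged when
#'   `odds(K >= 1 vs K = 0) > cutoff`. The default 1 is `P(K = 0 | D) < 1/2`.
#' @return object of class `candidate_config`.
#' @export
candidate_config <- function(lambda = 1e-4, min_mutated_cells = 2L,
                             cutoff = 1) {
  stopifnot(lambda > 0, lambda < 1, min_mutated_cells >= 1, cutoff > 0)
  structure(list(lambda = lambda,
                 min_mutated_cells = as.integer(min_mutated_cells),
                 cutoff = cutoff),
            class = "candidate_config")
}

#' Per-cell likelihood cache for candidate loci
#'
#' Precomputes per-locus, per-cell log likelihoods of the three genotype
#' states plus the derived quantities the tree marginal needs. The
#' heterozygous mixture terms are stored separately so that parameter updates
#' only recompute what changed.
#'
#' @param support `n x m` integer matrix of alternative-allele counts.
#' @param coverage `n x m` integer matrix of coverages.
#' @param params a [model_params()] object.
#' @return list with matrices `lwt`, `lhet`, `lhom`, mixture terms
#'   `t1`, `t2`, `t3`, ratio matrices `dhet`, `dhom` and row sums `tot_wt`.
#' @export
likelihood_cache <- function(support, coverage, params) {
  s <- support
  c <- coverage
  lwt <- log_beta_binomial(s, c, params$f_wt, params$omega_wt)
  t2 <- log_beta_binomial(c - s, c, params$f_wt, params$omega_wt)
  t3 <- log_beta_binomial(s, c, 0.5 - (2 / 3) * params$f_wt, params$omega_a)
  cache <- list(lwt = lwt, t1 = lwt, t2 = t2, t3 = t3)
  cache$lhom <- t2
  cache$lhet <- mix_het(cache, params$mu)
  finalize_cache(cache)
}

# Combine cached mixture terms for a given drop-out probability.
mix_het <- function(cache, mu) {
  if (mu == 0) return(cache$t3)
  if (mu == 1) return(logaddexp(log(0.5) + cache$t1, log(0.5) + cache$t2))
  logaddexp(logaddexp(log(mu / 2) + cache$t1, log(mu / 2) + cache$t2),
            log1p(-mu) + cache$t3)
}

finalize_cache <- function(cache) {
  cache$dhet <- cache$lhet - cache$lwt
  cache$dhom <- cache$lhom - cache$lwt
  cache$tot_wt <- rowSums(cache$lwt)
  cache
}

#' Likelihood of the counts at one locus given k mutated cells
#'
#' Averages the product of mutated-state and wild-type likelihoods over all
#' `choose(m, k)` cell subsets, for every `k = 0..m` at once, using the
#' standard subset-sum (Poisson-binomial style) dynamic programme in O(m^2)
#' log-space operations. The mutated state uses the heterozygous model
#' including the drop-out mixture.
#'
#' @param s,c integer vectors of length `m`: per-cell alternative counts and
#'   coverages at the locus.
#' @param params a [model_params()] object.
#' @return numeric vector of length `m + 1`: `log P(D_i | K = k)` for
#'   `k = 0..m`.
#' @export
likelihood_given_k <- function(s, c, params) {
  m <- length(s)
  stopifnot(length(c) == m, m >= 1)
  la <- log_p_het(s, c, params)
  lw <- log_p_wt(s, c, params)
  d <- 0
  for (j in seq_len(m)) {
    d <- logaddexp(c(d, -Inf) + lw[j], c(-Inf, d) + la[j])
  }
  d - lchoose(m, 0:m)
}

#' Prior on the number of cells carrying a mutation
#'
#' Probability that a mutation placed uniformly on the edges of a uniform
#' rooted binary tree with `m` leaves subtends exactly `k` leaves:
#' `choose(m, k)^2 / ((2k - 1) * choose(2m, 2k))`.
#'
#' @param m number of cells.
#' @param k number of mutated cells, `1 <= k <= m` (vectorized).
#' @return probability vector.
#' @export
prior_k <- function(m, k) {
  if (any(k < 1 | k > m)) stop("require 1 <= k <= m")
  exp(2 * lchoose(m, k) - log(2 * k - 1) - lchoose(2 * m, 2 * k))
}

#' Posterior odds that a locus carries at least one mutated cell
#'
#' Computes `[lambda * sum_k P(D|K=k) P(K=k)] / [(1 - lambda) * P(D|K=0)]`;
#' the marginal `P(D)` cancels and is never evaluated.
#'
#' @inheritParams likelihood_given_k
#' @param config a [candidate_config()] object.
#' @return list with `log_odds` and logical `flag` (`log_odds > log(cutoff)`).
#' @export
posterior_mutation_evidence <- function(s, c, params,
                                        config = candidate_config()) {
  m <- length(s)
  lk <- likelihood_given_k(s, c, params)
  lk1 <- logsumexp(lk[-1L] + log(prior_k(m, seq_len(m))))
  log_odds <- (log(config$lambda) + lk1) - (log1p(-config$lambda) + lk[1L])
  list(log_odds = log_odds, flag = log_odds > log(config$cutoff))
}

#' Select candidate mutated loci from a count matrix
#'
#' Retains loci whose posterior odds of at least one mutated cell exceed the
#' cutoff and that show alternative support in at least `min_mutated_cells`
#' distinct cells. The per-cell state likelihoods of retained loci are cached
#' for tree inference; all remaining loci contribute their `(s, c)` count
#' spectrum as the wild-type background.
#'
#' @param mat a `count_matrix` (see [count_matrix()]).
#' @param params a [model_params()] object.
#' @param config a [candidate_config()] object.
#' @return object of class `candidate_set` with elements `loci` (data.frame),
#'   `support`, `coverage` (`n x m`), `cells`, `cache`, `log_odds`,
#'   `background` (spectrum data.frame with `s`, `c`, `count`).
#' @export
select_candidates <- function(mat, params = model_params(),
                              config = candidate_config()) {
  S <- mat$support
  C <- mat$coverage
  N <- nrow(S)
  m <- ncol(S)
  n_support <- rowSums(S > 0L)
  eval_idx <- which(n_support >= config$min_mutated_cells)
  flags <- logical(N)
  odds <- rep(-Inf, N)
  for (i in eval_idx) {
    ev <- posterior_mutation_evidence(S[i, ], C[i, ], params, config)
    odds[i] <- ev$log_odds
    flags[i] <- ev$flag
  }
  keep <- which(flags)
  if (length(keep) == 0L)
    warning("no candidate loci found; tree inference will be uninformed")
  bg_idx <- setdiff(seq_len(N), keep)
  background <- count_spectrum(S[bg_idx, , drop = FALSE],
                               C[bg_idx, , drop = FALSE])
  support <- S[keep, , drop = FALSE]
  coverage <- C[keep, , drop = FALSE]
  structure(
    list(loci = mat$loci[keep, , drop = FALSE],
         support = support, coverage = coverage, cells = mat$cells,
         cache = likelihood_cache(support, coverage, params),
         log_odds = odds[keep],
         background = background),
    class = "candidate_set")
}

#' Bin counts into a unique-pair spectrum
#'
#' @param S,C integer matrices of identical shape.
#' @return data.frame with columns `s`, `c`, `count`; zero-coverage entries
#'   are dropped (they contribute probability one).
#' @export
count_spectrum <- function(S, C) {
  if (length(S) == 0L) return(data.frame(s = integer(), c = integer(),
                                         count = integer()))
  dt <- data.table::data.table(s = as.integer(S), c = as.integer(C))
  dt <- dt[dt$c > 0L, ]
  if (nrow(dt) == 0L) return(data.frame(s = integer(), c = integer(),
                                        count = integer()))
  agg <- dt[, list(count = .N), by = c("s", "c")]
  data.frame(s = agg$s, c = agg$c, count = agg$count)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", nrow(x$support), "loci x", length(x$cells),
      "cells;", sum(x$background$count), "background observations\n")
  invisible(x)
}
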