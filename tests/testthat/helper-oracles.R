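# Independent oracles used across the suite: direct (linear-space)
# evaluations of the model densities, brute-force subset/attachment
# enumeration, and exhaustive enumeration of labelled rooted binary
# topologies.

# Direct beta-binomial evaluation through the beta function (linear space),
# independent of the log-gamma implementation under test.
bb_oracle <- function(s, c, f, omega) {
  alpha <- f * omega
  b <- (1 - f) * omega
  log(choose(c, s) * beta(s + alpha, c - s + b) / beta(alpha, b))
}

# Three-term drop-out mixture summed in linear space.
het_oracle <- function(s, c, params) {
  f_het <- 0.5 - (2 / 3) * params$f_wt
  log(params$mu / 2 * exp(bb_oracle(s, c, params$f_wt, params$omega_wt)) +
      params$mu / 2 * exp(bb_oracle(c - s, c, params$f_wt,
                                    params$omega_wt)) +
      (1 - params$mu) * exp(bb_oracle(s, c, f_het, params$omega_a)))
}

# Brute-force subset enumeration of P(D | K = k) for one locus.
likelihood_given_k_oracle <- function(s, c, params) {
  m <- length(s)
  la <- log_p_het(s, c, params)
  lw <- log_p_wt(s, c, params)
  out <- numeric(m + 1)
  out[1] <- sum(lw)
  for (k in seq_len(m)) {
    subs <- utils::combn(m, k)
    vals <- apply(subs, 2L, function(ix) sum(la[ix]) + sum(lw[-ix]))
    mx <- max(vals)
    out[k + 1] <- mx + log(mean(exp(vals - mx)))
  }
  out
}

# All labelled rooted binary topologies on m leaves ((2m - 3)!! of them),
# built by inserting each leaf on every edge of every partial tree.
enum_topologies <- function(m, cells = paste0("cell", seq_len(m))) {
  nn <- 2L * m - 1L
  base <- list(
    parent = { p <- integer(nn); p[c(1L, 2L)] <- m + 1L; p },
    children = { ch <- matrix(NA_integer_, nn, 2)
                 ch[m + 1L, ] <- c(1L, 2L); ch },
    root = m + 1L)
  trees <- list(base)
  for (k in seq_len(m)[-(1:2)]) {
    newt <- vector("list", length(trees) * (2L * k - 3L))
    idx <- 0L
    nodes <- c(seq_len(k - 1L), (m + 1L):(m + k - 2L))
    for (tr in trees) {
      for (v in nodes) {
        parent <- tr$parent
        children <- tr$children
        root <- tr$root
        u <- m + k - 1L
        if (v == root) {
          children[u, ] <- c(v, k)
          parent[v] <- u
          root <- u
        } else {
          p <- parent[v]
          children[p, children[p, ] == v] <- u
          children[u, ] <- c(v, k)
          parent[v] <- u
          parent[u] <- p
        }
        parent[k] <- u
        idx <- idx + 1L
        newt[[idx]] <- list(parent = parent, children = children,
                            root = root)
      }
    }
    trees <- newt
  }
  lapply(trees, function(tr)
    lineage_tree(tr$parent, tr$children, tr$root, seq_len(m), cells))
}

# Attachment sums recomputed from explicit leaf sets (no DFS).
marginal_oracle <- function(tree, cache, params) {
  m <- tree$m
  nn <- 2L * m - 1L
  B <- below_matrix(tree)
  n <- nrow(cache$lwt)
  S_a <- S_h <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(seq_len(nn), function(v) {
      below <- B[v, ] > 0
      sum(cache$lhet[i, below]) + sum(cache$lwt[i, !below])
    }, 0)
    mx <- max(vals)
    S_a[i] <- mx + log(mean(exp(vals - mx)))
    valsh <- vapply((m + 1L):nn, function(v) {
      below <- B[v, ] > 0
      sum(cache$lhom[i, below]) + sum(cache$lwt[i, !below])
    }, 0)
    mx <- max(valsh)
    S_h[i] <- mx + log(mean(exp(valsh - mx)))
  }
  list(S_a = S_a, S_h = S_h)
}

# Exhaustive posterior over topologies (normalized P(D | T) with the
# uniform topology prior) and the genotype posterior averaged over it.
exhaustive_topology_posterior <- function(cand, params, cells) {
  ts <- enum_topologies(length(cells), cells)
  ls <- vapply(ts, function(tr) tree_log_score(tr, cand, params), 0)
  w <- exp(ls - max(ls))
  w <- w / sum(w)
  list(trees = ts, weights = w,
       ids = vapply(ts, tree_topology_id, ""))
}

exhaustive_genotype_posterior <- function(cand, params, cells) {
  post <- exhaustive_topology_posterior(cand, params, cells)
  Reduce(`+`, lapply(seq_along(post$trees), function(i)
    post$weights[i] * posterior_genotypes(post$trees[[i]], cand,
                                          params)$prob))
}

# Small count-matrix builder for hand-constructed examples.
make_counts <- function(S, C, cells = paste0("c", seq_len(ncol(S))),
                        ref = "A", alt = "C") {
  count_matrix(
    loci = data.frame(chrom = "chr1", pos = seq_len(nrow(S)), ref = ref,
                      alt = alt, stringsAsFactors = FALSE),
    cells = cells, support = S, coverage = C)
}

random_count_row <- function(m, max_cov = 30L) {
  c <- sample.int(max_cov, m, replace = TRUE)
  s <- vapply(c, function(ci) sample.int(ci + 1L, 1L) - 1L, 0L)
  list(s = as.integer(s), c = as.integer(c))
}
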