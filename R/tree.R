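# Rooted binary cell lineage tree: leaves are cells, every node identifies
# the edge above it as a mutation attachment point. Node ids are fixed:
# 1..m are leaves, (m+1)..(2m-1) are internal nodes (the root among them).

#' Construct a cell lineage tree object
#'
#' @param parent integer vector of length `2m - 1`; `parent[root] == 0`.
#' @param children integer matrix `(2m - 1) x 2`; `NA` rows for leaves.
#' @param root integer id of the root node.
#' @param leaf_cell integer vector of length `m`: `leaf_cell[v]` is the cell
#'   (column index) carried by leaf node `v`. Leaf-swap moves permute this.
#' @param cells character vector of cell names.
#' @return object of class `cell_lineage_tree`.
#' @export
lineage_tree <- function(parent, children, root, leaf_cell, cells) {
  m <- length(cells)
  tr <- structure(
    list(m = m, parent = as.integer(parent), children = children,
         root = as.integer(root), leaf_cell = as.integer(leaf_cell),
         cells = cells),
    class = "cell_lineage_tree")
  validate_tree(tr)
  tr
}

#' Validate cell lineage tree invariants
#'
#' Checks: `m` leaves and `m - 1` internal nodes, every internal node with
#' exactly two children, consistent parent/child pointers, a single root, and
#' a bijective leaf-to-cell labelling.
#'
#' @param tree a `cell_lineage_tree`.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  m <- tree$m
  nn <- 2L * m - 1L
  stopifnot(m >= 2L, length(tree$parent) == nn, nrow(tree$children) == nn)
  if (tree$parent[tree$root] != 0L) stop("root must have parent 0")
  if (sum(tree$parent == 0L) != 1L) stop("exactly one root required")
  for (v in seq_len(nn)) {
    ch <- tree$children[v, ]
    if (v <= m) {
      if (!all(is.na(ch))) stop("leaf ", v, " has children")
    } else {
      if (any(is.na(ch)) || length(unique(ch)) != 2L)
        stop("internal node ", v, " must have two distinct children")
      if (any(tree$parent[ch] != v))
        stop("parent/child mismatch at node ", v)
    }
  }
  if (!setequal(tree$leaf_cell, seq_len(m)))
    stop("leaf_cell must be a permutation of 1..m")
  po <- postorder(tree)
  if (length(po) != nn) stop("tree is not connected")
  invisible(tree)
}

#' Random uniform rooted binary tree topology
#'
#' Grows the tree by inserting each new leaf on a uniformly chosen edge
#' (the edge above the root included), which draws uniformly from the
#' `(2m - 3)!!` labelled rooted binary topologies.
#'
#' @param m number of cells (leaves), `m >= 2`.
#' @param cells optional cell names (default `cell1..cellm`).
#' @return a `cell_lineage_tree`.
#' @export
random_tree <- function(m, cells = NULL) {
  stopifnot(m >= 2)
  cells <- cells %||% paste0("cell", seq_len(m))
  stopifnot(length(cells) == m, !anyDuplicated(cells))
  nn <- 2L * m - 1L
  parent <- integer(nn)
  children <- matrix(NA_integer_, nn, 2)
  root <- m + 1L
  children[root, ] <- c(1L, 2L)
  parent[c(1L, 2L)] <- root
  nodes <- c(1L, 2L, root)
  for (k in seq_len(m)[-(1:2)]) {
    v <- nodes[sample.int(length(nodes), 1L)]
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
    nodes <- c(nodes, k, u)
  }
  lineage_tree(parent, children, root, seq_len(m), cells)
}

#' Postorder traversal (children before parents)
#' @param tree a `cell_lineage_tree`.
#' @param from node to start from (default the root).
#' @return integer vector of node ids in postorder.
#' @export
postorder <- function(tree, from = tree$root) {
  nn <- 2L * tree$m - 1L
  out <- integer(nn)
  stack <- integer(nn)
  stack[1L] <- from
  top <- 1L
  k <- 0L
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    k <- k + 1L
    out[k] <- v
    ch <- tree$children[v, ]
    if (!is.na(ch[1L])) {
      stack[top + 1L] <- ch[1L]
      stack[top + 2L] <- ch[2L]
      top <- top + 2L
    }
  }
  rev(out[seq_len(k)])
}

#' Nodes of the subtree rooted at a node
#' @inheritParams postorder
#' @param v subtree root.
#' @return integer node ids (including `v`).
#' @keywords internal
subtree_nodes <- function(tree, v) postorder(tree, from = v)

#' Leaf-below indicator matrix
#'
#' @param tree a `cell_lineage_tree`.
#' @return `(2m - 1) x m` 0/1 matrix `B` with `B[v, j] = 1` iff cell `j`
#'   labels a leaf in the subtree below node `v` (columns indexed by cell).
#' @export
below_matrix <- function(tree) {
  m <- tree$m
  nn <- 2L * m - 1L
  B <- matrix(0, nn, m)
  B[cbind(seq_len(m), tree$leaf_cell)] <- 1
  for (v in postorder(tree)) {
    if (v > m) {
      ch <- tree$children[v, ]
      B[v, ] <- B[ch[1L], ] + B[ch[2L], ]
    }
  }
  B
}

# One DFS pass: given per-locus per-cell log ratios delta (n x m), return the
# n x (2m-1) matrix of subtree log-ratio sums A[, v] = sum_{j below v} delta_j.
subtree_delta_sums <- function(tree, delta) {
  m <- tree$m
  nn <- 2L * m - 1L
  A <- matrix(0, nrow(delta), nn)
  A[, seq_len(m)] <- delta[, tree$leaf_cell, drop = FALSE]
  for (v in postorder(tree)) {
    if (v > m) {
      ch <- tree$children[v, ]
      A[, v] <- A[, ch[1L]] + A[, ch[2L]]
    }
  }
  A
}

#' Per-node attachment log products
#'
#' For each node `v`, the log probability of the data at one locus when the
#' mutation is attached to the edge above `v`: cells below `v` follow the
#' mutated state, all others the wild-type state. Computed for all loci at
#' once in a single depth-first pass per locus set, O(m) per locus.
#'
#' @param tree a `cell_lineage_tree`.
#' @param state_logp `n x m` matrix of per-cell mutated-state log
#'   probabilities (heterozygous or homozygous).
#' @param wt_logp `n x m` matrix of per-cell wild-type log probabilities.
#' @return `n x (2m - 1)` matrix of log products.
#' @export
subtree_products <- function(tree, state_logp, wt_logp) {
  A <- subtree_delta_sums(tree, state_logp - wt_logp)
  A + rowSums(wt_logp)
}

# Internal workhorse: marginal attachment sums for all candidate loci.
# cache holds lwt, lhet, lhom (n x m) plus dhet = lhet - lwt, dhom.
# Returns list with A_het, A_hom (n x nn, log-ratio scale), tot (n),
# lse_a, lse_h, S_a, S_h, combined (all n, log scale).
marginal_sums <- function(tree, cache, params) {
  m <- tree$m
  if (m < 2L) stop("need at least two cells")
  nn <- 2L * m - 1L
  internal <- (m + 1L):nn
  A_het <- subtree_delta_sums(tree, cache$dhet)
  A_hom <- subtree_delta_sums(tree, cache$dhom)
  tot <- cache$tot_wt
  lse_a <- row_logsumexp(A_het)
  lse_h <- row_logsumexp(A_hom[, internal, drop = FALSE])
  S_a <- lse_a - log(2 * m - 1) + tot
  S_h <- lse_h - log(m - 1) + tot
  nu <- params$nu
  combined <- if (nu == 0) {
    S_a
  } else if (nu == 1) {
    S_h
  } else {
    logaddexp(log1p(-nu) + S_a, log(nu) + S_h)
  }
  list(A_het = A_het, A_hom = A_hom, tot = tot,
       S_a = S_a, S_h = S_h, combined = combined)
}

#' Marginalized per-locus attachment sums
#'
#' Marginalizes the attachment point of each candidate mutation over the tree:
#' `S_a` averages the heterozygous attachment products over all `2m - 1`
#' nodes, `S_h` averages the homozygous products over the `m - 1` internal
#' nodes only (a homozygous observation in a single cell is better explained
#' as drop-out), and `combined = log[(1 - nu) S_a + nu S_h]` mixes the two
#' zygosity hypotheses.
#'
#' @param tree a `cell_lineage_tree`.
#' @param cache a per-locus likelihood cache from [likelihood_cache()] (or a
#'   `candidate_set`'s `$cache`).
#' @param params a [model_params()] object.
#' @return list with numeric vectors `S_a`, `S_h`, `combined` (log scale, one
#'   entry per locus).
#' @export
locus_marginal <- function(tree, cache, params) {
  ms <- marginal_sums(tree, cache, params)
  list(S_a = ms$S_a, S_h = ms$S_h, combined = ms$combined)
}

#' Background wild-type log likelihood from a count spectrum
#'
#' The non-candidate loci enter the tree score only through the wild-type
#' model, so their contribution is a sum over the multiset of observed
#' `(s, c)` pairs; binning by unique pairs makes it linear in the number of
#' distinct pairs while leaving the value exactly equal to the naive sum.
#'
#' @param spectrum data.frame with integer columns `s`, `c`, `count`.
#' @param params a [model_params()] object.
#' @return scalar log likelihood (0 for an empty spectrum).
#' @export
background_wt_loglik <- function(spectrum, params) {
  if (is.null(spectrum) || nrow(spectrum) == 0L) return(0)
  sum(spectrum$count * log_p_wt(spectrum$s, spectrum$c, params))
}

#' Log score of a tree
#'
#' `log P(D | T, theta)` up to a constant: the sum over candidate loci of the
#' zygosity-mixed marginal attachment term plus the background wild-type term.
#'
#' @param tree a `cell_lineage_tree`.
#' @param cand a `candidate_set` (see [select_candidates()]).
#' @param params a [model_params()] object.
#' @return scalar log score.
#' @export
tree_log_score <- function(tree, cand, params) {
  cache <- likelihood_cache(cand$support, cand$coverage, params)
  sum(marginal_sums(tree, cache, params)$combined) +
    background_wt_loglik(cand$background, params)
}

# Posterior per-cell mutation probabilities for one tree and parameter set.
# Returns list(prob = n x m, prob_hom = n x m hom-component share,
#              node_weight = n x (2m-1) posterior attachment weights).
genotype_weights <- function(tree, cache, params, ms = NULL) {
  m <- tree$m
  nn <- 2L * m - 1L
  internal <- (m + 1L):nn
  if (is.null(ms)) ms <- marginal_sums(tree, cache, params)
  nu <- params$nu
  # log denominator on the ratio scale (tot cancels)
  q <- ms$combined - ms$tot
  W_het <- if (nu == 1) {
    matrix(0, nrow(ms$A_het), nn)
  } else {
    exp(ms$A_het - q + log1p(-nu) - log(2 * m - 1))
  }
  W_hom <- if (nu == 0) {
    matrix(0, nrow(ms$A_hom), length(internal))
  } else {
    exp(ms$A_hom[, internal, drop = FALSE] - q + log(nu) - log(m - 1))
  }
  B <- below_matrix(tree)
  prob_het <- W_het %*% B
  prob_hom <- W_hom %*% B[internal, , drop = FALSE]
  node_weight <- W_het
  node_weight[, internal] <- node_weight[, internal] + W_hom
  list(prob = prob_het + prob_hom, prob_hom = prob_hom,
       node_weight = node_weight)
}

#' Posterior genotype probabilities for a fixed tree
#'
#' For each candidate locus and cell, the posterior probability that the cell
#' carries the mutation given the tree: attachment nodes are weighted by
#' their (zygosity-mixed) likelihood contribution and the weights of nodes
#' above the cell are summed.
#'
#' @inheritParams tree_log_score
#' @return list with `prob` (`n x m` mutation probabilities), `prob_hom`
#'   (share contributed by the homozygous state) and `node_weight`
#'   (`n x (2m - 1)` posterior attachment weights, rows summing to 1).
#' @export
posterior_genotypes <- function(tree, cand, params) {
  cache <- likelihood_cache(cand$support, cand$coverage, params)
  genotype_weights(tree, cache, params)
}

#' Expected number of mutations attached per node
#'
#' Sums posterior attachment weights over loci; the node totals add up to the
#' number of candidate mutations.
#'
#' @inheritParams tree_log_score
#' @return numeric vector of length `2m - 1`.
#' @export
expected_node_attachments <- function(tree, cand, params) {
  colSums(posterior_genotypes(tree, cand, params)$node_weight)
}

#' Canonical topology identifier
#'
#' A canonical newick-like string (children sorted lexicographically) that is
#' identical for trees with the same unordered leaf-labelled topology.
#'
#' @param tree a `cell_lineage_tree`.
#' @return character scalar.
#' @export
tree_topology_id <- function(tree) {
  build <- function(v) {
    ch <- tree$children[v, ]
    if (is.na(ch[1L])) return(tree$cells[tree$leaf_cell[v]])
    s <- sort(c(build(ch[1L]), build(ch[2L])))
    paste0("(", s[1L], ",", s[2L], ")")
  }
  build(tree$root)
}

#' Newick string for a cell lineage tree
#'
#' @param tree a `cell_lineage_tree`.
#' @param node_labels optional vector of length `2m - 1`; values for internal
#'   nodes are written as newick internal-node labels.
#' @return character scalar (terminated by `;`).
#' @export
tree_to_newick <- function(tree, node_labels = NULL) {
  build <- function(v) {
    ch <- tree$children[v, ]
    if (is.na(ch[1L])) return(tree$cells[tree$leaf_cell[v]])
    lab <- if (is.null(node_labels)) "" else as.character(node_labels[v])
    paste0("(", build(ch[1L]), ",", build(ch[2L]), ")", lab)
  }
  paste0(build(tree$root), ";")
}

#' @export
print.cell_lineage_tree <- function(x, ...) {
  cat("Cell lineage tree with", x$m, "cells:\n ", tree_to_newick(x), "\n")
  invisible(x)
}
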