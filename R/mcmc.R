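# MCMC over (tree, parameters): prune-and-reattach and leaf-swap tree moves,
# adaptive Gaussian parameter walks, Metropolis-Hastings acceptance, and
# accumulation of the posterior genotype matrix.

PARAM_NAMES <- c("f_wt", "omega_wt", "omega_a", "mu", "nu")
LOG_SCALE_PARAMS <- c("omega_wt", "omega_a")

#' MCMC configuration
#'
#' @param iterations total number of iterations; default
#'   `round(10 * m^2 * log(m))` (resolved inside [run_chain()]), following the
#'   convergence heuristic that chain length should grow as `m^2 log(m)`.
#' @param burn_in fraction of iterations discarded (and used for step-size
#'   adaptation), in `[0, 1)`.
#' @param thin record every `thin`-th post-burn-in state.
#' @param seed optional integer seed set at chain start.
#' @param move_weights weights of the prune-reattach, leaf-swap and
#'   parameter-walk move families (normalized internally; parameter weight is
#'   split evenly across the five parameters).
#' @param adapt_target target acceptance rate for the adaptive walks.
#' @param adapt_window number of proposals per adaptation update.
#' @param record_trees if `TRUE`, store the canonical topology id of every
#'   recorded sample.
#' @param check_every recompute the score from scratch every this many
#'   iterations and error if the cached value drifted.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = NULL, burn_in = 0.25, thin = 10L,
                        seed = NULL,
                        move_weights = c(prune_reattach = 0.45,
                                         leaf_swap = 0.10, param = 0.45),
                        adapt_target = 0.5, adapt_window = 50L,
                        record_trees = FALSE, check_every = 5000L) {
  stopifnot(is.null(iterations) || iterations > 0,
            burn_in >= 0, burn_in < 1, thin >= 1,
            all(move_weights >= 0), sum(move_weights) > 0)
  structure(list(iterations = iterations, burn_in = burn_in,
                 thin = as.integer(thin), seed = seed,
                 move_weights = move_weights / sum(move_weights),
                 adapt_target = adapt_target,
                 adapt_window = as.integer(adapt_window),
                 record_trees = record_trees,
                 check_every = as.integer(check_every)),
            class = "mcmc_config")
}

#' Prune-and-reattach tree proposal
#'
#' Detaches a uniformly drawn non-root node together with its subtree and
#' re-attaches it by subdividing the edge above a uniformly drawn node
#' outside the subtree. Re-attachment at the original sibling reproduces the
#' input tree (a valid self-move). Forward and backward choice counts are
#' equal (the pruned subtree size is unchanged), so the log proposal ratio
#' is 0.
#'
#' @param tree a `cell_lineage_tree`.
#' @return list with `tree` (the proposal) and `log_ratio`; `NULL` if
#'   `m < 3` (the move cannot change a 2-leaf tree).
#' @export
propose_prune_reattach <- function(tree) {
  m <- tree$m
  if (m < 3L) return(NULL)
  nn <- 2L * m - 1L
  nonroot <- setdiff(seq_len(nn), tree$root)
  v <- nonroot[sample.int(length(nonroot), 1L)]
  sub <- subtree_nodes(tree, v)
  p <- tree$parent[v]
  sib <- setdiff(tree$children[p, ], v)
  # detach: p is removed, sib takes its place
  parent <- tree$parent
  children <- tree$children
  root <- tree$root
  if (p == root) {
    root <- sib
    parent[sib] <- 0L
  } else {
    gp <- parent[p]
    children[gp, children[gp, ] == p] <- sib
    parent[sib] <- gp
  }
  targets <- setdiff(seq_len(nn), c(sub, p))
  w <- targets[sample.int(length(targets), 1L)]
  # reattach: reuse p as the junction above w
  if (w == root) {
    children[p, ] <- c(w, v)
    parent[w] <- p
    parent[p] <- 0L
    root <- p
  } else {
    gw <- parent[w]
    children[gw, children[gw, ] == w] <- p
    children[p, ] <- c(w, v)
    parent[w] <- p
    parent[p] <- gw
  }
  tr <- tree
  tr$parent <- parent
  tr$children <- children
  tr$root <- root
  list(tree = tr, log_ratio = 0)
}

#' Leaf-swap tree proposal
#'
#' Exchanges the cell labels of two distinct uniformly drawn leaves; the
#' proposal is symmetric.
#'
#' @param tree a `cell_lineage_tree`.
#' @return list with `tree` and `log_ratio = 0`.
#' @export
propose_leaf_swap <- function(tree) {
  m <- tree$m
  lv <- sample.int(m, 2L)
  tr <- tree
  tr$leaf_cell[lv] <- tr$leaf_cell[rev(lv)]
  list(tree = tr, log_ratio = 0)
}

#' Gaussian random-walk parameter proposal
#'
#' Perturbs one parameter by a Gaussian step: the overdispersion parameters
#' walk on the log scale (they are scale parameters), `f_wt`, `mu` and `nu`
#' on the natural scale. Proposals outside the parameter bounds are rejected
#' by returning `NULL` (counted as a rejected move).
#'
#' @param params a [model_params()] object (or plain list).
#' @param which parameter name, one of
#'   `f_wt, omega_wt, omega_a, mu, nu`.
#' @param sd proposal standard deviation.
#' @return list with `params` and `log_ratio = 0`, or `NULL` if out of
#'   bounds.
#' @export
propose_param <- function(params, which, sd) {
  stopifnot(which %in% PARAM_NAMES)
  p <- params
  if (which %in% LOG_SCALE_PARAMS) {
    p[[which]] <- exp(log(p[[which]]) + rnorm(1L, 0, sd))
  } else {
    p[[which]] <- p[[which]] + rnorm(1L, 0, sd)
  }
  if (!params_in_bounds(p)) return(NULL)
  list(params = p, log_ratio = 0)
}

#' Metropolis-Hastings acceptance decision
#'
#' Accepts with probability
#' `min(1, exp(log_ratio + log_score_new - log_score_old))` (uniform priors
#' cancel).
#'
#' @param log_score_old,log_score_new current and proposed log scores.
#' @param log_ratio log proposal ratio `q(old|new)/q(new|old)`.
#' @return logical.
#' @export
mh_accept <- function(log_score_old, log_score_new, log_ratio = 0) {
  if (is.nan(log_score_old) || is.nan(log_score_new) || is.nan(log_ratio))
    stop("NaN log score in Metropolis-Hastings acceptance")
  la <- log_ratio + log_score_new - log_score_old
  la >= 0 || log(runif(1L)) < la
}

#' Adaptive step-size update
#'
#' Multiplicative update pushing the recent acceptance rate toward the
#' target; applied only during burn-in so the post-burn-in kernel is fixed.
#'
#' @param accepted number of accepted proposals in the window.
#' @param proposed number of proposals in the window.
#' @param sd current standard deviation.
#' @param target target acceptance rate.
#' @return updated standard deviation, bounded in `[1e-6, 1e3]`.
#' @export
adapt_step <- function(accepted, proposed, sd, target = 0.5) {
  if (proposed == 0L) return(sd)
  rate <- accepted / proposed
  min(max(sd * exp(rate - target), 1e-6), 1e3)
}

# Update the likelihood cache after a parameter change, recomputing only the
# pieces the changed parameter touches.
update_cache <- function(cache, support, coverage, params, which) {
  if (which %in% c("f_wt", "omega_wt")) {
    return(likelihood_cache(support, coverage, params))
  }
  if (which == "omega_a") {
    cache$t3 <- log_beta_binomial(support, coverage,
                                  0.5 - (2 / 3) * params$f_wt,
                                  params$omega_a)
    cache$lhet <- mix_het(cache, params$mu)
  } else if (which == "mu") {
    cache$lhet <- mix_het(cache, params$mu)
  }
  # nu enters only the zygosity mixing, not the per-cell likelihoods
  finalize_cache(cache)
}

#' Run the MCMC chain over trees and parameters
#'
#' Samples from the joint posterior of the cell lineage tree and the model
#' parameters given the candidate loci and the wild-type background. After
#' burn-in, thinned samples accumulate the posterior genotype matrix: for
#' each locus the posterior attachment weights of the current tree are summed
#' over the nodes above each cell (mixing the heterozygous and homozygous
#' components) and averaged over the chain.
#'
#' @param cand a `candidate_set` with at least one locus.
#' @param params initial [model_params()].
#' @param config an [mcmc_config()].
#' @param tree optional initial tree (default: random topology).
#' @return list of class `mcmc_result` with elements `genotype` (`n x m`
#'   posterior genotype matrix), `genotype_hom` (homozygous share),
#'   `best_tree`, `best_score`, `params_mean`, `params_final`, `trace`
#'   (data.frame of thinned iteration, score and parameters), `topologies`
#'   (canonical ids if recorded), `acceptance` (per move family), `step_sd`,
#'   `n_samples`.
#' @export
run_chain <- function(cand, params = model_params(), config = mcmc_config(),
                      tree = NULL) {
  n <- nrow(cand$support)
  if (is.null(n) || n == 0L) stop("candidate set is empty")
  m <- length(cand$cells)
  if (!is.null(config$seed)) set.seed(config$seed)
  iterations <- config$iterations %||% max(1000L, round(10 * m^2 * log(m)))
  burn_iters <- floor(config$burn_in * iterations)
  if (is.null(tree)) tree <- random_tree(m, cand$cells)

  params <- unclass(params)
  cache <- likelihood_cache(cand$support, cand$coverage, params)
  ms <- marginal_sums(tree, cache, params)
  bg_ll <- background_wt_loglik(cand$background, params)
  score <- sum(ms$combined) + bg_ll

  # move schedule: two tree moves plus one walk per parameter
  mw <- config$move_weights
  move_p <- c(mw[["prune_reattach"]], mw[["leaf_swap"]],
              rep(mw[["param"]] / 5, 5))
  move_names <- c("prune_reattach", "leaf_swap", PARAM_NAMES)
  move_p <- move_p / sum(move_p)
  move_draws <- sample.int(7L, iterations, replace = TRUE, prob = move_p)

  sd <- c(f_wt = 0.001, omega_wt = 0.5, omega_a = 0.5, mu = 0.05, nu = 0.05)
  acc <- prop <- setNames(numeric(7L), move_names)
  win_acc <- win_prop <- setNames(numeric(5L), PARAM_NAMES)

  n_rec <- max(0L, (iterations - burn_iters) %/% config$thin)
  G <- matrix(0, n, m)
  G_hom <- matrix(0, n, m)
  par_sum <- setNames(numeric(5L), PARAM_NAMES)
  trace_it <- integer(n_rec)
  trace_score <- numeric(n_rec)
  trace_par <- matrix(0, n_rec, 5L, dimnames = list(NULL, PARAM_NAMES))
  topologies <- if (config$record_trees) character(n_rec) else NULL
  rec <- 0L
  best_tree <- tree
  best_score <- score

  for (it in seq_len(iterations)) {
    mv <- move_draws[it]
    mv_name <- move_names[mv]
    prop[mv] <- prop[mv] + 1
    if (mv <= 2L) {
      pr <- if (mv == 1L) propose_prune_reattach(tree) else
        propose_leaf_swap(tree)
      if (!is.null(pr)) {
        ms2 <- marginal_sums(pr$tree, cache, params)
        score2 <- sum(ms2$combined) + bg_ll
        if (mh_accept(score, score2, pr$log_ratio)) {
          tree <- pr$tree
          ms <- ms2
          score <- score2
          acc[mv] <- acc[mv] + 1
        }
      }
    } else {
      win_prop[mv_name] <- win_prop[mv_name] + 1
      pr <- propose_param(params, mv_name, sd[[mv_name]])
      if (!is.null(pr)) {
        cache2 <- update_cache(cache, cand$support, cand$coverage,
                               pr$params, mv_name)
        bg2 <- if (mv_name %in% c("f_wt", "omega_wt"))
          background_wt_loglik(cand$background, pr$params) else bg_ll
        ms2 <- marginal_sums(tree, cache2, pr$params)
        score2 <- sum(ms2$combined) + bg2
        if (mh_accept(score, score2, pr$log_ratio)) {
          params <- pr$params
          cache <- cache2
          bg_ll <- bg2
          ms <- ms2
          score <- score2
          acc[mv] <- acc[mv] + 1
          win_acc[mv_name] <- win_acc[mv_name] + 1
        }
      }
      if (it <= burn_iters && win_prop[mv_name] >= config$adapt_window) {
        sd[[mv_name]] <- adapt_step(win_acc[mv_name], win_prop[mv_name],
                                    sd[[mv_name]], config$adapt_target)
        win_acc[mv_name] <- win_prop[mv_name] <- 0
      }
    }
    if (score > best_score) {
      best_score <- score
      best_tree <- tree
    }
    if (config$check_every > 0L && it %% config$check_every == 0L) {
      fresh <- sum(marginal_sums(tree, cache, params)$combined) +
        background_wt_loglik(cand$background, params)
      if (abs(fresh - score) > 1e-8 * max(1, abs(fresh)))
        stop("cached log score drifted from recomputation at iteration ", it)
    }
    if (it > burn_iters && (it - burn_iters) %% config$thin == 0L &&
        rec < n_rec) {
      rec <- rec + 1L
      gw <- genotype_weights(tree, cache, params, ms)
      G <- G + gw$prob
      G_hom <- G_hom + gw$prob_hom
      par_sum <- par_sum + unlist(params[PARAM_NAMES])
      trace_it[rec] <- it
      trace_score[rec] <- score
      trace_par[rec, ] <- unlist(params[PARAM_NAMES])
      if (config$record_trees) topologies[rec] <- tree_topology_id(tree)
    }
  }
  if (rec == 0L) stop("no post-burn-in samples recorded; increase iterations")
  structure(list(
    genotype = G / rec,
    genotype_hom = G_hom / rec,
    best_tree = best_tree,
    best_score = best_score,
    params_mean = par_sum / rec,
    params_final = do.call(model_params, params),
    trace = data.frame(iteration = trace_it[seq_len(rec)],
                       score = trace_score[seq_len(rec)],
                       trace_par[seq_len(rec), , drop = FALSE]),
    topologies = if (config$record_trees) topologies[seq_len(rec)] else NULL,
    acceptance = ifelse(prop > 0, acc / prop, NA_real_),
    step_sd = sd,
    n_samples = rec,
    iterations = iterations), class = "mcmc_result")
}

#' Correlation between the genotype matrices of two chains
#'
#' The convergence diagnostic: Pearson correlation of the flattened
#' posterior genotype matrices of two independent runs.
#'
#' @param run1,run2 `mcmc_result` objects.
#' @return scalar correlation.
#' @export
genotype_correlation <- function(run1, run2) {
  cor(as.vector(run1$genotype), as.vector(run2$genotype))
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat("MCMC result:", x$iterations, "iterations,", x$n_samples,
      "recorded samples\n")
  cat("  best log score:", format(x$best_score), "\n")
  cat("  posterior parameter means:\n")
  print(round(x$params_mean, 4))
  invisible(x)
}
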