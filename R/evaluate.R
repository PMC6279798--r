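# Scoring against simulated truth, the independent-cells baseline caller,
# and the benchmark driver.

#' Full tree-based variant calling pipeline
#'
#' Convenience wrapper: candidate detection, MCMC over trees and parameters,
#' and assembly of the posterior genotype calls.
#'
#' @param mat a [count_matrix()].
#' @param params initial [model_params()].
#' @param cand_config a [candidate_config()].
#' @param mcmc an [mcmc_config()].
#' @param threshold hard-call probability cutoff.
#' @return list with `calls` (a [call_set()]), `chain` (the `mcmc_result`)
#'   and `candidates` (the `candidate_set`).
#' @export
call_variants <- function(mat, params = model_params(),
                          cand_config = candidate_config(),
                          mcmc = mcmc_config(), threshold = 0.5) {
  cand <- select_candidates(mat, params, cand_config)
  if (nrow(cand$support) == 0L) {
    calls <- call_set(cand$loci, matrix(0, 0L, length(mat$cells)),
                      mat$cells, threshold)
    return(list(calls = calls, chain = NULL, candidates = cand))
  }
  chain <- run_chain(cand, params, mcmc)
  calls <- call_set(cand$loci, chain$genotype, cand$cells,
                    threshold = threshold,
                    prob_hom = chain$genotype_hom,
                    coverage = cand$coverage)
  list(calls = calls, chain = chain, candidates = cand)
}

#' Independent-cells baseline caller
#'
#' After the shared candidate-detection step, each (locus, cell) pair is
#' genotyped independently: the posterior over wild type, heterozygous and
#' homozygous states under the fixed parameters with a flat state prior,
#' with no tree and no information sharing across cells. Zero-coverage
#' entries carry no information and are emitted as no-calls (probability 0).
#'
#' @param mat a [count_matrix()].
#' @param params a [model_params()] (not learned).
#' @param config a [candidate_config()].
#' @param threshold hard-call probability cutoff.
#' @return a [call_set()].
#' @export
baseline_caller <- function(mat, params = model_params(),
                            config = candidate_config(), threshold = 0.5) {
  cand <- select_candidates(mat, params, config)
  n <- nrow(cand$support)
  if (n == 0L)
    return(call_set(cand$loci, matrix(0, 0L, length(mat$cells)),
                    mat$cells, threshold))
  cache <- cand$cache
  denom <- logaddexp(logaddexp(cache$lwt, cache$lhet), cache$lhom)
  p_mut <- exp(logaddexp(cache$lhet, cache$lhom) - denom)
  p_hom <- exp(cache$lhom - denom)
  p_mut[cand$coverage == 0L] <- 0
  p_hom[cand$coverage == 0L] <- 0
  call_set(cand$loci, p_mut, cand$cells, threshold = threshold,
           prob_hom = p_hom, coverage = cand$coverage)
}

#' Score calls against simulated truth
#'
#' Compares hard calls with the post-drop-out truth genotypes per
#' (locus, cell) pair over the union of truth and called loci (matched by
#' `chrom:pos`); heterozygous and homozygous both count as mutated.
#'
#' @param calls a [call_set()].
#' @param truth a `ground_truth` with `$loci` (from [emit_dataset()]).
#' @param counts optional [count_matrix()] supplying coverage for loci
#'   absent from the call set.
#' @param exclude_zero_coverage drop (locus, cell) pairs without coverage
#'   from the confusion counts (default `TRUE`); requires coverage
#'   information.
#' @return data.frame row with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1` (harmonic mean of precision and recall; `NA` when undefined).
#' @export
score_calls <- function(calls, truth, counts = NULL,
                        exclude_zero_coverage = TRUE) {
  m <- ncol(truth$genotype)
  chr_pos <- function(loci) {
    if (nrow(loci) == 0L) return(character())
    paste0(loci$chrom, ":", loci$pos)
  }
  truth_keys <- chr_pos(truth$loci)
  call_keys <- chr_pos(calls$loci)
  keys <- union(truth_keys, call_keys)
  nk <- length(keys)
  truth_mut <- matrix(FALSE, nk, m)
  ti <- match(truth_keys, keys)
  if (length(ti) > 0L)
    truth_mut[ti, ] <- truth$genotype > 0L
  called_mut <- matrix(FALSE, nk, m)
  ci <- match(call_keys, keys)
  if (length(ci) > 0L)
    called_mut[ci, ] <- calls$prob > calls$threshold
  include <- matrix(TRUE, nk, m)
  if (exclude_zero_coverage) {
    cov <- matrix(NA_integer_, nk, m)
    if (!is.null(calls$coverage) && length(ci) > 0L)
      cov[ci, ] <- calls$coverage
    if (!is.null(counts)) {
      mk <- match(paste0(counts$loci$chrom, ":", counts$loci$pos), keys)
      hit <- which(!is.na(mk))
      cov[mk[hit], ] <- counts$coverage[hit, , drop = FALSE]
    }
    # loci absent from the count matrix were uncovered everywhere
    cov[is.na(cov)] <- if (is.null(counts) && is.null(calls$coverage))
      1L else 0L
    include <- cov > 0L
  }
  tp <- sum(called_mut & truth_mut & include)
  fp <- sum(called_mut & !truth_mut & include)
  fn <- sum(!called_mut & truth_mut & include)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
             recall = recall, f1 = f1)
}

#' Run the simulation benchmark
#'
#' For each grid point and replicate: simulate a dataset, call mutations
#' with the full tree-based pipeline and with the independent-cells
#' baseline, and score both against the simulated truth.
#'
#' @param grid list of named lists of [sim_config()] overrides (one per grid
#'   point), e.g. `list(list(dropout = 0.1), list(dropout = 0.3))`.
#' @param replicates replicates per grid point.
#' @param seed base seed; replicate r of grid point g uses
#'   `seed + 1000 * g + r`.
#' @param sim_defaults named list of [sim_config()] arguments shared by all
#'   grid points (the desk-scale default uses a 20 kb genome).
#' @param mcmc an [mcmc_config()] for the pipeline chains (desk-scale
#'   default: 5000 iterations).
#' @param params initial [model_params()].
#' @return data.frame with one row per (grid point, replicate, method).
#' @export
run_benchmark <- function(grid = list(list(dropout = 0.1)),
                          replicates = 10L, seed = 1L,
                          sim_defaults = list(m = 25L, genome_length = 2e4),
                          mcmc = mcmc_config(iterations = 5000L),
                          params = model_params()) {
  rows <- list()
  for (g in seq_along(grid)) {
    for (r in seq_len(replicates)) {
      args <- utils::modifyList(sim_defaults, grid[[g]])
      args$seed <- seed + 1000L * g + r
      cfg <- do.call(sim_config, args)
      row_meta <- data.frame(
        grid_point = g, replicate = r, m = cfg$m,
        dropout = cfg$dropout, cn_rate = cfg$cn_rate, seed = args$seed)
      res <- tryCatch({
        ds <- emit_dataset(cfg)
        mc <- mcmc
        mc$seed <- args$seed
        pipe <- call_variants(ds$counts, params, mcmc = mc)
        base <- baseline_caller(ds$counts, params)
        rbind(
          cbind(row_meta, method = "tree",
                score_calls(pipe$calls, ds$truth, ds$counts)),
          cbind(row_meta, method = "baseline",
                score_calls(base, ds$truth, ds$counts)))
      }, error = function(e) {
        warning("replicate ", r, " of grid point ", g, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Box plot of benchmark F1 scores
#'
#' @param results data.frame from [run_benchmark()].
#' @param x name of the stratification column (default `"dropout"`).
#' @return a ggplot object.
#' @export
plot_benchmark <- function(results, x = "dropout") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_benchmark requires ggplot2")
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data[[x]]), y = .data$f1,
                               fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1), size = 0.8) +
    ggplot2::labs(x = x, y = "F1") +
    ggplot2::theme_bw()
}
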