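# Ground-truth simulator: random cell lineage, mutation placement with
# drop-out and loss of heterozygosity, negative-binomial segment coverage,
# Polya-urn MDA amplification with copy-number and sequencing errors, and
# multi-sample pileup output.

#' Simulation configuration
#'
#' Defaults mirror the benchmark design: a 1 Mb reference split into ~1 kb
#' segments per cell, negative-binomial segment coverage with mean 25 and
#' variance 50, 10% zero-coverage segments, positional jitter with standard
#' deviation 10% of the segment mean, MDA polymerase error 5e-7 per copy and
#' sequencing error 1e-3 per read.
#'
#' @param m number of cells.
#' @param n_mut number of mutations placed on the tree.
#' @param genome_length reference length in bp.
#' @param segment_length amplification segment length in bp.
#' @param cov_mean,cov_var negative-binomial mean and variance of segment
#'   coverage (`cov_var > cov_mean`).
#' @param zero_segment_frac fraction of segments forced to zero coverage.
#' @param pos_cov_sd_frac positional coverage standard deviation as a
#'   fraction of the segment mean.
#' @param dropout fraction of mutations affected by drop-out: half become
#'   wild type (mutant allele lost), half homozygous (wild-type allele lost).
#' @param dropout_mode `"locus"` applies the conversion to every carrier cell
#'   of the selected mutation (clonal loss, the benchmark design);
#'   `"cell"` drops each carrier cell independently with probability
#'   `dropout` (the per-cell semantics of the drop-out mixture model).
#' @param cn_rate fraction of mutated loci receiving extra wild-type copies;
#'   the number of extra copies x follows `P(x) = 1/2^x`, x >= 1.
#' @param amp_error per-copy polymerase error probability of the urn process.
#' @param seq_error per-read sequencing error probability.
#' @param chrom chromosome name used in output.
#' @param seed optional integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(m = 25L, n_mut = 100L, genome_length = 1e6,
                       segment_length = 1000L, cov_mean = 25, cov_var = 50,
                       zero_segment_frac = 0.10, pos_cov_sd_frac = 0.10,
                       dropout = 0.1, dropout_mode = c("locus", "cell"),
                       cn_rate = 0, amp_error = 5e-7, seq_error = 1e-3,
                       chrom = "chr1", seed = NULL) {
  dropout_mode <- match.arg(dropout_mode)
  stopifnot(m >= 3, n_mut >= 1, genome_length >= n_mut,
            cov_var >= cov_mean,
            dropout >= 0, dropout <= 1, cn_rate >= 0, cn_rate <= 1,
            zero_segment_frac >= 0, zero_segment_frac <= 1)
  structure(list(m = as.integer(m), n_mut = as.integer(n_mut),
                 genome_length = as.integer(genome_length),
                 segment_length = as.integer(segment_length),
                 cov_mean = cov_mean, cov_var = cov_var,
                 zero_segment_frac = zero_segment_frac,
                 pos_cov_sd_frac = pos_cov_sd_frac,
                 dropout = dropout, dropout_mode = dropout_mode,
                 cn_rate = cn_rate, amp_error = amp_error,
                 seq_error = seq_error, chrom = chrom, seed = seed),
            class = "sim_config")
}

#' Simulate the ground-truth tree and genotypes
#'
#' Draws a uniform random binary lineage tree, places each mutation on a
#' uniformly drawn edge (rejecting placements carried by fewer than two
#' cells, which would be indistinguishable from sequencing errors), applies
#' the drop-out split (half of the selected mutations to wild type, half to
#' homozygous) and assigns extra wild-type copies to a `cn_rate` fraction of
#' loci.
#'
#' @param config a [sim_config()].
#' @param tree optional fixed tree (default: random).
#' @return object of class `ground_truth` with `tree`, `genotype`
#'   (`n x m`; 0 = wt, 1 = het, 2 = hom, after drop-out), `genotype_pre`
#'   (before drop-out), `dropout_class` (`none`/`wt`/`hom` per locus),
#'   `cn_extra` (extra wild-type copies per locus).
#' @export
simulate_truth <- function(config, tree = NULL) {
  m <- config$m
  n <- config$n_mut
  if (is.null(tree)) tree <- random_tree(m)
  B <- below_matrix(tree)
  sizes <- rowSums(B)
  nn <- 2L * m - 1L
  genotype <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    repeat {
      v <- sample.int(nn, 1L)
      if (sizes[v] >= 2L) break
    }
    genotype[i, B[v, ] > 0] <- 1L
  }
  genotype_pre <- genotype
  dropout_class <- rep("none", n)
  if (config$dropout > 0) {
    if (config$dropout_mode == "locus") {
      n_each <- floor(config$dropout * n / 2)
      n_wt <- n_each +
        as.integer(config$dropout * n - 2 * n_each >= 1)
      sel <- sample.int(n, n_wt + n_each)
      wt_loci <- sel[seq_len(n_wt)]
      hom_loci <- sel[-seq_len(n_wt)]
      genotype[wt_loci, ] <- 0L
      for (i in hom_loci) genotype[i, genotype[i, ] == 1L] <- 2L
      dropout_class[wt_loci] <- "wt"
      dropout_class[hom_loci] <- "hom"
    } else {
      carriers <- which(genotype == 1L)
      dropped <- carriers[runif(length(carriers)) < config$dropout]
      to_hom <- runif(length(dropped)) < 0.5
      genotype[dropped[to_hom]] <- 2L
      genotype[dropped[!to_hom]] <- 0L
    }
  }
  cn_extra <- integer(n)
  if (config$cn_rate > 0) {
    affected <- which(runif(n) < config$cn_rate)
    cn_extra[affected] <- rgeom(length(affected), 0.5) + 1L
  }
  structure(list(tree = tree, genotype = genotype,
                 genotype_pre = genotype_pre,
                 dropout_class = dropout_class, cn_extra = cn_extra,
                 m = m, config = config),
            class = "ground_truth")
}

#' Simulate per-cell, per-position coverage
#'
#' Each cell's genome is cut into segments whose coverage follows a
#' negative binomial with the configured mean and variance; a fraction of
#' segments is forced to zero, and positions jitter around the segment mean
#' with a discretized Gaussian.
#'
#' @param config a [sim_config()].
#' @return `genome_length x m` integer matrix.
#' @export
simulate_coverage <- function(config) {
  G <- config$genome_length
  m <- config$m
  nseg <- ceiling(G / config$segment_length)
  size <- config$cov_mean^2 / (config$cov_var - config$cov_mean)
  seg_len <- diff(c(seq(0L, G - 1L, by = config$segment_length), G))
  cov <- matrix(0L, G, m)
  for (j in seq_len(m)) {
    seg_mu <- rnbinom(nseg, size = size, mu = config$cov_mean)
    seg_mu[runif(nseg) < config$zero_segment_frac] <- 0
    mu_pos <- rep(seg_mu, times = seg_len)
    cov[, j] <- pmax(0L, as.integer(round(
      rnorm(G, mean = mu_pos, sd = config$pos_cov_sd_frac * mu_pos))))
  }
  cov
}

#' Polya-urn amplification of one locus in one cell
#'
#' The urn starts with one ball per initial allele copy (heterozygous: one
#' reference and one alternative, homozygous: the alternative only, plus any
#' extra wild-type copies from copy-number events). Each of the `c` draws
#' copies a uniformly drawn ball and returns both; with probability
#' `amp_error` the copy mutates to a different base. The copies are the
#' reads; each read is finally flipped to one of the three other bases with
#' probability `seq_error`.
#'
#' @param genotype 0 (wt), 1 (het) or 2 (hom), or `"wt"`/`"het"`/`"hom"`.
#' @param c coverage (number of draws).
#' @param extra_copies extra initial wild-type copies.
#' @param config a [sim_config()] (only `amp_error`/`seq_error` are used).
#' @return integer vector of length 4: reads on the reference allele, the
#'   alternative allele, and the two remaining (error) bases.
#' @export
polya_counts <- function(genotype, c, extra_copies = 0L,
                         config = sim_config()) {
  if (is.character(genotype))
    genotype <- match(genotype, c("wt", "het", "hom")) - 1L
  urn <- switch(genotype + 1L,
                c(2L + extra_copies, 0L, 0L, 0L),
                c(1L + extra_copies, 1L, 0L, 0L),
                c(extra_copies, 1L, 0L, 0L))
  urn <- as.numeric(urn)
  reads <- integer(4L)
  if (c <= 0L) return(reads)
  for (i in seq_len(c)) {
    ball <- sample.int(4L, 1L, prob = urn)
    copy <- ball
    if (config$amp_error > 0 && runif(1L) < config$amp_error) {
      copy <- sample(setdiff(1:4, ball), 1L)
    }
    urn[copy] <- urn[copy] + 1
    reads[copy] <- reads[copy] + 1L
  }
  if (config$seq_error > 0) {
    amplified <- reads
    for (b in 1:4) {
      k <- rbinom(1L, amplified[b], config$seq_error)
      if (k > 0L) {
        flips <- rmultinom(1L, k, rep(1 / 3, 3L))[, 1L]
        reads[b] <- reads[b] - k
        reads[setdiff(1:4, b)] <- reads[setdiff(1:4, b)] + flips
      }
    }
  }
  reads
}

# Map the 4 abstract urn channels (ref, alt, err1, err2) onto nucleotides.
channel_map <- function(ref, alt) {
  others <- setdiff(NUCLEOTIDES, c(ref, alt))
  c(ref, alt, others)
}

#' Simulate a full dataset and optionally write it to disk
#'
#' Generates ground truth, coverage and read counts, and assembles them into
#' a count matrix (and, when `out_prefix` is given, a multi-sample pileup
#' file plus ground-truth TSV and newick tree). Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_prefix optional path prefix; writes `<prefix>.pileup`,
#'   `<prefix>_truth.tsv`, `<prefix>_tree.nwk` and `<prefix>_cells.txt`.
#' @return list of class `sim_dataset` with `counts` (a [count_matrix()]
#'   over all covered sites), `truth` (with `$loci` data.frame), `cells`,
#'   `files` (named paths or `NULL`), `config`.
#' @export
emit_dataset <- function(config, out_prefix = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$m
  G <- config$genome_length
  cells <- paste0("cell", seq_len(m))
  truth <- simulate_truth(config)
  cov_full <- simulate_coverage(config)
  pos_mut <- sort(sample.int(G, config$n_mut))
  ref_full <- NUCLEOTIDES[(seq_len(G) - 1L) %% 4L + 1L]
  alt_mut <- vapply(ref_full[pos_mut],
                    function(r) sample(setdiff(NUCLEOTIDES, r), 1L), "")

  keep <- which(rowSums(cov_full > 0L) > 0L)
  N <- length(keep)
  cov <- cov_full[keep, , drop = FALSE]
  pos <- keep
  ref <- ref_full[keep]
  reads <- lapply(NUCLEOTIDES, function(b) matrix(0L, N, m))
  names(reads) <- NUCLEOTIDES
  for (b in NUCLEOTIDES) {
    rows <- ref == b
    reads[[b]][rows, ] <- cov[rows, , drop = FALSE]
  }

  # wild-type fast path: MDA polymerase errors (rare; full urn re-run) and
  # per-read sequencing errors on otherwise all-reference positions
  covv <- as.vector(cov)
  k_amp <- rbinom(length(covv), covv, config$amp_error)
  amp_entries <- which(k_amp > 0L)
  k_err <- rbinom(length(covv), covv, config$seq_error)
  k_err[amp_entries] <- 0L
  err_entries <- which(k_err > 0L)
  entry_row <- function(e) (e - 1L) %% N + 1L
  entry_col <- function(e) (e - 1L) %/% N + 1L
  for (e in err_entries) {
    i <- entry_row(e)
    j <- entry_col(e)
    flips <- rmultinom(1L, k_err[e], rep(1 / 3, 3L))[, 1L]
    others <- setdiff(NUCLEOTIDES, ref[i])
    reads[[ref[i]]][i, j] <- reads[[ref[i]]][i, j] - k_err[e]
    for (t in 1:3) {
      reads[[others[t]]][i, j] <- reads[[others[t]]][i, j] + flips[t]
    }
  }
  for (e in amp_entries) {
    i <- entry_row(e)
    j <- entry_col(e)
    r4 <- polya_counts(0L, cov[i, j], 0L, config)
    map <- channel_map(ref[i], setdiff(NUCLEOTIDES, ref[i])[1L])
    for (t in 1:4) reads[[map[t]]][i, j] <- r4[t]
  }

  # mutated loci: full urn per carrier cell (wild-type cells at these loci
  # follow the same all-reference law as the fast path above)
  row_of_pos <- integer(G)
  row_of_pos[pos] <- seq_len(N)
  for (i in seq_len(config$n_mut)) {
    r <- row_of_pos[pos_mut[i]]
    if (r == 0L) next  # locus uncovered in every cell
    map <- channel_map(ref_full[pos_mut[i]], alt_mut[i])
    for (j in seq_len(m)) {
      g <- truth$genotype[i, j]
      if (g == 0L || cov[r, j] == 0L) next
      r4 <- polya_counts(g, cov[r, j], truth$cn_extra[i], config)
      for (t in 1:4) reads[[map[t]]][r, j] <- r4[t]
    }
  }

  counts <- counts_from_reads(config$chrom, pos, ref, reads, cells)
  truth$loci <- data.frame(chrom = config$chrom, pos = pos_mut,
                           ref = ref_full[pos_mut], alt = alt_mut,
                           dropout_class = truth$dropout_class,
                           cn_extra = truth$cn_extra,
                           stringsAsFactors = FALSE)
  truth$cells <- cells
  files <- NULL
  if (!is.null(out_prefix)) {
    files <- c(pileup = paste0(out_prefix, ".pileup"),
               truth = paste0(out_prefix, "_truth.tsv"),
               tree = paste0(out_prefix, "_tree.nwk"),
               cells = paste0(out_prefix, "_cells.txt"))
    write_mpileup_file(files[["pileup"]], config$chrom, pos, ref, reads)
    gt <- as.data.frame(truth$genotype)
    colnames(gt) <- cells
    write.table(cbind(truth$loci, gt), files[["truth"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(tree_to_newick(truth$tree), files[["tree"]])
    writeLines(cells, files[["cells"]])
  }
  structure(list(counts = counts, truth = truth, cells = cells,
                 files = files, config = config),
            class = "sim_dataset")
}

# Build a count_matrix from full per-base read counts with the same
# alternative-allele policy as read_mpileup (max total non-reference count,
# ties in A < C < G < T order).
counts_from_reads <- function(chrom, pos, ref, reads, cells) {
  N <- length(pos)
  coverage <- Reduce(`+`, reads)
  totals <- vapply(NUCLEOTIDES, function(b) rowSums(reads[[b]]), numeric(N))
  if (N == 1L) totals <- matrix(totals, nrow = 1L,
                                dimnames = list(NULL, NUCLEOTIDES))
  for (b in NUCLEOTIDES) totals[ref == b, b] <- -1
  alt <- NUCLEOTIDES[max.col(totals, ties.method = "first")]
  support <- matrix(0L, N, length(cells))
  for (b in NUCLEOTIDES) {
    rows <- which(alt == b)
    if (length(rows) > 0L)
      support[rows, ] <- reads[[b]][rows, , drop = FALSE]
  }
  count_matrix(
    loci = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE),
    cells = cells, support = support, coverage = coverage)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", x$config$m, "cells,", x$config$n_mut,
      "mutations,", nrow(x$counts$support), "covered sites\n")
  invisible(x)
}
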