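# Call set container and the VCF / TSV / tree writers.

#' Construct a call set
#'
#' @param loci data.frame of candidate loci (`chrom`, `pos`, `ref`, `alt`).
#' @param prob `n x m` matrix of posterior probabilities that each cell
#'   carries each mutation.
#' @param cells cell names.
#' @param threshold probability cutoff for hard genotype calls.
#' @param prob_hom optional `n x m` matrix: the share of `prob` contributed
#'   by the homozygous state (used to choose between `0/1` and `1/1`).
#' @param coverage optional `n x m` coverage matrix (zero-coverage cells are
#'   written as `./.`).
#' @return object of class `call_set`.
#' @export
call_set <- function(loci, prob, cells, threshold = 0.5, prob_hom = NULL,
                     coverage = NULL) {
  stopifnot(nrow(prob) == nrow(loci), ncol(prob) == length(cells))
  if (any(prob < -1e-9 | prob > 1 + 1e-9))
    stop("genotype probabilities must lie in [0, 1]")
  prob <- pmin(pmax(prob, 0), 1)
  structure(list(loci = loci, prob = prob, cells = cells,
                 threshold = threshold, prob_hom = prob_hom,
                 coverage = coverage),
            class = "call_set")
}

#' Hard genotype calls from a call set
#'
#' @param calls a [call_set()].
#' @return character matrix of `0/0`, `0/1`, `1/1` or `./.` calls.
#' @export
hard_calls <- function(calls) {
  gt <- matrix("0/0", nrow(calls$prob), ncol(calls$prob))
  mut <- calls$prob > calls$threshold
  gt[mut] <- "0/1"
  if (!is.null(calls$prob_hom)) {
    hom <- mut & (calls$prob_hom > calls$prob - calls$prob_hom)
    gt[hom] <- "1/1"
  }
  if (!is.null(calls$coverage)) gt[calls$coverage == 0L] <- "./."
  dimnames(gt) <- list(locus_keys(calls$loci), calls$cells)
  gt
}

#' Write calls to a VCF 4.2 file
#'
#' One record per candidate locus, sorted by chromosome and position, with
#' per-cell `GT` (hard call at the call set's threshold; `./.` where the
#' cell has no coverage) and `PP` (posterior probability of carrying the
#' mutation) FORMAT fields.
#'
#' @param calls a [call_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=sctreecall-", as.character(packageVersion("sctreecall"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=PP,Number=1,Type=Float,Description=",
           "\"Posterior probability of carrying the mutation\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$cells), collapse = "\t"))
  n <- nrow(calls$loci)
  if (n == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (any(is.na(calls$loci$pos)) || any(is.na(calls$loci$chrom)))
    stop("unsortable loci: missing chrom or pos")
  ord <- order(calls$loci$chrom, calls$loci$pos)
  gt <- hard_calls(calls)[ord, , drop = FALSE]
  pp <- calls$prob[ord, , drop = FALSE]
  loci <- calls$loci[ord, , drop = FALSE]
  fmt <- matrix(paste0(gt, ":", sprintf("%.4f", pp)), nrow = n)
  records <- paste(loci$chrom, loci$pos, ".", loci$ref, loci$alt, ".",
                   "PASS", ".", "GT:PP",
                   apply(fmt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write the posterior genotype matrix as TSV
#'
#' Rows are loci keyed `chrom:pos:ref>alt`, columns are cells.
#'
#' @param calls a [call_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(calls, path) {
  df <- data.frame(locus = locus_keys(calls$loci),
                   calls$prob, check.names = FALSE)
  colnames(df) <- c("locus", calls$cells)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cell lineage tree to newick or GraphViz
#'
#' Leaves carry cell names; internal nodes are annotated with the expected
#' number of mutations attached to them (see
#' [expected_node_attachments()]).
#'
#' @param tree a `cell_lineage_tree`.
#' @param counts_per_node optional numeric vector of length `2m - 1`.
#' @param path output file.
#' @param format `"newick"` or `"graphviz"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, counts_per_node = NULL, path,
                       format = c("newick", "graphviz")) {
  format <- match.arg(format)
  validate_tree(tree)
  labels <- if (is.null(counts_per_node)) NULL else
    sprintf("%.3f", counts_per_node)
  if (format == "newick") {
    writeLines(tree_to_newick(tree, labels), path)
  } else {
    nn <- 2L * tree$m - 1L
    node_lab <- character(nn)
    for (v in seq_len(nn)) {
      base <- if (v <= tree$m) tree$cells[tree$leaf_cell[v]] else
        paste0("node", v)
      node_lab[v] <- if (is.null(labels) || v <= tree$m) base else
        paste0(base, "\\n", labels[v])
    }
    lines <- c("digraph cell_lineage_tree {",
               sprintf("  n%d [label=\"%s\"%s];", seq_len(nn), node_lab,
                       ifelse(seq_len(nn) <= tree$m,
                              ", shape=box", "")),
               sprintf("  n%d -> n%d;", tree$parent[tree$parent != 0L],
                       which(tree$parent != 0L)),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.call_set <- function(x, ...) {
  cat("Call set:", nrow(x$loci), "loci x", length(x$cells),
      "cells (threshold", x$threshold, ")\n")
  invisible(x)
}
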