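# Count matrix container and the multi-sample pileup reader/writer.

#' Per-locus, per-cell nucleotide count matrix
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single upper-case nucleotides, `ref != alt`).
#' @param cells character vector of unique cell names (`m >= 2`).
#' @param support `N x m` integer matrix of alternative-allele counts.
#' @param coverage `N x m` integer matrix of total read depths.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(loci, cells, support, coverage) {
  m <- length(cells)
  stopifnot(m >= 2L, !anyDuplicated(cells),
            is.matrix(support), is.matrix(coverage),
            all(dim(support) == dim(coverage)),
            ncol(support) == m, nrow(support) == nrow(loci))
  if (any(support < 0L) || any(support > coverage))
    stop("require 0 <= support <= coverage")
  if (any(loci$pos < 1L)) stop("positions are 1-based; require pos >= 1")
  if (any(loci$ref == loci$alt)) stop("ref and alt must differ")
  if (!all(loci$ref %in% NUCLEOTIDES) || !all(loci$alt %in% NUCLEOTIDES))
    stop("ref and alt must be A, C, G or T")
  storage.mode(support) <- "integer"
  storage.mode(coverage) <- "integer"
  colnames(support) <- colnames(coverage) <- cells
  structure(list(loci = loci, cells = cells, support = support,
                 coverage = coverage),
            class = "count_matrix")
}

#' Locus keys `chrom:pos:ref>alt`
#' @param loci data.frame as in [count_matrix()].
#' @return character vector.
#' @export
locus_keys <- function(loci) {
  paste0(loci$chrom, ":", loci$pos, ":", loci$ref, ">", loci$alt)
}

# Remove indel runs ('+<len><seq>' / '-<len><seq>') from one pileup base
# string; the inserted/deleted sequence is not part of the site's coverage.
strip_indels <- function(x) {
  repeat {
    mt <- regexpr("[+-][0-9]+", x)
    if (mt < 0L) return(x)
    len <- as.integer(substr(x, mt + 1L, mt + attr(mt, "match.length") - 1L))
    x <- paste0(substr(x, 1L, mt - 1L),
                substring(x, mt + attr(mt, "match.length") + len))
  }
}

count_char_class <- function(x, pattern) {
  nchar(x) - nchar(gsub(pattern, "", x))
}

# Parse one cell's pileup base-string column. Returns a list of integer
# vectors: match (., ,), one per nucleotide (case-collapsed), other (* N > <).
parse_pileup_column <- function(bases, depth, lines) {
  x <- bases
  nz <- depth > 0L
  x[!nz] <- ""
  x <- gsub("\\^.", "", x)
  x <- gsub("$", "", x, fixed = TRUE)
  has_indel <- grepl("[+-]", x)
  if (any(has_indel)) x[has_indel] <- vapply(x[has_indel], strip_indels, "")
  counts <- list(match = count_char_class(x, "[.,]"))
  for (b in NUCLEOTIDES) {
    counts[[b]] <- count_char_class(x, paste0("[", b, tolower(b), "]"))
  }
  counts$other <- count_char_class(x, "[*Nn><]")
  total <- Reduce(`+`, counts)
  bad <- which(total != depth)
  if (length(bad) > 0L)
    stop("malformed pileup base string at line ", lines[bad[1L]],
         ": expanded length ", total[bad[1L]], " != depth ", depth[bad[1L]])
  counts
}

#' Read a multi-sample pileup file into a count matrix
#'
#' Parses `samtools mpileup` text output with one (coverage, bases,
#' qualities) column triple per cell. Per cell and site the coverage is the
#' reported depth; `.`/`,` match the reference, letters are mismatches
#' (strand case collapsed), `*`/`N` and reference skips count toward
#' coverage but never as support; `^` (plus mapping quality), `$` and indel
#' runs are stripped. The alternative allele of a site is the non-reference
#' nucleotide with the highest total count over all cells, and the support
#' values count that nucleotide only. Sites with zero coverage in every cell
#' are dropped. Base qualities are not used (the model consumes counts).
#'
#' @param path pileup file.
#' @param cells cell names in the order of the column triples.
#' @param min_coverage a site is retained if any cell has coverage at least
#'   this value (default 1).
#' @return a [count_matrix()].
#' @export
read_mpileup <- function(path, cells, min_coverage = 1L) {
  m <- length(cells)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = "character", fill = FALSE)
  if (ncol(dt) != 3L + 3L * m)
    stop("configuration error: pileup has ", ncol(dt),
         " columns but ", m, " cells imply ", 3L + 3L * m)
  N <- nrow(dt)
  lines <- seq_len(N)
  chrom <- dt[[1L]]
  pos <- as.integer(dt[[2L]])
  ref <- toupper(dt[[3L]])
  coverage <- matrix(0L, N, m)
  base_counts <- lapply(NUCLEOTIDES, function(b) matrix(0L, N, m))
  names(base_counts) <- NUCLEOTIDES
  for (j in seq_len(m)) {
    depth <- as.integer(dt[[3L + 3L * (j - 1L) + 1L]])
    parsed <- parse_pileup_column(dt[[3L + 3L * (j - 1L) + 2L]], depth, lines)
    coverage[, j] <- depth
    for (b in NUCLEOTIDES) base_counts[[b]][, j] <- parsed[[b]]
  }
  # choose the alternative allele: max total non-reference count, ties and
  # all-zero sites resolved in A < C < G < T order
  totals <- vapply(NUCLEOTIDES, function(b) rowSums(base_counts[[b]]),
                   numeric(N))
  if (N == 1L) totals <- matrix(totals, nrow = 1L,
                                dimnames = list(NULL, NUCLEOTIDES))
  for (b in NUCLEOTIDES) totals[ref == b, b] <- -1
  alt <- NUCLEOTIDES[max.col(totals, ties.method = "first")]
  support <- matrix(0L, N, m)
  for (b in NUCLEOTIDES) {
    rows <- which(alt == b)
    if (length(rows) > 0L)
      support[rows, ] <- base_counts[[b]][rows, , drop = FALSE]
  }
  keep <- rowSums(coverage >= min_coverage) > 0L
  count_matrix(
    loci = data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
                      alt = alt[keep], stringsAsFactors = FALSE),
    cells = cells,
    support = support[keep, , drop = FALSE],
    coverage = coverage[keep, , drop = FALSE])
}

# Write a multi-sample pileup file from full per-base read counts.
# reads: list of four N x m integer matrices named A, C, G, T.
write_mpileup_file <- function(path, chrom, pos, ref, reads) {
  N <- length(pos)
  m <- ncol(reads$A)
  cols <- vector("list", 3L + 3L * m)
  cols[[1L]] <- rep(chrom, length.out = N)
  cols[[2L]] <- pos
  cols[[3L]] <- ref
  depth_all <- Reduce(`+`, reads)
  for (j in seq_len(m)) {
    depth <- depth_all[, j]
    bases <- strrep(".", 0L)
    parts <- character(N)
    for (b in NUCLEOTIDES) {
      cnt <- reads[[b]][, j]
      is_ref <- ref == b
      chunk <- strrep(ifelse(is_ref, ".", b), cnt)
      parts <- paste0(parts, chunk)
    }
    parts[depth == 0L] <- "*"
    quals <- strrep("I", depth)
    quals[depth == 0L] <- "*"
    cols[[3L + 3L * (j - 1L) + 1L]] <- depth
    cols[[3L + 3L * (j - 1L) + 2L]] <- parts
    cols[[3L + 3L * (j - 1L) + 3L]] <- quals
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$support), "sites x", length(x$cells),
      "cells\n")
  invisible(x)
}
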