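write_pileup_lines <- function(lines) {
  path <- tempfile(fileext = ".pileup")
  writeLines(lines, path)
  path
}

test_that("pileup symbols are counted per the format specification", {
  path <- write_pileup_lines(
    "chr1\t5\tA\t4\t..,.\tIIII\t3\t.CC\tIII")
  mat <- read_mpileup(path, c("c1", "c2"))
  expect_identical(as.vector(mat$coverage), c(4L, 3L))
  expect_identical(mat$loci$alt, "C")
  expect_identical(as.vector(mat$support), c(0L, 2L))
})

test_that("caret, dollar, indels, stars and case are handled", {
  # ^I starts a read (mapping quality I), $ ends one, +2AC is an insertion
  # run, * is a deleted base counted in coverage but never as support,
  # lower case (reverse strand) collapses with upper case
  path <- write_pileup_lines(c(
    "chr1\t10\tG\t5\t^I.aA+2CC,$*\tIIIII\t4\t..t*\tIIII",
    "chr1\t11\tT\t3\t.N.\tIII\t2\t,,\tII"))
  mat <- read_mpileup(path, c("c1", "c2"))
  expect_identical(as.vector(mat$coverage), c(5L, 3L, 4L, 2L))
  expect_identical(mat$loci$alt, c("A", "A"))
  expect_identical(as.vector(mat$support), c(2L, 0L, 0L, 0L))
})

test_that("sites with zero coverage everywhere are dropped", {
  path <- write_pileup_lines(c(
    "chr1\t1\tA\t0\t*\t*\t0\t*\t*",
    "chr1\t2\tC\t2\t..\tII\t0\t*\t*"))
  mat <- read_mpileup(path, c("c1", "c2"))
  expect_identical(nrow(mat$support), 1L)
  expect_identical(mat$loci$pos, 2L)
})

test_that("malformed pileup input raises informative errors", {
  bad <- write_pileup_lines(c(
    "chr1\t1\tA\t2\t..\tII\t2\t..\tII",
    "chr1\t2\tA\t3\t..\tII\t2\t..\tII"))
  expect_error(read_mpileup(bad, c("c1", "c2")), "line 2")
  ok <- write_pileup_lines("chr1\t1\tA\t2\t..\tII\t2\t..\tII")
  expect_error(read_mpileup(ok, c("c1", "c2", "c3")), "configuration")
})

test_that("simulator output round-trips through the parser exactly", {
  cfg <- sim_config(m = 10, n_mut = 30, genome_length = 1200, seed = 99)
  prefix <- file.path(tempdir(), "roundtrip")
  ds <- emit_dataset(cfg, out_prefix = prefix)
  mat <- read_mpileup(ds$files[["pileup"]], ds$cells)
  expect_identical(mat$support, ds$counts$support)
  expect_identical(mat$coverage, ds$counts$coverage)
  expect_identical(mat$loci$alt, ds$counts$loci$alt)
  expect_identical(mat$loci$pos, ds$counts$loci$pos)
  # coverage bookkeeping: every parsed site's symbols sum to the depth
  # (the parser errors otherwise), so total support never exceeds coverage
  expect_true(all(mat$support <= mat$coverage))
})

test_that("VCF output follows the hard-call semantics and re-parses", {
  loci <- data.frame(chrom = "chr1", pos = c(7L, 3L), ref = c("A", "G"),
                     alt = c("C", "T"), stringsAsFactors = FALSE)
  prob <- matrix(c(0.99, 0.01, 0.6, 0.2), 2, 2, byrow = TRUE)
  prob_hom <- matrix(c(0.9, 0, 0.1, 0.1), 2, 2, byrow = TRUE)
  cov <- matrix(c(10L, 10L, 10L, 0L), 2, 2, byrow = TRUE)
  calls <- call_set(loci, prob, c("c1", "c2"), threshold = 0.5,
                    prob_hom = prob_hom, coverage = cov)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  txt <- readLines(path)
  recs <- txt[!startsWith(txt, "#")]
  expect_identical(length(recs), 2L)
  # records are position sorted
  expect_identical(as.integer(sapply(strsplit(recs, "\t"), `[`, 2)),
                   c(3L, 7L))
  f <- strsplit(recs, "\t")
  # locus at pos 7: c1 has p=0.99 mostly homozygous -> 1/1; c2 wild type
  expect_match(f[[2]][10], "^1/1:")
  expect_match(f[[2]][11], "^0/0:")
  # locus at pos 3: c1 heterozygous call, c2 uncovered -> ./.
  expect_match(f[[1]][10], "^0/1:")
  expect_match(f[[1]][11], "^\\./\\.:")
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_identical(nrow(v@fix), 2L)
  expect_identical(unname(vcfR::extract.gt(v)[, "c1"]), c("0/1", "1/1"))
})

test_that("empty call sets give a header-only VCF", {
  calls <- call_set(data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character()),
                    matrix(0, 0, 2), c("c1", "c2"))
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  txt <- readLines(path)
  expect_true(all(startsWith(txt, "#")))
  expect_identical(txt[1], "##fileformat=VCFv4.2")
})

test_that("genotype TSV matrix round-trips", {
  loci <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "C")
  prob <- matrix(c(0.25, 0.75, 1, 0), 2, 2)
  calls <- call_set(loci, prob, c("c1", "c2"))
  path <- tempfile(fileext = ".tsv")
  write_genotype_tsv(calls, path)
  back <- read.delim(path, check.names = FALSE)
  expect_identical(back$locus, c("chr1:1:A>C", "chr1:2:A>C"))
  expect_equal(as.matrix(back[, c("c1", "c2")]), prob,
               ignore_attr = TRUE)
})

test_that("tree writers emit valid newick and GraphViz", {
  # two-leaf tree: the only topology
  tr2 <- random_tree(2, c("c1", "c2"))
  path <- tempfile(fileext = ".nwk")
  write_tree(tr2, NULL, path, "newick")
  expect_identical(readLines(path), "(c1,c2);")
  set.seed(1)
  tr <- random_tree(4, paste0("c", 1:4))
  ann <- c(rep(0, 4), 1.5, 2, 0.5)   # per-node expected mutation counts
  write_tree(tr, ann, path, "newick")
  expect_error(write_tree(tr, ann, path, "nexus"))
  dot <- tempfile(fileext = ".dot")
  write_tree(tr, ann, dot, "graphviz")
  txt <- readLines(dot)
  expect_identical(sum(grepl("->", txt)), 6L)  # 2m - 2 edges
  skip_if_not_installed("ape")
  at <- ape::read.tree(path)
  expect_identical(ape::Ntip(at), 4L)
  # topology preserved: every rooted clade reappears in the parsed tree
  pp <- ape::prop.part(at)
  clades_ape <- lapply(pp, function(ix) sort(attr(pp, "labels")[ix]))
  B <- below_matrix(tr)
  clades_ours <- lapply(5:7, function(v) sort(tr$cells[B[v, ] > 0]))
  for (cl in clades_ours) {
    expect_true(any(vapply(clades_ape, identical, NA, y = cl)))
  }
})

test_that("node annotations written to newick conserve mutation counts", {
  set.seed(2)
  m <- 4
  S <- matrix(c(6L, 6L, 0L, 0L, 0L, 6L, 6L, 0L), 2, m, byrow = TRUE)
  C <- matrix(12L, 2, m)
  cand <- select_candidates(make_counts(S, C), model_params(),
                            candidate_config(min_mutated_cells = 1))
  tr <- random_tree(m, cand$cells)
  ann <- expected_node_attachments(tr, cand, model_params())
  expect_equal(sum(ann), 2, tolerance = 1e-9)
})
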