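Package: sctreecall
Title: Joint Single-Cell Somatic Mutation Calling and Cell Lineage Tree
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls somatic single-nucleotide variants in single-cell DNA
    sequencing data jointly with the cell lineage tree. Read counts are
    modelled with beta-binomial distributions including an allelic
    drop-out mixture and a homozygosity (loss-of-heterozygosity) state;
    candidate loci are detected from the posterior over the number of
    mutated cells using a dynamic-programming likelihood; mutation
    attachment points are marginalized over a rooted binary cell tree and
    the joint posterior over trees and model parameters is sampled with
    Markov chain Monte Carlo, yielding a posterior genotype matrix per
    cell and locus. Includes a multi-sample pileup reader and VCF/newick
    writers, a ground-truth simulator of the multiple displacement
    amplification process (negative-binomial coverage, Polya-urn
    amplification, copy-number and sequencing errors), an
    independent-cells baseline caller, and benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    ape,
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
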