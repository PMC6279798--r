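# sctreecall

Joint somatic mutation calling and cell lineage tree inference for
single-cell DNA sequencing data.

## The problem

Single-cell whole-genome/exome sequencing requires whole-genome
amplification (typically MDA), which introduces noise that defeats bulk
variant callers: highly overdispersed allele fractions, frequent allelic
drop-out (one allele fails to amplify, so a heterozygous site looks wild
type or homozygous), and uneven, gappy coverage. Callers that genotype each
cell independently cannot recover a mutation in a cell whose mutant allele
dropped out. The cells of a tumor are, however, related by a lineage tree:
a mutation arises once on a branch and is inherited by all descendant
cells. `sctreecall` exploits this by inferring the genotypes and the tree
jointly, so that well-covered carrier cells rescue the calls of their
drop-out siblings.

## The model

Nucleotide counts `s` (alternative allele) out of coverage `c` follow
beta-binomial distributions parametrized by a mean frequency `f` and an
overdispersion `omega` (`alpha = f*omega`, `beta = (1-f)*omega`):

* wild type: `P_wt(s|c) = BB(s | c, f_wt, omega_wt)` — sequencing errors
  only;
* heterozygous, with allelic drop-out probability `mu`:
  `P_a(s|c) = (mu/2) BB(s | c, f_wt, omega_wt)
            + (mu/2) BB(c-s | c, f_wt, omega_wt)
            + (1-mu) BB(s | c, 1/2 - (2/3) f_wt, omega_a)`;
* homozygous alternative: `P_h(s|c) = BB(c-s | c, f_wt, omega_wt)`.

Candidate loci are detected from the posterior over the number `K` of
mutated cells: `P(D_i|K=k)` averages the product likelihood over all
`choose(m,k)` cell subsets (computed by an O(m^2) dynamic programme) and is
combined with the prior `P(K=k) = choose(m,k)^2 / ((2k-1) choose(2m,2k))`
implied by uniform mutation placement on a uniform tree. Loci whose
posterior odds of `K >= 1` exceed 1 and that show support in at least two
cells are retained.

For the tree likelihood, each mutation's attachment edge is marginalized:
`S_a` averages the attachment products over all `2m-1` edges (heterozygous
state), `S_h` over the `m-1` internal edges (homozygous state), and the
per-locus contribution is `(1-nu) S_a + nu S_h` with homozygosity
coefficient `nu`. All attachment products per locus are computed in one
depth-first pass, O(m) per locus; non-candidate loci enter through the
wild-type model binned by unique `(s, c)` pairs. A Metropolis–Hastings
sampler over `(T, theta)` — prune-and-reattach and leaf-swap tree moves
plus adaptive Gaussian walks on `theta = (f_wt, omega_wt, omega_a, mu, nu)`
— yields the posterior genotype matrix: the probability that cell `j`
carries mutation `i`, averaged over the chain.

The package also contains the ground-truth simulator used for validation
(uniform random lineage tree, negative-binomial segment coverage with
forced zero segments, Pólya-urn MDA amplification with polymerase and
sequencing errors, copy-number events, multi-sample pileup output), an
independent-cells baseline caller, and precision/recall/F1 benchmarking.

## Worked example

```r
library(sctreecall)

cfg <- sim_config(m = 10, n_mut = 50, genome_length = 5000,
                  dropout = 0.2, seed = 7)
ds  <- emit_dataset(cfg)
res <- call_variants(ds$counts, mcmc = mcmc_config(iterations = 4000,
                                                   seed = 7))
res$chain
#> MCMC result: 4000 iterations, 300 recorded samples
#>   best log score: -5918.923
#>   posterior parameter means:
#>     f_wt omega_wt  omega_a       mu       nu
#>   0.0011  83.9239   2.5571   0.0212   0.1504

score_calls(res$calls, ds$truth, ds$counts)
#>    tp fp fn precision    recall        f1
#> 1 147  0 12         1 0.9245283 0.9607843

score_calls(baseline_caller(ds$counts), ds$truth, ds$counts)
#>    tp fp fn precision    recall        f1
#> 1 142  1 17  0.993007 0.8930818 0.9403974
```

The simulator hid 50 mutations among 10 cells with 20% drop-out. The joint
caller genotypes 147 of the 159 covered (locus, cell) carrier pairs
correctly with no false positives (F1 0.96); the independent-cells baseline
misses five more carriers (F1 0.94) because it cannot use the lineage to
rescue drop-outs. The learned error frequency (`f_wt ~ 0.001`) matches the
simulated sequencing error rate, and `nu ~ 0.15` reflects the loci whose
wild-type allele was lost. `res$calls` holds the posterior genotype matrix;
`write_vcf()`, `write_genotype_tsv()` and `write_tree()` export calls and
the inferred tree.

A command-line interface wrapping the same functions is installed with the
package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sctreecall", package = "sctreecall"))')
Rscript "$CLI" simulate --out-prefix sim --cells 10 --mutations 50 --seed 7
Rscript "$CLI" call --in sim.pileup --cellNames sim_cells.txt \
        --out-prefix run --seed 7
```

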