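---
title: "Methods: joint single-cell mutation calling and lineage inference"
author: "sctreecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint single-cell mutation calling and lineage inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by `sctreecall`,
the choices made where the design was genuinely open, the simulator used
for validation, and the numerical details a user or maintainer should know.

## Count model

All inference operates on per-locus, per-cell pairs `(s, c)`: the number of
reads supporting the alternative nucleotide and the total coverage. Whole-
genome amplification (MDA) makes allele fractions far more variable than
binomial sampling, so every genotype state is modelled with a beta-binomial
in the mean/overdispersion parametrization `f = alpha/(alpha+beta)`,
`omega = alpha+beta`:

* **Wild type** — `BB(s | c, f_wt, omega_wt)`. `f_wt` is the expected
  frequency of the alternative base arising from sequencing error (unitless
  frequency, default 0.001); `omega_wt` is large (default 100) because
  errors are close to independent; as `omega_wt` grows the distribution
  approaches the binomial.
* **Heterozygous with drop-out** — a three-component mixture with drop-out
  probability `mu` (default 0.1): with probability `mu/2` the mutant allele
  failed to amplify (counts look wild type), with `mu/2` the wild-type
  allele failed (counts reflected, `c - s`), otherwise a genuine
  heterozygous signal `BB(s | c, 1/2 - (2/3) f_wt, omega_a)`. The mean is
  shifted below 1/2 because sequencing errors move reads to the two other
  bases. `omega_a` is small (default 2) — a handful of initial genomic
  fragments dominate the amplification — and is learned from data.
* **Homozygous alternative** — `BB(c - s | c, f_wt, omega_wt)`: the
  reference count plays the role of the error count.

At `mu = 0` the heterozygous state is exactly the pure beta-binomial; this
identity is asserted bitwise in the tests. All probability computations are
carried out in log space via `lchoose`/`lbeta`, so coverages up to 1e6 do
not overflow, and mixtures are combined with log-sum-exp.

## Candidate loci

With `m` cells, the likelihood that exactly `k` carry a mutation averages
the product `prod P_a * prod P_wt` over all `choose(m, k)` subsets. The
package computes all `k = 0..m` values simultaneously with the standard
subset-sum (elementary symmetric polynomial) dynamic programme in O(m^2)
log-space operations; the tests verify exact agreement with brute-force
subset enumeration up to `m = 8`.

The prior on `k` follows from placing a mutation uniformly on the `2m - 1`
edges of a uniform random rooted binary tree:
`P(K=k) = choose(m,k)^2 / ((2k-1) choose(2m,2k))`, verified exactly (in
integer arithmetic) against exhaustive enumeration of all labelled
topologies up to `m = 5`.

A locus is flagged when the posterior odds of `K >= 1` against `K = 0`
exceed 1 (i.e. `P(K = 0 | D) < 1/2`), with per-locus mutation prior
`lambda = 1e-4`; the marginal `P(D)` cancels in the odds and is never
computed. These two constants are design choices: no numeric threshold is
canonical, and the flag is provably monotone in `lambda` (tested), so a
user can trade sensitivity against the downstream tree size. Flagged loci
must additionally show alternative support in at least
`min_mutated_cells = 2` distinct cells, because a single-cell signal is
indistinguishable from sequencing error. Candidate detection runs before
parameter learning, with the default parameters; the heterozygous state
already includes the drop-out mixture at its default `mu`. Only the
wild-type and heterozygous states enter the `K`-posterior; loss of
heterozygosity is handled later by the zygosity mixture of the tree score.

## Tree likelihood

Cells are leaves of a rooted binary lineage tree `T`; a mutation attaches
to the edge above a node and is carried by all leaves below. For each
candidate locus the attachment is marginalized under a uniform prior over
the `2m - 1` edges:

```
S_a(D_i | T) = 1/(2m-1) * sum_over_nodes_v prod_j [ P_a if j below v else P_wt ]
S_h(D_i | T) = 1/(m-1)  * sum_over_internal_v prod_j [ P_h if j below v else P_wt ]
```

and the per-locus factor is `(1 - nu) S_a + nu S_h` with homozygosity
coefficient `nu` (default 0.1) — a controlled relaxation of the
infinite-sites assumption that captures loss of heterozygosity not caused
by drop-out. Homozygous attachments are restricted to internal nodes
(including the root, which the package counts among the `m - 1` internal
nodes): a homozygous signal in a single cell is better explained as a
drop-out event. The normalizing constants `1/(2m-1)` and `1/(m-1)` are
kept so the `nu`-mixture weighs two normalized averages.

All `2m - 1` attachment products for a locus are computed in one
depth-first pass that combines children's partial products, O(m) per locus
and state; the tests compare every node value against direct recomputation
from leaf sets up to `m = 10`.

Non-candidate loci contribute only through the wild-type model. Their
`(s, c)` observations are binned by unique pair once, so re-evaluating the
background term after a parameter move is linear in the number of distinct
pairs — equal in value to the naive sum over all N x m observations
(tested to 1e-8 relative), and at least as fine-grained as binning by
coverage alone.

## MCMC

The sampler targets `P(T, theta | D)` with uniform priors over the
parameter bounds, mixing three move families (45% prune-and-reattach, 10%
leaf swap, 45% parameter walks split evenly over the five parameters —
the schedule is a design choice):

* **Prune and reattach**: a uniformly drawn non-root node is detached with
  its subtree and re-inserted above a uniformly drawn node outside it.
  Forward and backward choice counts coincide, so the proposal ratio is 1;
  re-attachment at the original position is a legal self-move. The move is
  irreducible on topologies (verified exhaustively for m <= 4).
* **Leaf swap**: two distinct leaves exchange their cell labels
  (symmetric).
* **Parameter walks**: Gaussian steps, one parameter at a time.
  `omega_wt` and `omega_a` are scale parameters and walk on the log scale;
  the package treats their prior as uniform in `log omega` over the
  bounds, so the log-scale walk needs no Jacobian correction. `f_wt`,
  `mu`, `nu` walk on the natural scale. Proposals outside the bounds
  (`f_wt` in (1e-6, 0.49), `omega_wt` in (1, 1e9), `omega_a` in
  (0.1, 1e4), `mu`, `nu` in [0, 0.99]) are rejected; the bounds keep the
  beta-binomial well defined and are wide enough to be effectively
  uninformative.

Acceptance follows the standard Metropolis–Hastings ratio. During burn-in
(default 25%) each walk's step size is adapted every 50 proposals by the
multiplicative rule `sd <- sd * exp(rate - 0.5)`, bounded in
`[1e-6, 1e3]`, targeting 50% acceptance; adaptation freezes after burn-in
so the post-burn-in kernel is a fixed Markov chain. Any rule tracking the
target and frozen after burn-in would do; this one is chosen for its
simplicity. A toy-target calibration test confirms the adapted walk
reaches 50% +/- 10%.

The default chain length is `10 * m^2 * log(m)` iterations, following the
heuristic that mixing time grows as `m^2 log m`; thinning is 10. At each
recorded sample the posterior attachment weights of every locus are summed
over the nodes above each cell — mixing the heterozygous component
(weight `(1-nu) S_a`-normalized, all nodes) and the homozygous component
(`nu S_h`-normalized, internal nodes) — and these per-cell probabilities
are averaged over the chain into the posterior genotype matrix. The
cached score is compared against a from-scratch recomputation every 5000
iterations (a hard error on drift). Convergence is checked in practice by
the correlation between the genotype matrices of two independent chains;
the tests require r > 0.99 at 25 cells.

Rather than conditionally sampling one attachment per locus per iteration,
the full attachment weights are accumulated; this reduces Monte-Carlo
variance at no extra cost since the weights are already available from the
marginalization.

## What the model can and cannot rescue

A useful closed-form property: for a cell with `s = 0` and coverage
`c > 0` at a candidate locus, the per-locus genotype posterior is bounded
above by `r / (1 + r)` with `r = P_a(0|c) / P_wt(0|c)`, and

```
P_a(0|c) = (mu/2) P_wt(0|c) + (mu/2) P(c|c, f_wt, omega_wt)
         + (1-mu) BB(0 | c, ~1/2, omega_a)
```

is strictly smaller than `P_wt(0|c)` for every `mu <= 0.99` (the second
term is negligible and the third is roughly `1/(c+1)`). A well-covered
cell with zero support is therefore never pushed above probability 1/2,
no matter how strongly its clade carries the mutation — the data
legitimately outvote the tree. The tree's rescue operates on cells with
*missing* data: at `c = 0` all state likelihoods are 1, the attachment
weights are decided by the other cells, and a cell inside the carrying
clade ends just above 1/2 (the root attachment tips the balance). The
drop-out recovery test constructs exactly this situation and verifies the
sampled posterior against an exhaustive enumeration over all 15
four-leaf topologies. The independent-cells baseline, which has no
information at `c = 0`, emits a no-call (probability 0) there.

## Simulator

The generator reproduces the tumor-evolution benchmark design: a uniform
random lineage tree over `m` cells; 100 mutations placed uniformly on
edges, redrawn until each is carried by at least two cells; a 1 Mb
reference (repeating ACGT — content is irrelevant to a count model) cut
into ~1 kb segments per cell; segment coverage negative-binomial with mean
25 and variance 50, 10% of segments forced to zero; per-position coverage
jittered by a discretized Gaussian with sd 10% of the segment mean.
Nucleotides are drawn from a Pólya urn initialized with one ball per
allele copy (heterozygous sites would give uniform allele fractions
without errors); each draw copies a ball, mutates the copy with
probability 5e-7 (MDA polymerase error), returns both, and keeps the copy
as a read; reads are finally flipped to one of the three other bases with
probability 1e-3 (sequencing error). Copy-number events give a
`cn_rate` fraction of mutated loci `x >= 1` extra wild-type initial
copies with `P(x) = 1/2^x` (taken as already normalized over `x >= 1`;
all copy-number changes precede the mutations, which lower-bounds the
achievable performance since extra copies only depress the variant allele
fraction). Sequencing-error flips choose uniformly among the three other
bases. Output is a multi-sample pileup, a truth table and the true tree;
identical seeds give byte-identical files, and parsing the pileup
reproduces the simulator's internal count matrix exactly (tested).

Wild-type positions take a fast path — all-reference reads plus binomial
sequencing errors, with a full urn re-run whenever a polymerase error
event is drawn — which is distributionally identical to running the urn at
every position, since an all-reference urn only deviates from pure
reference reads when a polymerase error occurs.

**Drop-out granularity.** A fraction `dropout` of mutations is affected;
half become wild type (mutant allele lost), half homozygous (wild-type
allele lost), with an odd leftover going to the wild-type side. Two modes
exist because the phenomenon is ambiguous at the locus level:

* `"locus"` (default, the benchmark design): the conversion applies to
  every carrier cell — clonal loss. Under this mode a wild-type-converted
  mutation vanishes entirely and homozygous conversions are absorbed by
  `nu`, so the model's `mu` is only weakly informed.
* `"cell"`: each carrier cell drops out independently with probability
  `dropout` — exactly the generative semantics of the per-cell drop-out
  mixture. This is the mode under which "recovering `mu`" is well defined,
  and the parameter-recovery tests use it; the posterior mean of `mu`
  lands within 0.07 of the truth at 25 cells and 100 mutations.

**What the simulator does not emulate**: alignment and mapping artifacts,
doublets, germline variation (every non-mutated site is homozygous
reference), chimeric MDA reads, GC-dependent coverage, and dependence
between homologous chromosomes during amplification (a config hook exists
but only the independent-chromosome urn is implemented). Passing
benchmarks on these simulations therefore demonstrates correctness of the
inference under the stated noise model, not robustness to artifacts the
model does not represent.

## Numerical and interface choices

* **Alternative allele per site** (pileup input): the non-reference base
  with the highest total count summed over cells, ties broken in
  A < C < G < T order — consistent with the biallelic model, which tracks
  a single dominant somatic allele. Multi-allelic sites are not modelled.
* Positions are 1-based throughout (pileup/VCF convention). Base-quality
  strings are parsed but unused; strand case is collapsed; `*`, `N` and
  reference skips count toward coverage but never as support; sites with
  zero coverage in every cell are dropped.
* Degenerate inputs: `m = 2` trees have a single internal node (the
  root); a candidate set with zero loci leaves the tree uninformed (the
  pipeline warns and the score reduces to the background term);
  zero-coverage cells have likelihood 1 in every state and are genotyped
  by the lineage alone, and are reported as `./.` in VCF output.
* Genotype hard calls threshold the posterior at 0.5; `0/1` vs `1/1` is
  decided by the larger of the heterozygous and homozygous posterior
  shares. Probabilities are always emitted alongside.
* The benchmark driver runs desk-scale problem sizes chosen once for this
  package: 25 cells, 100 mutations on a 20 kb genome, 10 replicates per
  condition, 5000-iteration chains (convergence at this size was verified
  with the two-chain correlation diagnostic, r > 0.99). The simulator's
  own defaults keep the full 1 Mb genome.

## Known limitations

* Binary trees only; no multifurcations and no mutation-tree (genotype
  lattice) representation.
* No germline/somatic separation against a matched bulk sample; the
  caller assumes somatic-only input or downstream filtering.
* Copy-number events are simulated but not modelled in inference beyond
  what `omega_a` and `nu` absorb.
* The candidate stage uses fixed default parameters; loci near the
  decision boundary can enter or leave the candidate set if the defaults
  are changed (the flag is monotone in `lambda`, which bounds the effect).
* Indels are not called; the pileup parser skips indel runs entirely.
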