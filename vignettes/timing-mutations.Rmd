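---
title: "Timing point mutations in reprogrammed clones with burstline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing point mutations in reprogrammed clones with burstline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstline)
```

## The problem

Reprogrammed pluripotent stem cells — iPSCs and ntESCs — carry hundreds of
point mutations that were not present in the somatic cell they came from.
Two observations suggest these mutations are not ordinary culture artefacts:
their variant allele frequencies (VAFs) within a clone are strongly
structured, and their base-substitution spectrum is transversion-rich, with
a T>G-at-NTT pattern matching a known cancer mutational signature
(Signature 17). burstline packages the inference machinery needed to turn
read counts into a statement about *when* each mutation arose during the
clonal expansion, and whether the mutational process was a transient burst
confined to the first few cell divisions or a continuous background.

## The carrier model

The clone is modelled as a complete binary division tree: one founder cell,
`G` synchronous divisions, `2^G` final cells. A mutation acquired in one
cell at generation `k` is inherited by that cell's whole subtree, so it is
carried by a fraction `2^-k` of final cells. On an autosome it affects one
of two alleles, giving the central identity of the method:

> true VAF of a heterozygous mutation from generation `k` = `2^-(k+1)`.

A founder (`k = 0`) variant therefore sits at exactly 50% VAF — present in
every cell, on one allele — while a generation-1 mutation sits at 25%, and
a mutation from generation 10 at about 0.05%, far below what conventional
~40x WGS can call. Inverting the identity gives the origin-generation
estimator used throughout: `k_hat = round(log2(1 / (2 * vaf)))`, clamped at
zero. Hemizygous sites (male sex chromosome) have a single allele and VAF
`2^-k`.

This demographic model is deliberately minimal: no cell death, no selection,
no asynchrony. Those forces perturb carrier fractions away from exact powers
of two in real colonies; the model keeps the mapping between VAF and
generation invertible, which is what the timing analysis needs, and the
50% / 25% / sub-1% structure it predicts is exactly the structure deep
amplicon data show.

Mutations are indexed by `(generation, lineage index)` rather than by an
explicit tree of cells, so simulating a `G = 20` clone costs no more than a
small one. For `G <= 12` the package retains a fully explicit recursive tree
walk (`enumerate_leaf_mutations()`) used as an oracle in the tests: carrier
sets from index arithmetic are checked to be *identical* to those from leaf
enumeration, not merely close.

## The simulator and what it emulates

`sim_config()` fixes the study conditions; `simulate_clone()` draws from
them. Per generation `k` the number of new mutations is
`Poisson(2^k * mu_k)` with `mu_k = mu_burst` inside the burst window and
`mu_background` outside. The defaults describe one reprogrammed clone:

* `burst_window = c(1, 4)`: the transient G1/S-checkpoint-deficient phase
  spans a handful of early divisions. Days 2–3 after induction do not map
  to a documented division count, so the window is a modelling choice; four
  divisions keeps every burst mutation above 3% VAF, where deep amplicon
  sequencing can still see it.
* `mu_burst = 10`, `mu_background = 0.1`: the expected burst load is
  `sum(2^(1:4)) * 10 = 300` mutations, matching the several-hundred scale of
  reprogramming-associated SNVs per clone; the 100-fold rate ratio makes the
  burst an order-of-magnitude phenomenon rather than a statistical subtlety.
* `n_preexisting = 50` heterozygous founder variants model the somatic
  cell's own mutation load (all at exactly 50% VAF).
* `burst_signature = sig17_like()` concentrates burst mutations on T>G at
  NTT contexts; `background_signature = background_transition_signature()`
  spreads background mutations over C>T/T>C transitions. Both are synthetic
  profiles built in code, not catalogue values.
* Read model: totals `Poisson(depth)` at ~40x (WGS) or ~1e5 reads
  (amplicon); alt reads `Binomial(total, v(1-e) + (1-v)e/3)` with
  `seq_error = 3e-4` spread evenly over the three non-reference bases. With
  these values the 0.1% VAF detection floor (`vaf_floor = 0.001`) is
  binding: a true 0.05% variant is empirically indistinguishable from the
  error background.
* Sites are drawn without replacement from a 1 Mb virtual contig
  (infinite-sites); configurations whose expected load exceeds the contig
  are rejected. Coordinates are 1-based and fully closed, as in VCF.

`derive_subline()` picks one final cell and expands it for 14 generations
(a ~2-week single-cell expansion), carrying every inherited mutation at a
clonal 50% and accruing fresh background privately. What the generator does
*not* emulate: mapping artefacts, copy-number changes, contamination between
wells, or selection during colony growth. Tests passing on this generator
show the inference machinery is correct under the stated model, not that
real libraries are free of those artefacts.

## Filter chains

`filter_snvs()` and `filter_indels()` reproduce the post-call exclusion
chains applied to caller output: depth >= 20; exclusion of candidates with
>= 2 alt reads in the parental somatic cells, of known germline sites, of
calls shared among sister clones, and of repeat-flanked sites; then the VAF
window — 35–65% autosomal / >= 75% hemizygous for SNVs, with INDELs at
coverage >= 20, alt count >= 10, 30–70% / >= 70%. The stages are pure
conjunctions, so the kept set is order-independent; the per-variant trace
records each stage in a fixed order (exclusions before the window). A
variant with a missing required field receives an `error` verdict rather
than being silently dropped. Upstream caller internals (base quality,
alignment windows) are treated as already applied and are out of scope.

The window is also why conventional WGS misses young-but-not-founder
mutations: at depth ~40 a true 25% VAF variant reaches the 35% bound only
with the small binomial-tail probability, which the tests compute exactly
and compare against simulation.

## Sublines, Venn partition, and the developmental tree

Sequencing sublines grown from single cells reveals every mutation the
founding cell carried at a clonal ~50% VAF, regardless of how rare it was in
the parent colony. `venn_decompose()` maps each SNV to its exact carrier
subset of sublines. Because each SNV is a binary character whose ancestral
state (absent) is known, a conflict-free panel admits a rooted perfect
phylogeny: carrier sets must be pairwise nested or disjoint.
`build_tree()` checks exactly that, attaches each SNV to the edge above the
clade of its carriers, and emits Newick (readable by `ape`).

Real panels contain call errors, so conflicts are resolved greedily: the
SNV in the largest number of pairwise conflicts is removed first, with ties
broken by lower parent-clone VAF (the noisier call is sacrificed), until
the remainder is laminar. Removed SNVs are flagged `incompatible`, never
silently dropped. This greedy rule is a design choice — the minimal set of
characters to delete is NP-hard in general, and for the low conflict rates
of subline panels greedy-by-degree recovers the planted tree in the tests'
flipped-call scenarios.

`edge_timeline()` summarises each edge: SNV count, mean parent-clone VAF,
ts/tv counts, and the fraction a conventional WGS filter would have kept —
reproducing the qualitative pattern that shared (deep) edges are visible to
conventional WGS while subline-specific edges are not.

## Timing groups and the burst test

`estimate_vaf()` turns amplicon counts into point estimates with Wilson 95%
intervals and censors estimates below the floor. `classify_group()` splits
non-censored SNVs into group I (reprogramming-associated, higher VAF,
transversion-rich) and group II (spontaneous culture mutations, below ~1%,
transition-rich). The default split is contiguous at 1%; a text-faithful
mode with group I >= 5% and an explicit intermediate band is available,
because the two boundaries in circulation (~5–50% versus 1–25%) do not
agree. SNVs in the 35–65% window are flagged `clone_wide`: present in all
cells, but not demarcable as de novo versus pre-existing from VAF alone —
they stay in group I.

`burst_test()` formalises "transient, not continuous". SNVs are binned by
`k_hat` and two Poisson models are fit to the per-generation counts:

* continuous: `n_k ~ Poisson(mu * 2^k)` — one rate, exponentially growing
  counts because the population doubles;
* burst: one rate inside a window `[a, b]`, another outside, every window
  of width <= `w_max` scanned.

Two numerical guards matter. First, bins are only fit up to
`detectable_k_max(vaf_floor)`: near the floor, censoring depresses counts
below the `2^k` expectation, which a naive fit misreads as a rate change.
The bound keeps only generations whose true VAF is at least a factor 2
above the floor (k <= 7 at the 0.1% floor). Second, the burst model is
charged four parameters — two rates plus the two estimated window
endpoints, the usual changepoint accounting — so scanning many windows does
not buy free likelihood. The verdict is `burst` when
`AIC(continuous) - AIC(burst) > 4`, the conventional threshold for
considerable support; fewer than 10 usable calls yield `inconclusive`
rather than an error. With the full range as a window the burst model nests
the continuous one, and on model-consistent data the two likelihoods agree
to numerical precision — both properties are asserted in the tests.

Under the default study conditions (burst in generations 1–4 at 100x the
background rate, 1e5-read amplicons) the test recovers a window overlapping
[1, 4] in effectively all of 100 simulated clones, and calls fewer than 10%
of 100 continuous clones `burst`.

## Signature profiling by stage

`classify_96()` maps every substitution-plus-context onto the 96
pyrimidine-centred classes (purine-strand calls are reverse-complemented;
all 192 raw cases collapse 2-to-1, asserted exhaustively).
`signature_profile()`, `cosine_similarity()` and `tstv()` provide the
standard summaries. `stage_profiles()` partitions SNVs along the
reprogramming timeline — stage 1: pre-existing (detected in the parental
somatic cells, threshold 5% VAF); stage 2: de novo, parent-clone VAF in
1–25%; stage 3: prolonged culture, VAF < 1%; plus the separate clone-wide
~50% set — and reports each stage's cosine against a reference signature
set. On simulated clones the stage-2 profile's top match is the
Signature-17-like burst reference and stage 3's is the transition
background, reproducing the stage-restricted signature pattern. Whether a
visual signature judgement corresponds to any particular cosine value is
not something the package can anchor; it reports the metric and the top
match, nothing more.

No signature decomposition (NNLS/NMF) is performed: the scientific claim
is about *which* stage shows the pattern, not about exposure fractions.

## Problem sizes and reproducibility

The test suite and the acceptance script run the oracle comparisons on 50
random clones at `G <= 12` (where leaf enumeration is exact), the
parameter-recovery study on 100 burst plus 100 continuous clones at the
default `G = 13`, signature recovery on 8 pooled clones (>= 500 SNVs per
stage, as one pools lines when single clones are too small), and censoring
on 1000 replicate deep-amplicon draws. Every stochastic step flows from a
single seed; `run_pipeline()` hashes its configuration and reproduces
byte-identical outputs under the same seed.

## Known limitations

* The binary-tree carrier model ignores death and selection; `k_hat` is a
  model-based estimate, biased where those forces act.
* Group boundaries are conventions over a continuous VAF axis; SNVs near
  1% (or in the 1–5% band of the text-faithful mode) are genuinely
  ambiguous.
* The perfect-phylogeny conflict resolution is greedy, not optimal.
* The read model has a single uniform error rate; real amplicon error is
  context-dependent, so the effective detection floor varies by site.
* INDEL handling covers the filter chain only; the simulator draws SNVs.
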