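# burstline

Timing point-mutation acquisition during the clonal expansion of
reprogrammed pluripotent stem cells (iPSCs, ntESCs).

Reprogrammed clones carry hundreds of point mutations absent from the
somatic cells they were derived from. Their variant allele frequencies
(VAFs) are structured by clonal descent: a clone grown from one founder
through `G` binary divisions carries a mutation acquired at generation `k`
in a fraction `2^-k` of its cells, so a heterozygous autosomal mutation has

```
true VAF = 2^-(k+1)
```

— exactly 50% for a founder variant, 25% for generation 1, and below the
reach of conventional ~40x WGS within a few more divisions. Inverting this
identity (`k_hat = round(log2(1/(2*vaf)))`) turns ultra-deep amplicon VAFs
into origin-generation estimates, and the per-generation counts `n_k` can
then discriminate a **transient burst** of mutagenesis confined to the
first few divisions (one elevated Poisson rate inside a window, compared by
AIC against a single-rate model with `n_k ~ Poisson(mu * 2^k)`) from
continuous background mutagenesis.

The package provides, as composable functions:

* **`simulate_clone()` / `sample_reads()` / `derive_subline()`** — a
  ground-truthed clonal-expansion simulator with a transient early
  hypermutation window, signature-driven mutation classes, and a WGS /
  deep-amplicon read model with a 0.1% VAF detection floor;
* **`filter_snvs()` / `filter_indels()`** — the post-call exclusion chains
  (depth >= 20; parental sharing; known sites; sister clones; repeat
  flanks; VAF 35–65% autosomal / >= 75% hemizygous for SNVs, count >= 10
  and 30–70% for INDELs) with a full per-variant decision trace;
* **`venn_decompose()` / `build_tree()` / `edge_timeline()`** — subline
  panel decomposition and rooted perfect-phylogeny reconstruction of the
  developmental tree, with SNVs assigned to edges;
* **`estimate_vaf()` / `classify_group()` / `burst_test()`** — amplicon
  VAF estimation with Wilson intervals and floor censoring, group I / II
  classification, and the burst-versus-continuous likelihood test;
* **`classify_96()` / `signature_profile()` / `stage_profiles()`** —
  96-class trinucleotide signature profiling, tv/ts summaries, and
  stage-wise decomposition with cosine comparison to reference signatures;
* **`run_pipeline()`** — the end-to-end driver with a JSON run manifest,
  plus a thin CLI at `inst/cli/burstline`.

## Worked example

```r
library(burstline)
set.seed(42)

cfg  <- sim_config(seed = 42)        # G = 13, burst in generations 1-4
mset <- simulate_clone(cfg)
mset
#> <lineage_mutation_set> 2043 mutations, G = 13, burst window [1, 4]
#>   pre-existing: 50, burst: 309, background: 1684

# ultra-deep amplicon VAFs in the parent clone; drop pre-existing variants
amp <- sample_reads(mset, cfg, "amplicon", "parent")
som <- estimate_vaf(sample_reads(mset, cfg, "amplicon", "parental_somatic"))
rep <- timeline_report(cbind(amp, ref = mset$ref, alt = mset$alt,
                             context = mset$context)[som$vaf < 0.05, ])

table(rep$calls$group)
#> censored        I       II
#>     1583      315       95
rep$burst
#> <burst_test> burst | window [1, 4], dAIC = 1125.95, n = 338
```

The clone's mutation history is read straight off these numbers: 315
group I SNVs (VAF >= 1%, the reprogramming-associated class) against 95
group II SNVs (<1%, culture background), with most background mutations
censored below the 0.1% amplicon floor; the likelihood test identifies the
hypermutation window as generations 1–4 with overwhelming support
(delta-AIC ~ 1126). The substitution spectra split the same way:

```r
tstv(rep$calls[rep$calls$group == "I",  ])$tv_ts_ratio   # 25.25  (transversion-rich)
tstv(rep$calls[rep$calls$group == "II", ])$tv_ts_ratio   # 0.0795 (transition-rich)
```

`run_pipeline(sim_config(), "out/", seed = 1)` chains the same stages —
plus subline derivation, filtering, tree reconstruction and stage-wise
signature profiles — and writes VCF/TSV/Newick/JSON outputs under `out/`
with a manifest.

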