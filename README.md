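# gapcoloc

Gap-aware null models for statistical testing of genomic colocalization.

## The problem

Reference genome assemblies contain gaps — runs of unknown bases (Ns)
where sequencing reads cannot map. Every sequencing-derived track (ChIP-seq
peaks, DNase hypersensitive sites, ...) therefore avoids these regions, and
so does every other track on the same assembly. Monte Carlo permutation
tests of colocalization that resample one track uniformly over the *whole*
genome ignore this shared constraint: resampled tracks spend bases inside
gaps where real tracks have none, the null overlap distribution shifts
down, and truly unrelated track pairs come out "significant". Gaps cover
7.6% of hg19 and about 5% of hg38 — small enough to overlook, large
enough to matter.

`gapcoloc` is for analysts and method developers who want to measure and
avoid this bias. It provides:

* exact BED-style interval algebra (`read_bed`, `complement`,
  `base_overlap`, UCSC gap-table support);
* a constrained uniform shuffler that preserves element count and the
  exact segment-length multiset while avoiding a gap set
  (`shuffle_track`, `sample_uniform_placement`);
* the Monte Carlo colocalization test under both null models
  (`mc_coloc_test`, `null_model_spec`, `bh_fdr`);
* gap-overlap profiling of track collections (`profile_gap_overlap`,
  `overlap_vs_segment_length`);
* a synthetic-data study pipeline that generates truly-null gap-avoiding
  track pairs and quantifies false rejections under each null model
  (`simulate_genome`, `simulate_null_pair`, `run_study`, `study_preset`).

## The test

For tracks `A` (query) and `B` (reference) the statistic is the base
overlap `O = |A ∩ B|` in bp. The query is resampled `m` times, uniformly
and without intra-track overlap, over either the full genome
(`whole_genome`) or the genome minus the gap set (`exclude_gaps`), keeping
its element count and length multiset. The one-sided enrichment p-value is
the add-one Monte Carlo estimator

    p = (1 + #{ O_null >= O_obs }) / (1 + m).

For independent tracks with `b_A`, `b_B` covered bases on an accessible
space of `G_acc` bases, `E[O] = b_A * b_B / G_acc`; a gap-ignorant null
uses the genome size `G` instead, so its expected observed/null ratio is
`G / G_acc = 1 / (1 - gap_fraction)` — bias that more data turns into
arbitrarily small p-values.

## Worked example

A desk-scale version of the study (`analysis/03_null_model_contrast.R`):
100 truly-null pairs of gap-avoiding tracks (10,000 elements × 2,114 bp
each) on a 0.6 Gbp genome with 7.6% of bases in gaps, each pair tested
under both null models with m = 99:

```r
library(gapcoloc)
cfg <- study_preset("hg19-histone-like", scale = 0.2,
                    modes = c("whole_genome", "exclude_gaps"),
                    mc_samples = 99, seed = 301)
res <- run_study(cfg)
print(res)
#> <study_result> 100 truly-null pair(s), m = 99, FDR alpha = 0.05
#>   genome 6e+08 bp, gaps 4.56e+07 bp (7.60%)
#>   whole_genome : 44/100 rejected; KS 0.700 (p = 0); mean ratio 1.083
#>   exclude_gaps : 0/100 rejected; KS 0.060 (p = 0.864); mean ratio 1.000
```

Reading: every pair is independent by construction (H0 true), yet the
gap-ignorant null declares 44 of 100 pairs significant after BH-FDR
correction, with the observed statistic on average 1.083× its null mean —
matching the analytic `1/(1 - 0.076) = 1.082`. The gap-aware null on the
same pairs rejects nothing and its p-values are uniform (KS p = 0.86).
The false-rejection count rises with track size
(`analysis/04_bias_characterization.R`): at 50,000 elements per track —
the full-scale study conditions — nearly every truly-null pair is
rejected.

A single pair is tested directly with:

```r
sim  <- simulate_genome(genome_sim_spec(22, 3e7, 0.076, seed = 1))
pair <- simulate_null_pair(track_sim_spec(5000, list(law = "fixed", length = 2114)),
                           track_sim_spec(5000, list(law = "fixed", length = 2114)),
                           sim$genome, sim$gaps, seed = 2)
ns   <- null_model_spec("exclude_gaps", gaps = sim$gaps, mc_samples = 999)
mc_coloc_test(pair$a, pair$b, sim$genome, ns, seed = 3)
```

## The analysis workflow

Numbered drivers under `analysis/` (each writes tables under `results/`):

1. `01_simulate_data.R` — simulate a gapped genome and a truly-null track
   pair; export chrom.sizes/BED.
2. `02_gap_profiling.R` — profile a track collection against the gap set
   (per-gap relative overlap, start/middle/end thirds, hotspot) and the
   segment-length/gap-overlap relation.
3. `03_null_model_contrast.R` — the two-null-model experiment above.
4. `04_bias_characterization.R` — bias magnitude vs gap fraction
   (tracks `1/(1-γ)`) and false-rejection rate vs track size.

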