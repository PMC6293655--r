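---
title: "Gap-aware null models for genomic colocalization testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-aware null models for genomic colocalization testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Colocalization analysis asks whether two genomic tracks — sets of
intervals such as ChIP-seq peaks or DNase hypersensitive sites — overlap
more than expected under a null model of no association. The Monte Carlo
version of the test resamples the placement of one track many times and
compares the observed base overlap with the resampled overlaps.

Reference genome assemblies contain gaps: runs of unknown bases (Ns)
where sequencing reads cannot map. Every sequencing-derived track
therefore avoids these regions, and so does every other track derived
from the same assembly. A null model that places elements uniformly over
the *whole* genome ignores this shared constraint: its resampled tracks
spend a fraction of their bases inside gaps where the fixed reference
track has none, so the null overlap distribution is shifted *down*
relative to the observed statistic. Both tracks avoiding the same
excluded regions is enough to make the gap-ignorant null hypothesis
technically false for every pair — with enough elements, every test
rejects, whether or not any biological association exists.

`gapcoloc` implements both null models, a constrained shuffler, a
synthetic-data generator for truly-null track pairs, descriptive
statistics of track/gap intersection, and a study pipeline that
quantifies the false-rejection rate each null model produces.

## The test

The test statistic is the total base overlap
$O = \sum_{\text{bases } x} \mathbf{1}[x \in A]\,\mathbf{1}[x \in B]$.
One track (the *query*) is resampled $m$ times; each shuffle preserves
the element count and the exact segment-length multiset, and places the
elements uniformly, without intra-track overlap, in the placement
universe of the null model:

* `whole_genome` — the full genome (gap-ignorant);
* `exclude_gaps` — the genome minus the gap set (gap-aware).

The one-sided enrichment p-value uses the add-one estimator
$p = (1 + \#\{O^{(b)} \ge O_{\text{obs}}\})/(1 + m)$ with ties counted
as exceedances. It never returns zero, is valid for any $m$, and its
attainable values form the grid $k/(m+1)$. We require $m \ge 19$ so the
smallest attainable p-value is at most 0.05; the package default is
$m = 999$ and the study pipeline uses $m = 99$ (the p-value grid is part
of the reported output). Only the query is resampled — resampling one
track against a fixed reference is the minimal resampling scheme
consistent with the null-model definition, and which member of the pair
was resampled is recorded in the result.

Under the gap-aware null applied to gap-avoiding data, the observed
track and every shuffle are drawn from the *same* placement law, so the
p-value is uniform on its grid by exchangeability — this holds by
construction, independently of any approximation in the placement
algorithm, and is what the calibration tests verify.

For two independent tracks with $b_A$ and $b_B$ covered bases placed in
an accessible space of $G_{\text{acc}}$ bases, the expected overlap is
$b_A b_B / G_{\text{acc}}$ (exactly, for unit-length elements). A
gap-ignorant null replaces $G_{\text{acc}}$ by the genome size $G$, so
the expected observed/null-mean ratio is
$G/G_{\text{acc}} = 1/(1-\gamma)$ for gap fraction $\gamma$ — about
1.082 at the hg19-like $\gamma = 0.076$ and 1.053 at the hg38-like
$\gamma = 0.05$. The bias is a property of the null model's placement
universe, not of the amount of data; more data only makes the test more
certain about it.

## The shuffler

An arrangement is a set of non-overlapping intervals with the given
length multiset, each lying entirely inside one accessible run (an
element cannot span an N-stretch, matching the near-zero mid-gap overlap
of real tracks). Sampling is in two stages:

1. **Allocation** of elements to accessible runs.
   * When all lengths are equal and the problem is small (the counting
     DP needs at most $J(k+1)^2 \le 10^6$ cells for $J$ runs and $k$
     elements), the per-run counts are drawn *exactly* from
     $P(k_1..k_J) \propto \prod_j \binom{R_j - k_j \ell + k_j}{k_j}$,
     the uniform-over-arrangements allocation, via a backward counting
     DP in log space. Every enumeration-scale problem in the test suite
     takes this path, so small-genome draws are exactly uniform over all
     feasible arrangements.
   * Otherwise elements are assigned to runs i.i.d. with probability
     proportional to the capacity $R_j - \ell + 1$, with a bounded
     feasibility retry. This is exact for unit-length elements (it
     reduces to uniform sampling of distinct accessible positions) and
     asymptotically equivalent otherwise; every feasible arrangement
     keeps positive probability. A sequential "committed-length" scheme
     was considered and rejected: we could show by direct counting on a
     two-run, two-element example that no sequential capacity rule is
     exactly uniform across runs, so exactness is obtained where it is
     testable (the DP) and the large-scale law is kept simple,
     vectorizable and law-consistent between data generation and null
     resampling — which is what calibration actually requires.
2. **Starts within a run** by the order-statistics (stars-and-bars)
   construction: for $k_j$ elements with total length $L$ in a run of
   length $R_j$, draw $k_j$ distinct integers from
   $\{1..R_j - L + k_j\}$, sort them, and convert to gaps. This is
   exactly uniform over the feasible left-to-right configurations,
   rejection-free, and $O(k_j \log k_j)$.

Placed elements are kept unmerged even when bookended, so the length
multiset is conserved exactly on every draw (canonicalization elsewhere
merges bookended intervals; the shuffler's output is the one deliberate
exception, since merging two abutting elements would change the
multiset).

Arm-stratified placement (used when matching a template track's
distribution across chromosomal arms) splits the accessible runs at the
arm boundaries and allocates the requested count to each arm; the null
models themselves do not stratify by arm — both behaviours are available
because the synthetic tracks may match arm distribution while the basic
null models do not.

## The synthetic data

`simulate_genome()` builds the study genome: by default 22 equal-length
chromosomes (an hg19-like autosome count) with 10 gap runs per
chromosome totalling a configurable fraction of bases — 7.6% for the
hg19-like condition and 5% for the hg38-like condition, the gap
fractions of the two human assemblies the phenomenon is demonstrated on.
Ten long runs per chromosome mimic the dominance of large
centromeric/heterochromatic gaps in real gap tables while keeping the
accessible-run geometry simple; with the default fixed gap-length law
the total gap length hits its target exactly up to rounding, and
stochastic laws are rescaled to the target (the contract is ±1%).

`simulate_null_pair()` draws the two tracks of a pair from independent
random streams, so H0 (no association) is true by construction; the only
thing the tracks share is gap avoidance. Track element counts and the
fixed segment lengths of the presets (50,000 elements of 2,114 bp for
the histone-like condition; 50,000 of 4,000 bp for the DNase-like
condition) put the studies in the high-power regime where the bias, not
sampling noise, dominates the outcome; real per-track element counts for
the original collections are not published, so the presets' headline
rejection counts are lower-bound reproductions, not point reproductions.
The generator does not model clumping, inter-element distance laws, GC
or mappability covariates — deliberately, matching the basic null-model
definition being studied; passing tests therefore demonstrate the gap
bias in isolation and say nothing about those other structures in real
data.

Every stochastic stage takes an explicit seed, and composite runs derive
sub-seeds with `derive_seed()` (a Lehmer-style hash of the master seed
and small indices), so the two null modes are always compared on
identical pairs and any stage can be re-run alone.

## Gap-overlap profiling

`profile_gap_overlap()` reports, for a collection of tracks against a
gap set, the mean per-gap relative overlap and the same quantity
restricted to the start, middle and end portions of each gap, plus the
hotspot (the gap with the largest track-averaged relative overlap). The
portions are equal thirds (remainder bases to the middle) — the
simplest rule consistent with overlap concentrating at gap flanks — and
the rule is pluggable (`portioning =` a function) because the exact
flank definition is a reporting convention, not part of the statistics.
Relative values are per-portion (overlap divided by portion size), so a
track covering a gap exactly scores 1 for the gap and for each third.
`mean_interval_length_relative` (mean interval length divided by the
track's total covered bases) is a nonstandard descriptor kept for report
compatibility and flagged as such. Averages are unweighted over
(gap, track) pairs. Hotspot ties resolve to the first gap in canonical
order.

## Numerical and interface choices

* Coordinates are 0-based half-open (BED convention) throughout; strand
  is ignored; BED intervals running past a chromosome end are clipped
  with a warning; UCSC gap-table dumps are read with
  `read_bed(ucsc_gap_table = TRUE)` (columns 2–4).
* Interval algebra runs on linearized (absolute) double-precision
  coordinates — exact for genome sizes far beyond 2^53 bp — with the
  placement and sorted-overlap hot path in C++ driven by R's RNG, so
  `set.seed()` governs everything.
* A query that itself intersects the gap set under `exclude_gaps` is a
  warning, not an error: real tracks show tiny gap-flank overlaps.
* Each null mode is BH-corrected separately across the study's pairs,
  matching per-experiment correction denominators.
* KS uniformity diagnostics use the p-values as-is; on the $m = 99$
  grid the discreteness contributes at most $1/(m+1) = 0.01$ to the KS
  distance, negligible against the critical values at the study sizes.
  Where tests need an exactly continuous null (small $m$, many
  replicates) they apply the randomized PIT $u = p - U/(m+1)$.

## Problem sizes

The packaged studies run at these sizes, chosen so the full suite is an
ordinary desk-scale computation: the two full-scale studies (100 and 95
pairs, 3.0/3.1 Gbp genomes, 50,000-element tracks, $m = 99$) for the
headline counts; the calibration study at 1/10 scale (300 Mbp, 5,000
elements — `study_preset(scale = 0.1)` shrinks genome and element count
together, keeping the placement geometry and per-pair power comparable
in spirit while the headline studies carry the full-power conditions);
enumeration-scale toys (≤ 40 bp) wherever exactness is asserted against
brute force; and 2,000-replicate toy-genome runs for the analytic bias
magnitude.

## Limitations

* The large-scale allocation law is approximately, not exactly, uniform
  across runs for element lengths > 1 (edge effects of order
  $\ell/R_j$); this cancels between data generation and null resampling
  and is irrelevant to the bias phenomenon, but a user wanting exact
  uniformity at scale would need the DP path and its cost.
* Equal-length chromosomes and equal-length gap runs are a deliberate
  simplification; the placement machinery accepts arbitrary
  chromosome-length vectors and gap-length laws if realism matters.
* The headline rejection counts are reproduced as lower bounds under
  high-power presets, because the original per-track element counts are
  not published.
* Only enrichment (right-tail) testing is provided; depletion testing
  and analytical (e.g. Fisher) tests are out of scope, as are BED12/GFF
  parsing, tabix and liftover.
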