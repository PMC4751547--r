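---
title: "Methods and design notes for mugakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mugakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mugakit)
```

`mugakit` implements the computational methods behind a mouse genotyping
array platform: marker-panel design against the eight Collaborative Cross
(CC) / Diversity Outbred (DO) founder haplotypes, array-level quality
control, intensity normalization, multiallelic cluster detection,
informativeness analytics, congenic-background reconstruction, and
copy-number screening — together with a synthetic-data generator that
provides ground truth for every one of these analyses. This vignette is
the package's account of the underlying models, the parameters that
matter, and the numerical choices made where the design was open.

## Marker selection

### The window score

A biallelic SNP alone distinguishes few of the 36 genotype states formed
by 8 founder strains (8 homozygous states plus `choose(8, 2) = 28`
unordered heterozygous combinations, phase ignored). Discrimination
therefore works on *windows* of consecutive SNPs. For a window of `w`
SNPs, each founder state induces a joint genotype vector — one unordered
allele pair per SNP — and the score `f` is the number of **distinct**
vectors among the 36. This reading makes `f = 1` on a window where all
founders share one haplotype and `f ≤ 36` always, which is the range the
score is defined over; counting only uniquely identified states would
allow 0 and was rejected for that reason. A missing founder allele acts
as a wildcard: a state vector containing a wildcard collides with every
vector consistent with it (we count connected components of the
consistency graph), which scores conservatively rather than optimistically.

### Beam search

One target SNP is chosen per interval of a uniform genetic-map partition
of each chromosome. The objective is the sum of `f` over all complete
sliding windows of `window_size = 5` chosen SNPs. A path is one choice
per interval; paths are extended interval by interval, each extension
adds the newly completed window's `f`, and the set of paths is pruned to
the `beam_width = 1e5` highest-scoring ones (ties kept in insertion
order). Because the score of an extension depends only on the previous
`w − 1` choices, a beam at least as wide as the number of distinct paths
is exhaustive; the test suite verifies exact optimality against
brute-force enumeration on 200 instances with ≤ 3^8 paths, and that the
returned score is monotone in the beam width. An optional
suffix-deduplication mode keeps only the best path per distinct
`(w − 1)`-suffix before pruning; it is off by default because the
historical behavior of pruning by score alone is equally defensible and
we prefer the variant with fewer moving parts.

Two practical rules complete the partition step: if some interval of an
`n`-interval partition is empty, `n` is decremented until every interval
holds a candidate (keeping intervals uniform in cM, rather than merging
them, which would not); and a chromosome contributing fewer than `w`
selected SNPs scores 0 and is flagged.

### Local and spacing-based selection

Near recombination hotspots the chromosome-wide recursion is unnecessary:
among all runs of 4 consecutive candidates whose span overlaps the
central 100 bp of the hotspot, the run maximizing `f` is taken, ties
broken by smaller bp span and then proximity to the hotspot center; if no
run overlaps the center the nearest one is returned flagged
`off_center`. Substrain-informative and gap-filling markers use a greedy
uniform-spacing rule — repeatedly place a marker at the candidate closest
to the midpoint of the largest uncovered gap — which the tests compare
against exhaustive subset search on small instances. Wild-ascertained
novel SNPs are placed three per 1-Mb window (one transition per 500-kb
half, one transversion in the middle 333 kb), ranked by minor-allele
frequency with seeded random tie-breaks, accepting picks closer than
100 kb to a previous pick only when no compliant candidate exists (such
picks are flagged).

Candidate filtering retains SNPs assayable with a single bead type
(excluding `[A/T]` and `[C/G]`, which need two beads on this chemistry),
with unique 50-bp flanks, at least 50 bp from the nearest neighboring
variant — all strict, order-preserving subset operations.

## Quality control

The per-probe total intensity is `d = sqrt(x² + y²)`, the Euclidean norm
of the two channel intensities; the companion `R = x + y` overestimates
total intensity in heterozygous samples because the norm never exceeds
the channel sum. On a successful array `d` is approximately
Normal(mean 0.97, sd 0.42) in the platform's normalized units; each array
is scored with the two-sided Kolmogorov–Smirnov statistic `K` against
that reference (right-continuous ECDF, both one-sided deviations taken at
every sample point) and flagged at `K > 0.1`. Fewer than 100 probes make
`K` unstable, so that is an error.

Call-rate thresholds are strict counts as printed on the full-size
(141,090 SNP) product: more than 15,000 missing calls for *M. musculus*
samples, more than 45,000 for other *Mus* species, and more than 2,000
heterozygous calls for classical inbred strains only (wild-derived
inbreds are deliberately not subjected to the heterozygosity rule). On a
marker subset these absolute counts are rescaled by the fraction of the
full array present. Two desk-scale corrections follow from hemizygosity
and are immaterial at full array size: the intensity check is computed
over autosomal probes (male X/Y probes have half intensity by
construction, a ~0.14% effect on the real array but large on a small
subset), and call-rate counting excludes the 83 Y markers (female samples
carry ~83 structural no-calls which the full-size threshold absorbs).

Sex is inferred from the count of good (nonmissing, nonheterozygous)
calls at Y markers: ≤ 33 infers female, ≥ 42 male (bounds rescaled to the
number of Y markers present), and samples in between are resolved by mean
X-chromosome `d` against the midpoint of the known-female and known-male
batch means — females carry two X copies and hybridize hotter. A
mismatch against a known sex fails the sample.

Probe quality tiers are assigned from a reference panel with strict
bounds: tier 1 needs at least one sample called each of AA, AB and BB and
a no-call rate strictly below 10%; tier 2 drops the AB requirement;
tier 3 only the no-call bound; tier 4 is the remainder. Exactly 10%
missing is *not* below the bound.

## Normalization

Intensities are mapped to polar coordinates `R = x + y` and
`theta = (2/π)·atan2(y, x)`, so `theta` runs from 0 (pure reference
signal) to 1 (pure alternate). Per marker, the three genotype-cluster
centroids are the trimmed means of `theta` and `R` among samples called
AA, AB, BB — omitting the most extreme 5% of values, implemented as 2.5%
per tail per variable independently (the two variables are not coupled by
the trimming). BAF is the piecewise-linear map of `theta` through the
anchors (0, 0.5, 1 at the AA, AB, BB centroids), clipped outside;
`LRR = log2(R / R_expected)` with `R_expected` linearly interpolated from
the centroid `R` values at the observed `theta` and clamped to the
nearest centroid beyond the anchors. Markers with a single observed
cluster get missing BAF but a usable LRR against that cluster — the
transforms perform best when all three genotype states are observed, and
the `low_confidence` flag records when they were not.

The thresholded quantile normalization maps each channel of each array
onto reference quantiles (the mean of the per-array empirical quantile
functions of a designated reference batch, all on `(rank − 0.5)/n`
plotting positions) and caps the per-probe adjustment at a
normalized/raw ratio in `[1/1.5, 1.5]`, flagging capped probes. The
original method's exact modification is not public; this implementation
is documented as our simplification, not claimed identical.

## Multiallelic clusters and construct calls

Off-target variants near a probe create additional hybridization alleles.
The cluster model exploits the reference-panel pedigree: one seed cluster
per founder (centroid of its replicates), iterative merging of mutual
nearest neighbors whose centroid distance is within
`merge_dist_factor = 2` times the median within-cluster spread, then each
F1 class joins its parents' cluster if they share one and otherwise
founds a candidate heterozygous cluster, followed by a final merge pass.
Cluster labels are ordered by centroid `theta` for reproducible output.
The cited clustering literature does not fix the merge criterion; both
centroid-distance (default) and per-point-distance merging are
implemented behind a flag, and the calibration configurations — a
biallelic probe (3 clusters) and a three-allele probe with all F1s (6
clusters) — are regression-tested across seeds.

Construct probes have only one real allele, and the platform's two-allele
normalization introduces artifacts for them, so presence calls use **raw**
intensities: per target, the raw signal along each probe's informative
axis is summed, floored at 1 unit, log10-transformed, and fit with a
two-component Gaussian mixture by EM (initialized at the 25th/75th
percentiles, sd at the sample sd, equal weights; convergence at
|Δ log-likelihood| < 1e-8 or 500 iterations; component sds floored at
1e-6). A sample is present when the posterior of the higher-mean
component exceeds 0.5. A target is declared non-separable — all calls
absent, with a warning — when the component means differ by less than
twice the pooled sd **or** the mixture fails to beat a single Gaussian on
BIC; the second condition is needed because a fully converged EM can
split one tight mode into two overlapping components that formally pass
the mean-separation rule.

## Ancestry mosaic HMM

Congenic verification asks which donor strain contributed each genomic
segment. Hidden states are candidate donors; emissions score a call match
as `1 − ε` and a mismatch as `ε` (`ε = 0.01` by default; no-calls and
missing donor genotypes are uninformative; an observed heterozygous call
against homozygous donor panels counts as a mismatch, since congenic
samples are expected inbred — a diploid two-donor state space is out of
scope). The switch probability between adjacent markers is
`1 − exp(−d_cM / L)` with expected segment length `L = 10` cM, split
evenly among the other donors. The Viterbi path is decoded into segments
with boundaries at the midpoint between the flanking markers of a state
change, so segments exactly tile the marker span. None of these
parameters is canonical; all are config-exposed and validated by
simulation recovery (planted 20-cM blocks recovered to within two markers
in ≥ 95% of seeded replicates).

Closely related donors (substrains) are often indistinguishable over a
segment. Rather than overclaim, donors whose within-segment emission
log-likelihood is within `margin_delta = 2` of the best are reported as
an equivalence group (`"B6J|B6N"`-style labels), and forward–backward
posteriors (normalized at every marker) are attached as the group's mean
posterior.

## Copy number

Paralogous-SNP candidates for probe design are pileup positions with
pseudoheterozygosity (two or more bases each supported by **more than 3**
reads) and excess coverage (depth **more than 50**), thinned left-to-right
to a spacing of more than 50 bp; all bounds are strict, implemented as
`≥ 4`, `≥ 51`, `≥ 51`. Region-level screening averages LRR over the
probes in a region (at least 3, else the call is withheld) and calls gain
above +0.3, loss below −0.3; the threshold is a screening default of this
package, not a calibrated constant — serious CNV calling should use a
dedicated segmentation method downstream.

## The synthetic generator

The generator's primary simulated quantity is `d`, not `(x, y)`: the
channel pair is reconstructed as `x = d·cos(θπ/2)`, `y = d·sin(θπ/2)`
from the genotype cluster's angle plus noise. This pins the QC-relevant
marginal directly to the reference distribution. Good-mode `d` is
factored as a per-marker probe affinity (drawn once per panel,
Normal with the reference mean, floored at 0) times small within-marker
noise (`1 + Normal(0, cv)`, `cv = 0.08`), with the affinity variance set
so the array-level marginal keeps mean 0.97 and sd 0.42 exactly; negative
draws are floored at 0, which lifts the mean by +0.0015 (rejection
sampling would lift it by +0.012 and was rejected for that reason). The
affinity factorization matters because real probes differ in brightness
consistently across arrays — which is exactly the component per-marker
centroid normalization cancels; without it, region-level LRR would carry
the full array-level sd per probe and planted CNVs (which scale `d` by
`copy/2`) would be unrecoverable at realistic region sizes.

Failed arrays draw `d` i.i.d. from a Gamma with mean 0.45 (shape 4) — a
right-skewed shape chosen so the `K > 0.1` flag holds with wide margin —
plus a high no-call rate (35%). Diverged samples mix the good component
with a spike of near-zero intensities (`|Normal(0.05, 0.03)|`, spike
fraction 0.2). Females emit background intensity and no-calls at Y
markers; males carry half intensity on X and Y; VINO markers emit the
near-zero spike in samples carrying the affected founder haplotype.
Outbred mosaics switch haplotype ancestry along the genetic map with a
generation-scaled exponential switch rate. Every simulated observable has
a truth entry (diplotypes, mosaic segments, sexes, VINO carriers, CNV
regions, construct carriers).

The default desk-scale panel is two autosomes (1,000 + 900 markers), an X
(120) and a Y (83 markers, the full-size count, so the printed sex-call
bounds apply unscaled); 2 replicates of each of 8 founders, all 28 F1s,
and 4 outbred mosaics. The congenic generator defaults to donors that
differ at 95% of markers — emulating a donor panel genotyped at markers
informative for the comparison, which is the design condition for
congenic verification; boundary precision is information-limited by runs
of uninformative markers, so a panel with substantial uninformative
content cannot support two-marker breakpoint accuracy no matter the
decoder.

What the generator does **not** emulate: linkage disequilibrium and
realistic haplotype sharing among founders (alleles are drawn
independently per marker given a frequency), batch effects and plate
structure, GC waves in LRR, sequence-level artifacts (probes are abstract
identifiers), and the genotype-calling step itself (true genotypes are
degraded only by no-calls, not miscalls, outside the congenic
generator's explicit error rate). Passing tests therefore demonstrate the
correctness of the computations under the stated generative model, not
the field performance of the array.

## Problem sizes and reproducibility

The test suite runs the beam-search oracle comparison on 200 instances of
8 intervals × ≤ 3 candidates, the window-score bound on 10^5 random
configurations, one full-size (141,090-probe) simulated array for the
intensity reference checks, and 100 congenic replicates of 500 markers ×
3 donors — sizes at which every exhaustive oracle is computable exactly
and the whole suite completes in a few minutes. All stochastic tie-breaks
and generators take explicit seeds (package default 20151218), and the
acceptance script derives every random stream from its `--seed` argument.

## Known limitations

* The beam search assumes the window score is the only coupling between
  intervals; constraints spanning chromosomes (total probe budget) must
  be handled by the caller via `n_intervals`.
* The per-interval count `n` is an input: the historical allocation of
  the genome-wide budget across chromosomes is not reconstructable from
  printed information.
* Diagnostic-marker "mismatches" are counted as carrier individuals, not
  allele copies; the alternative reading is config-exposed via the
  carrier counting itself.
* `summarize_region_lrr()` is a screen, not a segmentation; PennCNV-class
  methods remain the tool of choice for discovery.
* The tQN implementation is a documented simplification of the cited
  approach (per-channel quantile map to a reference batch with a 1.5×
  ratio cap).
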