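---
title: "Mapping selective sweeps in breed-structured SNP panels"
author: "SweepScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping selective sweeps in breed-structured SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Modern dog breeds are closed populations formed a few hundred years ago from
a much larger domesticated-dog gene pool. Breed formation combined a severe
founding bottleneck with intense artificial selection on breed-defining
traits, so a breed genome is a mosaic of regions whose reduced diversity is
explained by drift alone and regions where a selected haplotype swept to
fixation. SweepScan implements a family of statistics designed to separate
the two on dense SNP-array genotypes of many breeds, together with a
coalescent simulation machinery that supplies the neutral expectation.

All functions operate on a `GenotypePanel`, a
`RangedSummarizedExperiment` whose rows are biallelic loci (`GRanges` with
`alleleA`, `alleleB`, `chromClass`), whose columns are samples labelled by
breed and sex, and whose assays hold B-allele dosages and, when available,
phased haplotypes. "Population" always means breed. Loci are classed as
`autosome`, `PAR` or `X_nonrec`; autosomes and the pseudo-autosomal region
are standardized together, the non-recombining X separately.

# Per-SNP differentiation

`fstMulti()` and `fstPair()` implement the Weir & Cockerham (1984) theta
estimator from per-breed allele frequency, sample size and observed
heterozygote fraction. The variance components are computed per locus and
breeds with no called allele at a locus are dropped from that locus rather
than failing. Negative estimates are retained internally — clipping before
moment computation would bias the standardization used by the d_i scan —
and clipped to [0, 1] only in `snpFstTable()`, which feeds thresholding.
When a frequency table is assembled by hand (`makeBreedFreq()`) without
heterozygosity information, the Hardy–Weinberg expectation 2p(1−p) is used;
`breedFrequencies()` always supplies the observed fractions. A
Hudson/Bhatia ratio estimator is available through
`fstPair(..., estimator = "hudson")` for sensitivity analysis.

The screen for selection shared across many breeds keeps SNPs with
all-breed F_ST > 0.55 and pooled minor-allele frequency > 0.15 and chains
passing SNPs within 500 kb of each other into regions
(`highFstRegions()`). The "pairwise fixation index" pq
(`pairwiseFixationIndex()`) counts breeds near-fixed (frequency > 0.95) for
each allele and multiplies the two counts; pq > 0 means at least two breeds
are fixed for opposite alleles.

# The S_i and d_i window scans

The genome is tiled with 150-kb windows advancing by 25 kb, anchored at
position 0 of every chromosome; windows with fewer than 5 array loci are
dropped (`makeWindows()`). The SNP count is taken before any per-breed
restriction — the retention rule sees the array, not the breed.

For a breed pair (i, j) and window w, relative heterozygosity is

θ_ij(w) = h_i / (h_i + h_j),

where h is the number of SNPs segregating in that breed inside w. The scan
statistic for breed i is the sum of standardized deviations over all
partners,

S_i(w) = Σ_{j≠i} ( θ_ij(w) − E[θ_ij] ) / sd[θ_ij],

with E[θ_ij] computed from the pooled genome-wide polymorphic-site counts
H_i/(H_i + H_j) and sd[θ_ij] the standard deviation of the window-level θ
values of that pair. Windows where a pair has h_i + h_j = 0 skip the pair
without rescaling the sum (a defined-pair count per window is reported).
A pair whose window θ values have zero standard deviation is excluded with
a warning. Strongly negative S_i marks loss of variation in breed i.

The d_i statistic standardizes the per-SNP pairwise F_ST in the same way,

d_i(snp) = Σ_{j≠i} ( F_ST^ij − E[F_ST^ij] ) / sd[F_ST^ij],

with moments taken over all SNPs of the chromosome class, and the window
value is the mean of its member-SNP d_i. Both scans compute moments
separately for autosome+PAR and the non-recombining X.

Per breed, the most extreme 1% of windows are flagged (bottom tail for
S_i, top for d_i). All windows tied with the threshold value are included.
This tie rule matters: inside a fully fixed sweep every window with all
pairs defined attains the identical floor value Σ_j (0 − E)/sd, so a sweep
longer than 1% of the genome is still flagged in full rather than being
truncated at the tail count. Flagged windows that overlap or exactly abut
are merged into candidate regions (`mergeToRegions()`).

# Region significance against a simulated length null

Region length, not depth, separates selection from drift: the same tail
fraction is flagged in neutral data, but neutral flagged windows rarely
chain into megabase regions. `nullRegionLengths()` runs the identical
pipeline (simulate → ascertainment-match → scan → flag → merge) on neutral
replicates and catalogues region lengths per breed and statistic. Each
observed region then receives a marginal p-value

p = (1 + #null regions strictly longer) / (1 + n_null)

for the same breed and statistic. The add-one convention keeps p away from
exactly zero before Benjamini–Hochberg adjustment; the plain proportion is
available with `addOne = FALSE`. Ties in length count as "not longer". BH
runs across all regions of one statistic over all breeds, and regions with
q ≤ 0.05 are called significant.

# Across-breed GWAS with breed-label permutation

Every dog carries its breed's trait value (`assignPhenotypes()`), so the
association unit is the breed even though the test runs per sample. The
per-SNP statistic is the squared t of a least-squares regression of
phenotype on dosage; dichotomous 0/1 traits go through the same regression,
which is equivalent to an allelic trend test up to a monotone transform and
keeps one code path.

Genome-wide significance comes from max-T permutation of the breed labels:
each permutation shuffles the breed-level phenotype values among breeds
(all dogs of a breed always share a value), recomputes every SNP statistic
and records the genome-wide maximum. Then

P_genome(snp) = (1 + #permutations with max ≥ observed) / (1 + n_perm),

whose floor at the default 1000 permutations is 1/1001. When the
permutation space (n_breeds! orderings) does not exceed n_perm, all
orderings are enumerated instead and the plain proportion over the
orderings (identity included) is reported; value multisets with ties can
make distinct orderings induce identical labelings, and they are still
counted as permutations. Statistic comparisons use a relative tolerance of
1e-8 so that tally counts do not depend on floating-point round-off.
A `femalesOnly` flag drops male samples before anything else, the protocol
used for X-chromosome traits.

# Shared haplotype cores

Within significant S_i regions, `homozygousCores()` extracts maximal runs
of consecutive SNPs at which a breed is completely homozygous (no
heterozygous call, one allele among non-missing genotypes). Missing
genotypes inside an otherwise fixed run are treated as compatible — array
missingness would otherwise shatter cores arbitrarily — and the per-core
missingness fraction is reported. Phase is never needed: at fixation the
two haplotypes are identical. Cores from different breeds are clustered by
single-linkage physical overlap (≥ 1 bp, `clusterCores()`), and
`maximalIbs()` finds, inside the joint intersection of a cluster's cores,
the widest-spanning run of consecutive SNPs at which every breed is fixed
for the same allele. Clusters without such a SNP yield nothing.

# XP-EHH validation

`ehhBetween()` computes extended haplotype homozygosity over a closed SNP
interval as the probability that two random haplotypes are identical
across it. `selectPairs()` removes SNPs with pooled MAF < 5% and retains,
for each anchor, the nearest partner per direction whose pooled EHH lies
in [0.03, 0.05] — EHH is non-increasing outward, so the scan stops once it
drops below the band, and anchors whose EHH jumps over the band contribute
no pair in that direction.

For each breed and retained pair, `xpehhScores()` integrates the breed's
EHH from anchor to partner over physical distance (iHH, trapezoidal rule;
genetic maps are unavailable at scan time) and forms the one-vs-rest log
ratio ln(iHH_i / mean_{j≠i} iHH_j), positive when breed i carries
unusually long shared haplotypes. Raw scores are z-standardized within
each breed × chromosome and the final score is the negated z-score — a
single global orientation choice so that swept breeds average negative
over sweep regions while each breed × chromosome keeps mean 0 and sd 1.
`regionMeanXpehh()` averages scores over pairs anchored inside a region
for the region's breed; regions without anchors are reported missing.

# The synthetic-data generator

`simulateNeutralPanel()` constructs the demographic program — a wolf
ancestor of diploid size 22,600 shrinking instantaneously to 5,650 at
domestication 5,000 generations ago, splitting simultaneously into breed
populations of size f × 22,600 at breed formation 100 generations ago,
sampled today — and hands it to msprime as the coalescent sampler, one
independent segment per chromosome. Mutation and recombination rates
default to 1e-8 per bp per generation and the generation time is 3 years.
Per-breed bottleneck fractions f lie on the canonical grid 0.001–0.03;
panels in the package's own experiments use f = 0.01 for every breed, the
grid midpoint, unless stated otherwise. Non-recombining X segments scale
all population sizes by the X/autosome effective-size ratio 9134/7752
times 3/4; the panels are phased, free of missingness, and all samples are
recorded female.

Array SNPs are not a random draw from the neutral site-frequency spectrum:
ascertainment during array design flattens it. `ascertainmentMatch()`
emulates this by rejection-sampling sites so the pooled-MAF histogram
matches a target — uniform over ten bins on (0, 0.5] by default, chosen
once as the array-like spectrum since the source arrays' empirical
spectrum is not published in a usable form — then thins uniformly at
random to one marker per 13,046 bp, the density of the emulated array.
Order and phasing are preserved.

For large panels, `simulateAscertainedPanel()` runs the same two steps
segment by segment — each independent segment is simulated, matched and
thinned before the next starts — so the full-density genotype matrices of
at most one segment are ever in memory; per-segment histogram matching is
distributionally identical to matching the concatenated panel.

`ldDecay()` computes haplotype r² for marker pairs up to 500 kb apart in
10-kb distance bins. `fitBottleneck()` simulates a single-breed panel at
each of the 59 grid values of f (segment seeds shared across grid points
as common random numbers), applies the identical ascertainment protocol,
and returns the grid value minimizing the summed squared difference
between observed and simulated binned r², breaking ties toward smaller f.

`plantSweep()` copies one randomly chosen haplotype of a breed over an
interval into every haplotype of that breed — complete fixation, the
hardest version of a sweep — leaving other breeds and outside loci
untouched. `simulateTraitPanel()` builds breed phenotypes as
effect × breed allele frequency at a causal locus plus Gaussian noise.

# Numerical and design choices

* Coordinates are GRanges conventions (1-based, closed) throughout;
  BED export is 0-based half-open. Windows anchor at position 0, i.e.
  the first window covers bases 1–150,000.
* E[θ_ij] uses pooled genome-wide polymorphic counts, not the mean of
  window θ values; the two differ when window SNP density varies.
* Marginal p-values use the add-one rule by default (see above).
* Tail selection includes threshold ties — a conservative superset with
  the important side effect on fixed sweeps described earlier.
* Male X genotypes are treated as haploid 0/2 dosages contributing one
  allele and never counting as heterozygous.
* The exhaustive-permutation branch of the GWAS reports the plain
  proportion over all orderings; the Monte-Carlo branch uses add-one.
* Zero-sd pairs (scan standardization) and zero-iHH pairs (XP-EHH) are
  excluded with a report rather than propagating NaN.

# What the tests show — and what they do not

The test suite exercises every operation against independent brute-force
oracles on small fixtures and runs the full pipeline on synthetic panels
at reduced scale: the neutral F_ST screen uses the study-shaped 30-breed
panel over twenty 5-Mb segments; scan calibration and planted-sweep
recovery use 3 breeds × 8 dogs over four 5-Mb segments with a null
catalogue of 100 neutral replicates; bottleneck recovery fits the 59-point
grid with twenty 4-Mb segments per grid value. These sizes were chosen so
the whole suite completes on a single CPU in well under half an hour while
keeping every check statistically meaningful (the BH floor arithmetic
dictates roughly sixty-plus null replicates per twenty observed regions
for a planted sweep to be callable at q ≤ 0.05).

Synthetic panels are neutral coalescent samples under a stylized
demography with uniform recombination and a uniform ascertainment target.
Real array data differ in ways the generator does not emulate: recombination
hotspots, genotyping error and missingness, relatedness within breeds,
non-equilibrium wolf history, and an ascertainment scheme tied to the
discovery panel of the actual array. Passing tests therefore demonstrate
internal correctness and statistical calibration under the stated model,
not field performance on any particular dataset.

# Known limitations

* The d_i scan rarely yields FDR-significant regions on small synthetic
  genomes — its null region lengths closely match the observed ones under
  neutrality, mirroring the statistic's behaviour as a validation rather
  than discovery tool here.
* XP-EHH is implemented as an unstandardized one-vs-rest log-ratio of
  integrated EHH with per-breed-per-chromosome normalization; allele-aware
  (core-haplotype) EHH and genetic-distance integration are out of scope.
* The coalescent engine runs in a separate Python process; a panel's
  reproducibility is guaranteed by seed, not by in-process RNG state.
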