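---
title: "Methods and design choices in multiproxy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in multiproxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiproxy)
```

`multiproxy` integrates three independent lines of biomolecular evidence —
ancient DNA, stable isotopes and radiocarbon — into one per-individual
dossier for commingled skeletal assemblages. This vignette explains the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the method left genuine freedom.

## Read-level QC and pseudo-haploid calling

Low-coverage ancient DNA does not support diploid genotype calling, so the
package works with *pseudo-haploid* calls: at each SNP covered by at least
one read that survives filtering, one read is drawn uniformly at random
(seeded) and its base becomes the haploid call — 0 for the panel reference
allele, 1 for the alternate, missing otherwise. Filters follow standard
ancient-DNA practice: mapping quality ≥ 10, base quality ≥ 20, and the two
bases nearest either read end excluded, since residual deamination after
partial-UDG treatment is confined to the terminal positions. Duplicate
molecules are collapsed on the key (start, end, orientation, library
barcode); among copies the read with the highest summed base quality
survives. "Highest quality" is not fully determined by the key definition
alone — mean and summed base quality order reads identically at equal
length — and the implementation uses the summed quality with ties broken by
input order, which makes deduplication deterministic.

Three authenticity screens gate each sample:

1. **Mitochondrial consensus match rate** (threshold ≥ 0.97). Implemented
   as a two-component read-likelihood mixture: each mitochondrial read is
   scored under the sample's own majority-base consensus and under the
   best-matching haplotype from a contaminant panel, with a symmetric
   per-base error rate ε (default 0.01); the authentic proportion is the
   maximum-likelihood mixture weight on a grid of step 0.001. This is a
   deliberate simplification of full mixture-model contamination software:
   it preserves the decision variable (the match rate) without modelling
   fragment-level error profiles.
2. **Terminal C→T damage rate** (threshold ≥ 0.03). The fraction of reads
   whose 5′-terminal base overlies a reference C but reads T. Genuinely
   ancient, partial-UDG-treated libraries retain at least ~3% terminal
   deamination; lower values suggest modern contamination.
3. **X-chromosome contamination in males** (threshold ≤ 0.015, defined only
   for males covering more than 200 X SNPs). Males are hemizygous, so
   apparent polymorphism on X measures contamination. The estimator is a
   two-equation method of moments: the error rate ê comes from sites
   invariant in the polymorphism panel, and the contamination ĉ solves
   (minor-allele rate at polymorphic sites) = ê/3 + ĉ·(mean panel MAF) —
   the ê/3 because a sequencing error hits one specific alternative base a
   third of the time. ĉ is clamped to [0, 1]. This replaces the
   likelihood-based X-heterogeneity estimator used with full read data; it
   preserves the thresholded quantity.

All thresholds are inclusive (a sample exactly at 0.97/0.03/0.015 passes),
and every failing screen is listed as a reason rather than the first one
found.

Genetic sex uses R_y = #Y/(#X + #Y) over sex-chromosome reads (minimum 100
observations). The ratio method itself carries no canonical cutoffs; the
defaults R_y ≥ 0.3 → male and R_y ≤ 0.05 → female were chosen so that
simulated males (R_y ≈ 0.5 with equal X/Y target sites) and females
(R_y ≈ 0) separate by many standard deviations at the coverages the
package simulates; anything between is reported undetermined rather than
guessed.

## Haplogroup assignment

**mtDNA.** Published multiplex-PCR panels report bare mutation *positions*
relative to the rCRS, without alleles, so matching is by position set.
Every tree node is scored as
|observed ∩ path| − λ·|path \\ observed|, with λ = 1 by default; positions
outside an explicit "assayed set" are never penalized, because a multiplex
panel covers few positions and unobserved does not mean ancestral. The
maximal-score node wins; among ties the shallower (more conservative) node
is returned, and a mutation list matching nothing returns the root
("rCRS-like"). Scoring every node and taking the argmax is exact — the
brute-force oracle in the test suite is the same computation written
independently — so no search heuristics are involved. Out-of-range
positions (> 16569), which occur as typographic slips in published lists,
are dropped with a message rather than invalidating the record.

The packaged mitochondrial tree is built from the printed lineages
themselves by set inclusion: each distinct printed mutation set is a node,
its parent the largest printed subset, and its label the majority
haplogroup among individuals sharing that exact set. This makes the tree
the best possible position-based classifier for that table: individuals
whose printed set is unique are always recovered, and the residual
discordance is exactly the rows whose identical sets were printed under
different labels (six such collisions exist, capping attainable concordance
at 58 of 66 eligible rows). An allele-aware tree would resolve these, but
the printed data do not carry alleles.

**Y chromosome.** A breadth-first search of the marker-annotated tree
accumulates, per node, Σ w·[derived observed] − w·[ancestral observed]
over the defining markers on the root-to-node path, with w = 1/3 for
transitions and 1 for transversions — post-mortem deamination manufactures
spurious transitions, so they carry a third of the evidential weight.
Missing markers contribute nothing. Derived observations *off* the
candidate path are ignored by default (the search counts mismatches in the
observed derived alleles along each branch); a flag switches on off-path
penalization for users who prefer the stricter convention. Calls from
samples with fewer than 100,000 autosomal SNPs carry a caution flag, and a
sample with no informative marker observations is "not callable" rather
than assigned to the root.

## Population structure

PCA follows the smartpca conventions for ancient samples: genotypes are
centered by the per-SNP mean call and scaled by √(p(1−p)); monomorphic
SNPs are dropped; component signs are fixed (largest-magnitude loading
positive) so repeated runs are byte-identical. Low-coverage samples are
*projected* by least squares using only their non-missing SNPs. Projected
coordinates shrink toward the origin when the panel is small relative to
the SNP count — the well-known projection-shrinkage effect; the package
deliberately does not correct for it (group assignment by nearest centroid
is invariant to the shared shrinkage direction), and the test suite checks
robustness of projections to missingness rather than coincidence with
in-sample scores.

F_ST uses the Hudson ratio-of-averages estimator with within-population
variance estimated treating calls as haploid draws — the appropriate
"inbreed" correction for pseudo-haploid data, where within-individual
heterozygosity is unobservable. f4-statistics are means of
(p_A−p_B)(p_C−p_D) over the SNPs at which that statistic's own four
populations are all called (the "allsnps" convention), with standard
errors from a weighted block jackknife: 5 Mb physical blocks where
positions exist, contiguous ~n/100-SNP blocks otherwise.

The cladality test is the rank-0 reduction of the full rank test: if
target and candidate form a clade relative to right populations O_1..O_m,
every f4(target, candidate; O_1, O_j) has expectation zero, and the
spanning vector of these statistics with its jackknife covariance gives a
Hotelling-style chi-square with m−1 degrees of freedom (pseudo-inverse and
reduced degrees of freedom if the covariance is singular). Higher ranks
are out of scope. Two-way admixture weights minimize the generalized
least-squares distance between the target's f4 vector and the α-weighted
combination of the sources' vectors; sources that are themselves cladal
with respect to the right set give the estimator no leverage, which is
detected (chi-square test on the source-difference vector) and reported as
an error advising different sources. α is clamped to [0, 1] with a
boundary warning; its standard error comes from delete-block
re-estimation.

Kinship scanning uses the pairwise mismatch rate over jointly-called SNPs,
normalized by the cohort median as the unrelated baseline — the
pseudo-haploid convention — with classification cutoffs at 0.625
(identical), 0.8125 (1st degree), 0.90625 (2nd degree) and 0.953
(3rd degree) on the normalized rate. The cited kinship method does not
print its thresholds, so these follow the standard normalized-mismatch
conventions and are configurable. Pairs with fewer than 5000 overlapping
calls are reported as having insufficient data.

## Sex-biased ancestry

The per-sample ancestry proportion is either a per-sample two-way
admixture α or, by default, the sample's scalar projection onto the axis
between two reference centroids, clamped to [0, 1]. The test statistic is
mean(female) − mean(male); sex labels are permuted across individuals
(default 9999 permutations) and the two-sided p-value uses the add-one
correction (#{|Δ_perm| ≥ |Δ_obs|} + 1)/(n_perm + 1), which cannot report
p = 0 from Monte-Carlo noise. The permutation is scoped to one ancestry
group at a time (the pipeline tests the largest group), since pooling
groups would confound group membership with sex composition. The
difference of means was chosen as the canonical statistic for a
"permutation test across individuals"; the testing function accepts any
pre-computed proportion column, so alternative statistics are pluggable
upstream.

## Diet

Replicate isotope measurements from different laboratories are averaged
per analyte (the standard plotting rule when multiple measurements exist);
replicates more than 2‰ apart warn but still average, and inter-laboratory
normalization beyond averaging is out of scope. The group comparison is a
two-sided Mann–Whitney test: U by pairwise comparison with half-credit for
ties, exact p for min(n) ≤ 25 without ties, otherwise the tie-corrected
normal approximation with continuity correction (the method used is
recorded in the output). Both lab-averaged and single-laboratory modes are
available; averaging is the default. Diet classes are interpretive
brackets on δ¹³C — below −18‰ "C3", −18 to −14‰ "mixed C3/C4", above
"C4-influenced", boundaries belonging to the upper class — chosen to
bracket the descriptive ranges reported for C3 consumers and
millet-influenced diets; they are configuration, not science, and are
exposed as parameters.

## Chronology

Calibration evaluates, on a 1-year calendar grid under a uniform prior,
posterior(t) ∝ exp(−(m − μ(t))² / 2(σ² + σ_curve(t)²)), normalizes to
unit mass (conserved to 10⁻⁹), and reports the smallest density-threshold
region holding ≥ 95.4% of the mass — possibly several disjoint intervals
when the curve wiggles through the measurement more than once. Endpoints
are converted to years CE (CE = 1950 − cal BP) and rounded to the nearest
5 years, matching the printing convention of the source tables; intervals
abutting the curve's recent end are flagged open-ended. Reference curves
are not bundled (they are external datasets); the reader accepts the
standard ".14c" column layout, and all tests run on synthetic curves.

The minimum number of depositional events consistent with a set of
calibrated intervals is the interval-piercing number: the smallest set of
calendar points such that every interval contains one. The greedy sweep on
right endpoints is provably optimal for intervals and is verified against
a brute-force oracle on small sets. Open-ended intervals are capped at the
curve's recent limit (default 1950 CE), which is conservative — it can
only lower the event count. This count is a *lower bound* on depositional
events, not an estimate of their number.

## The synthetic-data generator

The generator exists so that every stage is testable without external
data. Its defaults are the study conditions the package models: three
ancestry groups of 23, 14 and 1 individuals; per-sample coverage drawn
log-uniformly on 0.026–1.547× (the published range; the published mean
0.51× sits near the log-midpoint, and the shape within the range is a free
choice the source does not constrain); terminal damage rates near 5%
(published range 0.025–0.071); contamination 0.5%; two depositional
clusters ~1000 years apart (≈800 CE and ≈1800 CE, within-cluster standard
deviation 50 years); group δ¹³C means of −16‰ (varied, C4-influenced) and
−19.1‰ (C3), with measurement noise 0.2‰.

Population structure follows the Balding–Nichols model: ancestral
frequency p per SNP, population frequency Beta(p(1−F)/F, (1−p)(1−F)/F),
so the expected pairwise Hudson F_ST between populations with drift F is F
itself — the model is parameterized directly by the quantity the
estimators recover. A fixed nested topology ((S1,O3),(S2,O4)) with plain
outgroups, plus gene-pool mixtures, provides the non-exchangeable
structure that f4-based tests need. Damage is simulated only as 5′
terminal C→T (the 3′ G→A mirror is a flag, default off); contamination is
a single designated contaminant haplotype per sample — the simplest model
the estimators can detect; X-chromosome simulation places the panel major
allele on endogenous haplotypes so that minor-allele observations measure
contamination plus error, which is exactly the moments model the estimator
inverts. All randomness flows from one cohort-level seed through fixed
per-sample substreams, so equal seeds give byte-identical output.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: realistic fragment-length and
base-quality distributions, strand-asymmetric damage profiles along the
read, reference bias, linkage disequilibrium within jackknife blocks,
haplotype structure, heterogeneous contamination sources, marine-reservoir
or dietary radiocarbon offsets, and real calibration-curve shapes.

## Problem sizes and numerical choices

The test and acceptance runs use simulation sizes chosen to make the
statistical tolerances meaningful on one CPU: 50,000 SNPs for F_ST and
admixture recovery, 10,000 SNPs × 200 replicates for cladality test size,
50,000 SNPs × 20 replicates for its power, 2000 replicate calibrations for
HPD coverage, 200 simulated males for Y-caller accuracy, and a ~4000-SNP,
38-sample cohort for the end-to-end pipeline. Grid resolutions (0.001 for
the mixture weight, 1 year for calendar posteriors) are below the
reporting precision of the corresponding quantities. Ties are broken
deterministically everywhere (input order for reads, shallower node for
trees, lowest-index centroid for grouping) so that identical inputs give
identical outputs.

## Known limitations

Position-only mtDNA matching cannot separate lineages whose printed
mutation sets coincide; the packaged panel contains six such collisions.
The contamination and match-rate estimators are simplified stand-ins that
preserve decision variables, not drop-in reimplementations of the
likelihood tools used on real reads. The cladality machinery implements
only the rank-0 test. Projection shrinkage is uncorrected. Event counts
are lower bounds. And all statistical guarantees quoted by the test suite
are statements about the generator's assumptions, not about any particular
archaeological dataset.
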