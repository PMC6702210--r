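# multiproxy

Multi-proxy analysis of commingled skeletal assemblages: ancient DNA,
stable isotopes and radiocarbon in one tested R pipeline.

## The problem

Disturbed deposits of commingled human remains — the motivating case is the
several hundred skeletons scattered around a high-Himalayan lake — cannot be
read with ordinary archaeological stratigraphy. Three independent
biomolecular proxies can: genome-wide ancient DNA places each individual in
an ancestry group and determines genetic sex and uniparental lineages;
stable isotope ratios (δ¹³C, δ¹⁵N) of bone collagen record diet in the last
decades of life; and calibrated radiocarbon dates constrain when each
individual died. `multiproxy` implements that full analysis chain for
low-coverage, pseudo-haploid ancient-DNA data, and ships a synthetic-cohort
generator so that every stage is testable end-to-end with no external data.

## What is implemented

* **Read-level QC** — duplicate-molecule removal keyed on (start, end,
  orientation, library barcode); pseudo-haploid calling (MAPQ ≥ 10,
  base quality ≥ 20, two bases trimmed from each read end, one random read
  per site); the three authenticity tests: terminal C→T deamination rate
  (≥ 3% for partial-UDG libraries), mitochondrial consensus match rate via a
  two-component read-likelihood mixture (≥ 97%), and an X-chromosome
  contamination estimate for males (≤ 1.5%); genetic sexing from
  R_y = #Y/(#X+#Y).
* **Haplogroups** — mtDNA assignment from rCRS mutation lists by
  position-set scoring on a mutation-annotated tree; Y-chromosome
  assignment by breadth-first tree search in which a marker observed
  derived adds +w and ancestral −w along the path, with w = 1/3 for
  transitions (deamination mimics them) and 1 for transversions.
* **Population structure** — reference PCA with least-squares projection of
  missing-data samples; nearest-centroid / k-medoids grouping; Hudson F_ST
  with the haploid ("inbreed") correction; f4-statistics
  f4(A,B;C,D) = E[(p_A−p_B)(p_C−p_D)] with weighted block-jackknife errors;
  a rank-0 cladality test (qpWave-style); two-way admixture weights by
  generalized least squares on f4 vectors (qpAdm-style); a pairwise
  mismatch kinship scan.
* **Sex-biased ancestry** — permutation test of mean ancestry-proportion
  differences between genetic males and females.
* **Diet** — replicate merging across laboratories, exact/tie-corrected
  two-sided Mann–Whitney comparison of δ¹³C between groups, C3 / mixed /
  C4-influenced classification.
* **Chronology** — radiocarbon calibration against any ".14c"-layout curve
  under a uniform calendar prior, 95.4% highest-posterior-density interval
  sets, and the minimum number of depositional events as an
  interval-piercing problem solved by the (optimal) greedy sweep.
* **Simulation** — Balding–Nichols panels parameterized by F_ST, read
  simulation with coverage, terminal damage, contamination, duplicates and
  sex-consistent X/Y reads, lineage-marker simulation on haplogroup trees,
  isotope and radiocarbon measurement simulation, and an end-to-end
  `run_pipeline()` that mirrors the study design (ancestry groups of
  23/14/1, coverage 0.026–1.547×, two depositional clusters ~1000 years
  apart).

The package also ships machine-readable transcriptions of the published
per-individual data tables (`roopkund_dossier()`, `roopkund_mt_panel()`)
and a haplogroup tree built from the printed mitochondrial lineages
(`roopkund_mt_tree()`).

## Worked example

```r
library(multiproxy)

d <- roopkund_dossier()
s <- summarize_dossier(d)
s
#> <dossier_summary> 38 individuals
#>   coverage 0.51x (range 0.026-1.547); SNPs 350089 (range 30592-728448)
#>   sex: F=15 M=23
#>   groups: Roopkund_A=23 Roopkund_B=14 Roopkund_C=1
#>   dated: 37
#>   d13C Mann-Whitney Roopkund_A vs Roopkund_B: U = 262.0, p = 0.000225 (normal_tie_corrected)
#>   minimum depositional events: 4 overall (Roopkund_A: 3, Roopkund_B: 1, Roopkund_C: 1)
```

The 38 individuals average 0.51× coverage on the SNP capture and split into
three ancestry groups (23 South-Asian-related, 14 eastern-Mediterranean-
related, 1 Southeast-Asian-related). The δ¹³C distributions of the two main
groups differ decisively (p ≈ 2.3 × 10⁻⁴): the large group ate substantial
C4 (millet-type) food, the second group a C3 terrestrial diet. The
calibrated date intervals cannot be covered by fewer than four depositional
moments overall — the early group alone needs at least three, about a
millennium before the late group, whose intervals are mutually consistent
with a single event:

```r
dated <- d[!is.na(d$cal_from), ]
iv <- tibble::tibble(sample = dated$sample_id, from = dated$cal_from,
                     to = dated$cal_to, open_ended = dated$cal_open)
minimum_events(iv[dated$group != "Roopkund_A", ])
#> <event_count> minimum 1 depositional event(s); witnesses: 1915
```

A synthetic assemblage with the same design runs end to end in under a
minute:

```r
res <- run_pipeline(pipeline_config(seed = 1))
table(res$dossier$group, res$truth$population)   # exact recovery
res$summary$events_overall$n_events              # >= 2 events detected
```

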