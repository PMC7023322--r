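---
title: "Methods: the windowed selection-signature scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the windowed selection-signature scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# Scope and model

`sweepscan` detects candidate selective sweeps by comparing a focal
population (the group hypothesised to be under directional selection)
against a background population of the same species, from unphased diploid
genotypes at biallelic SNPs.  Three signals are combined, each computed in
sliding windows over genomic coordinates:

1. **Population differentiation.**  Per SNP we compute the Weir–Cockerham
   variance components for two populations: $a$ (among populations), $b$
   (among individuals within populations) and $c$ (within individuals),
   from each group's genotyped sample size $n_i$, ALT allele frequency
   $p_i$ and observed heterozygote fraction $h_i$.  The window estimate is
   the "weighted" ratio of sums $\hat\theta_W = \sum a / \sum (a+b+c)$ over
   the window's polymorphic SNPs.  Ratio-of-sums (rather than the mean of
   per-SNP ratios) is the standard windowed form: it is far less noisy at
   SNPs with low minor allele frequency and is the estimator windowed-scan
   tools report.  Window values are then standardised genome-wide
   ($Z(F_{st})$, zero mean, unit sample SD over defined windows).

2. **Diversity loss.**  Per-group nucleotide diversity
   $\theta_\pi$ adds, over the SNPs in a window, the mean pairwise
   difference among the group's observed alleles,
   $2 c_{ref} c_{alt} / (c (c-1))$, and divides by the *full window span in
   bp*.  Dividing by the span (not the SNP count) matches the convention of
   the windowed-diversity tools this scan mirrors and makes windows
   comparable; a windowless alternative can be had by running
   `windowed_pi()` on a single whole-chromosome window.  The ranking
   statistic is $\log_2(\theta_\pi^{bg} / \theta_\pi^{focal})$: positive
   when the focal group has lost diversity.

3. **Site-frequency-spectrum validation.**  Tajima's
   $D = (\Pi - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}$ in the focal group,
   where $\Pi$ is the window's mean pairwise difference count, $S$ its
   number of segregating sites, and $a_1, e_1, e_2$ the standard constants
   for $n$ haplotypes.  A sweep leaves an excess of rare variants and hence
   negative $D$.

The decision rule: take the upper $q$ (default 1 %) of windows by
$Z(F_{st})$ and independently by the log2 ratio; intersect by exact window
identity (both statistics live on one grid); keep shared windows with
$D \le 0$.  Windows with undefined $D$ (no segregating sites in the focal
group) are excluded from the final set: with $S = 0$ there is no SFS
evidence to validate, and such windows are typically fixed-difference
artefacts of small samples.  The final windows are annotated with
overlapping genes, intersected with runs of homozygosity, and optionally
tested for gene-set over-representation (one-sided Fisher exact test with
Benjamini–Hochberg FDR over user-supplied GMT sets — a deliberately
self-contained replacement for web-based GO services, whose databases
change release to release).

## Assumptions

* Sites are biallelic SNPs with known REF/ALT; phase is never used, so all
  statistics are functions of allele counts and genotype dosages.
* Windows are defined by coordinates, anchored at position 1 of each
  chromosome, with the last windows allowed to extend past the final SNP.
  Window content is a pure function of the SNPs inside it.
* Tajima's D constants use the full group haplotype count even when some
  sites have missing calls; per-site contributions use observed alleles.
  The approximation error is bounded by the upstream 10 % missingness QC,
  which is why the QC step precedes the scan.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_size_bp` | 100 000 | bp | window span for every windowed statistic |
| `step_bp` | 50 000 | bp | distance between window starts (50 % overlap) |
| `q` | 0.01 | fraction | upper tail taken from each ranking statistic |
| `maf_min` | 0.01 | frequency | minor-allele-frequency floor |
| `hwe_p_min` | 0.001 | p-value | Hardy–Weinberg exact-test floor |
| `site_call_rate_min` | 0.9 | fraction | per-site genotyping floor |
| `sample_call_rate_min` | 0.9 | fraction | per-sample genotyping floor (individuals missing more than 10 % are dropped, strictly greater) |
| ROH `window_snp/het/missing` | 50 / 1 / 5 | SNPs | scanning-window size and tolerance |
| ROH `gap_kb`, `density_kb_per_snp` | 1000, 50 | kb | run splitting and density check |
| ROH `min_snp`, `min_kb` | 100, 1000 | SNPs, kb | minimum reportable run |
| ROH `window_threshold` | 0.05 | fraction | minimum homozygous-window hit rate per SNP |
| LD `max_dist_bp`, `bin_bp` | 300 000, 10 000 | bp | pair distance limit and curve bins |

These defaults are the canonical whole-genome resequencing settings for
this kind of two-group scan (PLINK's `--homozyg` defaults for ROH; 100-kb /
50-kb windows and a 1 % tail for the selection statistics); the QC
thresholds are the ones customarily applied to medium-coverage resequencing
before such scans.  All of them are plain arguments (`qc_config()`,
`roh_params()`, `pipeline_config()`) or YAML keys
(`read_pipeline_config()`).

The Hardy–Weinberg test is the exact conditional test (the distribution of
the heterozygote count given the allele counts), not the chi-square
approximation: group sizes in two-cohort designs are small enough that the
asymptotic test misbehaves, and the exact test can be verified against
complete enumeration.  The paper-style "genotype frequency" filter is
implemented as the site call-rate filter (site missingness below 10 %), the
most common reading in standard pipelines; GATK-style annotation filters
(MQ, QD, FS, MQRankSum, mean GQ) apply per site and only when the VCF
actually carries those fields — absent fields are skipped and logged.

# The synthetic-data generator

`simulate_two_pop_dataset()` emulates the statistical structure the scan
assumes, not a full evolutionary history:

* **Background differentiation** is Balding–Nichols: an ancestral ALT
  frequency $p \sim U(0.05, 0.95)$ per SNP, each population's frequency
  drawn from $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, genotypes
  $\mathrm{Binomial}(2, q)$, independent across sites.  The Beta parameter
  $F$ *is* the Weir–Cockerham $F_{st}$ between the two populations, which
  gives a closed-form target for parameter-recovery tests.
* **Sweeps** are planted phenomenologically in grid-aligned 100-kb
  windows: most focal-group sites are fixed (pushed toward ALT with
  probability $\min(1, p + \mathrm{shift})$), and a calibrated fraction
  stays polymorphic at minor-allele counts 1–2 so that the focal group's
  expected diversity drops by the configured factor (default 5×) with an
  SFS skewed to singletons, i.e. negative Tajima's D.  The background
  group is untouched.  Planting the *signatures* rather than forward-
  simulating selection keeps effect sizes controllable and the tests fast.
* **Defaults** mirror a real two-cohort resequencing design: 16 vs 35
  diploids, 20 chromosomes × 5 Mb, 1 SNP/kb, $F = 0.05$, 10 sweeps.
* **Determinism**: one RNG stream per chromosome, all derived from the
  single config seed; the caller's RNG state is saved and restored.
  The written VCF re-reads into the identical genotype matrix.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: linkage disequilibrium along the chromosome
(background sites are independent; a separate two-locus sampler,
`simulate_linked_pair()`, calibrates the LD estimator), recombination
gradients, demographic history (bottlenecks, admixture, uneven relatedness
within groups), genotyping error and missingness structure, and a
coalescent-shaped site-frequency spectrum for the background.  That last
point matters for interpretation: with uniform ancestral frequencies the
background SFS is rich in intermediate-frequency variants, so background
windows have *positive* Tajima's D.  The $D \le 0$ validation step is
therefore conservative on simulated data (sweep windows are driven well
below zero and the tests assert that separation), while neutral-expectation
calibration of $D$ itself is done where it is valid — on the package's
coalescent window sampler, `simulate_coalescent_window()`, which implements
the standard neutral coalescent with infinite-sites mutation
($E[S] = \theta a_1$, $E[\Pi] = \theta$).

A caveat worth recording: at $n = 20$ haplotypes and $\theta = 10$ the true
expectation of Tajima's D under neutrality is not 0 but about $-0.09$ (the
normalisation fixes the variance near 1, not the mean at 0; the package's
estimate and an independent coalescent simulator agree on this value).
Tests of "D centred at 0" at these settings can only hold to within that
bias.

# Numerical and design choices

* **Ranking tail.**  Ranking uses *signed* $Z(F_{st})$ — the hypothesis is
  directional (selection in the focal group) — with an `absolute = TRUE`
  flag for the two-tailed variant.  At the 1 % tail the two give the same
  positive-side threshold on symmetric-looking genome-wide distributions.
* **Quantile convention.**  The top-$q$ threshold is the linear-
  interpolation empirical quantile (R type 7); every window at or above it
  is selected, so ties all enter (deterministic and order-independent).  A
  `fixed_count = TRUE` option selects exactly $\lceil qN \rceil$ windows
  instead, for users who prefer a fixed-size candidate list.
* **Degenerate ratios.**  A window with zero focal diversity but positive
  background diversity maps to $+\infty$: it is the strongest possible
  diversity-loss signal, is always selected, and never enters the quantile
  computation.  Windows with zero diversity in both groups are undefined
  and excluded from ranking, as are windows with no polymorphic SNPs for
  $F_{st}$ (scan tools only emit windows containing SNPs).
* **No clamping of $F_{st}$.**  Slightly negative window estimates are kept
  as-is before Z-transformation; clamping would distort the genome-wide
  mean and SD while leaving the top tail unchanged.
* **ROH.**  The scanning-window algorithm follows PLINK `--homozyg`:
  per-SNP hit rates against a 0.05 threshold, runs split at inter-SNP gaps
  above `gap_kb`, an average-density check (`length_kb / n_snps`
  $\le$ `density_kb_per_snp`) and the `min_snp`/`min_kb` floors.  Segment
  coordinates are first/last SNP positions.  Chromosomes with fewer SNPs
  than one window yield no calls and are logged.
* **LD.**  Composite (genotype-dosage) $r^2$ over pairwise-complete
  samples, since the data are unphased; monomorphic sites are skipped.
  Above $10^6$ pairs per chromosome a seeded uniform pair subsample is
  taken; everything else is exact and bit-for-bit reproducible.  Under
  independence $E[r^2] \approx 1/(n-1)$, the finite-sample floor the tests
  check.
* **Trees.**  The distance is allele-sharing
  (mean $|d_i - d_j|/2$ over co-called sites — simple, bounded, phase-free);
  neighbor joining is the Saitou–Nei agglomeration, for which tree-additive
  distances are reconstructed exactly — the main oracle used in testing.
  Negative NJ branch lengths (possible on non-additive input) are clamped
  to zero with a warning and a count attribute.
* **QC order.**  MAF → HWE → call-rate → annotations, then sample QC, once,
  no iteration; each filter sees only survivors of the previous one so the
  removal counts add up exactly.  Filtering is idempotent.
* **Window grid.**  Starts at 1, 1+step, … on each chromosome for every
  start not exceeding the chromosome's maximum position; the final windows
  may extend past the last SNP.  All windowed statistics share one grid, so
  "shared windows" is exact identity, not bp overlap.

# Problem sizes used in the tests

The suite validates each statistic against independent brute-force
implementations on hundreds of random small instances (up to 10 samples ×
50 sites; up to a few thousand SNPs for ROH), calibrates the coalescent
sampler with 2000 replicates at $n = 20$, $\theta = 10$, recovers
Balding–Nichols $F \in \{0.05, 0.1, 0.2\}$ from 2000-site simulations with
16 + 35 diploids, and runs the full pipeline on the generator's default
20 × 5 Mb genome (100 000 SNPs, 10 planted sweeps), checking that at least
8 of 10 planted windows reach the final candidate set and that the nested
set inclusions hold.  These sizes were chosen to exercise every code path
at full statistical fidelity on a desktop-class machine.

# Known limitations

* Haplotype-based statistics (iHS, XP-EHH) and per-site $F_{st}$ output are
  out of scope; so are BCF input, structural variants and phased analyses.
* The enrichment test is a generic over-representation test over
  user-supplied gene sets; it does not fetch or version any annotation
  database.
* With very small groups (2–3 diploids) the Weir–Cockerham components and
  Tajima's D variance constants are defined but noisy; the scan's defaults
  assume cohorts of at least ~10 diploids per group.
* ROH detection assumes WGS-scale SNP density; on sparse array data the
  density and size defaults must be relaxed, exactly as with the original
  PLINK parameters.
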