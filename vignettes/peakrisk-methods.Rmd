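---
title: "Methods: matched-peak enrichment of GWAS variants in binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-peak enrichment of GWAS variants in binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakrisk)
```

## The problem and the model

Transcription-factor ChIP-seq yields a set of binding peaks; GWAS yields
index SNPs tagging risk haplotypes. The question `peakrisk` answers is
whether the risk variants — index SNPs plus their linkage-disequilibrium
(LD) proxies — overlap the peak set more often than chance placement of
peaks would allow.

The test statistic is deliberately simple: the number of **distinct**
variants lying inside at least one peak (a variant covered by two
overlapping peaks counts once, so peak merging is irrelevant). The null
model re-places each peak uniformly at random on **its own chromosome with
its own length**, leaving the variant positions fixed. Matching chromosome
and length controls for the two dominant covariates of interval overlap —
per-chromosome variant density and total covered base pairs — without
assuming anything about the overlap distribution. Simulated peaks are
placed independently and may overlap each other; an exclusion rule would
change the null only at the third decimal for realistic densities while
making it analytically opaque.

With `n_sets` null replicates and `x` of them reaching the observed count
(exceedance, counted with `>=` by default; a strict `>` flag is provided,
and the two coincide when `x = 0`), the package reports:

* `p_empirical = x / n_sets` — the plain permutation estimate;
* `p_addone = (x + 1) / (n_sets + 1)` — the add-one estimate, which is
  never exactly zero;
* the **Wilson score interval** on the exceedance proportion at
  `conf_level`.

Both point estimators are emitted because, at zero exceedances, no single
point estimate is satisfactory: `0/n` understates uncertainty and the
add-one estimate depends on `n` alone. The Wilson interval is the stable
summary — its upper bound at `x = 0` is `z²/(n + z²)`, e.g. 0.00038 for
`n = 10000` at 95% — and is what the acceptance machinery checks. The
lower bound at `x = 0` is set to exactly 0 (the closed form guarantees it;
floating-point evaluation is clamped).

## LD proxy expansion

r² between two biallelic variants is computed by direct counting on phased
0/1 haplotype columns: `r² = D²/(pA(1−pA)pB(1−pB))`, `D = pAB − pA·pB`.
No EM estimation is attempted: the intended substrate is phased panels
(reference-panel genotypes or the package's own generator), where counting
is exact. Monomorphic columns are an error, multi-allelic sites are
rejected at panel construction, and the value is invariant under swapping
the 0/1 labels of either column — all properties under test.

`expand_index_snps()` searches a window of 1 Mb each side of the index
position (the conventional LD horizon; configurable) and keeps proxies
with `r² >= r2_min`, ties at the threshold included. Each index variant is
its own proxy with r² = 1, so the expanded set always contains the index
set, and proxy sets nest as the threshold is lowered — the property behind
threshold-sensitivity analyses at 0.2 / 0.5 / 0.7.

## Peak-to-gene assignment and primary target calling

A gene receives a peak if the peak overlaps the half-open window
`[TSS − w, TSS + w)` (default `w` = 50 kb) **or** overlaps the gene body
`[start, end)`. The two clauses are kept separate on purpose: the window
anchors on the transcription start site only, and the body clause catches
intragenic peaks arbitrarily far from the TSS. The TSS is strand-aware
(`start` for `+`, `end − 1` for `−`); `ignore_strand = TRUE` reproduces
the naive plain-start alternative, since public peak-to-gene recipes are
often ambiguous on this point.

A gene is *regulated* at a timepoint when its BH-adjusted p-value is at or
below `alpha` (boundary included; no fold-change floor); *same-direction*
when regulated at both timepoints with equal nonzero sign of log
fold-change; *primary* when additionally it has at least one assigned
peak. Genes present in only one table are treated as unregulated at the
missing timepoint and reported via a message, not an error — expression
tables routinely differ in gene universe.

Nearest-TSS distances (for the distance profile) are signed from the peak
midpoint, negated on the minus strand so positive always means downstream;
equidistant genes tie-break on the lexicographically smaller id, making
the profile deterministic.

## Motif co-occurrence

The observed statistic is the fraction of A-instances whose start lies
within `max_dist_bp` (default 100) of some B-instance start, with
positions resolved from window-relative offsets. Distances are
start-to-start: the instance TSV carries no motif length, so start
anchoring is the only choice that needs no extra input; a `motif_length`
parameter (default 1 bp) bounds the valid offsets in the null instead.

The null re-draws every instance's (window, offset) uniformly — window
uniform over all windows, offset uniform over valid offsets — preserving
instance counts per motif type exactly. This is a design choice, not a
published recipe: "random coincidence" is underdetermined, and uniform
re-placement within the scanned windows is the weakest assumption that
preserves the marginal instance density. The expected coincidence rate is
the mean over permutations and the empirical p the fraction of
permutations at or above the observed fraction.

## Tissue statistics

* **Pfaffl ratio** `R = E_t^ΔCt_t / E_r^ΔCt_r`, ΔCt = Ct(calibrator) −
  Ct(sample). With both efficiencies 2 this is algebraically `2^−ΔΔCt`
  (tested over a grid to 1e−12). Efficiencies ≤ 1 are errors; values just
  above 2 (super-doubling) only warn, since standard-curve estimates
  overshoot slightly in practice. The calibrator only rescales R by a
  constant, so carrier-vs-noncarrier comparisons are calibrator-invariant.
* **IHC score**: per core, mean intensity × percent positive cells; per
  patient and tissue, the mean over the available (≤ 3) cores. Mixing
  tissue types in one call is an error — benign and cancer cores are
  scored separately by design.
* **Group comparisons** use Welch's unequal-variance t-test, Pearson
  correlation with the t-transform p-value, and Pearson's chi-square
  without continuity correction, all via the standard R implementations;
  the package adds input validation (degenerate groups, zero marginals)
  and tidy one-row outputs. Genotype stratification defaults to the
  dominant carrier model (heterozygotes pooled with minor homozygotes),
  with a per-genotype summary alongside; strata with fewer than two
  patients in a group are skipped with a warning rather than producing an
  unstable test. No multiple-testing correction is applied across strata;
  each comparison is reported on its own.

## The synthetic generator: what it emulates, and what not

The generator's defaults define the package's reference study conditions:

| quantity | default | why |
|---|---|---|
| genome | 4 × 2.5 Mb | 10 Mb total; large enough for ~1% peak coverage |
| peaks | 300, log-normal lengths, median 300 bp | ChIP-seq-like length spread; ~1% of the genome covered |
| peak scores | 30 + Exp(70) | a heavy right tail straddling the score-50 cutoff |
| variants | 200 (10 index + 190 background) | desk-scale risk-SNP set |
| planted in-peak fraction | 0.3 | clearly detectable, not saturated |
| haplotypes | 120; blocks of 6; flip rate 0.05/column | r² decays with block distance |
| DE tables | 120 planted primaries + 80 decoys | decoys cover every failure mode of the calling rule |
| cohort | 100 patients, MAF 0.13, β = −1 SD | Hardy-Weinberg genotypes; dominant-model effect |
| motifs | 60 A / 30 B over ~300 windows, 20 planted pairs | B sparse relative to windows, as motif hits are relative to scanned regions, so the null coincidence (~10%) sits below the planted rate (~33%) |

Planting is exact, not in expectation: `round(f·n)` variants are placed
inside peaks, the rest **outside** them by rejection sampling, with all
positions globally distinct — so overlap counts, primary-target sets and
carrier groups can be asserted exactly against ground truth. LD is
block-copy with per-column flips: r² within a block decays with copying
distance, across blocks it is independent. This exercises the r²
machinery fully but is not a coalescent model — no recombination gradient,
no allele-frequency spectrum, no population structure. Likewise the
genome has no gaps, no blacklist regions, no GC or mappability texture:
passing the planted-signal tests shows the *machinery* is correct, not
that chromosome/size matching is a sufficient null for any particular
real genome (an exclusion-list option on the null is the first thing to
reach for when it is not).

Calibration studies use `uniform_variants()` — positions uniform over the
whole genome, peaks included — because under strictly-outside placement
the observed count is identically zero and a p-value distribution cannot
be probed. qPCR Ct values are back-computed from the latent expression
through the Pfaffl relation at the configured efficiencies, with Gaussian
noise in Ct space (the natural measurement scale), so the analysis path
recovers the planted effect exactly when noise is switched off.

## Numerical and reproducibility choices

* Coordinates: peaks and genes 0-based half-open (BED); variants 1-based
  (VCF), converted internally. Chromosome matching is exact string
  equality; `normalize_chrom()` converts styles explicitly, never
  implicitly.
* The score filter is strict (`score > 50`), and the TSS window is
  half-open `[TSS − w, TSS + w)`, consistent with the half-open geometry
  everywhere else.
* Interval overlap runs on IRanges; equality with a naive O(n·m) double
  loop is asserted in the test suite on randomized instances.
* One integer seed drives everything. Stochastic stages take explicit
  seeds; `simulate_study()` and `run_study()` derive per-stage child
  seeds from the master seed with a fixed multiplicative scheme (kept
  below 2³¹). Null sets are generated in large vectorized batches from a
  single seeded stream rather than per-set substreams — at the package's
  problem sizes a single stream is faster and equally reproducible; the
  batch size only chunks memory and does not affect the draw sequence.
  The caller's RNG state is saved and restored around every seeded
  operation.
* Problem sizes in the test suite: calibration uses 200 replicates at 500
  null sets; power uses 50 replicates at 1,000 null sets; genotype
  recovery uses 100 + 200 cohorts of 100 patients; LD oracle equivalence
  uses 1,000 random column pairs. The full-scale setting (`n_sets =
  10000`) is the default of `enrichment_test()` itself.

## Known limitations

* The null matches chromosome and size only — no GC, mappability or
  distance-to-TSS matching as in covariate-matched samplers; for peak
  sets with strong sequence-composition bias the test will be
  anticonservative, and the optional exclusion of known-unmappable
  regions is the minimum mitigation.
* r² requires phased haplotypes; unphased genotype data would need an EM
  step that is deliberately out of scope.
* The motif null randomizes placement, not sequence: it cannot detect
  co-occurrence driven by sequence composition inside windows.
* The empirical p-value is bounded below by `1/n_sets`; at the default
  10,000 sets, claims below 1e−4 rest on the Wilson interval, not the
  point estimate.
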