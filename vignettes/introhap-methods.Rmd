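---
title: "Methods: haplotype-based analysis of exotic introgression in topcross pre-breeding lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based analysis of exotic introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pre-breeding programs introgress diversity from gene-bank accessions
("exotics": landraces, synthetic hexaploids, wild-relative derivatives) into
elite wheat germplasm through three-way topcrosses, exotic/elite1//elite2,
selfed to fixation (TC1F5 and beyond). Two questions drive the analysis this
package implements:

1. **How much exotic genome did the derived lines actually retain?** Under
   Mendelian expectation a topcross line carries 25% exotic and 75% elite
   genome; selection during line advancement can push the realized
   contribution below that.
2. **Did the exotics contribute rare, favorable haplotypes** — low-frequency
   allele combinations with a beneficial effect under stress (e.g. heat)
   and no penalty under favorable conditions, not explained by phenology?

Because SNP panels for such populations are typically not deposited, every
stage here is paired with a forward simulator of the breeding scheme that
carries per-segment ancestry truth, so each estimator can be validated
against a known answer.

## Pipeline overview

```
simulate (or load)  →  marker QC  →  haplotype blocks  →  origin tracing
                                              ↓                 ↓
                                      mixed-model scan  →  rare-haplotype screen
```

Each stage is an exported function; `run_pipeline()` chains them and writes
TSV artifacts plus a JSON manifest with seed, timings and output checksums.

## The synthetic topcross simulator

`simulate_topcross()` draws fully inbred founders, performs
F1 = exotic × elite1, topcrosses F1 × elite2, then selfs by single-seed
descent for `selfing_generations` (default 4) generations. Meiosis follows
the Haldane model: crossover counts per chromosome are Poisson with mean
length/100 cM, positions uniform, no interference — interference is
irrelevant at the map resolution analyzed here. Every line records, per
marker and chromatid, which founder role (exotic, elite1, elite2) the
segment descends from; this ancestry truth is the oracle for all
origin-tracing checks.

Defaults emulate the study system: 21 chromosomes of 150 cM, ~95 markers
each (~2,000 total), 10 crosses × 30 lines = 300 lines, elite pairwise
divergence 0.05 (a narrow breeding pool), exotic divergence 0.30. The
10 × 30 cross plan mirrors a parent-of-origin analysis design (few crosses
with many progeny each); association-scan experiments instead use
30 crosses × 10 lines, emulating a panel drawn from many small crosses,
which is the regime where haplotype effects are separable from family
structure.

Two founder models are available. The default (`"iid"`) draws founder
alleles independently per marker so that pairwise difference rates equal the
configured divergences exactly; it is the model under which the closed-form
expectations (25% exotic; het rate $0.5 \cdot 2^{-g}$ at informative loci)
are tested. The `"mosaic"` model builds founders as segmental mosaics of a
small ancestral-haplotype pool (3 elite vs 12 exotic ancestors by default),
which creates realistic linkage structure *within* founder panels — long
shared elite haplotypes versus shorter exotic ones — at approximately the
configured divergences. The mosaic model is what makes the "fewer, larger
blocks in elites" contrast reproducible in simulation; the iid model cannot
produce founder-panel LD at all.

Phenotypes are environment mean + planted haplotype-class QTL effects
(active in configurable environments only) + a kinship-structured polygenic
term (drawn once per trait, shared across environments) + Gaussian residual.
For fully inbred lines the VanRaden kinship diagonal is ≈ 2, so a polygenic
variance parameter $\sigma^2_{poly}$ contributes ≈ $2\sigma^2_{poly}$ of
phenotypic variance. The planted-QTL experiments use a residual-dominated
trait (polygenic share ≈ 15% of phenotypic variance): the package's power
expectations for a 10%-frequency, one-SD effect at n = 300 are only
attainable — for *any* calibrated test — when the trait is not strongly
structured, and a line-mean trait from replicated managed trials is
plausibly in that regime. The planted block uses the tightest available
marker run, emulating the physically compact rare-haplotype blocks the
screen is designed for and avoiding dilution of the joint F test by
recombinant classes. What the simulator does **not** model: genotyping
error beyond uniform missingness, mutation, segregation distortion,
epistasis, and genotype-by-environment interaction beyond on/off QTL
activity — so passing tests validate estimator logic, not robustness to
those artifacts.

## Marker and line QC

`qc_filter()` applies, in order: lines with > 75% missing calls removed;
markers with minor allele frequency < 0.05 removed; a Hardy–Weinberg exact
test at p < 0.001 *when engaged* (see below); co-located markers (same
chromosome and cM) reduced to the first in map order, since fully
correlated positions carry no extra blocking information.

A panel of selfed TC1F5 lines violates Hardy–Weinberg proportions at every
marker by construction (heterozygote deficit), so a literal HWE filter would
discard the entire panel. `hwe_mode = "skip_inbred"` (default) therefore
disables the filter automatically when the panel heterozygous call rate is
below 2%; `"apply"` enforces the exact test literally for outbred panels.

## Haplotype blocks

Blocks are built by the confidence-interval D′ rule. For every marker pair
within `ld_window` (default 5 cM — read as a hard pairwise window, the only
interpretation that yields a deterministic rule), two-locus haplotype
frequencies are estimated by EM (`em_haplotype_freqs()`): phase-known
configurations are counted directly and double heterozygotes are split
between coupling and repulsion phases, iterated to |Δ| < 1e-8 (≤ 1000
iterations). On inbred panels the EM reduces exactly to gamete counting.

`dprime_ci()` computes D′ = |D|/D<sub>max</sub> and a 95% CI from the profile
multinomial likelihood over a 101-point D′ grid (allele frequencies held at
their estimates, sign of D fixed; bounds at the 5th/95th percentiles of the
normalized likelihood mass). Pairs are classified **strong LD** (upper bound
> 0.98 and lower bound > 0.70), **strong recombination** (upper bound
< 0.90, a bound taken from the block-definition literature and
configurable), else **inconclusive**. Monomorphic pairs are degenerate and
skipped.

A run of consecutive markers is accepted as a block when ≥ 95% of its
informative (non-inconclusive) pairs are strong LD. Accepted candidates are
ranked by marker count, then cM span, then leftmost position, and taken
greedily without overlap — a deterministic output contract, verified against
an exhaustive-interval oracle in the tests. Blocks are named
`HB<chromosome index>.<rank>` (1 = 1A ... 21 = 7D, ranks left to right).
Per-line haplotype classes are allele strings over member markers, assigned
only to lines fully homozygous at all members; class frequencies are
computed over assigned lines. `multiallelic_dprime()` summarizes
between-block recombination as the frequency-weighted mean |D′| over class
pairs, each from a 2×2 class-vs-rest collapse.

## Parent-of-origin tracing

`classify_abh()` codes each line×marker of a cross against its three
parents: a marker is informative iff all parents are homozygous, the elites
agree, and the exotic differs. Informative calls become **B** (exotic
homozygote), **A** (elite homozygote), **H** (heterozygous); everything else
is **U** (unidentified origin), kept distinct from missing because the two
enter denominators differently. `summarize_contribution()` reports raw
A/B/H/U/missing fractions and renormalized fractions among {A, B, H}; the
headline estimates split heterozygous calls evenly: exotic = B + H/2,
elite = A + H/2. Both denominators are always emitted because the choice
(include or exclude missing) changes the headline number by a few points.

`exotic_specific_blocks()` flags a derived-panel block as exotic-specific
when at least one of its observed classes occurs in the exotic parent panel
and in no elite parent (presence = ≥ 1 assigned line; parent panels are
small, so exact presence is the defensible rule; a majority-class variant is
available). The block-based imprint fraction is reported alongside the
SNP-based estimate; when elites and exotics share haplotypes the block-based
number is biased downward, which is why both are kept.

## Mixed-model association scan

Per trait × environment cell, `scan_features()`:

1. computes the VanRaden kinship K = WW′ / 2Σp(1−p) from mean-imputed,
   centered dosages (missing imputed for this computation only);
2. selects the number of principal-component covariates (0..`k_max`) by BIC
   on maximum-likelihood fits of the null mixed model — ML, not REML,
   because REML likelihoods are not comparable across fixed-effect
   structures; ties go to fewer components;
3. fits the null model y = Xβ + u + e, u ~ N(0, σ²g K), by the spectral
   reparameterization (one eigendecomposition, then one-dimensional
   optimization of the variance ratio with O(n) likelihood evaluations);
   REML components are used for testing;
4. tests each feature by P3D generalized least squares: V = σ̂²g K + σ̂²e I
   is held fixed, lines missing the feature are dropped for that test only
   (Cholesky on the line subset), and the block's class dummies (reference =
   most frequent class; classes under 1% pooled into `rare-other` to avoid
   rank deficiency) are tested jointly by an F test. With identity kinship
   and no covariates this reduces exactly to one-way ANOVA, the oracle the
   tests assert at 1e-9.

**LOCO kinship.** By default the kinship used for testing a feature excludes
the feature's own chromosome (leave-one-chromosome-out, computed cheaply by
subtracting per-chromosome cross-products from the global one). Without it,
the tested haplotype's own signal and its chromosome-mates inflate σ̂²g and
the polygenic correction absorbs part of the tested effect (proximal
contamination), costing most of the power against structure-aligned
haplotypes — exactly the exotic-introgression segments this package targets.
LOCO is standard practice in mixed-model association tools. Its cost is that
own-chromosome polygenic variance is uncorrected; at 21 chromosomes that is
1/21 of σ²g and simulation shows the permutation type-I error and genomic
inflation factor stay nominal. `loco = FALSE` restores the single global
kinship.

Significance is two-conditional: p at or below the scan threshold (the
empirical bottom-0.1-percentile of the scan's p-values by default, or a
fixed per-trait-family constant such as 0.001 for yield and 0.0001 for
disease traits) **and** deviation from uniformity in the QQ sense — the
observed p falls below the 5% pointwise band of the corresponding uniform
order statistic, Beta(i, n−i+1). The genomic inflation factor λ (median
χ² ratio) is reported per scan.

## Rare-haplotype screen

`class_profiles()` tabulates, per block class and trait × environment cell,
the class frequency, mean, carrier count, and differences against (a) the
best other adequately-supported class and (b) the block's most frequent
(reference) class with a standard error. Classes with fewer than `min_n`
(default 3) carriers are flagged low-support and excluded both from the
"best other" comparison and from candidacy — one or two outlier lines can
neither fake nor mask a difference.

`screen_rare_favorable()` nominates (block, class) pairs that are rare
(frequency ≤ 15%, a default chosen to cover single-digit-to-low-teens
carrier frequencies and configurable), significant for the target trait in
≥ `min_instances` environments, **not** significant for the confounder
trait (days to heading by default — a block whose apparent stress advantage
operates through earliness is excluded, and the confounder scan is
mandatory), leading the trait mean in at least one significant environment,
and free of penalties. A penalty requires the class mean to fall below the
reference class by more than `penalty_tol` (default 0.25) trait SDs *and*
by more than two standard errors of the class-mean difference: raw class
means at 20–30 carriers have SEs near 0.2 SD, so a tolerance alone would
flag spurious penalties in roughly one environment in five. Favorability is
deliberately defined on class means (as in the figures such screens feed),
with model effects attached for reference. Candidates are ranked by
favorable-instance count, then best p, then observed margin.
`consistency_matrix()` renders the scan as a feature × instance significance
grid with row sums.

## Numerical and degenerate-input choices

- Dosage coding 0/1/2 with per-marker allele labels; inbred panels live in
  {0, 2}.
- Marker order within a chromosome is (cM, marker id) — the lexicographic
  tie-break makes co-located-marker handling deterministic.
- EM tolerance 1e-8, 1000 iterations; D′ grid 101 points; both configurable.
- Constant traits yield zero variance components without division errors;
  monomorphic pairs, one-class blocks and empty panels return explicit
  degenerate signals rather than NaNs.
- All stochastic stages derive child seeds from one root seed per
  (operation, cross, line), so adding lines does not perturb existing ones,
  and identical seeds give bit-identical outputs.

## Problem sizes used by the test-suite experiments

Simulation-backed checks run at the full default genome (21 chromosomes,
~2,000 markers, 300 lines). The planted-haplotype recovery experiment uses
50 simulation replicates for the detection-power estimate and runs the full
block-scan-screen chain on 25 of them; unit tests use smaller panels (2–6
chromosomes, 100–300 lines) chosen so each check exercises its estimator at
meaningful sample sizes.

## Known limitations

- The 5 cM window reading caps block spans; panels whose true LD extends
  further will report several adjacent blocks instead of one long one (the
  between-block multi-allelic D′ quantifies this).
- The exotic-specificity rule is presence-based and conservative when elite
  and exotic pools share haplotypes; the block-based imprint is then a
  lower bound on exotic contribution.
- P3D reuses null-model variance components; features explaining a large
  variance share are tested slightly conservatively.
- The screen's penalty logic compares raw class means; strongly related
  carriers make those means noisier than their nominal SEs suggest, which
  the two-SE guard mitigates but does not eliminate.
- No local-ancestry HMM: U-coded markers are never imputed from flanking
  origin calls.
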