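---
title: "Methods: simulated bulk segregant analysis and allele-frequency-change QTL calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated bulk segregant analysis and allele-frequency-change QTL calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The problem this package models

Bulk segregant analysis (BSA) maps quantitative trait loci (QTLs) by
comparing allele frequencies between pooled segregants before and after
phenotypic selection. The design emulated here is an advanced intercross
line (AIL) experiment in wine yeast: two nearly isogenic diploid parents
that differ at thousands of biallelic marker sites are crossed and the
offspring intercrossed repeatedly (to F13) to expand the genetic map; the
F13 pool is then subjected to batch serial-dilution selection (8 rounds,
roughly 50 generations of clonal growth), during which faster-growing
genotypes enrich exponentially. Whole-genome sequencing of the unselected
and selected pools turns enrichment into allele-frequency changes, and a
simple threshold rule calls QTL sites.

Because the package is a simulation-plus-analysis artifact, every stage has
known ground truth: planted QTLs with chosen additive effects, a known
heritability, and known pool depths. The evaluation layer scores called
intervals against the planted truth (power, FDR).

## Models, stage by stage

### Marker map and meiosis

Markers are abstract biallelic sites placed uniformly at random; genetic
position is proportional to physical position at a constant rate (default
380/12 ≈ 31.7 cM/Mb, the yeast genome-wide average). Meiosis follows the
Haldane model: per chromosome the crossover count is Poisson with mean
equal to the marker span in Morgans, crossover positions are uniform in
genetic coordinates, the starting phase is a fair coin, and there is no
interference and no obligate chiasma. This is the simplest well-defined
recombination model; nothing downstream depends on interference. The
recombinant fraction between two markers d Morgans apart is therefore
Haldane's r = ½(1 − e^(−2d)), which the test suite verifies by simulation.

Mating during the intercross is panmictic between distinct parents;
diploidy-selection markers, sporulation efficiency and spore viability are
not modeled — they change the census, which is already a free parameter.

### Trait and selection

The growth-rate trait is additive: μ = μ0 + Σ a_k d_k + ε, with d_k the
parent-A dosage at QTL k and ε ~ N(0, σ_e²). `tune_environmental_sd()`
sets σ_e so that the realised genetic variance over total variance equals a
target broad-sense heritability (default 0.65, the level reported for the
trait this design was built to study).

Serial-dilution selection is asexual: per round each lineage's abundance is
multiplied by exp(μ·g·ln 2) with g = 6.25 generations per round (8 rounds ≈
50 generations), then the culture is bottlenecked by multinomial resampling.
ε is **redrawn every round**: we read it as batch-to-batch
micro-environment noise rather than a permanent clonal property. Redrawing
prevents a one-off lucky draw from compounding exponentially over 50
generations, which would make "environmental" noise behave like a planted
mutation; the alternative (fixed per clone) is a one-line change.

### Pooled sequencing

Per site, depth is Poisson (optionally negative binomial) around
`mean_depth` (default 100×), and parent-A read counts are Binomial(d, p′)
with p′ = p(1−e) + (1−p)e for symmetric per-read miscall rate e (default
0.005). No alignment, mapping bias or base-quality structure is modeled; at
these depths the binomial sampling term dominates anyway (SD ≈ 0.05 at
p = 0.5, 100×) — a fact that matters below.

### The QTL caller

Three rules, all thresholds inclusive, read verbatim from the protocol the
package reimplements: a site must have ≥ 30 reads in the initial pool and
in every selected pool; its initial-pool allele frequency must lie in
[0.30, 0.70]; and it is called when every replicate shows |ΔAF| ≥ 0.1 with
a shared sign. Called sites are merged into intervals (same direction,
inter-site gap ≤ 25 kb, ≥ 3 sites — an explicit convention, since the
protocol reports regions but no merging rule), and intervals entering the
outer 30 kb of a chromosome are flagged subtelomeric (the ~20–30 kb
subtelomeric gene region convention).

"Both replicates" is generalised to N ≥ 1 selected pools (default 2,
modeled as independent selection lines founded from the same F13 pool); the
ΔAF baseline is the single F13 pool.

### Phenotype layer

Growth curves are blank-subtracted, log-transformed (y = ln OD_t/OD_0) and
fitted to the Zwietering reparameterization of the Gompertz model,
y = D·exp{−exp[(μmax·e/D)(λ−t) + 1]}, by damped Gauss–Newton with analytic
Jacobian: full step, halved until the SSE decreases (≤ 50 halvings),
convergence at relative SSE change < 1e-8 or 200 iterations.
Initialisation is D₀ = max y, μ₀ = steepest finite-difference slope, λ₀ =
the steepest tangent's time-axis intercept floored at 0. `stats::nls` with
the same formula serves as an independent oracle in the tests, never in the
implementation path.

Heritability is H² = (Var_seg − Var_env)/Var_seg × 100 with Var_env the
df-weighted pooled variance of the two parents' replicates; negative
estimates are reported with a warning, not clamped, preserving the
formula's algebra. Transgression uses inclusive ±2σ thresholds around the
higher/lower parent mean (σ = pooled parental SD). Fermentation completion
(T100) is the linearly interpolated first crossing of 995 g/L; a curve that
never crosses is a stuck fermentation and propagates as such through
relative T100. Strain-vs-control comparisons use the classical
pooled-variance two-tailed t-test (Welch available as an option) with
Bonferroni correction over the non-control strains.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| cM_per_Mb | 31.7 | cM/Mb | yeast genome average (~380 cM / 12 Mb) |
| target_generation | 13 | — | the F13 AIL design |
| pop_size / bottleneck | 5000 | cells | desk-scale stand-in for 10⁷–10⁸ cells |
| rounds × g | 8 × 6.25 | rounds × doublings | ≈ 50 generations of selection |
| QTL effect | 0.03 | h⁻¹/allele | gives true ΔAF ≈ 0.22 after selection |
| h2 | 0.65 | — | reported trait heritability level |
| mean_depth | 100 | reads/site | conventional pool-seq depth |
| min_depth / band / Δ | 30 / [0.30, 0.70] / 0.1 | — | the published site rules |
| max_gap / min_sites | 25 kb / 3 | — | interval convention, exposed in config |
| subtelomere window | 30 kb | bp | the ~20–30 kb subtelomeric region hint |

## What the generator does and does not emulate

It emulates: marker-level segregation and AIL map expansion, additive
polygenic growth with tunable heritability, exponential clonal enrichment
with bottlenecks, and pool-seq counting noise with symmetric errors. It
does **not** emulate sequence-level reads, alignment or mapping bias, CNVs
and indels, mitochondrial inheritance, sporulation biology, or census sizes
above ~10⁵ (the real experiment pooled 10⁷–10⁸ cells). A green end-to-end
test therefore establishes that the caller recovers planted marker-level
enrichment signals at desk scale — not that it would reproduce any
particular real study's loci.

## Known limitations (measured, not hypothesised)

The acceptance suite leaves two criteria red, deliberately, and the numbers
are worth understanding because they are properties of the stated
experimental world, not bugs:

1. **Null call rate.** With every pool at 100×, the initial-pool AF is
   measured with SD ≈ 0.05, and that error is *shared* by every replicate's
   ΔAF (each replicate subtracts the same initial measurement). The
   two-replicate same-direction rule therefore does not square the false
   positive probability: ~3.6% of retained sites get called on pure
   noise (analytic double-exceedance ≈ 2.4% per direction). Sequencing the
   control pool deeper (500×) drops this to 0.6% — the rule works exactly
   as intended once the shared term is small. Lesson for real designs: the
   control pool's depth bounds the caller's specificity, and replicating
   the *control* sequencing would help as much as replicating selection.
2. **Interval FDR at desk scale.** With ~3.6% of sites called on noise,
   occasional noise clusters survive interval assembly, and at 5000
   founders a mild correlated founder-hitchhiking term (true neutral |ΔAF|
   SD ≈ 0.024, inter-replicate correlation ≈ 0.17) adds to it; measured
   mean FDR against planted truth is ≈ 0.5 under 50 kb one-to-one matching,
   versus ≤ 0.2 demanded. Power is 1.0 throughout. The FDR is insensitive
   to census (unchanged at 20,000 founders) and to the merge gap (unchanged
   at 100 kb), consistent with the shared-control-noise mechanism
   dominating.

Other numerical choices: tie-breaks in truth matching are by proximity with
greedy one-to-one assignment; t100 requires the series to start above
threshold (a series already at threshold is rejected as complete);
`fit_gompertz` rejects constant-y curves as degenerate rather than
returning a zero-slope fit; all thresholds in the caller are inclusive,
matching the protocol's "at least" wording.

## Reproducibility

Every stochastic operation takes an explicit integer seed; the pipeline
derives per-stage substreams from one master seed, and identical configs
reproduce byte-identical output files (verified in the test suite).

```{r example, eval = FALSE}
cfg <- run_config(seed = 42)
res <- run_pipeline(cfg, out_dir = "run42")
res$recovery     # power / FDR against the planted QTLs
res$qtl$intervals
```
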