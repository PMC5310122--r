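# bsaqtl

Simulation and analysis toolkit for **bulk segregant analysis (BSA)** of
quantitative traits in yeast-like genomes. The package is aimed at
quantitative geneticists who want to prototype or stress-test a
pool-sequencing QTL-mapping design before running it: it forward-simulates
an advanced intercross line (AIL) to F13, an additive polygenic growth-rate
trait with planted QTLs and controllable heritability, a batch
serial-dilution selection experiment (~50 generations of clonal
enrichment), and pooled sequencing of the segregant pools — then maps QTLs
with the classical threshold-based allele-frequency-change caller and
scores the calls against the planted truth.

It also implements the accompanying phenotype statistics used in
low-temperature adaptation studies of wine yeast: reparameterized Gompertz
growth-curve fitting, broad-sense heritability, transgressive segregation,
generation counting, fermentation endpoints (T100), and
strain-versus-control comparisons.

## The statistics at the core

**QTL calling.** For each site with parent-A read count a and parent-B
count b, the pool allele frequency is p̂ = a/(a+b). A site is *retained* if
it has ≥ 30 reads in the initial (unselected) pool and in every selected
pool, and its initial frequency lies in [0.30, 0.70]. A retained site is
*called* when every replicate selection line shows

&nbsp;&nbsp;&nbsp;&nbsp;ΔAF = p̂(selected) − p̂(initial), with |ΔAF| ≥ 0.1 and a shared sign.

Same-direction calls within 25 kb merge into intervals (≥ 3 sites), and
intervals within 30 kb of a chromosome end are flagged subtelomeric.

**Growth kinetics.** Blank-corrected OD600 curves are transformed to
y = ln(OD_t/OD_0) and fitted by damped Gauss–Newton to the Zwietering
Gompertz form

&nbsp;&nbsp;&nbsp;&nbsp;y(t) = D · exp{ −exp[ (μ_max·e/D)(λ − t) + 1 ] }

with D the asymptote, μ_max the maximum specific growth rate (h⁻¹) and λ
the lag (h).

**Heritability / transgression.** H² = (Var_seg − Var_env)/Var_seg × 100,
with Var_env the pooled parental replicate variance; transgressive
segregants lie ≥ 2σ beyond the higher/lower parental mean (σ = pooled
parental SD). Generations: n = log₂(N_t/N_0). Fermentations complete when
must density reaches 995 g/L (T100, linearly interpolated; never reaching
it = stuck).

## Worked example

```r
library(bsaqtl)
cfg <- run_config(seed = 42)      # 16 chr x 100 markers, F13, 3 QTLs, 2 lines
res <- run_pipeline(cfg, out_dir = "run42")

res$recovery
#> recovery: tp 3, fp 5, fn 0 (power 1.00, fdr 0.62)
res$arch$qtls[, 1:3]              # the planted truth
#>    chrom    pos effect
#> 1 chrXII 532032   0.03
#> 2 chrVII 504919   0.03
#> 3  chrVI  52717   0.03
head(res$qtl$intervals, 3)
#>    chrom  start    end n_sites mean_abs_delta direction subtelomeric
#> 1  chrVI  38654 111934      11      0.2494774         1        FALSE
#> 2  chrVI 173266 231354       7      0.1528026         1        FALSE
#> 3 chrVII 346451 562972      23      0.2000135         1        FALSE
res$phenotype$h2_percent
#> [1] 59.12694
```

All three planted QTLs are recovered (power 1.00); the extra intervals are
shoulders and correlated-noise clusters — the FDR behaviour analysed in the
vignette. The phenotype panel estimates H² ≈ 59% against the 65% simulated
target from 96 segregants.

Growth-curve fitting and fermentation endpoints:

```r
tt <- seq(0, 96, 0.5)
y  <- gompertz_y(tt, D = 2.5, mu_max = 0.3, lam = 5) + rnorm(length(tt), 0, 0.01)
fit_gompertz(data.frame(time = tt, y = y))
#> gompertz_fit: D = 2.5, mu_max = 0.2996 h^-1, lam = 4.989 h (sse 0.0165, converged in 4 iter)
t100(c(0, 135), c(1100, 995))
#> fermentation: T100 = 135.00 h
```

`run_pipeline()` writes every intermediate table (marker map, counts TSVs,
retained sites, calls, intervals TSV + BED, truth), a structured log, and a
machine-readable `summary.json`; identical config + seed reproduce
byte-identical outputs. A CLI wrapper with `simulate`, `phenotype`,
`map-qtl`, `evaluate` and `run-all` subcommands is installed at
`inst/cli/bsaqtl.R`.

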