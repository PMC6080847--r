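# fibrilAI

Orientation analysis of fibrillar fluorescence images — such as the
sub-epidermal collagen-I network of larval zebrafish skin — by the 2D
Fourier power-spectrum (directionality) method, summarised by the
**Alignment Index (AI)**.

During skin development, collagen I is deposited first as sparse, randomly
oriented wisps and is then remodelled into an orthogonal cross-hatch of two
perpendicular fibril families; after wounding, the denuded domain refills
with wispy random collagen that gradually re-aligns.  `fibrilAI` provides
the quantitative readout for such studies: for each single-channel
maximum-intensity projection it computes the angular distribution of
spectral energy, subtracts the orientation-independent background, splits
the angular range at 90° so each lattice family is assessed independently,
and reports

```
AI = | (1/N) Σ (2 cos²(θᵢ − θth) − 1) |  =  | Σ wᵢ cos 2(θᵢ − θth) / Σ wᵢ |
```

with θth the doubled-angle circular mean orientation.  AI = 1 means no
angular dispersion (full alignment); AI = 0 means entirely random
orientations over the full 0–180° range.  AI is the 2D nematic order
parameter of the orientation distribution.

The package also contains a fully seeded synthetic fibril-image generator
(axial von Mises orientation mixtures rendered as blurred, noisy line
segments, with developmental and wound-repair presets and exported ground
truth), the group statistics used by imaging timecourse designs (one-way
ANOVA with Tukey HSD; Welch t tests wounded vs unwounded), and a batch
pipeline that turns a manifest of TIFFs — or a simulation preset — into
per-image AI tables, group summaries and test reports.

## Worked example

```r
library(fibrilAI)

## a synthetic orthogonal cross-hatch and its analysis
sim <- simulateFibrilScene(OrientationMixture(mu = c(45, 135), kappa = 20),
                           nFibrils = 150, size = 256, seed = 1)
img <- renderScene(sim$scene)
analyzeImage(img)
#> AIResult
#>   0-90 deg  : AI 0.9034, theta_th 47.38 deg, mass 830.6
#>   90-180 deg: AI 0.8949, theta_th 135.64 deg, mass 477.3
#>   combined  : AI 0.9003 (mass-weighted)
```

Each of the two orthogonal families (one per angular range) is tightly
aligned — AI ≈ 0.9 around mean orientations ≈ 45° and ≈ 135° — and the
combined, mass-weighted AI is 0.90.

```r
## the two emulated timecourses, end to end
res <- emulateFigureTimecourses(seed = 1, nPerGroup = 12, imageSize = 256)

res$development$summary
#>   group  n  mean     sd
#> 1  2dpf 12 0.698 0.0874
#> 2  3dpf 12 0.796 0.0326
#> 3  4dpf 12 0.893 0.0163

res$development$report[, c("test", "comparison", "statistic", "p.value", "stars")]
#>    test comparison statistic  p.value stars
#> 1 anova    omnibus   38.4258 2.41e-09  ****
#> 2 tukey  3dpf-2dpf    0.0979 3.20e-04   ***
#> 3 tukey  4dpf-2dpf    0.1957 1.17e-09  ****
#> 4 tukey  4dpf-3dpf    0.0978 3.25e-04   ***

res$wound$report[, c("timepoint", "statistic", "p.value", "stars")]
#>   timepoint statistic  p.value stars
#> 1      1dpi    -28.24 9.67e-19  ****
#> 2      5dpi     -8.64 2.40e-07  ****
#> 3     10dpi     -3.46 2.28e-03    **
#> 4     16dpi      1.49 1.50e-01    ns
```

Mean AI rises monotonically across the developmental stages (random wisps →
loose cross-hatch → tight lattice), and the wounded-vs-unwounded comparison
is strongly significant while the wound is empty or wispy, weakens as the
infill re-aligns, and is non-significant once the lattice has fully
recovered.  Note that the per-range AI of a *structureless* image floors
near 2/π ≈ 0.64 (a 90° range doubles onto a half circle), so group
comparisons are relative; see the methods vignette.

A thin command-line wrapper with `simulate`, `directionality`, `ai`,
`stats` and `run` subcommands is installed at `inst/scripts/fibrilai.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/fibrilai.R", package="fibrilAI"))')" \
    run --mode full --preset wound --seed 1 --outdir out
```

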