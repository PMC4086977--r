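# grazefd

Trait-based analysis of secondary (livestock) productivity in grazed
grasslands: does plant functional *identity* drive how much animal
production a sward supports, does functional *diversity* drive the mean of
production, or does diversity instead buffer its year-to-year variability
(resilience)?

`grazefd` implements the full analysis chain for long-term grazing
experiments in which productivity is recorded as the livestock density (LU
ha⁻¹ yr⁻¹) needed to hold the vegetation at a set height, alongside
point-quadrat botanical records and growing-season (May–September) weather:

1. **Functional composition.** Species × trait tables are built from
   database-style entries (replication-weighted means, ordinal codings for
   life-form, canopy structure, life span, phenology and vegetative spread,
   natural-log transforms for canopy height and leaf size). Community-level
   metrics are computed from weighted Gower dissimilarities
   `d_ij = Σ_k w_k |x_ik − x_jk| / range_k / Σ_k w_k`:
   the community-weighted mean `CWM = Σ_i p_i x_i`, Rao's quadratic entropy
   `Q = Σ_i Σ_j p_i p_j d_ij`, and functional evenness
   `FEve = (Σ_l min(PEW_l, 1/(S−1)) − 1/(S−1)) / (1 − 1/(S−1))`
   over the minimum spanning tree of the species present — for the full
   response-trait suite and for the single leaf traits SLA and LDMC.
2. **Productivity model.** An exponential-decay transform of
   community-weighted leaf dry matter content, `exp(−k·LDMC)`, is estimated
   by nonlinear least squares and frozen; productivity is then modelled by
   nested random-intercept mixed models (`nlme`), with REML simplification
   of the random ladder (`experiment/block/plot` → `experiment/plot` → …)
   and ML backward elimination of fixed terms (decay-transformed LDMC,
   rainfall, rainfall², temperature), plus a within-plot lag-1 residual
   autocorrelation check.
3. **Hypothesis tests.** Forward selection asks whether any FD metric
   (overall or LDMC-specific Rao's Q / FEve) improves the mean model
   (likelihood-ratio tests); plot-mean regressions relate long-term
   productivity to long-term diversity; and the resilience analysis
   regresses the absolute residuals of the combined trait + weather model on
   each FD metric, with the slope's denominator df revised downward by one
   because the response comes from a previous fit.
4. **Synthetic experiments.** A seeded generator emulates the whole design —
   9 experiments × 3 plots × 4–15 years, a 40-species pool with grassland
   trait marginals, Dirichlet communities on a fertility gradient that
   couples high productivity to low LDMC-diversity, and a residual SD that
   shrinks with RaoQ of LDMC (`sd(ε) = σ₀·e^(−γ·RaoQ)`) — providing ground
   truth for every stage.

## Worked example

```r
library(grazefd)

ds <- simulateGrazingData(generatorConfig(seed = 1))
an <- runFullAnalysis(ds)
an
#> <grazefd_analysis> 270 plot-years, 9 experiments
#>   decay rate k = 0.01768 | random: experiment/plot | fixed: expLDMC + rain
#>   H1 (FD explains mean productivity): some FD term adds power
#>   H2 (FD explains variability): significant for rao_all, rao_ldmc

an$transform$k                      # estimated LDMC decay rate (true 0.0170)
#> [1] 0.01767755
an$summary$coefficients
#> (Intercept)     expLDMC        rain
#>  -0.4923036 102.9403735   0.0017648
an$h2_resilience[an$h2_resilience$predictor == "rao_ldmc",
                 c("slope", "df_nominal", "df_adjusted", "p")]
#>        slope df_nominal df_adjusted           p
#> 4 -0.0885218        242         241 0.004907727
```

The fitted coefficients sit close to the generator's truth (−0.687, 95.31,
0.0018); the resilience slope on RaoQ of LDMC is negative and significant —
productivity is more predictable where leaf-trait diversity is higher —
while its df has been reduced from 242 to 241 by the adjustment for the
previously fitted base model. On any single replicate the H1 forward
selection may or may not flag an FD term (here it does); across replicates
no FD term is added in the majority, while the dispersion signal is
detected in over 80% — the package's operating-characteristic tests
quantify exactly this.

Write the machine-readable summary and the tables with
`writeRunSummary(an, "run.json")` and `writeFDProfile(an$profile, "fd.csv")`.

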