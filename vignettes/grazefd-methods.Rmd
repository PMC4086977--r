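---
title: "Functional composition, productivity and resilience in grazed grasslands: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grazefd methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Grassland ecosystems deliver animal production — measurable as the
livestock density (livestock units, LU ha⁻¹ yr⁻¹) required to keep a sward
at a target height. Three candidate controls on that service are
distinguished here: functional *identity* (which trait values dominate the
community, summarised by community-weighted means), functional *diversity*
as a driver of the *mean* rate (H1), and functional diversity as a source
of *resilience*, i.e. reduced divergence of realised production from its
trait-and-weather expectation (H2). `grazefd` implements this three-part
analysis as a reusable, tested pipeline, together with a synthetic
grazing-experiment generator that provides known ground truth for every
stage.

## Trait coding and composition metrics

Traits follow the standard grassland response-trait suite: bud height
(life-form) coded 0–1, canopy structure (rosette 0, hemirosette 0.5,
erosulate 1), leafing period, life span, start of flowering (month 1–12),
canopy height and leaf size (natural log), LDMC (mg g⁻¹), SLA (mm² mg⁻¹),
and the two vegetative-spread attributes (rhizome, stolon), each weighted
0.5 so vegetative spread as a whole counts once. Species values are
replication-weighted means of database entries; entry values are coded
(including the log) before averaging, so logged traits are averaged on the
log scale. Trait values are fixed per species across sites and years, so
temporal change in CWMs reflects abundance change only; the trait table is
immutable after construction, and a missing species × trait cell is a hard
error rather than an imputation (the metrics assume complete coverage).

Distances are weighted Gower: per-trait absolute differences normalised by
the trait's range over the *full species pool* (not per community), so
plot-years are comparable; traits with zero pool range contribute nothing
and are dropped from the weight sum, with a record. The log base for height
and leaf size only rescales an axis that Gower re-normalises anyway; the
natural log is used and recorded. Flowering month is kept as 1–12 in the
table but mapped to (m−1)/11 on the distance side — with pool-range
normalisation this is a no-op for the metrics, and is done so every coded
axis enters on the same footing (and so single-trait distances on phenology
are interpretable without knowing the month range).

Rao's quadratic entropy uses the ordered-pair convention
Q = Σᵢ Σⱼ pᵢ pⱼ d_ij (equivalently 2 Σ_{i<j}), computed as p′Dp; the test
suite holds the fast path to a brute-force double sum at 1e−12. FEve is the
minimum-spanning-tree construction: branch evenness EW = d_ij/(pᵢ+pⱼ),
partial evenness PEW = EW/ΣEW, and
FEve = (Σ min(PEW, 1/(S−1)) − 1/(S−1))/(1 − 1/(S−1)). Species at zero
abundance are excluded before the MST; ties among equal-length candidate
edges are broken deterministically in lexicographic species-pair order
(FEve can differ across tie-broken trees, so determinism matters for
reproducibility). FEve is undefined below three present species and is
propagated as a flagged `NA`, never silently dropped; downstream tests
subset to defined rows and refit their null model on the same subset so
likelihood-ratio comparisons stay nested. Single-trait Rao is reported both
on the normalised scale and in raw trait units (scaled by the pool range)
for transparency.

## The productivity model

Productivity declines with community LDMC in a saturating, decaying
fashion; the pipeline linearises this with the transform e^(−k·LDMC). The
decay rate k is estimated once by nonlinear least squares of
`productivity = a + b·e^(−k·LDMC)` on pooled plot-year records — random
effects deliberately ignored at this stage — and then frozen as a fixed
covariate inside the mixed models; joint nonlinear mixed estimation is a
non-goal. Initialisation tries the asymptotic-regression self-start
(`SSasymp`), a profiled grid (for fixed k the model is linear in (a, b), so
RSS is profiled over a log-spaced k grid and polished by `nls`), and a
tail-asymptote log-linearisation; the lowest-RSS converged fit wins, making
the estimator robust to the occasional bad local optimum. The pooled fit's
nominal standard errors understate the true replicate-to-replicate spread
of k̂, because the ignored experiment-level structure is exactly what the
pooled regression cannot average away — a known cost of the two-stage
approach, quantified in the tests.

Mixed models are fitted with `nlme` (`gls` when no random term remains).
The random ladder is restricted to nested random intercepts —
`experiment/block/plot`, `experiment/plot`, `experiment`, none — compared
under REML with the full fixed model, ties going to the simpler structure.
A date-by-plot random slope is not in the ladder: it is discarded early in
this kind of analysis and random-slope support is uneven across estimation
backends, so nested intercepts are the normative contract here. Fixed terms
(decay-transformed LDMC; rainfall and rainfall², added because production
can be limited at both ends of the rainfall range; temperature) are then
simplified under ML: at each step every single-term deletion is assessed by
a 1-df likelihood-ratio test; among deletions that are *non-significant* at
α = 0.05 the one yielding the lowest AIC is applied; elimination stops when
every remaining term is significant, and the final model is refitted by
REML. The gate is the LRT, with AIC only ranking admissible deletions: a
null term has ≈95% probability of leaving the model under this rule,
whereas demanding an AIC improvement as well would cap removal at
P(χ²₁ < 2) ≈ 84% and routinely strand null terms. Marginality is respected
(rainfall stays while rainfall² is present). p-values for fixed terms are
LRT-based: denominator-df conventions for Wald tests differ across
backends, so likelihood ratios are the contract. Variance components
estimated at the zero boundary are reported with a flag, never errors.

Temporal autocorrelation of the final model is checked by pooling lag-1
products of residuals over consecutive years within plots:
r₁ = mean(eₜeₜ₊₁)/mean(e²), flagged when |r₁| > 1.96/√n_pairs. Series with
zero residual variance, or designs without three years in any plot, return
a defined = FALSE flag.

## H1, mean-level patterns, and H2 (resilience)

Forward selection adds each FD candidate (overall and LDMC-specific Rao's Q
and FEve) singly to the combined trait + weather model under ML and tests
it by likelihood ratio; a candidate (nearly) collinear with the base
covariates is refused with a warning rather than tested. Long-term
structure is examined by regressing plot-level multi-year mean FD on mean
productivity with experiment random intercepts.

The resilience analysis takes the absolute values of the raw (innermost,
observed − fitted) residuals of the combined model and regresses them on
each FD metric in a mixed model with the same random structure (REML, the
final-estimation convention; the mode is recorded). Because the response is
the output of a previous fit, the slope's denominator df is revised
downward by exactly one before the t-test — "one" meaning one degree of
freedom, the reading fixed by the nominal-vs-adjusted bookkeeping the
procedure is anchored to — which can only reduce significance. Raw
p-values are primary, with an optional Holm column across the four
predictors, and a squared-residual variant exists behind a flag for
sensitivity analysis only; no joint mean–variance model is fitted — the
two-stage procedure is the contract.

## The synthetic generator

The generator emulates the study conditions end to end. Design: 9
experiments × 3 plots (one block per plot, so the full random ladder is
exercisable), each experiment observed for 4–15 years. Species pool (40
species): LDMC truncated-normal (mean 250, SD 60 mg g⁻¹, support
[80, 500]); log-SLA negatively correlated with LDMC (the leaf-economics
axis); lognormal canopy height and leaf size; categorical traits with
hemicryptophyte-dominated, mostly perennial frequencies and flowering
starts April–August. Communities: each experiment carries a fertility score
(evenly spread over experiments, jittered per plot and per year); weights
`exp(base − 2.5·coupling·fertility·z_LDMC)` tilt abundance toward low-LDMC
species, which simultaneously raises expected productivity and lowers RaoQ
of LDMC — the fertility–diversity trade-off; plot-year compositions are
Dirichlet draws whose concentration varies lognormally between years
(dominance shifts), with lognormal yearly species fluctuations on top.
Point-quadrat sampling is approximated by this Dirichlet noise rather than
explicit pin hits, since the analysis consumes relative abundances only.

Records: rainfall has a per-experiment regime (means drawn from
450–650 mm, yearly SD 90 mm, shared by all plots of an experiment-year);
temperature is generated but carries no true effect, giving the
fixed-model simplification a true-negative term to drop. Productivity is
`β₀ + β₁·e^(−k·CWM_LDMC) + β₂·rain + u_exp + u_plot + ε` with β = (−0.687,
95.31, 0.0018) and k = 0.0170 by default, Gaussian random intercepts, and
`sd(ε) = σ₀·e^(−γ·RaoQ_LDMC)`; negative draws are truncated at zero and
counted (the defaults make truncation essentially absent).

Free parameters were fixed once, by calibration, and are not revisited:
σ_exp = 0.06 and σ_plot = 0.08 LU ha⁻¹ yr⁻¹ (site effects after LDMC and
rainfall are accounted for; small enough that the pooled transform fit
stays identifiable across only nine experiments), σ₀ = 0.10, and γ = 2.7,
chosen so that the expected absolute-residual-vs-RaoQ slope is ≈ −0.11 —
the empirical scale of such dispersion effects — while a one-sided test
detects it in ~85% of replicates and the homoscedastic (γ = 0) special
case keeps its nominal type-I error. The community-dynamics SDs
(plot-level lognormal 1.0, yearly fluctuation 0.7, yearly fertility jitter
0.25, concentration log-SD 1.2) give plot-years realistic year-to-year
turnover in both CWM-LDMC and RaoQ-LDMC, which is what makes the two-stage
k estimate precise and the dispersion test powered.

What the generator does *not* emulate: real point-quadrat pin geometry,
spatially explicit dynamics, grazing feedbacks on composition across
years, previous-season weather carry-over, and intraspecific trait
variation. Passing tests therefore demonstrate that the pipeline recovers
the structures it assumes, at realistic design sizes — not that those
structures exhaust real grassland data.

## Numerical choices and degenerate inputs

* Abundance rows must sum to 1 within 1e−9; readers can renormalise with a
  warning under an explicit flag.
* Gower with every requested trait constant is an error ("zero trait
  variation"); single constant traits are dropped and recorded.
* `nls` uses a scale offset so zero-residual (noiseless) fits converge;
  k ≤ 0 at the optimum is an error.
* `lme` retries with both `nlminb` and `optim` optimisers before reporting
  a convergence failure; random-ladder candidates that fail to converge are
  dropped from the comparison (an error only if all fail).
* Random-effect SDs below 1e−5 of the residual SD set a boundary flag.
* The ML/REML distinction is enforced: likelihood-ratio tests refuse mixed
  modes; REML is used for random-structure comparison and final estimates,
  ML for fixed-term comparison.
* All analysis stages are deterministic; all generator randomness flows
  from a single integer seed.

## Validation design and problem sizes

The test suite validates each operation against independent oracles:
hand-derived Gower/Rao/FEve values (including the 1-D three-species FEve
benchmark whose MST gives partial evennesses 0.25/0.75 and FEve = 0.5),
`cluster::daisy` and `vegan::spantree` as external cross-checks,
brute-force double sums for Rao, and simulation-based operating
characteristics at the default design size: 95% CI coverage of the fixed
coefficients over 100 replicates (with the transform frozen at its true
value — conditional on k̂, since a few percent of error in k rescales
e^(−kL) beyond any sensible CI for its coefficient; the k estimate itself
is checked separately for ±20% recovery), random-ladder and
backward-elimination success rates over 100 replicates, resilience type-I
error and p-value uniformity over 500 homoscedastic replicates, and
resilience power with H1 parsimony over 200 replicates. These replicate
counts keep the full suite within a desktop-scale run while leaving the
binomial margins interpretable.

## Known limitations

* The package's CIs are `nlme` plug-in intervals; with nine experiments
  they can be mildly anticonservative for contrasts that lean on
  between-group information (no Kenward–Roger correction is applied).
* The two-stage transform-then-mixed-model procedure understates the
  uncertainty in k; coefficient inference is conditional on the frozen
  transform, as in the analysis tradition it follows.
* The H2 test is a two-stage dispersion regression, not a joint
  mean–variance model; its df adjustment is a pragmatic guard, not an
  exact correction.
* Livestock-unit conversion factors are taken as given in the input
  records; the package does not convert grazing days across animal
  species.
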