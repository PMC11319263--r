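---
title: "Methods: crop-model-assisted genomic prediction of sorghum biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crop-model-assisted genomic prediction of sorghum biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Aboveground fresh weight in sorghum is an *integrative* trait: it emerges
from leaf initiation and expansion rates, tillering, radiation capture and
carbon allocation, each under partially independent genetic control, with
epistatic interactions and genotype-by-environment effects layered on top.
Direct whole-genome regression of such a trait must absorb all of that
non-linearity at once. The alternative implemented here is a two-stage
scheme (CGM-GP): regress the *parameters* of a crop growth model (CGM) on
the markers — each parameter being a simpler, more heritable quantity —
and then let the crop model compose them, together with the weather, into
the trait. `cgmgp` implements both routes end to end on synthetic data and
compares them under shared cross-validation folds.

## The growth model

The simulator is a deliberately compact sink-driven model of vegetative
sorghum growth at organ level, driven by eight genotypic parameters (the
calibration intervals are available as `parameter_bounds()`):

| parameter | meaning | unit | interval |
|---|---|---|---|
| `epsib` | light conversion coefficient | g MJ^-1 | [3, 8] |
| `plasto_init` | plastochron (phytomer initiation) | °Cd | [25, 45] |
| `phyllo_init` | phyllochron (leaf appearance) | °Cd | [25, 45] |
| `ligulo_init` | ligulochron (leaf ligulation) | °Cd | [25, 45] |
| `ict` | competition-index threshold for tillering | – | [0.5, 2.5] |
| `mgr_init` | meristem growth rate (leaf pre-sizing per rank) | mm rank^-1 | [6, 14] |
| `ll_to_il` | internode/leaf length ratio | – | [0.1, 0.2] |
| `slap` | per-rank decrease of specific leaf area | rank^-1 | [0, 0.1] |

Each day the model (i) accumulates thermal time above a base temperature
(11 °C, a standard sorghum base); (ii) advances phenology on every axis —
a phytomer is initiated every `plasto_init` °Cd, leaf rank *r* appears once
the axis has accumulated *r*·`phyllo_init` °Cd, and ligulates
`ligulo_init` °Cd later; (iii) pre-dimensions newly appearing organs:
potential blade length grows additively with rank at `mgr_init`, scaled by
`min(1, IC)` so a carbon-starved plant initiates smaller leaves, blade area
follows a fixed allometry, and blade mass is area over a specific leaf area
that declines by the factor `(1 - slap)` per rank; internodes take a fixed
fraction `ll_to_il` of their blade's length and grow over three
ligulochrons; (iv) sums organ demands (potential mass spread over each
organ's thermal growth window); (v) computes supply as
`epsib × radiation × ground area × (1 − exp(−k · LAI))`, plus a small seed
reserve released over the first three days (without it a zero-area plant
could never start growing); and (vi) scales all organ growth by
`min(1, supply/demand)`.

Two competition indices are deliberately distinguished. Growth scaling uses
the *same-day* supply/demand ratio, which makes carbon conservation exact:
cumulative structural growth can never exceed cumulative supply plus the
seed reserve (the test suite asserts this to 1e-9 g). Tillering and organ
pre-dimensioning use a *trailing-window* index IC (supply over demand summed
across the days spanning one phyllochron, clamped to [0, 5]), because a
tiller bud should respond to the plant's recent carbon status, not to a
single day's weather; a tiller is emitted at a mainstem leaf-appearance
event (rank ≥ 4, up to 8 tillers) when IC exceeds the genotypic threshold
`ict`. Tiller organs are scaled by 0.8 relative to the main stem and
tillers do not themselves tiller.

Constants the narrative requires but no publication pins down — light
extinction (0.5), plant ground area (0.08 m², i.e. 0.4 m × 0.2 m spacing),
first-leaf length (100 mm), blade allometry (width/length 0.1, shape factor
0.72), specific leaf area of leaf 1 (30,000 mm² g^-1 dry), dry matter
content (0.15 g g^-1), internode diameter (8 mm) and density
(1e-4 g mm^-3), seed reserve (0.2 g) — live in `model_constants()` with
these defaults. Reported biomass traits are fresh weight (dry mass / dry
matter content); all internal bookkeeping is in dry mass. Plant height is
the summed length of ligulated mainstem internodes plus the last ligulated
blade, made non-decreasing by a running maximum.

The model is deterministic; identical inputs give identical trajectories.

## Calibration by Differential Evolution

The "observed" parameter values of a genotype are obtained by model
inversion: minimize the mean over traits of the replicate-mean NRMSE

\[ \mathrm{NRMSE} = \sqrt{\tfrac1n \sum_i \left( \frac{y_i - \hat y_i}{y_i} \right)^2 } \]

between observed and simulated trajectories of the seven calibration
traits (`calibration_traits()`): appeared and ligulated leaf counts,
tiller count (weekly), fresh biomass and plant height (daily), mainstem
fresh weight and area of the last ligulated leaf (harvest). Zero-valued
observations — early tiller counts, typically — are dropped from the
relative-error sums, since the metric divides by the observation.

The optimizer is the classic DE/rand/1/bin: mutation `v = a + F(b − c)`,
binomial crossover with a forced index, reflection at the bounds, greedy
selection. Defaults `NP = 80` (ten per dimension), `F = 0.8`, `CR = 0.9`.
The number of generations is the budget knob: production-style runs use
thousands, the test suite uses 150 generations with `NP = 40`, which on
noise-free self-generated data already drives the objective below 0.05 and
recovers `epsib` within 5%. Parameter *identifiability* is weaker than
functional recovery: biomass-linked parameters (`epsib`, `mgr_init`) are
well constrained by the starred traits, while the three thermal-time
clocks can partially trade off against each other at near-zero objective;
tests therefore assert objective recovery and the two identifiable
parameters only.

## Genomic prediction engines

All engines share one contract: `gp_fit(engine, X, Y)` on an `{-1, 0, 1}`
marker matrix, `predict()` on the original target scale. Cross-validation
folds are drawn once (`kfold_split()`) and reused by every engine and both
scenarios; reports carry a fold checksum so the sharing is verifiable.

**LASSO** minimizes `(1/2n)·RSS + λΣ|βj|` with an unpenalized intercept
(glmnet's coordinate descent), λ chosen by inner 5-fold cross-validation
on a log-spaced path from `λ_max` (the smallest λ with an all-zero
solution) down four decades. `lasso_kkt_violation()` exposes the
stationarity residual used by the tests.

**Bayes C** is a spike-and-slab Gibbs sampler written for this package:
each SNP effect is zero with probability π (default 0.99) and otherwise
drawn from a normal slab with a *common* variance across SNPs;
scaled-inverse-χ² priors on both variances (ν = 4, scales solved from
`var(y)` split half-and-half), flat prior on the mean, joint update of
each (inclusion, effect) pair, prediction by posterior-mean genomic value.
The polygenic term sometimes added to this model is omitted — there is no
pedigree here, and the marker term already spans the genomic covariance.
With π = 1 the model is returned analytically as the train mean; with
π = 0 and fixed variances the sampler collapses onto ridge regression,
which the tests exploit as a closed-form oracle. Chains are driven by R's
RNG, so a seed fixes the chain exactly.

**CNN**: a 1D convolutional network along the marker sequence — five
convolution layers with kernel sizes 11, 11, 9, 13, 9 and strides 1, 3, 5,
5, 5 under 'same' padding (so a 2000-marker input shrinks to feature
lengths 2000, 667, 134, 27, 6), then a 32-unit dense layer and a sigmoid
output head of size 8 (parameter mode) or 1 (trait mode). Hidden
activations are ReLU throughout. Channel widths are not architectural
constants of the published design; this implementation defaults to
(8, 16, 16, 32, 32), widths chosen so that desk-scale experiments train in
CPU minutes, and exposes them in `cnn_settings()`. Targets are scaled to
[0, 1] — genotypic parameters by their calibration bounds (a
genotype-independent map), traits by their training range — because a
sigmoid head demands bounded targets. The loss is the relative
root-mean-square error on the scaled targets with a floor of 0.1 added to
the denominator: a raw relative error is undefined at the fold minimum
(which scales to exactly 0), and a tiny offset would let that single point
dominate the loss; the floor keeps the loss relative in spirit while
numerically well-posed. Training uses Adam (defaults lr 1e-3, batch 16) with
optional early stopping on a 10% validation split. Forward and backward
passes are im2col convolutions through BLAS with the gather/scatter steps
in C++; the backward pass is verified against numerical gradients in the
test suite.

## Evaluation

Both scenarios are scored by NMAE (`mean(|(y − ŷ)/y|)`) and predictive
ability (the Pearson correlation of observed and predicted), computed on
the *pooled* out-of-fold predictions — pooling, rather than averaging
per-fold metrics, uses every genotype exactly once and is the convention
adopted here. In the CGM-GP scenario the marker→parameter models are fit
per parameter for the linear engines and jointly (8 outputs) for the CNN;
predicted parameters are clamped into their calibration intervals before
simulation (the simulator's domain contract), and per-parameter NMAEs are
reported alongside the trait metrics. Genotypes whose simulation fails are
recorded and excluded from metrics with a warning rather than poisoning
the report.

## The synthetic data generator

The generator emulates the structure of a greenhouse phenotyping trial of
a sorghum diversity panel: `n` genotypes × `p` markers with
linkage disequilibrium, four replicates, a 45-day trial at 30 °C day /
23 °C night (daily mean 26.5 °C plus jitter), lognormal daily radiation
(mean 8 MJ m^-2 day^-1, CV 0.2). The default scale is 300 genotypes ×
3,000 markers, chosen so the full two-scenario pipeline runs in CPU
minutes; the original panel scale (136 × 31,713) remains one
`trial_design()` call away.

Genotypes: two haplotypes per chromosome (10 chromosomes by default) with
first-order Markov copying — an allele is copied from the previous marker
with probability ρ (default 0.9), otherwise redrawn from its frequency.
This is the cheapest mechanism with tunable, monotonically decaying LD. A
minimum minor-allele-frequency floor of 0.05 is enforced exactly by
flipping the minimal number of haplotype alleles in violating columns
(reading the source data's ambiguous SNP filter phrase as a minimum-MAF
condition, the only interpretation that keeps common variants).

Parameters: per parameter, a genetic score sums additive QTL effects and
optional epistatic terms (products of the `{-1,0,1}` codes of adjacent
marker pairs — tightly linked interactions, the kind a convolutional
receptive field can in principle see); Gaussian noise brings the score to
a target narrow-sense heritability (drawn from [0.5, 0.9] per parameter by
default), and a population min-max affine map — which preserves
heritability — places the values inside the calibration intervals, so the
simulator never receives out-of-range inputs. Phenotypes: the growth model
is run once per genotype, and each replicate measurement gets
mean-preserving multiplicative lognormal noise at a trait-level CV
(default 0.1) at the platform cadence (daily / weekly / harvest).

What the generator does *not* emulate: population structure and pedigree,
genotyping error and missingness, spatial greenhouse gradients and
neighbour competition, the water-deficit treatment arm, and any mismatch
between the data-generating growth model and the fitted one. Passing tests
therefore demonstrate internal consistency of the machinery, and that the
*qualitative* comparisons (crop-model route ≥ direct route; non-linear
engine competitive under epistasis) hold under a data-generating process
whose assumptions favour neither scenario a priori — they say nothing
quantitative about real sorghum panels.

## Heritability

`vanraden_grm()` builds the genomic relationship matrix from allele
dosages (method 1: `Z Z' / (2 Σ p(1−p))`), refusing monomorphic markers by
name. `marker_h2()` fits `y = μ + g + e`, `g ~ N(0, G σ²_g)`, by
restricted maximum likelihood: one eigendecomposition of G reduces the
profile restricted log-likelihood to a scalar function of
`h² = σ²_g/(σ²_g + σ²_e)`, scanned on a 101-point grid and refined by
Brent's method — exact, dependency-free, and guaranteed (and tested) to
match the grid optimum. The model is intercept-only; no further covariates
enter.

## Numerical choices and degenerate inputs

* Relative-error metrics (`nrmse`, `nmae`) raise an error on zero
  observations; callers that can legitimately drop such points (the
  calibration objective on early tiller counts, parameter NMAE at a bound
  of zero) do so explicitly.
* A constant target gives an intercept-only LASSO (with a warning), an
  exact-mean Bayes C at π = 1, and a degenerate target scaler that maps to
  0.5 and inverts to the constant for the CNN.
* DE candidates are reflected (not clamped) at the bounds, preserving
  search diversity near edges; a final clamp guards pathological `F`.
* The DE objective returns `Inf` for failing simulations, which greedy
  selection discards naturally.
* The REML search domain is `[0, 1]`; a singular G (one zero eigenvalue is
  expected, since the dosage-centred Z has rank ≤ n−1) is handled by the
  residual variance keeping the likelihood finite for h² < 1.
* Gradient checks jitter the CNN parameters before comparing against
  central differences: zero-initialized biases plus discrete inputs put
  some pre-activations exactly at a ReLU kink, where a subgradient and a
  central difference legitimately disagree.

## Problem sizes in the shipped tests

The test suite runs the complete comparison at the generator's default
scale (300 × 3,000) over five seeds with reduced engine budgets — LASSO on
a 40-step path, Bayes C chains of 800 iterations, CNN trained for 8–10
epochs at batch 16 — and the calibration recovery at `NP = 40` × 150
generations; `scripts/acceptance.R` runs one seed with fuller budgets
(3,000-iteration chains, 20-epoch CNN with early stopping). These sizes
are the package's choice of a desk-scale experiment: large enough for the
qualitative contrasts to be stable, small enough to run in minutes.

## Known limitations

* The crop-model route reliably beats direct prediction for the *linear*
  engines at desk scale, but not for the CNN: its stride chain
  (1, 3, 5, 5, 5) compresses 3,000 markers to 8 feature positions, too
  coarse to localize the individual QTL sets behind each genotypic
  parameter. The per-parameter NMAE tables in the evaluation reports show
  the CNN's parameter predictions lagging well behind the linear engines
  while its direct trait prediction is competitive, so the CNN's CGM-GP
  delta comes out negative at this scale and the corresponding end-to-end
  test records that failure rather than hiding it. At the original panel
  scale (31,713 markers, GPU-scale training budgets) the relative
  positional resolution is roughly 40× finer; the desk-scale result
  should not be read as a property of the method at full scale.
* The growth model is a compact re-design, not a port: no reproductive
  phase, senescence, water balance, leaf-level photosynthesis, or DEVS
  scheduling; numeric equality with any existing simulator is a non-goal.
* Clock parameters are only weakly identifiable from the calibration
  traits (see above).
* The Bayes C π is fixed (no hyperprior update), and the CNN performs no
  architecture search — both are inputs, not estimated quantities.
* Heritability is single-kernel and intercept-only; repeated measures and
  covariates are out of scope.
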