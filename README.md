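# salocc

Hierarchical detection models for temporally replicated wildlife surveys,
built around the workflow used to study woodland-salamander populations
along environmental gradients: where a species occurs, how many individuals
are there, whether two species co-occur more or less often than chance, and
how much of "detection" is really surface availability.

Counts and detections from visual encounter surveys underestimate both
occurrence and abundance because detection is imperfect. `salocc` fits the
three standard hierarchical correction models by maximum likelihood:

- **Single-season occupancy** (zero-inflated binomial): site *i* is occupied
  with probability ψᵢ = logit⁻¹(xᵢ′β_ψ), and an occupied site yields a
  detection on visit *j* with conditional capture probability
  p_ψ,ij = logit⁻¹(w_ij′β_p). The site likelihood is
  ψᵢ ∏ⱼ p^y (1−p)^(1−y) + (1−ψᵢ)·I(no detections).
- **N-mixture abundance**: latent abundance Nᵢ ~ Poisson(λᵢ),
  log λᵢ = xᵢ′β_λ, counts y_ij ~ Binomial(Nᵢ, p_λ,ij); the likelihood sums
  the latent state out up to a truncation bound that is checked by doubling.
- **Two-species co-occurrence** under the conditional (ψ_Ba)
  parameterization: species A occupies with ψ_A; species B with ψ_BA where A
  is present and ψ_Ba where it is absent. The **Species Interaction Factor**
  φ = ψ_AB / (ψ_A·ψ_B) equals 1 under independence, exceeds 1 for
  aggregation, and falls below 1 for segregation.

Because the occupancy model's p_ψ conditions on presence while the
N-mixture model's "effective detection" p_λ folds in whether an individual
is at the surface at all, their ratio identifies **availability**
(p_λ / p_ψ) and its complement, **temporary emigration** — e.g. salamanders
withdrawn into subterranean refugia during a survey.

Around the fitters: AIC/AICc ranking and Akaike weights, model-averaged
effect sizes β̄ with unconditional (within- plus between-model) intervals,
model-averaged predictions, cumulative-weight comparisons of model subsets,
parametric-bootstrap goodness-of-fit with the overdispersion ratio ĉ, the
Beers aspect transformation, TPI neighborhood-scale selection, density
extrapolation, and a fully seeded synthetic-data generator emulating a
40-site × 4-visit survey design (see the methods vignette).

## Worked example

Simulate a survey from the packaged scenario, fit an occupancy model with a
soil-moisture (MST) effect on occupancy and a time-of-day (TOD) effect on
detection, and decompose detection:

```r
library(salocc)

scenario <- load_scenario()                       # 40 sites x 4 visits
sim <- simulate_scenario(scenario, "occupancy", seed = 11)
naive_poa(sim$dataset)
#> [1] 0.75

std <- standardize_covariates(sim$dataset)
fit <- fit_occupancy(std$data, model_spec(~MST, ~TOD, "occupancy"), seed = 2)
fit
#> Single-season occupancy model (zero-inflated binomial)
#>   formula(s): state: ~MST; detection: ~TOD
#>                 Estimate Std. Error
#> psi_(Intercept)   2.4203     1.2056
#> psi_MST          -0.6000     0.7483
#> p_(Intercept)    -0.7040     0.2295
#> p_TOD            -0.6275     0.2066
#>   logLik -93.6884  K 4  AIC 195.377  AICc 196.520  converged

decompose_detection(p_psi = 0.24, p_lambda = 0.05)
#> Detection decomposition
#>   conditional capture p_psi   0.2400
#>   effective detection p_lambda 0.0500
#>   availability                 0.2083
#>   temporary emigration         0.7917
```

Three of four sampled sites had at least one detection (naive proportion of
area occupied 0.75), but the fitted model says detection is well below 1
(logit⁻¹(−0.70) ≈ 0.33 per visit at the mean time of day) and declines later
in the day (negative TOD coefficient), so the occupancy probability at mean
soil moisture, logit⁻¹(2.42) ≈ 0.92, is above the naive rate. The
decomposition shows what an effective detection probability of 0.05 against
a conditional capture probability of 0.24 implies: only ~21% of individuals
were at the surface during a visit; ~79% were temporarily emigrated.

The full stepwise workflow (detection covariates first, then state
covariates carrying the selected detection structure, model-averaged
effects and predictions at each step) is `run_stepwise()`; the two-species
analogue with null-vs-environment weight comparison and φ is
`run_cooccurrence()`.

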