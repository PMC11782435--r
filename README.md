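# osteoimpact

Detecting the moment an osteotome crosses a thin bone plate from the force
signals of an instrumented surgical mallet.

## The problem

In craniofacial procedures such as Le Fort osteotomies, the surgeon drives an
osteotome through the pterygoid plates with mallet blows, without visual
control, and must decide from proprioception alone when the blade has crossed
the plate — stopping too late risks vascular and nerve damage. A mallet
fitted with a piezoelectric force sensor records, for every blow, a force
trace *s(t)* (51.2 kHz, 20 ms) whose shape carries information about the
material under the blade tip. `osteoimpact` implements the complete analysis
chain that turns those traces into a crossing detector, for biomechanics
researchers working with instrumented-impact data.

## The model

Each trace shows two dominant peaks: the hammer impact and the first rebound
of the osteotome. Each peak *p* is fitted with a Gaussian
*a·exp(−(t−c)²/2w²)* of area *L\_p = √(2π)·w\_p·a\_p*, giving two per-impact
indicators:

- **τ** — the delay (ms) between the two peak centres, a proxy for the
  rigidity at the blade tip (τ rises as rigidity falls);
- **λ = L₂/L₁** — the peak-area ratio, linked to viscoelasticity (λ drops
  at crossing).

Across an osteotomy sequence, τ stays on a plateau until the plate under the
blade becomes thin, then rises. The dependence on plate thickness *Th* is
piecewise linear,

    τ̃(Th) = τ₀                      if Th > d_f
    τ̃(Th) = τ₀ + k_f (Th − d_f)     if Th ≤ d_f

with parameters estimated by Nelder–Mead minimisation of the mean absolute
residual e\_τ = Σ|τ(j) − τ̃(Th(j))|/P over the P locations
(`fit_tau_thickness()`).

For detection, each impact *i* > 1 contributes the features
(τ, λ, Δτ, Δλ) with Δτ(i) = τ(i) − τ(i−1), Δλ(i) = λ(i) − λ(i−1), labelled
*Bone* or *Crossing*. The features are projected onto canonical variables
(c₁: Fisher discriminant direction; c₂: orthogonal residual-variance axis)
and classified with a soft-margin linear SVM evaluated by stratified 5-fold
cross-validation. Because a missed crossing (false negative) is the costly
error, training errors are weighted by a misclassification cost matrix
σ = [[σ\_BB, σ\_CB], [σ\_BC, σ\_CC]] (diagonal 0, σ\_BC = 1) and σ\_CB is
tuned by minimising the cross-validated Negative Likelihood Ratio

    NLR = (FN / (TP + FN)) / (TN / (FP + TN)).

A seeded phenomenological generator (`generate_database()`) synthesises
whole experiments — per-plate osteotomy and thickness-assessment procedures
with two-Gaussian pulses, linear per-location damage and configurable
crossing effect sizes — so the entire chain is testable without any
measurement campaign.

## Worked example

```r
library(osteoimpact)

# fit the piecewise tau-thickness model on 60 simulated locations
set.seed(1)
d <- simulate_location_tau(60, tau0 = 0.95, d_f = 1.2, k_f = -0.89,
                           noise_sd = 0.03)
fit <- fit_tau_thickness(tau_ms ~ thickness_mm, d)
fit
#> Piecewise-linear tau-thickness fit (Nelder-Mead, mean |residual|)
#>   tau0 = 0.9546 ms, d_f = 1.2073 mm, k_f = -0.8646 ms/mm
#>   E_tau = 0.0200 ms over P = 60 locations
```

The fit recovers the simulation truths (0.95 ms, 1.2 mm, −0.89 ms/mm) to
within the noise, with a mean absolute residual of 0.02 ms — the level of
the injected per-impact noise.

```r
# full pipeline: simulate -> extract -> fit-thickness -> train
res <- run_pipeline(run_config(seed = 42, n_plates = 4))
res
#> <pipeline_result>
#>   266 impacts, 167 feature records, config hash 8b8820057c6b74616d0a8c3be12bab6e
#>   osteotomy fit: tau0 1.1499 ms, d_f 1.50 mm, k_f -0.6172 ms/mm
#>   thickness_assessment fit: tau0 0.9551 ms, d_f 1.19 mm, k_f -0.8946 ms/mm
#>   classifier: accuracy 0.9940, NLR 0.0000, sigma_CB 1, detection 1.000
```

Here 266 simulated traces are reduced to 167 feature records (the first
impact of each plate has no Δ features); the thickness-assessment fit
recovers the generator's piecewise parameters, while the osteotomy fit sits
higher because accumulating damage lowers rigidity beyond what thickness
alone predicts. The classifier separates Bone from Crossing impacts with
99.4% pooled cross-validated accuracy and detects every crossing within one
impact of its true position; with no false negatives at σ_CB = 1 the NLR is
already 0, so cost tuning keeps the unweighted matrix. On noisier or more
overlapping data the search raises σ_CB above 1 to trade false positives
for fewer missed crossings.

A thin command-line front end over the same functions is installed at
`inst/cli/osteoimpact.R`
(`simulate | extract | fit-thickness | train | run`).

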