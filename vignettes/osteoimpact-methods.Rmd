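---
title: "Methods: impact-hammer indicators, the piecewise thickness model, and cost-sensitive crossing detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impact-hammer indicators, the piecewise thickness model, and cost-sensitive crossing detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoimpact)
```

## The measurement and its indicators

An instrumented mallet records, for each blow on the osteotome, the contact
force `s(t)` at 51.2 kHz for 20 ms. The trace shows a first peak (the hammer
striking the osteotome) followed by a rebound peak (the osteotome bouncing
between bone and hammer). The rebound delay grows when the material under
the blade is compliant, which motivates the two per-impact indicators the
package extracts:

* `tau` (ms): delay between the first two peak centres — inversely related
  to rigidity at the blade tip;
* `lambda` (dimensionless): ratio `L2/L1` of the Gaussian peak areas
  `L_p = sqrt(2*pi) * w_p * a_p` — related to viscoelasticity, and observed
  to drop sharply when the blade breaks through.

### Peak detection

`detect_first_two_peaks()` takes the first two local maxima in time order
whose topographic prominence is at least `min_prominence_fraction` (default
0.1) of the global maximum, merging maxima closer than 0.1 ms. The
prominence filter exists to reject sensor ripple; 10% is deliberately
permissive since the rebound peak of a heavily damped impact can be small
relative to the strike peak. Fewer than two qualifying maxima is an error
naming the impact, not a silent skip — an impact without a rebound peak has
no defined indicators.

### Gaussian peak fits

Each peak is fitted by least squares with `a * exp(-(t - c)^2 / (2 w^2))`
on a window of ±0.3 ms around the raw maximum (truncated at the trace
edges), using Levenberg–Marquardt with initial values from the raw maximum
and the half-width at half-maximum (`w0 = HWHM / 1.177`). `w` is the
Gaussian *standard deviation*: with that convention the closed form
`L = sqrt(2*pi) * w * a` is exactly the Gaussian area, which the test suite
verifies against trapezoid integration to much better than 0.5%. Fits that
fail to converge, leave the admissible width range `(0, window span]`, or
return an amplitude outside the window's force range ±50% raise a
"fit failed" error.

`tau` is measured between the two *fitted centres* by default
(`use_fit_centers = TRUE`). Raw-maximum timing is quantised to the 19.5 µs
sample period; the fitted centre interpolates below it. The raw-maximum
convention remains available as an option, and on clean signals the two
agree to within one sample period.

### Feature table

For each impact `i` with `1 < i <= N` within a plate, the classification
features are `(tau, lambda, dtau, dlambda)` with differences taken against
the immediately preceding impact of the same plate, *across* osteotomy
location boundaries — impacts are indexed chronologically per plate and the
difference is simply the previous blow, which is also what an intra-operative
detector would see. The first impact of a plate has no differences and is
dropped. The `Crossing` class contains the impact at which the operator felt
the blade cross plus the single additional post-rupture impact; everything
else is `Bone`.

## The piecewise thickness model

Location-mean `tau` (Bone impacts only — Crossing impacts reflect the
ruptured plate) follows a plateau-plus-ramp in plate thickness `Th`:

$$\tilde\tau(Th) = \begin{cases}\tau_0 & Th > d_f\\
\tau_0 + k_f\,(Th - d_f) & Th \le d_f\end{cases}$$

The breakpoint `d_f` is the thinnest plate that still behaves rigidly;
`k_f < 0` so `tau` rises as the plate thins. Parameters minimise the mean
absolute residual `e_tau` over locations. Choices:

* **Optimiser**: Nelder–Mead (the cost is piecewise linear in its
  parameters, hence non-smooth; a simplex method needs no gradient),
  relative tolerance 1e-10 on the cost, at most 2000 iterations,
  10 restarts — the first from data-driven initials (`tau0`: median `tau`
  of the thickest thickness tercile; `d_f`: median thickness; `k_f`:
  least-squares slope through the thinnest tercile), the rest jittered
  multiplicatively by ±20%.
* **Constraints**: `d_f` is clamped to the observed thickness range inside
  the objective — a breakpoint outside the data is meaningless.
* **Tie-break**: among restarts whose costs agree to 1e-9, the smallest
  `d_f` is returned (the most conservative "plate still rigid" claim).
* **Degenerate designs**: if fewer than two locations lie below the fitted
  breakpoint, or the fitted ramp moves `tau` by less than twice the
  residual scale, the fit is flagged `identifiable = FALSE` with a warning
  — `tau0` is still meaningful, `d_f` and `k_f` are not. Flat-but-noisy
  designs can evade this flag when the spurious ramp happens to exceed the
  threshold; the flag is a guard, not a test of regime existence.
* **Pooling**: fits are run on location summaries pooled across plates per
  procedure (the pipeline fits thickness-assessment and osteotomy locations
  separately). Per-plate fits are possible by subsetting, but with 2–5
  locations per plate a single plate rarely spans both regimes.

Mean-absolute (rather than squared) deviation follows the definition of
`e_tau` above and is what `E_tau` reports, in ms over the `P` locations.

## Cost-sensitive crossing classification

With two classes, a canonical discriminant analysis has a single axis: `c1`
is the Fisher direction `S_w^{-1}(m_C - m_B)` on z-scored features
(features are standardized because `tau` in ms and `lambda` near unity are
not commensurate; the within-class covariance is ridge-regularized with
1e-6 only if computationally singular, with a warning). As a second display
axis, `c2` is the direction of maximal residual variance orthogonal to
`c1`. This orthogonal-variance construction is this package's documented
choice for the second canonical variable; it affects visualisation and
gives the classifier a second, weakly informative coordinate.

The classifier is a soft-margin linear SVM (margin penalty `C = 1`, not
tuned) on `(c1, c2)`. The misclassification cost matrix enters as class
weights on the hinge loss — the standard realization of class-dependent
misclassification cost for margin classifiers: errors on true-Crossing
records are weighted by `sigma_CB`, on true-Bone records by `sigma_BC`.
Only the ratio `sigma_CB / sigma_BC` matters up to a rescaling of `C`, so
the search fixes `sigma_BC = 1` and scans `sigma_CB` over 1 to 10 in steps
of 0.25. With `sigma_CB = sigma_BC = 1` the classifier is exactly the
unweighted SVM, and the search's `sigma_CB = 1` cell reproduces its counts
on identical folds.

Evaluation is stratified 5-fold cross-validation with a seeded fold draw;
every record is predicted exactly once by a model trained on the other four
folds. Pooled confusion counts over the validation folds are the primary
report (per-fold accuracies and their mean are also returned). The
cost-matrix search minimises the pooled Negative Likelihood Ratio
`NLR = (FN/(TP+FN)) / (TN/(FP+TN))`, the metric of a diagnostic test that
must not miss positives; candidates with `TN = 0` get an infinite NLR, and
ties break to the smallest `sigma_CB`. All candidates share one fold
partition so that differences reflect the cost weights, not fold noise.

## What the synthetic generator emulates — and what it does not

`generate_database()` reproduces the *statistical structure* the analysis
relies on, not the contact mechanics:

* **Pulse shape**: each impact is two equal-width (0.15 ms) Gaussian pulses,
  the first at 1 ms with amplitude 100–200 N (low-energy thickness
  assessment) or 200–400 N (osteotomy), the second `tau` later with area
  `lambda` times the first. Separations below three pulse widths are
  rejected as unresolvable.
* **Experiment structure**: per-plate osteotomy location counts drawn from
  the empirical distribution {2: 2/31, 3: 13/31, 4: 14/31, 5: 2/31} (mean
  3.52); per-location impact counts Gaussian around rank-wise means 14.60,
  10.32, 7.83, 7.94, 8.00 (sds 12.82, 4.66, 3.60, 3.32, 2.83), rounded and
  clipped to 4–45; thickness-assessment passes with 5 impacts at each of
  ~5.65 locations. Plate thickness decreases from 3.0 to 0.5 mm along the
  locations with 0.15 mm jitter.
* **Indicator truths**: bone-phase `tau` follows the piecewise model at the
  *effective* thickness `Th * (1 - damage)` with per-impact noise
  (sd 0.03 ms); damage grows linearly over a location's bone-phase impacts
  (the simplest monotone law — no per-impact damage law is established).
  `lambda` is Gaussian (mean 0.6, sd 0.1). Each location ends with exactly
  two Crossing impacts: the felt crossing and one post-rupture blow, with
  `tau` jumped by N(0.5, 0.1) ms above the fully-damaged level and `lambda`
  multiplied by a factor uniform in [0.3, 0.7]. These crossing effect sizes
  are qualitative calibrations (no printed values exist for them) and are
  config parameters, not constants.
* **Detectability floor**: `lambda` truths are clamped to [0.12, 0.95] so
  the rebound peak always clears the 10% prominence floor — the generator
  only emits impacts whose indicators are well defined. The clamp touches
  well under 1% of draws at the default crossing-drop range.
* **Default truths** for the piecewise model are `tau0 = 0.95` ms,
  `d_f = 1.2` mm, `k_f = -0.89` ms/mm.

Not emulated: crack initiation and propagation (the osteotomy-procedure
scatter that damage accumulation produces here is smooth, whereas real
cracks produce jumps), operator variability, soft tissue, sensor noise
other than optional white noise, energy dependence of `tau` (assumed
absent: low-energy and osteotomy impacts differ only in amplitude range),
and any geometry. Consequently, passing tests demonstrate that the
*analysis chain* is correct and well-conditioned at realistic effect sizes
— e.g. that the fitting machinery recovers known truths and that the cost
matrix trades false positives for false negatives as designed — not that
the classifier would reach the same accuracy on measured signals, whose
class overlap near rupture is governed by crack physics the generator does
not model. On the synthetic database the Bone/Crossing separation is
stronger than measured data would show; the overlapping-cloud test-bed
(`simulate_overlapping_classes()`, 15% positives) is therefore used to
exercise the cost-matrix behaviour under genuine class overlap.

## Problem sizes and seeds

The shipped tests and the acceptance script use: 50 noise-free signals for
the indicator round-trip; 20 random peaks for the area identity; 100
datasets of 60 locations (noise sd 0.03 ms) for piecewise recovery, each
cross-checked against a 50^3 brute-force parameter lattice; an 800-record
overlapping test-bed for the cost-matrix effect; and a 16-plate synthetic
database (~1000–1300 impacts) for the end-to-end run. These sizes give
stable statistics while keeping a full run in the tens of seconds on one
CPU. Every random draw traces to a single user-supplied seed.

## Known limitations

* The piecewise fit assumes exactly one breakpoint; designs whose `tau`
  rises twice (e.g. partially detached plates, where `tau` keeps rising as
  rigidity falls despite increasing thickness) violate the model and
  inflate `E_tau`.
* The two-class canonical projection fixes `c2` by a variance criterion;
  any rotation of the orthogonal complement would serve equally, so `c2`
  loadings should not be interpreted mechanistically.
* Pooled cross-validation counts treat impacts as exchangeable records;
  impacts within a plate are correlated, so pooled accuracy estimates are
  optimistic relative to leave-one-plate-out evaluation, which the package
  does not implement.
* `E_tau` is reported in ms; comparisons against residuals quoted in other
  units or as unnormalised sums require care.
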