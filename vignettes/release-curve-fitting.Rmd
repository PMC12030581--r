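---
title: "Fitting in vitro PLGA release curves: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting in vitro PLGA release curves: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plgarelease)
```

## The problem

PLGA micro- and nanoparticles release their payload over hours to weeks
through a combination of diffusion, polymer swelling and bulk erosion.
An in vitro release experiment (typically PBS, pH 7.4, 37 °C) yields a
cumulative release curve: percent of the dose released at each sampled
time. This package fits such curves three ways — two semi-empirical
kinetic laws fitted per sample, and a neural network fitted across
samples — and scores all of them with the same per-sample MSE/R²
protocol, so the flexible model and the mechanistic ones can be compared
on equal footing.

## The kinetic models

The Korsmeyer–Peppas law, $M_t/M_\infty = k\,t^n$, is a local power-law
description of the rising part of a release curve. It is deliberately
uncapped: the package never clips its predictions at 100%, because the
law is stated without a cap and the misfit of a diverging power law at
late times is informative. The exponent classifies the transport
mechanism; the thresholds ($n \le 0.5$ Fickian, $0.5 < n < 1$ anomalous,
$n = 1$ Case II, $n > 1$ super-Case-II) are applied with a tolerance band
$|n - 1| \le 0.01$ for the exact-equality rule, since a fitted exponent
is never exactly 1.

The Weibull law, $M_t/M_\infty = 1 - \exp(-(t/\tau)^\beta)$, is bounded
in $[0, 1)$ and monotone; $\tau$ (hours) is the 63.2%-release time and
$\beta$ classifies the release ($\beta < 1$ diffusion-controlled,
$\beta = 1$ first order, $\beta > 1$ swelling/degradation influenced,
with the same $\pm 0.01$ band at 1).

### Fitting

Both laws are fitted on the percent scale — model fraction × 100 against
observed percent — by bounded Levenberg–Marquardt least squares
(`minpack.lm`), over *all* observed points of a sample. Percent-scale
fitting makes the reported MSE directly interpretable in squared percent
and keeps loss magnitudes commensurate with the network's.

Nonlinear least squares on power laws and stretched exponentials is
multimodal enough to deserve multi-start: up to 8 starts combining
exponent/shape values {0.3, 0.6, 1.0, 1.5} with rate/scale guesses from
the data range, plus an initial start from linearization (log release vs
log time for the power law, whose slope estimates $n$; the double-log
transform for the Weibull). Zero-time and zero-release points are
excluded from the initializers but kept in the objective. The best
optimum wins; ties (within $10^{-12}$ of objective) go to the smaller
parameter norm. Bounds are $k, \tau > 0$ and exponent/shape in
$(10^{-6}, 20]$. Non-convergence is reported honestly via a `converged`
flag with best-so-far parameters; an all-zero curve is an error.

On noise-free curves generated from either law the fitter recovers the
generating parameters to better than $10^{-6}$ relative (this is a
package test), so residual misfit on real curves measures model
inadequacy, not optimizer failure.

## The drug feature vector

Fourteen descriptors are computed per drug from its SMILES: molecular
weight, logP, H-bond donors, H-bond acceptors, heavy atoms, rotatable
bonds, TPSA, ring count (SSSR), aromatic ring count, molar refractivity,
and the four Lipinski pass flags (MW ≤ 500, logP ≤ 5, HBD ≤ 5,
HBA ≤ 10, each 0/1, always derived from the computed values). The
donor/acceptor counts and logP follow the OpenBabel (JoelLib)
definitions; rotatable bonds are counted on the molecular graph as
acyclic single bonds between non-terminal heavy atoms excluding
triple-bond neighbours, and the count is cross-checked against the
`obabel` rotors descriptor in the tests. The fixed concatenation order
of the 21-vector (6 carrier, 14 drug, time last) is exposed by
`feature_names()` and shared by feature rows, scalers and trained
models.

The name→SMILES cache shipped in `inst/extdata/drug_structures.csv` was
curated offline and each entry validated against the compound's known
molecular formula; entries marked `biologic` (insulin, VEGF, DNase I,
cerebrolysin, a plant profilin) have no small-molecule structure. Their
descriptors stay missing and are mean-imputed, which effectively places
a protein at the dataset's descriptor centroid — crude, but it keeps
protein samples usable by the network, and their carrier features and
time points still carry signal.

## The network

`train_release_mlp()` fits a fully connected network, by default
21–64–64–1 with ReLU and a linear output, minimizing squared error in
squared-percent units with minibatch Adam (learning rate $10^{-3}$,
batch 32, 2000 epochs). The architecture and optimizer settings are
package defaults exposed in `mlp_config()`, chosen as the smallest
standard configuration that reliably reaches the synthetic noise floor;
nothing in the method depends on them specifically. Weights are
He-uniform; the output bias starts at the mean training target, so the
first iterate is the mean predictor rather than zero on a 0–100 scale.
Predictions are not clamped to [0, 100] — out-of-range predictions are
a visible symptom rather than a hidden one.

Preprocessing is deliberately minimal and leakage-free: missing features
are mean-imputed; features are z-scored with center/scale fitted on the
training rows only (constant features get scale 1); the target stays on
the percent scale, which is what makes loss values like "from ~600 down
to ~2" meaningful in squared percent. The 80/20 split is a plain random
partition of the pooled (sample × time point) rows — not of samples — so
each curve typically contributes points to both sides; the held-out rows
double as the validation trace. Train size is `round(0.8 n)`. With a
fixed seed the whole pipeline (split, initialization, shuffling) is
reproducible; one global seed feeds the stages through independently
derived streams so a change in one stage's draw count does not perturb
the others.

Two open choices deserve a note. Whether the original evaluation
protocol scored the network on all of a sample's points or only its
held-out ones is ambiguous; `score_sample()` defaults to all points
(matching how the kinetic fits are scored, sample by sample over all
data) and offers `mode = "test_only"`. And whether the target was
normalized alongside the features is equally ambiguous; the package
keeps it unnormalized because squared-percent loss magnitudes in the
hundreds-to-tens range are only consistent with an unscaled target.

## The synthetic generator

`generate_dataset()` emulates the structure of a 39-sample literature
compilation of PLGA release experiments: 6–37 points per curve, seven
release time-scale bins from 0–10 h up to 400–1000 h, release 0–100%.
Carriers are drawn from plausible PLGA ranges (MW 10–120 kDa, PDI
0.05–0.4, size 80–400 nm, zeta −40 to +10 mV, lactide fraction 0.5–0.9,
EE 40–95%); drugs are real structures drawn from the cache; curves come
from a Korsmeyer–Peppas or Weibull truth model (Weibull: $\tau$ at
15–50% of the horizon, $\beta \in [0.6, 1.4]$; K-P: $n \in [0.3, 0.9]$
with $k$ set for 60–95% final release) times 100 plus i.i.d. Gaussian
noise, default sd 2 percentage points, clipped below at 0. Times are
log-spaced by default, mimicking the dense-early/sparse-late sampling of
real release studies. Everything is a deterministic function of the
seed.

What the generator does *not* emulate matters for interpreting green
tests: real curves are not exact realizations of either law (burst
release, lag phases, sigmoidal erosion phases are all missing), noise is
not i.i.d. Gaussian (cumulative assays have correlated, often
heteroscedastic errors), and carrier features are drawn independently
rather than with realistic correlations. Passing recovery tests
therefore demonstrates the estimation machinery, not real-world
validity. A visible consequence: on synthetic data the Weibull fit beats
the network (the truths *are* Weibull/K-P curves, so the semi-empirical
models are the true model class there), whereas on the real compilation
the reference tables show the network ahead. Both behaviours are
expected, and the acceptance script reports both sets of numbers.

## Evaluation conventions

`metric_mse()`/`metric_r2()` implement the standard definitions;
R² of a constant observation vector is an error rather than a silent
`NaN`. Aggregate tables append the arithmetic mean and the *population*
(N-divisor) standard deviation; the package treats the population form
as the canonical dispersion because only that form reconciles the
shipped per-sample reference columns with their published dispersion row
(the sample form gives ≈ 39.83 for the first column where 39.317 is
printed — this reconciliation is itself a package test). Display
rounding is half-even to 3 decimals and never feeds back into
computation.

## Problem sizes and numerical details

The test-suite and acceptance problem sizes are chosen as the smallest
that demonstrate each property cleanly: 10 noise-free curves for exact
recovery, 50 noisy curves for the <5% median-relative-error property,
a 300-row (15 × 20) dataset for network convergence to ≤2× the noise
floor, and a fresh 39-sample dataset for the end-to-end comparison.
Scaler inversion is exact to $10^{-12}$; model serialization is
plain-text JSON at full printed double precision (reloaded predictions
agree to ~$10^{-10}$ percent; rewriting a model is byte-identical).
Times must be strictly increasing within a sample and duplicates are
rejected at load; release values up to 110% are tolerated as assay
noise, beyond that the loader refuses.

## Known limitations

Only the two shipped kinetic laws are implemented (no Higuchi,
Hixson–Crowell or zero-order variants); descriptor definitions follow
one toolkit and will differ slightly from others (e.g. acceptor counts);
the online name-resolution path exists but is opt-in and untested by
design; and the network is a deliberately plain MLP — no architecture
search, no uncertainty quantification, no cross-curve generalization
claims beyond what the pooled split provides.
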