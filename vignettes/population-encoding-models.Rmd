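---
title: "Population encoding models for auditory cortex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population encoding models for auditory cortex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Sensory encoding models predict a neuron's time-varying firing rate from a
stimulus. In auditory cortex the workhorse is the linear-nonlinear (LN)
spectro-temporal receptive field: a linear filter applied to a sound
spectrogram followed by a static output nonlinearity. LN models are
interpretable but saturate well below the reliability ceiling of cortical
responses. This package implements a family of models that generalize the
LN model in two directions — intermediate convolutional nonlinearities, and
*population* fitting in which many neurons share a common nonlinear
stimulus representation ("core") and differ only in a per-neuron linear
readout — together with the fitting, noise-corrected evaluation and
generalization protocols needed to compare them fairly.

# Models

All models consume a log-compressed gammatone spectrogram `s(f, t)` with
`F = 18` channels log-spaced from 200 Hz to 20 kHz and 10 ms time bins,
and emit nonnegative firing rates.

**LN.** The linear stage is
`r_lin(t) = sum_f sum_u h[f, u] s(f, t − u)` with an 18 × 25 filter `h`
(250 ms of memory). In practice `h` is a rank-D factorization: D Gaussian
spectral weight vectors (each parameterized by a center and width in
channel-index units, 2 parameters per component) times D 25-tap temporal
kernels. The output nonlinearity is the double exponential
`r = b + a·exp(−exp(k (y − s)))` with per-neuron baseline `b`, amplitude
`a`, threshold `s` and gain `k`. It is bounded between `b` and `b + a` and
monotone in `y`.

**single-CNN.** A bank of 1D convolutional units (Gaussian spectral
weighting, 250 ms temporal kernel, offset ReLU) feeding one dense output
unit with the double exponential; one neuron per model.

**Population models** share all layers except the output:

* *pop-LN* — one convolutional layer with **no** activation function, then
  a dense output layer: per neuron it collapses to an LN model, making it
  the minimal population control.
* *1D-CNN* — convolutional layer (ReLU) → hidden dense layer (ReLU) →
  output layer.
* *1Dx2-CNN* — two convolutional layers (150 ms then 100 ms kernels,
  preserving the 250 ms total context) → hidden dense → output.
* *2D-CNN* — three stacked 2D convolutional layers of ten 3 × 8 kernels
  (causal in time, zero-padded and centered in frequency) → hidden dense →
  output.

Deeper 1D layers weight their input channels with unconstrained dense
vectors; only the spectrogram-facing layer is restricted to Gaussian
spectral weights. Gaussian widths are floored at 0.25 channels and centers
may drift 2 channels beyond the edges to fit edge-tuned units; the
Gaussians are unnormalized, their amplitude being absorbed by the temporal
kernel. Temporal convolutions are causal and zero-padded at each stimulus
snippet's onset, and never carry context across snippet boundaries.

Parameter counting follows the "trainable values" convention: 2 per
Gaussian unit, one per tap, fan-in per dense unit, 4 per output
nonlinearity, 1 per offset ReLU — with the convention that the
spectrogram-facing convolutional layer's activation offsets are not
counted in the headline total (`count_parameters()` reports both
conventions). Under it, a 70-unit first layer with 15 taps has
70·2 + 70·15 = 1,190 parameters.

# Fitting

Optimization is full-batch Adam on mean squared error, computed for all
neurons of the population simultaneously (unweighted across neurons).
Datasets at this scale fit comfortably in one batch, which also keeps runs
exactly reproducible: (seed, config, data) determine the result bitwise.

*Early stopping.* 20% of the estimation **snippets** (never time bins —
temporal correlation would leak across a within-snippet split) are held
out; fitting stops after `patience` epochs without improvement and the
best epoch's weights are restored. The reported model is never worse on
the early-stop split than its initialization.

*Initializations.* `n_init − 1` random draws from documented per-role
distributions plus one deterministic draw at the distribution means.
Weight-like roles are zero-mean with ~1/sqrt(fan-in) spread; Gaussian
centers are uniform over the channel range; output nonlinearity scales are
tied to the data's firing-rate scale.

*Three-step heuristic, stage 1.* For each initialization: (A) fit a
submodel excluding the output layer — made concrete by attaching a
temporary linear per-neuron readout (weights + offset, no double
exponential, offsets starting at each neuron's mean rate), discarded
afterwards; (B) freeze the core and fit the true output layer from its
initialization values. The initialization with the lowest early-stop loss
after B seeds (C), a joint fit of everything. Divergent initializations
(NaN loss) restart once at half the learning rate, then are dropped;
at least one must survive.

*Stage 2.* Each neuron's output layer (readout weights + double
exponential) is refit alone against that neuron's own MSE, with the core
frozen and its outputs precomputed. Stage 2 corrects the unweighted
population loss (which under-serves low-rate neurons) and — critically for
the generalization protocols — makes the fitting process identical for
neurons that were and were not in the stage-1 population: every neuron
gets the same fresh multi-start readout fit, with the stage-1 parameters
joining as one extra candidate when they exist. Readout fits are
low-dimensional, so the protocols give them a ~3× epoch budget relative
to the core fit.

Two internal standardizations keep Adam's unit-scale steps appropriate:
stimulus channels are z-scored over the estimation set, and responses are
divided by one population-wide standard deviation during optimization
(inverted at prediction time). Neither changes the relative weighting of
neurons in the loss.

Defaults: learning rate 1e-3, `max_epochs` 5000, patience 30, relative
improvement tolerance 1e-6. The protocol examples in the tests and the
acceptance script use learning rate 7e-3, 150 epochs, patience 15 and 2
initializations — budgets at which the small specs used there converge
stably on the desk-scale fixture.

# Evaluation

**TTRC** — the mean Pearson correlation over all unordered pairs of a
neuron's validation trials — estimates the signal-variance fraction `q` of
the response (for additive independent noise its expectation is `q`).
Pairs containing a zero-variance trial are excluded and counted.

**Noise-corrected prediction correlation.** The mean correlation between
the prediction and each single trial has ceiling `sqrt(q)`, so the
corrected score divides by `sqrt(TTRC)`: a prediction equal to the true
signal scores 1 in expectation at any noise level, and on noise-free data
the score reduces exactly to the raw PSTH correlation. Sampling noise can
push individual scores slightly above 1; they are reported unclamped.
Below `ttrc_floor = 0.05` the normalization is unstable and the score is
flagged `NA` (such neurons are excluded from medians).

**Significance.** Above-chance prediction uses a jackknifed t-test over 20
contiguous time folds of the validation PSTH (leave-one-fold-out
correlations, jackknife SE, two-sided t with 19 df); the paired variant
tests per-fold correlation differences between two models. Population
comparisons use the two-sided Wilcoxon signed-rank test (paired) or
Mann-Whitney U test (unpaired). "Auditory-responsive" neurons are those
predicted above chance (p < 0.05) by all models in a designated set.

**SNR** is estimated as the signal-variance fraction from the repeat-wise
variance decomposition (PSTH variance corrected by `noise_var / M`,
divided by total variance). The package uses it for SNR-matched
subsetting, which needs only monotonicity in the true signal fraction.

**Equivalence** between two models is the plain Pearson correlation of
their predicted validation PSTHs. This simple form cannot separate models
that both explain most of the variance; it is intended for relative
comparisons of score distributions.

# Generalization protocols

*Held-out vs matched.* For each recording site S with K neurons: the
held-out arm excludes all of site S from stage 1, the matched arm excludes
K off-site neurons with the most similar baseline single-neuron LN scores
(greedy nearest-score matching without replacement, descending — a
deterministic, auditable reading of "similar"). Both arms then refit only
the readouts of site-S neurons. Equal performance means the shared core
captures a population-general subspace; the package's synthetic
orthogonal-subspace control (a held-out site reading a disjoint channel
bank) verifies the protocol can detect the alternative.

*Cross-population transfer.* Stage 1 on one population, stage 2 readouts
on another recorded with the same stimulus, compared against the target's
own held-out scores.

*SNR-matched subsets.* SNR values of two populations are histogrammed
into 20 shared equal-width bins; each side keeps the `min(count_a,
count_b)` highest-SNR neurons per bin, producing identical binned
distributions by construction.

*Subsampling.* Estimation snippets (never partial snippets, to preserve
convolutional context) are drawn uniformly once per seed and shared by
both arms, nested across fractions. The pre-trained arm fits the core on
all data minus the held-out site and readouts on the subsample; the
standard arm fits everything on the subsample. Curves are normalized to
the standard arm's full-data median.

# The synthetic-data generator

`simulate_dataset()` builds the desk-scale fixture the protocols are
validated on: 60 neurons in 3 sites, 120 one-second estimation snippets
(single repeat), 12 validation snippets with 20 repeats, F = 18 at 100 Hz
— the single-repeat-estimation / many-repeat-validation design the
evaluation metrics assume. Stimuli are 2D Gaussian noise shaped to a 1/f
joint modulation spectrum (a first-order summary of natural-sound
statistics), squashed into the frontend's output range, with 0.1 s silent
gaps; true populations read from a shared low-dimensional bank of
nonlinear spectro-temporal channels (Gaussian spectral tuning, smooth
temporal kernels, offset ReLU at the 30th percentile of drive, calibrated
double exponential outputs) so that population cores are genuinely
recoverable and genuinely nonlinear; per-neuron SNR is drawn in
[0.15, 0.85] and Gaussian trial noise is scaled per neuron to hit it
(Poisson spiking is available instead). What the generator does **not**
emulate: acoustic structure beyond second-order statistics, adaptation or
other state-dependence across snippets, correlated (shared) trial-to-trial
noise, and non-auditory neurons. Passing tests therefore demonstrate
correctness of the machinery and the qualitative protocol logic, not
performance on real cortical data.

# Numerical choices and degenerate inputs

* The double exponential's inner exponent is clipped at ±30; gradients
  vanish there naturally.
* Gaussian width floor 0.25 channels and center range [−2, F + 1] are
  enforced by projection after each Adam step.
* Correlations are computed on 10 ms bins without smoothing; constant
  predictions or trials yield flagged `NA` scores rather than errors.
* Zero-variance trials are excluded pairwise from TTRC; folds shorter
  than 3 bins reduce the jackknife fold count with a warning.
* The frontend's log compression `log10(1 + p / (1e-5 · max p))` maps
  silence to exactly 0 and is monotone; gammatone impulse responses are
  truncated where their envelope falls below 1e-6 of peak.
* Ties in greedy score matching resolve to the first (lowest-index)
  candidate; SNR bin assignment uses right-closed intervals.

# Convergence and the held-out/matched equivalence

At desk scale the held-out protocol excludes a third of the population
(one of three 20-neuron sites) — a far harsher perturbation of the
stage-1 fit than excluding one site from hundreds of neurons. Piloting
the protocol on the synthetic fixture showed that the equivalence of
held-out and matched cores is a *convergence* property: an
under-converged shared core is systematically better for neurons that
were in its stage-1 population (their readout weights steer where the
remaining fit error lives), and this in-population advantage decays as
the stage-1 fit approaches its optimum, which is population-independent
whenever both neuron subsets span the shared subspace. Cores whose
capacity is below the subspace dimension never shed the bias — their
forced choice of directions stays population-weighted. The protocol
examples therefore use a core at least as wide as the fixture's subspace
(10 + 8 convolutional units, 12 hidden) with a deep fit budget (400
epochs, patience 30) for the held-out/matched comparison, while the
orthogonal-subspace control — whose held-out deficit is an order of
magnitude larger — runs at the standard budget. Paired score differences
between arms share the same validation raster, so even ~0.01 systematic
shifts are statistically visible at 40-60 pairs; equivalence claims at
this scale are meaningful only for converged fits.

# Design choices that were genuinely open

* **Step A's objective.** "Excluding the output layer" leaves the
  submodel's loss undefined; the package attaches a temporary linear
  per-neuron readout so the population MSE remains the objective, then
  discards it. Alternatives (e.g. fitting the core against PCA scores)
  would change the objective mid-fit.
* **R_norm's normalizer.** Dividing the mean single-trial correlation by
  TTRC itself would give a perfect model 1/sqrt(q) > 1; the square root
  is the normalization under which the score is bounded and calibrated
  (verified by simulation in the tests).
* **Counting activation offsets.** The 1,190 first-layer example forces
  their exclusion there; deeper-layer offsets are trainable values and are
  counted. Both totals are always reported.
* **Best initialization** is selected by early-stop-split loss, consistent
  with the early-stopping criterion.
* **Envelope extraction** in the frontend defaults to squared filter
  output averaged per 10 ms bin; half-wave rectification is available via
  `envelope = "halfwave"`.
* **Above-chance testing** compares to zero correlation; a paired
  comparison against a second model's predictions is available where a
  stronger null is wanted.

# Known limitations

* Fitting is CPU-bound, full-batch R/Rcpp: exemplar-scale population
  models (hundreds of units, ~10^5 parameters) fit in hours, not minutes;
  the protocol examples use smaller specs of the same architectures.
* The 2D-CNN's three 8-tap causal layers span 22 bins (220 ms) of
  cumulative memory — slightly less than the 1D architectures' 250 ms.
* Stage-1 loss traces are per-epoch (full-batch), so "epochs" and
  "gradient steps" coincide; there is no mini-batch or learning-rate
  schedule.
* The SNR estimator is a variance-decomposition surrogate; it is monotone
  in the true signal fraction (sufficient for matched subsetting) but not
  the only possible definition.

# Worked example

```{r}
library(popstrf)
ds <- simulate_dataset(n_neurons = 20, subspace_dim = 5, n_sites = 2,
                       n_est_snippets = 40, n_val_snippets = 8, seed = 3)
spec <- model_spec("1D-CNN", n_neurons = 20, n_units = 6, hidden = 8)
cfg <- fit_config(learning_rate = 5e-3, max_epochs = 400, patience = 30,
                  n_init = 3, seed = 11)
fit1 <- fit_stage1(spec, ds, cfg)
fit2 <- fit_stage2(fit1, ds)
scores <- score_models(list(cnn = fit2), ds)
dplyr::summarise(scores, median_r_norm = median(r_norm, na.rm = TRUE))
autoplot(scores)
```
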