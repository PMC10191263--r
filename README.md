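# popstrf

Population spectro-temporal encoding models for auditory neurons.

`popstrf` is for researchers who model spiking responses of auditory
cortical neurons to natural sounds. It predicts each neuron's time-varying
firing rate from a sound spectrogram, and asks how much is gained by (a)
nonlinear convolutional stimulus transformations and (b) fitting many
neurons *jointly*, with a shared nonlinear core and only a thin per-neuron
readout — versus the classical single-neuron linear-nonlinear (LN)
receptive-field model.

## The models

All architectures consume a fixed gammatone log-spectrogram *s(f, t)*
(F = 18 channels, 200 Hz – 20 kHz log-spaced, 10 ms bins) and emit
nonnegative rates:

* **LN** — rank-D spectro-temporal filter
  *r*<sub>lin</sub>(*t*) = Σ<sub>f</sub> Σ<sub>u</sub> *h*[*f*,*u*] *s*(*f*, *t* − *u*),
  with *h* factorized into Gaussian spectral weights × 25-tap temporal
  kernels, followed by the double exponential output nonlinearity
  *r* = *b* + *a*·exp(−exp(*k*(*y* − *s*))).
* **single-CNN** — Gaussian-weighted 1D convolutional units with offset
  ReLUs, one dense output unit, one neuron per model.
* **pop-LN / 1D-CNN / 1Dx2-CNN / 2D-CNN** — population models: a shared
  convolutional core (linear for pop-LN; one, two 1D, or three 2D
  nonlinear convolutional layers otherwise), a hidden dense layer for the
  CNNs, and one dense output unit + double exponential per neuron.

Fitting is two-stage, multi-initialization, full-batch Adam on population
MSE with snippet-wise early stopping; evaluation uses prediction
correlation corrected by the trial-to-trial response correlation (TTRC)
noise ceiling, jackknifed significance tests, and rank-based population
comparisons. Generalization protocols (held-out vs score-matched site
exclusion, cross-population transfer, SNR-matched subsetting, data
subsampling) probe whether the shared core transfers to neurons it never
saw. A synthetic-data module generates ground-truth populations tuned
within a shared low-dimensional subspace so every claim is testable
without recorded data.

## Worked example

```r
library(popstrf)

# ground-truth population: 20 neurons tuned in a shared 5-dim subspace
ds <- simulate_dataset(n_neurons = 20, subspace_dim = 5, n_sites = 2,
                       n_est_snippets = 40, n_val_snippets = 8, seed = 3)

spec <- model_spec("1D-CNN", n_neurons = 20, n_units = 6, hidden = 8)
cfg  <- fit_config(learning_rate = 5e-3, max_epochs = 400, patience = 30,
                   n_init = 3, seed = 11)
fit1 <- fit_stage1(spec, ds, cfg)   # shared core + readouts, population MSE
fit2 <- fit_stage2(fit1, ds)        # per-neuron readout refits

scores <- score_models(list(cnn = fit2), ds)
median(scores$r_norm, na.rm = TRUE)
#> [1] 0.811
median(scores$raw_r, na.rm = TRUE)
#> [1] 0.783
sum(scores$p_above_chance < 0.05)
#> [1] 20
```

`r_norm` is the noise-corrected prediction correlation: mean single-trial
correlation divided by the √TTRC reliability ceiling, so 1 means "as good
as the noise allows" and 0 is chance. Here the median corrected score is
0.81 (raw PSTH correlation 0.78), and all 20 neurons are predicted above
chance by the jackknifed t-test. `count_parameters(spec)` reports model
complexity under the trainable-values convention (e.g. a 70-unit, 15-tap
first convolutional layer has 70·2 + 70·15 = 1,190 parameters).

A thin CLI wraps the same functions for shell use
(`inst/cli/popstrf simulate|fit|evaluate|heldout|crossfit|subsample|report`).

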