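---
title: "Behavior-aligned latent dynamics: model, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior-aligned latent dynamics: model, simulator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(band)
```

## The problem

Neural population activity in motor cortex during a planned reach is well
described by autonomous latent dynamics launched from a preparatory
state: most neural and behavioral variability is decided before movement
begins. Online corrections — e.g. responses to a force-field perturbation
— break this picture: they are driven by sensory feedback arriving during
the movement, and they can dominate behavioral variability while leaving
only a small imprint on population firing. Purely unsupervised latent
variable models, which are rewarded only for reconstructing spikes, tend
to discard exactly this small-but-behaviorally-critical variability.

This package implements a semi-supervised sequential autoencoder that
addresses the problem by reconstructing spikes *and* behavior jointly,
together with the unsupervised and controller-ablated reference variants
needed to attribute what each pathway contributes, a fully synthetic
center-out-reach world with ground truth for recovery tests, and the
analysis battery (oscillation detection, decoder-weight lag structure,
fixed-lag regression, controller-contribution decomposition).

## Model

For each trial, binned spike counts $s_{1:T}$ (bins of width
$\Delta$, default 10 ms) are modeled as Poisson emissions from latent
factors:

* an **initial-condition encoder** — a bidirectional GRU that sees *only*
  the preparatory window (bins $1..P$, default $P = 25$, i.e. 250 ms) —
  outputs a diagonal Gaussian posterior over the generator's initial
  state $g_0$;
* a **controller encoder** — a strictly causal forward GRU over movement
  bins $P+1..T$ — outputs a per-bin diagonal Gaussian posterior over
  control inputs $u_t$ (dimension `n_control`, 0 disables it);
* a **generator** GRU unrolls $T$ steps from $g_0$, receiving $u_t$ at
  movement bins (zero during preparation); factors $f_t$ are a linear
  readout of its state and rates are $\lambda_t = \exp(W f_t + b)$
  (spikes/bin);
* a **sequence-to-sequence linear behavior decoder** maps the flattened
  factor sequence (length $T \cdot F$) to the flattened behavior
  sequence (length $T \cdot B$) with a single affine map, trained
  jointly with everything else.

The training objective (maximized) is

$$\mathcal{L} = \mathcal{L}_x + \theta\,\mathcal{L}_b
  - \alpha\,\mathcal{L}_{L2}
  - \beta_{g_0} \mathrm{KL}_{g_0} - \beta_u \mathrm{KL}_u,$$

with $\mathcal{L}_x$ the Poisson log-likelihood,
$\mathcal{L}_b = -\mathrm{MSE}(b, \hat b)$ (averaged over trials, bins
and components), an L2 penalty on the recurrent kernels of generator and
controller, and standard-normal KL terms for both posteriors. All data
terms are per-trial averages. $\theta = 0$ recovers the unsupervised
model with identical capacity. Both KL weights default to 1 and stay
there: the objective is then a proper evidence lower bound, and the
posteriors retain their interpretation (initial conditions encode the
movement plan, control inputs encode within-trial corrections) instead of
collapsing into an overused controller.

Three structural constraints make the parts interpretable, and are
enforced by construction (the test suite checks them by direct
perturbation, exactly, not approximately):

1. the initial condition cannot depend on movement-phase spikes (the
   encoder's input shape admits only the preparatory window);
2. the control input at movement bin $t$ cannot depend on spikes after
   $t$ (forward recurrence only);
3. the ablated model (`ablate_controller()`) forces $u \equiv 0$ while
   sharing parameters, and is bit-identical to the full model run with
   zero inputs.

### Decoder weights as a causal map

Because factors at every time bin map linearly to behavior at every
time bin, the $T \times T$ block of decoder weights for one
factor/behavior pair separates feedforward structure (factor time before
behavior time, upper triangle) from feedback (behavior before factor,
lower triangle). `diagonal_lag_profile()` sums a block's entries along
fixed factor-to-behavior offsets; `fixed_lag_regression()` is the
complementary predictive version (one ridge regression per lag from the
per-bin latent state to lagged behavior). The sign convention is fixed
throughout: **negative lag means behavior leads the latent factors**,
i.e. feedback.

When aggregating diagonal profiles across factors we sum magnitudes, not
signed values: the sign of any individual latent factor is arbitrary (a
GRU readout can be flipped with its downstream weights), so signed sums
across factors cancel structure that is consistently present per factor.
The per-pair profile itself remains signed.

## Tunable parameters that matter

| parameter | default | units | why this default |
|---|---|---|---|
| `prep_bins` | 25 | bins | 250 ms preparatory window at 10 ms bins; the bin width is not stated for the perturbation sessions and both remain configurable |
| `bin_width` | 0.010 | s | inferred from 25 bins ≈ 250 ms |
| `n_factors` | 8 | – | the interpretable-model size; large-scale comparisons use 100 |
| `n_control` | 4 | – | baseline controller dimensionality |
| `generator_dim` / `encoder_dim` | 200 / 64 | – | baseline sizes; desk-scale tests use 48/24, which suffice at 40 neurons |
| `theta` | 1 | – | supervision weight; intermediate values balance neural and behavioral reconstruction, the PBT loop searches it |
| `beta_kl_g0`, `beta_kl_u` | 1 (fixed) | – | ELBO property and interpretability; freeing them collapses to controller overuse |
| `alpha` | 1e-4 | – | mild L2 on recurrent kernels |
| `input_dropout` | 0.25 | prob. | see "Numerical choices" |

## The synthetic world

`sim_config()` defaults define one stated world; they were chosen once,
to embody the structure the model assumes, and are not tuned per test:

* 8 targets on a ring, 10 trials per target per epoch (BL/AD/WO), 240
  trials of 60 bins at 10 ms; 40 neurons at 30 Hz base rate.
* **Planned dynamics**: the true latent space holds two rotation planes
  whose initial state encodes target angle and reach vigor; the state is
  held through the preparatory window and rotates during movement
  (period 1 s), producing half-sine velocity profiles (peak ~20 cm/s).
  Trial-to-trial planned variability comes almost entirely from
  initial-condition jitter (`ic_jitter_scale * noise_sd`), with only
  faint per-step state noise — planning, not execution, is the dominant
  source of planned variability.
* **Corrective inputs**: adaptation trials only; a decaying 5 Hz
  quadrature sinusoid (decay 0.3 s) enters two dedicated latent
  dimensions at movement onset plus a uniform jitter of up to 200 ms —
  one full cycle, so condition averages wash the oscillation out, as
  required for the condition-average baseline to miss it.
* **Feedback**: realized hand velocity re-enters two "feedback" latent
  dimensions after a 90 ms delay with gain 0.1. These dimensions drive
  neurons (loading 0.12) but are not read out into behavior, giving a
  ground-truth negative-lag relationship.
* **Scales**: corrective oscillation amplitude in behavior is large
  (~30 cm/s, comparable to the planned speed), so corrective+feedback
  signals carry a *majority* (~70%) of adaptation-trial behavior
  variance. On the neural side the corrective input's own log-rate
  variance share is ~2%; the feedback stream — which exists in every
  epoch and mostly carries planned velocity — contributes a further
  ~18%, of which the corrective-driven part is ~13%
  (`log_rate_variance_share()` / `behavior_variance_share()` report the
  decomposition). This
  deliberately exaggerates the behavioral share of corrections relative
  to the monkey sessions (~16%), because desk-scale ablation contrasts
  (a ≥10-point R² drop, a halved fixed-lag peak) are unresolvable when
  corrections carry a sixth of behavioral variance: an autonomous linear
  world predicts the planned share at every lag, flooring the ablated
  profile at ~80% of the full one. The condition-average baseline
  consequently scores ~0.8 on baseline trials and ~0.3–0.4 on
  adaptation trials (the monkey values are 0.87/0.84) — ordering, not
  levels, is what the recovery tests assert.
* The oscillation reaches the rates mostly through the feedback copy
  (corrective-dimension loading 0.16 versus planned 0.5): motor
  corrections live in the feedback stream, which is how a flattened
  fixed-lag peak after controller ablation arises mechanically.

What the generator does **not** emulate: biomechanics (no muscle model,
velocity is read out linearly), spike-history effects (Poisson given the
rate), electrode noise and unit contamination, multi-session
nonstationarity, reaction-time variability (all trials share one
alignment), and any reward/learning dynamics across the adaptation
epoch. A green recovery test therefore establishes that the estimator
recovers the stated structure from Poisson spikes at realistic counts —
not that real cortex contains that structure.

`motor_noise_sd` (default 0) optionally adds white execution noise to
velocity; the noise re-enters the latents through the feedback delay
only, making it decodable from neural activity solely at −90 ms. It is
off in the stated world.

## Numerical choices

* **Optimization**: Adam (lr 5e-3 default, 8e-3 in the bundled
  experiment configs), global gradient-norm clipping, minibatches of
  whole trials, exponential lr decay. Gradients are exact
  backpropagation through time, verified against central finite
  differences to 1e-4 relative error in the test suite.
* **KL/L2 warmup**: linear over the first 10–15 epochs, standard
  practice to avoid early posterior collapse.
* **Encoder-input dropout** (default 0.25): each spike-count entry is
  dropped from the *encoder* views (never from the Poisson target)
  during training. Without it, the causal controller absorbs structure
  the generator could produce autonomously — it reads concurrent spikes
  and "buys" per-bin likelihood — which corrupts the ablation analyses
  that attribute reconstruction to planning versus correction. This is
  the same failure mode that coordinated dropout addresses in the
  AutoLFADS lineage.
* **Controller dropout** (default 0.2): a random fifth of the trials in
  every batch is trained with the control input forced to zero and its
  KL term silenced, so the autonomous pathway — exactly the ablated
  model — is part of the training objective. Without this, occasional
  seeds converge to generators that cannot run autonomously at all
  (ablated reconstruction below the mean-rate null), which makes the
  planning/correction attribution meaningless rather than merely noisy.
* **Evaluation**: deterministic posterior-mean forward passes.
  Bits/spike is reported in two forms: the raw all-neuron form, and
  `cosmooth_bits_per_spike()`, which masks a seeded fraction of neurons
  from the encoders and scores only those. The co-smoothing form is the
  one comparable across model variants — a causal controller can always
  inflate raw bits on observed neurons by partially copying concurrent
  spikes, and that contribution is not population structure. The bits
  definition places the base-2 log inside the per-spike normalization
  (the established benchmark form); the printed-formula variant with
  `log2` outside the sum is available behind `as_printed = TRUE` for
  comparison and is undefined for non-positive summed improvements.
* **Posterior parameterization**: encoders emit means and log-variances;
  log-variances are clamped to [−12, 8] for numerical safety (gradient
  zero at the clamp, which is never active in practice).
* **Ties and degenerate inputs**: `mode_nearest()` breaks frequency ties
  toward the lower mode via `which.min`; zero-amplitude modes yield `NA`
  phase similarity; a zero rate is accepted only against a zero count;
  splits refuse datasets with fewer trials than folds.
* **Seeds**: every stochastic operation (simulation, splits, training,
  shuffle nulls, co-smoothing masks) takes an explicit seed and restores
  the caller's RNG state, so library calls never perturb user RNG.

## Design decisions where the design was open

* **Controller wiring**: the controller encoder is a standalone causal
  GRU over movement-phase spikes; the generator state is *not* fed back
  into it. This matches the operation signature (controller input =
  movement spikes), keeps inference and generation separable, and none
  of the causality/ablation properties depend on the richer wiring.
* **Prior over control inputs**: zero-mean unit Gaussian, independent
  across bins. An autoregressive prior is a known alternative; it was
  not implemented because the independent prior already yields the
  transient, movement-locked inputs the analyses require.
* **$g_0$ dimensionality**: equal to the generator state size (the
  posterior directly parameterizes the initial state).
* **Behavior loss support**: the decoder emits all $T$ bins and the
  behavior loss covers all bins by default (`behavior_loss_bins =
  "movement"` restricts it).
* **Splits** are stratified by condition when every condition has enough
  trials, so condition-average baselines are computable on every side of
  every split.
* **Cross-validation pooling**: per-fold R² is computed against the
  grand mean of the pooled out-of-fold set, so the per-fold values
  decompose the pooled score exactly and the pooled R² provably lies
  within their range.
* **Fixed-lag regression target composition**: by default the predicted
  time bins are restricted to the inner window reachable at every lag,
  so the R² denominator is identical across lags; otherwise profile
  shape confounds lag structure with within-trial nonstationarity of
  behavioral variance.
* **Peak flattening**: whether ablation "flattens" a fixed-lag peak is
  quantified by peak prominence (profile maximum minus profile median),
  reported as `peak_prominence`. An autonomous model predicts its
  planned share at every lag, so its profile is a high flat line: its
  raw maximum measures the planned share, its prominence measures the
  peak. `peak_lag` stays the argmax of the raw profile.
* **Phase similarity pooling**: the default pools complex coefficients
  across trials with amplitude weighting
  ($\sum \langle v_t, v_p\rangle / (\|v_t\|\|v_p\|)$); an unweighted
  per-trial phase-cosine variant is available via `method =
  "per_trial"`. Neither is claimed to be the original figure's exact
  estimator.
* **Oscillatory-neuron nulls** share the per-trial, per-shuffle time
  permutations across neurons (the population is shuffled jointly);
  each neuron's marginal null distribution is unchanged and runtime
  drops by the neuron count.

## Known limitations

* The recurrent stack is plain R matrix algebra: fine at desk scale
  (hundreds of trials, tens of neurons, ~50 dimensional states; a
  200-epoch fit of the bundled configuration takes about 90 s on one
  CPU), not at the scale of the 200-dimensional published architecture
  on long sessions.
* The native bundle is JSON (lossless for counts and for doubles at 17
  significant digits); there is no HDF5/NWB reader in this build
  because no HDF5 binding is available in the target environment.
* The population-based training loop is a sequential, single-machine
  simulation (truncation selection, multiplicative perturbation); it is
  a faithful miniature, not a cluster implementation.
* Checkpoints use R serialization (RDS) and are runtime artifacts, not
  an exchange format.
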