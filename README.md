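# band — behavior-aligned latent dynamics for spiking populations

`band` models trial-aligned spiking neural population recordings with a
semi-supervised sequential autoencoder: Poisson spike counts are
reconstructed from low-dimensional latent dynamics *and*, jointly, a
continuous behavioral signal (e.g. 2-D hand velocity) is reconstructed
from the latent factors. The package is aimed at systems neuroscientists
asking where behavioral variability lives in motor cortical activity —
in particular, at the regime where online movement *corrections* carry a
large share of behavioral variability but only a small share of neural
variability, so purely unsupervised latent models discard them.

## The model

For spike counts $s_{1:T}$ (bins of width $\Delta$) and behavior
$b_{1:T}$, the model maximizes

$$\mathcal{L} = \mathcal{L}_x + \theta\,\mathcal{L}_b
 - \alpha\,\mathcal{L}_{L2} - \beta_{g_0}\mathrm{KL}_{g_0}
 - \beta_u \mathrm{KL}_u,
\qquad
\mathcal{L}_x = \Big\langle \sum_t \log \mathrm{Poisson}(s_t \mid f_t)
\Big\rangle_{g_0, u_{1:T}},
\qquad
\mathcal{L}_b = -\mathrm{MSE}(b, \hat b),$$

where $g_0$ (the initial condition) is inferred from the preparatory
window only, per-bin control inputs $u_t$ are inferred *causally* from
movement-phase spikes, a GRU generator unrolls the latent trajectory,
rates are an exponential-affine readout of the factors, and $\hat b$ is
a sequence-to-sequence linear readout of the whole factor sequence.
Both KL weights are fixed at 1 (the objective is an ELBO). $\theta = 0$
gives the unsupervised baseline; `ablate_controller()` gives the
autonomous variant ($u \equiv 0$) used to attribute reconstruction to
planning versus correction. Evaluation metrics include the Poisson
likelihood, bits/spike and bits/second against a mean-rate null
(co-smoothing variant on held-out neurons included), isotropic $R^2$
pooled over trials/bins/components, and explained behavior variance.

A bundled simulator generates 8-target center-out reaches with
target-dependent initial states, rotational planned dynamics, transient
4–5 Hz corrective oscillations in adaptation-epoch trials, Poisson
spiking, and hand velocity re-entering the latent state with a
configurable ~90 ms sensory delay — with full ground truth for recovery
tests. See `vignettes/band-methods.Rmd` for the model, the simulator's
stated world, and all design decisions.

## Worked example

```r
library(band)

gd <- generate_dataset(sim_config(seed = 1))   # 240 trials, 40 neurons
ds <- gd$dataset
sp <- split_trials(ds, split_spec("holdout", seed = 101))
val <- sample(sp$train, 24)

cfg <- model_config(n_factors = 8, n_control = 4, generator_dim = 48,
                    encoder_dim = 24, prep_bins = 25, theta = 3)
fit <- train_model(cfg, ds, list(train = setdiff(sp$train, val), val = val),
                   train_config(epochs = 120, batch_size = 56, lr = 8e-3,
                                kl_warmup_epochs = 10, seed = 1))

tst <- sp$test
traj  <- band_forward(fit$model, ds[tst])
abl   <- ablate_controller(fit$model)
traj_a <- band_forward(abl, ds[tst])
```

Output of this script (about two minutes on one CPU):

```
trial_dataset: 240 trials x 60 bins x 40 neurons (2 behavior dims)
  bin width 10 ms, prep window 25 bins, aligned to movement_onset
  epochs: BL=80 AD=80 WO=80
   planned corrective   feedback
     0.797      0.023      0.181
band_fit: 120 epochs (best 86), final L_x -1726.589, val obj -0.8511
held-out R2: full 0.85 | ablated 0.53
co-smoothing bits/spike: full 0.130 | ablated 0.119
decoder-weight diagonal peak: -100 ms (truth: -90 ms)
```

Reading it: the simulated world puts ~2% of log-rate variance in the
corrective input and ~18% in the delayed-feedback stream. The full
model reconstructs held-out behavior well ($R^2 = 0.85$); forcing the
control input to zero wipes out the corrective share of behavior
($R^2 \to 0.53$) while the co-smoothing bits/spike on held-out neurons
barely moves (0.130 → 0.119) — corrections are behaviorally large but
neurally small. The behavior-decoder weight matrix, summed in magnitude
along diagonals over the movement phase, peaks at −100 ms, one bin from
the simulator's true −90 ms sensory feedback delay (behavior *leading*
the factors), recovered from spikes alone.

A command-line interface wraps the same functions
(`exec/band simulate|data|train|cv|pbt|ablate|infer|eval|analyze|run`),
and `run_experiment()` executes a declared simulate → train → ablate →
eval → analyze pipeline with a hashed manifest.

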