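#' Poisson log-likelihood of spike counts given rates
#'
#' Total log-likelihood `sum(y * log(lambda) - lambda - log(y!))` over all
#' entries, in nats. Rates are expressed in spikes per bin (same units as
#' the counts). A rate of zero is admissible only where the count is zero
#' (the term is then `-lambda = 0`).
#'
#' @param rates non-negative array of predicted rates, spikes/bin.
#' @param spikes non-negative integral array, same shape as `rates`.
#' @param per_trial if TRUE and inputs are 3-d (trials x bins x neurons),
#'   also return the per-trial totals.
#' @return total log-likelihood (nats); with `per_trial = TRUE`, a list
#'   with `total` and `per_trial`.
#' @export
poisson_log_likelihood <- function(rates, spikes, per_trial = FALSE) {
  if (length(rates) != length(spikes) ||
      !identical(dim(rates) %||% length(rates),
                 dim(spikes) %||% length(spikes)))
    stopf("rates and spikes must have identical shapes")
  if (anyNA(rates) || anyNA(spikes)) stopf("NA in rates or spikes")
  if (any(spikes < 0) || any(spikes != round(spikes)))
    stopf("spikes must be non-negative integers")
  if (any(rates < 0)) stopf("negative rate")
  bad <- rates <= 0 & spikes > 0
  if (any(bad)) stopf("zero rate with nonzero count (%d entries)", sum(bad))
  term <- -rates - lgamma(spikes + 1)
  pos <- rates > 0
  term[pos] <- term[pos] + spikes[pos] * log(rates[pos])
  if (per_trial && length(dim(rates)) == 3L) {
    pt <- apply(term, 1, sum)
    list(total = sum(term), per_trial = pt)
  } else {
    sum(term)
  }
}

#' KL divergence between diagonal Gaussians
#'
#' Closed-form KL(q || p) for diagonal Gaussians, summed over every
#' dimension (and bin) supplied. Defaults to a standard normal prior.
#'
#' @param mu_q,sd_q posterior means and standard deviations (any shape).
#' @param mu_p,sd_p prior means and standard deviations (scalars or
#'   arrays recyclable to the posterior shape).
#' @return scalar KL divergence in nats (>= 0).
#' @export
kl_gaussian <- function(mu_q, sd_q, mu_p = 0, sd_p = 1) {
  if (any(sd_q <= 0) || any(sd_p <= 0)) stopf("non-positive sd")
  sum(log(sd_p / sd_q) + (sd_q^2 + (mu_q - mu_p)^2) / (2 * sd_p^2) - 0.5)
}

## likelihood improvement over the per-neuron mean-rate null, in nats
delta_ll_nats <- function(rates, spikes, baseline_rates = NULL) {
  stopifnot(length(dim(rates)) == 3L, all(dim(rates) == dim(spikes)))
  N <- dim(spikes)[3]
  lam_bar <- baseline_rates %||%
    apply(spikes, 3, mean)  # MLE: mean observed count per bin, per neuron
  base <- aperm(array(lam_bar, dim = c(N, dim(spikes)[1], dim(spikes)[2])),
                c(2, 3, 1))
  poisson_log_likelihood(rates, spikes) -
    poisson_log_likelihood(base, spikes)
}

#' Bits-per-spike and bits-per-second neural reconstruction metrics
#'
#' Poisson log-likelihood improvement of the predicted rates over a
#' per-neuron mean-rate null model, in base-2 units: the established
#' co-smoothing definition `sum(dLL) / (n_sp * ln 2)` bits per spike,
#' and bits/sec = bits/spike * n_sp / total seconds. The variant with the
#' base-2 logarithm applied outside the sum (as occasionally printed) is
#' available via `as_printed = TRUE` for comparison; it is undefined when
#' the summed improvement is non-positive.
#'
#' @param rates predicted rates, trials x bins x neurons, spikes/bin.
#' @param spikes observed counts, same shape.
#' @param bin_width bin width in seconds (required for bits/sec).
#' @param baseline_rates optional per-neuron null rates (spikes/bin);
#'   default: each neuron's mean observed count over the evaluated set.
#' @param as_printed debug flag selecting the log2-outside-the-sum reading.
#' @return scalar metric value.
#' @export
bits_per_spike <- function(rates, spikes, baseline_rates = NULL,
                           as_printed = FALSE) {
  n_sp <- sum(spikes)
  if (n_sp == 0) stopf("no spikes in the evaluation set (n_sp = 0)")
  d <- delta_ll_nats(rates, spikes, baseline_rates)
  if (as_printed) return(log2(d) / n_sp)
  d / (n_sp * log(2))
}

#' @rdname bits_per_spike
#' @export
bits_per_second <- function(rates, spikes, bin_width,
                            baseline_rates = NULL, as_printed = FALSE) {
  n_sp <- sum(spikes)
  total_s <- dim(spikes)[1] * dim(spikes)[2] * bin_width
  bits_per_spike(rates, spikes, baseline_rates, as_printed) * n_sp / total_s
}

#' Isotropic variance-explained R-squared
#'
#' `1 - SSE/SST` pooled over all trials, bins and behavior components,
#' with SST taken against each component's grand mean over trials and
#' bins. Pooling respects that velocity components live in one Euclidean
#' space (the "isotropic" reading); `r2_per_component()` gives the
#' average of per-component scores for comparison.
#'
#' @param y true behavior, trials x bins x components (or matrix/vector).
#' @param f predicted behavior, same shape.
#' @return scalar R-squared (<= 1; unbounded below).
#' @export
r2_isotropic <- function(y, f) {
  if (length(y) != length(f)) stopf("shape mismatch between y and f")
  ym <- as_3d(y); fm <- as_3d(f)
  mu <- apply(ym, 3, mean)
  sst <- sum(sweep(ym, 3, mu)^2)
  if (sst == 0) stopf("zero total variance in y")
  1 - sum((ym - fm)^2) / sst
}

#' @rdname r2_isotropic
#' @export
r2_per_component <- function(y, f) {
  ym <- as_3d(y); fm <- as_3d(f)
  B <- dim(ym)[3]
  mean(vapply(seq_len(B), function(b) {
    yy <- ym[, , b]; ff <- fm[, , b]
    1 - sum((yy - ff)^2) / sum((yy - mean(yy))^2)
  }, 0))
}

as_3d <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  array(x, dim = c(length(x), 1L, 1L))
}

#' Explained behavior variance (total variance minus MSE)
#'
#' `Var(true) - MSE(true, predicted)` with both terms pooled over trials,
#' bins and components exactly as in [r2_isotropic()], so that the
#' identity `EV = Var * R^2` holds. Units are behavior units squared
#' (cm^2/s^2 for velocity).
#'
#' @inheritParams r2_isotropic
#' @return scalar explained variance.
#' @export
explained_behavior_variance <- function(y, f) {
  ym <- as_3d(y); fm <- as_3d(f)
  mu <- apply(ym, 3, mean)
  v <- sum(sweep(ym, 3, mu)^2) / length(ym)
  mse <- mean((ym - fm)^2)
  v - mse
}

#' Co-smoothing bits per spike on held-out neurons
#'
#' The benchmark-style evaluation of population-dynamics reconstruction:
#' a seeded fraction of neurons is masked from the encoders (channels
#' zeroed, held-in channels rescaled to preserve input statistics, as
#' during input-dropout training), rates are generated for all neurons,
#' and the bits/spike improvement over the mean-rate null is scored on
#' the held-out neurons only. Because the causal controller cannot see
#' the held-out channels, concurrent "self-copying" of spike noise into
#' rates cannot inflate this score; it measures shared latent structure.
#'
#' @param model a `band_model`.
#' @param dataset a `trial_dataset` (or spikes array).
#' @param holdout_fraction fraction of neurons held out (default 0.25).
#' @param seed seed for the neuron selection.
#' @return scalar co-smoothing bits/spike, with attribute
#'   `held_out` (neuron indices).
#' @export
cosmooth_bits_per_spike <- function(model, dataset, holdout_fraction = 0.25,
                                    seed = 1L) {
  spikes <- if (inherits(dataset, "trial_dataset")) dataset$spikes else
    dataset
  N <- dim(spikes)[3]
  n_out <- max(1L, round(holdout_fraction * N))
  held_out <- with_seed(seed, sort(sample.int(N, n_out)))
  masked <- spikes
  masked[, , held_out] <- 0
  keep_scale <- N / (N - n_out)
  masked[, , -held_out] <- masked[, , -held_out] * keep_scale
  traj <- band_forward(model, masked)
  out <- bits_per_spike(traj$rates[, , held_out, drop = FALSE],
                        spikes[, , held_out, drop = FALSE])
  attr(out, "held_out") <- held_out
  out
}

#' Hyperparameter-search objectives
#'
#' `pbt_objective()` is the normalized objective used for population-based
#' training: the Poisson log-likelihood per neuron-bin minus the
#' behavior-reconstruction deficit, `L_x/(N*T) - (1 - R2)`.
#' `pbt_objective_nlb()` is the benchmark variant `L_x - 1e-4 * MSE`.
#' Both are to be maximized.
#'
#' @param L_x Poisson log-likelihood (nats).
#' @param N number of neurons; `T` number of bins per trial.
#' @param T number of time bins.
#' @param r2 behavior R-squared.
#' @param mse behavior mean squared error.
#' @return scalar objective (maximize).
#' @export
pbt_objective <- function(L_x, N, T, r2) {
  stopifnot(N > 0, T > 0)
  L_x / (N * T) - (1 - r2)
}

#' @rdname pbt_objective
#' @export
pbt_objective_nlb <- function(L_x, mse) L_x - 1e-4 * mse
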