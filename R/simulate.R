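#' Configuration for the center-out reach simulator
#'
#' The simulator generates trial-aligned spiking + behavior data with the
#' statistical structure the model assumes: a preparatory window in which
#' target-dependent initial latent states are held, planned movement as
#' autonomous rotational latent dynamics, transient 4-5 Hz oscillatory
#' corrective inputs present only in adaptation-epoch trials, behavior as
#' a linear readout of the latents, delayed behavioral feedback re-entering
#' designated latent dimensions, and Poisson spike emission.
#'
#' The true latent space has a fixed layout of 8 dimensions: 4 "planned"
#' dimensions (two rotation planes whose initial state encodes the target
#' angle), 2 "corrective" dimensions carrying the decaying oscillation,
#' and 2 "feedback" dimensions carrying the (gain-scaled) hand velocity
#' from `feedback_lag` seconds earlier.
#'
#' @param n_neurons number of Poisson neurons.
#' @param n_factors_true true latent dimensionality; the layout is fixed,
#'   so this must be 8.
#' @param T trial length in bins.
#' @param prep_bins preparatory window length in bins (default 25, i.e.
#'   250 ms at the default 10 ms bin).
#' @param bin_width bin width in seconds.
#' @param n_targets number of reach targets on the ring (default 8).
#' @param trials_per_epoch named counts of trials per target for the
#'   BL / AD / WO epochs.
#' @param rotation_period period (s) of the planned rotational dynamics.
#' @param osc_freq corrective oscillation frequency, Hz (default 5).
#' @param osc_onset_jitter corrective-onset jitter window (s), uniform
#'   after movement onset; a full-cycle window (default 0.2 s at 5 Hz)
#'   de-phase-locks oscillations from the go cue so condition averages
#'   wash them out.
#' @param osc_amplitude corrective oscillation amplitude, latent units.
#' @param osc_decay_tau corrective envelope decay constant (s).
#' @param feedback_lag sensory feedback delay (s), default 0.090.
#' @param feedback_gain gain applied to delayed behavior before it
#'   re-enters the feedback latents (latent units per behavior unit).
#' @param base_rate baseline firing rate, Hz.
#' @param noise_sd per-step latent state noise on the planned dimensions
#'   (latent units); 0 gives deterministic latents per target.
#' @param ic_jitter_scale initial-condition jitter expressed as a
#'   multiple of `noise_sd` (trial-to-trial variability of reach angle,
#'   radians, and radius); most planned variability is preparatory, so
#'   the jitter dominates the per-step noise by default.
#' @param neural_load_plan,neural_load_corr,neural_load_fb standard
#'   deviations of per-neuron log-rate loadings on the planned,
#'   corrective and feedback latents.
#' @param behavior_gain_plan peak planned speed scale, cm/s.
#' @param behavior_gain_corr corrective-latent to velocity gain, cm/s.
#' @param motor_noise_sd optional motor/execution noise added to each
#'   velocity sample (cm/s; default 0). When nonzero, this component is
#'   absent from the concurrent latent state and re-enters the latents
#'   only through the delayed feedback pathway, so it is decodable from
#'   neural activity solely at the feedback lag.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 40L,
                       n_factors_true = 8L,
                       T = 60L,
                       prep_bins = 25L,
                       bin_width = 0.010,
                       n_targets = 8L,
                       trials_per_epoch = c(BL = 10L, AD = 10L, WO = 10L),
                       rotation_period = 1.0,
                       osc_freq = 5.0,
                       osc_onset_jitter = 0.2,
                       osc_amplitude = 1.0,
                       osc_decay_tau = 0.30,
                       feedback_lag = 0.090,
                       feedback_gain = 0.10,
                       base_rate = 30,
                       noise_sd = 0.01,
                       ic_jitter_scale = 12,
                       neural_load_plan = 0.50,
                       neural_load_corr = 0.16,
                       neural_load_fb = 0.12,
                       behavior_gain_plan = 20,
                       behavior_gain_corr = 40,
                       motor_noise_sd = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  ## accept list input (e.g. parsed YAML) and unnamed length-3 counts,
  ## which are taken in BL, AD, WO order
  tpe <- unlist(cfg$trials_per_epoch)
  if (is.null(names(tpe)) && length(tpe) == 3L)
    names(tpe) <- c("BL", "AD", "WO")
  cfg$trials_per_epoch <- tpe
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(config$n_factors_true == 8L,
              "latent layout is fixed: 4 planned + 2 corrective + 2 feedback")
  assert_that(config$base_rate > 0, "base_rate must be > 0")
  assert_that(config$prep_bins > 0 && config$prep_bins < config$T,
              "prep_bins must satisfy 0 < prep_bins < T")
  if (config$osc_freq >= 1 / (2 * config$bin_width))
    stopf("osc_freq %.1f Hz violates the Nyquist limit %.1f Hz",
          config$osc_freq, 1 / (2 * config$bin_width))
  assert_that(config$feedback_lag >= 0, "feedback_lag must be >= 0")
  assert_that(all(c("BL", "AD", "WO") %in% names(config$trials_per_epoch)),
              "trials_per_epoch must name BL, AD, WO")
  invisible(config)
}

PLAN_DIMS <- 1:4
CORR_DIMS <- 5:6
FB_DIMS <- 7:8

#' Simulate ground-truth latent trajectories and behavior
#'
#' Draws per-trial latent trajectories under the stated update rule
#' (see [sim_config()]), returning full ground truth for recovery tests:
#' the latents, the additive corrective inputs (exactly zero in every
#' BL/WO trial), the realized state noise, both readout maps, and the
#' feedback lag in bins. With the corrective input and noise subtracted,
#' the latent sequence satisfies the update rule to machine precision
#' (see [check_latent_recursion()]).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`.
#' @export
simulate_latents <- function(config) {
  validate_sim_config(config)
  Tn <- config$T; prep <- config$prep_bins
  lag_bins <- as.integer(round(config$feedback_lag / config$bin_width))
  epochs <- rep(names(config$trials_per_epoch),
                times = config$n_targets * unlist(config$trials_per_epoch))
  targets <- unlist(lapply(unlist(config$trials_per_epoch), function(m)
    rep(seq_len(config$n_targets), each = m)))
  K <- length(epochs)
  D <- 8L

  ## readouts: behavior reads planned velocity dims (2,4) and the
  ## corrective dims; feedback dims are read by neurons only.
  C_beh <- matrix(0, 2, D)
  C_beh[1, 2] <- config$behavior_gain_plan
  C_beh[2, 4] <- config$behavior_gain_plan
  C_beh[1, 5] <- config$behavior_gain_corr
  C_beh[2, 6] <- config$behavior_gain_corr

  omega <- 2 * pi / config$rotation_period * config$bin_width
  R2 <- matrix(c(cos(omega), sin(omega), -sin(omega), cos(omega)), 2, 2)

  out <- with_seed(config$seed, {
    W <- cbind(
      matrix(rnorm(config$n_neurons * 4, sd = config$neural_load_plan),
             config$n_neurons, 4),
      matrix(rnorm(config$n_neurons * 2, sd = config$neural_load_corr),
             config$n_neurons, 2),
      matrix(rnorm(config$n_neurons * 2, sd = config$neural_load_fb),
             config$n_neurons, 2))
    latents <- array(0, dim = c(K, Tn, D))
    corr_in <- array(0, dim = c(K, Tn, D))
    noise <- array(0, dim = c(K, Tn, D))
    behavior <- array(0, dim = c(K, Tn, 2))
    onset_bin <- integer(K)
    for (k in seq_len(K)) {
      jit_sd <- config$ic_jitter_scale * config$noise_sd
      phi <- 2 * pi * (targets[k] - 1) / config$n_targets +
        jit_sd * rnorm(1)
      r0 <- 1 + jit_sd * rnorm(1)
      x <- matrix(0, Tn, D)
      eta <- matrix(0, Tn, D)
      if (config$noise_sd > 0)
        eta[, PLAN_DIMS] <- rnorm(Tn * 4, sd = config$noise_sd)
      eta[1, ] <- 0  # the initial condition is not part of the recursion
      x[1, PLAN_DIMS] <- r0 * c(cos(phi), 0, sin(phi), 0)
      ## corrective input: decaying sinusoid, adaptation trials only
      s <- matrix(0, Tn, D)
      if (epochs[k] == "AD" && config$osc_amplitude > 0) {
        jit <- stats::runif(1, 0, config$osc_onset_jitter)
        t0 <- prep + 1L + as.integer(round(jit / config$bin_width))
        onset_bin[k] <- t0
        a <- config$osc_amplitude * stats::runif(1, 0.75, 1.25)
        if (t0 <= Tn) {
          tt <- (seq(t0, Tn) - t0) * config$bin_width
          env <- a * exp(-tt / config$osc_decay_tau)
          s[seq(t0, Tn), 5] <- env * sin(2 * pi * config$osc_freq * tt)
          s[seq(t0, Tn), 6] <- env * cos(2 * pi * config$osc_freq * tt)
        }
      }
      eps_m <- matrix(0, Tn, 2)
      if (config$motor_noise_sd > 0)
        eps_m[] <- rnorm(Tn * 2, sd = config$motor_noise_sd)
      bmat <- matrix(0, Tn, 2)
      bmat[1, ] <- drop(C_beh %*% x[1, ]) + eps_m[1, ]
      for (t in 2:Tn) {
        p_prev <- x[t - 1, PLAN_DIMS]
        p <- if (t <= prep + 1L) p_prev else {
          c(R2 %*% p_prev[1:2], R2 %*% p_prev[3:4])
        }
        x[t, PLAN_DIMS] <- p + eta[t, PLAN_DIMS]
        x[t, CORR_DIMS] <- s[t, CORR_DIMS]    # decay 0: state = input
        ## delayed feedback of the realized (motor-noisy) behavior
        b_lag <- if (t - lag_bins >= 1) bmat[t - lag_bins, ] else c(0, 0)
        x[t, FB_DIMS] <- config$feedback_gain * b_lag
        bmat[t, ] <- drop(C_beh %*% x[t, ]) + eps_m[t, ]
      }
      latents[k, , ] <- x
      corr_in[k, , ] <- s
      noise[k, , ] <- eta
      behavior[k, , ] <- bmat
    }
    list(W = W, latents = latents, corr_in = corr_in, noise = noise,
         behavior = behavior, onset_bin = onset_bin)
  })

  structure(list(
    latents = out$latents,
    corrective_input = out$corr_in,
    state_noise = out$noise,
    behavior = out$behavior,
    readout_neural = list(W = out$W,
                          b0 = log(config$base_rate * config$bin_width)),
    readout_behavior = C_beh,
    feedback_lag_bins = lag_bins,
    condition = targets,
    epoch = epochs,
    onset_bin = out$onset_bin,
    config = config
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  d <- dim(x$latents)
  cat(sprintf("sim_truth: %d trials x %d bins x %d true latents\n",
              d[1], d[2], d[3]))
  sh <- log_rate_variance_share(x)
  cat(sprintf("  log-rate variance shares: planned %.1f%%, corrective %.1f%%, feedback %.1f%%\n",
              100 * sh["planned"], 100 * sh["corrective"], 100 * sh["feedback"]))
  invisible(x)
}

#' Verify the stated latent update rule on simulated ground truth
#'
#' Reconstructs every latent step from the previous state, the recorded
#' corrective input, the recorded state noise and the lagged-behavior
#' feedback term, and returns the maximum absolute discrepancy. With the
#' corrective input subtracted the remaining sequence satisfies the
#' autonomous (plus feedback) recursion exactly, so the result is at
#' machine precision for any noise level.
#'
#' @param truth a `sim_truth`.
#' @return maximum absolute deviation from the stated recursion.
#' @export
check_latent_recursion <- function(truth) {
  cfg <- truth$config
  Tn <- cfg$T; prep <- cfg$prep_bins
  omega <- 2 * pi / cfg$rotation_period * cfg$bin_width
  R2 <- matrix(c(cos(omega), sin(omega), -sin(omega), cos(omega)), 2, 2)
  lag <- truth$feedback_lag_bins
  K <- dim(truth$latents)[1]
  err <- 0
  for (k in seq_len(K)) {
    x <- truth$latents[k, , ]
    s <- truth$corrective_input[k, , ]
    eta <- truth$state_noise[k, , ]
    b <- truth$behavior[k, , ]
    for (t in 2:Tn) {
      p_prev <- x[t - 1, PLAN_DIMS]
      p <- if (t <= prep + 1L) p_prev else c(R2 %*% p_prev[1:2],
                                             R2 %*% p_prev[3:4])
      pred <- numeric(8)
      pred[PLAN_DIMS] <- p + eta[t, PLAN_DIMS]
      pred[CORR_DIMS] <- s[t, CORR_DIMS]
      pred[FB_DIMS] <- cfg$feedback_gain *
        (if (t - lag >= 1) b[t - lag, ] else c(0, 0))
      err <- max(err, max(abs(pred - x[t, ])))
    }
  }
  err
}

#' Emit Poisson spikes from simulated ground truth
#'
#' Rates are `exp(b0 + latents %*% t(W))` spikes per bin; counts are
#' drawn independently per trial, bin and neuron. Reproducible given the
#' config seed (a derived stream, so latents and spikes have independent
#' randomness).
#'
#' @param truth a `sim_truth` from [simulate_latents()].
#' @param config the same [sim_config()] used to build `truth`.
#' @return a [trial_dataset()] carrying condition/epoch labels and
#'   `prep_bins` from the config.
#' @export
emit_spikes <- function(truth, config = truth$config) {
  log_rates <- sim_log_rates(truth)
  rates <- exp(log_rates)
  if (!all(is.finite(rates))) stopf("rate overflow: non-finite Poisson rate")
  K <- dim(rates)[1]
  spikes <- with_seed(config$seed + 1000003L, {
    array(stats::rpois(length(rates), lambda = rates), dim = dim(rates))
  })
  trial_dataset(
    spikes = spikes,
    behavior = truth$behavior,
    bin_width = config$bin_width,
    condition = truth$condition,
    epoch = truth$epoch,
    prep_bins = config$prep_bins,
    alignment = "movement_onset",
    units = "cm/s"
  )
}

## trials x bins x neurons array of log rates (spikes/bin)
sim_log_rates <- function(truth) {
  W <- truth$readout_neural$W; b0 <- truth$readout_neural$b0
  d <- dim(truth$latents)
  flat <- matrix(truth$latents, d[1] * d[2], d[3])
  lr <- flat %*% t(W) + b0
  array(lr, dim = c(d[1], d[2], nrow(W)))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Composition of [simulate_latents()] and [emit_spikes()].
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a `trial_dataset`) and `truth`
#'   (a `sim_truth`).
#' @export
generate_dataset <- function(config = sim_config()) {
  truth <- simulate_latents(config)
  dataset <- emit_spikes(truth, config)
  list(dataset = dataset, truth = truth)
}

#' Variance decomposition of the simulated log rates
#'
#' Fraction of pooled log-rate variance (over trials and bins, summed
#' over neurons) contributed by the planned, corrective and feedback
#' latent groups. Reports how "small" the neural footprint of the
#' corrective signal is.
#'
#' @param truth a `sim_truth`.
#' @param epoch restrict to trials of one epoch (default `"AD"`, where
#'   corrective inputs live).
#' @return named numeric vector of shares summing to ~1 (cross terms
#'   are attributed proportionally via total-variance normalization).
#' @export
log_rate_variance_share <- function(truth, epoch = "AD") {
  keep <- truth$epoch == epoch
  if (!any(keep)) keep <- rep(TRUE, length(truth$epoch))
  W <- truth$readout_neural$W
  x <- truth$latents[keep, , , drop = FALSE]
  d <- dim(x)
  flat <- matrix(x, d[1] * d[2], d[3])
  contrib_var <- function(dims) {
    c_ <- flat[, dims, drop = FALSE] %*% t(W[, dims, drop = FALSE])
    sum(apply(c_, 2, stats::var))
  }
  v <- c(planned = contrib_var(PLAN_DIMS),
         corrective = contrib_var(CORR_DIMS),
         feedback = contrib_var(FB_DIMS))
  v / sum(v)
}

#' Variance decomposition of simulated behavior
#'
#' Fraction of pooled behavior variance (movement bins of the selected
#' epoch) contributed by the corrective latents versus the planned
#' latents. Together with [log_rate_variance_share()] this quantifies
#' the premise that a small share of neural variability can carry a
#' large share of behavioral variability.
#'
#' @inheritParams log_rate_variance_share
#' @return named vector with `planned` and `corrective` shares.
#' @export
behavior_variance_share <- function(truth, epoch = "AD") {
  keep <- truth$epoch == epoch
  cfg <- truth$config
  mv <- seq(cfg$prep_bins + 1L, cfg$T)
  x <- truth$latents[keep, mv, , drop = FALSE]
  d <- dim(x)
  flat <- matrix(x, d[1] * d[2], d[3])
  C <- truth$readout_behavior
  part <- function(dims) {
    b <- flat[, dims, drop = FALSE] %*% t(C[, dims, drop = FALSE])
    sum(apply(b, 2, stats::var))
  }
  v <- c(planned = part(PLAN_DIMS), corrective = part(CORR_DIMS))
  v / sum(v)
}
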