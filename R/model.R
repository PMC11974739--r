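#' Model configuration for the behavior-aligned sequential autoencoder
#'
#' Architecture and loss weights for the semi-supervised sequential
#' autoencoder: a bidirectional GRU initial-condition encoder restricted
#' to the preparatory window, a strictly causal forward-GRU controller
#' encoder over movement bins, a GRU generator whose state is read out
#' linearly into factors and exponential-affine into Poisson rates, and a
#' jointly trained sequence-to-sequence linear behavior decoder. Setting
#' `theta = 0` gives the unsupervised variant (same capacity, no behavior
#' supervision).
#'
#' @param n_factors number of latent factors (8 for the interpretable
#'   variant analysed here; 100 in large-scale comparisons).
#' @param n_control controller (inferred input) dimensionality; 0 removes
#'   the controller entirely.
#' @param generator_dim generator GRU state size (default 200).
#' @param encoder_dim encoder GRU state size (default 64), used for both
#'   the initial-condition and controller encoders.
#' @param prep_bins preparatory window length in bins (default 25): the
#'   initial-condition encoder sees only bins 1..prep_bins, the
#'   controller only bins prep_bins+1..T.
#' @param causal_controller must the controller be a strictly
#'   forward-in-time recurrence (default TRUE; FALSE is not implemented —
#'   causality is a structural commitment of this model).
#' @param behavior_dims number of behavior channels (default 2).
#' @param behavior_decoder `"seq2seq_linear"` (one affine map from the
#'   flattened factor sequence to the flattened behavior sequence) or
#'   `"per_step_linear"` (the same map per bin).
#' @param behavior_loss_bins compute the behavior loss over `"all"` bins
#'   (default) or only `"movement"` bins.
#' @param theta behavior-supervision weight (0 = unsupervised).
#' @param alpha L2 weight on the recurrent kernels of generator and
#'   controller.
#' @param beta_kl_g0,beta_kl_u KL weights; fixed to 1 by default so the
#'   objective is a proper evidence lower bound.
#' @return object of class `model_config`.
#' @export
model_config <- function(n_factors = 8L,
                         n_control = 4L,
                         generator_dim = 200L,
                         encoder_dim = 64L,
                         prep_bins = 25L,
                         causal_controller = TRUE,
                         behavior_dims = 2L,
                         behavior_decoder = c("seq2seq_linear",
                                              "per_step_linear"),
                         behavior_loss_bins = c("all", "movement"),
                         theta = 1,
                         alpha = 1e-4,
                         beta_kl_g0 = 1,
                         beta_kl_u = 1) {
  behavior_decoder <- match.arg(behavior_decoder)
  behavior_loss_bins <- match.arg(behavior_loss_bins)
  assert_that(n_control >= 0, "n_control must be >= 0")
  assert_that(isTRUE(causal_controller),
              "only the causal controller is implemented")
  assert_that(theta >= 0 && alpha >= 0 && beta_kl_g0 >= 0 && beta_kl_u >= 0,
              "loss weights must be >= 0")
  structure(list(
    n_factors = as.integer(n_factors), n_control = as.integer(n_control),
    generator_dim = as.integer(generator_dim),
    encoder_dim = as.integer(encoder_dim),
    prep_bins = as.integer(prep_bins),
    causal_controller = TRUE,
    behavior_dims = as.integer(behavior_dims),
    behavior_decoder = behavior_decoder,
    behavior_loss_bins = behavior_loss_bins,
    theta = theta, alpha = alpha,
    beta_kl_g0 = beta_kl_g0, beta_kl_u = beta_kl_u
  ), class = "model_config")
}

#' Initialize a model
#'
#' Builds all parameter tensors for a given dataset geometry. The
#' sequence-to-sequence decoder is specific to the trial length `T` used
#' at initialization (the map is T-by-T in time).
#'
#' @param config a [model_config()].
#' @param n_neurons number of observed neurons.
#' @param T trial length in bins.
#' @param seed RNG seed for initialization.
#' @param init_log_rate initial per-neuron log rate (spikes/bin) for the
#'   rate readout bias; set it near `log(mean count)` of the data.
#' @return object of class `band_model`.
#' @export
band_model <- function(config, n_neurons, T, seed = 1L,
                       init_log_rate = log(0.1)) {
  stopifnot(inherits(config, "model_config"))
  assert_that(config$prep_bins < T, "prep_bins must be < T")
  E <- config$encoder_dim; G <- config$generator_dim
  Fn <- config$n_factors; C <- config$n_control
  Bd <- config$behavior_dims
  params <- with_seed(seed, {
    p <- list(
      enc_f = gru_init(n_neurons, E),
      enc_b = gru_init(n_neurons, E),
      ic_head = linear_init(2 * E, 2 * G),
      gen = gru_init(max(C, 1L), G),
      fac = list(W = matrix(stats::rnorm(G * Fn, sd = 1 / sqrt(G)), G, Fn)),
      rate = linear_init(Fn, n_neurons, scale = 0.1 / sqrt(Fn)),
      beh = if (config$behavior_decoder == "seq2seq_linear") {
        list(W = matrix(0, T * Fn, T * Bd), b = numeric(T * Bd))
      } else {
        list(W = matrix(0, Fn, Bd), b = numeric(Bd))
      }
    )
    if (C > 0) {
      p$con <- gru_init(n_neurons, E)
      p$con_head <- linear_init(E, 2 * C)
      p$con_head$b[(C + 1):(2 * C)] <- -2  # posterior sd ~ exp(-1)
    }
    p$ic_head$b[(G + 1):(2 * G)] <- -2
    p$rate$b <- rep(init_log_rate, n_neurons)
    p
  })
  structure(list(config = config, params = params, T = as.integer(T),
                 n_neurons = as.integer(n_neurons), ablated = FALSE),
            class = "band_model")
}

#' @export
print.band_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "band_model: %d factors, %d control dims%s, generator %d, encoders %d\n",
    cfg$n_factors, cfg$n_control,
    if (x$ablated) " (controller ablated)" else "",
    cfg$generator_dim, cfg$encoder_dim))
  cat(sprintf("  %d neurons, T = %d bins (prep %d), theta = %g\n",
              x$n_neurons, x$T, cfg$prep_bins, cfg$theta))
  invisible(x)
}

clamp_logvar <- function(lv) pmin(pmax(lv, -12), 8)

#' Encode the initial-condition posterior from preparatory spikes
#'
#' The encoder sees only the preparatory window: its input shape is
#' trials x prep_bins x neurons, so movement-phase spikes cannot
#' influence the inferred initial condition by construction. A
#' bidirectional GRU is run over the window and the two final states are
#' mapped to the mean and standard deviation of a diagonal Gaussian
#' posterior over the generator's initial state.
#'
#' @param model a `band_model`.
#' @param spikes_prep array trials x prep_bins x neurons.
#' @return list with `mean` and `sd` (trials x generator_dim matrices).
#' @export
encode_initial_condition <- function(model, spikes_prep) {
  cfg <- model$config
  if (dim(spikes_prep)[2] != cfg$prep_bins)
    stopf("initial-condition encoder expects exactly %d preparatory bins, got %d",
          cfg$prep_bins, dim(spikes_prep)[2])
  ic <- ic_encoder_forward(model$params, cfg, spikes_prep)
  list(mean = ic$mean, sd = ic$sd)
}

ic_encoder_forward <- function(params, cfg, spikes_prep) {
  X <- seq_to_list(spikes_prep)
  B <- nrow(X[[1]])
  E <- cfg$encoder_dim
  h0 <- matrix(0, B, E)
  fwd <- gru_forward(X, h0, params$enc_f)
  bwd <- gru_forward(rev(X), h0, params$enc_b)
  hcat <- cbind(fwd$H[[length(X)]], bwd$H[[length(X)]])
  out <- linear_forward(hcat, params$ic_head)
  G <- cfg$generator_dim
  lv <- clamp_logvar(out[, (G + 1):(2 * G), drop = FALSE])
  list(mean = out[, 1:G, drop = FALSE], sd = exp(0.5 * lv), lv = lv,
       fwd = fwd, bwd = bwd, hcat = hcat, X = X)
}

#' Encode the controller posterior from movement-phase spikes
#'
#' A strictly causal (forward-in-time) GRU over movement bins; the
#' posterior over the control input at movement bin t is a function only
#' of movement-phase spikes at bins <= t. With `n_control = 0` an empty
#' posterior is returned and the model is purely autonomous.
#'
#' @param model a `band_model`.
#' @param spikes_move array trials x (T - prep_bins) x neurons.
#' @return list with `mean` and `sd` arrays, trials x movement bins x
#'   n_control (zero-width when the model has no controller).
#' @export
encode_controller <- function(model, spikes_move) {
  cfg <- model$config
  Tm <- dim(spikes_move)[2]
  B <- dim(spikes_move)[1]
  if (cfg$n_control == 0L) {
    z <- array(0, dim = c(B, Tm, 0L))
    return(list(mean = z, sd = z))
  }
  if (Tm < 1) stopf("controller requested (n_control > 0) but there are no movement bins")
  con <- controller_forward(model$params, cfg, spikes_move)
  list(mean = con$mean, sd = con$sd)
}

controller_forward <- function(params, cfg, spikes_move) {
  X <- seq_to_list(spikes_move)
  B <- nrow(X[[1]])
  h0 <- matrix(0, B, cfg$encoder_dim)
  rnn <- gru_forward(X, h0, params$con)
  C <- cfg$n_control
  mean_l <- vector("list", length(X)); lv_l <- vector("list", length(X))
  for (t in seq_along(X)) {
    out <- linear_forward(rnn$H[[t]], params$con_head)
    mean_l[[t]] <- out[, 1:C, drop = FALSE]
    lv_l[[t]] <- clamp_logvar(out[, (C + 1):(2 * C), drop = FALSE])
  }
  list(mean = list_to_seq(mean_l),
       sd = exp(0.5 * list_to_seq(lv_l)),
       lv = lv_l, mean_l = mean_l, rnn = rnn, X = X)
}

#' Unroll the generator from an initial condition and control inputs
#'
#' The generator GRU receives zero input during the preparatory window
#' and the control input at movement bins, unrolls T steps from
#' `g0`, and is read out linearly into factors and exponential-affine
#' into strictly positive Poisson rates (spikes/bin). Supplying `u = NULL`
#' (or all zeros) reproduces the autonomous trajectory exactly.
#'
#' @param model a `band_model`.
#' @param g0 trials x generator_dim matrix of initial states.
#' @param u trials x movement-bins x n_control control inputs, or NULL.
#' @return list with `factors` (trials x T x n_factors), `rates`
#'   (trials x T x neurons) and `states`.
#' @export
generate_trajectory <- function(model, g0, u = NULL) {
  cfg <- model$config
  gen <- generator_forward(model$params, cfg, model$T, g0, u)
  if (!all(is.finite(gen$rates))) stopf("non-finite rates in generator output")
  list(factors = gen$factors, rates = gen$rates, states = gen$H)
}

generator_forward <- function(params, cfg, Tn, g0, u = NULL) {
  B <- nrow(g0)
  Cin <- max(cfg$n_control, 1L)
  prep <- cfg$prep_bins
  X <- vector("list", Tn)
  zero <- matrix(0, B, Cin)
  for (t in seq_len(Tn)) X[[t]] <- zero
  if (!is.null(u) && cfg$n_control > 0L && dim(u)[3] > 0) {
    for (t in seq_len(dim(u)[2])) {
      X[[prep + t]] <- array(u[, t, ], dim = c(B, cfg$n_control))
    }
  }
  rnn <- gru_forward(X, g0, params$gen)
  fac_l <- lapply(rnn$H, function(h) h %*% params$fac$W)
  lograte_l <- lapply(fac_l, function(f) linear_forward(f, params$rate))
  list(factors = list_to_seq(fac_l),
       rates = list_to_seq(lapply(lograte_l, exp)),
       lograte_l = lograte_l, fac_l = fac_l, H = rnn$H, rnn = rnn, X = X)
}

## time-major flattening: feature (t-1)*F + f  <->  factors[, t, f]
flatten_seq <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1, 3, 2)), d[1], d[2] * d[3])
}

unflatten_seq <- function(m, Tn, D) {
  aperm(array(m, dim = c(nrow(m), D, Tn)), c(1, 3, 2))
}

#' Decode behavior from a factor sequence
#'
#' Applies the sequence-to-sequence affine map: the factor sequence of a
#' trial is flattened (time-major) into one feature vector and mapped to
#' the flattened behavior sequence. The map is trained jointly with the
#' rest of the model and is specific to the trial length T.
#'
#' @param model a `band_model`.
#' @param factors trials x T x n_factors array.
#' @return trials x T x behavior_dims array of predicted behavior.
#' @export
decode_behavior_seq2seq <- function(model, factors) {
  cfg <- model$config
  if (dim(factors)[2] != model$T)
    stopf("decoder was trained for T = %d bins, got %d", model$T,
          dim(factors)[2])
  if (cfg$behavior_decoder == "seq2seq_linear") {
    flat <- flatten_seq(factors)
    pred <- linear_forward(flat, model$params$beh)
    unflatten_seq(pred, model$T, cfg$behavior_dims)
  } else {
    d <- dim(factors)
    flat <- matrix(aperm(factors, c(1, 2, 3)), d[1] * d[2], d[3])
    pred <- linear_forward(flat, model$params$beh)
    array(pred, dim = c(d[1], d[2], cfg$behavior_dims))
  }
}

#' Extract the sequence-to-sequence decoder weight matrix
#'
#' Returns the full (T*n_factors) x (T*behavior_dims) affine map together
#' with an indexed per-pair view: `weight_block(dw, f, b)` is the T x T
#' matrix whose entry (tf, tb) is the weight from factor f at bin tf to
#' behavior component b at bin tb. Rows above the diagonal are
#' feedforward (factors preceding behavior), rows below are feedback.
#'
#' @param model a trained `band_model` with the seq2seq decoder.
#' @return object of class `decoder_weights`.
#' @export
band_decoder_weights <- function(model) {
  cfg <- model$config
  assert_that(cfg$behavior_decoder == "seq2seq_linear",
              "decoder weight matrix requires the seq2seq decoder")
  structure(list(weights = model$params$beh$W, bias = model$params$beh$b,
                 T = model$T, n_factors = cfg$n_factors,
                 behavior_dims = cfg$behavior_dims),
            class = "decoder_weights")
}

#' @rdname band_decoder_weights
#' @param dw a `decoder_weights` object.
#' @param factor factor index.
#' @param behavior_dim behavior component index.
#' @export
weight_block <- function(dw, factor, behavior_dim) {
  stopifnot(inherits(dw, "decoder_weights"))
  rows <- (seq_len(dw$T) - 1L) * dw$n_factors + factor
  cols <- (seq_len(dw$T) - 1L) * dw$behavior_dims + behavior_dim
  dw$weights[rows, cols, drop = FALSE]
}

#' Full forward pass of the model
#'
#' Runs both encoders, draws (or fixes at the posterior mean) the latent
#' samples, unrolls the generator and decodes behavior. In evaluation
#' mode (`sample = FALSE`, default) the pass is deterministic. With
#' `n_samples > 1` and `sample = TRUE`, rates are averaged over posterior
#' samples (factors/behavior are from the first sample).
#'
#' @param model a `band_model`.
#' @param data a `trial_dataset` (its `prep_bins` must equal the
#'   model's) or a plain spikes array trials x T x neurons.
#' @param sample draw posterior samples instead of using means.
#' @param n_samples number of posterior samples for rate averaging.
#' @param seed optional seed for the posterior draws.
#' @return object of class `latent_trajectory`: `g0_mean`, `g0_sd`,
#'   `u_mean`, `u_sd`, `factors`, `rates`, `behavior_pred`.
#' @export
band_forward <- function(model, data, sample = FALSE, n_samples = 1L,
                         seed = NULL) {
  cfg <- model$config
  spikes <- if (inherits(data, "trial_dataset")) {
    assert_that(data$prep_bins == cfg$prep_bins,
                "dataset prep_bins differs from model prep_bins")
    data$spikes
  } else data
  stopifnot(dim(spikes)[2] == model$T, dim(spikes)[3] == model$n_neurons)
  prep <- cfg$prep_bins
  sp_prep <- spikes[, seq_len(prep), , drop = FALSE]
  sp_move <- spikes[, seq(prep + 1L, model$T), , drop = FALSE]
  ic <- encode_initial_condition(model, sp_prep)
  con <- encode_controller(model, sp_move)
  B <- dim(spikes)[1]
  Tm <- model$T - prep
  use_u <- cfg$n_control > 0L && !model$ablated
  draw <- function() {
    g0 <- if (sample) ic$mean + ic$sd * matrix(stats::rnorm(length(ic$mean)),
                                               nrow(ic$mean)) else ic$mean
    u <- if (!use_u) NULL else if (sample) {
      con$mean + con$sd * array(stats::rnorm(length(con$mean)),
                                dim = dim(con$mean))
    } else con$mean
    generate_trajectory(model, g0, u)
  }
  out <- with_seed(seed, {
    first <- draw()
    rates <- first$rates
    if (sample && n_samples > 1L) {
      for (i in seq_len(n_samples - 1L)) rates <- rates + draw()$rates
      rates <- rates / n_samples
    }
    list(first = first, rates = rates)
  })
  behavior_pred <- decode_behavior_seq2seq(model, out$first$factors)
  structure(list(
    g0_mean = ic$mean, g0_sd = ic$sd,
    u_mean = if (use_u) con$mean else array(0, dim = c(B, Tm, 0L)),
    u_sd = if (use_u) con$sd else array(0, dim = c(B, Tm, 0L)),
    factors = out$first$factors, rates = out$rates,
    behavior_pred = behavior_pred
  ), class = "latent_trajectory")
}

#' Ablate the controller of a trained model
#'
#' Returns a model whose forward pass forces the control input to the
#' prior mean (zero) while sharing all parameters with the original
#' (which is left unmodified). The result depends only on preparatory
#' spikes: autonomous dynamics from the inferred initial condition.
#' Ablation is idempotent; a model built with `n_control = 0` has no
#' controller to ablate and raises an error.
#'
#' @param model a `band_model` with `n_control > 0`.
#' @return the autonomous model.
#' @export
ablate_controller <- function(model) {
  if (model$config$n_control == 0L)
    stopf("model is already autonomous: it was built with n_control = 0")
  if (model$ablated) return(model)
  model$ablated <- TRUE
  model
}

#' Assemble the composite training loss
#'
#' Combines the Poisson reconstruction likelihood, the behavior term, the
#' L2 penalty on recurrent kernels and the two KL divergences into the
#' semi-supervised objective
#' `L = L_x + theta * L_b - alpha * L_L2 - beta_g0 * KL_g0 - beta_u * KL_u`
#' (maximized; trainers minimize `-L`). All terms are per-trial averages;
#' the behavior MSE additionally averages over bins and components.
#'
#' @param trajectory a `latent_trajectory` from [band_forward()].
#' @param batch a `trial_dataset` (or list with `spikes`, `behavior`).
#' @param weights list/config with `theta`, `alpha`, `beta_kl_g0`,
#'   `beta_kl_u`; defaults to the model's config if `model` is given.
#' @param model optional `band_model`, needed for the L2 term.
#' @return object of class `loss_breakdown`.
#' @export
band_loss <- function(trajectory, batch, weights = NULL, model = NULL) {
  w <- weights %||% model$config
  B <- dim(batch$spikes)[1]
  L_x <- poisson_log_likelihood(trajectory$rates, batch$spikes) / B
  bins <- seq_len(dim(batch$behavior)[2])
  if (identical(w$behavior_loss_bins, "movement")) {
    prep <- (model$config$prep_bins) %||% w$prep_bins
    bins <- bins[bins > prep]
  }
  L_b <- -mean((batch$behavior[, bins, , drop = FALSE] -
                  trajectory$behavior_pred[, bins, , drop = FALSE])^2)
  KL_g0 <- kl_gaussian(trajectory$g0_mean, trajectory$g0_sd) / B
  KL_u <- if (length(trajectory$u_mean) > 0) {
    kl_gaussian(trajectory$u_mean, trajectory$u_sd) / B
  } else 0
  L_L2 <- if (!is.null(model)) {
    sum(model$params$gen$U^2) +
      (if (model$config$n_control > 0) sum(model$params$con$U^2) else 0)
  } else 0
  total <- L_x + w$theta * L_b - w$alpha * L_L2 -
    w$beta_kl_g0 * KL_g0 - w$beta_kl_u * KL_u
  structure(list(L_x = L_x, L_b = L_b, L_L2 = L_L2, KL_g0 = KL_g0,
                 KL_u = KL_u,
                 weights = list(theta = w$theta, alpha = w$alpha,
                                beta_kl_g0 = w$beta_kl_g0,
                                beta_kl_u = w$beta_kl_u),
                 total = total),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total %.4f | L_x %.3f  L_b %.4f  L2 %.3f  KL_g0 %.3f  KL_u %.3f\n",
    x$total, x$L_x, x$L_b, x$L_L2, x$KL_g0, x$KL_u))
  invisible(x)
}
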