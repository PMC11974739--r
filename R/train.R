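## Training: exact gradients of the semi-supervised ELBO through the
## reparameterized posteriors, the generator GRU and both encoder GRUs.
## The loss minimized is J = -(L_x + theta*L_b) + alpha*L2
##                          + beta_g0*KL_g0 + beta_u*KL_u
## with every data term a per-trial average (band_loss() conventions).

## One training-mode forward/backward pass. `eps` fixes the posterior
## noise (for gradient checks); when NULL it is drawn. Returns the loss
## value, the additive terms, and gradients for every parameter.
band_loss_grad <- function(params, model, spikes, behavior, weights,
                           eps = NULL, input_dropout = 0,
                           controller_dropout = 0) {
  cfg <- model$config
  Tn <- model$T; prep <- cfg$prep_bins
  Tm <- Tn - prep
  C <- cfg$n_control
  B <- dim(spikes)[1]
  Fn <- cfg$n_factors
  Bd <- cfg$behavior_dims

  sp_prep <- spikes[, seq_len(prep), , drop = FALSE]
  sp_move <- spikes[, seq(prep + 1L, Tn), , drop = FALSE]

  ## input dropout on the encoder views only (the likelihood target stays
  ## raw): discourages the controller from carrying structure the
  ## generator can produce autonomously
  if (input_dropout > 0) {
    keep <- 1 - input_dropout
    mp <- eps$drop_prep %||%
      array(stats::rbinom(length(sp_prep), 1, keep), dim = dim(sp_prep))
    mm <- eps$drop_move %||%
      array(stats::rbinom(length(sp_move), 1, keep), dim = dim(sp_move))
    sp_prep_in <- sp_prep * mp / keep
    sp_move_in <- sp_move * mm / keep
  } else {
    sp_prep_in <- sp_prep
    sp_move_in <- sp_move
  }

  ic <- ic_encoder_forward(params, cfg, sp_prep_in)
  con <- if (C > 0) controller_forward(params, cfg, sp_move_in) else NULL

  eps_g0 <- eps$g0 %||% matrix(stats::rnorm(length(ic$mean)), B)
  g0 <- ic$mean + ic$sd * eps_g0
  u <- NULL
  eps_u <- NULL
  ## controller dropout: a fraction of trials trains with u forced to
  ## zero (and no KL_u), so the autonomous pathway — the ablated model —
  ## is itself part of the training objective
  con_keep <- rep(1, B)
  if (C > 0 && controller_dropout > 0) {
    con_keep <- eps$con_keep %||%
      as.numeric(stats::runif(B) >= controller_dropout)
  }
  if (C > 0) {
    eps_u <- eps$u %||% array(stats::rnorm(length(con$mean)),
                              dim = dim(con$mean))
    u <- (con$mean + con$sd * eps_u) * con_keep
  }
  gen <- generator_forward(params, cfg, Tn, g0, u)

  ## ----- losses -----
  lam_l <- lapply(gen$lograte_l, exp)
  y_l <- seq_to_list(spikes)
  L_x <- 0
  for (t in seq_len(Tn)) {
    L_x <- L_x + sum(y_l[[t]] * gen$lograte_l[[t]] - lam_l[[t]] -
                       lgamma(y_l[[t]] + 1))
  }
  L_x <- L_x / B

  flat_fac <- do.call(cbind, gen$fac_l)  # B x (T*Fn), time-major
  seq2seq <- cfg$behavior_decoder == "seq2seq_linear"
  if (seq2seq) {
    pred_flat <- linear_forward(flat_fac, params$beh)
  } else {
    stacked <- do.call(rbind, gen$fac_l)  # (T*B) x Fn, time blocks
    pred_stacked <- linear_forward(stacked, params$beh)
  }
  beh_flat <- flatten_seq(behavior)      # B x (T*Bd), time-major
  bins <- seq_len(Tn)
  if (identical(cfg$behavior_loss_bins, "movement")) bins <- bins[bins > prep]
  sel_cols <- as.vector(outer(seq_len(Bd), (bins - 1L) * Bd, "+"))
  pred_mat <- if (seq2seq) pred_flat else {
    ## reorder (T*B) x Bd stacked rows into B x (T*Bd) time-major
    do.call(cbind, lapply(seq_len(Tn), function(t)
      pred_stacked[((t - 1L) * B + 1L):(t * B), , drop = FALSE]))
  }
  resid <- pred_mat[, sel_cols, drop = FALSE] -
    beh_flat[, sel_cols, drop = FALSE]
  nb <- length(resid)
  L_b <- -sum(resid^2) / nb

  KL_g0 <- sum(-log(ic$sd) + (ic$sd^2 + ic$mean^2) / 2 - 0.5) / B
  KL_u <- if (C > 0) {
    sum(con_keep * apply(-log(con$sd) + (con$sd^2 + con$mean^2) / 2 - 0.5,
                         1, sum)) / B
  } else 0
  L2 <- sum(params$gen$U^2) + (if (C > 0) sum(params$con$U^2) else 0)

  J <- -(L_x + weights$theta * L_b) + weights$alpha * L2 +
    weights$beta_kl_g0 * KL_g0 + weights$beta_kl_u * KL_u

  ## ----- backward -----
  grads <- param_zeros(params)

  ## behavior head
  dpred_sel <- (2 * weights$theta / nb) * resid
  dflat_fac <- matrix(0, B, Tn * Fn)
  if (seq2seq) {
    dpred <- matrix(0, B, Tn * Bd)
    dpred[, sel_cols] <- dpred_sel
    grads$beh$W <- crossprod(flat_fac, dpred)
    grads$beh$b <- colSums(dpred)
    dflat_fac <- dpred %*% t(params$beh$W)
  } else {
    dpred <- matrix(0, B, Tn * Bd)
    dpred[, sel_cols] <- dpred_sel
    dstacked <- do.call(rbind, lapply(seq_len(Tn), function(t)
      dpred[, ((t - 1L) * Bd + 1L):(t * Bd), drop = FALSE]))
    grads$beh$W <- crossprod(stacked, dstacked)
    grads$beh$b <- colSums(dstacked)
    dfac_stacked <- dstacked %*% t(params$beh$W)
  }

  ## rate head + factor readout, per bin
  dH_gen <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dlr <- (lam_l[[t]] - y_l[[t]]) / B           # d(-L_x)/d lograte
    grads$rate$W <- grads$rate$W + crossprod(gen$fac_l[[t]], dlr)
    grads$rate$b <- grads$rate$b + colSums(dlr)
    dfac <- dlr %*% t(params$rate$W)
    if (seq2seq) {
      dfac <- dfac + dflat_fac[, ((t - 1L) * Fn + 1L):(t * Fn),
                               drop = FALSE]
    } else {
      dfac <- dfac + dfac_stacked[((t - 1L) * B + 1L):(t * B), ,
                                  drop = FALSE]
    }
    grads$fac$W <- grads$fac$W + crossprod(gen$rnn$H[[t]], dfac)
    dH_gen[[t]] <- dfac %*% t(params$fac$W)
  }

  gb <- gru_backward(dH_gen, gen$rnn$cache, params$gen, want_dx = C > 0)
  grads$gen <- gb$grads
  grads$gen$U <- grads$gen$U + 2 * weights$alpha * params$gen$U
  dg0 <- gb$dh0

  ## initial-condition posterior (reparameterization + KL)
  dmu_g0 <- dg0 + weights$beta_kl_g0 * ic$mean / B
  dsd_g0 <- dg0 * eps_g0 +
    weights$beta_kl_g0 * (ic$sd - 1 / ic$sd) / B
  dlv_g0 <- dsd_g0 * 0.5 * ic$sd
  dlv_g0[ic$lv <= -12 | ic$lv >= 8] <- 0
  dic_out <- cbind(dmu_g0, dlv_g0)
  lb <- linear_backward(ic$hcat, dic_out, params$ic_head)
  grads$ic_head <- lb$grads
  E <- cfg$encoder_dim
  dh_f <- lb$dx[, seq_len(E), drop = FALSE]
  dh_b <- lb$dx[, E + seq_len(E), drop = FALSE]
  n_prep <- length(ic$X)
  dHf <- vector("list", n_prep); dHf[[n_prep]] <- dh_f
  dHb <- vector("list", n_prep); dHb[[n_prep]] <- dh_b
  grads$enc_f <- gru_backward(dHf, ic$fwd$cache, params$enc_f,
                              want_dx = FALSE)$grads
  grads$enc_b <- gru_backward(dHb, ic$bwd$cache, params$enc_b,
                              want_dx = FALSE)$grads

  ## controller posterior
  if (C > 0) {
    dH_con <- vector("list", Tm)
    for (t in seq_len(Tm)) {
      du <- array(gb$dX[[prep + t]][, seq_len(C)], dim = c(B, C)) *
        con_keep
      mu_t <- con$mean_l[[t]]
      sd_t <- array(con$sd[, t, ], dim = c(B, C))
      dmu <- du + weights$beta_kl_u * con_keep * mu_t / B
      dsd <- du * array(eps_u[, t, ], dim = c(B, C)) +
        weights$beta_kl_u * con_keep * (sd_t - 1 / sd_t) / B
      dlv <- dsd * 0.5 * sd_t
      dlv[con$lv[[t]] <= -12 | con$lv[[t]] >= 8] <- 0
      dout <- cbind(dmu, dlv)
      lb_c <- linear_backward(con$rnn$H[[t]], dout, params$con_head)
      grads$con_head$W <- grads$con_head$W + lb_c$grads$W
      grads$con_head$b <- grads$con_head$b + lb_c$grads$b
      dH_con[[t]] <- lb_c$dx
    }
    grads$con <- gru_backward(dH_con, con$rnn$cache, params$con,
                              want_dx = FALSE)$grads
    grads$con$U <- grads$con$U + 2 * weights$alpha * params$con$U
  }

  list(J = J,
       terms = list(L_x = L_x, L_b = L_b, L_L2 = L2, KL_g0 = KL_g0,
                    KL_u = KL_u),
       grads = grads)
}

#' Training configuration
#'
#' Optimization defaults (Adam, gradient-norm clipping, linear KL/L2
#' warmup) follow common sequential-autoencoder practice; none of them
#' is claimed to reproduce any published schedule.
#'
#' @param epochs number of passes over the training trials.
#' @param batch_size trials per gradient step (`Inf` = full batch).
#' @param lr Adam learning rate.
#' @param lr_decay multiplicative decay applied each epoch.
#' @param clip global gradient-norm clip.
#' @param kl_warmup_epochs KL/L2 weights ramp linearly from 0 to their
#'   configured values over this many epochs.
#' @param input_dropout probability of dropping each spike-count entry
#'   from the encoder inputs during training (the Poisson target is
#'   never dropped). Pushes autonomous-predictable structure out of the
#'   controller and into the generator dynamics.
#' @param controller_dropout fraction of trials per batch trained with
#'   the control input forced to zero (and its KL term silenced): the
#'   autonomous (ablated) pathway becomes part of the training
#'   objective, so planned structure cannot hide in the controller.
#' @param patience early-stopping patience (epochs without improvement of
#'   the validation objective); `Inf` disables.
#' @param objective validation objective used for checkpoint selection
#'   and early stopping: `"eq6"` (normalized likelihood + R2 deficit) or
#'   `"eq7"` (likelihood minus 1e-4 * behavior MSE).
#' @param seed RNG seed controlling initialization, batching and
#'   posterior sampling; a fixed seed gives identical training runs.
#' @param verbose print a line per epoch.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 60L, batch_size = Inf, lr = 5e-3,
                         lr_decay = 0.995, clip = 200,
                         kl_warmup_epochs = 15L, input_dropout = 0.25,
                         controller_dropout = 0.2, patience = Inf,
                         objective = c("eq6", "eq7"), seed = 1L,
                         verbose = FALSE) {
  objective <- match.arg(objective)
  stopifnot(epochs >= 1, lr > 0)
  structure(as.list(environment()), class = "train_config")
}

eval_objective <- function(model, dataset, idx, objective) {
  sub <- dataset[idx]
  traj <- band_forward(model, sub)
  B <- length(idx)
  L_x <- poisson_log_likelihood(traj$rates, sub$spikes) / B
  r2 <- r2_isotropic(sub$behavior, traj$behavior_pred)
  mse <- mean((sub$behavior - traj$behavior_pred)^2)
  bps <- bits_per_spike(traj$rates, sub$spikes)
  obj <- if (objective == "eq6") {
    pbt_objective(L_x, model$n_neurons, model$T, r2)
  } else {
    pbt_objective_nlb(L_x, mse)
  }
  list(objective = obj, r2 = r2, bits_per_spike = bps, L_x = L_x)
}

#' Train a model
#'
#' Minimizes the negative composite objective by Adam with
#' reparameterized single-sample gradients, records every loss term and
#' validation metrics per epoch, and returns the checkpoint that
#' maximizes the configured validation objective. Non-finite losses
#' abort training and return the last finite checkpoint.
#'
#' @param config a [model_config()] (or an initialized `band_model` to
#'   warm-start from).
#' @param dataset a `trial_dataset`.
#' @param split list with `train` (and optionally `val`) trial indices;
#'   `NULL` trains on all trials with selection on the training
#'   objective.
#' @param tc a [train_config()].
#' @return object of class `band_fit`: `model` (selected checkpoint),
#'   `final_model`, `history` (one row per epoch), `split`, `config`.
#' @export
train_model <- function(config, dataset, split = NULL, tc = train_config()) {
  validate_trial_dataset(dataset)
  train_idx <- split$train %||% seq_len(n_trials(dataset))
  val_idx <- split$val %||% NULL
  model <- if (inherits(config, "band_model")) config else {
    band_model(config, n_neurons = dim(dataset$spikes)[3],
               T = dim(dataset$spikes)[2], seed = tc$seed,
               init_log_rate = log(max(mean(
                 dataset$spikes[train_idx, , , drop = FALSE]), 1e-4)))
  }
  cfg <- model$config
  assert_that(dataset$prep_bins == cfg$prep_bins,
              "dataset prep_bins differs from model prep_bins")
  params <- model$params
  opt <- adam_init(params)
  history <- vector("list", tc$epochs)
  best <- list(obj = -Inf, params = params, epoch = 0L)
  lr <- tc$lr
  diverged <- FALSE

  with_seed(tc$seed + 7L, {
    for (epoch in seq_len(tc$epochs)) {
      warm <- min(1, epoch / max(tc$kl_warmup_epochs, 1L))
      w_eff <- list(theta = cfg$theta, alpha = warm * cfg$alpha,
                    beta_kl_g0 = warm * cfg$beta_kl_g0,
                    beta_kl_u = warm * cfg$beta_kl_u)
      idx <- if (is.finite(tc$batch_size) &&
                 tc$batch_size < length(train_idx)) {
        sample(train_idx)
      } else train_idx
      nb <- if (is.finite(tc$batch_size)) {
        split(idx, ceiling(seq_along(idx) / tc$batch_size))
      } else list(idx)
      terms_acc <- NULL
      for (batch_idx in nb) {
        res <- band_loss_grad(
          params, model,
          dataset$spikes[batch_idx, , , drop = FALSE],
          dataset$behavior[batch_idx, , , drop = FALSE], w_eff,
          input_dropout = tc$input_dropout,
          controller_dropout = tc$controller_dropout %||% 0)
        if (!is.finite(res$J)) { diverged <- TRUE; break }
        st <- adam_step(params, res$grads, opt, lr = lr, clip = tc$clip)
        params <- st$params; opt <- st$state
        terms_acc <- if (is.null(terms_acc)) res$terms else {
          mapply(`+`, terms_acc, res$terms, SIMPLIFY = FALSE)
        }
      }
      if (diverged) {
        warnf("non-finite loss at epoch %d; keeping last good checkpoint",
              epoch)
        break
      }
      terms_acc <- lapply(terms_acc, function(x) x / length(nb))
      lr <- lr * tc$lr_decay
      model$params <- params
      ev <- if (!is.null(val_idx)) {
        eval_objective(model, dataset, val_idx, tc$objective)
      } else {
        list(objective = terms_acc$L_x + cfg$theta * terms_acc$L_b -
               cfg$alpha * terms_acc$L_L2 - cfg$beta_kl_g0 * terms_acc$KL_g0 -
               cfg$beta_kl_u * terms_acc$KL_u,
             r2 = NA_real_, bits_per_spike = NA_real_, L_x = terms_acc$L_x)
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, L_x = terms_acc$L_x, L_b = terms_acc$L_b,
        L_L2 = terms_acc$L_L2, KL_g0 = terms_acc$KL_g0,
        KL_u = terms_acc$KL_u, val_objective = ev$objective,
        val_r2 = ev$r2, val_bits_per_spike = ev$bits_per_spike)
      if (tc$verbose) {
        cat(sprintf(
          "epoch %3d  L_x %.2f  L_b %.4f  KLg0 %.2f  KLu %.2f  obj %.4f  r2 %.3f\n",
          epoch, terms_acc$L_x, terms_acc$L_b, terms_acc$KL_g0,
          terms_acc$KL_u, ev$objective, ev$r2))
      }
      if (ev$objective > best$obj) {
        best <- list(obj = ev$objective, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= tc$patience) break
    }
  })

  model$params <- best$params
  final <- model; final$params <- params
  structure(list(model = model, final_model = final,
                 history = do.call(rbind, history[!vapply(history, is.null,
                                                          TRUE)]),
                 best_epoch = best$epoch, split = split,
                 train_config = tc, config = cfg),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("band_fit: %d epochs (best %d), final L_x %.3f, val obj %.4f\n",
              nrow(h), x$best_epoch, h$L_x[nrow(h)],
              h$val_objective[nrow(h)]))
  invisible(x)
}

#' k-fold cross-validation
#'
#' Trains one model per fold and scores each trial exactly once by the
#' model that never saw it. Out-of-fold predictions are returned in the
#' original trial order. Per-fold R2 values are computed against the
#' grand mean of the pooled out-of-fold set (not the fold-local mean), so
#' they decompose the pooled score and the pooled R2 always lies within
#' their min/max. A fraction of each training set is carved out as a
#' validation split for checkpoint selection.
#'
#' @param config a [model_config()].
#' @param dataset a `trial_dataset`.
#' @param k number of folds (default 5).
#' @param tc a [train_config()].
#' @param seed fold-assignment seed.
#' @return object of class `band_cv`: `oof_behavior`, `oof_rates`,
#'   `folds`, `pooled` metrics, `per_fold` data.frame, `fits`.
#' @export
cross_validate <- function(config, dataset, k = 5L, tc = train_config(),
                           seed = 1L) {
  folds <- split_trials(dataset, split_spec("kfold", k = k, seed = seed))
  K <- n_trials(dataset)
  oof_beh <- array(NA_real_, dim = dim(dataset$behavior))
  oof_rates <- array(NA_real_, dim = dim(dataset$spikes))
  fits <- vector("list", k)
  for (j in seq_len(k)) {
    test_idx <- folds[[j]]
    train_all <- setdiff(seq_len(K), test_idx)
    nval <- max(1L, floor(0.1 * length(train_all)))
    val_idx <- with_seed(seed + j, sample(train_all, nval))
    sp <- list(train = setdiff(train_all, val_idx), val = val_idx)
    fit <- train_model(config, dataset, sp, tc)
    traj <- band_forward(fit$model, dataset[test_idx])
    oof_beh[test_idx, , ] <- traj$behavior_pred
    oof_rates[test_idx, , ] <- traj$rates
    fits[[j]] <- fit
  }
  stopifnot(!anyNA(oof_beh))
  pooled_r2 <- r2_isotropic(dataset$behavior, oof_beh)
  pooled_bps <- bits_per_spike(oof_rates, dataset$spikes)
  mu <- apply(dataset$behavior, 3, mean)
  lam_bar <- apply(dataset$spikes, 3, mean)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(j) {
    idx <- folds[[j]]
    y <- dataset$behavior[idx, , , drop = FALSE]
    f <- oof_beh[idx, , , drop = FALSE]
    r2 <- 1 - sum((y - f)^2) / sum(sweep(y, 3, mu)^2)
    data.frame(fold = j, n = length(idx), r2 = r2,
               bits_per_spike = bits_per_spike(
                 oof_rates[idx, , , drop = FALSE],
                 dataset$spikes[idx, , , drop = FALSE],
                 baseline_rates = lam_bar))
  }))
  structure(list(oof_behavior = oof_beh, oof_rates = oof_rates,
                 folds = folds,
                 pooled = list(r2 = pooled_r2, bits_per_spike = pooled_bps,
                               r2_sd = stats::sd(per_fold$r2),
                               bps_sd = stats::sd(per_fold$bits_per_spike)),
                 per_fold = per_fold, fits = fits),
            class = "band_cv")
}
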