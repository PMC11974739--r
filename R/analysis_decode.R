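#' Condition-average behavior predictor
#'
#' The baseline model that knows only the cued target: the prediction
#' for a test trial is the training-set mean behavior time course of its
#' condition. Quantifies how much behavioral variability is explained by
#' the task cue alone.
#'
#' @param train a `trial_dataset` used to form per-condition averages.
#' @param test a `trial_dataset` to predict (every test condition must
#'   appear in `train`).
#' @return list with `behavior_pred` (array like `test$behavior`) and
#'   `r2` (isotropic, pooled over the test set).
#' @export
condition_average_predictor <- function(train, test) {
  missing_cond <- setdiff(unique(test$condition), unique(train$condition))
  if (length(missing_cond) > 0)
    stopf("condition(s) %s absent from the training set",
          paste(missing_cond, collapse = ", "))
  pred <- array(0, dim = dim(test$behavior))
  for (cc in unique(test$condition)) {
    avg <- apply(train$behavior[train$condition == cc, , , drop = FALSE],
                 c(2, 3), mean)
    for (i in which(test$condition == cc)) pred[i, , ] <- avg
  }
  list(behavior_pred = pred, r2 = r2_isotropic(test$behavior, pred))
}

## closed-form ridge through the SVD of the centered design; cheap to
## sweep lambda. X: n x p, Y: n x q.
ridge_svd_fit <- function(X, Y, lambdas) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  UtY <- crossprod(sv$u, Yc)
  lapply(lambdas, function(lam) {
    shrink <- sv$d / (sv$d^2 + lam)
    W <- sv$v %*% (shrink * UtY)
    list(W = W, b = ym - drop(crossprod(W, xm)), lambda = lam)
  })
}

ridge_predict <- function(fit, X) sweep(X %*% fit$W, 2, fit$b, "+")

#' Sequence-to-sequence ridge regression from latent factors
#'
#' Post-hoc linear decoding of behavior from a (typically unsupervised)
#' model's latent factors: each trial's factor sequence is flattened
#' (time-major) into one feature vector and mapped to the flattened
#' behavior sequence by L2-regularized least squares. The ridge strength
#' is selected on a validation subset of the training trials, then the
#' map is refit on the full training set.
#'
#' @param factors trials x T x n_factors array.
#' @param behavior trials x T x behavior_dims array.
#' @param split list with `train` and `test` trial indices.
#' @param lambdas candidate ridge strengths (default a log grid).
#' @param val_fraction fraction of training trials used for selection.
#' @param seed seed for the validation carve-out.
#' @return list with `behavior_pred` (test trials, array), `r2`,
#'   `weights` (a `decoder_weights` view), `lambda`.
#' @export
fit_seq2seq_ridge <- function(factors, behavior, split,
                              lambdas = 10^seq(-2, 4, by = 1),
                              val_fraction = 0.2, seed = 1L) {
  d <- dim(factors)
  X <- flatten_seq(factors)
  Y <- flatten_seq(behavior)
  tr <- split$train
  if (length(tr) < ncol(X))
    warnf("more features (%d) than training trials (%d); relying on ridge",
          ncol(X), length(tr))
  nval <- max(1L, floor(val_fraction * length(tr)))
  val <- with_seed(seed, sample(tr, nval))
  core <- setdiff(tr, val)
  fits <- ridge_svd_fit(X[core, , drop = FALSE], Y[core, , drop = FALSE],
                        lambdas)
  val_err <- vapply(fits, function(f)
    mean((ridge_predict(f, X[val, , drop = FALSE]) -
            Y[val, , drop = FALSE])^2), 0)
  lam <- lambdas[which.min(val_err)]
  fit <- ridge_svd_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                       list(lam))[[1]]
  pred <- ridge_predict(fit, X[split$test, , drop = FALSE])
  pred_arr <- unflatten_seq(pred, d[2], dim(behavior)[3])
  dw <- structure(list(weights = fit$W, bias = fit$b, T = d[2],
                       n_factors = d[3],
                       behavior_dims = dim(behavior)[3]),
                  class = "decoder_weights")
  list(behavior_pred = pred_arr,
       r2 = r2_isotropic(behavior[split$test, , , drop = FALSE], pred_arr),
       weights = dw, lambda = lam)
}

#' Bidirectional recurrent behavior decoder
#'
#' A supervised non-latent baseline: stacked bidirectional GRU layers map
#' binned spike counts to behavior per bin, using both past and future
#' neural activity (the backward pass accounts for sensory feedback).
#' Serves as an approximate upper bound ("oracle") on decodable
#' behavioral variability. Architecture defaults are desk-scale
#' placeholders governed entirely by `birnn_config()`.
#'
#' @param dataset a `trial_dataset`.
#' @param split list with `train` and `test` indices.
#' @param config a [birnn_config()].
#' @return list with `behavior_pred` (test trials), `r2`, `params`,
#'   `history` (training MSE per epoch).
#' @export
train_birnn_decoder <- function(dataset, split, config = birnn_config()) {
  validate_trial_dataset(dataset)
  N <- dim(dataset$spikes)[3]
  Bd <- dim(dataset$behavior)[3]
  H <- config$hidden
  params <- with_seed(config$seed, {
    p <- list()
    for (l in seq_len(config$n_layers)) {
      ind <- if (l == 1) N else 2 * H
      p[[paste0("f", l)]] <- gru_init(ind, H)
      p[[paste0("b", l)]] <- gru_init(ind, H)
    }
    p$head <- linear_init(2 * H, Bd)
    p
  })
  tr <- split$train
  opt <- adam_init(params)
  history <- numeric(config$epochs)
  with_seed(config$seed + 13L, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(tr)
      batches <- split(idx, ceiling(seq_along(idx) /
                                      min(config$batch_size, length(idx))))
      mse_acc <- 0
      for (bi in batches) {
        res <- birnn_loss_grad(params, config,
                               dataset$spikes[bi, , , drop = FALSE],
                               dataset$behavior[bi, , , drop = FALSE],
                               train = TRUE)
        st <- adam_step(params, res$grads, opt, lr = config$lr,
                        clip = config$clip)
        params <- st$params; opt <- st$state
        mse_acc <- mse_acc + res$mse
      }
      history[epoch] <- mse_acc / length(batches)
      if (!is.finite(history[epoch])) stopf("biRNN training diverged")
    }
  })
  pred <- birnn_forward(params, config,
                        dataset$spikes[split$test, , , drop = FALSE])$pred
  list(behavior_pred = pred,
       r2 = r2_isotropic(dataset$behavior[split$test, , , drop = FALSE],
                         pred),
       params = params, history = history)
}

#' @rdname train_birnn_decoder
#' @param hidden GRU state size per direction.
#' @param n_layers stacked bidirectional layers.
#' @param dropout inter-layer dropout probability (training only).
#' @param epochs,batch_size,lr,clip,seed optimization settings.
#' @export
birnn_config <- function(hidden = 64L, n_layers = 2L, dropout = 0.2,
                         epochs = 40L, batch_size = 32L, lr = 5e-3,
                         clip = 50, seed = 1L) {
  structure(as.list(environment()), class = "birnn_config")
}

birnn_forward <- function(params, config, spikes, train = FALSE) {
  X <- seq_to_list(spikes)
  B <- nrow(X[[1]])
  Tn <- length(X)
  H <- config$hidden
  layers <- vector("list", config$n_layers)
  masks <- vector("list", config$n_layers)
  inp <- X
  for (l in seq_len(config$n_layers)) {
    h0 <- matrix(0, B, H)
    fwd <- gru_forward(inp, h0, params[[paste0("f", l)]])
    bwd <- gru_forward(rev(inp), h0, params[[paste0("b", l)]])
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      out[[t]] <- cbind(fwd$H[[t]], bwd$H[[Tn - t + 1L]])
    }
    if (train && config$dropout > 0 && l < config$n_layers) {
      mask <- matrix(stats::rbinom(B * 2 * H, 1, 1 - config$dropout) /
                       (1 - config$dropout), B, 2 * H)
      out <- lapply(out, function(o) o * mask)
      masks[[l]] <- mask
    }
    layers[[l]] <- list(fwd = fwd, bwd = bwd, out = out, inp = inp)
    inp <- out
  }
  pred_l <- lapply(inp, function(o) linear_forward(o, params$head))
  list(pred = list_to_seq(pred_l), layers = layers, masks = masks,
       top = inp, pred_l = pred_l)
}

birnn_loss_grad <- function(params, config, spikes, behavior, train = TRUE) {
  fwdres <- birnn_forward(params, config, spikes, train = train)
  Tn <- dim(spikes)[2]
  y_l <- seq_to_list(behavior)
  nb <- length(behavior)
  grads <- param_zeros(params)
  dtop <- vector("list", Tn)
  mse <- 0
  for (t in seq_len(Tn)) {
    resid <- fwdres$pred_l[[t]] - y_l[[t]]
    mse <- mse + sum(resid^2)
    dpred <- 2 * resid / nb
    lb <- linear_backward(fwdres$top[[t]], dpred, params$head)
    grads$head$W <- grads$head$W + lb$grads$W
    grads$head$b <- grads$head$b + lb$grads$b
    dtop[[t]] <- lb$dx
  }
  dout <- dtop
  H <- config$hidden
  for (l in rev(seq_len(config$n_layers))) {
    if (!is.null(fwdres$masks[[l]])) {
      dout <- lapply(dout, function(d) d * fwdres$masks[[l]])
    }
    dHf <- lapply(dout, function(d) d[, seq_len(H), drop = FALSE])
    dHb_disp <- lapply(dout, function(d) d[, H + seq_len(H), drop = FALSE])
    Tn_ <- length(dout)
    dHb <- lapply(seq_len(Tn_), function(t) dHb_disp[[Tn_ - t + 1L]])
    need_dx <- l > 1
    gf <- gru_backward(dHf, fwdres$layers[[l]]$fwd$cache,
                       params[[paste0("f", l)]], want_dx = need_dx)
    gb <- gru_backward(dHb, fwdres$layers[[l]]$bwd$cache,
                       params[[paste0("b", l)]], want_dx = need_dx)
    grads[[paste0("f", l)]] <- gf$grads
    grads[[paste0("b", l)]] <- gb$grads
    if (need_dx) {
      dout <- lapply(seq_len(Tn_), function(t)
        gf$dX[[t]] + gb$dX[[Tn_ - t + 1L]])
    }
  }
  list(mse = mse / nb, grads = grads)
}

#' Diagonal lag profile of a sequence-to-sequence decoder block
#'
#' Restricts the T x T weight block of one factor/behavior pair to the
#' movement-phase window and sums its entries along diagonals of fixed
#' lag (behavior bin minus factor bin). Negative lag means behavior
#' leads the factor (feedback); positive lag means the factor leads
#' behavior (feedforward). The summed mass over all lags equals the sum
#' of the windowed block.
#'
#' @param dw a `decoder_weights` object.
#' @param factor factor index.
#' @param behavior_dim behavior component index.
#' @param movement_window integer bin range (e.g. `(prep+1):T`).
#' @param bin_width bin width, seconds.
#' @return object of class `lag_profile` with `lags_bins`, `lags_s`,
#'   `value`, `peak_lag_s`.
#' @export
diagonal_lag_profile <- function(dw, factor, behavior_dim, movement_window,
                                 bin_width) {
  stopifnot(inherits(dw, "decoder_weights"))
  if (length(movement_window) == 0) stopf("empty movement window")
  blk <- weight_block(dw, factor, behavior_dim)[movement_window,
                                                movement_window,
                                                drop = FALSE]
  L <- nrow(blk)
  lags <- seq(-(L - 1L), L - 1L)
  value <- vapply(lags, function(l) {
    sum(blk[col(blk) - row(blk) == l])
  }, 0)
  structure(list(lags_bins = lags, lags_s = lags * bin_width,
                 value = value,
                 peak_lag_s = lags[which.max(value)] * bin_width),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf("lag_profile: %d lags in [%.0f, %.0f] ms; peak at %.0f ms\n",
              length(x$lags_s), 1000 * min(x$lags_s), 1000 * max(x$lags_s),
              1000 * x$peak_lag_s))
  invisible(x)
}

#' Fixed-lag regression from per-bin latent state to lagged behavior
#'
#' The multivariate analog of a cross-correlation: for each lag, a ridge
#' regression predicts behavior at bin t + lag from the latent state at
#' bin t, pooling (trial, bin) samples over the movement window; the
#' out-of-sample R-squared traces a lag profile. A negative peak lag
#' means behavior leads the latent state (feedback). Features are
#' standardized on the training samples; a single mild ridge strength is
#' used for every lag so profiles are comparable across inputs.
#'
#' @param latents trials x T x D array (model factors, smoothed rates,
#'   or any per-bin state).
#' @param behavior trials x T x B behavior array.
#' @param bin_width bin width, seconds.
#' @param split list with `train`/`test` trial indices.
#' @param lags_s lags in seconds (default -150 ms .. +150 ms).
#' @param window integer bin range to pool over (default all bins).
#' @param fixed_targets if TRUE (default), target bins are restricted to
#'   the inner window reachable at every lag, so the set of predicted
#'   time points — and hence the R-squared denominator — is identical
#'   across lags and profiles are comparable lag to lag. If FALSE, each
#'   lag uses every admissible pair (more data, shifting composition).
#' @param lambda ridge strength on standardized features.
#' @return object of class `lag_profile` with per-lag R-squared values.
#' @export
fixed_lag_regression <- function(latents, behavior, bin_width, split,
                                 lags_s = NULL, window = NULL,
                                 fixed_targets = TRUE, lambda = 1) {
  d <- dim(latents)
  Tn <- d[2]
  lags_s <- lags_s %||% seq(-0.15, 0.15, by = bin_width)
  lags <- unique(as.integer(round(lags_s / bin_width)))
  window <- window %||% seq_len(Tn)
  inner <- window[window - max(lags) >= min(window) &
                    window - min(lags) <= max(window) &
                    (window - max(lags)) %in% window &
                    (window - min(lags)) %in% window]
  if (fixed_targets && length(inner) < 3)
    stopf("lag window exhausts the trial: only %d fixed target bins",
          length(inner))
  value <- vapply(lags, function(l) {
    tf <- if (fixed_targets) inner - l else {
      window[window + l >= 1 & window + l <= Tn & (window + l) %in% window]
    }
    if (length(tf) < 3) return(NA_real_)
    gather <- function(idx) {
      X <- do.call(rbind, lapply(tf, function(t)
        matrix(latents[idx, t, ], length(idx), d[3])))
      Y <- do.call(rbind, lapply(tf, function(t)
        matrix(behavior[idx, t + l, ], length(idx), dim(behavior)[3])))
      list(X = X, Y = Y)
    }
    trd <- gather(split$train)
    ted <- gather(split$test)
    sds <- apply(trd$X, 2, stats::sd)
    sds[sds == 0] <- 1
    Xtr <- sweep(trd$X, 2, sds, "/")
    Xte <- sweep(ted$X, 2, sds, "/")
    fit <- ridge_svd_fit(Xtr, trd$Y, list(lambda))[[1]]
    pred <- ridge_predict(fit, Xte)
    1 - sum((ted$Y - pred)^2) /
      sum(sweep(ted$Y, 2, colMeans(ted$Y))^2)
  }, 0)
  structure(list(lags_bins = lags, lags_s = lags * bin_width,
                 value = value,
                 peak_lag_s = (lags * bin_width)[which.max(value)],
                 ## peak height above the profile's typical level: an
                 ## autonomous model predicts its predictable share at
                 ## every lag, so a flat profile has ~zero prominence no
                 ## matter how high its floor sits
                 peak_prominence = max(value, na.rm = TRUE) -
                   stats::median(value, na.rm = TRUE)),
            class = "lag_profile")
}

#' Controller contribution to neural and behavioral reconstruction
#'
#' Compares a full model with its controller-ablated counterpart on the
#' same trials: per-trial and per-bin differences in neural
#' reconstruction (bits/spike against the per-neuron mean-rate null) and
#' in explained behavior variance (behavior units squared, computed
#' against the grand mean of the evaluated set).
#'
#' @param model_full trained `band_model`.
#' @param model_ablated its ablated counterpart (see
#'   [ablate_controller()]).
#' @param dataset a `trial_dataset`.
#' @param idx trial indices to evaluate (default: all).
#' @return list with `per_trial` and `per_bin` data.frames and `totals`.
#' @export
controller_contribution <- function(model_full, model_ablated, dataset,
                                    idx = NULL) {
  assert_that(model_ablated$ablated,
              "second model must be controller-ablated")
  if (!isTRUE(all.equal(model_full$params, model_ablated$params)))
    stopf("ablated model does not share parameters with the full model")
  idx <- idx %||% seq_len(n_trials(dataset))
  sub <- dataset[idx]
  tf <- band_forward(model_full, sub)
  ta <- band_forward(model_ablated, sub)
  y <- sub$spikes
  lam_bar <- apply(y, 3, mean)
  ll <- function(rates) {
    out <- y * log(rates) - rates - lgamma(y + 1)
    out
  }
  dll <- ll(tf$rates) - ll(ta$rates)
  nsp_trial <- apply(y, 1, sum)
  nsp_bin <- apply(y, 2, sum)
  b <- sub$behavior
  mu <- apply(b, 3, mean)
  sq <- function(pred) (b - pred)^2
  dev_full <- sweep(b, 3, mu)^2 - sq(tf$behavior_pred)
  dev_abl <- sweep(b, 3, mu)^2 - sq(ta$behavior_pred)
  d_ev <- dev_full - dev_abl  # pointwise explained-variance difference
  per_trial <- data.frame(
    trial = idx,
    epoch = sub$epoch,
    condition = sub$condition,
    d_bits_per_spike = apply(dll, 1, sum) / pmax(nsp_trial, 1) / log(2),
    d_ev = apply(d_ev, 1, mean))
  per_bin <- data.frame(
    bin = seq_len(dim(y)[2]),
    time_s = (seq_len(dim(y)[2]) - 0.5) * sub$bin_width,
    d_bits_per_spike = apply(dll, 2, sum) / pmax(nsp_bin, 1) / log(2),
    d_ev = apply(d_ev, 2, mean))
  list(per_trial = per_trial, per_bin = per_bin,
       totals = list(
         d_bits_per_spike = sum(dll) / sum(y) / log(2),
         d_ev = mean(d_ev),
         r2_full = r2_isotropic(b, tf$behavior_pred),
         r2_ablated = r2_isotropic(b, ta$behavior_pred)))
}
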