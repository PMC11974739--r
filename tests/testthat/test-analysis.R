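test_that("condition averages: exact world, permutation null, error", {
  ds <- tiny_dataset(noise_sd = 0, feedback_gain = 0, osc_amplitude = 0,
                     motor_noise_sd = 0, seed = 21)
  sp <- split_trials(ds, split_spec("holdout", seed = 1))
  res <- condition_average_predictor(ds[sp$train], ds[sp$test])
  expect_equal(res$r2, 1, tolerance = 1e-9)

  # shuffled condition labels: R2 within the permutation null band
  ds2 <- tiny_dataset(seed = 22)
  sp2 <- split_trials(ds2, split_spec("holdout", seed = 2))
  set.seed(3)
  null_r2 <- replicate(200, {
    shuf <- ds2
    shuf$condition <- sample(shuf$condition)
    condition_average_predictor(shuf[sp2$train], shuf[sp2$test])$r2
  })
  expect_lt(max(null_r2), 0.2)  # far below the true-label score
  true_r2 <- condition_average_predictor(ds2[sp2$train], ds2[sp2$test])$r2
  expect_gt(true_r2, max(null_r2))

  missing <- ds2[sp2$train]
  missing$condition[missing$condition == 3] <- 4L
  expect_error(condition_average_predictor(missing, ds2[sp2$test]),
               "absent")
})

test_that("gaussian smoothing: impulse response, conservation, warning", {
  Tn <- 41L
  x <- numeric(Tn); x[21] <- 1
  sm <- smooth_rates_gaussian(x, sigma = 0.03, bin_width = 0.01)
  kern <- sm * 0.01   # back to counts
  expect_equal(sum(kern), 1, tolerance = 1e-9)   # area preserved
  expect_equal(which.max(kern), 21L)
  # matches the gaussian shape at the center
  offs <- -5:5
  expected <- exp(-offs^2 / (2 * 9))
  expect_equal(kern[21 + offs] / kern[21], expected, tolerance = 1e-9)
  # constant input stays constant (rows sum to one with reflection)
  const <- smooth_rates_gaussian(rep(3, Tn), sigma = 0.03,
                                 bin_width = 0.01)
  expect_equal(const, rep(300, Tn), tolerance = 1e-9)
  expect_warning(smooth_rates_gaussian(x, sigma = 0.004,
                                       bin_width = 0.01), "sigma")
  # total preserved for interior-supported input (reflection only
  # redistributes mass near the edges)
  interior <- matrix(0, Tn, 3)
  interior[15:27, ] <- rpois(13 * 3, 2)
  smi <- smooth_rates_gaussian(interior, sigma = 0.03, bin_width = 0.01)
  expect_equal(colSums(smi) * 0.01, colSums(interior), tolerance = 1e-9)
  # 3-d dataset input: shape preserved
  ds <- tiny_dataset(seed = 31)
  r <- smooth_rates_gaussian(ds)
  expect_equal(dim(r), dim(ds$spikes))
})

test_that("fft spectrum: grid sinusoid, Parseval, decaying 5 Hz", {
  Tn <- 120L; dt <- 0.01
  tt <- (0:(Tn - 1)) * dt
  # pure sinusoid at exact grid frequency 5 Hz -> all non-DC amplitude
  # in that mode (and its conjugate)
  x <- matrix(sin(2 * pi * 5 * tt), 1)
  spec <- fft_amplitude_spectrum(x, dt)
  m5 <- mode_nearest(spec, 5)
  expect_equal(spec$frequencies[m5], 5)
  others <- setdiff(seq_len(Tn), c(m5, Tn - m5 + 2L))
  expect_lt(max(spec$amplitude[1, others, 1]), 1e-9)
  # Parseval under the documented normalization
  set.seed(4)
  y <- matrix(rnorm(3 * Tn), 3)
  sp <- fft_amplitude_spectrum(y, dt)
  expect_equal(rowSums(sp$power[, , 1]), rowSums(y^2), tolerance = 1e-9)
  # decaying 5 Hz sinusoid, T = 1.2 s: max non-DC mean power near 5 Hz
  set.seed(5)
  dec <- t(replicate(8, exp(-tt / 0.3) *
                       sin(2 * pi * 5 * tt + runif(1, 0, 2 * pi)) +
                       0.05 * rnorm(Tn)))
  sd5 <- fft_amplitude_spectrum(dec, dt)
  nn <- sd5$nonneg[-1]
  expect_equal(nn[which.max(sd5$mean_power[nn])], mode_nearest(sd5, 5))
  expect_error(fft_amplitude_spectrum(matrix(c(1, NA), 1), dt), "NaN")
})

test_that("phase similarity: identity, antiphase, range", {
  Tn <- 60L; dt <- 0.01
  set.seed(6)
  x <- array(rnorm(5 * Tn * 2), c(5, Tn, 2))
  ps <- fft_phase_similarity(x, x, dt)
  expect_true(all(abs(ps$similarity[-1] - 1) < 1e-9, na.rm = TRUE))
  # phase-shift one grid mode by pi: similarity -1 there, 1 elsewhere
  m <- 4L  # mode index (frequency (m-1)/(T dt) = 5 Hz)
  shift <- x
  for (k in 1:5) for (b in 1:2) {
    co <- fft(x[k, , b])
    co[m] <- -co[m]; co[Tn - m + 2L] <- -co[Tn - m + 2L]
    shift[k, , b] <- Re(fft(co, inverse = TRUE)) / Tn
  }
  ps2 <- fft_phase_similarity(x, shift, dt)
  expect_equal(ps2$similarity[m], -1, tolerance = 1e-9)
  expect_equal(ps2$similarity[m + 1], 1, tolerance = 1e-9)
  expect_true(all(abs(ps2$similarity) <= 1 + 1e-12, na.rm = TRUE))
  # per-trial variant agrees on these exact cases
  ps3 <- fft_phase_similarity(x, shift, dt, method = "per_trial")
  expect_equal(ps3$similarity[m], -1, tolerance = 1e-9)
  # condition-mean prediction of phase-jittered oscillation: ~0 at 5 Hz
  tt <- (0:(Tn - 1)) * dt
  osc <- t(replicate(40, sin(2 * pi * 5 * tt + runif(1, 0, 2 * pi))))
  pred <- matrix(colMeans(osc), 40, Tn, byrow = TRUE) +
    0.01 * matrix(rnorm(40 * Tn), 40)
  m5 <- mode_nearest(fft_amplitude_spectrum(osc, dt), 5)
  ps4 <- fft_phase_similarity(osc, pred, dt)
  expect_lt(abs(ps4$similarity[m5]), 0.35)
})

test_that("diagonal lag profile: enumerated example and conservation", {
  # build a decoder_weights object with a known 3x3 block
  dw <- structure(list(
    weights = matrix(0, 3 * 1, 3 * 1), bias = numeric(3),
    T = 3L, n_factors = 1L, behavior_dims = 1L), class = "decoder_weights")
  dw$weights[] <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE)
  prof <- diagonal_lag_profile(dw, 1, 1, 1:3, bin_width = 0.01)
  expect_equal(prof$lags_bins, -2:2)
  expect_equal(prof$value, c(7, 12, 15, 8, 3))
  expect_equal(sum(prof$value), sum(dw$weights))   # conservation
  # identity block: all mass at lag zero
  dw$weights[] <- diag(3)
  prof2 <- diagonal_lag_profile(dw, 1, 1, 1:3, 0.01)
  expect_equal(prof2$value, c(0, 0, 3, 0, 0))
  expect_equal(prof2$peak_lag_s, 0)
  expect_error(diagonal_lag_profile(dw, 1, 1, integer(0), 0.01), "empty")
})

test_that("fixed-lag regression: constructed shift, identity, null", {
  set.seed(8)
  K <- 30L; Tn <- 40L; D <- 3L
  beh <- array(rnorm(K * Tn * 2), c(K, Tn, 2))
  # latent = behavior shifted so behavior LEADS by 5 bins:
  # latent(t) = behavior(t-5)
  lat <- array(0, c(K, Tn, 2))
  lat[, 6:Tn, ] <- beh[, 1:(Tn - 5), ]
  sp <- list(train = 1:20, test = 21:30)
  prof <- fixed_lag_regression(lat, beh, 0.01, sp,
                               lags_s = seq(-0.08, 0.08, 0.01),
                               lambda = 1e-4)
  expect_equal(prof$peak_lag_s, -0.05)
  expect_gt(max(prof$value), 0.95)
  # latents = behavior at lag 0 gives R2 = 1 exactly (tiny ridge)
  prof0 <- fixed_lag_regression(beh, beh, 0.01, sp, lags_s = 0,
                                lambda = 1e-9)
  expect_equal(prof0$value, 1, tolerance = 1e-6)
  # white-noise latents: flat profile near zero
  noise <- array(rnorm(K * Tn * D), c(K, Tn, D))
  profn <- fixed_lag_regression(noise, beh, 0.01, sp,
                                lags_s = seq(-0.05, 0.05, 0.01))
  expect_lt(max(abs(profn$value)), 0.1)
  # exhausted window errors
  expect_error(fixed_lag_regression(beh, beh, 0.01, sp,
                                    lags_s = seq(-0.2, 0.2, 0.01),
                                    window = 15:25), "exhausts")
})

test_that("seq2seq ridge: exact linear recovery and pure-noise null", {
  set.seed(9)
  K <- 60L; Tn <- 12L; Fn <- 3L
  fac <- array(rnorm(K * Tn * Fn), c(K, Tn, Fn))
  W <- matrix(rnorm(Tn * Fn * Tn * 2, sd = 0.3), Tn * Fn, Tn * 2)
  beh_flat <- band:::flatten_seq(fac) %*% W
  beh <- band:::unflatten_seq(beh_flat, Tn, 2L)
  sp <- list(train = 1:45, test = 46:60)
  fit <- fit_seq2seq_ridge(fac, beh, sp, lambdas = c(1e-8, 1e-4, 1))
  expect_gt(fit$r2, 0.999)
  # pure-noise factors: test R2 near zero (not large)
  fac_n <- array(rnorm(K * Tn * Fn), c(K, Tn, Fn))
  fit_n <- fit_seq2seq_ridge(fac_n, beh, sp)
  expect_lt(abs(fit_n$r2), 0.25)
  expect_s3_class(fit$weights, "decoder_weights")
})

test_that("biRNN decoder: capacity on a linear map, null on shuffles", {
  set.seed(10)
  cfg <- sim_config(n_neurons = 8L, T = 20L, prep_bins = 8L,
                    trials_per_epoch = c(BL = 4L, AD = 4L, WO = 4L),
                    seed = 44L)
  ds <- generate_dataset(cfg)$dataset
  # behavior = exact noiseless linear map of the observed counts
  M <- matrix(rnorm(8 * 2, sd = 0.5), 8, 2)
  lin <- array(0, c(n_trials(ds), 20, 2))
  for (k in seq_len(n_trials(ds))) lin[k, , ] <- ds$spikes[k, , ] %*% M
  ds_lin <- ds; ds_lin$behavior <- lin
  sp <- split_trials(ds, split_spec("holdout", seed = 3))
  bc <- birnn_config(hidden = 12L, n_layers = 1L, dropout = 0,
                     epochs = 80L, lr = 1e-2, seed = 2L)
  fit <- train_birnn_decoder(ds_lin, sp, bc)
  expect_gt(fit$r2, 0.8)
  # behavior shuffled across trials: no decodable signal
  ds_shuf <- ds_lin
  set.seed(5)
  ds_shuf$behavior <- ds_lin$behavior[sample(n_trials(ds)), , ,
                                      drop = FALSE]
  fit_s <- train_birnn_decoder(ds_shuf, sp, bc)
  expect_lt(fit_s$r2, 0.15)
})

test_that("oscillatory-neuron detection separates induced from constant", {
  # hand-built world: 60-bin trials at 10 ms; neurons:
  # 1: AD-only 5 Hz modulation, 2: constant, 3: oscillates in both epochs
  set.seed(11)
  Tn <- 60L; nAD <- 8L; nBL <- 8L
  tt <- (0:(Tn - 1)) * 0.01
  mk_trial <- function(osc) {
    base <- 12
    r1 <- if (osc) base + 10 * sin(2 * pi * 5 * tt + runif(1, 0, 2 * pi))
          else rep(base, Tn)
    r3 <- base + 10 * sin(2 * pi * 5 * tt + runif(1, 0, 2 * pi))
    cbind(rpois(Tn, r1 * 0.01 * 8),  # higher counts: SNR >= 1
          rpois(Tn, base * 0.01 * 8),
          rpois(Tn, r3 * 0.01 * 8))
  }
  spikes <- array(0L, c(nAD + nBL, Tn, 3))
  for (k in seq_len(nAD)) spikes[k, , ] <- mk_trial(TRUE)
  for (k in nAD + seq_len(nBL)) spikes[k, , ] <- mk_trial(FALSE)
  ds <- trial_dataset(
    spikes = spikes,
    behavior = array(0, c(nAD + nBL, Tn, 1)) + rnorm(1),
    bin_width = 0.01,
    condition = rep(1L, nAD + nBL),
    epoch = rep(c("AD", "BL"), c(nAD, nBL)),
    prep_bins = 10L)
  res <- detect_oscillatory_neurons(ds, n_shuffle = 200L, seed = 3L)
  expect_true(res$flagged[1])    # induced oscillation
  expect_false(res$flagged[2])   # constant rate
  expect_false(res$flagged[3])   # oscillates regardless of epoch
  # invariance to neuron relabeling
  perm <- c(3L, 1L, 2L)
  ds2 <- ds; ds2$spikes <- ds$spikes[, , perm]
  res2 <- detect_oscillatory_neurons(ds2, n_shuffle = 200L, seed = 3L)
  expect_equal(res2$flagged, res$flagged[perm])
  expect_error(detect_oscillatory_neurons(ds[1:9], n_shuffle = 10L),
               "BL")
})

test_that("controller contribution is zero when the controller is silent", {
  ds <- tiny_dataset(seed = 51)
  cfg <- tiny_model_cfg()
  m <- band_model(cfg, dim(ds$spikes)[3], dim(ds$spikes)[2], seed = 4)
  # force the controller head to emit exactly zero mean
  m$params$con_head$W[] <- 0
  m$params$con_head$b[1:cfg$n_control] <- 0
  mab <- ablate_controller(m)
  res <- controller_contribution(m, mab, ds)
  expect_equal(max(abs(res$per_trial$d_bits_per_spike)), 0)
  expect_equal(max(abs(res$per_bin$d_ev)), 0)
  # mismatched checkpoints are rejected
  other <- band_model(cfg, dim(ds$spikes)[3], dim(ds$spikes)[2], seed = 9)
  expect_error(controller_contribution(other, mab, ds), "share")
  expect_error(controller_contribution(m, m, ds), "ablated")
})
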