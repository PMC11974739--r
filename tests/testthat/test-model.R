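make_model <- function(..., N = 12L, T = 30L, seed = 2L) {
  band_model(tiny_model_cfg(...), n_neurons = N, T = T, seed = seed)
}

rand_spikes <- function(N = 12L, T = 30L, B = 4L, seed = 3L) {
  set.seed(seed)
  array(rpois(B * T * N, 0.4), c(B, T, N))
}

test_that("initial-condition encoder sees only the preparatory window", {
  m <- make_model()
  sp <- rand_spikes()
  prep <- m$config$prep_bins
  ic1 <- encode_initial_condition(m, sp[, 1:prep, , drop = FALSE])
  # identical preparatory windows give identical posteriors
  ic2 <- encode_initial_condition(m, sp[, 1:prep, , drop = FALSE])
  expect_identical(ic1, ic2)
  expect_true(all(ic1$sd > 0))
  # wrong temporal extent is rejected
  expect_error(encode_initial_condition(m, sp[, 1:(prep + 1), ,
                                              drop = FALSE]),
               "preparatory bins")
  # via the full forward pass: movement-phase perturbations cannot touch g0
  t1 <- band_forward(m, sp)
  sp2 <- sp
  sp2[, (prep + 1):dim(sp)[2], ] <- sp2[, (prep + 1):dim(sp)[2], ] + 3
  t2 <- band_forward(m, sp2)
  expect_identical(t1$g0_mean, t2$g0_mean)
  expect_identical(t1$g0_sd, t2$g0_sd)
})

test_that("controller is strictly causal", {
  m <- make_model()
  sp <- rand_spikes()
  prep <- m$config$prep_bins
  Tn <- dim(sp)[2]
  mv <- sp[, (prep + 1):Tn, , drop = FALSE]
  u1 <- encode_controller(m, mv)
  # perturb spikes at the final movement bin only
  mv2 <- mv
  mv2[, dim(mv)[2], ] <- mv2[, dim(mv)[2], ] + 5
  u2 <- encode_controller(m, mv2)
  Tm <- dim(mv)[2]
  expect_identical(u1$mean[, 1:(Tm - 1), ], u2$mean[, 1:(Tm - 1), ])
  expect_identical(u1$sd[, 1:(Tm - 1), ], u2$sd[, 1:(Tm - 1), ])
  expect_false(identical(u1$mean[, Tm, ], u2$mean[, Tm, ]))
  # exhaustive causality: perturbing any bin t leaves all earlier bins
  # untouched, exactly
  for (t in c(3L, 5L)) {
    mv3 <- mv
    mv3[1, t, 2] <- mv3[1, t, 2] + 1
    u3 <- encode_controller(m, mv3)
    if (t > 1) {
      expect_identical(u1$mean[, 1:(t - 1), ], u3$mean[, 1:(t - 1), ])
    }
    expect_false(identical(u1$mean[, t, ], u3$mean[, t, ]))
  }
})

test_that("n_control = 0 yields an empty posterior and autonomous model", {
  m <- make_model(n_control = 0L)
  sp <- rand_spikes()
  prep <- m$config$prep_bins
  u <- encode_controller(m, sp[, (prep + 1):dim(sp)[2], , drop = FALSE])
  expect_equal(dim(u$mean)[3], 0L)
  traj <- band_forward(m, sp)
  sp2 <- sp
  sp2[, (prep + 1):dim(sp)[2], ] <- 0
  traj2 <- band_forward(m, sp2)
  expect_identical(traj$rates, traj2$rates)
  expect_error(ablate_controller(m), "autonomous")
})

test_that("generator determinism, positivity, and ablation identity", {
  m <- make_model()
  sp <- rand_spikes()
  prep <- m$config$prep_bins
  ic <- encode_initial_condition(m, sp[, 1:prep, , drop = FALSE])
  con <- encode_controller(m, sp[, (prep + 1):dim(sp)[2], , drop = FALSE])
  g1 <- generate_trajectory(m, ic$mean, con$mean)
  g2 <- generate_trajectory(m, ic$mean, con$mean)
  expect_identical(g1$factors, g2$factors)
  # u = 0 equals the ablated forward bit for bit
  u0 <- array(0, dim = dim(con$mean))
  gz <- generate_trajectory(m, ic$mean, u0)
  mab <- ablate_controller(m)
  tab <- band_forward(mab, sp)
  expect_identical(gz$factors, tab$factors)
  expect_identical(gz$rates, tab$rates)
  # ablation is idempotent and leaves the original untouched
  expect_identical(ablate_controller(mab), mab)
  expect_false(m$ablated)
  # ablated outputs ignore movement-phase spikes entirely
  sp2 <- sp
  sp2[, (prep + 1):dim(sp)[2], ] <- rand_spikes(seed = 99)[, (prep + 1):
                                                             dim(sp)[2], ]
  tab2 <- band_forward(mab, sp2)
  expect_identical(tab$rates, tab2$rates)
  expect_identical(tab$behavior_pred, tab2$behavior_pred)
})

test_that("rates are strictly positive across random models and inputs", {
  for (seed in 1:25) {
    m <- make_model(seed = seed, T = 16L, N = 6L)
    sp <- rand_spikes(N = 6L, T = 16L, B = 2L, seed = seed + 100)
    traj <- band_forward(m, sp, sample = TRUE, seed = seed)
    expect_true(all(traj$rates > 0))
  }
})

test_that("seq2seq decoder is the advertised affine map", {
  m <- make_model()
  set.seed(8)
  m$params$beh$W[] <- rnorm(length(m$params$beh$W), sd = 0.2)
  m$params$beh$b[] <- rnorm(length(m$params$beh$b))
  Tn <- m$T; Fn <- m$config$n_factors
  # one-hot factor at (t0, f0) reproduces column (t0-1)*F + f0 plus bias
  t0 <- 7L; f0 <- 2L
  fac <- array(0, c(1, Tn, Fn))
  fac[1, t0, f0] <- 1
  pred <- decode_behavior_seq2seq(m, fac)
  manual <- m$params$beh$W[(t0 - 1) * Fn + f0, ] + m$params$beh$b
  expect_equal(as.vector(band:::flatten_seq(pred)), manual,
               tolerance = 1e-12)
  # homogeneity: doubling factors doubles (pred - bias)
  fac2 <- fac * 2
  pred2 <- decode_behavior_seq2seq(m, fac2)
  bias <- array(rep(m$params$beh$b, each = 1),
                dim = dim(band:::flatten_seq(pred)))
  expect_equal(band:::flatten_seq(pred2) - bias,
               2 * (band:::flatten_seq(pred) - bias), tolerance = 1e-12)
  # weight_block indexing agrees with the flat map
  dw <- band_decoder_weights(m)
  blk <- weight_block(dw, f0, 1)
  expect_equal(blk[t0, 4], m$params$beh$W[(t0 - 1) * Fn + f0,
                                          (4 - 1) * 2 + 1])
  # trial length is part of the contract
  expect_error(decode_behavior_seq2seq(m, fac[, 1:10, , drop = FALSE]),
               "T = ")
})

test_that("eval-mode forward is deterministic; sampling is seeded", {
  m <- make_model()
  sp <- rand_spikes()
  t1 <- band_forward(m, sp)
  t2 <- band_forward(m, sp)
  expect_identical(t1$rates, t2$rates)
  s1 <- band_forward(m, sp, sample = TRUE, seed = 5)
  s2 <- band_forward(m, sp, sample = TRUE, seed = 5)
  expect_identical(s1$rates, s2$rates)
  expect_false(identical(s1$rates, t1$rates))
  # untrained model still yields a finite Poisson likelihood
  expect_true(is.finite(poisson_log_likelihood(t1$rates, sp)))
})

test_that("posterior-sample averaging changes held-out rates measurably", {
  m <- make_model()
  sp <- rand_spikes()
  r1 <- band_forward(m, sp, sample = TRUE, n_samples = 1, seed = 9)$rates
  r64 <- band_forward(m, sp, sample = TRUE, n_samples = 64, seed = 9)$rates
  delta <- abs(bits_per_spike(r64, sp) - bits_per_spike(r1, sp))
  expect_gt(delta, 0)
  # with many samples the average approaches the deterministic-mean pass
  r_mean <- band_forward(m, sp)$rates
  expect_lt(mean(abs(r64 - r_mean)), mean(abs(r1 - r_mean)))
})
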