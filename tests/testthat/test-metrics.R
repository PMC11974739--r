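# Independent brute-force oracles, written before the implementations:
# plain elementwise loops with no shared code.

oracle_poisson_ll <- function(rates, spikes) {
  total <- 0
  for (i in seq_along(rates)) {
    l <- rates[i]; y <- spikes[i]
    total <- total + (if (l > 0) y * log(l) else 0) - l - lgamma(y + 1)
  }
  total
}

oracle_kl <- function(mq, sq, mp = 0, sp = 1) {
  total <- 0
  for (i in seq_along(mq)) {
    total <- total + log(sp / sq[i]) +
      (sq[i]^2 + (mq[i] - mp)^2) / (2 * sp^2) - 0.5
  }
  total
}

oracle_bits_per_spike <- function(rates, spikes) {
  lam_bar <- apply(spikes, 3, mean)
  acc <- 0
  for (k in seq_len(dim(spikes)[1])) for (t in seq_len(dim(spikes)[2]))
    for (n in seq_len(dim(spikes)[3])) {
      y <- spikes[k, t, n]
      ll <- function(l) (if (l > 0) y * log(l) else 0) - l - lgamma(y + 1)
      acc <- acc + ll(rates[k, t, n]) - ll(lam_bar[n])
    }
  acc / (sum(spikes) * log(2))
}

oracle_r2 <- function(y, f) {
  sse <- 0; sst <- 0
  for (b in seq_len(dim(y)[3])) {
    mu <- mean(y[, , b])
    for (k in seq_len(dim(y)[1])) for (t in seq_len(dim(y)[2])) {
      sse <- sse + (y[k, t, b] - f[k, t, b])^2
      sst <- sst + (y[k, t, b] - mu)^2
    }
  }
  1 - sse / sst
}

rand_tensors <- function(seed) {
  set.seed(seed)
  d <- c(sample(2:4, 1), sample(2:5, 1), sample(1:3, 1))
  list(rates = array(exp(rnorm(prod(d), -1, 0.7)), d),
       spikes = array(rpois(prod(d), 0.8), d),
       y = array(rnorm(prod(d)), d),
       f = array(rnorm(prod(d)), d))
}

test_that("poisson_log_likelihood: closed forms and brute-force oracle", {
  expect_identical(poisson_log_likelihood(array(1, c(1, 1, 1)),
                                          array(0L, c(1, 1, 1))), -1)
  # lambda = y is the per-entry MLE
  y <- array(c(3, 1, 4, 2), c(1, 2, 2))
  best <- poisson_log_likelihood(y, y)
  for (i in 1:4) {
    pert <- y; pert[i] <- pert[i] + 0.2
    expect_lt(poisson_log_likelihood(pert, y), best)
  }
  for (seed in 1:100) {
    tt <- rand_tensors(seed)
    expect_equal(poisson_log_likelihood(tt$rates, tt$spikes),
                 oracle_poisson_ll(tt$rates, tt$spikes),
                 tolerance = 1e-12)
  }
  expect_error(poisson_log_likelihood(array(0, c(1, 1, 1)),
                                      array(2L, c(1, 1, 1))), "zero rate")
  # zero rate with zero count is admissible
  expect_identical(poisson_log_likelihood(array(0, c(1, 1, 1)),
                                          array(0L, c(1, 1, 1))), 0)
})

test_that("kl_gaussian: closed forms, oracle, Monte-Carlo check", {
  expect_equal(kl_gaussian(rep(0, 5), rep(1, 5)), 0)
  mu <- c(0.5, -2, 1)
  expect_equal(kl_gaussian(mu, rep(1, 3)), sum(mu^2) / 2)
  for (seed in 1:100) {
    set.seed(seed)
    mq <- rnorm(6); sq <- exp(rnorm(6, 0, 0.4))
    expect_equal(kl_gaussian(mq, sq), oracle_kl(mq, sq), tolerance = 1e-12)
  }
  expect_error(kl_gaussian(0, -1), "sd")

  # Monte-Carlo estimate of E_q[log q - log p], 1e6 samples, within 3 SE
  set.seed(7)
  mq <- 0.8; sq <- 1.7
  z <- rnorm(1e6, mq, sq)
  w <- dnorm(z, mq, sq, log = TRUE) - dnorm(z, 0, 1, log = TRUE)
  expect_lt(abs(kl_gaussian(mq, sq) - mean(w)), 3 * sd(w) / sqrt(1e6))
})

test_that("bits metrics: null model, oracle, permutation invariance", {
  set.seed(1)
  spikes <- array(rpois(3 * 4 * 2, 1.2), c(3, 4, 2))
  lam_bar <- apply(spikes, 3, mean)
  base <- aperm(array(lam_bar, c(2, 3, 4)), c(2, 3, 1))
  expect_equal(bits_per_spike(base, spikes), 0)
  expect_equal(bits_per_second(base, spikes, 0.01), 0)
  for (seed in 1:100) {
    tt <- rand_tensors(seed)
    if (sum(tt$spikes) == 0) next
    expect_equal(bits_per_spike(tt$rates, tt$spikes),
                 oracle_bits_per_spike(tt$rates, tt$spikes),
                 tolerance = 1e-12)
  }
  # printed fixture: 2 neurons x 4 bins, one trial
  rates <- array(c(0.5, 1.0, 1.5, 1.0, 0.2, 0.4, 0.2, 0.4), c(1, 4, 2))
  y <- array(c(1L, 1L, 2L, 1L, 0L, 1L, 0L, 0L), c(1, 4, 2))
  expect_equal(bits_per_spike(rates, y), oracle_bits_per_spike(rates, y),
               tolerance = 1e-12)
  # bits/sec = bits/spike * n_sp / seconds
  expect_equal(bits_per_second(rates, y, 0.01),
               bits_per_spike(rates, y) * sum(y) / (4 * 0.01))
  # neuron permutation invariance
  tt <- rand_tensors(5)
  perm <- sample(dim(tt$spikes)[3])
  expect_equal(bits_per_spike(tt$rates[, , perm, drop = FALSE],
                              tt$spikes[, , perm, drop = FALSE]),
               bits_per_spike(tt$rates, tt$spikes))
  expect_error(bits_per_spike(tt$rates, 0 * tt$spikes), "n_sp")
})

test_that("bits/spike increases toward true rates along the null path", {
  gd <- generate_dataset(tiny_sim(seed = 31))
  ds <- gd$dataset
  truth_rates <- exp(band:::sim_log_rates(gd$truth))
  lam_bar <- apply(ds$spikes, 3, mean)
  base <- aperm(array(lam_bar, c(dim(ds$spikes)[3], dim(ds$spikes)[1],
                                 dim(ds$spikes)[2])), c(2, 3, 1))
  vals <- sapply(seq(0, 1, length.out = 5), function(a) {
    bits_per_spike((1 - a) * base + a * truth_rates, ds$spikes)
  })
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[5], 0)  # true generating rates beat the null
})

test_that("r2 variants and explained variance", {
  y <- array(c(0, 1, 2), c(3, 1, 1))
  f <- array(0, c(3, 1, 1))
  expect_equal(r2_isotropic(y, f), -1.5)
  expect_equal(r2_isotropic(y, y), 1)
  fm <- array(mean(y), c(3, 1, 1))
  expect_equal(r2_isotropic(y, fm), 0)
  for (seed in 1:100) {
    tt <- rand_tensors(seed)
    r2 <- r2_isotropic(tt$y, tt$f)
    expect_equal(r2, oracle_r2(tt$y, tt$f), tolerance = 1e-12)
    expect_lte(r2, 1)
    # algebraic identity EV = Var * R2 with pooled conventions
    mu <- apply(tt$y, 3, mean)
    v <- sum(sweep(tt$y, 3, mu)^2) / length(tt$y)
    expect_equal(explained_behavior_variance(tt$y, tt$f), v * r2,
                 tolerance = 1e-12)
  }
  # equal-variance components: isotropic equals per-component average
  set.seed(2)
  y2 <- array(rnorm(60), c(10, 3, 2))
  y2[, , 2] <- y2[, , 2] * sd(y2[, , 1]) / sd(y2[, , 2])
  y2[, , 2] <- y2[, , 2] - mean(y2[, , 2]) + mean(y2[, , 1]) * 0
  f2 <- y2 + array(rnorm(60, 0, 0.3), c(10, 3, 2))
  expect_equal(r2_isotropic(y2, f2), r2_per_component(y2, f2),
               tolerance = 0.05)
  expect_equal(explained_behavior_variance(y2, y2),
               sum(apply(y2, 3, function(m) mean((m - mean(m))^2))) / 2)
  expect_equal(explained_behavior_variance(y2,
                 array(rep(apply(y2, 3, mean), each = 30), dim(y2))), 0)
  expect_error(r2_isotropic(array(1, c(2, 1, 1)), array(1, c(2, 1, 1))),
               "variance")
})

test_that("hyperparameter-search objectives are the stated arithmetic", {
  expect_equal(pbt_objective(-120, 10, 30, 1), -120 / 300)
  expect_equal(pbt_objective_nlb(-120, 0), -120)
  for (seed in 1:20) {
    set.seed(seed)
    lx <- rnorm(1, -100, 30); n <- sample(5:50, 1); tt <- sample(10:60, 1)
    r2 <- runif(1, -1, 1); mse <- rexp(1)
    expect_equal(pbt_objective(lx, n, tt, r2), lx / (n * tt) - (1 - r2))
    expect_equal(pbt_objective_nlb(lx, mse), lx - 1e-4 * mse)
  }
})

test_that("composite loss assembles per the stated formula", {
  ds <- tiny_dataset(seed = 8)
  cfg <- tiny_model_cfg(theta = 0.7, alpha = 1e-3)
  m <- band_model(cfg, dim(ds$spikes)[3], dim(ds$spikes)[2], seed = 2)
  traj <- band_forward(m, ds)
  w <- list(theta = 0.7, alpha = 1e-3, beta_kl_g0 = 1, beta_kl_u = 1)
  lb <- band_loss(traj, ds, w, model = m)
  # total reproducible from parts
  expect_equal(lb$total,
               lb$L_x + w$theta * lb$L_b - w$alpha * lb$L_L2 -
                 lb$KL_g0 - lb$KL_u, tolerance = 1e-12)
  expect_gte(lb$KL_g0, 0)
  expect_gte(lb$KL_u, 0)
  # doubling theta changes the total by exactly +L_b
  w2 <- w; w2$theta <- 1.4
  lb2 <- band_loss(traj, ds, w2, model = m)
  expect_equal(lb2$total - lb$total, 0.7 * lb$L_b, tolerance = 1e-10)
  # theta = 0: total independent of behavior predictions
  traj2 <- traj
  traj2$behavior_pred <- traj$behavior_pred + 5
  w0 <- w; w0$theta <- 0
  expect_equal(band_loss(traj, ds, w0, model = m)$total,
               band_loss(traj2, ds, w0, model = m)$total)
  # all weights zero except L_x: reduction to the Poisson term
  wx <- list(theta = 0, alpha = 0, beta_kl_g0 = 0, beta_kl_u = 0)
  expect_equal(band_loss(traj, ds, wx, model = m)$total,
               poisson_log_likelihood(traj$rates, ds$spikes) /
                 n_trials(ds))
})
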