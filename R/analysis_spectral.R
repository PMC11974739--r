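#' Gaussian-kernel firing-rate estimates
#'
#' Convolves each neuron's binned counts with a normalized Gaussian
#' kernel (default sigma = 30 ms) along time, using reflecting edge
#' handling, and converts to rates in Hz. Reflection plus kernel
#' normalization preserves the total count of interior-supported signals.
#'
#' @param spikes counts array (trials x bins x neurons), matrix
#'   (bins x series) or vector, or a `trial_dataset`.
#' @param sigma kernel standard deviation in seconds (default 0.030).
#' @param bin_width bin width in seconds (taken from the dataset when one
#'   is supplied).
#' @return smoothed rates in Hz, same shape as the input counts.
#' @export
smooth_rates_gaussian <- function(spikes, sigma = 0.030, bin_width = NULL) {
  if (inherits(spikes, "trial_dataset")) {
    bin_width <- spikes$bin_width
    spikes <- spikes$spikes
  }
  if (is.null(bin_width)) stopf("bin_width is required")
  assert_that(sigma > 0, "sigma must be > 0")
  if (sigma < bin_width / 2)
    warnf("sigma (%.1f ms) is below half a bin; smoothing is near-trivial",
          1000 * sigma)
  Tn <- if (is.array(spikes) && length(dim(spikes)) == 3L) dim(spikes)[2]
    else if (is.matrix(spikes)) nrow(spikes) else length(spikes)
  S <- gaussian_smoother_matrix(Tn, sigma / bin_width)
  if (is.array(spikes) && length(dim(spikes)) == 3L) {
    d <- dim(spikes)
    flat <- matrix(aperm(spikes, c(2, 1, 3)), Tn, d[1] * d[3])
    sm <- S %*% flat
    aperm(array(sm, dim = c(Tn, d[1], d[3])), c(2, 1, 3)) / bin_width
  } else if (is.matrix(spikes)) {
    (S %*% spikes) / bin_width
  } else {
    drop(S %*% spikes) / bin_width
  }
}

## T x T smoothing operator: normalized Gaussian kernel with reflecting
## boundaries, so each row sums to 1.
gaussian_smoother_matrix <- function(Tn, sigma_bins) {
  w <- max(1L, ceiling(4 * sigma_bins))
  offs <- seq(-w, w)
  kern <- exp(-offs^2 / (2 * sigma_bins^2))
  kern <- kern / sum(kern)
  S <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn)) {
    j <- i + offs
    ## reflect indices about the edges (1 and Tn)
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > Tn, 2 * Tn - j, j)
    for (m in seq_along(j)) S[i, j[m]] <- S[i, j[m]] + kern[m]
  }
  S
}

#' Per-trial FFT amplitude spectrum
#'
#' Applies the discrete Fourier transform to every trial (and behavior
#' component), retaining the complex coefficients. Normalization:
#' unnormalized forward transform, `amplitude = |X_k|`,
#' `power = |X_k|^2 / T`, so that summing power over all T modes equals
#' the summed squared signal (Parseval). Mean power is averaged over
#' trials and components per mode.
#'
#' @param x signal: trials x bins matrix or trials x bins x components
#'   array.
#' @param bin_width bin width in seconds.
#' @return object of class `spectrum_result` with `frequencies` (Hz, all
#'   T modes), `coefficients` (trials x modes x components, complex),
#'   `amplitude`, `power`, `mean_power`, and `nonneg` (indices of the
#'   DC..Nyquist modes).
#' @export
fft_amplitude_spectrum <- function(x, bin_width) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  if (anyNA(x)) stopf("NaN in signal")
  K <- dim(x)[1]; Tn <- dim(x)[2]; Bc <- dim(x)[3]
  co <- array(complex(real = 0), dim = c(K, Tn, Bc))
  for (b in seq_len(Bc)) {
    xb <- matrix(x[, , b], K, Tn)
    co[, , b] <- t(stats::mvfft(t(xb)))
  }
  amp <- Mod(co)
  pow <- amp^2 / Tn
  structure(list(
    frequencies = (seq_len(Tn) - 1) / (Tn * bin_width),
    coefficients = co,
    amplitude = amp,
    power = pow,
    mean_power = apply(pow, 2, mean),
    nonneg = seq_len(floor(Tn / 2) + 1L),
    bin_width = bin_width
  ), class = "spectrum_result")
}

#' Index of the FFT mode nearest a target frequency
#'
#' @param spec a `spectrum_result` (or numeric frequency grid).
#' @param f target frequency, Hz.
#' @return integer mode index (restricted to DC..Nyquist).
#' @export
mode_nearest <- function(spec, f) {
  freqs <- if (inherits(spec, "spectrum_result")) {
    spec$frequencies[spec$nonneg]
  } else spec
  which.min(abs(freqs - f))
}

#' Detect perturbation-induced oscillatory neurons
#'
#' For each neuron, single-trial firing rates (Gaussian-smoothed counts,
#' sigma = 30 ms) are Fourier transformed and the trial-mean power of the
#' modes nearest the target frequencies (default 4 and 5 Hz) is compared
#' to a shuffle null: each trial's count sequence is independently
#' permuted across time `n_shuffle` times, re-smoothed and re-transformed.
#' A neuron is flagged when its adaptation-epoch band power exceeds the
#' null mean + `threshold_sd` standard deviations while its baseline
#' band power stays within the baseline null band — i.e. oscillations
#' must be induced by the perturbation, not present throughout.
#'
#' The same per-trial permutations are shared across neurons (the whole
#' population is shuffled jointly), which leaves each neuron's marginal
#' null unchanged and keeps runtime practical.
#'
#' @param dataset a `trial_dataset` with both AD and BL trials.
#' @param freqs target frequencies, Hz (default `c(4, 5)`).
#' @param sigma smoothing kernel sd, seconds.
#' @param n_shuffle number of within-trial permutations (default 500).
#' @param threshold_sd null exceedance threshold (default 4).
#' @param min_trials minimum trials per epoch required.
#' @param seed RNG seed for the permutations.
#' @return data.frame, one row per neuron: observed and null band power
#'   by epoch and the logical `flagged`.
#' @export
detect_oscillatory_neurons <- function(dataset, freqs = c(4, 5),
                                       sigma = 0.030, n_shuffle = 500L,
                                       threshold_sd = 4, min_trials = 4L,
                                       seed = 1L) {
  validate_trial_dataset(dataset)
  for (ep in c("AD", "BL")) {
    if (sum(dataset$epoch == ep) < min_trials)
      stopf("need at least %d %s trials, found %d", min_trials, ep,
            sum(dataset$epoch == ep))
  }
  Tn <- dim(dataset$spikes)[2]
  N <- dim(dataset$spikes)[3]
  S <- gaussian_smoother_matrix(Tn, sigma / dataset$bin_width)
  grid <- (seq_len(floor(Tn / 2) + 1L) - 1L) / (Tn * dataset$bin_width)
  modes <- unique(vapply(freqs, function(f) which.min(abs(grid - f)), 0L))
  modes <- modes[modes > 1L]  # DC is never an oscillation
  tt <- seq_len(Tn) - 1L
  ## projection vectors for the selected modes, after smoothing:
  ## power_m(x) = |e_m^H S x|^2 / T
  proj <- vapply(modes, function(m) {
    e <- exp(-2i * pi * (m - 1L) * tt / Tn)
    as.vector(t(Conj(e)) %*% S)
  }, complex(Tn))
  proj <- matrix(proj, ncol = length(modes))  # T x modes

  band_power <- function(counts_mat) {
    ## counts_mat: T x series; returns modes x series power
    z <- crossprod(proj, counts_mat)
    (Mod(z)^2) / Tn
  }

  epochs <- list(AD = which(dataset$epoch == "AD"),
                 BL = which(dataset$epoch == "BL"))
  res <- list()
  with_seed(seed, {
    for (ep in names(epochs)) {
      idx <- epochs[[ep]]
      obs <- matrix(0, length(modes), N)
      null_acc <- matrix(0, length(modes), N * n_shuffle)
      ## shuffles are processed in blocks to bound memory at large N
      block <- max(1L, min(n_shuffle, floor(2.5e6 / (Tn * N))))
      starts <- seq(1L, n_shuffle, by = block)
      for (k in idx) {
        counts <- t(matrix(dataset$spikes[k, , ], Tn, N))  # N x T
        obs <- obs + band_power(t(counts))
        ## one permutation of this trial per shuffle, shared across neurons
        perms <- replicate(n_shuffle, sample.int(Tn))
        for (st in starts) {
          en <- min(st + block - 1L, n_shuffle)
          shuf <- matrix(0, Tn, N * (en - st + 1L))
          for (s in st:en) {
            shuf[, ((s - st) * N + 1L):((s - st + 1L) * N)] <-
              t(counts[, perms[, s]])
          }
          cols <- ((st - 1L) * N + 1L):(en * N)
          null_acc[, cols] <- null_acc[, cols] + band_power(shuf)
        }
      }
      obs <- obs / length(idx)
      null_acc <- null_acc / length(idx)   # trial-mean per shuffle
      dim(null_acc) <- c(length(modes), N, n_shuffle)
      res[[ep]] <- list(
        obs = obs,
        null_mean = apply(null_acc, c(1, 2), mean),
        null_sd = apply(null_acc, c(1, 2), stats::sd))
    }
  })
  ad <- res$AD; bl <- res$BL
  exceed_ad <- ad$obs > ad$null_mean + threshold_sd * ad$null_sd
  within_bl <- bl$obs <= bl$null_mean + threshold_sd * bl$null_sd
  flagged <- apply(exceed_ad & within_bl, 2, any)
  data.frame(
    neuron = seq_len(N),
    ad_power = apply(ad$obs, 2, max),
    ad_null_mean = apply(ad$null_mean, 2, max),
    bl_power = apply(bl$obs, 2, max),
    bl_null_mean = apply(bl$null_mean, 2, max),
    flagged = flagged
  )
}

#' Cosine similarity between Fourier modes of true and predicted signals
#'
#' Treats each trial's complex coefficient at a mode as a 2-vector
#' (Re, Im). The default pooled variant is amplitude-weighted:
#' `sum(<v_true, v_pred>) / (||v_true|| * ||v_pred||)` with sums over
#' trials and components per mode, giving 1 for perfect phase+shape
#' agreement and -1 for antiphase. The `"per_trial"` variant averages
#' unweighted phase cosines over trials. Modes with zero amplitude in
#' the truth are reported as NA.
#'
#' @param true,predicted trials x bins (x components) signals.
#' @param bin_width bin width, seconds.
#' @param method `"pooled"` (default) or `"per_trial"`.
#' @return data.frame with `frequency` (DC..Nyquist) and `similarity`.
#' @export
fft_phase_similarity <- function(true, predicted, bin_width,
                                 method = c("pooled", "per_trial")) {
  method <- match.arg(method)
  st <- fft_amplitude_spectrum(true, bin_width)
  sp <- fft_amplitude_spectrum(predicted, bin_width)
  nn <- st$nonneg
  sim <- vapply(nn, function(m) {
    xt <- st$coefficients[, m, ]
    xp <- sp$coefficients[, m, ]
    if (all(Mod(xt) == 0)) return(NA_real_)
    if (method == "pooled") {
      den <- sqrt(sum(Mod(xt)^2)) * sqrt(sum(Mod(xp)^2))
      if (den == 0) return(NA_real_)
      sum(Re(xt * Conj(xp))) / den
    } else {
      ok <- Mod(xt) > 0 & Mod(xp) > 0
      if (!any(ok)) return(NA_real_)
      mean(Re(xt[ok] * Conj(xp[ok])) / (Mod(xt[ok]) * Mod(xp[ok])))
    }
  }, 0)
  data.frame(frequency = st$frequencies[nn], similarity = sim)
}
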