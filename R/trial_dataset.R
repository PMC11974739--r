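#' Trial-aligned spiking + behavior dataset
#'
#' The universal container used by every other function in the package:
#' binned spike counts, paired continuous behavior, and per-trial labels
#' for a set of trial-aligned recordings (or simulations).
#'
#' @param spikes non-negative integer array, trials x time bins x neurons.
#' @param behavior numeric array, trials x time bins x behavior components
#'   (e.g. 2-D hand velocity in cm/s).
#' @param bin_width bin width in seconds (> 0).
#' @param condition integer target label per trial (1..C).
#' @param epoch per-trial epoch label, one of `"BL"`, `"AD"`, `"WO"`
#'   (baseline / adaptation / washout).
#' @param prep_bins number of bins in the preparatory window
#'   (0 < prep_bins < T). The initial-condition encoder may only see these
#'   bins; the controller only the rest.
#' @param alignment alignment event, `"go_cue"` or `"movement_onset"`.
#'   Bin t covers `[ (t-1)*bin_width, t*bin_width )` of trial time; trial
#'   time zero is the alignment event minus the preparatory duration.
#' @param units units of the behavior channels (default `"cm/s"`).
#'
#' @return an object of class `trial_dataset`.
#' @export
trial_dataset <- function(spikes, behavior, bin_width, condition, epoch,
                          prep_bins, alignment = "movement_onset",
                          units = "cm/s") {
  x <- structure(
    list(
      spikes = spikes, behavior = behavior, bin_width = bin_width,
      condition = as.integer(condition),
      epoch = as.character(epoch),
      prep_bins = as.integer(prep_bins),
      alignment = alignment, units = units
    ),
    class = "trial_dataset"
  )
  validate_trial_dataset(x)
  x
}

EPOCH_LEVELS <- c("BL", "AD", "WO")

#' Validate a trial_dataset's invariants
#'
#' Checks every container invariant: integral non-negative spikes, matched
#' leading dimensions of spikes and behavior, 0 < prep_bins < T,
#' bin_width > 0, label lengths, and known epoch/alignment levels.
#'
#' @param x a `trial_dataset`.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_trial_dataset <- function(x) {
  assert_that(inherits(x, "trial_dataset"), "not a trial_dataset")
  s <- x$spikes; b <- x$behavior
  assert_that(is.array(s) && length(dim(s)) == 3L,
              "spikes must be a 3-d array (trials x bins x neurons)")
  assert_that(is.array(b) && length(dim(b)) == 3L,
              "behavior must be a 3-d array (trials x bins x components)")
  if (anyNA(s)) stopf("NaN/NA in spikes")
  if (anyNA(b)) stopf("NaN/NA in behavior")
  assert_that(all(s >= 0), "negative spike count")
  assert_that(all(s == round(s)), "non-integral spike count")
  assert_that(all(dim(s)[1:2] == dim(b)[1:2]),
              "spikes and behavior must share trials x bins dimensions")
  assert_that(is.numeric(x$bin_width) && length(x$bin_width) == 1L &&
                x$bin_width > 0, "bin_width must be > 0")
  T_ <- dim(s)[2]
  assert_that(is_count(x$prep_bins) && x$prep_bins < T_,
              "prep_bins must satisfy 0 < prep_bins < T")
  assert_that(length(x$condition) == dim(s)[1],
              "condition must have one label per trial")
  assert_that(length(x$epoch) == dim(s)[1],
              "epoch must have one label per trial")
  assert_that(all(x$epoch %in% EPOCH_LEVELS),
              "epoch labels must be in {BL, AD, WO}")
  assert_that(x$alignment %in% c("go_cue", "movement_onset"),
              "alignment must be go_cue or movement_onset")
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- dim(x$spikes)
  cat(sprintf(
    "trial_dataset: %d trials x %d bins x %d neurons (%d behavior dims)\n",
    d[1], d[2], d[3], dim(x$behavior)[3]))
  cat(sprintf("  bin width %.0f ms, prep window %d bins, aligned to %s\n",
              1000 * x$bin_width, x$prep_bins, x$alignment))
  cat("  epochs: ",
      paste(sprintf("%s=%d", EPOCH_LEVELS,
                    vapply(EPOCH_LEVELS, function(e) sum(x$epoch == e), 0L)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of trials in a dataset
#' @param x a `trial_dataset`.
#' @export
n_trials <- function(x) dim(x$spikes)[1]

#' Subset a trial_dataset by trial index
#' @param x a `trial_dataset`.
#' @param i trial indices.
#' @param ... unused.
#' @export
`[.trial_dataset` <- function(x, i, ...) {
  out <- x
  out$spikes <- x$spikes[i, , , drop = FALSE]
  out$behavior <- x$behavior[i, , , drop = FALSE]
  out$condition <- x$condition[i]
  out$epoch <- x$epoch[i]
  out
}

#' Remove trials with unrealistically high speeds
#'
#' Drops every trial whose Euclidean speed exceeds `max_speed` at any bin;
#' used to exclude trials with corrupted velocity readings. The threshold
#' is given in `units` (default m/s, matching the conventional > 1 m/s
#' cutoff) and converted to the dataset's behavior units before comparing.
#'
#' @param dataset a `trial_dataset` whose behavior is a velocity.
#' @param max_speed exclusion threshold (default 1.0).
#' @param units units of `max_speed`: `"m/s"` or `"cm/s"`.
#' @return list with `dataset` (kept trials, original order) and
#'   `excluded` (integer indices of dropped trials).
#' @export
filter_extreme_velocity_trials <- function(dataset, max_speed = 1.0,
                                           units = "m/s") {
  validate_trial_dataset(dataset)
  if (!units %in% c("m/s", "cm/s"))
    stopf("unsupported threshold units '%s'", units)
  if (!dataset$units %in% c("m/s", "cm/s"))
    stopf("dataset behavior units '%s' are not a velocity", dataset$units)
  thr <- max_speed
  if (units == "m/s" && dataset$units == "cm/s") thr <- max_speed * 100
  if (units == "cm/s" && dataset$units == "m/s") thr <- max_speed / 100
  speed2 <- apply(dataset$behavior^2, c(1, 2), sum)  # trials x bins
  bad <- which(apply(speed2, 1, max) > thr^2)
  keep <- setdiff(seq_len(n_trials(dataset)), bad)
  list(dataset = dataset[keep], excluded = bad)
}

#' Train/test split specification
#'
#' @param scheme `"holdout"` (single split) or `"kfold"`.
#' @param train_fraction training fraction in (0,1) for holdout
#'   (default 0.8, i.e. the conventional 80/20 split).
#' @param k number of folds for kfold (default 5).
#' @param seed integer RNG seed; splits are deterministic given the seed.
#' @param stratify stratify by condition label when every condition has
#'   enough trials (default TRUE).
#' @export
split_spec <- function(scheme = c("holdout", "kfold"), train_fraction = 0.8,
                       k = 5L, seed = 1L, stratify = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "holdout") {
    assert_that(is.numeric(train_fraction) && train_fraction > 0 &&
                  train_fraction < 1, "train_fraction must be in (0,1)")
  } else {
    assert_that(is_count(k) && k >= 2, "kfold requires k >= 2")
  }
  structure(list(scheme = scheme, train_fraction = train_fraction,
                 k = as.integer(k), seed = as.integer(seed),
                 stratify = isTRUE(stratify)),
            class = "split_spec")
}

## proportional allocation with largest remainders so per-stratum train
## counts sum exactly to ceiling(frac * n)
allocate_train_counts <- function(sizes, frac) {
  total <- ceiling(frac * sum(sizes))
  raw <- frac * sizes
  base <- floor(raw)
  need <- total - sum(base)
  if (need > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(need)]] <- base[ord[seq_len(need)]] + 1L
  }
  pmin(base, sizes)
}

#' Split trials into train/test sets or k folds
#'
#' Deterministic given `spec$seed`. Holdout uses `ceiling(frac * n)`
#' training trials; k-fold folds are disjoint and exhaustive. When
#' stratification is enabled and every condition has at least `k`
#' (holdout: 2) trials, strata are split separately so each side contains
#' every condition.
#'
#' @param dataset a `trial_dataset` (or an integer trial count).
#' @param spec a [split_spec()].
#' @return holdout: `list(train=, test=)` of trial indices; kfold: a list
#'   of `k` integer vectors of test-fold indices partitioning the trials.
#' @export
split_trials <- function(dataset, spec) {
  stopifnot(inherits(spec, "split_spec"))
  if (inherits(dataset, "trial_dataset")) {
    n <- n_trials(dataset)
    cond <- dataset$condition
  } else {
    n <- as.integer(dataset)
    cond <- rep(1L, n)
  }
  min_per <- if (spec$scheme == "kfold") spec$k else 2L
  if (spec$scheme == "kfold" && n < spec$k)
    stopf("fewer trials (%d) than folds (%d)", n, spec$k)
  if (n < 2) stopf("need at least 2 trials to split")
  strata <- if (spec$stratify && all(table(cond) >= min_per)) {
    split(seq_len(n), cond)
  } else {
    list(seq_len(n))
  }
  with_seed(spec$seed, {
    if (spec$scheme == "holdout") {
      sizes <- vapply(strata, length, 0L)
      ntr <- allocate_train_counts(sizes, spec$train_fraction)
      train <- integer(0)
      for (j in seq_along(strata)) {
        idx <- strata[[j]]
        train <- c(train, sort(sample(idx, ntr[j])))
      }
      train <- sort(train)
      list(train = train, test = setdiff(seq_len(n), train))
    } else {
      folds <- vector("list", spec$k)
      for (idx in strata) {
        perm <- sample(idx, length(idx))
        f <- rep_len(seq_len(spec$k), length(perm))
        for (j in seq_len(spec$k)) {
          folds[[j]] <- c(folds[[j]], perm[f == j])
        }
      }
      lapply(folds, sort)
    }
  })
}
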