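#' Population-based training configuration
#'
#' A desk-scale, single-machine, sequential simulation of the
#' population-based hyperparameter search used with sequential
#' autoencoders: the population trains in generations; after each
#' generation the bottom fraction of members copies parameters and
#' hyperparameters from randomly chosen top members (exploit) and
#' perturbs the searched hyperparameters (explore).
#'
#' @param population population size (>= 2).
#' @param generations number of exploit/explore rounds.
#' @param steps_per_generation training epochs per member per generation.
#' @param truncation fraction defining the top/bottom sets (default 0.25).
#' @param explore `"perturb"` (multiply by a random factor) or
#'   `"resample"` (draw uniformly from the range).
#' @param perturb_factors multiplicative perturbation factors.
#' @param searched named list of hyperparameter ranges `c(lo, hi)`;
#'   supported names: `theta`, `lr`, `alpha`. With `objective = "eq7"`
#'   theta is fixed to 1e-4 and must not be searched.
#' @param objective `"eq6"` or `"eq7"` (see [pbt_objective()]).
#' @param seed RNG seed.
#' @return object of class `pbt_config`.
#' @export
pbt_config <- function(population = 4L, generations = 4L,
                       steps_per_generation = 5L, truncation = 0.25,
                       explore = c("perturb", "resample"),
                       perturb_factors = c(0.8, 1.25),
                       searched = list(theta = c(0.1, 10)),
                       objective = c("eq6", "eq7"), seed = 1L) {
  explore <- match.arg(explore)
  objective <- match.arg(objective)
  assert_that(population >= 2, "population must be >= 2")
  assert_that(all(names(searched) %in% c("theta", "lr", "alpha")),
              "searched hyperparameters must be among theta, lr, alpha")
  for (r in searched) assert_that(length(r) == 2 && r[1] <= r[2],
                                  "searched ranges must be ordered c(lo, hi)")
  if (objective == "eq7") {
    assert_that(!"theta" %in% names(searched),
                "objective eq7 fixes theta = 1e-4; do not search it")
  }
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 steps_per_generation = as.integer(steps_per_generation),
                 truncation = truncation, explore = explore,
                 perturb_factors = perturb_factors, searched = searched,
                 objective = objective, seed = as.integer(seed)),
            class = "pbt_config")
}

apply_hypers <- function(config, tc, hypers) {
  if (!is.null(hypers$theta)) config$theta <- hypers$theta
  if (!is.null(hypers$alpha)) config$alpha <- hypers$alpha
  if (!is.null(hypers$lr)) tc$lr <- hypers$lr
  list(config = config, tc = tc)
}

#' Run population-based training
#'
#' @param config a [model_config()] shared by all members (searched
#'   hyperparameters override its fields per member; with
#'   `objective = "eq7"` theta is fixed to 1e-4).
#' @param dataset a `trial_dataset`.
#' @param split list with `train` and `val` indices; the configured
#'   objective is evaluated on `val` for selection.
#' @param pc a [pbt_config()].
#' @param tc a [train_config()] providing base optimization settings.
#' @return object of class `band_pbt`: `best` (a `band_fit`),
#'   `best_member`, `lineage` (one row per member per generation:
#'   objective, action, copied_from, hyperparameters), `members`.
#' @export
run_pbt <- function(config, dataset, split, pc = pbt_config(),
                    tc = train_config()) {
  stopifnot(inherits(pc, "pbt_config"))
  if (pc$objective == "eq7") config$theta <- 1e-4
  tc$objective <- pc$objective
  P <- pc$population
  members <- with_seed(pc$seed, {
    lapply(seq_len(P), function(i) {
      hy <- lapply(pc$searched, function(r) stats::runif(1, r[1], r[2]))
      list(id = i, hypers = hy, model = NULL, objective = -Inf)
    })
  })
  lineage <- list()
  for (gen in seq_len(pc$generations)) {
    for (i in seq_len(P)) {
      mem <- members[[i]]
      ah <- apply_hypers(config, tc, mem$hypers)
      tcg <- ah$tc
      tcg$epochs <- pc$steps_per_generation
      tcg$seed <- pc$seed + 1000L * gen + i
      tcg$kl_warmup_epochs <- if (gen == 1) tc$kl_warmup_epochs else 1L
      start <- mem$model %||% ah$config
      fit <- train_model(start, dataset, split, tcg)
      mem$model <- fit$final_model
      mem$model$config <- ah$config
      mem$objective <- eval_objective(mem$model, dataset, split$val,
                                      pc$objective)$objective
      members[[i]] <- mem
      lineage[[length(lineage) + 1L]] <- data.frame(
        generation = gen, member = i, objective = mem$objective,
        action = "train", copied_from = NA_integer_,
        theta = mem$hypers$theta %||% config$theta,
        lr = mem$hypers$lr %||% tc$lr,
        alpha = mem$hypers$alpha %||% config$alpha)
    }
    if (gen == pc$generations) break
    objs <- vapply(members, function(m) m$objective, 0)
    n_cut <- max(1L, ceiling(pc$truncation * P))
    ord <- order(objs, decreasing = TRUE)
    top <- ord[seq_len(n_cut)]
    bottom <- rev(ord)[seq_len(n_cut)]
    with_seed(pc$seed + 37L * gen, {
      for (b in bottom) {
        if (b %in% top) next
        src <- if (length(top) == 1L) top else sample(top, 1L)
        members[[b]]$model <- members[[src]]$model
        members[[b]]$hypers <- members[[src]]$hypers
        members[[b]]$objective <- members[[src]]$objective
        for (h in names(members[[b]]$hypers)) {
          r <- pc$searched[[h]]
          members[[b]]$hypers[[h]] <- if (pc$explore == "perturb") {
            min(max(members[[b]]$hypers[[h]] *
                      sample(pc$perturb_factors, 1L), r[1]), r[2])
          } else stats::runif(1, r[1], r[2])
        }
        lineage[[length(lineage) + 1L]] <- data.frame(
          generation = gen, member = b, objective = members[[b]]$objective,
          action = "exploit", copied_from = src,
          theta = members[[b]]$hypers$theta %||% config$theta,
          lr = members[[b]]$hypers$lr %||% tc$lr,
          alpha = members[[b]]$hypers$alpha %||% config$alpha)
      }
    })
  }
  objs <- vapply(members, function(m) m$objective, 0)
  if (all(!is.finite(objs))) stopf("all population members diverged")
  best_i <- which.max(objs)
  best_fit <- structure(list(model = members[[best_i]]$model,
                             final_model = members[[best_i]]$model,
                             history = NULL, best_epoch = NA_integer_,
                             split = split, train_config = tc,
                             config = members[[best_i]]$model$config),
                        class = "band_fit")
  structure(list(best = best_fit, best_member = best_i,
                 lineage = do.call(rbind, lineage), members = members),
            class = "band_pbt")
}

#' @export
print.band_pbt <- function(x, ...) {
  li <- x$lineage[x$lineage$action == "train", ]
  gmax <- tapply(li$objective, li$generation, max)
  cat(sprintf("band_pbt: best member %d; per-generation max objective: %s\n",
              x$best_member, paste(sprintf("%.4f", gmax), collapse = " ")))
  invisible(x)
}
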