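# The hybrid metaheuristic driver: per generation the BUMDA population is
# evaluated, its best AND worst members are refined by simulated annealing,
# the global best is updated on strict improvement, and -- the diversity
# control -- the population is sorted worst-first whenever the refined worst
# member outranks the refined best, so some generations are modeled on
# low-fitness individuals and the marginal model keeps exploring.  Baseline
# optimizers (GA, plain SA, plain BUMDA, hybrid without diversity) share the
# logging contract for side-by-side benchmarks.

#' Run the diversity-controlled hybrid selector
#'
#' @param ds a [labeled_dataset()].
#' @param part a [split_dataset()] partition.
#' @param cfg a [run_config()]; `cfg$seed` governs all randomness.
#' @param diversity enable the worst-first sorting rule (default `TRUE`);
#'   `FALSE` gives the plain BUMDA + SA hybrid.
#' @param fitness_fn optional fitness override, a function of a bit vector
#'   returning a value in `[0, 1]`; defaults to the memoized
#'   [wrapper_fitness()] on the validation split.
#' @return A `run_result`: `gbest` (list with `bits`, `fitness`), `logs`
#'   (one row per generation: best/worst/gbest fitness, `sort_inverted`),
#'   `counts` (generations x features matrix of per-feature selection
#'   counts), `selection_frequency`, `best_generation`, and bookkeeping
#'   fields.  The gbest trace is non-decreasing.
#' @export
run_hybrid <- function(ds, part, cfg, diversity = TRUE, fitness_fn = NULL) {
  .run_engine(ds, part, cfg, refine = TRUE, diversity = diversity,
              fitness_fn = fitness_fn,
              method = if (diversity) "proposed" else "hybrid")
}

#' Run a baseline optimizer
#'
#' @inheritParams run_hybrid
#' @param method `"ga"` (elitist generational genetic algorithm:
#'   parents drawn from the best `selection_rate` fraction, one-point
#'   crossover, per-bit mutation at rate `1/n`), `"sa"` (single-solution
#'   annealing over the full schedule, one log row per iteration),
#'   `"bumda"` (the generation loop without SA refinement or diversity), or
#'   `"hybrid_no_diversity"` (alias `"hybrid"`).
#' @return A `run_result` with the same logging contract as [run_hybrid()].
#' @export
run_baseline <- function(method, ds, part, cfg, fitness_fn = NULL) {
  switch(method,
    ga = .run_ga(ds, part, cfg, fitness_fn),
    sa = .run_sa(ds, part, cfg, fitness_fn),
    bumda = .run_engine(ds, part, cfg, refine = FALSE, diversity = FALSE,
                        fitness_fn = fitness_fn, method = "bumda"),
    hybrid_no_diversity = ,
    hybrid = .run_engine(ds, part, cfg, refine = TRUE, diversity = FALSE,
                         fitness_fn = fitness_fn, method = "hybrid"),
    proposed = run_hybrid(ds, part, cfg, diversity = TRUE,
                          fitness_fn = fitness_fn),
    stop_ssfs("unknown method '%s'", method, class = "driver_error")
  )
}

.default_fitness <- function(ds, part, cfg, fitness_fn) {
  fitness_fn %||% wrapper_fitness(ds, part, cfg)
}

.new_result <- function(method, gbest, best_generation, logs, counts,
                        cfg, n_features) {
  freq <- colSums(counts) / (nrow(counts) * cfg$pop_size)
  structure(list(
    method = method, gbest = gbest, best_generation = best_generation,
    logs = logs, counts = counts, selection_frequency = freq,
    n_generations = nrow(logs), pop_size = cfg$pop_size,
    n_features = n_features, seed = cfg$seed
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "<run_result %s: gbest %.4f (%d features) at generation %d of %d>\n",
    x$method, x$gbest$fitness, sum(x$gbest$bits), x$best_generation,
    x$n_generations))
  invisible(x)
}

.run_engine <- function(ds, part, cfg, refine, diversity, fitness_fn,
                        method) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  fit_fn <- .default_fitness(ds, part, cfg, fitness_fn)
  n <- if (inherits(ds, "labeled_dataset")) ncol(ds$features) else
    attr(fitness_fn, "n_features")
  npop <- cfg$pop_size
  G <- cfg$n_generations
  # per-generation refinement runs the tail of the configured schedule:
  # same constant step, last sa_refine_iters iterations (the cold phase,
  # where annealing actually climbs)
  refine_sched <- anneal_schedule(
    cfg$sa_t_end + cfg$sa_step * cfg$sa_refine_iters,
    cfg$sa_t_end, cfg$sa_step)

  bits <- init_population(npop, n)
  gbest <- NULL
  best_generation <- NA_integer_
  theta <- -Inf
  logs <- data.frame(generation = seq_len(G), best_fitness = NA_real_,
                     worst_fitness = NA_real_, gbest_fitness = NA_real_,
                     sort_inverted = FALSE)
  counts <- matrix(0L, nrow = G, ncol = n)

  for (t in seq_len(G)) {
    fitness <- vapply(seq_len(npop), function(i) fit_fn(bits[i, ]),
                      numeric(1))
    counts[t, ] <- colSums(bits)
    inverted <- FALSE
    if (refine) {
      bi <- which.max(fitness)
      wi <- which.min(fitness)
      rb <- anneal(bits[bi, ], fit_fn, refine_sched, f_start = fitness[bi])
      rw <- if (wi != bi) {
        anneal(bits[wi, ], fit_fn, refine_sched, f_start = fitness[wi])
      } else rb
      # the population receives the annealed endpoints (refined members
      # replace their originals before sorting); the best-so-far of each
      # refinement feeds the global best, so discoveries are never lost
      bits[bi, ] <- rb$final_bits; fitness[bi] <- rb$final_fitness
      if (wi != bi) {
        bits[wi, ] <- rw$final_bits; fitness[wi] <- rw$final_fitness
      }
      for (cand in list(rb, rw)) {
        if (is.null(gbest) || cand$fitness > gbest$fitness) {
          gbest <- list(bits = cand$bits, fitness = cand$fitness)
          best_generation <- t
        }
      }
      # diversity rule: the refined worst "is the best SA-refined
      # individual" when its annealed endpoint reaches at least the
      # refined best's -- those generations are sorted worst-first
      inverted <- diversity && (rw$final_fitness >= rb$final_fitness)
    } else {
      bi <- which.max(fitness)
      if (is.null(gbest) || fitness[bi] > gbest$fitness) {
        gbest <- list(bits = bits[bi, ], fitness = fitness[bi])
        best_generation <- t
      }
    }
    ord <- if (inverted) order(fitness) else order(-fitness) # stable
    bits <- bits[ord, , drop = FALSE]
    fitness <- fitness[ord]
    logs$best_fitness[t] <- max(fitness)
    logs$worst_fitness[t] <- min(fitness)
    logs$gbest_fitness[t] <- gbest$fitness
    logs$sort_inverted[t] <- inverted
    theta <- update_theta(sort(fitness, decreasing = TRUE), theta, t)
    if (t < G) {
      sel <- select_for_model(bits, fitness, theta, cfg$selection_rate)
      model <- weighted_moments(sel$bits, sel$fitnesses, cfg$boltzmann_beta)
      bits <- sample_population(model, npop)
    }
  }
  .new_result(method, gbest, best_generation, logs, counts, cfg, n)
}

.run_ga <- function(ds, part, cfg, fitness_fn = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  fit_fn <- .default_fitness(ds, part, cfg, fitness_fn)
  n <- if (inherits(ds, "labeled_dataset")) ncol(ds$features) else
    attr(fitness_fn, "n_features")
  npop <- cfg$pop_size
  G <- cfg$n_generations
  pmut <- cfg$ga_mutation_rate %||% (1 / n)

  bits <- init_population(npop, n)
  gbest <- NULL
  best_generation <- NA_integer_
  logs <- data.frame(generation = seq_len(G), best_fitness = NA_real_,
                     worst_fitness = NA_real_, gbest_fitness = NA_real_,
                     sort_inverted = FALSE)
  counts <- matrix(0L, nrow = G, ncol = n)

  for (t in seq_len(G)) {
    fitness <- vapply(seq_len(npop), function(i) fit_fn(bits[i, ]),
                      numeric(1))
    counts[t, ] <- colSums(bits)
    bi <- which.max(fitness)
    if (is.null(gbest) || fitness[bi] > gbest$fitness) {
      gbest <- list(bits = bits[bi, ], fitness = fitness[bi])
      best_generation <- t
    }
    logs$best_fitness[t] <- fitness[bi]
    logs$worst_fitness[t] <- min(fitness)
    logs$gbest_fitness[t] <- gbest$fitness
    if (t < G) {
      pool <- order(-fitness)[seq_len(max(2L, ceiling(cfg$selection_rate *
                                                        npop)))]
      children <- matrix(0L, nrow = npop, ncol = n)
      children[1, ] <- bits[bi, ] # elitism
      for (k in 2:npop) {
        pr <- sample(pool, 2L, replace = length(pool) < 2L)
        cut <- if (n > 1L) sample.int(n - 1L, 1L) else 1L
        child <- c(bits[pr[1], seq_len(cut)],
                   bits[pr[2], setdiff(seq_len(n), seq_len(cut))])
        if (pmut > 0) {
          flip <- stats::runif(n) < pmut
          child <- as.integer(xor(child == 1L, flip))
        }
        children[k, ] <- child
      }
      bits <- repair_bits(children)
    }
  }
  .new_result("ga", gbest, best_generation, logs, counts, cfg, n)
}

.run_sa <- function(ds, part, cfg, fitness_fn = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  fit_fn <- .default_fitness(ds, part, cfg, fitness_fn)
  n <- if (inherits(ds, "labeled_dataset")) ncol(ds$features) else
    attr(fitness_fn, "n_features")
  sched <- anneal_schedule(cfg$sa_t0, cfg$sa_t_end, cfg$sa_step)
  G <- sched$n_iterations

  cur <- init_population(1L, n)[1, ]
  f_cur <- fit_fn(cur)
  gbest <- list(bits = cur, fitness = f_cur)
  best_generation <- 1L
  logs <- data.frame(generation = seq_len(G), best_fitness = NA_real_,
                     worst_fitness = NA_real_, gbest_fitness = NA_real_,
                     sort_inverted = FALSE)
  counts <- matrix(0L, nrow = G, ncol = n)
  temp <- sched$t0
  for (t in seq_len(G)) {
    cand <- neighbor(cur)
    f_cand <- fit_fn(cand)
    if (stats::runif(1) <= accept_probability(f_cand, f_cur, temp)) {
      cur <- cand; f_cur <- f_cand
    }
    if (f_cand > gbest$fitness) {
      gbest <- list(bits = cand, fitness = f_cand)
      best_generation <- t
    }
    counts[t, ] <- cur
    logs$best_fitness[t] <- f_cur
    logs$worst_fitness[t] <- f_cur
    logs$gbest_fitness[t] <- gbest$fitness
    temp <- max(sched$t_end, temp - sched$step)
  }
  cfg1 <- cfg; cfg1$pop_size <- 1L
  .new_result("sa", gbest, best_generation, logs, counts, cfg1, n)
}

#' Per-feature selection frequencies of a run
#'
#' `frequency_i` is the share of individual-slots across all logged
#' generations in which feature `i` was selected:
#' `sum_t counts[t, i] / (n_generations * pop_size)`.
#'
#' @param x a `run_result`, or a generations-x-features count matrix.
#' @param pop_size population size (required when `x` is a matrix).
#' @return A numeric vector in `[0, 1]`, one entry per feature.
#' @export
selection_frequencies <- function(x, pop_size = NULL) {
  if (inherits(x, "run_result")) return(x$selection_frequency)
  counts <- as.matrix(x)
  if (nrow(counts) < 1L) {
    stop_ssfs("no generation logs", class = "driver_error")
  }
  if (is.null(pop_size)) {
    stop_ssfs("pop_size is required for a raw count matrix",
              class = "driver_error")
  }
  colSums(counts) / (nrow(counts) * pop_size)
}

#' Order/moment statistics of selection frequencies
#'
#' @param freqs numeric vector of per-feature selection frequencies.
#' @return Named vector `min, max, median, mean, variance, std`
#'   (`variance == std^2`).
#' @export
frequency_stats <- function(freqs) {
  if (!length(freqs)) {
    stop_ssfs("empty frequency vector", class = "driver_error")
  }
  stats_six(freqs)
}

#' Statistics of the best-result generation across independent trials
#'
#' @param results list of `run_result` objects (>= 2).
#' @return Named vector `min, max, median, mean, variance, std` of
#'   `best_generation` across trials.
#' @export
best_generation_stats <- function(results) {
  if (length(results) < 2L) {
    stop_ssfs("need at least 2 trials", class = "driver_error")
  }
  stats_six(vapply(results, function(r) as.numeric(r$best_generation),
                   numeric(1)))
}

#' Final evaluation of a selected subset on the test split
#'
#' Applies the fine-tuned kernel from `cfg$kernel` to the gbest mask and
#' reports the full benchmark-table row.
#'
#' @param result a `run_result`.
#' @param ds,part dataset and partition used for the run.
#' @param cfg a [run_config()] (its `kernel` is used).
#' @return A list with `confusion`, `metrics` ([classification_metrics()])
#'   and `row` ([metric_row()]).
#' @export
finalize_result <- function(result, ds, part, cfg) {
  ev <- evaluate_subset(ds, part, result$gbest$bits, cfg$kernel, "test")
  met <- classification_metrics(ev$confusion)
  list(confusion = ev$confusion, metrics = met,
       row = metric_row(met, sum(result$gbest$bits), result$n_features,
                        result$method))
}
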