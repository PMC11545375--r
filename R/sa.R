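# Simulated annealing over feature-subset bit vectors.  The temperature
# falls linearly from t0 to t_end in constant steps; a worsening move of
# size dE < 0 is accepted with the Metropolis/Boltzmann probability
# exp(dE / T) (improvements are always accepted), and the best-so-far
# solution is returned.

#' Annealing temperature schedule
#'
#' @param t0 initial temperature (> `t_end`).
#' @param t_end final temperature (>= 0).
#' @param step constant temperature decrement (> 0); the schedule runs
#'   `ceiling((t0 - t_end) / step)` iterations.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = 1, t_end = 0, step = 0.001) {
  if (!(t0 > t_end && t_end >= 0) || step <= 0) {
    stop_ssfs("require t0 > t_end >= 0 and step > 0", class = "sa_error")
  }
  structure(list(t0 = t0, t_end = t_end, step = step,
                 n_iterations = as.integer(ceiling((t0 - t_end) / step))),
            class = "anneal_schedule")
}

#' Shortened schedule with a given iteration count
#'
#' Keeps the endpoint temperatures of `schedule` but re-derives the step so
#' the schedule runs exactly `n_iterations` iterations (used for the
#' per-generation refinement inside the hybrid loop).
#'
#' @param schedule an [anneal_schedule()].
#' @param n_iterations desired iteration count.
#' @return An [anneal_schedule()].
#' @export
shorten_schedule <- function(schedule, n_iterations) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  anneal_schedule(schedule$t0, schedule$t_end,
                  (schedule$t0 - schedule$t_end) / n_iterations)
}

#' Neighborhood move on a bit vector
#'
#' Each bit is flipped independently with probability `1/n`, with at least
#' one flip forced; the result is repaired to keep at least one set bit.
#' Expected Hamming distance to the input is about 1 for large `n`.  Uses
#' the ambient RNG stream.
#'
#' @param bits 0/1 vector.
#' @return A 0/1 vector of the same length.
#' @export
neighbor <- function(bits) {
  n <- length(bits)
  flip <- stats::runif(n) < 1 / n
  if (!any(flip)) flip[sample.int(n, 1L)] <- TRUE
  out <- as.integer(xor(bits == 1L, flip))
  if (!any(out == 1L)) out[sample.int(n, 1L)] <- 1L
  out
}

#' Metropolis acceptance probability
#'
#' @param f_new fitness of the candidate solution.
#' @param f_old fitness of the current solution.
#' @param temperature current temperature `T >= 0`.
#' @return 1 for any improvement; `exp((f_new - f_old) / T)` for a worsening
#'   move at `T > 0`; 0 at `T = 0`.
#' @export
accept_probability <- function(f_new, f_old, temperature) {
  if (temperature < 0) {
    stop_ssfs("temperature must be >= 0", class = "sa_error")
  }
  if (f_new >= f_old) return(1)
  if (temperature == 0) return(0)
  exp((f_new - f_old) / temperature)
}

#' Anneal a feature subset
#'
#' Runs the full schedule, proposing one [neighbor()] per iteration and
#' accepting it with [accept_probability()]; exactly one fitness evaluation
#' is spent per iteration.  Returns the best-so-far solution, whose fitness
#' is never below the start's.
#'
#' @param bits 0/1 start vector (its fitness is computed if `f_start` is
#'   not supplied).
#' @param fitness_fn function mapping a bit vector to a fitness in `[0, 1]`.
#' @param schedule an [anneal_schedule()].
#' @param f_start optional known fitness of `bits` (saves one evaluation).
#' @param trace if `TRUE`, attach a per-iteration data frame (temperature,
#'   current and best fitness) as attribute `"trace"`.
#' @return A list with `bits` and `fitness` of the best solution found,
#'   `n_evals`, and the last accepted state as `final_bits` /
#'   `final_fitness` (the annealed endpoint, which unlike the best-so-far
#'   may be worse than the start).
#' @export
anneal <- function(bits, fitness_fn, schedule = anneal_schedule(),
                   f_start = NULL, trace = FALSE) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  cur <- as.integer(bits)
  f_cur <- f_start %||% fitness_fn(cur)
  best <- cur
  f_best <- f_cur
  iters <- schedule$n_iterations
  tr <- if (trace) {
    data.frame(iteration = seq_len(iters), temperature = NA_real_,
               fitness = NA_real_, best_fitness = NA_real_)
  }
  temp <- schedule$t0
  n_evals <- 0L
  for (it in seq_len(iters)) {
    cand <- neighbor(cur)
    f_cand <- fitness_fn(cand)
    n_evals <- n_evals + 1L
    if (stats::runif(1) <= accept_probability(f_cand, f_cur, temp)) {
      cur <- cand
      f_cur <- f_cand
    }
    if (f_cand > f_best) {
      best <- cand
      f_best <- f_cand
    }
    if (trace) tr[it, 2:4] <- c(temp, f_cur, f_best)
    temp <- max(schedule$t_end, temp - schedule$step)
  }
  out <- list(bits = best, fitness = f_best, n_evals = n_evals,
              final_bits = cur, final_fitness = f_cur)
  if (trace) attr(out, "trace") <- tr
  out
}
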