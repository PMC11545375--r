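# Boltzmann Univariate Marginal Distribution Algorithm over bit vectors.
#
# Each generation, individuals are weighted by fitness,
#   W(X_j)  = g(X_j) / sum_j g(X_j),
# the per-feature marginal mean and variance follow as
#   mu_i = sum_j W(X_j) x_ij,
#   nu_i = sum_j W'(X_j) (x_ij - mu_i)^2,  W'(X_j) = g(X_j) / (sum g + 1),
# a truncation threshold theta is raised according to
#   theta_1     = f(x_npop)                       (worst member, first gen)
#   theta_{t+1} = f(x_{npop/2})                   if it is >= theta_t, else
#                 the smallest lower-half fitness >= theta_t (theta_t kept
#                 when none qualifies),
# and the next population is sampled bit-wise from Bernoulli(mu_i), with
# mu clamped to [p_min, 1 - p_min] (p_min = 1/n) so no feature can fixate.

#' Boltzmann selection weights
#'
#' @param fitnesses non-negative fitness vector with at least one positive
#'   entry; an all-zero vector falls back to uniform weights with a warning.
#' @param beta optional exponent: weights proportional to
#'   `exp(beta * fitness)` when `beta > 0`, raw fitness otherwise (default).
#' @return Weights summing to 1, proportional to `g`.
#' @export
boltzmann_weights <- function(fitnesses, beta = 0) {
  if (any(fitnesses < 0)) {
    stop_ssfs("fitness values must be non-negative", class = "bumda_error")
  }
  g <- if (beta > 0) exp(beta * fitnesses) else fitnesses
  total <- sum(g)
  if (total <= 0) {
    warning("all-zero fitnesses: falling back to uniform weights")
    return(rep(1 / length(g), length(g)))
  }
  g / total
}

#' Fitness-weighted marginal moments of a bit population
#'
#' @param bits 0/1 matrix, one row per individual.
#' @param fitnesses evaluated fitness per row (no unset entries).
#' @param beta see [boltzmann_weights()].
#' @return A `marginal_model`: `mu` (per-feature selection probability),
#'   `nu` (weighted variance with the `sum(g) + 1` denominator, so the
#'   variance weights sum to `G / (G + 1)`), and `p_min = 1/n_features`.
#' @export
weighted_moments <- function(bits, fitnesses, beta = 0) {
  bits <- as.matrix(bits)
  if (anyNA(fitnesses) || length(fitnesses) != nrow(bits)) {
    stop_ssfs("every individual must carry an evaluated fitness",
              class = "bumda_error")
  }
  w <- boltzmann_weights(fitnesses, beta)
  mu <- as.numeric(crossprod(w, bits))
  g <- if (beta > 0) exp(beta * fitnesses) else fitnesses
  wv <- g / (sum(g) + 1)
  dev2 <- sweep(bits, 2L, mu)^2
  nu <- as.numeric(crossprod(wv, dev2))
  structure(list(mu = mu, nu = nu, p_min = 1 / ncol(bits)),
            class = "marginal_model")
}

#' Update the truncation threshold
#'
#' @param sorted_fitnesses fitness vector sorted in decreasing order.
#' @param theta_prev threshold of the previous generation (ignored at
#'   `t = 1`).
#' @param t generation index (>= 1).
#' @return The new threshold; never smaller than `theta_prev` for `t > 1`.
#' @export
update_theta <- function(sorted_fitnesses, theta_prev = -Inf, t = 1L) {
  if (is.unsorted(rev(sorted_fitnesses))) {
    stop_ssfs("fitnesses must be sorted in decreasing order",
              class = "bumda_error")
  }
  npop <- length(sorted_fitnesses)
  if (t == 1L) return(sorted_fitnesses[npop])
  half <- ceiling(npop / 2)
  if (sorted_fitnesses[half] >= theta_prev) return(sorted_fitnesses[half])
  if (half < npop) {
    lower <- sorted_fitnesses[(half + 1L):npop]
    ok <- lower[lower >= theta_prev]
    if (length(ok)) return(min(ok))
  }
  theta_prev
}

#' Truncation selection for the marginal model
#'
#' The candidate pool is the first `ceiling(selection_rate * npop)` members
#' in current population order -- the order the diversity controller may
#' have inverted, which is how worst-first sorting steers the marginal
#' model toward low-fitness members.  Within the pool, only members whose
#' fitness reaches the `theta` floor are kept.  Never empty: falls back to
#' the single first member.
#'
#' @param bits 0/1 matrix, one row per individual, in population order.
#' @param fitnesses fitness per row.
#' @param theta truncation threshold.
#' @param selection_rate fraction in (0, 1].
#' @return A list with the retained `bits` and `fitnesses`.
#' @export
select_for_model <- function(bits, fitnesses, theta, selection_rate) {
  bits <- as.matrix(bits)
  if (nrow(bits) < 2L) {
    stop_ssfs("population must have at least 2 members", class = "bumda_error")
  }
  cap <- ceiling(selection_rate * nrow(bits))
  keep <- seq_len(cap)[fitnesses[seq_len(cap)] >= theta]
  if (length(keep) == 0L) keep <- 1L
  list(bits = bits[keep, , drop = FALSE], fitnesses = fitnesses[keep])
}

# Set one uniformly random bit in any all-zero row (individuals must select
# at least one feature); rows are otherwise untouched.
repair_bits <- function(bits) {
  empty <- which(rowSums(bits) == 0L)
  for (i in empty) bits[i, sample.int(ncol(bits), 1L)] <- 1L
  bits
}

#' Sample a new population from a marginal model
#'
#' Bit `i` is drawn independently as Bernoulli(`mu_i`) with `mu` clamped to
#' `[p_min, 1 - p_min]`; every sampled individual is repaired to carry at
#' least one set bit.  Uses the ambient RNG stream (seed it for
#' reproducibility).
#'
#' @param model a `marginal_model` from [weighted_moments()].
#' @param npop number of individuals to draw.
#' @return A 0/1 matrix of dimension `npop x n_features`.
#' @export
sample_population <- function(model, npop) {
  stopifnot(inherits(model, "marginal_model"))
  p <- pmin(pmax(model$mu, model$p_min), 1 - model$p_min)
  n <- length(p)
  bits <- matrix(
    (stats::runif(npop * n) < rep(p, each = npop)) + 0L,
    nrow = npop, ncol = n
  )
  repair_bits(bits)
}

#' Random initial population
#'
#' @param npop population size.
#' @param n_features bit-vector length.
#' @param p probability that a bit starts set (default 0.5).
#' @return A repaired 0/1 matrix.
#' @export
init_population <- function(npop, n_features, p = 0.5) {
  repair_bits(matrix((stats::runif(npop * n_features) < p) + 0L,
                     nrow = npop, ncol = n_features))
}
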