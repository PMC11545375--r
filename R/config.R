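# Run configuration.  Defaults mirror the reference experiment: 1000
# generations, population 100, selection rate 0.80, SA temperature 1 -> 0 in
# steps of 0.001, fitness weights 0.90 (accuracy) / 0.10 (feature reduction),
# and a fine-tuned polynomial SVM (order 5, scale 2, offset 0.3569) applied
# only after selection finishes; a linear kernel is used inside the loop.

#' Kernel specification for the SVM classifier
#'
#' The polynomial kernel is `(<x, x'> / kernel_scale + kernel_offset) ^
#' poly_order`.
#'
#' @param kind `"linear"` or `"polynomial"`.
#' @param poly_order polynomial order (>= 1).
#' @param kernel_scale positive scale divisor of the inner product.
#' @param kernel_offset additive offset.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial"), poly_order = 5,
                        kernel_scale = 2, kernel_offset = 0.3569) {
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    if (poly_order < 1 || kernel_scale <= 0) {
      stop_ssfs("polynomial kernel requires poly_order >= 1, kernel_scale > 0",
                class = "config_error")
    }
  }
  structure(list(kind = kind, poly_order = as.integer(poly_order),
                 kernel_scale = kernel_scale, kernel_offset = kernel_offset),
            class = "kernel_spec")
}

#' Fitness weights for the scalarized two-objective fitness
#'
#' @param w_accuracy weight on classification accuracy (default 0.90).
#' @param w_fdr weight on the feature decreasing rate (default 0.10).
#' @return An object of class `fitness_weights`.
#' @export
fitness_weights <- function(w_accuracy = 0.90, w_fdr = 0.10) {
  if (w_accuracy < 0 || w_fdr < 0 || abs(w_accuracy + w_fdr - 1) > 1e-12) {
    stop_ssfs("fitness weights must be non-negative and sum to 1",
              class = "config_error")
  }
  structure(list(w_accuracy = w_accuracy, w_fdr = w_fdr),
            class = "fitness_weights")
}

#' Run configuration for the selection metaheuristics
#'
#' @param n_generations number of generations (default 1000).
#' @param pop_size population size (default 100, >= 2).
#' @param selection_rate fraction of the population eligible for the marginal
#'   model, in (0, 1] (default 0.80).
#' @param sa_t0,sa_t_end,sa_step simulated-annealing temperature schedule:
#'   start, end and constant decrement (defaults 1, 0, 0.001, i.e. about 1000
#'   iterations).
#' @param sa_refine_iters length of the shortened SA schedule used when
#'   refining the best/worst member inside each generation of the hybrid
#'   loop (default 25; set to `(sa_t0 - sa_t_end) / sa_step` for the full
#'   schedule).
#' @param w_accuracy,w_fdr fitness weights (defaults 0.90 / 0.10).
#' @param seed integer master seed for the whole run.
#' @param kernel [kernel_spec()] of the final, fine-tuned classifier.
#' @param boltzmann_beta if positive, the marginal model weights individuals
#'   by `exp(beta * fitness)` instead of the raw fitness (default 0 = raw).
#' @param ga_mutation_rate per-bit mutation rate of the GA baseline;
#'   `NULL` (default) means `1 / n_features`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_generations = 1000L, pop_size = 100L,
                       selection_rate = 0.80, sa_t0 = 1, sa_t_end = 0,
                       sa_step = 0.001, sa_refine_iters = 25L,
                       w_accuracy = 0.90, w_fdr = 0.10, seed = 1L,
                       kernel = kernel_spec("polynomial"),
                       boltzmann_beta = 0, ga_mutation_rate = NULL) {
  if (pop_size < 2L) {
    stop_ssfs("pop_size must be >= 2", class = "config_error")
  }
  if (selection_rate <= 0 || selection_rate > 1) {
    stop_ssfs("selection_rate must lie in (0, 1]", class = "config_error")
  }
  if (!(sa_t0 > sa_t_end && sa_t_end >= 0) || sa_step <= 0) {
    stop_ssfs("require sa_t0 > sa_t_end >= 0 and sa_step > 0",
              class = "config_error")
  }
  weights <- fitness_weights(w_accuracy, w_fdr)
  stopifnot(inherits(kernel, "kernel_spec"))
  structure(list(
    n_generations = as.integer(n_generations),
    pop_size = as.integer(pop_size),
    selection_rate = selection_rate,
    sa_t0 = sa_t0, sa_t_end = sa_t_end, sa_step = sa_step,
    sa_refine_iters = as.integer(sa_refine_iters),
    weights = weights, seed = as.integer(seed), kernel = kernel,
    boltzmann_beta = boltzmann_beta, ga_mutation_rate = ga_mutation_rate
  ), class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file whose keys match the
#'   arguments of [run_config()] (kernel given as a nested map).
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  kern <- vals$kernel
  vals$kernel <- if (is.null(kern)) kernel_spec("polynomial") else {
    kernel_spec(kern$kind %||% "polynomial",
                kern$poly_order %||% 5,
                kern$kernel_scale %||% 2,
                kern$kernel_offset %||% 0.3569)
  }
  known <- names(formals(run_config))
  do.call(run_config, vals[intersect(names(vals), known)])
}

#' Save a run configuration as JSON
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(
    n_generations = cfg$n_generations, pop_size = cfg$pop_size,
    selection_rate = cfg$selection_rate, sa_t0 = cfg$sa_t0,
    sa_t_end = cfg$sa_t_end, sa_step = cfg$sa_step,
    sa_refine_iters = cfg$sa_refine_iters,
    w_accuracy = cfg$weights$w_accuracy, w_fdr = cfg$weights$w_fdr,
    seed = cfg$seed, boltzmann_beta = cfg$boltzmann_beta,
    kernel = unclass(cfg$kernel)
  )
  if (!is.null(cfg$ga_mutation_rate)) {
    out$ga_mutation_rate <- cfg$ga_mutation_rate
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
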