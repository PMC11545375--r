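#' @keywords internal
"_PACKAGE"

# Package-level cache for precomputed kernel FFT banks.
.ssfs_cache <- new.env(parent = emptyenv())

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers (dataset splits,
#' generators) do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream seed from a master seed and a label
#'
#' A single run seed governs every source of randomness; module-level
#' generators draw from streams derived deterministically from it, so that a
#' run is reproducible end to end while sub-steps stay independent.
#'
#' @param seed integer master seed.
#' @param label character stream label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Six order/moment statistics used by the frequency and generation tables.
stats_six <- function(x) {
  v <- stats::var(x)
  if (length(x) == 1L) v <- 0
  c(
    min = min(x), max = max(x), median = stats::median(x), mean = mean(x),
    variance = v, std = sqrt(v)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ssfs <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "stenoselect_error")))
}
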