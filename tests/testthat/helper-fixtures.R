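# Shared fixtures, all generated in code.

# A small planted-signal dataset plus a 60/20/20-style partition.
tiny_problem <- function(n_samples = 100L, n_features = 12L,
                         n_informative = 3L, effect_size = 2, seed = 1L) {
  gen <- make_feature_dataset(synthetic_spec(
    n_samples = n_samples, n_features = n_features,
    n_informative = n_informative, effect_size = effect_size, seed = seed))
  n_val <- round(n_samples * 0.2)
  n_test <- round(n_samples * 0.2)
  part <- split_dataset(gen$dataset,
                        c(n_samples - n_val - n_test, n_val, n_test),
                        seed = derive_seed(seed, "part"))
  list(ds = gen$dataset, part = part, truth = gen$truth_mask)
}

# Cheap deterministic fitness: fraction of bits agreeing with a hidden
# target mask.  Global optimum (fitness 1) is the target itself.
bitmatch_fitness <- function(target) {
  n <- length(target)
  fn <- function(bits) sum(bits == target) / n
  attr(fn, "n_features") <- n
  fn
}

# Fitness rewarding small subsets that cover a planted set: accuracy
# surrogate + reduction term, mimicking the wrapper objective's shape.
planted_fitness <- function(informative, n_features, w_acc = 0.9) {
  fn <- function(bits) {
    hit <- sum(bits[informative] == 1L) / length(informative)
    fdr <- 1 - sum(bits) / n_features
    w_acc * hit + (1 - w_acc) * fdr
  }
  attr(fn, "n_features") <- n_features
  fn
}

# Exhaustive search over all non-empty masks of n bits (oracle).
exhaustive_best <- function(fitness_fn, n) {
  best <- -Inf
  best_mask <- NULL
  for (code in seq_len(2^n - 1L)) {
    mask <- as.integer(intToBits(code)[seq_len(n)] == as.raw(1))
    f <- fitness_fn(mask)
    if (f > best) {
      best <- f
      best_mask <- mask
    }
  }
  list(fitness = best, mask = best_mask)
}

# Independent ASCII PGM writers used to cross-check read_pgm.
write_pgm_p2_independent <- function(pixels, path, maxval = 255L) {
  lines <- c("P2", paste(ncol(pixels), nrow(pixels)), as.character(maxval),
             apply(pixels, 1, paste, collapse = " "))
  writeLines(lines, path)
}

write_pgm_p5_independent <- function(pixels, path, maxval = 255L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(pixels), nrow(pixels), maxval),
            con, eos = NULL)
  writeBin(as.raw(as.integer(t(pixels))), con)
}
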