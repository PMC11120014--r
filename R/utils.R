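# internal helpers

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive per-item sub-seeds (< 2^31) from a master seed, reproducibly
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# stratified fold assignment: within each class, ids are shuffled under the
# seed and dealt round-robin; depends only on (seed, order of labels)
stratifiedFolds <- function(labels, k, seed) {
  stopifnot(k >= 2L)
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# tiny stable content hash (polynomial over serialized bytes), hex string
contentHash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h1 <- 0; h2 <- 5381
  for (v in b) {
    h1 <- (h1 * 31 + v) %% 2147483647
    h2 <- (h2 * 33 + v) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
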