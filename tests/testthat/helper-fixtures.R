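# Small programmatic fixtures shared across test files.

# unrelated-founder dosage matrix with known allele frequency
toy_dosages <- function(n, m, p = 0.4, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, p), n, m)
  rownames(X) <- sprintf("A%05d", seq_len(n))
  colnames(X) <- sprintf("snp%04d", seq_len(m))
  X
}

# 3-generation, 8-animal hand pedigree:
#   founders F1 (sire), F2 (dam), F3 (sire), F4 (dam)
#   P1 = F1 x F2, P2 = F1 x F2 (full sibs), P3 = F3 x F4
#   O1 = P1 x P2 (full-sib mating)
hand_pedigree <- function() {
  data.frame(
    id = c("F1", "F2", "F3", "F4", "P1", "P2", "P3", "O1"),
    sire = c(NA, NA, NA, NA, "F1", "F1", "F3", "P1"),
    dam = c(NA, NA, NA, NA, "F2", "F2", "F4", "P2"),
    generation = c(1, 1, 1, 1, 2, 2, 2, 3),
    stringsAsFactors = FALSE)
}

# random valid pedigree for property tests
random_pedigree <- function(n, seed) {
  set.seed(seed)
  n_founders <- max(4L, round(n / 4))
  id <- sprintf("R%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    sire[i] <- id[sample(i - 1L, 1L)]
    dam[i] <- id[sample(i - 1L, 1L)]
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# small simulated population, cached per option set within a test file run
small_population <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 800, m = 200, seed = 42, ...) {
    key <- paste(n, m, seed, ...)
    if (is.null(cache[[key]])) {
      cfg <- sim_config(n_individuals = n, n_markers = m, seed = seed, ...)
      cache[[key]] <- simulate_population(cfg)
    }
    cache[[key]]
  }
})
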