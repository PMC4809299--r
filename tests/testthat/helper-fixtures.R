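# small in-code fixtures shared across test files

tiny_map <- function(n_chrom = 2, len = 100, m = 10) {
  make_genetic_map(n_chrom, len, m, seed = 42)
}

# population small enough for unit tests, large enough for stable OLS
tiny_pop <- function(map = tiny_map(), n_fam = 3, lines = 40, seed = 7,
                     polymorphism_rate = 1) {
  build_nam_population(map, n_fam, lines, polymorphism_rate, seed = seed)
}

# trait built directly on the dosage of one marker plus iid noise
marker_trait <- function(geno, marker, beta, sd = 1, seed = 1) {
  d <- geno$dosage[, marker]
  d[is.na(d)] <- 0
  namqtl:::with_seed(seed,
                     beta * d + stats::rnorm(nrow(geno$dosage), 0, sd))
}

# independent step-down Holm oracle, kept deliberately naive
holm_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}
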