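# Small in-code fixtures shared across tests.

# A tiny hand-built two-species count object with known structure.
toy_counts <- function() {
  caste_counts(list(
    spA = data.frame(gene_id = c("a1", "a2", "a3", "a4"),
                     length = c(1000, 500, 2000, 1000),
                     queen = c(100, 50, 10, 5),
                     worker = c(100, 10, 50, 2)),
    spB = data.frame(gene_id = c("b1", "b2", "b3"),
                     length = c(1000, 1500, 800),
                     queen = c(80, 40, 3),
                     worker = c(60, 80, 5))))
}

# Map with one single-copy row, one isoform row, one missing row.
toy_map <- function() {
  orthogroup_map(list(
    OG1 = list(spA = "a1", spB = "b1"),
    OG2 = list(spA = c("a2", "a3"), spB = "b2"),
    OG3 = list(spA = "a4", spB = character(0))),
    species = c("spA", "spB"))
}

# Independent enumeration oracle for the conditional NB exact test:
# negative-hypergeometric split probabilities computed directly from
# gamma functions (a different route than the implementation's dnbinom
# parameterisation).
oracle_nb_exact <- function(q, w, phi) {
  t <- q + w
  if (t == 0) return(1)
  r <- 1 / phi
  a <- 0:t
  # half-weights combined with their mirror so that mirrored splits get
  # bit-identical probabilities (they are equal mathematically)
  half <- lgamma(a + r) - lgamma(a + 1)
  logw <- half + rev(half)
  pr <- exp(logw - max(logw))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[q + 1]]))
}

# Exhaustive hypergeometric tail oracle: enumerate every possible draw of
# set B over a universe of size N with A fixed, and accumulate the exact
# overlap distribution.
oracle_hypergeom_tail <- function(N, a, b, obs, lower) {
  if (b == 0 || a == 0) {
    d <- c(`0` = 1)
  } else {
    combos <- utils::combn(N, b)
    ov <- colSums(combos <= a)
    d <- table(ov) / ncol(combos)
  }
  ks <- as.integer(names(d))
  if (lower) sum(d[ks <= obs]) else sum(d[ks >= obs])
}

# A small simulated dataset reused by several suites.
small_sim <- function(seed = 3, ...) {
  generate_dataset(simulation_config(n_species = 4, n_orthogroups = 300,
                                     toolkit_size = 30, seed = seed, ...))
}

# Reduced hyperparameter grid: keeps classifier unit tests fast while
# exercising the same code paths as the full grid.
fast_config <- function(seed = 1) {
  svm_config(gamma_grid = 10^c(-5, -4, -3), cost_grid = 2^c(1, 5, 10),
             seed = seed)
}
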