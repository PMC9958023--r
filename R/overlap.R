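#' Cross-species sharing of directed caste-biased genes
#'
#' For each orthogroup, counts in how many species it is caste-biased. With
#' `same_direction = TRUE` a gene contributes at the size of its largest
#' direction-consistent species subset (a gene queen-biased in 3 species
#' and worker-biased in 1 counts at k = 3), matching the "same direction
#' (either queen- or worker-biased only)" reading of shared caste bias.
#'
#' @param deg_sets Named list (per species) of data frames with columns
#'   `orthogroup` and `direction` ("queen"/"worker"), as produced by
#'   [call_degs()].
#' @param universe Character vector of all testable orthogroups; every
#'   listed gene must belong to it.
#' @param same_direction Require directional agreement (default TRUE).
#' @return List with `k` (named integer vector: per orthogroup, the number
#'   of species sharing it), `exact` (histogram of orthogroup counts at
#'   exactly k = 1..n_species), `at_least` (cumulative counts, at least k),
#'   and `members` (orthogroup IDs per exact-k level).
#' @export
count_shared_degs <- function(deg_sets, universe, same_direction = TRUE) {
  stopifnot(is.list(deg_sets), length(deg_sets) >= 1)
  n_species <- length(deg_sets)
  all_genes <- unlist(lapply(deg_sets, `[[`, "orthogroup"))
  if (!all(all_genes %in% universe))
    stop("gene(s) outside the universe: ",
         paste(utils::head(setdiff(all_genes, universe), 3), collapse = ", "))
  long <- do.call(rbind, lapply(names(deg_sets), function(sp) {
    d <- deg_sets[[sp]]
    if (!nrow(d)) return(NULL)
    data.frame(orthogroup = d$orthogroup, direction = d$direction)
  }))
  k <- integer(0)
  if (!is.null(long) && nrow(long)) {
    k <- vapply(split(long$direction, long$orthogroup), function(dirs) {
      if (same_direction) max(sum(dirs == "queen"), sum(dirs == "worker"))
      else length(dirs)
    }, integer(1))
  }
  lev <- seq_len(n_species)
  exact <- vapply(lev, function(i) sum(k == i), integer(1))
  at_least <- rev(cumsum(rev(exact)))
  names(exact) <- names(at_least) <- lev
  members <- lapply(lev, function(i) names(k)[k == i])
  names(members) <- lev
  list(k = k, exact = exact, at_least = at_least, members = members)
}

#' Permutation null for cross-species gene-set overlap
#'
#' Draws, for each species, a uniform random subset of the universe of the
#' same size as its observed caste-biased set (directions assigned
#' uniformly at random when directional agreement is required), recomputes
#' the shared-gene histogram, and summarises the null distribution at each
#' sharing level k. Observed counts are compared with the rounded expected
#' counts by a two-sided Fisher exact test on the 2x2 table
#' [observed_k, N - observed_k; round(expected_k), N - round(expected_k)].
#'
#' @inheritParams count_shared_degs
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the single permutation RNG stream.
#' @return Data frame with one row per k: `k`, `observed` (exact-k count),
#'   `expected_mean`, `expected_sd`, `fisher_p`.
#' @export
permutation_overlap_null <- function(deg_sets, universe, n_perm = 1000,
                                     seed = 1L, same_direction = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_species <- length(deg_sets)
  sizes <- vapply(deg_sets, nrow, integer(1))
  if (any(sizes > length(universe)))
    stop("set size exceeds universe size")
  obs <- count_shared_degs(deg_sets, universe, same_direction)$exact
  set.seed(seed)
  lev <- seq_len(n_species)
  null_counts <- matrix(0L, n_perm, n_species)
  for (b in seq_len(n_perm)) {
    perm <- lapply(seq_len(n_species), function(s) {
      genes <- sample(universe, sizes[s])
      dir <- if (same_direction)
        sample(c("queen", "worker"), sizes[s], replace = TRUE)
      else rep("queen", sizes[s])
      data.frame(orthogroup = genes, direction = dir)
    })
    names(perm) <- names(deg_sets)
    null_counts[b, ] <- count_shared_degs(perm, universe,
                                          same_direction)$exact
  }
  N <- length(universe)
  expected <- colMeans(null_counts)
  esd <- apply(null_counts, 2, stats::sd)
  fisher_p <- vapply(lev, function(i) {
    e <- round(expected[i])
    tab <- matrix(c(obs[i], N - obs[i], e, N - e), 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(k = lev, observed = as.integer(obs), expected_mean = expected,
             expected_sd = esd, fisher_p = fisher_p)
}

#' One-tailed hypergeometric overlap between two gene sets
#'
#' Tests whether two gene sets drawn from a common universe overlap more
#' (enrichment) or less (depletion) than the chance expectation a*b/N. The
#' tail is chosen by the sign of observed - expected; the fold ratio is
#' reported as observed/expected when enriched and expected/observed when
#' depleted, so fold >= 1 always, with the direction recorded.
#'
#' @param set_a,set_b Character vectors of gene IDs (subsets of
#'   `universe`), or integers giving the set sizes when `observed` is
#'   supplied directly.
#' @param universe Character vector of the common gene universe, or an
#'   integer universe size.
#' @param observed Optional integer overlap; required when sizes rather
#'   than ID vectors are given.
#' @return List with `universe_n`, `set_a_n`, `set_b_n`, `observed`,
#'   `expected`, `fold`, `direction` ("enriched"/"depleted"/"none") and
#'   `p` (one-tailed hypergeometric).
#' @examples
#' # fewer shared genes than chance predicts between two predictor sets
#' hypergeom_overlap(1420, 353, 5536, observed = 35)
#' @export
hypergeom_overlap <- function(set_a, set_b, universe, observed = NULL) {
  if (length(universe) == 1 && is.numeric(universe)) {
    N <- as.integer(universe)
    a <- as.integer(set_a); b <- as.integer(set_b)
    if (is.null(observed))
      stop("'observed' is required when sets are given as sizes")
  } else {
    if (length(universe) == 0) stop("empty universe")
    if (!all(set_a %in% universe) || !all(set_b %in% universe))
      stop("sets must be subsets of the universe")
    N <- length(unique(universe))
    a <- length(unique(set_a)); b <- length(unique(set_b))
    observed <- length(intersect(set_a, set_b))
  }
  if (N < 1) stop("empty universe")
  if (observed > min(a, b)) stop("observed overlap exceeds set sizes")
  expected <- a * b / N
  if (observed < expected) {
    p <- stats::phyper(observed, a, N - a, b)
    direction <- "depleted"
    fold <- if (observed > 0) expected / observed else Inf
  } else if (observed > expected) {
    p <- stats::phyper(observed - 1, a, N - a, b, lower.tail = FALSE)
    direction <- "enriched"
    fold <- observed / expected
  } else {
    p <- 1
    direction <- "none"
    fold <- 1
  }
  list(universe_n = N, set_a_n = a, set_b_n = b,
       observed = as.integer(observed), expected = expected,
       fold = fold, direction = direction, p = p)
}
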