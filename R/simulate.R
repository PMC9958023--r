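#' Configuration for the multi-species caste count simulator
#'
#' Defines the generative model for a synthetic comparative dataset: several
#' species, one pooled queen and one pooled worker sample each, negative
#' binomial count noise, per-gene per-species expression offsets, a planted
#' direction-consistent "toolkit" of caste-biased orthogroups shared by all
#' species, species-private caste genes, and the structural nuisances the
#' harmonisation stage must handle (within-species isoform duplications,
#' missing orthologs).
#'
#' @param n_species Number of species (>= 2).
#' @param n_orthogroups Number of orthogroups.
#' @param toolkit_size Number of toolkit orthogroups: caste-biased in every
#'   species, always in the same direction.
#' @param private_caste_frac Fraction of the non-toolkit orthogroups that are
#'   caste-biased in exactly one (random) species.
#' @param effect_log2fc Mean absolute log2 queen/worker fold change of
#'   caste-biased genes (applied as a fixed symmetric shift of +/- fc/2 to
#'   the two castes).
#' @param species_sd SD (log2 scale) of the per-gene per-species expression
#'   offset shared by both castes; this is what makes species, not caste,
#'   dominate unnormalised expression.
#' @param dispersion Negative binomial dispersion of the count noise
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param lib_size Target sequencing depth (expected reads per sample).
#' @param length_range Length-2 integer vector; gene effective lengths are
#'   drawn uniformly from this range (bp).
#' @param dup_rate Fraction of (orthogroup, species) cells whose gene is
#'   split into 2-3 isoforms (Dirichlet-shared signal).
#' @param missing_rate Fraction of (orthogroup, species) cells with no gene
#'   at all (absent from counts and from the orthogroup map).
#' @param group_labels Optional character vector of length `n_species`
#'   with exactly two distinct values, partitioning species into two groups
#'   (used by [generate_group_asymmetry()]).
#' @param seed Integer seed; one RNG stream drives every stochastic choice,
#'   so an identical config yields byte-identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 9, n_orthogroups = 2000,
                              toolkit_size = 150, private_caste_frac = 0.05,
                              effect_log2fc = 1, species_sd = 1,
                              dispersion = 0.1, lib_size = 2e6,
                              length_range = c(300L, 3000L),
                              dup_rate = 0.05, missing_rate = 0.02,
                              group_labels = NULL, seed = 1L) {
  stopifnot(n_species >= 2, n_orthogroups >= 1,
            effect_log2fc >= 0, species_sd >= 0, dispersion >= 0,
            lib_size > 0, length(length_range) == 2,
            length_range[1] > 0, length_range[2] >= length_range[1])
  for (frac in c(private_caste_frac, dup_rate, missing_rate))
    if (frac < 0 || frac > 1) stop("fractions must lie in [0, 1]")
  if (toolkit_size < 0 || toolkit_size > n_orthogroups)
    stop("toolkit_size must lie in [0, n_orthogroups]")
  if (!is.null(group_labels)) {
    if (length(group_labels) != n_species ||
        length(unique(group_labels)) != 2L)
      stop("group_labels must assign each species to one of two groups")
  }
  structure(list(n_species = as.integer(n_species),
                 n_orthogroups = as.integer(n_orthogroups),
                 toolkit_size = as.integer(toolkit_size),
                 private_caste_frac = private_caste_frac,
                 effect_log2fc = effect_log2fc, species_sd = species_sd,
                 dispersion = dispersion, lib_size = lib_size,
                 length_range = as.integer(length_range),
                 dup_rate = dup_rate, missing_rate = missing_rate,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "simulation_config")
}

# Draw NB counts with mean mu and dispersion phi (Poisson when phi == 0).
rnbinom_disp <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

# Shared sampling backend. fc is the n_orthogroups x n_species matrix of
# true log2(Q/W) effects. RNG draws happen in a fixed documented order:
# baseline abundances, lengths, species offsets, missing cells, duplication
# cells + isoform shares, then per-species counts (queen, worker).
simulate_from_fc <- function(config, fc, truth_extra = NULL) {
  n <- config$n_orthogroups
  S <- config$n_species
  species <- sprintf("sp%02d", seq_len(S))
  og_ids <- sprintf("OG%06d", seq_len(n))

  # baseline abundance on the TPM scale: log-normal dynamic range
  base_tpm <- stats::rlnorm(n, meanlog = 3, sdlog = 1.2)
  len <- matrix(round(stats::runif(n * S, config$length_range[1],
                                   config$length_range[2])), n, S,
                dimnames = list(og_ids, species))
  offset <- matrix(stats::rnorm(n * S, 0, config$species_sd), n, S)
  missing <- matrix(stats::runif(n * S) < config$missing_rate, n, S)
  dup <- matrix(stats::runif(n * S) < config$dup_rate, n, S) & !missing
  n_iso <- matrix(1L, n, S)
  n_iso[dup] <- sample(2:3, sum(dup), replace = TRUE)

  # abundance per caste; caste effect is a symmetric +/- fc/2 log2 shift
  abQ <- base_tpm * 2^(offset + fc / 2)
  abW <- base_tpm * 2^(offset - fc / 2)

  tables <- vector("list", S)
  names(tables) <- species
  members <- lapply(seq_len(n), function(i) {
    m <- rep(list(character(0)), S)
    names(m) <- species
    m
  })
  names(members) <- og_ids

  for (s in seq_len(S)) {
    pres <- which(!missing[, s])
    k_iso <- n_iso[pres, s]
    gene_og <- rep.int(pres, k_iso)
    iso_idx <- sequence(k_iso)
    gene_id <- ifelse(rep.int(k_iso, k_iso) == 1L,
                      sprintf("%s_g%05d", species[s], gene_og),
                      sprintf("%s_g%05d_i%d", species[s], gene_og, iso_idx))
    # Dirichlet(1,...,1) shares split a duplicated gene's signal
    share <- stats::rgamma(length(gene_og), shape = 1)
    share <- share / stats::ave(share, gene_og, FUN = sum)
    share[rep.int(k_iso, k_iso) == 1L] <- 1

    # expected read counts: reads proportional to abundance x length
    wQ <- abQ[gene_og, s] * len[gene_og, s] * share
    wW <- abW[gene_og, s] * len[gene_og, s] * share
    muQ <- config$lib_size * wQ / sum(abQ[pres, s] * len[pres, s])
    muW <- config$lib_size * wW / sum(abW[pres, s] * len[pres, s])
    cntQ <- rnbinom_disp(length(muQ), muQ, config$dispersion)
    cntW <- rnbinom_disp(length(muW), muW, config$dispersion)

    tables[[s]] <- data.frame(gene_id = gene_id, length = len[gene_og, s],
                              queen = cntQ, worker = cntW)
    split_ids <- split(gene_id, og_ids[gene_og])
    for (og in names(split_ids))
      members[[og]][[species[s]]] <- split_ids[[og]]
  }

  biased <- fc != 0
  direction <- ifelse(rowSums(fc) > 0, "queen",
                      ifelse(rowSums(fc) < 0, "worker", "none"))
  truth <- list(
    orthogroup = og_ids,
    toolkit_member = if (is.null(truth_extra$toolkit)) rep(FALSE, n) else
      seq_len(n) %in% truth_extra$toolkit,
    direction = direction,
    biased_species = lapply(seq_len(n), function(i) species[biased[i, ]]),
    true_log2fc = structure(fc, dimnames = list(og_ids, species)),
    species = species,
    group_labels = truth_extra$group_labels,
    shared = truth_extra$shared, group2_extra = truth_extra$group2_extra)
  names(truth$biased_species) <- og_ids

  list(counts = caste_counts(tables),
       map = orthogroup_map(members, species = species),
       truth = truth)
}

#' Generate a synthetic multi-species two-caste dataset
#'
#' Draws a complete comparative dataset from the model described in
#' [simulation_config()]: per-species count tables, the matching orthogroup
#' map (with planted isoform duplications and missing orthologs), and a
#' ground-truth record of which orthogroups are caste-biased, where, and in
#' which direction.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `counts` (a [caste_counts()]), `map`
#'   (an [orthogroup_map()]) and `truth` (orthogroup-level ground truth:
#'   `toolkit_member`, `direction`, `biased_species`, `true_log2fc`).
#' @examples
#' sim <- generate_dataset(simulation_config(n_species = 3,
#'   n_orthogroups = 50, toolkit_size = 5, seed = 1))
#' sum(sim$truth$toolkit_member)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_orthogroups
  S <- config$n_species

  toolkit <- if (config$toolkit_size > 0) sample.int(n, config$toolkit_size)
             else integer(0)
  rest <- setdiff(seq_len(n), toolkit)
  n_priv <- round(config$private_caste_frac * length(rest))
  priv <- if (n_priv > 0) sample(rest, n_priv) else integer(0)
  priv_sp <- if (n_priv > 0) sample.int(S, n_priv, replace = TRUE) else integer(0)
  dir_sign <- sample(c(1, -1), n, replace = TRUE)

  fc <- matrix(0, n, S)
  if (length(toolkit))
    fc[toolkit, ] <- dir_sign[toolkit] * config$effect_log2fc
  if (length(priv))
    fc[cbind(priv, priv_sp)] <- dir_sign[priv] * config$effect_log2fc

  simulate_from_fc(config, fc,
                   truth_extra = list(toolkit = toolkit,
                                      group_labels = config$group_labels))
}

#' Generate a dataset with asymmetric group-specific toolkits
#'
#' Splits the species into two groups and plants two kinds of caste genes:
#' a shared toolkit biased in every species of both groups, and an extra set
#' biased only in group-2 species. Classifiers trained on group 1 should
#' therefore transfer to group 2 better than the reverse: group-1 training
#' concentrates on the shared toolkit, while group-2 training dilutes it
#' with group-private genes that carry no signal in group 1.
#'
#' @param config A [simulation_config()]; its `group_labels` (or, if absent,
#'   a half/half split in species order) define the two groups, each of
#'   which must contain at least 2 species.
#' @param shared_size Number of shared toolkit orthogroups.
#' @param extra_group2_size Number of orthogroups caste-biased only in
#'   group-2 species (0 recovers the symmetric [generate_dataset()] design).
#' @return As [generate_dataset()]; `truth` additionally records
#'   `group_labels`, `shared` and `group2_extra` orthogroup indices.
#' @export
generate_group_asymmetry <- function(config, shared_size,
                                     extra_group2_size) {
  stopifnot(inherits(config, "simulation_config"),
            shared_size >= 0, extra_group2_size >= 0)
  n <- config$n_orthogroups
  S <- config$n_species
  groups <- config$group_labels
  if (is.null(groups))
    groups <- rep(c("group1", "group2"), c(floor(S / 2), ceiling(S / 2)))
  lev <- unique(groups)
  if (min(table(groups)) < 2)
    stop("each group must contain at least 2 species")
  if (shared_size + extra_group2_size > n)
    stop("shared_size + extra_group2_size exceeds n_orthogroups")
  in_g2 <- groups == lev[2]

  set.seed(config$seed)
  picked <- if (shared_size + extra_group2_size > 0)
    sample.int(n, shared_size + extra_group2_size) else integer(0)
  shared <- picked[seq_len(shared_size)]
  extra <- picked[shared_size + seq_len(extra_group2_size)]
  dir_sign <- sample(c(1, -1), n, replace = TRUE)

  fc <- matrix(0, n, S)
  if (length(shared))
    fc[shared, ] <- dir_sign[shared] * config$effect_log2fc
  if (length(extra))
    fc[extra, in_g2] <- dir_sign[extra] * config$effect_log2fc

  simulate_from_fc(config, fc,
                   truth_extra = list(toolkit = shared,
                                      group_labels = groups,
                                      shared = shared, group2_extra = extra))
}

#' Write a simulated dataset to plain-text files
#'
#' Counts go to one TSV per species, the orthogroup map to an
#' `Orthogroups.tsv`-dialect table, and the ground truth to JSON.
#'
#' @param sim Result of [generate_dataset()] or
#'   [generate_group_asymmetry()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_tables(sim$counts, dir)
  write_orthogroups(sim$map, file.path(dir, "Orthogroups.tsv"))
  truth <- sim$truth
  truth$true_log2fc <- as.data.frame(truth$true_log2fc)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
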