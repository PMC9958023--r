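test_that("TPM normalises by length and sums to one million", {
  counts <- caste_counts(list(
    spA = data.frame(gene_id = c("g1", "g2"), length = c(1000, 500),
                     queen = c(10, 10), worker = c(7, 7))))
  map <- orthogroup_map(list(OG1 = list(spA = "g1"),
                             OG2 = list(spA = "g2")), species = "spA")
  h <- harmonize(counts, map, "strict")
  tpm <- compute_tpm(h)
  # equal counts, g2 half the length -> twice the rate
  expect_equal(unname(tpm[, "spA_queen"]), c(1e6 / 3, 2e6 / 3))
  expect_equal(unname(colSums(tpm)), rep(1e6, 2), tolerance = 1e-9)
  # equal counts and lengths split evenly
  expect_equal(unname(tpm[, "spA_worker"]), c(1e6 / 3, 2e6 / 3))
})

test_that("quantile normalisation equalises column distributions", {
  # two columns whose log2(x+1) values are (1,3) and (2,4):
  # mean-of-sorted gives (1.5, 3.5) in each column's rank order
  m <- cbind(a = 2^c(1, 3) - 1, b = 2^c(2, 4) - 1)
  out <- log_quantile(m)
  expect_equal(unname(out[, "a"]), c(1.5, 3.5))
  expect_equal(unname(out[, "b"]), c(1.5, 3.5))
  # identical columns are a fixed point
  m2 <- cbind(2^c(0, 2, 5) - 1, 2^c(0, 2, 5) - 1)
  expect_equal(unname(log_quantile(m2)[, 1]), c(0, 2, 5))
  # any output: all columns share one multiset of values
  set.seed(1)
  m3 <- matrix(rexp(60, 1 / 50), 12, 5)
  out3 <- log_quantile(m3)
  sorted <- apply(out3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_error(log_quantile(matrix(c(-1, 2), 1)), "non-negative")
})

test_that("species scaling gives the (Q-W)/(Q+W) contrast", {
  m <- rbind(g1 = c(2, 2), g2 = c(3, 1), g3 = c(5, 0))
  colnames(m) <- c("spA_queen", "spA_worker")
  out <- species_scale(m, species = c("spA", "spA"))
  expect_equal(unname(out["g1", ]), c(0, 0))        # Q = W
  expect_equal(unname(out["g2", ]), c(0.5, -0.5))   # (3-2)/2
  expect_equal(unname(out["g3", ]), c(1, -1))       # boundary W = 0
  # zero species mean is zeroed and counted
  m0 <- rbind(g = c(0, 0, 4, 2))
  out0 <- species_scale(m0, species = c("spA", "spA", "spB", "spB"))
  expect_equal(unname(out0[1, ]), c(0, 0, 1 / 3, -1 / 3))
  expect_identical(attr(out0, "zero_mean"), 1L)
})

test_that("species scaling invariants hold on random matrices", {
  set.seed(42)
  for (i in 1:1000) {
    ns <- sample(2:5, 1)
    ng <- sample(3:12, 1)
    m <- matrix(rexp(ng * 2 * ns), ng, 2 * ns)
    species <- rep(paste0("s", seq_len(ns)), each = 2)
    out <- species_scale(m, species = species)
    expect_true(all(out >= -1 - 1e-12 & out <= 1 + 1e-12))
    for (s in unique(species)) {
      cols <- which(species == s)
      expect_true(all(abs(out[, cols[1]] + out[, cols[2]]) < 1e-12))
    }
    # invariant to per-species positive rescaling
    m2 <- m
    m2[, species == "s1"] <- m2[, species == "s1"] * 7.3
    expect_equal(species_scale(m2, species = species), out,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("low-expression filter drops rows quiet in both castes of any species", {
  tabs <- list(
    spA = data.frame(gene_id = c("g1", "g2", "g3"), length = rep(1e3, 3),
                     queen = c(50, 2, 2), worker = c(50, 3, 30)),
    spB = data.frame(gene_id = c("h1", "h2", "h3"), length = rep(1e3, 3),
                     queen = c(50, 40, 2), worker = c(50, 40, 30)))
  counts <- caste_counts(tabs, lib_sizes = matrix(
    1e6, 2, 2, dimnames = list(c("spA", "spB"), c("queen", "worker"))))
  map <- orthogroup_map(list(OG1 = list(spA = "g1", spB = "h1"),
                             OG2 = list(spA = "g2", spB = "h2"),
                             OG3 = list(spA = "g3", spB = "h3")),
                        species = c("spA", "spB"))
  h <- harmonize(counts, map, "strict")
  keep <- filter_low_expression(h, threshold_cpm = 10)
  expect_true(keep[["OG1"]])   # high everywhere
  expect_false(keep[["OG2"]])  # both castes low in spA
  expect_true(keep[["OG3"]])   # worker sample rescues both species
})

test_that("filled cells do not trigger the low-expression filter", {
  tabs <- lapply(1:3, function(i)
    data.frame(gene_id = "g", length = 1000, queen = 5000, worker = 5000))
  names(tabs) <- paste0("sp", 1:3)
  members <- list(OG1 = list(sp1 = "g", sp2 = "g", sp3 = character(0)))
  counts <- caste_counts(tabs)
  map <- orthogroup_map(members, species = paste0("sp", 1:3))
  h <- fill_missing(map, counts, max_missing_species = 1)
  # the filled sp3 cell has CPM far below 10 but carries no evidence
  expect_true(filter_low_expression(h, 10)[["OG1"]])
})

test_that("the full normalisation chain is deterministic and bounded", {
  sim <- small_sim(seed = 10)
  h <- harmonize(sim$counts, sim$map, "iso3na2")
  n1 <- normalize_expression(h)
  n2 <- normalize_expression(h)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values >= -1 & n1$values <= 1))
  qcols <- n1$caste == "queen"
  expect_true(all(abs(n1$values[, qcols] + n1$values[, !qcols]) < 1e-10))
})

test_that("PCA scores recover rank structure and variance ordering", {
  sim <- small_sim(seed = 12)
  norm <- normalize_expression(harmonize(sim$counts, sim$map, "iso3"))
  pr <- pca_samples(norm, 4)
  expect_equal(nrow(pr$scores), ncol(norm$values))
  expect_true(all(diff(pr$variance_fraction) <= 1e-12))
  expect_lte(sum(pr$variance_fraction), 1 + 1e-8)
  # duplicated sample set: no variance beyond the original rank
  m <- norm$values[, c(1, 2, 1, 2)]
  pr2 <- stats::prcomp(t(m))
  expect_lt(pr2$sdev[3], 1e-8)
})

test_that("species scaling flips the dominant PCA axis from species to caste", {
  sim <- generate_dataset(simulation_config(
    n_species = 6, n_orthogroups = 800, toolkit_size = 100,
    effect_log2fc = 1, species_sd = 1.5, seed = 5))
  h <- harmonize(sim$counts, sim$map, "iso3na2")
  keep <- filter_low_expression(h)
  hf <- h
  for (fl in c("queen", "worker", "length", "gene_id", "filled",
               "collapsed_n"))
    hf[[fl]] <- h[[fl]][keep, , drop = FALSE]
  raw <- log_quantile(compute_tpm(hf))
  pr_raw <- pca_samples(raw, 2)
  sil_sp_raw <- silhouette_width(pr_raw$scores, attr(raw, "species"))
  sil_ca_raw <- silhouette_width(pr_raw$scores, attr(raw, "caste"))
  expect_gt(sil_sp_raw, sil_ca_raw)
  norm <- normalize_expression(h)
  pr_sc <- pca_samples(norm, 2)
  sil_sp <- silhouette_width(pr_sc$scores, norm$species)
  sil_ca <- silhouette_width(pr_sc$scores, norm$caste)
  expect_gt(sil_ca, sil_sp)
})
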