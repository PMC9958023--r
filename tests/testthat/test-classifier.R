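test_that("feature regression matches the closed-form OLS oracle", {
  x <- c(-0.5, 0.5, -0.4, 0.4)
  y <- c(0, 1, 0, 1)
  mat <- rbind(g1 = x, g2 = rep(0.3, 4))
  rk <- rank_features(mat, y)
  beta_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sum((x - mean(x))^2)
  expect_equal(rk$beta[1], beta_oracle)
  fit <- stats::lm(y ~ x)
  expect_equal(rk$p[1], summary(fit)$coefficients["x", 4])
  # constant gene: no association, ranked last
  expect_equal(rk$beta[2], 0)
  expect_equal(rk$p[2], 1)
  expect_equal(rk$rank[2], 2L)
})

test_that("a perfectly caste-separating gene ranks first", {
  set.seed(3)
  mat <- matrix(rnorm(50 * 8, sd = 0.3), 50, 8,
                dimnames = list(paste0("g", 1:50), NULL))
  y <- rep(c(1, 0), 4)
  mat["g7", ] <- ifelse(y == 1, 0.5, -0.5)
  rk <- rank_features(mat, y)
  expect_equal(rk$orthogroup[rk$rank == 1], "g7")
  expect_error(rank_features(mat[, 1:3], y[1:3]), "4 training samples")
  expect_error(rank_features(mat, rep(1, 8)), "4 training samples")
})

test_that("SVM training is deterministic and separates a clean toy problem", {
  set.seed(5)
  n <- 12
  y <- rep(c(1, 0), n / 2)
  x <- cbind(f1 = ifelse(y == 1, 1, -1) + rnorm(n, sd = 0.2),
             f2 = rnorm(n, sd = 0.2))
  fit1 <- train_svm(x, y, fast_config(seed = 2))
  fit2 <- train_svm(x, y, fast_config(seed = 2))
  expect_identical(fit1$gamma, fit2$gamma)
  expect_identical(fit1$cost, fit2$cost)
  expect_equal(fit1$cv_accuracy, 1)
  # a duplicate of a queen training sample classifies queen-wards
  est <- classify(fit1, x[c(1, 2), , drop = FALSE])
  expect_identical(classify(fit1, x[c(1, 2), , drop = FALSE]), est)
  expect_gt(est[1], 0.5)
  expect_lt(est[2], 0.5)
  expect_true(all(est >= 0 & est <= 1))
  expect_error(train_svm(x, rep(1, n), fast_config()), "each caste")
})

test_that("swapping the class coding mirrors the estimates", {
  set.seed(6)
  n <- 12
  y <- rep(c(1, 0), n / 2)
  x <- cbind(f1 = ifelse(y == 1, 0.8, -0.8) + rnorm(n, sd = 0.3),
             f2 = ifelse(y == 1, -0.4, 0.4) + rnorm(n, sd = 0.3))
  xtest <- rbind(c(0.9, -0.5), c(-0.7, 0.5))
  colnames(xtest) <- colnames(x)
  cfg <- fast_config(seed = 4)
  e_direct <- classify(train_svm(x, y, cfg), xtest)
  e_swapped <- classify(train_svm(x, 1 - y, cfg), xtest)
  expect_equal(e_direct, 1 - e_swapped, tolerance = 0.05)
})

test_that("classification on label-shuffled data carries no signal", {
  set.seed(8)
  y <- rep(c(1, 0), 8)
  x <- matrix(rnorm(16 * 40), 16, 40,
              dimnames = list(NULL, paste0("g", 1:40)))
  fit <- train_svm(x, y, fast_config(seed = 8))
  expect_lt(fit$cv_accuracy, 0.85)
  est <- classify(fit, matrix(rnorm(30 * 40), 30, 40,
                              dimnames = list(NULL, paste0("g", 1:40))))
  expect_lt(abs(mean(est) - 0.5), 0.15)
})

test_that("classify demands the training features", {
  set.seed(9)
  y <- rep(c(1, 0), 4)
  x <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("g", 1:5)))
  fit <- train_svm(x, y, fast_config())
  expect_error(classify(fit, x[, 1:3]), "g4")
})

test_that("feature ranking sees only the training species", {
  sim <- generate_dataset(simulation_config(
    n_species = 5, n_orthogroups = 200, toolkit_size = 20,
    effect_log2fc = 1, dup_rate = 0, missing_rate = 0, seed = 31))
  norm <- normalize_expression(harmonize(sim$counts, sim$map, "strict"))
  v <- norm$values
  test_sp <- "sp05"
  tr <- norm$species != test_sp
  rk_before <- rank_features(v[, tr], as.integer(norm$caste[tr] == "queen"))
  # make one gene caste-perfect in the held-out species only
  g <- rownames(v)[1]
  v2 <- v
  v2[g, !tr] <- ifelse(norm$caste[!tr] == "queen", 1, -1)
  rk_after <- rank_features(v2[, tr], as.integer(norm$caste[tr] == "queen"))
  expect_identical(rk_before$rank, rk_after$rank)
})

test_that("leave-one-species-out separates castes on planted data", {
  sim <- generate_dataset(simulation_config(
    n_species = 5, n_orthogroups = 400, toolkit_size = 60,
    effect_log2fc = 1.2, seed = 33))
  norm <- normalize_expression(harmonize(sim$counts, sim$map, "iso3na2"))
  loo <- leave_one_species_out(norm, fractions = c(0.5, 0.2),
                               config = fast_config(seed = 33))
  cv <- loo$curves
  # retained feature counts shrink with the fraction
  expect_true(all(cv$n_features[cv$fraction == 0.2] <
                    cv$n_features[cv$fraction == 0.5]))
  # queens score above workers within every species/fraction
  for (sp in unique(cv$species)) {
    for (f in unique(cv$fraction)) {
      sub <- cv[cv$species == sp & cv$fraction == f, ]
      expect_gt(sub$estimate_queen[sub$caste == "queen"],
                sub$estimate_queen[sub$caste == "worker"])
    }
  }
  expect_true(all(cv$estimate_queen >= 0 & cv$estimate_queen <= 1))
  # too few species is rejected
  two <- norm
  keep_cols <- norm$species %in% unique(norm$species)[1:2]
  two$values <- norm$values[, keep_cols]
  two$species <- norm$species[keep_cols]
  two$caste <- norm$caste[keep_cols]
  expect_error(leave_one_species_out(two), ">= 3 species")
})

test_that("group transfer validates its species sets", {
  sim <- small_sim(seed = 35)
  norm <- normalize_expression(harmonize(sim$counts, sim$map, "iso3"))
  sp <- unique(norm$species)
  expect_error(group_transfer(norm, sp[1:2], sp[2:3]), "disjoint")
  expect_error(group_transfer(norm, sp[1:2], "spXX"), "unknown")
})

test_that("group transfer recovers caste in held-out species and extracts a toolkit", {
  sim <- generate_dataset(simulation_config(
    n_species = 6, n_orthogroups = 400, toolkit_size = 60,
    effect_log2fc = 1.2, seed = 37))
  norm <- normalize_expression(harmonize(sim$counts, sim$map, "iso3na2"))
  sp <- unique(norm$species)
  res <- group_transfer(norm, sp[1:3], sp[4:6], fractions = 0.2,
                        config = fast_config(seed = 37))
  cv <- res$curves
  expect_gt(mean(cv$estimate_queen[cv$caste == "queen"]),
            mean(cv$estimate_queen[cv$caste == "worker"]))
  expect_true(all(res$toolkit %in% rownames(norm$values)))
  tk <- sim$truth$orthogroup[sim$truth$toolkit_member]
  expect_gt(mean(res$toolkit %in% tk), 0.3)
})

test_that("toolkit extraction from leave-one-out recovers planted genes", {
  # Note on the attainable precision: the two-sample-per-species design
  # makes the species-scaled matrix antisymmetric (worker = -queen), so
  # the per-gene caste regression has fewer independent observations than
  # its nominal df and its p < 0.05 set is anticonservative under the
  # null. The extracted toolkit is therefore judged against the chance
  # baseline (planted fraction ~7.5%): a strong multiple of chance
  # precision plus high recall, rather than an arbitrary absolute cut.
  for (seed in c(7, 8, 9)) {
    sim <- generate_dataset(simulation_config(
      n_species = 6, n_orthogroups = 2000, toolkit_size = 150,
      effect_log2fc = 1.0, dispersion = 0.1, seed = seed))
    norm <- normalize_expression(harmonize(sim$counts, sim$map, "iso3na2"))
    loo <- leave_one_species_out(norm, fractions = 0.99,
                                 config = fast_config(seed = seed))
    tkhat <- toolkit_genes(loo, p_cutoff = 0.05)
    tk <- intersect(sim$truth$orthogroup[sim$truth$toolkit_member],
                    rownames(norm$values))
    chance <- length(tk) / nrow(norm$values)
    expect_gt(mean(tkhat %in% tk), 4 * chance)
    expect_gt(mean(tk %in% tkhat), 0.6)
  }
})

test_that("learning curves fall with feature selection on separable data", {
  sim <- generate_dataset(simulation_config(
    n_species = 6, n_orthogroups = 400, toolkit_size = 60,
    effect_log2fc = 1.5, seed = 39))
  norm <- normalize_expression(harmonize(sim$counts, sim$map, "iso3na2"))
  lc <- learning_curves(norm, fractions = c(0.99, 0.2), folds = 6,
                        config = fast_config(seed = 39))
  expect_lte(lc$cv_error[lc$fraction == 0.2],
             lc$cv_error[lc$fraction == 0.99])
  expect_lt(lc$cv_error[lc$fraction == 0.2], 0.2)
  expect_error(learning_curves(norm, fractions = 0.5, folds = 100),
               "folds")
  # null data: error near chance
  sim0 <- generate_dataset(simulation_config(
    n_species = 6, n_orthogroups = 400, toolkit_size = 0,
    private_caste_frac = 0, seed = 41))
  norm0 <- normalize_expression(harmonize(sim0$counts, sim0$map, "iso3na2"))
  lc0 <- learning_curves(norm0, fractions = 0.5, folds = 6,
                         config = fast_config(seed = 41))
  expect_gt(lc0$cv_error, 0.2)
})
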