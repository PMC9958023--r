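#' Rank genes by their regression association with caste
#'
#' Per-gene ordinary least squares of the binary caste label (1 = queen,
#' 0 = worker) on expression, computed in closed form. Genes are ranked by
#' ascending regression p-value (equivalently descending |correlation|,
#' the scale-free measure of caste association), with ties broken by
#' |beta| and then gene ID so the ranking is deterministic. Ranking by
#' raw |beta| is available via `order_by` but is scale-sensitive: because
#' beta = cov(x, y) / var(x), genes with small expression variance are
#' inflated, so chance correlations in near-flat genes can outrank real
#' caste signal. Zero-variance genes get beta 0, p 1 and rank last.
#'
#' @param mat Expression matrix, genes x training samples (the species-free
#'   [-1, 1] scale is the intended input).
#' @param caste Binary vector per sample (1 = queen, 0 = worker) or a
#'   character vector of "queen"/"worker".
#' @param order_by `"p"` (default) or `"beta"`.
#' @return Data frame with columns `orthogroup`, `beta`, `p`, `rank`
#'   (1 = most caste-associated), in input row order.
#' @export
rank_features <- function(mat, caste, order_by = c("p", "beta")) {
  order_by <- match.arg(order_by)
  y <- caste_binary(caste)
  n <- length(y)
  if (ncol(mat) != n) stop("one caste label per sample required")
  if (n < 4 || length(unique(y)) < 2)
    stop("need >= 4 training samples with both castes present")
  xm <- rowMeans(mat)
  ym <- mean(y)
  sxx <- rowSums((mat - xm)^2)
  sxy <- as.vector(mat %*% y) - n * xm * ym
  syy <- sum((y - ym)^2)
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- pmax(syy - beta * sxy, 0)
  se2 <- rss / (n - 2) / sxx
  tstat <- ifelse(sxx > 0 & se2 > 0, beta / sqrt(se2), 0)
  p <- ifelse(sxx > 0,
              ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df = n - 2), 0), 1)
  ogs <- rownames(mat)
  if (is.null(ogs)) ogs <- as.character(seq_len(nrow(mat)))
  key <- if (order_by == "beta") order(-abs(beta), p, ogs)
         else order(p, -abs(beta), ogs)
  rank <- integer(length(key))
  rank[key] <- seq_along(key)
  data.frame(orthogroup = ogs, beta = beta, p = p, rank = rank,
             row.names = NULL)
}

caste_binary <- function(caste) {
  if (is.character(caste) || is.factor(caste)) {
    caste <- as.character(caste)
    if (!all(caste %in% c("queen", "worker")))
      stop("caste labels must be 'queen'/'worker' or 0/1")
    as.integer(caste == "queen")
  } else {
    if (!all(caste %in% c(0, 1))) stop("binary caste labels must be 0/1")
    as.integer(caste)
  }
}

#' SVM training configuration
#'
#' Holds the kernel, hyperparameter grids, tuning-CV settings and seed used
#' by [train_svm()] and the experiment drivers. Defaults reproduce the
#' standard grid for this pipeline: radial kernel, gamma in 10^(-8..-3) and
#' cost in 2^(1..10).
#'
#' @param kernel One of "radial", "linear", "polynomial", "sigmoid".
#' @param gamma_grid,cost_grid Non-empty numeric grids.
#' @param tuning_folds Folds for the tuning cross-validation; `NULL` means
#'   min(10, n_samples), reduced automatically for tiny n.
#' @param seed Integer seed driving all CV splits and the probability
#'   calibration, so a given input always selects the same model.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = c("radial", "linear", "polynomial",
                                  "sigmoid"),
                       gamma_grid = 10^(-8:-3), cost_grid = 2^(1:10),
                       tuning_folds = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  if (!length(gamma_grid) || !length(cost_grid))
    stop("hyperparameter grids must be non-empty")
  structure(list(kernel = kernel, gamma_grid = gamma_grid,
                 cost_grid = cost_grid, tuning_folds = tuning_folds,
                 seed = as.integer(seed)),
            class = "svm_config")
}

# Deterministic stratified fold assignment: within each class, samples are
# shuffled (seeded) and dealt round-robin across folds.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Queen-oriented decision values: positive = queen side. e1071/libsvm
# orient the raw decision value towards whichever class libsvm saw first,
# and report the orientation in the column name ("0/1" vs "1/0"), so we
# re-sign to a fixed convention.
decision_queen <- function(model, x) {
  pred <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  f <- unname(dv[, 1])
  # Orient empirically: the predicted class of the largest-margin sample
  # reveals which side is the queen ("1") side (column-name conventions
  # are not stable across refits).
  if (any(f != 0)) {
    i <- which.max(abs(f))
    queen_side <- as.character(pred[i]) == "1"
    if (xor(queen_side, f[i] > 0)) f <- -f
  }
  f
}

# Platt sigmoid calibration: fit p(queen | f) = 1 / (1 + exp(A f + B)) by
# maximum likelihood against Platt's regularised targets, on decision
# values f from held-out predictions. The regularised targets keep the fit
# finite even under perfect separation. Decision values are standardised
# internally for optimiser conditioning; A, B are returned on the raw
# scale.
platt_calibrate <- function(f, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  s <- stats::sd(f)
  if (!is.finite(s) || s == 0) s <- 1
  fs <- f / s
  nll <- function(par) {
    p <- 1 / (1 + exp(par[1] * fs + par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS")
  c(A = fit$par[1] / s, B = fit$par[2])
}

# Held-out decision values for calibration over the given folds.
calibration_decisions <- function(x, y, config, gamma, cost, folds_id) {
  f <- numeric(nrow(x))
  for (fold in unique(folds_id)) {
    tr <- folds_id != fold
    if (length(unique(y[tr])) < 2) { f[!tr] <- 0; next }
    fit <- e1071::svm(x[tr, , drop = FALSE],
                      factor(y[tr], levels = c(0, 1)),
                      kernel = config$kernel, gamma = gamma, cost = cost,
                      scale = FALSE)
    f[!tr] <- decision_queen(fit, x[!tr, , drop = FALSE])
  }
  f
}

# Cross-validated accuracy of one (gamma, cost) point.
cv_accuracy <- function(x, y, config, gamma, cost, folds_id) {
  f <- calibration_decisions(x, y, config, gamma, cost, folds_id)
  mean(ifelse(f == 0, 0.5, (f > 0) == (y == 1)))
}

# Calibrated negative log-likelihood of the true labels given held-out
# decision values (lower is better): the tie-breaker that separates
# hyperparameters which merely get the sign right from those that place
# held-out samples at confident, consistent margins.
cv_logloss <- function(f, y) {
  ab <- platt_calibrate(f, y)
  p <- 1 / (1 + exp(ab["A"] * f + ab["B"]))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a caste SVM with grid-searched hyperparameters
#'
#' Features are standardised on the training block (the scale the gamma
#' grid assumes; stored and re-applied to test samples by [classify()]).
#' Grid search over (gamma, cost) by seeded stratified cross-validated
#' accuracy, then a final refit on all training samples. A Platt sigmoid is
#' fitted to held-out decision values (leave-one-out for small training
#' sets) so that [classify()] returns calibrated queen probabilities even
#' with the handful of samples a comparative design provides. Ties in CV
#' accuracy resolve to the first grid point (smallest gamma, then smallest
#' cost), keeping model selection deterministic.
#'
#' @param x Training samples x features matrix (feature columns named by
#'   orthogroup).
#' @param y Binary caste labels (1 = queen, 0 = worker), both classes
#'   present with >= 2 samples each.
#' @param config An [svm_config()].
#' @param groups Optional grouping label per training sample (e.g. the
#'   species). When given, tuning and calibration use leave-one-group-out
#'   folds, so hyperparameters are selected for, and probabilities are
#'   calibrated on, cross-group generalisation — the relevant regime when
#'   the model will be asked about an unseen species. Without it, seeded
#'   stratified `tuning_folds`-fold CV is used.
#' @return A `caste_svm` list: the fitted e1071 `model`, chosen `gamma`
#'   and `cost`, `cv_accuracy` at the chosen point, and the training
#'   `features`.
#' @export
train_svm <- function(x, y, config = svm_config(), groups = NULL) {
  y <- caste_binary(y)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("need >= 2 training samples in each caste")
  # standardise features on the training block (zero-variance features are
  # left centred only); the hyperparameter grids assume this scale
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  if (!is.null(groups)) {
    if (length(groups) != nrow(x))
      stop("'groups' must give one grouping label per training sample")
    folds_id <- as.integer(factor(groups))
  } else {
    k <- config$tuning_folds
    if (is.null(k)) k <- min(10L, nrow(x))
    k <- max(2L, min(k, nrow(x)))
    folds_id <- stratified_folds(y, k, config$seed)
  }
  grid <- expand.grid(gamma = config$gamma_grid, cost = config$cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  fcv <- lapply(seq_len(nrow(grid)), function(i)
    calibration_decisions(xs, y, config, grid$gamma[i], grid$cost[i],
                          folds_id))
  acc <- vapply(fcv, function(f)
    mean(ifelse(f == 0, 0.5, (f > 0) == (y == 1))), numeric(1))
  ll <- vapply(fcv, cv_logloss, numeric(1), y = y)
  # select by held-out accuracy; break ties towards well-calibrated
  # confident margins, then towards the first grid point
  top <- which(acc == max(acc))
  best <- top[which.min(ll[top])]
  model <- e1071::svm(xs, factor(y, levels = c(0, 1)),
                      kernel = config$kernel, gamma = grid$gamma[best],
                      cost = grid$cost[best], scale = FALSE)
  fcal <- fcv[[best]]
  structure(list(model = model, gamma = grid$gamma[best],
                 cost = grid$cost[best], cv_accuracy = acc[best],
                 platt = platt_calibrate(fcal, y),
                 center = mu, scale = sdv,
                 features = colnames(x), config = config),
            class = "caste_svm")
}

#' Queen-probability classification of test samples
#'
#' Calibrated probability that each test sample is a queen: 1 means
#' maximally queen-like, 0 maximally worker-like, 0.5 that the model cannot
#' tell the castes apart.
#'
#' @param fit A `caste_svm` from [train_svm()].
#' @param newx Test samples x features matrix; its columns must contain
#'   every training feature.
#' @return Numeric vector of queen-class probabilities in [0, 1].
#' @export
classify <- function(fit, newx) {
  stopifnot(inherits(fit, "caste_svm"))
  missing <- setdiff(fit$features, colnames(newx))
  if (length(missing))
    stop("test samples lack training feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  newx <- newx[, fit$features, drop = FALSE]
  newx <- sweep(sweep(newx, 2, fit$center, "-"), 2, fit$scale, "/")
  f <- decision_queen(fit$model, newx)
  p <- 1 / (1 + exp(fit$platt["A"] * f + fit$platt["B"]))
  unname(pmin(pmax(p, 0), 1))
}

# Number of retained features at fraction f of a ranked list.
n_retained <- function(n_features, fraction) {
  pmin(n_features, pmax(1L, ceiling(fraction * n_features)))
}

standardise_train <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(x = sweep(sweep(x, 2, mu, "-"), 2, sdv, "/"), center = mu,
       scale = sdv)
}

# One train/test experiment: rank features on the training block only,
# sweep retention fractions, train at each and classify the test samples.
#
# Hyperparameter selection and probability calibration are fully nested:
# for every leave-one-training-species-out fold the feature ranking itself
# is redone without the held-out species, so the decision values that
# drive both model selection (accuracy, then calibrated log-loss) and the
# Platt fit measure performance on a species that had no say in feature
# selection — the regime the final model faces on the real test species.
run_retention_sweep <- function(values, caste, train_cols, test_cols,
                                fractions, config, ranking = NULL,
                                groups = NULL) {
  y_tr <- caste_binary(caste[train_cols])
  if (is.null(ranking))
    ranking <- rank_features(values[, train_cols, drop = FALSE],
                             y_tr)
  ord <- ranking$orthogroup[order(ranking$rank)]
  n_genes <- length(ord)
  nested <- !is.null(groups) && length(unique(groups)) >= 3
  if (nested) {
    # per-fold rankings are fraction-independent: compute once
    fold_ids <- unique(groups)
    fold_pre <- lapply(fold_ids, function(g) {
      inner <- groups != g
      cols_in <- train_cols[inner]
      rk <- rank_features(values[, cols_in, drop = FALSE],
                          caste_binary(caste[cols_in]))
      list(inner = inner, cols_in = cols_in,
           ord = rk$orthogroup[order(rk$rank)])
    })
    grid <- expand.grid(gamma = config$gamma_grid, cost = config$cost_grid,
                        KEEP.OUT.ATTRS = FALSE)
  }
  res <- lapply(fractions, function(f) {
    nf <- n_retained(n_genes, f)
    feats <- ord[seq_len(nf)]
    if (nested) {
      # held-out decision values per fold, for every grid point
      fmat <- matrix(0, length(train_cols), nrow(grid))
      for (fp in fold_pre) {
        feats_in <- fp$ord[seq_len(nf)]
        std <- standardise_train(t(values[feats_in, fp$cols_in,
                                          drop = FALSE]))
        x_out <- t(values[feats_in, train_cols[!fp$inner], drop = FALSE])
        xs_out <- sweep(sweep(x_out, 2, std$center, "-"), 2, std$scale, "/")
        y_in <- factor(y_tr[fp$inner], levels = c(0, 1))
        for (i in seq_len(nrow(grid))) {
          fit_in <- e1071::svm(std$x, y_in, kernel = config$kernel,
                               gamma = grid$gamma[i], cost = grid$cost[i],
                               scale = FALSE)
          fmat[!fp$inner, i] <- decision_queen(fit_in, xs_out)
        }
      }
      acc <- apply(fmat, 2, function(fv)
        mean(ifelse(fv == 0, 0.5, (fv > 0) == (y_tr == 1))))
      ll <- apply(fmat, 2, cv_logloss, y = y_tr)
      top <- which(acc == max(acc))
      best <- top[which.min(ll[top])]
      std <- standardise_train(t(values[feats, train_cols, drop = FALSE]))
      model <- e1071::svm(std$x, factor(y_tr, levels = c(0, 1)),
                          kernel = config$kernel, gamma = grid$gamma[best],
                          cost = grid$cost[best], scale = FALSE)
      fit <- structure(list(model = model, gamma = grid$gamma[best],
                            cost = grid$cost[best],
                            cv_accuracy = acc[best],
                            platt = platt_calibrate(fmat[, best], y_tr),
                            center = std$center, scale = std$scale,
                            features = feats, config = config),
                       class = "caste_svm")
    } else {
      fit <- train_svm(t(values[feats, train_cols, drop = FALSE]), y_tr,
                       config, groups = groups)
    }
    est <- classify(fit, t(values[feats, test_cols, drop = FALSE]))
    data.frame(fraction = f, n_features = nf,
               sample = test_cols, caste = caste[test_cols],
               estimate_queen = est, gamma = fit$gamma, cost = fit$cost,
               row.names = NULL)
  })
  list(curve = do.call(rbind, res), ranking = ranking)
}

#' Leave-one-species-out caste classification
#'
#' For each species in turn: rank all genes by caste association on the
#' remaining species only (no information from the held-out species leaks
#' into feature selection or tuning), sweep feature-retention fractions,
#' train an SVM at each fraction, and classify the held-out queen and
#' worker samples. The result is one certainty curve per species.
#'
#' @param norm A `normalized_expr` from [normalize_expression()].
#' @param fractions Retention fractions of the ranked gene list (default
#'   0.99 down to 0.01 in steps of 0.01); the retained count is
#'   ceiling(f * n_genes).
#' @param config An [svm_config()].
#' @return A `loo_result` list: `curves` (long data frame: species,
#'   fraction, n_features, caste, estimate_queen, chosen gamma/cost) and
#'   `rankings` (per held-out species, the training-block
#'   [rank_features()] table).
#' @export
leave_one_species_out <- function(norm, fractions = seq(0.99, 0.01, by = -0.01),
                                  config = svm_config()) {
  stopifnot(inherits(norm, "normalized_expr"))
  species <- unique(norm$species)
  if (length(species) < 3) stop("need >= 3 species for leave-one-out")
  curves <- list()
  rankings <- list()
  for (sp in species) {
    test_cols <- which(norm$species == sp)
    train_cols <- which(norm$species != sp)
    sweep <- run_retention_sweep(norm$values, norm$caste, train_cols,
                                 test_cols, fractions, config,
                                 groups = norm$species[train_cols])
    cv <- sweep$curve
    cv$species <- sp
    cv$sample <- colnames(norm$values)[cv$sample]
    curves[[sp]] <- cv
    rankings[[sp]] <- sweep$ranking
  }
  structure(list(curves = do.call(rbind, curves), rankings = rankings,
                 fractions = fractions),
            class = "loo_result")
}

#' Group-to-group caste transfer classification
#'
#' Trains on all samples of a fixed set of species and classifies each test
#' species in turn, sweeping feature-retention fractions; the vehicle for
#' asking whether a toolkit learned in one kind of society (simple,
#' swarm-founding, one subfamily) predicts caste in another. The toolkit
#' gene set extracted from the experiment is the set of genes whose
#' caste regression is significant (p < `toolkit_p`) in the training block.
#'
#' @param norm A `normalized_expr`.
#' @param train_species,test_species Disjoint character vectors of species
#'   names.
#' @inheritParams leave_one_species_out
#' @param toolkit_p Regression significance cut-off defining the toolkit
#'   set (default 0.05).
#' @return A `transfer_result` list: `curves`, the training-block
#'   `ranking`, and `toolkit` (orthogroup IDs significant at `toolkit_p`).
#' @export
group_transfer <- function(norm, train_species, test_species,
                           fractions = seq(0.99, 0.01, by = -0.01),
                           config = svm_config(), toolkit_p = 0.05) {
  stopifnot(inherits(norm, "normalized_expr"))
  if (length(intersect(train_species, test_species)))
    stop("training and test species sets must be disjoint")
  species <- unique(norm$species)
  if (!all(c(train_species, test_species) %in% species))
    stop("unknown species name(s)")
  train_cols <- which(norm$species %in% train_species)
  ranking <- rank_features(norm$values[, train_cols, drop = FALSE],
                           caste_binary(norm$caste[train_cols]))
  curves <- list()
  for (sp in test_species) {
    test_cols <- which(norm$species == sp)
    sweep <- run_retention_sweep(norm$values, norm$caste, train_cols,
                                 test_cols, fractions, config,
                                 ranking = ranking,
                                 groups = norm$species[train_cols])
    cv <- sweep$curve
    cv$species <- sp
    cv$sample <- colnames(norm$values)[cv$sample]
    curves[[sp]] <- cv
  }
  structure(list(curves = do.call(rbind, curves), ranking = ranking,
                 toolkit = ranking$orthogroup[ranking$p < toolkit_p],
                 train_species = train_species,
                 test_species = test_species, fractions = fractions),
            class = "transfer_result")
}

#' Toolkit gene set from a leave-one-species-out experiment
#'
#' The orthogroups whose caste regression is significant in every
#' training-block ranking of the experiment: genes that carry a consistent
#' caste signal no matter which species is withheld.
#'
#' @param loo A `loo_result` from [leave_one_species_out()].
#' @param p_cutoff Regression p-value cut-off (default 0.05).
#' @return Character vector of orthogroup IDs.
#' @export
toolkit_genes <- function(loo, p_cutoff = 0.05) {
  stopifnot(inherits(loo, "loo_result"))
  sets <- lapply(loo$rankings, function(r) r$orthogroup[r$p < p_cutoff])
  Reduce(intersect, sets)
}

#' Learning curves: tuning-block CV error across feature retention
#'
#' On a fixed block of samples (e.g. the training species of one
#' leave-one-out replicate): at each retention fraction, tune the SVM and
#' measure its stratified k-fold cross-validation misclassification
#' error. Within each CV fold the feature ranking is recomputed from that
#' fold's training samples only, so the error estimate does not inherit
#' the optimism of selecting features on the very samples being held out
#' (on null data the error sits near 0.5 rather than collapsing to 0).
#'
#' @param norm A `normalized_expr`, or a genes x samples matrix with caste
#'   labels supplied via `caste`.
#' @param fractions Retention fractions to evaluate.
#' @param folds CV folds for the error estimate (default 6).
#' @param config An [svm_config()].
#' @param caste Caste labels when `norm` is a bare matrix.
#' @return Data frame with columns `fraction`, `n_features`, `cv_error`,
#'   `gamma`, `cost`.
#' @export
learning_curves <- function(norm, fractions = seq(0.99, 0.01, by = -0.01),
                            folds = 6L, config = svm_config(),
                            caste = NULL) {
  groups <- NULL
  if (inherits(norm, "normalized_expr")) {
    values <- norm$values
    caste <- norm$caste
    groups <- norm$species
  } else {
    values <- norm
    if (is.null(caste)) stop("'caste' labels required for a bare matrix")
  }
  y <- caste_binary(caste)
  if (folds > ncol(values)) stop("more folds than samples")
  ranking <- rank_features(values, y)
  ord <- ranking$orthogroup[order(ranking$rank)]
  # With the two-sample design every worker profile is the exact mirror
  # of its species' queen, so folds that split a species place a twin of
  # each held-out sample in the training half and the error collapses
  # regardless of signal. Folds therefore hold out whole species when
  # species labels are available.
  if (!is.null(groups)) {
    lev <- unique(groups)
    set.seed(config$seed)
    sp_fold <- stats::setNames(rep_len(seq_len(min(folds, length(lev))),
                                       length(lev)), sample(lev))
    folds_id <- unname(sp_fold[groups])
  } else {
    folds_id <- stratified_folds(y, folds, config$seed)
  }
  # fold-wise rankings are fraction-independent
  fold_ord <- lapply(sort(unique(folds_id)), function(fd) {
    tr <- folds_id != fd
    rk <- rank_features(values[, tr, drop = FALSE], y[tr])
    rk$orthogroup[order(rk$rank)]
  })
  out <- lapply(fractions, function(f) {
    nf <- n_retained(length(ord), f)
    x <- t(values[ord[seq_len(nf)], , drop = FALSE])
    fit <- train_svm(x, y, config, groups = groups)
    correct <- 0L
    for (fd in sort(unique(folds_id))) {
      tr <- folds_id != fd
      if (length(unique(y[tr])) < 2) next
      feats <- fold_ord[[fd]][seq_len(nf)]
      std <- standardise_train(t(values[feats, tr, drop = FALSE]))
      fit_in <- e1071::svm(std$x, factor(y[tr], levels = c(0, 1)),
                           kernel = config$kernel, gamma = fit$gamma,
                           cost = fit$cost, scale = FALSE)
      x_out <- t(values[feats, !tr, drop = FALSE])
      xs_out <- sweep(sweep(x_out, 2, std$center, "-"), 2, std$scale, "/")
      pred <- stats::predict(fit_in, xs_out)
      correct <- correct + sum(pred == y[!tr])
    }
    data.frame(fraction = f, n_features = nf,
               cv_error = 1 - correct / length(y),
               gamma = fit$gamma, cost = fit$cost)
  })
  do.call(rbind, out)
}
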