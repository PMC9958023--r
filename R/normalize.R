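#' Transcripts per million from a harmonised count matrix
#'
#' Length-normalised abundance per sample: for each sample the count of
#' each orthogroup is divided by its effective length, and the resulting
#' rates are scaled to sum to one million. Columns are the
#' `<species>_queen` / `<species>_worker` samples.
#'
#' @param h A `harmonized_expr` from [harmonize()] / [fill_missing()].
#' @return Numeric matrix (orthogroups x samples) with column sums 1e6,
#'   plus attributes `species` and `caste` describing the columns.
#' @export
compute_tpm <- function(h) {
  stopifnot(inherits(h, "harmonized_expr"))
  species <- colnames(h$queen)
  cnt <- cbind(h$queen, h$worker)
  len <- cbind(h$length, h$length)
  colnames(cnt) <- c(paste0(species, "_queen"), paste0(species, "_worker"))
  rate <- cnt / len
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample with zero total count/length rate")
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  attr(tpm, "species") <- rep(species, 2)
  attr(tpm, "caste") <- rep(c("queen", "worker"), each = length(species))
  tpm
}

#' Log-transform and quantile-normalise an expression matrix
#'
#' Applies `log2(x + pseudocount)` and then quantile normalisation jointly
#' across all samples: each column's sorted values are replaced by the
#' row-wise mean of the sorted columns (ties averaged), so afterwards every
#' sample shares an identical distribution of values.
#'
#' @param mat Non-negative matrix (genes x samples), e.g. TPMs.
#' @param pseudocount Added before the log to keep zeros finite
#'   (default 1).
#' @return Matrix of the same shape; column attributes are preserved.
#' @export
log_quantile <- function(mat, pseudocount = 1) {
  if (any(mat < 0)) stop("input must be non-negative")
  out <- limma::normalizeQuantiles(log2(mat + pseudocount), ties = TRUE)
  dimnames(out) <- dimnames(mat)
  attr(out, "species") <- attr(mat, "species")
  attr(out, "caste") <- attr(mat, "caste")
  out
}

#' Species-mean scaling onto the [-1, 1] caste axis
#'
#' For each gene within each species, every sample value x is replaced by
#' (x - m) / m where m is the gene's mean over that species' samples. This
#' removes species-level location and scale, leaving only relative
#' queen/worker contrast: with the two-sample design the queen value equals
#' (Q - W) / (Q + W) and the worker value its negation, so each value lies
#' in [-1, 1] and the two castes sum to zero. Genes with m = 0 in a species
#' are set to 0 for that species (and counted in attribute `zero_mean`);
#' upstream low-expression filtering should make this unreachable.
#'
#' @param mat Non-negative matrix (genes x samples).
#' @param species Character vector assigning each column to a species;
#'   defaults to the matrix's `species` attribute.
#' @return Matrix of scaled values in [-1, 1] with the column attributes
#'   preserved and attribute `zero_mean` (number of zero-mean gene/species
#'   events).
#' @export
species_scale <- function(mat, species = attr(mat, "species")) {
  if (is.null(species) || length(species) != ncol(mat))
    stop("'species' must assign each column to a species")
  out <- mat
  zero_events <- 0L
  for (sp in unique(species)) {
    cols <- species == sp
    m <- rowMeans(mat[, cols, drop = FALSE])
    zero <- m == 0
    zero_events <- zero_events + sum(zero)
    m[zero] <- 1 # placeholder; affected rows are zeroed below
    out[, cols] <- (mat[, cols, drop = FALSE] - m) / m
    out[zero, cols] <- 0
  }
  attr(out, "species") <- attr(mat, "species")
  attr(out, "caste") <- attr(mat, "caste")
  attr(out, "zero_mean") <- zero_events
  out
}

#' Low-expression orthogroup filter
#'
#' Flags orthogroups for removal when, in at least one species, the counts
#' per million fall below `threshold_cpm` in both the queen and the worker
#' sample: one quietly-expressed species is enough to disqualify the row,
#' but a single well-expressed caste rescues its species. Cells that were
#' pseudo-filled for missing orthologs carry no real expression evidence
#' and are ignored by the filter.
#'
#' @param h A `harmonized_expr`.
#' @param threshold_cpm CPM threshold (default 10).
#' @return Named logical vector, TRUE for orthogroups to keep.
#' @export
filter_low_expression <- function(h, threshold_cpm = 10) {
  stopifnot(inherits(h, "harmonized_expr"))
  cpm_q <- sweep(h$queen, 2, h$lib_sizes[, "queen"], "/") * 1e6
  cpm_w <- sweep(h$worker, 2, h$lib_sizes[, "worker"], "/") * 1e6
  low_both <- (cpm_q < threshold_cpm) & (cpm_w < threshold_cpm) & !h$filled
  keep <- rowSums(low_both) == 0
  names(keep) <- rownames(h$queen)
  keep
}

#' Full normalisation chain to the species-free expression matrix
#'
#' Runs the pipeline's transform chain in order: low-expression filtering
#' on raw counts, TPM, log2(+pseudocount), joint quantile normalisation,
#' then species-mean scaling onto [-1, 1]. The chain is deterministic.
#'
#' @param h A `harmonized_expr`.
#' @param cpm_min CPM threshold for [filter_low_expression()]; use `NULL`
#'   to skip filtering.
#' @param pseudocount Log pseudocount (default 1).
#' @return A `normalized_expr` object: `values` (orthogroups x samples in
#'   [-1, 1]), `species` and `caste` per column, `steps` applied, and the
#'   filter `mask`.
#' @export
normalize_expression <- function(h, cpm_min = 10, pseudocount = 1) {
  stopifnot(inherits(h, "harmonized_expr"))
  mask <- if (is.null(cpm_min)) {
    stats::setNames(rep(TRUE, nrow(h$queen)), rownames(h$queen))
  } else filter_low_expression(h, cpm_min)
  hf <- h
  for (fld in c("queen", "worker", "length", "gene_id", "filled",
                "collapsed_n"))
    hf[[fld]] <- h[[fld]][mask, , drop = FALSE]
  tpm <- compute_tpm(hf)
  lq <- log_quantile(tpm, pseudocount = pseudocount)
  sc <- species_scale(lq)
  structure(list(values = sc, species = attr(tpm, "species"),
                 caste = attr(tpm, "caste"),
                 steps = c(sprintf("cpm_filter(min=%s)",
                                   if (is.null(cpm_min)) "none" else cpm_min),
                           "tpm", sprintf("log2(+%g)", pseudocount),
                           "quantile", "species_scale"),
                 mask = mask, mode = h$mode),
            class = "normalized_expr")
}

#' @export
print.normalized_expr <- function(x, ...) {
  cat("normalized_expr [", x$mode, "]: ", nrow(x$values), " orthogroups x ",
      ncol(x$values), " samples\n  steps: ",
      paste(x$steps, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of samples
#'
#' Centred PCA of the samples (columns) of an expression matrix; a quick
#' view of whether species or caste dominates the variance structure.
#'
#' @param mat Matrix (genes x samples) or a `normalized_expr`.
#' @param n_components Number of components to return (capped at the rank).
#' @return List with `scores` (samples x components) and
#'   `variance_fraction` per component (non-increasing, sums to <= 1).
#' @export
pca_samples <- function(mat, n_components = 2) {
  if (inherits(mat, "normalized_expr")) mat <- mat$values
  if (ncol(mat) < 2) stop("need at least 2 samples")
  fit <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  varfrac <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       variance_fraction = varfrac[seq_len(k)])
}

#' Mean silhouette width of a labelling on sample coordinates
#'
#' Measures how well a grouping (species, caste) explains sample positions,
#' e.g. on the first two principal components.
#'
#' @param scores Numeric matrix, samples x coordinates.
#' @param labels Grouping vector, one per sample (>= 2 groups).
#' @return Mean silhouette width (in [-1, 1]).
#' @export
silhouette_width <- function(scores, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 groups")
  sil <- cluster::silhouette(labels, stats::dist(scores))
  mean(sil[, "sil_width"])
}
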