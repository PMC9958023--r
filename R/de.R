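#' Fixed-dispersion negative binomial conditional exact test
#'
#' Exact two-sided test for a difference in relative abundance between one
#' pooled queen and one pooled worker count, under a negative binomial
#' model with a fixed, known dispersion. With no replication the dispersion
#' cannot be estimated, so it is supplied (default 0.1, a typical value for
#' pooled bulk RNA-seq).
#'
#' Counts are first rescaled to the geometric mean of the two library
#' sizes. Conditional on the (rounded) rescaled total t, each split
#' (a, t - a) is weighted by the product of two NB(t/2, dispersion)
#' probabilities; the conditional split distribution is in fact free of the
#' mean, so the test is exact given t. The two-sided p-value sums the
#' probabilities of all splits no more likely than the observed one
#' (small-p-sum convention), which guarantees p <= 1 and equals 1 for a
#' perfectly balanced observation.
#'
#' @param count_q,count_w Non-negative counts (vectors allowed, recycled
#'   pairwise).
#' @param lib_q,lib_w Library sizes (> 0).
#' @param dispersion NB dispersion phi (> 0); variance = mu + phi * mu^2.
#' @return P-values in (0, 1]; a (0, 0) pair carries no information and
#'   returns 1.
#' @examples
#' nb_exact_test(0, 20, 1e6, 1e6)    # strongly unbalanced
#' nb_exact_test(15, 15, 1e6, 1e6)   # balanced: p = 1
#' @export
nb_exact_test <- function(count_q, count_w, lib_q, lib_w, dispersion = 0.1) {
  stopifnot(all(count_q >= 0), all(count_w >= 0),
            all(lib_q > 0), all(lib_w > 0), dispersion > 0)
  n <- max(length(count_q), length(count_w))
  count_q <- rep_len(count_q, n); count_w <- rep_len(count_w, n)
  lib_q <- rep_len(lib_q, n); lib_w <- rep_len(lib_w, n)
  r <- 1 / dispersion
  vapply(seq_len(n), function(i) {
    L <- sqrt(lib_q[i] * lib_w[i])
    q <- count_q[i] * L / lib_q[i]
    w <- count_w[i] * L / lib_w[i]
    s <- q + w
    t <- round(s)
    if (t == 0) return(1)
    mu <- s / 2
    # conditional split weights on the integer support; the observed
    # (possibly non-integer after library rescaling) pair is scored with
    # the same continuously-extended log-density, which keeps the test
    # exactly symmetric under caste swap
    lg <- ldnbinom(0:t, r, mu)
    lp <- lg + rev(lg)
    lp_obs <- ldnbinom(q, r, mu) + ldnbinom(w, r, mu)
    m <- max(lp)
    pr <- exp(lp - m)
    tot <- sum(pr)
    min(1, sum(pr[pr <= exp(lp_obs - m)]) / tot)
  }, numeric(1))
}

# NB log-density continuously extended to non-integer x via the gamma
# function; coincides with dnbinom(x, size = r, mu = mu, log = TRUE) on
# integers.
ldnbinom <- function(x, r, mu) {
  lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
    r * log(r / (r + mu)) + x * log(mu / (r + mu))
}

#' Library-size-adjusted log2 fold change with a prior count
#'
#' Queen/worker log2 ratio after rescaling both counts to the geometric
#' mean library size, with a prior count added to each side to shrink fold
#' changes of low counts; antisymmetric under caste swap.
#'
#' @inheritParams nb_exact_test
#' @param prior_count Prior added to each rescaled count (default 0.5).
#' @return log2((q' + prior) / (w' + prior)) where q', w' are the rescaled
#'   counts.
#' @export
log2_fold_change <- function(count_q, count_w, lib_q, lib_w,
                             prior_count = 0.5) {
  L <- sqrt(lib_q * lib_w)
  q <- count_q * L / lib_q
  w <- count_w * L / lib_w
  log2((q + prior_count) / (w + prior_count))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order preserved, values monotone in rank
#' and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-species caste differential expression over a harmonised matrix
#'
#' Runs the fixed-dispersion exact test for every (orthogroup, species)
#' cell of a harmonised matrix, with BH-FDR correction within each
#' species. Filled pseudo-cells are tested like any other (their equal
#' queen/worker counts make them caste-neutral by construction) but are
#' flagged in the output.
#'
#' @param h A `harmonized_expr`.
#' @param dispersion NB dispersion (default 0.1).
#' @param prior_count Prior for [log2_fold_change()].
#' @param keep Optional logical mask of orthogroups to test (e.g. from
#'   [filter_low_expression()]).
#' @return Data frame of class `deg_table` with columns `orthogroup`,
#'   `species`, `log2fc`, `p`, `fdr`, `filled`.
#' @export
de_test <- function(h, dispersion = 0.1, prior_count = 0.5, keep = NULL) {
  stopifnot(inherits(h, "harmonized_expr"))
  ogs <- rownames(h$queen)
  if (!is.null(keep)) ogs <- ogs[keep[ogs]]
  species <- colnames(h$queen)
  res <- do.call(rbind, lapply(species, function(sp) {
    q <- h$queen[ogs, sp]; w <- h$worker[ogs, sp]
    lq <- h$lib_sizes[sp, "queen"]; lw <- h$lib_sizes[sp, "worker"]
    p <- nb_exact_test(q, w, lq, lw, dispersion = dispersion)
    data.frame(orthogroup = ogs, species = sp,
               log2fc = log2_fold_change(q, w, lq, lw,
                                         prior_count = prior_count),
               p = p, fdr = bh_fdr(p), filled = h$filled[ogs, sp],
               row.names = NULL)
  }))
  class(res) <- c("deg_table", "data.frame")
  res
}

#' Call directed caste-biased gene sets per species
#'
#' Applies a significance rule to a [de_test()] table and returns, for each
#' species, the orthogroups passing it with their bias direction (queen if
#' log2fc > 0, worker if < 0).
#'
#' @param deg_table A `deg_table` from [de_test()].
#' @param rule `"fdr_0.05"` (BH-adjusted p < 0.05) or `"raw_p_0.05"`
#'   (unadjusted p < 0.05, the cross-species comparison rule).
#' @param alpha Cut-off (default 0.05).
#' @return Named list (per species) of data frames with columns
#'   `orthogroup` and `direction`.
#' @export
call_degs <- function(deg_table, rule = c("fdr_0.05", "raw_p_0.05"),
                      alpha = 0.05) {
  rule <- match.arg(rule)
  crit <- if (rule == "fdr_0.05") deg_table$fdr < alpha
          else deg_table$p < alpha
  crit <- crit & deg_table$log2fc != 0
  hits <- deg_table[crit, , drop = FALSE]
  out <- lapply(split(hits, hits$species), function(d)
    data.frame(orthogroup = d$orthogroup,
               direction = ifelse(d$log2fc > 0, "queen", "worker"),
               row.names = NULL))
  # species with no hits still get an (empty) entry
  for (sp in setdiff(unique(deg_table$species), names(out)))
    out[[sp]] <- data.frame(orthogroup = character(0),
                            direction = character(0))
  out[unique(deg_table$species)]
}
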