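#' Collapse within-species isoforms to a single representative gene
#'
#' Where an orthogroup has several member genes in one species (isoform
#' duplications from de novo assemblies, recent paralogs), only the most
#' highly expressed member is kept to represent the orthogroup in that
#' species. Orthogroups where any species exceeds `max_isoforms` members
#' are dropped entirely; the drop reasons are recorded.
#'
#' "Most highly expressed" is measured as the queen + worker summed raw
#' count; ties break lexicographically on gene ID so the collapse is
#' deterministic.
#'
#' @param counts A [caste_counts()].
#' @param map An [orthogroup_map()]; every listed gene must exist in the
#'   corresponding species' count table.
#' @param max_isoforms Maximum members per (orthogroup, species) cell before
#'   the orthogroup is discarded (default 3).
#' @return An `orthogroup_map` with at most one member gene per cell, plus
#'   attributes `collapsed_n` (integer matrix of original member counts) and
#'   `dropped` (data frame of removed orthogroups with reasons).
#' @export
collapse_isoforms <- function(counts, map, max_isoforms = 3L) {
  stopifnot(inherits(counts, "caste_counts"), inherits(map, "orthogroup_map"),
            max_isoforms >= 1)
  totals <- lapply(counts$tables, function(tab) {
    tot <- tab$queen + tab$worker
    names(tot) <- tab$gene_id
    tot
  })
  nmem <- member_counts(map)
  keep <- rowSums(nmem > max_isoforms) == 0
  dropped <- data.frame(orthogroup = rownames(nmem)[!keep],
                        reason = rep(sprintf("more than %d members in >=1 species",
                                             max_isoforms), sum(!keep)))
  members <- map$members[keep]
  for (og in names(members)) {
    for (sp in map$species) {
      genes <- members[[og]][[sp]]
      if (length(genes) > 1L) {
        tot <- totals[[sp]][genes]
        if (anyNA(tot))
          stop("gene(s) ", paste(genes[is.na(tot)], collapse = ", "),
               " in orthogroup ", og, " missing from counts of ", sp)
        genes <- genes[order(-tot, genes)]
        members[[og]][[sp]] <- genes[1L]
      } else if (length(genes) == 1L && !genes %in% names(totals[[sp]])) {
        stop("gene ", genes, " in orthogroup ", og,
             " missing from counts of ", sp)
      }
    }
  }
  out <- orthogroup_map(members, species = map$species)
  attr(out, "collapsed_n") <- nmem[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Restrict a map to strict single-copy orthogroups
#'
#' Keeps only orthogroups with exactly one member gene in every species:
#' the classical single-copy ortholog set, free of isoform collapse and
#' missing-data fill.
#'
#' @param map An [orthogroup_map()].
#' @return The filtered `orthogroup_map`.
#' @export
strict_single_copy <- function(map) {
  stopifnot(inherits(map, "orthogroup_map"))
  nmem <- member_counts(map)
  keep <- rowSums(nmem == 1L) == ncol(nmem)
  out <- orthogroup_map(map$members[keep], species = map$species)
  attr(out, "dropped") <- data.frame(
    orthogroup = rownames(nmem)[!keep],
    reason = rep("not single-copy in every species", sum(!keep)))
  out
}

#' Build a harmonised orthogroup x (species, caste) count matrix
#'
#' Resolves a collapsed orthogroup map against the count tables, optionally
#' tolerating orthogroups with missing genes in up to `max_missing_species`
#' species. A missing (orthogroup, species) cell is filled with a neutral
#' pseudo-gene: `fill_count` raw reads in both the queen and the worker
#' sample, with the median effective length of the orthogroup's present
#' members. Orthogroups missing in more species are dropped.
#'
#' @param map An [orthogroup_map()] with at most one member per cell (after
#'   [collapse_isoforms()] or [strict_single_copy()]).
#' @param counts A [caste_counts()].
#' @param max_missing_species Maximum species allowed to lack the
#'   orthogroup (default 2); must be < number of species.
#' @param fill_count Raw count injected per caste for filled cells
#'   (default 10).
#' @return A `harmonized_expr` object: count matrices `queen` and `worker`
#'   (orthogroups x species), `length` and `gene_id` matrices, flag matrices
#'   `filled` (logical) and `collapsed_n` (members before collapse),
#'   `lib_sizes`, and a `dropped` audit table.
#' @export
fill_missing <- function(map, counts, max_missing_species = 2L,
                         fill_count = 10L) {
  stopifnot(inherits(map, "orthogroup_map"), inherits(counts, "caste_counts"))
  if (max_missing_species >= length(map$species))
    stop("max_missing_species must be smaller than the number of species")
  nmem <- member_counts(map)
  if (any(nmem > 1L))
    stop("map has cells with >1 member; run collapse_isoforms() first")
  n_missing <- rowSums(nmem == 0L)
  keep <- n_missing <= max_missing_species
  dropped <- data.frame(orthogroup = rownames(nmem)[!keep],
                        reason = sprintf("missing in %d species (max %d)",
                                         n_missing[!keep],
                                         max_missing_species))
  build_harmonized(map, counts, keep, fill_count = fill_count,
                   dropped = dropped,
                   mode = if (max_missing_species > 0) "isoforms_na"
                          else "complete")
}

# shared constructor for harmonized_expr
build_harmonized <- function(map, counts, keep, fill_count, dropped, mode) {
  ogs <- names(map$members)[keep]
  species <- map$species
  idx <- lapply(counts$tables, function(tab) {
    i <- seq_len(nrow(tab))
    names(i) <- tab$gene_id
    i
  })
  dims <- list(ogs, species)
  queen <- worker <- len <- matrix(NA_real_, length(ogs), length(species),
                                   dimnames = dims)
  gene_id <- matrix(NA_character_, length(ogs), length(species),
                    dimnames = dims)
  filled <- matrix(FALSE, length(ogs), length(species), dimnames = dims)
  for (og in ogs) {
    for (sp in species) {
      g <- map$members[[og]][[sp]]
      if (length(g)) {
        i <- idx[[sp]][g]
        if (is.na(i))
          stop("gene ", g, " in orthogroup ", og,
               " missing from counts of ", sp)
        row <- counts$tables[[sp]][i, ]
        queen[og, sp] <- row$queen
        worker[og, sp] <- row$worker
        len[og, sp] <- row$length
        gene_id[og, sp] <- g
      }
    }
    miss <- is.na(queen[og, ])
    if (any(miss)) {
      queen[og, miss] <- fill_count
      worker[og, miss] <- fill_count
      len[og, miss] <- stats::median(len[og, !miss])
      filled[og, miss] <- TRUE
    }
  }
  collapsed_n <- attr(map, "collapsed_n")
  collapsed_n <- if (is.null(collapsed_n))
    matrix(1L, length(ogs), length(species), dimnames = dims)
  else collapsed_n[ogs, , drop = FALSE]
  prior_drops <- attr(map, "dropped")
  if (!is.null(prior_drops)) dropped <- rbind(prior_drops, dropped)
  structure(list(queen = queen, worker = worker, length = len,
                 gene_id = gene_id, filled = filled,
                 collapsed_n = collapsed_n,
                 lib_sizes = counts$lib_sizes[species, , drop = FALSE],
                 mode = mode, dropped = dropped),
            class = "harmonized_expr")
}

#' @export
print.harmonized_expr <- function(x, ...) {
  cat("harmonized_expr [", x$mode, "]: ", nrow(x$queen), " orthogroups x ",
      ncol(x$queen), " species; ", sum(x$filled), " filled cells, ",
      sum(x$collapsed_n > 1), " collapsed cells; ", nrow(x$dropped),
      " orthogroups dropped\n", sep = "")
  invisible(x)
}

#' Harmonise counts onto orthogroup rows under a named mode
#'
#' Convenience wrapper around the harmonisation operators implementing the
#' three inclusion regimes used throughout the pipeline:
#' \describe{
#'   \item{`strict`}{true single-copy orthogroups only (one gene in every
#'     species); no collapse, no fill.}
#'   \item{`iso3`}{up to 3 isoforms per species collapsed to the most
#'     highly expressed; orthogroup must still be present in all species.}
#'   \item{`iso3na2`}{as `iso3`, additionally tolerating up to 2 species
#'     with a missing gene, filled with `fill_count` reads per caste.}
#' }
#' The retained row sets nest: strict is a subset of iso3, which is a
#' subset of iso3na2.
#'
#' @param counts A [caste_counts()].
#' @param map An [orthogroup_map()].
#' @param mode One of `"strict"`, `"iso3"`, `"iso3na2"`.
#' @param max_isoforms,max_missing_species,fill_count Rule parameters; see
#'   [collapse_isoforms()] and [fill_missing()].
#' @return A `harmonized_expr` object (see [fill_missing()]).
#' @export
harmonize <- function(counts, map, mode = c("strict", "iso3", "iso3na2"),
                      max_isoforms = 3L, max_missing_species = 2L,
                      fill_count = 10L) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    m <- strict_single_copy(map)
    out <- fill_missing(m, counts, max_missing_species = 0L,
                        fill_count = fill_count)
  } else {
    m <- collapse_isoforms(counts, map, max_isoforms = max_isoforms)
    out <- fill_missing(m, counts,
                        max_missing_species =
                          if (mode == "iso3") 0L else max_missing_species,
                        fill_count = fill_count)
  }
  out$mode <- mode
  out
}
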