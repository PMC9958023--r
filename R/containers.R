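#' Per-species caste count tables
#'
#' Bundles one gene-level count table per species, each with gene effective
#' lengths and a single pooled sample per caste (queen, worker), together
#' with per-sample library sizes. This is the raw-count entry point of the
#' pipeline: real data arrives here via [read_count_tables()], synthetic
#' data via [generate_dataset()].
#'
#' @param tables Named list (one element per species) of data frames with
#'   columns `gene_id`, `length`, `queen`, `worker`. Gene IDs must be unique
#'   within a species and lengths strictly positive.
#' @param lib_sizes Optional numeric matrix (species x c("queen","worker")).
#'   Defaults to the column sums of each species' counts, i.e. the totals of
#'   the assembled table stand in for sequencing depth.
#' @return An object of class `caste_counts`.
#' @export
caste_counts <- function(tables, lib_sizes = NULL) {
  if (!is.list(tables) || is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a named list of per-species data frames")
  for (sp in names(tables)) {
    tab <- tables[[sp]]
    need <- c("gene_id", "length", "queen", "worker")
    if (!all(need %in% colnames(tab)))
      stop("species '", sp, "': table must have columns ",
           paste(need, collapse = ", "))
    if (anyDuplicated(tab$gene_id))
      stop("species '", sp, "': duplicated gene IDs")
    if (any(tab$length <= 0))
      stop("species '", sp, "': gene lengths must be > 0")
    if (any(tab$queen < 0) || any(tab$worker < 0))
      stop("species '", sp, "': counts must be non-negative")
    tables[[sp]] <- tab[, need]
  }
  if (is.null(lib_sizes)) {
    lib_sizes <- t(vapply(tables, function(tab)
      c(queen = sum(tab$queen), worker = sum(tab$worker)), numeric(2)))
  } else {
    lib_sizes <- as.matrix(lib_sizes)
    if (!identical(sort(rownames(lib_sizes)), sort(names(tables))))
      stop("'lib_sizes' rownames must match species names")
    lib_sizes <- lib_sizes[names(tables), c("queen", "worker"), drop = FALSE]
  }
  if (any(lib_sizes <= 0))
    stop("library sizes must be > 0")
  structure(list(tables = tables, lib_sizes = lib_sizes),
            class = "caste_counts")
}

#' @export
print.caste_counts <- function(x, ...) {
  cat("caste_counts:", length(x$tables), "species\n")
  for (sp in names(x$tables))
    cat(sprintf("  %-10s %6d genes  lib(Q)=%.3g lib(W)=%.3g\n", sp,
                nrow(x$tables[[sp]]), x$lib_sizes[sp, "queen"],
                x$lib_sizes[sp, "worker"]))
  invisible(x)
}

#' Species present in a count object
#' @param counts A `caste_counts` object.
#' @return Character vector of species names.
#' @export
species_names <- function(counts) names(counts$tables)

#' Orthogroup membership map
#'
#' An orthogroup map relates cross-species orthogroup rows to the member
#' gene IDs of each species, in the Orthofinder `Orthogroups.tsv` sense: an
#' orthogroup may have 0 (missing), 1, or several (isoform/paralog) member
#' genes per species.
#'
#' @param members Named list: orthogroup ID -> named list: species ->
#'   character vector of member gene IDs (possibly empty).
#' @param species Character vector fixing the species universe (and column
#'   order); defaults to the union seen in `members`.
#' @return An object of class `orthogroup_map`.
#' @export
orthogroup_map <- function(members, species = NULL) {
  if (is.null(species))
    species <- unique(unlist(lapply(members, names)))
  members <- lapply(members, function(m) {
    m <- m[intersect(names(m), species)]
    miss <- setdiff(species, names(m))
    m[miss] <- list(character(0))
    lapply(m[species], as.character)
  })
  structure(list(members = members, species = species),
            class = "orthogroup_map")
}

#' @export
print.orthogroup_map <- function(x, ...) {
  cat("orthogroup_map:", length(x$members), "orthogroups x",
      length(x$species), "species\n")
  invisible(x)
}

#' @export
length.orthogroup_map <- function(x) length(x$members)

#' Number of member genes per (orthogroup, species) cell
#' @param map An `orthogroup_map`.
#' @return Integer matrix, orthogroups x species.
#' @export
member_counts <- function(map) {
  out <- vapply(map$members,
                function(m) vapply(m, length, integer(1)),
                integer(length(map$species)))
  if (length(map$species) == 1L) out <- matrix(out, nrow = 1)
  out <- t(out)
  dimnames(out) <- list(names(map$members), map$species)
  out
}

#' Write / read an Orthogroups.tsv table
#'
#' The Orthofinder dialect: a header row of species names after an
#' `Orthogroup` column, one row per orthogroup, each species cell a
#' comma-space-separated gene list; an empty cell means the species has no
#' member.
#'
#' @param map An `orthogroup_map`.
#' @param path File path.
#' @return `write_orthogroups` returns `path` invisibly;
#'   `read_orthogroups` returns an `orthogroup_map`.
#' @export
write_orthogroups <- function(map, path) {
  rows <- vapply(names(map$members), function(og) {
    cells <- vapply(map$members[[og]],
                    function(g) paste(g, collapse = ", "), character(1))
    paste(c(og, cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("Orthogroup", map$species), collapse = "\t"), rows),
             path)
  invisible(path)
}

#' @rdname write_orthogroups
#' @export
read_orthogroups <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  species <- colnames(tab)[-1]
  members <- lapply(seq_len(nrow(tab)), function(i) {
    m <- lapply(species, function(sp) {
      cell <- tab[i, sp]
      if (is.na(cell) || !nzchar(cell)) character(0)
      else strsplit(cell, ",[ ]?")[[1]]
    })
    names(m) <- species
    m
  })
  names(members) <- tab[[1]]
  orthogroup_map(members, species = species)
}

#' Write / read per-species count tables
#'
#' One TSV per species (columns `gene_id`, `length`, `queen_count`,
#' `worker_count`) named `<species>.counts.tsv` under `dir`.
#'
#' @param counts A `caste_counts` object.
#' @param dir Directory (created if absent).
#' @return `write_count_tables` returns `dir` invisibly;
#'   `read_count_tables` returns a `caste_counts`.
#' @export
write_count_tables <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in species_names(counts)) {
    tab <- counts$tables[[sp]]
    out <- data.frame(gene_id = tab$gene_id, length = tab$length,
                      queen_count = tab$queen, worker_count = tab$worker)
    utils::write.table(out, file.path(dir, paste0(sp, ".counts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_count_tables
#' @export
read_count_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.counts\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no *.counts.tsv files under ", dir)
  tables <- lapply(files, function(f) {
    tab <- utils::read.delim(f)
    data.frame(gene_id = as.character(tab$gene_id), length = tab$length,
               queen = tab$queen_count, worker = tab$worker_count)
  })
  names(tables) <- sub("\\.counts\\.tsv$", "", basename(files))
  caste_counts(tables)
}
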