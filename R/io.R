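# Readers, writers, label alignment and configuration.
#
# Interchange dialect: comma-separated UTF-8 text with a header row;
# per-mil values as plain decimals. Species names are matched
# case-insensitively after trimming, with underscores and spaces treated as
# equivalent (Newick files usually carry underscores, field tables spaces).

#' Normalize a species name for matching
#'
#' Trims whitespace, lower-cases, and maps underscores to spaces so that
#' labels from Newick files and field tables compare equal.
#'
#' @param x character vector of species names.
#' @return character vector of normalized keys.
#' @export
normalize_species_name <- function(x) {
  tolower(gsub("_", " ", trimws(as.character(x)), fixed = TRUE))
}

#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline. `enrichment_per_transfer`
#' is the assumed per-mil increase in \eqn{\delta^{15}}N per trophic
#' transfer (2.5 by default; 2.54 is a common meta-analytic alternative).
#' `ethanol_d13C_offset` is an optional constant correction for
#' ethanol-preserved liver tissue (subtracting ~1.5 per mil when enabled).
#'
#' @param enrichment_per_transfer per-mil d15N enrichment per trophic level.
#' @param n_permutations permutation count for Mantel-type tests (>= 99).
#' @param rng_seed optional integer seed recorded in run reports.
#' @param min_diet_n minimum stomach sample size for a species to enter
#'   diet-based analyses.
#' @param standardize_habitat column-standardize habitat variables before
#'   computing Euclidean distances.
#' @param ethanol_d13C_offset per-mil correction subtracted from d13C.
#' @param tail default tail for permutation tests: "upper", "lower", "two".
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(enrichment_per_transfer = 2.5,
                            n_permutations = 999,
                            rng_seed = NULL,
                            min_diet_n = 5,
                            standardize_habitat = TRUE,
                            ethanol_d13C_offset = 0,
                            tail = c("upper", "lower", "two")) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(enrichment_per_transfer), length(enrichment_per_transfer) == 1L)
  if (!is.finite(enrichment_per_transfer) || enrichment_per_transfer <= 0)
    stop("`enrichment_per_transfer` must be a positive finite per-mil value")
  if (n_permutations < 99) stop("`n_permutations` must be at least 99")
  if (!is.finite(ethanol_d13C_offset))
    stop("`ethanol_d13C_offset` must be finite")
  structure(list(
    enrichment_per_transfer = enrichment_per_transfer,
    n_permutations = as.integer(n_permutations),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
    min_diet_n = as.integer(min_diet_n),
    standardize_habitat = isTRUE(standardize_habitat),
    ethanol_d13C_offset = ethanol_d13C_offset,
    tail = tail
  ), class = "analysis_config")
}

#' Read a flat key = value configuration file
#'
#' @param path file of `key = value` lines mirroring [analysis_config()]
#'   fields; `#` starts a comment.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      tail = v,
      standardize_habitat = as.logical(v),
      as.numeric(v))
  }
  do.call(analysis_config, args)
}

#' Read a per-individual isotope table
#'
#' Expects a CSV with one row per specimen. Column names are remapped via
#' `schema`, so files with arbitrary headers can be ingested.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical names
#'   (`specimen_id`, `species`, `site`, `d13C`, `d15N`) to the file's
#'   column names.
#' @return a data.frame with canonical columns; character fields trimmed,
#'   isotope values finite numerics.
#' @export
read_isotope_table <- function(path,
                               schema = c(specimen_id = "specimen_id",
                                          species = "species",
                                          site = "site",
                                          d13C = "d13C",
                                          d15N = "d15N")) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("specimen_id", "species", "site", "d13C", "d15N")
  if (!all(need %in% names(schema)))
    stop("schema must map: ", paste(setdiff(need, names(schema)), collapse = ", "))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(
    specimen_id = trimws(raw[[schema[["specimen_id"]]]]),
    species = trimws(raw[[schema[["species"]]]]),
    site = trimws(raw[[schema[["site"]]]]),
    stringsAsFactors = FALSE
  )
  for (iso in c("d13C", "d15N")) {
    txt <- trimws(raw[[schema[[iso]]]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- !is.finite(val)
    if (any(bad))
      stop("non-numeric ", iso, " value in row ", which(bad)[1L],
           " (\"", txt[which(bad)[1L]], "\")")
    out[[iso]] <- val
  }
  validate_isotope_table(out)
}

#' Validate an isotope measurement table
#'
#' Enforces finite isotope values, non-empty species and site labels, and
#' specimen ids unique within the dataset.
#'
#' @param x data.frame with columns specimen_id, species, site, d13C, d15N.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_isotope_table <- function(x) {
  need <- c("specimen_id", "species", "site", "d13C", "d15N")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(x$d13C)) || !all(is.finite(x$d15N)))
    stop("isotope values must be finite")
  if (any(!nzchar(x$species)) || any(!nzchar(x$site)))
    stop("species and site labels must be non-empty")
  if (anyDuplicated(x$specimen_id))
    stop("duplicate specimen_id: ", x$specimen_id[duplicated(x$specimen_id)][1L])
  x
}

#' Write an isotope table as CSV
#'
#' @param x isotope data.frame (see [read_isotope_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(x, path) {
  validate_isotope_table(x)
  write.csv(x[, c("specimen_id", "species", "site", "d13C", "d15N")],
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a diet-proportion table
#'
#' @param proportions species-by-category numeric matrix of mean proportion
#'   of stomach volume, on the 0-1 scale; rownames are species, colnames
#'   prey categories.
#' @param n_individuals per-species stomach sample sizes (named or in row
#'   order).
#' @return an object of class `diet_table`.
#' @export
diet_table <- function(proportions, n_individuals) {
  proportions <- as.matrix(proportions)
  if (is.null(rownames(proportions)) || is.null(colnames(proportions)))
    stop("proportions must have species rownames and category colnames")
  if (any(!is.finite(proportions)) || any(proportions < 0) || any(proportions > 1))
    stop("proportions must be finite and in [0, 1]")
  rs <- rowSums(proportions)
  if (any(rs <= 0) || any(rs > 1 + 1e-6))
    stop("row sums must lie in (0, 1]: offending species ",
         rownames(proportions)[which(rs <= 0 | rs > 1 + 1e-6)][1L])
  n_individuals <- as.integer(n_individuals)
  if (length(n_individuals) != nrow(proportions))
    stop("n_individuals must have one entry per species")
  if (any(n_individuals < 1L)) stop("n_individuals must be >= 1")
  structure(list(
    species = rownames(proportions),
    prey_categories = colnames(proportions),
    proportions = proportions,
    n_individuals = setNames(n_individuals, rownames(proportions))
  ), class = "diet_table")
}

#' Read a diet-proportion table from CSV
#'
#' Layout: a `species` column, an `n` column of stomach sample sizes, and
#' one numeric column per prey category.
#'
#' @param path CSV file path.
#' @return a [diet_table()].
#' @export
read_diet_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("species", "n") %in% names(raw)))
    stop("diet table needs `species` and `n` columns")
  cats <- setdiff(names(raw), c("species", "n"))
  if (!length(cats)) stop("diet table has no prey-category columns")
  m <- as.matrix(raw[, cats, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- trimws(raw$species)
  diet_table(m, raw$n)
}

#' Write a diet table as CSV
#' @param x a `diet_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diet_table <- function(x, path) {
  stopifnot(inherits(x, "diet_table"))
  df <- data.frame(species = x$species, n = unname(x$n_individuals),
                   x$proportions, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a trophic coding
#'
#' Maps prey categories to trophic ranks on the 1-5 scale used for
#' weighted trophic rank: 1 producer, 2 primary grazer, 3 omnivorous
#' consumer, 4 predator of omnivores, 5 predator of vertebrates. Ambiguous
#' higher taxa spanning two adjacent ranks take the midpoint, so halves are
#' permitted.
#'
#' @param ranks named numeric vector (names are prey categories, values in
#'   `{1, 1.5, ..., 5}`).
#' @return an object of class `trophic_coding`.
#' @export
trophic_coding <- function(ranks) {
  if (is.null(names(ranks)) || any(!nzchar(names(ranks))))
    stop("ranks must be a named vector of prey categories")
  ok <- ranks %in% seq(1, 5, by = 0.5)
  if (!all(ok))
    stop("ranks must be in {1, 1.5, ..., 5}; offending: ",
         paste(names(ranks)[!ok], collapse = ", "))
  structure(list(category_rank = ranks), class = "trophic_coding")
}

#' Read a trophic coding CSV (`category,rank`)
#' @param path CSV file path.
#' @return a [trophic_coding()].
#' @export
read_trophic_coding <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "rank") %in% names(raw)))
    stop("coding file needs `category` and `rank` columns")
  trophic_coding(setNames(raw$rank, trimws(raw$category)))
}

#' Default prey trophic coding
#'
#' The 63-category coding shipped with the package
#' (`inst/extdata/trophic_coding.csv`). Ranks follow the standard scheme
#' (producers 1, phytophages 2, omnivores 3, predators of omnivores 4,
#' vertebrate predators 5, midpoints for ambiguous higher taxa). The table
#' is a reconstruction assembled from exemplar assignments and general
#' arthropod natural history; it is meant to be edited per study.
#'
#' @return a [trophic_coding()].
#' @export
default_trophic_coding <- function() {
  read_trophic_coding(system.file("extdata", "trophic_coding.csv",
                                  package = "isotroph", mustWork = TRUE))
}

#' Construct a per-trap habitat table
#'
#' @param traps data.frame with a `trap_id` column plus numeric habitat
#'   variables (vegetation structure and substrate measurements).
#' @param n_vars expected number of habitat variables (default 14).
#' @return an object of class `trap_habitat_table`.
#' @export
trap_habitat_table <- function(traps, n_vars = 14L) {
  if (!"trap_id" %in% names(traps)) stop("traps need a `trap_id` column")
  vars <- setdiff(names(traps), "trap_id")
  if (length(vars) != n_vars)
    stop("expected ", n_vars, " habitat variables, found ", length(vars))
  m <- as.matrix(traps[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("habitat variables must be complete and finite")
  rownames(m) <- trimws(as.character(traps$trap_id))
  if (anyDuplicated(rownames(m))) stop("duplicate trap_id")
  pct <- grepl("_pct$", vars)
  if (any(pct) && (any(m[, pct] < 0) || any(m[, pct] > 100)))
    stop("percentage variables (\"*_pct\") must lie in [0, 100]")
  structure(list(variables = m), class = "trap_habitat_table")
}

#' Read a trap habitat table from CSV
#' @param path CSV path (`trap_id` column + habitat variables).
#' @param n_vars expected number of habitat variables.
#' @return a [trap_habitat_table()].
#' @export
read_habitat_table <- function(path, n_vars = 14L) {
  trap_habitat_table(read.csv(path, stringsAsFactors = FALSE,
                              check.names = FALSE), n_vars = n_vars)
}

#' Read capture records (`species,trap_id`)
#'
#' @param path CSV path.
#' @param traps optional `trap_habitat_table` against which trap ids are
#'   checked.
#' @return data.frame with columns `species`, `trap_id`.
#' @export
read_captures <- function(path, traps = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "trap_id") %in% names(raw)))
    stop("capture file needs `species` and `trap_id` columns")
  out <- data.frame(species = trimws(raw$species),
                    trap_id = trimws(as.character(raw$trap_id)),
                    stringsAsFactors = FALSE)
  if (!is.null(traps)) {
    stopifnot(inherits(traps, "trap_habitat_table"))
    unknown <- setdiff(out$trap_id, rownames(traps$variables))
    if (length(unknown))
      stop("capture refers to unknown trap(s): ",
           paste(utils::head(unknown, 3L), collapse = ", "))
  }
  out
}

#' Read a Newick tree and check it
#'
#' Parses a single Newick tree, requires unique tip labels and complete
#' non-negative branch lengths, and flags (but does not reject)
#' non-ultrametric trees. Ultrametricity is judged to a relative tolerance
#' of 1e-6 of tree depth, reported in the `ultrametric` attribute.
#'
#' @param path Newick file path.
#' @return an `ape` `phylo` with a logical `ultrametric` attribute.
#' @export
read_newick_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse a Newick tree from ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  check_phylogeny(tree)
}

#' Validate a phylogeny
#'
#' @param tree an `ape` `phylo`.
#' @return the tree with an `ultrametric` attribute set.
#' @export
check_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("tree must have a branch length on every edge")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("every tip must be labelled")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  tol <- 1e-6 * max(depths)
  attr(tree, "ultrametric") <- (max(depths) - min(depths)) <= tol
  tree
}

#' Write a tree as Newick
#' @param tree `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# -- label access and reindexing ---------------------------------------------

species_labels <- function(x) {
  if (inherits(x, "phylo")) return(x$tip.label)
  if (inherits(x, "dist_matrix")) return(rownames(unclass(x)))
  if (inherits(x, "diet_table")) return(x$species)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("matrix lacks species rownames")
    return(rownames(x))
  }
  if (is.data.frame(x)) {
    if (!"species" %in% names(x)) stop("data.frame lacks a `species` column")
    return(unique(x$species))
  }
  if (is.atomic(x) && !is.null(names(x))) return(names(x))
  if (is.character(x)) return(x)
  stop("cannot extract species labels from class ",
       paste(class(x), collapse = "/"))
}

reindex_species <- function(x, labels) {
  key <- normalize_species_name(labels)
  if (inherits(x, "phylo")) {
    own <- normalize_species_name(x$tip.label)
    keep <- x$tip.label[match(key, own)]
    out <- ape::keep.tip(x, keep)
    out$tip.label <- labels[match(normalize_species_name(out$tip.label), key)]
    return(check_phylogeny(out))
  }
  if (inherits(x, "dist_matrix")) {
    m <- unclass(x)
    idx <- match(key, normalize_species_name(rownames(m)))
    out <- m[idx, idx, drop = FALSE]
    dimnames(out) <- list(labels, labels)
    return(dist_matrix(out))
  }
  if (inherits(x, "diet_table")) {
    idx <- match(key, normalize_species_name(x$species))
    return(diet_table(`rownames<-`(x$proportions[idx, , drop = FALSE], labels),
                      x$n_individuals[idx]))
  }
  if (is.matrix(x)) {
    own <- normalize_species_name(rownames(x))
    idx <- match(key, own)
    square <- !is.null(colnames(x)) && ncol(x) == nrow(x) &&
      identical(normalize_species_name(colnames(x)), own)
    out <- if (square) x[idx, idx, drop = FALSE] else x[idx, , drop = FALSE]
    rownames(out) <- labels
    if (square) colnames(out) <- labels
    return(out)
  }
  if (is.data.frame(x)) {
    keep <- normalize_species_name(x$species) %in% key
    return(x[keep, , drop = FALSE])
  }
  if (is.atomic(x) && !is.null(names(x))) {
    idx <- match(key, normalize_species_name(names(x)))
    return(setNames(x[idx], labels))
  }
  if (is.character(x)) return(labels)
  stop("cannot reindex class ", paste(class(x), collapse = "/"))
}

#' Align labelled structures on their shared species
#'
#' Takes two or more labelled objects (distance matrices, species-by-feature
#' matrices, trees, diet tables, named vectors, isotope data.frames) and
#' reindexes every one to the intersection of their species sets, in a
#' canonical sorted order. Matching is case-insensitive after trimming,
#' with underscores and spaces equivalent.
#'
#' @param ... labelled objects (optionally named arguments).
#' @return list with elements `labels` (the shared ordering), `objects`
#'   (reindexed inputs), and `dropped` (labels discarded from each input).
#' @export
align_labels <- function(...) {
  objs <- list(...)
  if (length(objs) < 2L) stop("need at least two labelled structures")
  labs <- lapply(objs, species_labels)
  keys <- lapply(labs, normalize_species_name)
  shared <- Reduce(intersect, keys)
  if (!length(shared)) stop("label intersection is empty")
  shared <- sort(shared)
  # display form: first spelling seen for each key
  all_labs <- unlist(labs, use.names = FALSE)
  all_keys <- normalize_species_name(all_labs)
  display <- all_labs[match(shared, all_keys)]
  dropped <- lapply(seq_along(objs), function(i)
    labs[[i]][!keys[[i]] %in% shared])
  names(dropped) <- names(objs)
  out <- lapply(objs, reindex_species, labels = display)
  names(out) <- names(objs)
  list(labels = display, objects = out, dropped = dropped)
}
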