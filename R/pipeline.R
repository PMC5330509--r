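# End-to-end analysis pipeline: summaries, classical tests, weighted
# trophic rank, distance matrices, Mantel machinery and phylogenetic
# signal, driven by one configuration object.

#' Run the full community isotope analysis
#'
#' Executes every stage the data supports: preservation correction,
#' per-site species summaries and community trophic span, two-way and
#' Welch ANOVA plus Bartlett's test, weighted trophic rank and its
#' concordance with d15N ordering, isotopic / dietary / habitat distance
#' matrices, Mantel tests among them (plain and, when a tree is given,
#' phylogenetically permuted), and Pagel's lambda for species mean d13C
#' and d15N. Stages whose inputs are absent are skipped silently; the run
#' report records the configuration, seed and package version.
#'
#' @param isotopes per-individual isotope data.frame
#'   (see [read_isotope_table()]).
#' @param diet optional [diet_table()].
#' @param coding optional [trophic_coding()] (defaults to the shipped
#'   coding when a diet table is given).
#' @param traps optional [trap_habitat_table()].
#' @param captures optional capture records data.frame.
#' @param tree optional `phylo`.
#' @param config an [analysis_config()].
#' @return object of class `isotroph_pipeline` (a nested result list).
#' @export
run_pipeline <- function(isotopes, diet = NULL, coding = NULL,
                         traps = NULL, captures = NULL, tree = NULL,
                         config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  isotopes <- apply_preservation_offset(isotopes, config$ethanol_d13C_offset)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  sites <- sort(unique(isotopes$site))
  out <- list(report = list(
    package_version = as.character(packageVersion("isotroph")),
    config = unclass(config),
    sites = sites,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ))

  out$summaries <- lapply(sites, function(s)
    summarize_species(isotopes, s, min_n = config$min_diet_n))
  names(out$summaries) <- sites
  out$trophic_span <- lapply(out$summaries, community_trophic_span,
                             enrichment = config$enrichment_per_transfer)

  out$anova <- list()
  if (length(sites) >= 2L) {
    out$anova$d15N <- two_way_anova(isotopes$d15N, isotopes$species,
                                    isotopes$site)
    out$anova$d13C <- two_way_anova(isotopes$d13C, isotopes$species,
                                    isotopes$site)
  }
  multi <- names(which(table(isotopes$species) >= 2L))
  sub <- isotopes[isotopes$species %in% multi, , drop = FALSE]
  if (length(unique(sub$species)) >= 2L) {
    out$anova$welch_d15N <- welch_oneway(sub$d15N, sub$species)
    out$anova$welch_d13C <- welch_oneway(sub$d13C, sub$species)
    varok <- names(which(tapply(sub$d15N, sub$species, var) > 0 &
                           tapply(sub$d13C, sub$species, var) > 0))
    sub2 <- sub[sub$species %in% varok, , drop = FALSE]
    if (length(varok) >= 2L) {
      out$anova$bartlett_d15N <- bartlett_variances(sub2$d15N, sub2$species)
      out$anova$bartlett_d13C <- bartlett_variances(sub2$d13C, sub2$species)
    }
  }

  # per-site analyses that need species means
  out$per_site <- lapply(sites, function(s) {
    res <- list(site = s)
    sm <- out$summaries[[s]]$summaries
    means <- as.matrix(sm[, c("mean_d13C", "mean_d15N")])
    rownames(means) <- sm$species
    res$isotope_distance <- euclidean_distance(scale(means))

    if (!is.null(diet)) {
      cod <- if (is.null(coding)) default_trophic_coding() else coding
      res$wtr <- diet_wtr(diet, cod, min_n = config$min_diet_n)
      wtr_v <- setNames(res$wtr$wtr, res$wtr$species)
      d15 <- setNames(sm$mean_d15N, sm$species)
      shared <- intersect(normalize_species_name(names(wtr_v)),
                          normalize_species_name(names(d15)))
      if (length(shared) >= 3L)
        res$concordance <- tryCatch(rank_concordance(d15, wtr_v),
                                    error = function(e) NULL)
      res$diet_distance <- tryCatch(
        diet_distance(diet, min_n = config$min_diet_n),
        error = function(e) NULL)
      res$termite_distance <- tryCatch(
        diet_distance(diet, categories = "Isoptera",
                      min_n = config$min_diet_n),
        error = function(e) NULL)
    }

    if (!is.null(traps) && !is.null(captures)) {
      hm <- species_habitat_means(traps, captures)
      res$habitat_matrix <- transform_habitat_matrix(hm)
      res$habitat_distance <- habitat_distance(
        res$habitat_matrix, standardize = config$standardize_habitat)
    }

    run_mantel <- function(Da, Db, label) {
      al <- tryCatch(align_labels(Da, Db), error = function(e) NULL)
      if (is.null(al) || length(al$labels) < 4L) return(NULL)
      m <- tryCatch(
        mantel_test(al$objects[[1L]], al$objects[[2L]],
                    n_perm = config$n_permutations, tail = config$tail),
        error = function(e) NULL)
      if (is.null(m)) return(NULL)
      pm <- NULL
      if (!is.null(tree)) {
        tipk <- normalize_species_name(tree$tip.label)
        if (all(normalize_species_name(al$labels) %in% tipk))
          pm <- tryCatch(
            phylo_mantel_test(al$objects[[1L]], al$objects[[2L]], tree,
                              n_perm = config$n_permutations,
                              tail = config$tail),
            error = function(e) NULL)
      }
      list(comparison = label, mantel = m, phylo_mantel = pm)
    }
    res$mantel <- Filter(Negate(is.null), list(
      habitat_isotope = if (!is.null(res$habitat_distance))
        run_mantel(res$habitat_distance, res$isotope_distance,
                   "habitat vs isotope"),
      diet_isotope = if (!is.null(res$diet_distance))
        run_mantel(res$diet_distance, res$isotope_distance,
                   "diet vs isotope"),
      termite_isotope = if (!is.null(res$termite_distance))
        run_mantel(res$termite_distance, res$isotope_distance,
                   "termite-only diet vs isotope"),
      habitat_diet = if (!is.null(res$habitat_distance) &&
                         !is.null(res$diet_distance))
        run_mantel(res$habitat_distance, res$diet_distance,
                   "habitat vs diet")
    ))
    res
  })
  names(out$per_site) <- sites

  if (!is.null(tree)) {
    # pooled species means across sites for phylogenetic signal
    pool <- lapply(c("d15N", "d13C"), function(iso) {
      v <- tapply(isotopes[[iso]], isotopes$species, mean)
      setNames(as.numeric(v), names(v))
    })
    names(pool) <- c("d15N", "d13C")
    out$phylo_signal <- lapply(pool, function(tr)
      tryCatch(pagel_lambda(tree, tr), error = function(e) NULL))
  }

  structure(out, class = "isotroph_pipeline")
}

#' @export
print.isotroph_pipeline <- function(x, ...) {
  cat("isotroph pipeline run (package", x$report$package_version, ")\n")
  for (s in names(x$summaries)) {
    sm <- x$summaries[[s]]
    cat(sprintf("- %s: %d species, community d15N range %.2f, d13C range %.2f; %.2f trophic transfers\n",
                s, nrow(sm$summaries), sm$community_range_d15N,
                sm$community_range_d13C, x$trophic_span[[s]]$transfers))
    for (m in x$per_site[[s]]$mantel) {
      cat(sprintf("    Mantel %s: r = %.3f, p = %.3g\n",
                  m$comparison, m$mantel$r, m$mantel$p))
      if (!is.null(m$phylo_mantel))
        cat(sprintf("      (phylo-permuted: r = %.3f, p = %.3g)\n",
                    m$phylo_mantel$r, m$phylo_mantel$p))
    }
  }
  if (!is.null(x$phylo_signal)) {
    for (iso in names(x$phylo_signal)) {
      ps <- x$phylo_signal[[iso]]
      if (!is.null(ps))
        cat(sprintf("- Pagel's lambda (%s): %.4g, LRT p = %.3g\n",
                    iso, ps$lambda, ps$p))
    }
  }
  invisible(x)
}

#' Run the pipeline on a dataset directory
#'
#' Reads the files written by [write_community()] (or assembled by hand in
#' the same layout) and calls [run_pipeline()]. Missing optional files are
#' skipped.
#'
#' @param dir dataset directory with `isotopes.csv` and optionally
#'   `diet.csv`, `coding.csv`, `traps.csv`, `captures.csv`, `tree.nwk`.
#' @param config an [analysis_config()].
#' @return an `isotroph_pipeline` result.
#' @export
run_pipeline_dir <- function(dir, config = analysis_config()) {
  p <- function(f) file.path(dir, f)
  has <- function(f) file.exists(p(f))
  if (!has("isotopes.csv")) stop("no isotopes.csv in ", dir)
  traps <- if (has("traps.csv")) read_habitat_table(p("traps.csv")) else NULL
  run_pipeline(
    isotopes = read_isotope_table(p("isotopes.csv")),
    diet = if (has("diet.csv")) read_diet_table(p("diet.csv")) else NULL,
    coding = if (has("coding.csv")) read_trophic_coding(p("coding.csv")) else NULL,
    traps = traps,
    captures = if (has("captures.csv")) read_captures(p("captures.csv"), traps) else NULL,
    tree = if (has("tree.nwk")) read_newick_tree(p("tree.nwk")) else NULL,
    config = config
  )
}
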