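# Prey trophic coding, weighted trophic rank, diet-space distances and
# concordance of trophic rank with d15N ordering.

#' Trophic rank of a prey category
#'
#' Looks a category up in a [trophic_coding()] (case-insensitive after
#' trimming). Ambiguous higher taxa spanning two adjacent ranks are stored
#' in the coding at the midpoint of the two ranks.
#'
#' @param category prey category name(s).
#' @param coding a `trophic_coding`.
#' @return numeric rank(s) on the 1-5 scale.
#' @export
assign_trophic_rank <- function(category, coding = default_trophic_coding()) {
  stopifnot(inherits(coding, "trophic_coding"))
  key <- normalize_species_name(category)
  idx <- match(key, normalize_species_name(names(coding$category_rank)))
  if (anyNA(idx))
    stop("no trophic rank coded for: ",
         paste(category[is.na(idx)], collapse = ", "))
  unname(coding$category_rank[idx])
}

#' Midpoint rank for a taxon spanning two adjacent ranks
#' @param lower,upper the two spanned ranks.
#' @return their midpoint.
#' @export
intermediate_rank <- function(lower, upper) {
  if (abs(upper - lower) != 1) stop("spanned ranks must be adjacent")
  (lower + upper) / 2
}

#' Weighted trophic rank of one species
#'
#' The diet-proportion-weighted mean of prey trophic ranks,
#' \eqn{\sum_i p_i T_i}, over the prey types present in the stomach
#' (p_i > 0). With `normalize = TRUE` (default) proportions are rescaled
#' to sum to one first, so the statistic is a true weighted mean bounded by
#' the prey ranks; the flag is recorded because mean percent-volume rows
#' need not sum exactly to one.
#'
#' @param proportions named numeric vector of diet proportions (>= 0, not
#'   all zero). Names are prey categories unless `ranks` is given.
#' @param coding a `trophic_coding` used to look up ranks by name.
#' @param ranks optional numeric vector of ranks aligned with
#'   `proportions`, bypassing the coding lookup.
#' @param normalize rescale proportions to sum to 1 before weighting.
#' @return object of class `wtr`: list with `wtr`, `n_prey_types`,
#'   `normalized`.
#' @export
weighted_trophic_rank <- function(proportions, coding = default_trophic_coding(),
                                  ranks = NULL, normalize = TRUE) {
  p <- as.numeric(proportions)
  if (any(!is.finite(p)) || any(p < 0))
    stop("proportions must be finite and >= 0")
  if (sum(p) <= 0) stop("empty stomach: all proportions are zero")
  if (is.null(ranks)) {
    if (is.null(names(proportions)))
      stop("proportions must be named when no `ranks` vector is given")
    ranks <- assign_trophic_rank(names(proportions), coding)
  }
  if (length(ranks) != length(p))
    stop("ranks and proportions must have equal length")
  keep <- p > 0
  p <- p[keep]; tr <- ranks[keep]
  if (normalize) p <- p / sum(p)
  structure(list(wtr = sum(p * tr),
                 n_prey_types = sum(keep),
                 normalized = isTRUE(normalize)),
            class = "wtr")
}

#' @export
print.wtr <- function(x, ...) {
  cat(sprintf("Weighted trophic rank: %.3f (%d prey types%s)\n",
              x$wtr, x$n_prey_types,
              if (x$normalized) ", proportions renormalized" else ""))
  invisible(x)
}

#' Weighted trophic rank for every species in a diet table
#'
#' @param diet a [diet_table()].
#' @param coding a `trophic_coding`.
#' @param normalize see [weighted_trophic_rank()].
#' @param min_n drop species with fewer than `min_n` stomachs (set 1 to
#'   keep all).
#' @return data.frame with species, n, wtr, n_prey_types.
#' @export
diet_wtr <- function(diet, coding = default_trophic_coding(),
                     normalize = TRUE, min_n = 1L) {
  stopifnot(inherits(diet, "diet_table"))
  keep <- diet$n_individuals >= min_n
  if (!any(keep)) stop("no species meets the sample-size floor")
  ranks <- assign_trophic_rank(diet$prey_categories, coding)
  sp <- diet$species[keep]
  w <- vapply(sp, function(s) {
    weighted_trophic_rank(diet$proportions[s, ], ranks = ranks,
                          normalize = normalize)$wtr
  }, 1)
  npt <- vapply(sp, function(s) sum(diet$proportions[s, ] > 0), 1L)
  data.frame(species = sp, n = unname(diet$n_individuals[keep]),
             wtr = unname(w), n_prey_types = unname(npt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Euclidean distances between species diets
#'
#' Distance between species' diet-proportion vectors, optionally
#' restricted to a subset of prey categories (e.g. termites only). Species
#' with fewer than `min_n` stomachs are excluded before computing
#' distances.
#'
#' @param diet a [diet_table()].
#' @param categories optional character subset of prey categories.
#' @param min_n stomach sample-size floor (default 5).
#' @return a [dist_matrix()].
#' @export
diet_distance <- function(diet, categories = NULL, min_n = 5L) {
  stopifnot(inherits(diet, "diet_table"))
  keep <- diet$n_individuals >= min_n
  m <- diet$proportions[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least two species after the N >= ",
                         min_n, " filter")
  if (!is.null(categories)) {
    idx <- match(normalize_species_name(categories),
                 normalize_species_name(colnames(m)))
    if (all(is.na(idx)))
      stop("requested categories absent from the diet table: ",
           paste(categories, collapse = ", "))
    m <- m[, idx[!is.na(idx)], drop = FALSE]
  }
  euclidean_distance(m)
}

#' Concordance of d15N ordering with weighted trophic rank
#'
#' Correlates species' mean d15N with their weighted trophic rank. The
#' default is the product-moment correlation with a two-sided t-based p;
#' a rank-based (Spearman) variant is available.
#'
#' @param mean_d15N named per-species mean d15N values.
#' @param wtr named per-species weighted trophic ranks.
#' @param method "pearson" (default) or "spearman".
#' @return object of class `concordance`: list with `r`, `p`, `n`,
#'   `method`.
#' @export
rank_concordance <- function(mean_d15N, wtr,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(mean_d15N)) && !is.null(names(wtr))) {
    al <- align_labels(mean_d15N, wtr)
    mean_d15N <- al$objects[[1L]]
    wtr <- al$objects[[2L]]
  }
  if (length(mean_d15N) != length(wtr)) stop("vectors must align")
  n <- length(mean_d15N)
  if (n < 3L) stop("need at least three species")
  if (sd(mean_d15N) == 0 || sd(wtr) == 0)
    stop("correlation undefined: zero variance")
  ct <- suppressWarnings(cor.test(mean_d15N, wtr, method = method,
                                  alternative = "two.sided"))
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 method = method),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("d15N vs trophic-rank concordance (%s): r = %.2f, p = %.2f, n = %d\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}
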