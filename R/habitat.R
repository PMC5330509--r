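# Species habitat scores from pitfall-trap measurements: per-species trap
# means, normality-driven transform selection, habitat-space distances.

#' Per-species means of trap habitat variables
#'
#' Averages each habitat variable over the pitfall traps where a species
#' was collected. By default every distinct trap counts once per species
#' regardless of how many captures it produced ("distinct-trap"
#' convention); `weighted = TRUE` weights traps by capture count instead.
#'
#' @param traps a [trap_habitat_table()].
#' @param captures data.frame of (species, trap_id) capture records.
#' @param weighted capture-weighted means instead of distinct-trap means.
#' @param species optional species universe; members with zero captures
#'   are excluded and reported in the `dropped` attribute.
#' @return species-by-variable matrix of raw means, with a `dropped`
#'   attribute listing zero-capture species.
#' @export
species_habitat_means <- function(traps, captures, weighted = FALSE,
                                  species = NULL) {
  stopifnot(inherits(traps, "trap_habitat_table"))
  unknown <- setdiff(captures$trap_id, rownames(traps$variables))
  if (length(unknown))
    stop("capture refers to unknown trap(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  if (is.null(species)) species <- sort(unique(captures$species))
  caught <- species %in% captures$species
  dropped <- species[!caught]
  species <- species[caught]
  if (!length(species)) stop("no species with captures")
  out <- t(vapply(species, function(s) {
    ids <- captures$trap_id[captures$species == s]
    if (!weighted) ids <- unique(ids)
    colMeans(traps$variables[ids, , drop = FALSE])
  }, numeric(ncol(traps$variables))))
  rownames(out) <- species
  attr(out, "dropped") <- dropped
  out
}

# admissible [0,1] rescaling: values already in [0,1], or percent-style
# values in [0,100] (divided by 100). NULL when neither applies.
unit_scale <- function(values) {
  if (all(values >= 0 & values <= 1)) return(values)
  if (all(values >= 0 & values <= 100)) return(values / 100)
  NULL
}

# shift exact 0s (and, for two-sided transforms, exact 1s) into the open
# interval by half the smallest nonzero margin
eps_shift <- function(u, two_sided = FALSE) {
  eps <- 0
  if (any(u == 0)) {
    nz <- u[u > 0]
    eps <- if (length(nz)) min(nz) / 2 else 0.5
    u[u == 0] <- eps
  }
  if (two_sided && any(u == 1)) {
    nz <- 1 - u[u < 1]
    e1 <- if (length(nz[nz > 0])) min(nz[nz > 0]) / 2 else 0.5
    u[u == 1] <- 1 - e1
    eps <- max(eps, e1)
  }
  list(values = u, epsilon = eps)
}

#' Choose the transform that best normalizes a variable
#'
#' Evaluates the admissible members of {log, logit, arcsine square root}
#' for one habitat variable's per-species means, scores each candidate by
#' the Shapiro-Wilk W statistic of the transformed values, and returns the
#' highest-scoring transform. Ties break in the fixed order log > logit >
#' arcsine-sqrt. Logit and arcsine-sqrt are only offered when the values
#' are representable on [0, 1] (directly or as percentages on [0, 100]);
#' log requires non-negative values. Exact zeros (and ones, for the
#' bounded transforms) are shifted into the domain by half the smallest
#' nonzero margin, and the shift is recorded. When no transform is
#' admissible the values are returned untransformed ("none").
#'
#' @param values per-species means of one habitat variable (n >= 3).
#' @return list with `transform`, `values` (transformed), `W`
#'   (Shapiro-Wilk statistic), and `epsilon` (boundary shift used).
#' @export
select_transform <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least three species")
  if (any(!is.finite(values))) stop("values must be finite")
  cand <- list()
  if (all(values >= 0)) {
    # log acts on the raw scale; shift raw zeros by half min nonzero raw value
    raw <- values
    epsl <- 0
    if (any(raw == 0)) {
      nz <- raw[raw > 0]
      epsl <- if (length(nz)) min(nz) / 2 else 0.5
      raw[raw == 0] <- epsl
    }
    cand$log <- list(values = log(raw), epsilon = epsl)
  }
  u <- unit_scale(values)
  if (!is.null(u)) {
    s2 <- eps_shift(u, two_sided = TRUE)
    cand$logit <- list(values = log(s2$values / (1 - s2$values)),
                       epsilon = s2$epsilon)
    s1 <- eps_shift(u, two_sided = TRUE)
    cand$`arcsine-sqrt` <- list(values = asin(sqrt(s1$values)),
                                epsilon = s1$epsilon)
  }
  if (!length(cand))
    return(list(transform = "none", values = values, W = NA_real_,
                epsilon = 0))
  score <- vapply(cand, function(ci) {
    if (sd(ci$values) == 0) return(-Inf)
    tryCatch(unname(shapiro.test(ci$values)$statistic),
             error = function(e) -Inf)
  }, 1)
  if (all(!is.finite(score)))
    return(list(transform = "none", values = values, W = NA_real_,
                epsilon = 0))
  order_pref <- c("log", "logit", "arcsine-sqrt")
  present <- intersect(order_pref, names(cand))
  best <- present[which.max(score[present])]   # which.max keeps first on ties
  list(transform = best, values = cand[[best]]$values,
       W = unname(score[best]), epsilon = cand[[best]]$epsilon)
}

#' Transform a species habitat-mean matrix column-wise
#'
#' Applies [select_transform()] to every variable.
#'
#' @param means species-by-variable matrix of raw habitat means.
#' @return object of class `species_habitat_matrix`: list with the
#'   transformed `matrix` and per-variable `transform_used`.
#' @export
transform_habitat_matrix <- function(means) {
  means <- as.matrix(means)
  out <- means
  used <- character(ncol(means))
  names(used) <- colnames(means)
  for (j in seq_len(ncol(means))) {
    tr <- select_transform(means[, j])
    out[, j] <- tr$values
    used[j] <- tr$transform
  }
  structure(list(matrix = out, transform_used = used),
            class = "species_habitat_matrix")
}

#' Euclidean distances between species in habitat space
#'
#' @param x a `species_habitat_matrix` (or a plain species-by-variable
#'   matrix).
#' @param standardize center and scale each variable to unit variance
#'   first (default TRUE: the variables mix percentages, counts and
#'   volumes).
#' @return a [dist_matrix()].
#' @export
habitat_distance <- function(x, standardize = TRUE) {
  m <- if (inherits(x, "species_habitat_matrix")) x$matrix else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least two species")
  if (standardize) {
    sds <- apply(m, 2L, sd)
    if (any(sds == 0))
      stop("constant column under standardization: ",
           colnames(m)[which(sds == 0)][1L])
    m <- scale(m)
  }
  euclidean_distance(m)
}
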