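# Mantel and partial Mantel permutation tests, with an optional
# phylogenetically restricted permutation null. Implemented from first
# principles: the permutation machinery (not a wrapper) is the point.

mantel_r <- function(v1, v2) {
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("Mantel correlation undefined: zero variance in a distance triangle")
  cor(v1, v2)
}

perm_pvalue <- function(r_obs, r_perm, tail) {
  n <- length(r_perm) + 1L   # identity permutation counts in the null
  switch(tail,
         upper = (1 + sum(r_perm >= r_obs)) / n,
         lower = (1 + sum(r_perm <= r_obs)) / n,
         two   = (1 + sum(abs(r_perm) >= abs(r_obs))) / n)
}

check_same_labels <- function(D1, D2, what = "distance matrices") {
  if (!identical(rownames(D1), rownames(D2)))
    stop(what, " must share identical species labels and ordering; ",
         "use align_labels() first")
}

partial_r <- function(r12, r13, r23) {
  if (abs(r13) >= 1 || abs(r23) >= 1)
    stop("degenerate partial correlation: a control correlation is +/-1")
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

new_mantel_result <- function(r, p, n_perm, tail, seed, n, method,
                              partial_controls = NULL) {
  structure(list(r = r, p = p, n_perm = n_perm, tail = tail, seed = seed,
                 n = n, method = method, partial_controls = partial_controls),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$partial_controls))
    cat("  controlling for:", x$partial_controls, "\n")
  cat(sprintf("  r = %.4f, p = %.4g (%s tail, %d permutations, n = %d)\n",
              x$r, x$p, x$tail, x$n_perm, x$n))
  invisible(x)
}

#' Mantel test between two species distance matrices
#'
#' Correlates the strictly-lower-triangle entries of two aligned distance
#' matrices and builds the null by simultaneously permuting the rows and
#' columns of the second matrix. The permutation p-value counts the
#' identity permutation, so p >= 1/(n_perm + 1). The default tail is
#' upper (one-sided for positive association), the usual convention in
#' ecological applications; `tail = "two"` gives a two-sided test.
#'
#' An optional third matrix `D3` turns this into a partial Mantel test:
#' the statistic becomes the partial correlation r12.3 over triangles, and
#' D2 is permuted while D1 and D3 stay fixed.
#'
#' @param D1,D2 [dist_matrix()] objects over the same species ordering.
#' @param D3 optional control `dist_matrix` (partial Mantel).
#' @param n_perm number of permutations (default 999).
#' @param tail "upper", "lower" or "two".
#' @param seed optional integer seed for the permutation generator.
#' @return a `mantel_result`: list with `r`, `p`, `n_perm`, `tail`,
#'   `seed`, `n`.
#' @export
mantel_test <- function(D1, D2, D3 = NULL, n_perm = 999L,
                        tail = c("upper", "lower", "two"), seed = NULL) {
  tail <- match.arg(tail)
  stopifnot(inherits(D1, "dist_matrix"), inherits(D2, "dist_matrix"))
  check_same_labels(D1, D2)
  n <- nrow(D1)
  if (n < 4L) stop("need at least four species")
  if (!is.null(seed)) set.seed(seed)
  v1 <- lower_tri(D1)
  v2 <- lower_tri(D2)
  partial <- !is.null(D3)
  if (partial) {
    stopifnot(inherits(D3, "dist_matrix"))
    check_same_labels(D1, D3)
    v3 <- lower_tri(D3)
    if (sd(v3) == 0)
      stop("control matrix has zero variance in its distance triangle")
    r13 <- mantel_r(v1, v3)
    r_obs <- partial_r(mantel_r(v1, v2), r13, mantel_r(v2, v3))
  } else {
    r_obs <- mantel_r(v1, v2)
  }
  m2 <- unclass(D2)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    vp <- lower_tri(m2[idx, idx])
    if (sd(vp) == 0) return(NA_real_)
    if (partial) partial_r(cor(v1, vp), r13, cor(vp, v3)) else cor(v1, vp)
  }, 1)
  r_perm <- r_perm[is.finite(r_perm)]
  new_mantel_result(
    r = r_obs, p = perm_pvalue(r_obs, r_perm, tail),
    n_perm = as.integer(n_perm), tail = tail, seed = seed, n = n,
    method = if (partial) "Partial Mantel test (label permutations)"
             else "Mantel test (label permutations)",
    partial_controls = if (partial) "D3" else NULL)
}

#' Phylogenetically restricted label permutation
#'
#' Builds one permutation of `1:n` by a sequence of pairwise swaps in
#' which the probability of swapping two labels decays with their
#' patristic distance: a pair (i, j) is drawn with weight
#' 1 / (d_patristic(i, j) + delta) at each of `n_swaps` steps. Close
#' relatives therefore trade places often while distant tips rarely do,
#' preserving the phylogenetic structure of the matrix under the null.
#'
#' @param patristic symmetric matrix of patristic distances.
#' @param delta damping constant added to distances (default one tenth of
#'   the mean off-diagonal patristic distance).
#' @param n_swaps number of sequential swaps (default the number of tips).
#' @return an integer permutation of `1:n`.
#' @export
phylo_permutation <- function(patristic, delta = NULL, n_swaps = NULL) {
  n <- nrow(patristic)
  if (is.null(delta)) delta <- 0.1 * mean(lower_tri(patristic))
  if (is.null(n_swaps)) n_swaps <- n
  pairs <- which(lower.tri(patristic), arr.ind = TRUE)
  w <- 1 / (patristic[pairs] + delta)
  p <- seq_len(n)
  picks <- sample.int(nrow(pairs), n_swaps, replace = TRUE, prob = w)
  for (k in picks) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  }
  p
}

#' Mantel test with a phylogenetically restricted null
#'
#' Same statistic as [mantel_test()] (plain or partial Mantel r), but the
#' null distribution is generated by phylogenetically restricted
#' permutations ([phylo_permutation()]): labels that are close on the tree
#' swap with higher probability, so the null keeps the phylogenetic
#' autocorrelation that inflates the naive Mantel test's type-I error.
#' When no explicit control matrix is given, the patristic distance matrix
#' itself can be used as the partial-Mantel control via
#' `control = "patristic"`.
#'
#' @param D1,D2 aligned [dist_matrix()] objects.
#' @param tree `phylo` whose tips cover the species labels.
#' @param D3 optional control `dist_matrix`.
#' @param control "none" (default) or "patristic" (use the tree's
#'   patristic distances as the partial-Mantel control when `D3` is NULL).
#' @param n_perm,tail,seed as in [mantel_test()].
#' @param delta,n_swaps tuning of the restricted swaps; see
#'   [phylo_permutation()].
#' @return a `mantel_result`.
#' @export
phylo_mantel_test <- function(D1, D2, tree, D3 = NULL,
                              control = c("none", "patristic"),
                              n_perm = 999L,
                              tail = c("upper", "lower", "two"),
                              seed = NULL, delta = NULL, n_swaps = NULL) {
  tail <- match.arg(tail)
  control <- match.arg(control)
  stopifnot(inherits(D1, "dist_matrix"), inherits(D2, "dist_matrix"))
  check_same_labels(D1, D2)
  tree <- check_phylogeny(tree)
  labels <- rownames(D1)
  key <- normalize_species_name(labels)
  tip_key <- normalize_species_name(tree$tip.label)
  if (!all(key %in% tip_key))
    stop("tree tips must cover all species labels")
  tree <- reindex_species(tree, labels)
  pat <- ape::cophenetic.phylo(tree)[labels, labels]
  if (is.null(D3) && control == "patristic") {
    pd <- pat; diag(pd) <- 0
    D3 <- dist_matrix((pd + t(pd)) / 2)
  }
  n <- nrow(D1)
  if (n < 4L) stop("need at least four species")
  if (!is.null(seed)) set.seed(seed)
  v1 <- lower_tri(D1)
  v2 <- lower_tri(D2)
  partial <- !is.null(D3)
  if (partial) {
    check_same_labels(D1, D3)
    v3 <- lower_tri(D3)
    if (sd(v3) == 0)
      stop("control matrix has zero variance in its distance triangle")
    r13 <- mantel_r(v1, v3)
    r_obs <- partial_r(mantel_r(v1, v2), r13, mantel_r(v2, v3))
  } else {
    r_obs <- mantel_r(v1, v2)
  }
  m2 <- unclass(D2)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- phylo_permutation(pat, delta = delta, n_swaps = n_swaps)
    vp <- lower_tri(m2[idx, idx])
    if (sd(vp) == 0) return(NA_real_)
    if (partial) partial_r(cor(v1, vp), r13, cor(vp, v3)) else cor(v1, vp)
  }, 1)
  r_perm <- r_perm[is.finite(r_perm)]
  new_mantel_result(
    r = r_obs, p = perm_pvalue(r_obs, r_perm, tail),
    n_perm = as.integer(n_perm), tail = tail, seed = seed, n = n,
    method = paste0(if (partial) "Partial " else "",
                    "Mantel test (phylogenetically restricted permutations)"),
    partial_controls = if (partial) {
      if (control == "patristic") "patristic distances" else "D3"
    } else NULL)
}
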