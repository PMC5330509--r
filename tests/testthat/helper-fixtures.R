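# Shared fixture builders; everything is generated in code.

# distance matrix from random points in feature space
random_dist <- function(n, p = 3, labels = sprintf("s%02d", seq_len(n))) {
  X <- matrix(rnorm(n * p), n, p, dimnames = list(labels, NULL))
  euclidean_distance(X)
}

# tiny hand-checkable tree: ((A:1,B:1):1,C:2);
cherry_tree <- function() {
  check_phylogeny(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
}

# a small isotope table with known structure
toy_isotopes <- function() {
  data.frame(
    specimen_id = sprintf("sp%02d", 1:6),
    species = rep(c("A", "B", "C"), each = 2),
    site = "main",
    d13C = c(-18, -20, -17, -17, -22, -21),
    d15N = c(7, 9, 8, 8, 10, 12),
    stringsAsFactors = FALSE
  )
}

# correlation of two matrices' lower triangles, permuting D2 by `idx`
tri_cor_perm <- function(D1, D2, idx) {
  m2 <- unclass(D2)[idx, idx]
  cor(D1[lower.tri(D1)], m2[lower.tri(m2)])
}
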