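test_that("affinely related matrices give Mantel r = 1 and small p", {
  set.seed(101)
  D1 <- random_dist(8)
  m2 <- 0.3 + 2 * unclass(D1); diag(m2) <- 0
  D2 <- dist_matrix(m2)
  res <- mantel_test(D1, D2, n_perm = 199, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lte(res$p, 0.05)
  expect_gte(res$p, 1 / 200)
})

test_that("mantel r is invariant under a common relabeling of both matrices", {
  set.seed(102)
  D1 <- random_dist(9)
  D2 <- random_dist(9)
  r0 <- mantel_test(D1, D2, n_perm = 99, seed = 2)$r
  idx <- sample(9)
  relab <- function(D) {
    m <- unclass(D)[idx, idx]
    dist_matrix(m)
  }
  r1 <- mantel_test(relab(D1), relab(D2), n_perm = 99, seed = 2)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("mantel agrees with an independent implementation on the statistic", {
  set.seed(103)
  D1 <- random_dist(10)
  D2 <- random_dist(10)
  ours <- mantel_test(D1, D2, n_perm = 99, seed = 3)$r
  ref <- vegan::mantel(as.dist(unclass(D1)), as.dist(unclass(D2)),
                       permutations = 99)
  expect_equal(ours, unname(ref$statistic), tolerance = 1e-12)
})

test_that("permutation p matches exact enumeration at n = 4", {
  # independent oracle: enumerate all 4! relabelings of D2
  set.seed(104)
  perms4 <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms4 <- perms4[apply(perms4, 1, function(p) length(unique(p)) == 4L), ]
  for (rep in 1:3) {
    D1 <- random_dist(4)
    D2 <- random_dist(4)
    r_obs <- cor(D1[lower.tri(D1)], D2[lower.tri(D2)])
    r_all <- apply(perms4, 1, function(p) tri_cor_perm(D1, D2, p))
    p_exact <- mean(r_all >= r_obs - 1e-12)
    p_perm <- mantel_test(D1, D2, n_perm = 999, seed = 200 + rep)$p
    expect_lt(abs(p_perm - p_exact), 0.03)
  }
})

test_that("a strongly negative observed r yields an upper-tail p near 1", {
  set.seed(105)
  D1 <- random_dist(10)
  m2 <- max(unclass(D1)) + 0.1 - unclass(D1)   # anti-correlated distances
  diag(m2) <- 0
  res <- mantel_test(D1, dist_matrix(m2), n_perm = 199, seed = 6)
  expect_lt(res$r, -0.9)
  expect_gt(res$p, 0.9)
  # lower tail flips the verdict
  res_lo <- mantel_test(D1, dist_matrix(m2), n_perm = 199, tail = "lower",
                        seed = 6)
  expect_lte(res_lo$p, 0.05)
})

test_that("p never drops below 1/(n_perm + 1)", {
  set.seed(106)
  D1 <- random_dist(12)
  for (np in c(99, 199)) {
    res <- mantel_test(D1, D1, n_perm = np, seed = 7)
    expect_gte(res$p, 1 / (np + 1))
  }
})

test_that("degenerate inputs are rejected", {
  set.seed(107)
  D1 <- random_dist(5)
  flat <- matrix(1, 5, 5); diag(flat) <- 0
  dimnames(flat) <- dimnames(unclass(D1))
  expect_error(mantel_test(D1, dist_matrix(flat), n_perm = 99),
               "zero variance")
  # control with constant off-diagonal: degenerate partial
  expect_error(mantel_test(D1, random_dist(5), D3 = dist_matrix(flat),
                           n_perm = 99), "zero variance")
  # label mismatch
  D3 <- random_dist(5, labels = sprintf("z%d", 1:5))
  expect_error(mantel_test(D1, D3, n_perm = 99), "labels")
  expect_error(mantel_test(random_dist(3), random_dist(3), n_perm = 99),
               "four")
})

test_that("partial Mantel reduces to plain Mantel when the control is independent", {
  set.seed(108)
  diffs <- replicate(20, {
    D1 <- random_dist(50)
    m2 <- unclass(D1) + as.matrix(dist(matrix(rnorm(50), 50)))
    dimnames(m2) <- dimnames(unclass(D1)); diag(m2) <- 0
    D2 <- dist_matrix((m2 + t(m2)) / 2)
    D3 <- random_dist(50)
    plain <- mantel_test(D1, D2, n_perm = 99, seed = 9)$r
    part <- mantel_test(D1, D2, D3 = D3, n_perm = 99, seed = 9)$r
    abs(part - plain)
  })
  expect_lt(mean(diffs), 0.05)
})

test_that("phylogenetically restricted permutations are valid and seeded", {
  tr <- simulate_tree(12, seed = 110)
  pat <- ape::cophenetic.phylo(tr)
  set.seed(1); p1 <- phylo_permutation(pat)
  set.seed(1); p2 <- phylo_permutation(pat)
  expect_identical(p1, p2)
  expect_setequal(p1, 1:12)
  # near pairs swap more often than the most distant pair
  # with a single swap, the swapped pair is identifiable: the nearest
  # pair must be drawn more often than the most distant pair
  far <- sort(as.integer(which(pat == max(pat), arr.ind = TRUE)[1, ]))
  near <- sort(as.integer(which(pat == min(pat[pat > 0]),
                                arr.ind = TRUE)[1, ]))
  set.seed(2)
  swapped_far <- 0; swapped_near <- 0
  for (i in 1:500) {
    p <- phylo_permutation(pat, n_swaps = 1)
    pair <- which(p != seq_along(p))
    if (identical(pair, near)) swapped_near <- swapped_near + 1
    if (identical(pair, far)) swapped_far <- swapped_far + 1
  }
  expect_gt(swapped_near, swapped_far)
})

test_that("the phylo-restricted null rejects less often under shared signal", {
  # two traits evolved with strong phylogenetic signal on the same tree:
  # their distance matrices correlate through the tree alone, inflating
  # the naive Mantel test; the restricted null should temper that.
  set.seed(111)
  n_rep <- 150
  naive_rej <- 0; phylo_rej <- 0
  for (i in 1:n_rep) {
    tr <- simulate_tree(20, seed = 1000 + i)
    C <- phylo_covariance(tr)
    ch <- chol(C + diag(1e-10, 20))
    y1 <- drop(crossprod(ch, rnorm(20))); names(y1) <- tr$tip.label
    y2 <- drop(crossprod(ch, rnorm(20))); names(y2) <- tr$tip.label
    D1 <- euclidean_distance(cbind(y1))
    D2 <- euclidean_distance(cbind(y2))
    pm <- mantel_test(D1, D2, n_perm = 99)$p
    pp <- phylo_mantel_test(D1, D2, tr, n_perm = 99)$p
    naive_rej <- naive_rej + (pm <= 0.05)
    phylo_rej <- phylo_rej + (pp <= 0.05)
  }
  expect_lt(phylo_rej, naive_rej)
})

test_that("phylo mantel accepts the patristic matrix as control", {
  set.seed(112)
  tr <- simulate_tree(10, seed = 113)
  D1 <- random_dist(10, labels = tr$tip.label)
  D2 <- random_dist(10, labels = tr$tip.label)
  res <- phylo_mantel_test(D1, D2, tr, control = "patristic",
                           n_perm = 99, seed = 8)
  expect_equal(res$partial_controls, "patristic distances")
  expect_true(abs(res$r) <= 1)
  # tree must cover the labels
  Dz <- random_dist(10, labels = sprintf("q%d", 1:10))
  expect_error(phylo_mantel_test(Dz, Dz, tr, n_perm = 99), "cover")
})
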