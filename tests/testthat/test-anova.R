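test_that("two-way ANOVA isolates constructed effects", {
  # balanced 2x2, cell means differ along species only (exact responses)
  sp <- rep(c("a", "b"), each = 8)
  st <- rep(rep(c("x", "y"), each = 4), 2)
  y <- ifelse(sp == "b", 1, 0)
  at <- two_way_anova(y, sp, st)
  expect_gt(at$F[at$term == "species"], 0)
  expect_equal(at$F[at$term == "site"], 0)
  expect_equal(at$F[at$term == "species:site"], 0)
  # all observations equal: F = 0 everywhere
  at0 <- two_way_anova(rep(3, 16), sp, st)
  expect_equal(at0$F[1:3], c(0, 0, 0))
})

test_that("sequential sums of squares match the balanced-design formulas", {
  # 3 species x 2 sites, n = 2 per cell: orthogonal design, so the
  # sequential SS equal the direct between-group formulas
  set.seed(402)
  sp <- rep(c("a", "b", "c"), each = 4)
  st <- rep(rep(c("x", "y"), each = 2), 3)
  y <- rnorm(12, mean = c(0, 0, 1, 1, 2, 2, 0, 0, 3, 3, 1, 1))
  gm <- mean(y)
  ss_sp <- sum(tapply(y, sp, function(v) length(v) * (mean(v) - gm)^2))
  ss_st <- sum(tapply(y, st, function(v) length(v) * (mean(v) - gm)^2))
  cell <- interaction(sp, st)
  ss_cells <- sum(tapply(y, cell, function(v) length(v) * (mean(v) - gm)^2))
  ss_int <- ss_cells - ss_sp - ss_st
  ss_res <- sum((y - ave(y, cell))^2)
  F_sp <- (ss_sp / 2) / (ss_res / 6)
  F_st <- (ss_st / 1) / (ss_res / 6)
  F_int <- (ss_int / 2) / (ss_res / 6)
  at <- two_way_anova(y, sp, st)
  expect_equal(at$df[1:4], c(2, 1, 2, 6))
  expect_equal(at$F[1:3], c(F_sp, F_st, F_int), tolerance = 1e-10)
  expect_equal(at$p[1], pf(F_sp, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("interaction df shrink to the species shared across sites", {
  # 14 species total, 12 at one site, 9 at the other, 7 shared:
  # sequential df should be 13, 1 and 6
  set.seed(403)
  species <- sprintf("sp%02d", 1:14)
  site1 <- species[1:12]
  site2 <- c(species[6:12], species[13:14])   # 7 shared with site1
  rows <- rbind(
    expand.grid(species = site1, site = "one", rep = 1:3,
                stringsAsFactors = FALSE),
    expand.grid(species = site2, site = "two", rep = 1:3,
                stringsAsFactors = FALSE)
  )
  y <- rnorm(nrow(rows))
  at <- two_way_anova(y, rows$species, rows$site)
  expect_equal(at$df[1:3], c(13, 1, 6))
  expect_true(attr(at, "restricted_interaction"))
})

test_that("two-way F statistics are invariant under affine response transforms", {
  set.seed(404)
  sp <- sample(c("a", "b", "c"), 30, replace = TRUE)
  st <- sample(c("x", "y"), 30, replace = TRUE)
  y <- rnorm(30)
  f1 <- two_way_anova(y, sp, st)$F
  f2 <- two_way_anova(5 - 3 * y, sp, st)$F
  expect_equal(f2, f1, tolerance = 1e-9)
})

test_that("Welch one-way ANOVA behaves at its edge cases and equals t^2", {
  g <- rep(c("a", "b"), each = 10)
  y <- rep(c(1, 1), each = 10)
  expect_error(welch_oneway(y[1:3], c("a", "a", "b")), "two observations")
  # equal group means: F ~ 0
  set.seed(405)
  y2 <- rnorm(20)
  y2 <- y2 - ave(y2, g) # both group means exactly 0
  res <- welch_oneway(y2, g)
  expect_lt(res$statistic, 1e-20)
  # two groups: F = t^2 with the same df2
  x <- rnorm(12); z <- rnorm(9, 1, 2)
  fw <- welch_oneway(c(x, z), rep(c("a", "b"), c(12, 9)))
  tw <- welch_t(x, z)
  expect_equal(fw$statistic, tw$statistic^2, tolerance = 1e-10)
  expect_equal(fw$df[2], tw$df, tolerance = 1e-10)
  # shift invariance
  fs <- welch_oneway(c(x, z) + 100, rep(c("a", "b"), c(12, 9)))
  expect_equal(fs$statistic, fw$statistic, tolerance = 1e-9)
})

test_that("Bartlett's statistic matches the direct formula", {
  set.seed(406)
  y <- c(rnorm(6, 0, 1), rnorm(8, 0, 2), rnorm(5, 0, 0.5))
  g <- rep(c("a", "b", "c"), c(6, 8, 5))
  res <- bartlett_variances(y, g)
  ni <- tapply(y, g, length); vi <- tapply(y, g, var)
  k <- 3; N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  K2 <- ((N - k) * log(sp2) - sum((ni - 1) * log(vi))) /
    (1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  expect_equal(res$statistic, unname(K2), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p, pchisq(unname(K2), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical samples shifted: equal variances, K^2 = 0
  base <- rnorm(6)
  res0 <- bartlett_variances(c(base, base + 5), rep(c("a", "b"), each = 6))
  expect_equal(res0$statistic, 0, tolerance = 1e-10)
  expect_error(bartlett_variances(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "zero variance")
})

test_that("Welch's t matches the closed formula on a small sample pair", {
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7, 23.2,
         17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 24.0, 13.2)
  res <- welch_t(x, y)
  se <- sqrt(var(x) / 10 + var(y) / 20)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 10)^2 / 9 + (var(y) / 20)^2 / 19)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # symmetry: flipping the difference flips t, keeps p
  res2 <- welch_t(y, x)
  expect_equal(res2$statistic, -res$statistic)
  expect_equal(res2$p, res$p)
  # identical samples: t = 0, p = 1
  set.seed(407); z <- rnorm(8)
  res3 <- welch_t(z, z)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p, 1)
})

test_that("site correlation flags the planted influential species", {
  set.seed(408)
  x <- 1:7 + rnorm(7, 0, 0.05)
  y <- 2 * (1:7) + rnorm(7, 0, 0.05)
  y[4] <- -5  # planted outlier
  names(x) <- names(y) <- sprintf("sp%d", 1:7)
  res <- site_correlation(x, y)
  expect_equal(res$influential, "sp4")
  expect_equal(nrow(res$leave_one_out), 7)
  best <- max(abs(res$leave_one_out$r_without))
  expect_equal(abs(res$leave_one_out$r_without[4]), best)
  # collinear points give |r| = 1 at any scale
  res2 <- site_correlation(setNames(c(1, 2, 3), letters[1:3]),
                           setNames(c(10, 20, 30), letters[1:3]),
                           leave_one_out = FALSE)
  expect_equal(res2$r, 1, tolerance = 1e-12)
  expect_error(site_correlation(setNames(1:3, letters[1:3]),
                                setNames(rep(1, 3), letters[1:3])),
               "zero variance")
})

test_that("p-values are uniform under the null (classical tests)", {
  set.seed(409)
  n_rep <- 400
  p_w <- p_b <- numeric(n_rep)
  g <- rep(c("a", "b", "c"), each = 8)
  for (i in 1:n_rep) {
    y <- rnorm(24)
    p_w[i] <- welch_oneway(y, g)$p
    p_b[i] <- bartlett_variances(y, g)$p
  }
  expect_lt(abs(mean(p_w <= 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(p_b <= 0.05) - 0.05), 0.03)
})
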