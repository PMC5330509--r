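make_traps <- function(values) {
  # single-variable trap table padded with 13 noise columns so the
  # 14-variable invariant holds
  n <- length(values)
  df <- data.frame(trap_id = sprintf("t%02d", seq_len(n)), var1 = values)
  for (j in 2:14) df[[paste0("var", j)]] <- seq_len(n) * j
  trap_habitat_table(df)
}

test_that("species habitat means average over distinct traps by default", {
  traps <- make_traps(c(10, 30, 40))
  caps <- data.frame(species = c("a", "a", "b", "b", "b"),
                     trap_id = c("t01", "t02", "t01", "t01", "t03"),
                     stringsAsFactors = FALSE)
  m <- species_habitat_means(traps, caps)
  expect_equal(unname(m["a", "var1"]), 20)
  # b caught twice in t01 (10) and once in t03 (40): distinct-trap mean 25
  expect_equal(unname(m["b", "var1"]), 25)
  # capture-weighted alternative: (10 + 10 + 40) / 3
  mw <- species_habitat_means(traps, caps, weighted = TRUE)
  expect_equal(unname(mw["b", "var1"]), 20)
  # single-trap species: that trap's values
  caps1 <- data.frame(species = "c", trap_id = "t02")
  expect_equal(unname(species_habitat_means(traps, caps1)["c", "var1"]), 30)
})

test_that("zero-capture species are excluded and reported", {
  traps <- make_traps(c(1, 2, 3))
  caps <- data.frame(species = "a", trap_id = "t01")
  m <- species_habitat_means(traps, caps, species = c("a", "ghost"))
  expect_equal(rownames(m), "a")
  expect_equal(attr(m, "dropped"), "ghost")
  expect_error(species_habitat_means(traps,
    data.frame(species = "a", trap_id = "t99")), "unknown trap")
})

test_that("habitat means commute with trap relabelling", {
  set.seed(51)
  traps_df <- data.frame(trap_id = sprintf("t%02d", 1:10))
  for (j in 1:14) traps_df[[paste0("v", j)]] <- rnorm(10)
  traps <- trap_habitat_table(traps_df)
  caps <- data.frame(species = sample(c("a", "b"), 30, replace = TRUE),
                     trap_id = sample(traps_df$trap_id, 30, replace = TRUE),
                     stringsAsFactors = FALSE)
  m1 <- species_habitat_means(traps, caps)
  relab <- setNames(sprintf("x%02d", 10:1), traps_df$trap_id)
  traps2_df <- traps_df; traps2_df$trap_id <- relab[traps_df$trap_id]
  caps2 <- caps; caps2$trap_id <- relab[caps$trap_id]
  m2 <- species_habitat_means(trap_habitat_table(traps2_df), caps2)
  expect_equal(m2, m1, ignore_attr = TRUE)
})

test_that("transform selection scores normality and breaks ties in fixed order", {
  # U-shaped values on (0,1): logit should beat log and arcsine-sqrt,
  # verified against directly computed Shapiro-Wilk scores
  set.seed(61)
  v <- rbeta(40, 0.3, 0.3)
  v <- pmin(pmax(v, 1e-4), 1 - 1e-4)
  sel <- select_transform(v)
  w_log <- shapiro.test(log(v))$statistic
  w_logit <- shapiro.test(log(v / (1 - v)))$statistic
  w_asin <- shapiro.test(asin(sqrt(v)))$statistic
  best <- c("log", "logit", "arcsine-sqrt")[which.max(c(w_log, w_logit, w_asin))]
  expect_equal(sel$transform, best)
  expect_equal(sel$transform, "logit")
  expect_equal(sel$W, unname(max(c(w_log, w_logit, w_asin))),
               tolerance = 1e-10)
})

test_that("boundary values are epsilon-shifted before log/logit", {
  v <- c(0, 0.2, 0.4, 0.8, 0.3, 0.6)
  sel <- select_transform(v)
  expect_true(all(is.finite(sel$values)))
  expect_equal(sel$epsilon, 0.1)   # half the smallest nonzero value
  # values outside [0,100] leave only log admissible; negatives leave none
  sel2 <- select_transform(c(150, 200, 300, 120))
  expect_equal(sel2$transform, "log")
  sel3 <- select_transform(c(-1, 0, 1, 2))
  expect_equal(sel3$transform, "none")
})

test_that("habitat distance is Euclidean and standardization-invariant", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  colnames(m) <- c("v1", "v2")
  expect_equal(unname(unclass(habitat_distance(m, standardize = FALSE))[1, 2]),
               5)
  m1 <- rbind(a = 1, b = 4, c = 2); colnames(m1) <- "v"
  expect_equal(unname(unclass(habitat_distance(m1, standardize = FALSE))["a", "b"]),
               3)
  # identical rows -> 0
  m2 <- rbind(a = c(1, 2), b = c(1, 2)); colnames(m2) <- c("v1", "v2")
  expect_equal(unname(unclass(habitat_distance(m2, standardize = FALSE))[1, 2]),
               0)
  # affine rescaling of a column leaves standardized distances unchanged
  set.seed(71)
  m3 <- matrix(rnorm(24), 6, 4,
               dimnames = list(sprintf("s%d", 1:6), sprintf("v%d", 1:4)))
  d1 <- habitat_distance(m3, standardize = TRUE)
  m4 <- m3; m4[, 2] <- 100 * m4[, 2] - 7
  d2 <- habitat_distance(m4, standardize = TRUE)
  expect_equal(unclass(d2), unclass(d1), tolerance = 1e-12)
  m5 <- m3; m5[, 3] <- 2
  expect_error(habitat_distance(m5, standardize = TRUE), "v3")
})

test_that("preferential captures raise the species mean above the trap mean", {
  set.seed(81)
  sc <- sim_scenario(n_species = 8, habitat_coupling = 0, seed = 81)
  u <- setNames(rep(2, 8), sprintf("sp%02d", 1:8))  # all prefer high axis
  hb <- simulate_habitat(sc, u, seed = 82)
  m <- species_habitat_means(hb$traps, hb$captures)
  trap_mean <- mean(hb$traps$variables[, "spinifex_cover_pct"])
  expect_true(all(m[, "spinifex_cover_pct"] > trap_mean))
})
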