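# Classical tests for between-species and between-site comparisons:
# sequential two-way ANOVA, Welch one-way ANOVA, Bartlett's test, Welch's
# t, and between-site correlation of species means. These wrap the base R
# fitters; the module's value is the study-shaped interface around them.

new_test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p = p, method = method),
            class = "iso_test")
}

#' @export
print.iso_test <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p))
  invisible(x)
}

#' Two-way ANOVA of an isotope response on species and site
#'
#' Fixed-effects linear model with sequential (type-I) sums of squares:
#' species entered first, then site, then their interaction. With species
#' unevenly shared across sites the interaction is automatically
#' restricted to the estimable cells (species present at more than one
#' site), and its degrees of freedom reflect that; the restriction is
#' reported via the `restricted_interaction` attribute.
#'
#' @param values per-individual responses (e.g. d15N).
#' @param species,site factors (or coercible) of the same length.
#' @return an `anova_table` data.frame with term, df, F, p rows
#'   (including Residuals with NA F/p).
#' @export
two_way_anova <- function(values, species, site) {
  species <- factor(species); site <- factor(site)
  if (nlevels(species) < 2L || nlevels(site) < 2L)
    stop("need at least two levels of species and of site")
  stopifnot(length(values) == length(species),
            length(values) == length(site))
  fit <- lm(values ~ species + site + species:site)
  # perfect fits are handled explicitly below; silence the stock caveat
  at <- withCallingHandlers(anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  full_int_df <- (nlevels(species) - 1L) * (nlevels(site) - 1L)
  Fv <- at$`F value`
  pv <- at$`Pr(>F)`
  # degenerate fits (residual SS numerically zero) need explicit handling:
  # terms explaining nothing get F = 0, terms explaining everything Inf
  ss <- at$`Sum Sq`
  tol <- 1e-10 * max(sum(ss), .Machine$double.eps)
  if (ss[length(ss)] <= tol) {
    null_term <- c(ss[-length(ss)] <= tol, FALSE)
    Fv[null_term] <- 0
    pv[null_term] <- 1
    real_term <- c(ss[-length(ss)] > tol, FALSE)
    Fv[real_term] <- Inf
    pv[real_term] <- 0
  }
  out <- data.frame(
    term = c("species", "site", "species:site", "Residuals"),
    df = at$Df,
    F = Fv,
    p = pv,
    stringsAsFactors = FALSE
  )
  # aliased interaction columns (species absent from a site) are dropped
  # by lm(); flag when the realized df fall short of the full factorial
  attr(out, "restricted_interaction") <- at$Df[3L] < full_int_df
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Sequential (type-I) two-way ANOVA\n")
  print.data.frame(format.data.frame(x, digits = 4), row.names = FALSE)
  if (isTRUE(attr(x, "restricted_interaction")))
    cat("(interaction restricted to species present at multiple sites)\n")
  invisible(x)
}

#' Welch one-way ANOVA (unequal variances)
#'
#' @param values numeric responses.
#' @param groups grouping factor; every group needs n >= 2.
#' @return an `iso_test` with Welch's F, (df1, df2) and p.
#' @export
welch_oneway <- function(values, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("every group needs at least two observations")
  zerovar <- tapply(values, groups, var) == 0
  if (any(zerovar))
    warning("zero within-group variance in: ",
            paste(names(tab)[zerovar], collapse = ", "))
  ot <- oneway.test(values ~ groups, var.equal = FALSE)
  new_test_result(unname(ot$statistic),
                  unname(ot$parameter),
                  ot$p.value,
                  "Welch one-way ANOVA")
}

#' Bartlett's test of homogeneity of variances
#'
#' @param values numeric responses.
#' @param groups grouping factor (>= 2 groups, each n >= 2, nonzero
#'   variance).
#' @return an `iso_test` with K-squared, df = k - 1 and the chi-squared p.
#' @export
bartlett_variances <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  v <- tapply(values, groups, var)
  if (any(v == 0))
    stop("zero variance in group(s): ",
         paste(names(v)[v == 0], collapse = ", "))
  bt <- bartlett.test(values ~ groups)
  new_test_result(unname(bt$statistic), unname(bt$parameter), bt$p.value,
                  "Bartlett's K-squared")
}

#' Welch's two-sample t-test
#'
#' @param x,y numeric samples (each n >= 2).
#' @return an `iso_test` with t, Welch-Satterthwaite df and two-sided p.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("both samples need n >= 2")
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y))
    stop("t undefined: both samples constant and equal")
  tt <- t.test(x, y, var.equal = FALSE)
  new_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  "Welch two-sample t-test")
}

#' Between-site correlation of species means
#'
#' Product-moment correlation of shared species' mean values between two
#' sites, with a two-sided t-based p, plus an optional leave-one-out
#' report identifying the species whose removal most increases |r|
#' (influential-point diagnostic).
#'
#' @param means_site1,means_site2 named per-species values (aligned on
#'   shared species, >= 3).
#' @param leave_one_out include the per-species removal report.
#' @return object of class `site_correlation`: `r`, `p`, `n`, and when
#'   requested `leave_one_out` (data.frame) and `influential` (species
#'   whose removal maximizes |r|).
#' @export
site_correlation <- function(means_site1, means_site2, leave_one_out = TRUE) {
  al <- align_labels(means_site1, means_site2)
  x <- as.numeric(al$objects[[1L]]); y <- as.numeric(al$objects[[2L]])
  labels <- al$labels
  n <- length(x)
  if (n < 3L) stop("need at least three shared species")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined: zero variance")
  ct <- cor.test(x, y)
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = n)
  if (leave_one_out && n > 3L) {
    loo <- vapply(seq_len(n), function(i) {
      cti <- cor.test(x[-i], y[-i])
      c(unname(cti$estimate), cti$p.value)
    }, numeric(2))
    out$leave_one_out <- data.frame(species = labels,
                                    r_without = loo[1L, ],
                                    p_without = loo[2L, ],
                                    stringsAsFactors = FALSE)
    out$influential <- labels[which.max(abs(loo[1L, ]))]
  }
  structure(out, class = "site_correlation")
}

#' @export
print.site_correlation <- function(x, ...) {
  cat(sprintf("Between-site correlation of species means: r = %.2f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  if (!is.null(x$influential))
    cat("  most influential species (removal maximizes |r|):",
        x$influential, "\n")
  invisible(x)
}
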