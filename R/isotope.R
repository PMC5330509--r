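# Delta notation, two-point standard normalization, species summaries and
# trophic-transfer arithmetic.

#' Delta value from isotope ratios
#'
#' Converts heavy/light isotope ratios to delta notation in per mil:
#' \deqn{\delta = (R_{sample} - R_{standard}) / R_{standard} \times 1000.}
#' For carbon the standard is V-PDB; for nitrogen, atmospheric N2.
#'
#' @param r_sample heavy/light isotope ratio of the sample (> 0).
#' @param r_standard heavy/light ratio of the reference (> 0).
#' @return delta value(s) in per mil.
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be finite and strictly positive")
  (r_sample - r_standard) / r_standard * 1000
}

#' Two-point normalization against in-house standards
#'
#' Fits the unique line mapping the measured delta values of two standards
#' onto their known values, the usual correction for instrument linearity.
#' Sample values are corrected via `predict()`:
#' `known = slope * measured + intercept`.
#'
#' @param known per-mil known (accepted) values of the two standards.
#' @param measured per-mil measured values of the same two standards.
#' @return an object of class `iso_norm` with `slope` and `intercept`.
#' @export
fit_two_point_normalization <- function(known, measured) {
  stopifnot(length(known) == 2L, length(measured) == 2L)
  if (any(!is.finite(known)) || any(!is.finite(measured)))
    stop("standard values must be finite")
  if (known[1L] == known[2L])
    stop("the two known standard values must differ")
  if (measured[1L] == measured[2L])
    stop("degenerate fit: the two measured standard values are identical")
  slope <- (known[2L] - known[1L]) / (measured[2L] - measured[1L])
  intercept <- known[1L] - slope * measured[1L]
  structure(list(slope = slope, intercept = intercept,
                 standards = list(known = known, measured = measured)),
            class = "iso_norm")
}

#' @export
predict.iso_norm <- function(object, newdata, ...) {
  object$slope * newdata + object$intercept
}

#' @export
print.iso_norm <- function(x, ...) {
  cat("Two-point isotope normalization: corrected =",
      format(x$slope), "* measured +", format(x$intercept), "\n")
  invisible(x)
}

#' Apply two-point normalization to an isotope table
#'
#' @param x isotope data.frame (see [read_isotope_table()]).
#' @param model_d13C,model_d15N `iso_norm` models, fit per isotope; either
#'   may be NULL to leave that isotope untouched.
#' @return the corrected data.frame.
#' @export
normalize_isotopes <- function(x, model_d13C = NULL, model_d15N = NULL) {
  validate_isotope_table(x)
  if (!is.null(model_d13C)) x$d13C <- predict(model_d13C, x$d13C)
  if (!is.null(model_d15N)) x$d15N <- predict(model_d15N, x$d15N)
  x
}

#' Correct for ethanol-preservation enrichment of d13C
#'
#' Preservation of liver tissue in 95% ethanol can raise d13C by roughly
#' 1.5 per mil; this subtracts a constant offset from every d13C value and
#' leaves d15N untouched. The default offset of 0 (no correction) reflects
#' the common finding that preservation effects are negligible for most
#' tissues.
#'
#' @param x isotope data.frame.
#' @param offset per-mil value subtracted from d13C (default from config: 0).
#' @return corrected data.frame.
#' @export
apply_preservation_offset <- function(x, offset = 0) {
  validate_isotope_table(x)
  if (!is.finite(offset)) stop("offset must be finite")
  x$d13C <- x$d13C - offset
  x
}

#' Species-level isotopic summary for one site
#'
#' Computes per-species means, ranges (max minus min over individuals) and
#' sample sizes for both isotopes at a site, plus the community-wide range
#' of species means. Species with fewer individuals than `min_n` are
#' flagged (`low_n`), not dropped.
#'
#' @param x isotope data.frame.
#' @param site site label (matched exactly after trimming).
#' @param min_n sample-size floor below which a species is flagged.
#' @return an object of class `community_summary`: a list with the site,
#'   a per-species data.frame `summaries`, and `community_range_d15N` /
#'   `community_range_d13C` (max minus min of species means).
#' @export
summarize_species <- function(x, site, min_n = 1L) {
  validate_isotope_table(x)
  rows <- x[x$site == trimws(site), , drop = FALSE]
  if (!nrow(rows)) stop("no measurements at site \"", site, "\"")
  sp <- sort(unique(rows$species))
  stat <- function(s, col, f) f(rows[[col]][rows$species == s])
  summaries <- data.frame(
    species = sp,
    n = vapply(sp, function(s) sum(rows$species == s), 1L),
    mean_d15N = vapply(sp, stat, 1, col = "d15N", f = mean),
    mean_d13C = vapply(sp, stat, 1, col = "d13C", f = mean),
    range_d15N = vapply(sp, stat, 1, col = "d15N", f = function(v) diff(range(v))),
    range_d13C = vapply(sp, stat, 1, col = "d13C", f = function(v) diff(range(v))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  summaries$low_n <- summaries$n < min_n
  structure(list(
    site = site,
    summaries = summaries,
    community_range_d15N = diff(range(summaries$mean_d15N)),
    community_range_d13C = diff(range(summaries$mean_d13C))
  ), class = "community_summary")
}

#' @export
print.community_summary <- function(x, digits = 2, ...) {
  cat("Community isotopic summary -", x$site, "\n")
  df <- x$summaries
  df[c("mean_d15N", "mean_d13C", "range_d15N", "range_d13C")] <-
    lapply(df[c("mean_d15N", "mean_d13C", "range_d15N", "range_d13C")],
           round, digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("Community range of species means: d15N %.2f, d13C %.2f (per mil)\n",
              x$community_range_d15N, x$community_range_d13C))
  invisible(x)
}

#' Trophic transfers implied by a d15N difference
#'
#' Under a constant per-transfer enrichment of d15N, the number of trophic
#' transfers separating two values is their difference divided by the
#' enrichment factor; the number of trophic levels spanned is that plus
#' one. A negative result signals reversed ordering.
#'
#' @param d15N_high,d15N_low per-mil d15N values.
#' @param enrichment per-mil enrichment per transfer (> 0; default 2.5).
#' @return number of transfers (real-valued).
#' @export
trophic_transfers <- function(d15N_high, d15N_low, enrichment = 2.5) {
  if (!is.finite(enrichment) || enrichment <= 0)
    stop("enrichment must be positive")
  (d15N_high - d15N_low) / enrichment
}

#' @rdname trophic_transfers
#' @export
trophic_levels_spanned <- function(d15N_high, d15N_low, enrichment = 2.5) {
  trophic_transfers(d15N_high, d15N_low, enrichment) + 1
}

#' Trophic span of a community summary
#'
#' Transfers and levels spanned by a community, either across species mean
#' d15N values (default) or across individual extremes.
#'
#' @param summary a [summarize_species()] result, or the isotope
#'   data.frame itself when `use = "individuals"` needs raw values.
#' @param enrichment per-mil enrichment per transfer.
#' @param use "means" (range of species means) or "individuals" (range of
#'   individual values; requires the raw table via `data`).
#' @param data raw isotope data.frame, needed for `use = "individuals"`.
#' @return list with `transfers` and `levels_spanned`.
#' @export
community_trophic_span <- function(summary, enrichment = 2.5,
                                   use = c("means", "individuals"),
                                   data = NULL) {
  use <- match.arg(use)
  stopifnot(inherits(summary, "community_summary"))
  span <- if (use == "means") {
    summary$community_range_d15N
  } else {
    if (is.null(data)) stop("`data` required when use = \"individuals\"")
    rows <- data[data$site == summary$site, , drop = FALSE]
    diff(range(rows$d15N))
  }
  transfers <- span / enrichment
  list(transfers = transfers, levels_spanned = transfers + 1)
}
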