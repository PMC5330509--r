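---
title: "Methods: community stable-isotope analysis with isotroph"
author: "isotroph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community stable-isotope analysis with isotroph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isotroph)
```

# Scope and data model

`isotroph` analyses a community of co-occurring species through three data
streams: per-individual carbon and nitrogen stable isotope measurements
(δ¹³C, δ¹⁵N in per mil), per-species stomach-content proportions over prey
categories, and per-trap habitat measurements linked to species by capture
records. A time-calibrated ultrametric phylogeny ties the comparative
tests together. All interchange is plain CSV (UTF-8, header row, decimal
per-mil values) and Newick; species names are matched case-insensitively
after trimming, with underscores and spaces treated as equivalent, because
tree files and field tables habitually disagree on exactly this point.

# Isotope arithmetic

Delta notation is δ = (R_sample − R_standard)/R_standard × 1000, with R
the heavy/light isotope ratio. Instrument linearity is corrected by
two-point normalization: the unique line mapping the measured delta values
of two in-house standards onto their accepted values, fit per isotope and
applied to samples. The package assumes inputs are drift-stable (no
run-order correction): a run-sequence drift model needs the sample order,
which field datasets rarely retain.

An optional constant (`ethanol_d13C_offset`, default 0, conventionally
1.5‰) is subtracted from δ¹³C to undo the enrichment reported for liver
tissue stored in 95% ethanol. It is off by default because preservation
effects are negligible for most tissues; when used it is a uniform shift,
so all range- and distance-based results are unchanged and only absolute
δ¹³C positions move.

Community trophic structure is summarized by the range of species mean
δ¹⁵N divided by a constant per-transfer enrichment
(`enrichment_per_transfer`, default 2.5‰ per trophic level; 2.54‰ is the
common meta-analytic alternative). Transfers + 1 gives trophic levels
spanned. Whether a community's span should be computed over species means
or over individual extremes is genuinely ambiguous in practice; both modes
exist (`community_trophic_span(use = "means")`, the default, and
`use = "individuals"`), and the default is means because the rest of the
pipeline operates on species means.

# Weighted trophic rank

Prey categories carry ranks on a 1–5 scale (1 producer, 2 primary grazer,
3 omnivorous consumer, 4 predator of omnivores, 5 vertebrate predator);
higher taxa that may span two adjacent ranks take the midpoint, so halves
are legal. A species' weighted trophic rank is WTR = Σᵢ pᵢTᵢ over the prey
present in its stomachs. Proportions are renormalized to sum to one by
default — mean percent-volume rows from the literature rarely sum exactly
to one, and without renormalization the statistic is no longer bounded by
the prey ranks. The `normalized` flag records which convention produced a
value. The shipped 63-category coding is a reconstruction from exemplar
assignments and general arthropod natural history (e.g. Isoptera 2,
Pentatomidae 2, Araneae and Chilopoda 3.5 as omnivore/predator
intermediates, vertebrates 5) and is meant to be edited per study: rank
assignments for many taxa are judgment calls, which is why the coding is
data, not code.

Species enter diet-based analyses only with at least `min_diet_n` stomachs
(default 5), the usual floor below which mean proportions are dominated by
individual meals. Diet distances are plain Euclidean distances between
proportion vectors, optionally restricted to a category subset (e.g.
termites only); whether raw or transformed proportions are the better
substrate is unsettled, so the package computes on whatever the table
holds and leaves transformations to the user.

# Habitat scores

Species habitat scores are means of each trap-level variable over the
distinct traps where the species was caught: a trap that caught a species
many times counts once, since repeat captures measure trappability, not a
different habitat. A capture-weighted mode exists for users who prefer
effort weighting. Each variable is then transformed by whichever of log,
logit, or arcsine-square-root scores highest on the Shapiro–Wilk W of the
transformed values — the candidate set is standard for mixtures of
percentages and counts, and W is used because it is a single, comparable
normality score. Ties break in the fixed order log > logit > arcsine-sqrt;
"none" is used when no transform is admissible (e.g. negative values).
Logit and arcsine-sqrt are offered only for values representable on
[0, 1], with percentage-scale columns divided by 100. Exact boundary
values are shifted into the domain by half the smallest nonzero margin and
the shift is recorded. Habitat distances are Euclidean over
column-standardized transformed means; standardization defaults on because
the 14 variables mix percentages, counts and volumes, and a flag preserves
the unstandardized alternative since either convention is defensible.

# Mantel machinery

The Mantel statistic is the product-moment correlation of the strictly
lower triangles of two species distance matrices sharing one label order.
The null permutes rows and columns of the second matrix simultaneously
with a seeded generator; the p-value is (1 + #{r_perm ≥ r_obs})/(n_perm + 1),
so the identity permutation is always counted and p ≥ 1/(n_perm + 1). The
default tail is upper (one-sided for positive association), the usual
convention for ecological distance association — a strongly negative
observed r therefore yields p near 1, and a two-tailed option exists. The
partial Mantel statistic is the partial correlation
r₁₂·₃ = (r₁₂ − r₁₃r₂₃)/√((1 − r₁₃²)(1 − r₂₃²)) with the third matrix held
fixed while the second is permuted.

The phylogenetically restricted null replaces uniform label permutations
with a sequence of pairwise swaps in which pair (i, j) is drawn with
weight 1/(d_patristic(i, j) + δ): close relatives trade places often,
distant tips rarely, so the null preserves the phylogenetic
autocorrelation that inflates the naive test's type-I error when both
matrices carry signal from the same tree. Defaults: n swaps per
permutation equal to the number of species, δ = one tenth of the mean
off-diagonal patristic distance (small enough to make near-pair swaps
dominate, large enough to keep all pairs reachable). The literature
describes several restricted-permutation schemes without a canonical
algorithm; this one is an explicit documented choice, and its p-values
should be compared across schemes qualitatively, not to the second
decimal. When no control matrix is supplied, the patristic distance matrix
itself can serve as the partial-Mantel control (`control = "patristic"`),
which addresses the related but distinct question of association beyond
linear phylogenetic-distance effects.

# Pagel's λ

The trait model is multivariate normal: y ~ MVN(μ1, σ²C(λ)), where C is
the Brownian-motion covariance (shared root-to-ancestor branch length) and
C(λ) scales the off-diagonal by λ ∈ [0, 1]. μ and σ² are profiled
analytically by GLS/ML; λ is maximized on a 1001-point grid (step 10⁻³)
followed by golden-section refinement in the bracketing interval
(tolerance 10⁻⁸). For ultrametric trees the diagonal of C is constant, so
C(λ) = λ(C − T·I) + T·I shares C's eigenvectors; one eigendecomposition
makes every λ evaluation O(n), which is what keeps 128-tip fits cheap.
Non-ultrametric trees fall back to a Cholesky factorization per λ.
Estimates below 10⁻³ are flagged "effectively zero". The significance test
is a likelihood-ratio test of λ̂ against λ = 0 referred to χ²(1) — the
common convention despite the boundary — with the conservative 50:50
chi-bar-squared mixture behind a flag. λ is estimated within [0, 1] only;
implementations that allow λ slightly above 1 can report marginally higher
likelihoods on strong-signal data, which matters only at the boundary.

# Classical tests

The species-by-site ANOVA is a fixed-effects linear model with sequential
(type-I) sums of squares, species entered first. With species unevenly
shared across sites, the interaction is automatically restricted to the
estimable cells — its degrees of freedom equal the number of species
present at multiple sites minus one — and the restriction is flagged.
Welch's one-way ANOVA, Welch's t and Bartlett's K² wrap the base R
implementations; degenerate inputs (zero-variance groups, constant
responses) are either rejected with a clear error or, for a constant
response in the two-way ANOVA, mapped to F = 0 by convention. Between-site
comparisons correlate shared species' means (Pearson, two-sided t-based p)
and report a leave-one-out table naming the species whose removal most
increases |r|.

# The synthetic community generator

The generator's role is to plant known truth behind every pipeline stage.
Species trophic positions evolve on a unit-depth pure-birth tree as a
Brownian trait with covariance σ²C(λ_true) around a central position of 3,
clamped to [1.5, 4.5] (the clamp rarely binds at the default σ² = 0.5, so
λ recovery is not materially distorted). Diets are Dirichlet draws
(concentration 50 by default) around a softmax base composition solved so
the expected WTR equals the planted position — position first, diet
second, because acceptance testing needs exact ground truth for WTR.
Species mean δ¹⁵N is baseline + enrichment × (position − 1) with
enrichment 2.5‰; δ¹³C mixes C3 (−27‰) and C4 (−13‰) baselines through a
weight compressed to (0.25, 0.75), reflecting that most desert skinks feed
across both vegetation pathways and keeping community δ¹³C spreads in the
4–7‰ band typical of such assemblages. Individuals (2–20 per species) are
drawn around species means with a 1‰ within-species SD; additional sites
shift δ¹⁵N by +2‰ per site, mimicking between-region baseline differences.

Habitat data are 14 trap variables at 120 traps: four
vegetation/substrate variables load on one latent spinifex-vs-Acacia axis,
ten are noise. Captures follow a log-linear preference for the axis. Two
latent species-level variables matter: the capture-preference axis, which
is correlated with trophic position (hence δ¹⁵N) at `habitat_coupling`,
and an independent dietary-carbon variable driving δ¹³C. Keeping these
separate is what makes `habitat_coupling = 0` a genuine null — habitat and
isotope distances are then independent — while `habitat_coupling = 0.9`
plants a recoverable association.

What the generator does not emulate: spatial autocorrelation among traps,
fire-succession dynamics, ontogenetic diet shifts, site-specific prey
baselines, and measurement error in the isotope ratios themselves. Tests
passing on synthetic data therefore validate the estimators and their
calibration, not the field realism of any particular dataset.

# Numerical choices and problem sizes

Distance matrices must be symmetric to 10⁻¹², non-negative, with an
exactly zero diagonal; CSV round trips symmetrize to absorb
decimal-printing asymmetry. Covariance matrices receive a 10⁻¹⁰ diagonal
jitter before Cholesky in the simulators. Permutation counts default to
999; all draws come from one seeded generator per call, and the run report
records seed, configuration and package version.

The validation suite runs at sizes chosen to make each property sharp but
cheap: exact Mantel enumeration at n = 4 against 999 permutations; type-I
calibration over 2000 independent 8-species datasets at 199 permutations;
λ recovery on 128-tip trees over 100 replicates at both λ = 1 and λ = 0,
with a 10⁻³-step grid brute force on 16-tip problems; WTR recovery over
200 Dirichlet replicates at concentration 50; and end-to-end power over
100 simulated 30-species communities at coupling 0.9. On the λ = 0
recovery, note that the proportion of fits with λ̂ < 0.05 under
independent traits sits near 0.9 on 128-tip pure-birth trees — that is the
genuine null spread of the MLE (estimates agree with independent
implementations to 10⁻⁴), so a ≥ 90% pass proportion over 100 replicates
is intrinsically at the sampling boundary.

# Known limitations

Pagel's λ assumes an ultrametric tree for its fast path and a single
multivariate-normal trait; no Ornstein–Uhlenbeck or Blomberg's K
alternatives are provided. The phylogenetically restricted permutation
scheme is one of several in the literature and its p-values are
scheme-dependent. Bayesian ellipse niche metrics and isotope mixing models
are out of scope. The Bartlett and Welch wrappers require the grouping to
be chosen explicitly by the caller — with species crossed with sites there
is no single canonical grouping, and the package does not guess.
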