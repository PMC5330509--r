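# isotroph

Community-level stable-isotope trophic ecology for species-rich lizard
assemblages (and similar terrestrial communities).

Field surveys of desert skink communities yield three loosely coupled data
streams: carbon and nitrogen stable isotope ratios measured on individual
specimens, stomach-content proportions summarized per species, and habitat
measurements taken at the pitfall traps where each species was captured.
`isotroph` provides the full analysis path for asking whether these streams
tell a consistent story — whether species that sit close together in
isotopic space also eat similar prey, use similar habitat, or are simply
close relatives. It is aimed at community and trophic ecologists working
with multi-species isotope datasets plus a time-calibrated phylogeny.

## What it computes

**Delta notation and normalization.** Isotope ratios are expressed in per
mil as δ = (R_sample − R_standard)/R_standard × 1000, with two-point
normalization against in-house standards (the unique line mapping measured
standard values onto their accepted values) and an optional constant
correction for ethanol-preserved liver tissue.

**Species and community summaries.** Per-species means and ranges of δ¹⁵N
and δ¹³C at each site, the community-wide range of species means, and the
number of trophic transfers that range implies under a constant per-transfer
δ¹⁵N enrichment (default 2.5‰, i.e. transfers = Δδ¹⁵N / 2.5).

**Weighted trophic rank.** From stomach contents, each prey category gets a
trophic rank T on a 1–5 scale (1 producer … 5 vertebrate predator, with
midpoints for ambiguous higher taxa), and a species' rank is the
proportion-weighted mean WTR = Σᵢ pᵢTᵢ over the prey in its stomachs. A
63-category coding table ships as an editable CSV.

**Habitat scores.** Per-species means of 14 trap-level habitat variables
over the distinct traps where the species was caught, each variable
transformed by whichever of log / logit / arcsine-square-root best
normalizes it (Shapiro–Wilk W), then Euclidean distances over standardized
columns.

**Comparative tests.** Mantel and partial Mantel permutation tests between
Euclidean distance matrices (isotopic, dietary, habitat spaces), written
from first principles with a seeded permutation engine; an optional
phylogenetically restricted null in which the probability that two species
trade places decays with their patristic distance (weight ∝ 1/(d + δ)); and
maximum-likelihood Pagel's λ for phylogenetic signal, profiling the GLS
mean and rate analytically and optimizing λ on [0, 1] by a dense grid plus
golden-section refinement, with a likelihood-ratio test against λ = 0.
Classical tests (sequential two-way ANOVA, Welch one-way ANOVA and t-test,
Bartlett's variance test, between-site correlations with leave-one-out
diagnostics) round out the toolkit.

**Synthetic communities.** A generator plants known ground truth — trophic
positions evolving on a pure-birth tree with tunable λ, Dirichlet diets
whose expected WTR equals the planted position, C3/C4-mixed δ¹³C, and a
latent spinifex-vs-Acacia habitat axis with tunable coupling to δ¹⁵N — so
every stage of the pipeline can be validated end to end.

## Worked example

```r
library(isotroph)
scenario <- sim_scenario(n_species = 12, habitat_coupling = 0.9, seed = 1)
sim <- simulate_community(scenario)
result <- run_pipeline(sim$isotopes, diet = sim$diet,
                       coding = trophic_coding(sim$truth$prey_ranks),
                       traps = sim$traps, captures = sim$captures,
                       tree = sim$tree,
                       config = analysis_config(n_permutations = 999,
                                                rng_seed = 1))
print(result)
```

```
isotroph pipeline run (package 0.1.0 )
- site1: 12 species, community d15N range 4.08, d13C range 6.93; 1.63 trophic transfers
    Mantel habitat vs isotope: r = 0.424, p = 0.005
      (phylo-permuted: r = 0.424, p = 0.009)
    Mantel diet vs isotope: r = 0.283, p = 0.045
      (phylo-permuted: r = 0.283, p = 0.059)
    Mantel termite-only diet vs isotope: r = 0.077, p = 0.311
      (phylo-permuted: r = 0.077, p = 0.336)
    Mantel habitat vs diet: r = 0.293, p = 0.023
      (phylo-permuted: r = 0.293, p = 0.033)
- Pagel's lambda (d15N): 0, LRT p = 1
- Pagel's lambda (d13C): 0, LRT p = 1
```

The community's species means span 4.08‰ in δ¹⁵N — about 1.6 trophic
transfers at 2.5‰ per transfer. The planted habitat–isotope coupling of 0.9
is recovered by the Mantel test (r = 0.42, one-tailed permutation
p = 0.005) and survives the phylogenetically restricted null (p = 0.009).
Phylogenetic signal is correctly absent here: with strong habitat coupling
the isotope means track the (non-heritable) capture axis, and λ̂ = 0.

`summarize_species(sim$isotopes, "site1")` prints the per-species table
behind the first line (means, max-minus-min ranges and n per species).

A command-line front end with the same verbs (`summarize`, `normalize`,
`wtr`, `distances`, `mantel`, `phylosig`, `anova`, `simulate`, `run-all`)
is installed at `system.file("cli", "isotroph.R", package = "isotroph")`.

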