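# sisca — Stable Isotope Cluster Analysis for protein-SIP metaproteomics

Protein stable isotope probing (protein-SIP) feeds a microbial community
an isotopically labeled substrate — here ¹³C-bicarbonate/¹³CO₂ — and reads
the label back out of peptide mass spectra. The isotopologue pattern of a
peptide (peaks spaced by the ¹³C−¹²C mass difference over charge) encodes
the fraction of its carbon that is ¹³C, the *relative isotope abundance*
(RIA; natural abundance ≈ 1.07%). This package is for microbial ecologists
and metaproteomics practitioners who want to turn such spectra into
time-resolved, genome-bin-level statements about who assimilates which
carbon, how fast they grow, and how much of the community's carbon the
labeled pool has replaced.

## What it computes

For each peptide, the measured pattern is compared against 21 predicted
patterns at 5% RIA intervals (0–100%); each comparison yields a
coefficient of determination

R² = 1 − Σᵢ(mᵢ − pᵢ)² / Σᵢ(mᵢ − m̄)²,

and the full 21-vector of R² values — not just its argmax — is the
feature retained. Vectors are averaged per MAG (metagenome-assembled
genome) and time point, ordinated by PCA, validated with 95%
confidence ellipses, and classified into trophic lifestyles (strict
autotroph, switching mixotroph, cross-feeding incorporator, unlabeled
heterotroph). Growth is quantified from the intensity split between the
unlabeled and labeled peptide populations: doublings
n = log₂[(I₁₂C + I₁₃C)/I₁₃C] and generation time t_d = Δt/n, plus a
community-level ¹³C carbon-replacement fraction. A separate module
processes single-cell Raman spectra from D₂O incubations (despiking, ALS
baseline, vector normalization) into C-D ratios
A(C-D)/[A(C-D)+A(C-H)] and PCA+LDA labeled/unlabeled calls. A
ground-truth simulator generates protein databases, identification
tables, labeled peak lists, and Raman spectra so that every stage is
testable without external data.

## Worked example

Simulate a four-MAG community (one MAG per trophic archetype, 2
replicates, 3 time points at 21/43/70 days, 2% spectral noise), extract
and validate the isotopologue patterns, and fit the cluster analysis:

```r
library(sisca)

mags <- list(
  mag_spec("MAG01", "Thiobacillus",   "strict_autotroph",          n_peptides = 10),
  mag_spec("MAG02", "Polaromonas",    "switching_mixotroph",       n_peptides = 10),
  mag_spec("MAG03", "Hydrogenophaga", "crossfeeding_incorporator", n_peptides = 10),
  mag_spec("MAG04", "Acidovorax",     "unlabeled_heterotroph",     n_peptides = 10))
spec <- community_spec(mags, noise_cv = 0.02, seed = 42)
sim  <- simulate_community(spec)

ex  <- extract_patterns(sim$identifications, sim$peaklists, sim$mag_map)
fit <- sisca(ex$patterns)
summary(fit)
#> Per-MAG most probable RIA by time point and lifestyle call
#>   label   T1   T2   T3                 lifestyle
#> 1 MAG01 0.95 0.95 0.95          strict_autotroph
#> 2 MAG02 0.65 0.90 0.90       switching_mixotroph
#> 3 MAG03 0.20 0.55 0.75 crossfeeding_incorporator
#> 4 MAG04 0.05 0.05 0.05     unlabeled_heterotroph
```

Each row is one MAG's trajectory of most probable RIA: MAG01 is stably
~95% labeled (pure CO₂ fixation), MAG02 rises from 65% to ~90% (a
mixotroph switching to autotrophy), MAG03 climbs gradually (cross-feeding
on labeled organic carbon), MAG04 stays at ~5% (unlabeled organic
carbon). `ordinate(fit)` and `plot(fit, labels = ...)` give the PC1/PC2
ordination with confidence ellipses; `validate_clusters()` reports which
cluster ellipses overlap.

Growth and community labeling at the first time point (Δt = 21 days):

```r
t1  <- ex$patterns[vapply(ex$patterns, \(p) p$id$timepoint == "T1", TRUE)]
tab <- growth_table(t1, delta_t = 21)
mag_generation_times(tab$t_d, tab$label)
#>   label n_determinations  mean_td     sd_td quantifiable
#> 1 MAG01               20 20.74771 0.3695377         TRUE
#> 2 MAG02               19 21.06519 0.4090295         TRUE
#> ...
biomass_label_fraction(tab$i_unlabeled, tab$i_labeled, tab$ria)$fraction
#> 0.234
```

With the simulator's default labeled fraction of 0.5 at T1, every MAG has
completed one doubling, so mean generation times sit at ~21 days (Δt/1),
and 23.4% of the community's peptide carbon is ¹³C at T1. The doublings
convention is the printed one (labeled intensity in the denominator); a
conventional alternative is available via
`doublings(..., convention = "unlabeled_denominator")`.

A thin command-line front end over these functions ships in
`inst/scripts/sisca.R` (subcommands `simulate`, `profile`, `classify`,
`growth`, `raman`).

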