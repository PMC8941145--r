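---
title: "Stable isotope cluster analysis of protein-SIP data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable isotope cluster analysis of protein-SIP data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisca)
```

## The problem

In a protein stable isotope probing (protein-SIP) experiment a microbial
community is fed a ^13^C-labeled substrate (here ^13^C-bicarbonate /
^13^CO~2~). Organisms that assimilate labeled carbon build it into their
proteins, and the isotopologue pattern of each peptide in a mass spectrum
— the series of peaks spaced by the ^13^C–^12^C mass difference divided by
charge — encodes the fraction of its carbon atoms that are ^13^C (the
relative isotope abundance, RIA). Natural abundance is about 1.07%; an
organism growing purely on the labeled inorganic carbon pool approaches
the RIA of that pool.

The package turns centroided peak lists from labeled samples, plus peptide
identifications from parallel unlabeled samples, into:

* per-peptide RIA profiles (a vector of R² values over a grid of candidate
  RIAs),
* per-MAG (metagenome-assembled genome) trajectories over incubation time,
* an ordination of MAGs by carbon-utilization profile with
  confidence-ellipse cluster validation,
* trophic lifestyle calls (strict autotroph, switching mixotroph,
  cross-feeding incorporator, unlabeled heterotroph),
* growth estimates (doublings, generation time) and a community-level
  carbon-replacement fraction,

and, independently, processes single-cell Raman spectra from D~2~O-amended
incubations into C-D ratios and labeled/unlabeled classifications.

## Isotopologue pattern model

A peptide's elemental composition is the sum of its residue compositions
plus one water; carbamidomethylation (+C~2~H~3~NO on cysteine) and
oxidation (+O on methionine) are supported. For a composition with $n_C$
carbon atoms at RIA $r$, the number of extra neutrons contributed by
carbon is Binomial($n_C$, $r$); hydrogen, nitrogen, oxygen, and sulfur
contribute at their natural isotope abundances (IUPAC values, shipped as a
versioned plain-text table). The per-element neutron-shift distributions
are combined by exact discrete convolution, aggregating by nominal mass
shift — fine isotopic structure is deliberately not resolved, matching
unit-isotopologue Orbitrap practice, and peak positions use the
^13^C–^12^C spacing 1.003355 Da divided by charge. Patterns are truncated
at the shortest prefix reaching a cumulative abundance of 0.999 (bounding
pattern length while losing <0.1% of abundance) and renormalized.

The test suite checks this model against an independent oracle that
enumerates every per-atom isotope assignment for small compositions; the
two agree to ≤1e-10 per isotopologue.

## The R² grid and clustering

Each measured pattern is compared against 21 predicted patterns at 5% RIA
intervals from 0 to 100%. The comparison statistic is the coefficient of
determination

$$R^2 = 1 - \frac{\sum_i (m_i - p_i)^2}{\sum_i (m_i - \bar m)^2}$$

with both patterns normalized to sum one and aligned on isotopologue index
(missing positions are zeros). Values can be negative for badly mismatched
patterns and are retained unclipped — only relative ordering and means
matter downstream. The full 21-vector, not just its argmax, is the feature
retained per peptide: it distinguishes a population uniformly labeled at a
moderate RIA from a mixture of unlabeled and highly labeled populations,
which an argmax alone cannot.

Profiles are averaged element-wise over all peptides and replicate
microcosms assigned to the same MAG and time point; MAG/time-point groups
supported by fewer than two replicates are dropped. Per-MAG feature
vectors are then either the concatenation of the per-time-point profiles
(the default, one point per MAG) or one observation per MAG and time
point; both layouts are implemented because the natural reading of the
method differs between its textual description ("21 values per time point
per MAG") and its graphical presentation (one point per organism). PCA is
computed on centered, unscaled features — all features share the R² scale
— with a deterministic sign convention (the largest-magnitude loading of
each component is made positive) so results are reproducible across
platforms.

Clusters are supplied by the analyst (a Ward-linkage helper is provided
but never chooses the number of clusters itself). Validation constructs,
per cluster, the 2-D standard-error ellipse of the cluster mean on the
first two components, scaled by the chi-square quantile at the requested
confidence (95% by default), and tests every pair of ellipses for
boundary intersection or containment. Overlapping ellipses flag
non-distinct clusters. Singleton clusters have no ellipse and are flagged
rather than failing.

## Lifestyle classification

Trophic calls are made from the trajectory of per-time-point most probable
RIA with an ordered rule set and configurable thresholds
(`lifestyle_thresholds()`: high = 0.90, stable range = 0.10, mixotroph
start = 0.75, low = 0.10):

1. all time points above 0.90 with range ≤ 0.10 → **strict autotroph**
   (stable, near-complete labeling; exclusive CO~2~ fixation),
2. final RIA ≥ 0.90 with initial ≤ 0.75 → **switching mixotroph** (early
   organic-carbon use, later switch to autotrophic growth),
3. monotone rise to a final RIA in (0.10, 0.90] → **cross-feeding
   incorporator** (gradual uptake of labeled organic carbon),
4. all time points ≤ 0.10 → **unlabeled heterotroph**,
5. otherwise unclassified; every call reports the rule that fired.

The final-RIA comparison in rule 2 is inclusive because estimates are
grid-quantized: an underlying RIA of 0.91 lands exactly on the 0.90 grid
point, and a strict inequality would exclude it on a knife edge. The
thresholds are defaults distilled from the narrative distinctions between
the four lifestyles, not measured constants; they live in configuration
and are never hard-coded in the rules.

## Pattern extraction and quality gates

Identifications from the unlabeled run provide the peptide's m/z and
retention time; the labeled run is assumed co-chromatographed. Candidate
isotopologue positions are searched up to the peptide's carbon count (the
largest possible shift). A centroid matches a position if its mass
deviation is strictly below 10 p.p.m. and its retention-time deviation
strictly below 3 minutes; among in-tolerance candidates the smallest
absolute p.p.m. deviation wins, ties going to the higher intensity.
Missing intermediate isotopologues are recorded as zeros rather than
aborting — labeled patterns can have near-zero valleys between the
unlabeled and labeled envelopes.

Patterns are rejected when a signal sits one spacing before the
monoisotopic peak (M−1) above 5% of the pattern's maximum (the threshold
is configurable; manual practice gives no numeric criterion), or when
another peptide's expected positions intersect the pattern within
tolerance while the retention-time windows overlap. Peptides are retained
only when unique to one protein, one MAG, or to MAGs sharing a genus-level
classification, and carry a single resolved MAG-or-genus label thereafter.

## Growth quantification

The number of doublings is computed exactly as printed in the source
method,

$$n = \log_2 \frac{I_{12C} + I_{13C}}{I_{13C}},$$

with the labeled intensity in the denominator, and generation time is
$t_d = \Delta t / n$. The printed form behaves counter-intuitively as
labeling approaches completeness ($n \to 0$ as $I_{12C} \to 0$); because
this cannot be resolved from the method description alone, a
literature-conventional variant with the unlabeled intensity in the
denominator is available behind `convention =
"unlabeled_denominator"`, and every result records which convention
produced it. Generation times below the 2-day detection limit are
reported censored ("<2 days"); per-MAG summaries require at least four
determinations, otherwise the MAG is reported as not quantifiable.

When unlabeled and labeled envelopes overlap, the monoisotopic peak
anchors the unlabeled population: $I_{12C}$ is the measured monoisotopic
intensity divided by the natural pattern's relative abundance at
isotopologue zero; the scaled natural envelope is subtracted (negative
residuals floored at zero) and the remainder is $I_{13C}$. The labeled
population's most probable RIA is estimated from this residual envelope
rather than from the raw mixed pattern: when the unlabeled population
dominates, the mixed pattern's best single-pattern match is pulled toward
the natural end of the grid, while the residual isolates the labeled
envelope (this matters for mixtures with ≥70% unlabeled material at high
RIA).

The community carbon-replacement fraction at a time point is the mean over
peptides of $(I_{13C} \cdot \mathrm{RIA} + I_{12C} \cdot a_{nat}) /
(I_{13C} + I_{12C})$ with $a_{nat} = 0.0107$; equal-per-peptide weighting
is the default because the upstream method does not state a weighting, and
intensity weighting is available.

## Raman C-D pipeline

Spectra pass through a fixed stage order — despiking, calibration hooks,
asymmetric least-squares (ALS) baseline subtraction, vector normalization.
Despiking replaces points deviating from a running median (window 7) by
more than 8 robust SDs; the robust SD is floored at a small fraction of
the overall signal spread so noiseless smooth spectra pass through
unchanged. Wavenumber and intensity calibration against physical standards
require standard spectra that cannot be synthesized faithfully, so the
hooks are identity functions and synthetic data are generated on a
calibrated axis. The ALS baseline uses a second-difference penalty
(λ = 1e5) with asymmetry p = 0.01 over at most 10 reweighting iterations —
standard practice values; non-convergence returns the last iterate with a
flag.

The C-D ratio is A(C-D)/[A(C-D)+A(C-H)] with trapezoidal integration over
2040–2300 cm^−1^ (C-D) and 2800–3100 cm^−1^ (C-H), negatives floored at
zero first; it is invariant to global intensity scaling. Classification of
labeled versus unlabeled cells projects preprocessed spectra onto five
principal components and fits a linear discriminant; singular within-class
covariance triggers a deterministic tiny-jitter regularization, flagged in
the model.

A known quantification property: flooring zero-mean noise before
integrating fixed 260/300 cm^−1^ windows adds a positive offset of about
0.4·σ per wavenumber to each band integral. At a signal-to-noise ratio of
100 this biases the recovered ratio upward by roughly +0.01 at a true
ratio of 0.25; medians over 100 simulated cells land near 0.26. The bias
shrinks with the noise level and with the fraction of each window occupied
by the band. It is a property of the floor-then-integrate rule itself, so
the package reports it here rather than compensating for it silently.

## The simulator

`simulate_community()` generates random protein sequences per MAG (uniform
residue frequencies — compositional realism is irrelevant to the math
being tested), digests them with trypsin in silico (cleavage after K/R,
not before proline, up to two missed cleavages supported), and emits
peptides of 7–30 residues at charges 2–3 with uniform retention times
shared across samples (the co-chromatography assumption above). Peptides
are unique to their MAG by construction unless a shared fraction is
requested.

Labeled-sample peaks follow the mixture model
$(1-f)\cdot$natural $+\,f\cdot$pattern(RIA), scaled to a lognormal total
intensity, with per-peak multiplicative lognormal noise (default CV 5%),
an additive drop floor, and ±2 p.p.m. m/z jitter. The four archetype RIA
trajectories are (0.95, 0.95, 0.95), (0.65, 0.91, 0.91),
(0.18, 0.53, 0.76), and (0.06, 0.06, 0.06) over the default time points
(21, 43, 70 days with two replicate microcosms) — fixtures encoding the
four trophic narratives, not measured data. Default labeled fractions
rise 0.5 → 0.7 → 0.85 across time points, a plausible course for an
actively growing labeled community. Everything is deterministic under the
mandatory seed.

Raman cells are simulated as Gaussian C-D and C-H bands (centers 2170 and
2935 cm^−1^, SD 40 cm^−1^, chosen to sit inside the integration windows)
whose area ratio realizes the requested true C-D ratio, on a gentle cubic
fluorescence-like background with additive Gaussian noise (SD expressed
relative to the C-H peak height) and optional cosmic spikes.

What the simulator does *not* emulate: ionization efficiency and
co-elution chemistry, realistic proteome composition, chromatographic
drift between runs, detector saturation, or multi-component Raman band
shapes. Passing recovery tests on this generator therefore demonstrates
the correctness of the computations under the stated noise model, not
robustness to every artifact of real instruments.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 2000 peptides (500 per
archetype) for RIA recovery at 5% CV; a 20-MAG community (5 per archetype,
20 peptides each, 3 time points, 2 replicates, 1% CV) for cluster
separation; a 5-MAG community designed at 43% labeled carbon for the
replacement fraction; and 100–1000 cells per Raman check. These sizes make
every recovery criterion measurable with comfortable margins while keeping
a full run in a few minutes.

Tie-breaks and degenerate inputs are handled explicitly: argmax ties on
the R² grid resolve to the lower RIA with an ambiguity flag; a flat
profile returns RIA 0 flagged; a zero monoisotopic peak with downstream
signal yields zero unlabeled intensity, flagged; zero labeled intensity is
below-detection (doublings undefined); singleton clusters have no ellipse;
an all-zero Raman spectrum cannot be vector-normalized and is an error.
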