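---
title: "Models and methods behind turtlestock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind turtlestock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turtlestock)
```

turtlestock implements the analysis chain used in green turtle
(*Chelonia mydas*) mitochondrial population genetics: haplotype calling
for control-region markers, diversity and differentiation statistics, and
Bayesian mixed stock analysis (MSA). This vignette documents the models,
the tunable parameters and their defaults, the numerical conventions, and
the limits of what the synthetic-data tests demonstrate.

## Markers and haplotype calling

Three marker systems are supported:

* the **short D-loop** (~486 bp), the legacy control-region fragment on
  which most historical baselines are published;
* the **extended D-loop** (~738 bp), which contains the short fragment as
  its leading window and resolves additional variants (names carry a `.k`
  suffix: `CM-A8.1` and `CM-A8.3` both collapse to the short haplotype
  `CM-A8`);
* the **mtSTR**, a ~200 bp region with four short-tandem-repeat loci of
  `AT` dinucleotides, written as the four repeat counts, e.g. `7-12-4-4`.

A **combined haplotype** is the pair `extended/mtSTR`, e.g.
`CM-A8.1/7-12-4-4`.

D-loop calling is by *exact sequence identity*: control-region haplotypes
are defined nomenclaturally by their exact sequence, so no mismatch
tolerance is applied. A query read is positioned against the library by
best ungapped sliding-window alignment to the majority consensus of the
extended records (real protocols trim by primer position, which is not
available to a reusable tool), truncated to the 738-base window, and
compared to each record. A query that matches nothing is flagged
`novel_candidate` and the closest record is reported with its mismatch
count, mirroring how novel haplotypes are actually discovered and then
submitted to a registry. Queries shorter than the short window fail with
`dloop_failed`.

mtSTR repeat counting locates each locus by a flanking anchor motif and
counts the maximal run of `AT` units after it. The anchor motifs are
configuration, not code: they differ between amplicon designs, and the
defaults shipped here are the motifs used by the package's own synthetic
sequence builder. A missing anchor flags the sample
`mtstr_unidentified`; a zero-length repeat run is treated as a corrupt
anchor specification and raises an error rather than a call of 0.

**Heteroplasmy.** Essentially all mtSTR chromatograms show some secondary
signal. The resolution rule follows the dominant-peak convention: at every
locus with more than one candidate, the variant with the largest intensity
fraction is accepted if that fraction reaches the dominance threshold;
otherwise the sample is excluded from mtSTR-based tables
(`heteroplasmy_unclear`). The literature states no numeric rule, so the
threshold is an explicit parameter, default **0.6**, with the boundary
counting as dominant (a fraction of exactly 0.6 resolves). The choice of
0.6 encodes "clearly more than half the signal" while not demanding
near-fixation; it is logged in the run manifest so analyses are
reproducible under a different choice.

Tabulation keeps strict books: for any cohort, assigned + excluded counts
reconstruct the input size exactly, and excluded samples are reported by
reason. Published tables of this kind report percentages against the full
sample count rounded half-up to one decimal, and `tabulation_percent()`
follows that convention.

## Diversity and differentiation

**Haplotype diversity** is Nei's unbiased estimator
$\hat h = \frac{n}{n-1}(1 - \sum_i p_i^2)$ with its sampling variance
(Nei 1987, eq. 8.12); the package reports $\hat h \pm \mathrm{SD}$.

**Pairwise F~ST~ and Φ~ST~** are the two-level AMOVA fixation index
computed from variance components of squared inter-individual distances.
For F~ST~ the inter-haplotype distance is 0/1 (frequency-based); for
Φ~ST~ it is the number of differing aligned sites between haplotype
sequences, with pairwise deletion of gap/`N` positions and no
substitution-model correction (the raw p-distance numerator). When every
pair of haplotypes is equally distant the two statistics coincide
exactly, which the tests exploit. Negative estimates are reported as
computed — they are informative small-sample noise around zero and are
printed as such in the field's tables — and only clamped where a
nonnegative distance is structurally required (PCoA input).

Significance uses permutation of individuals between the two populations
with the plus-one correction $p = (b+1)/(m+1)$, default $m = 10{,}000$
with an explicit seed. The Narum-modified false discovery rate threshold
$\alpha' = \alpha / \sum_{i=1}^{k} 1/i$ is computed with $k$ always equal
to the number of comparisons in the current result matrix, and $k$ is
reported so any published per-figure family can be reproduced; $\alpha'$
is rounded to three decimals for display only, with comparisons at full
precision.

**PCoA** double-centers $-\tfrac12 D \circ D$ (Gower) and
eigendecomposes. Conventions where tools differ, made explicit here:
negative input distances are clamped to zero (count logged); percent
variance is relative to the sum of the *positive* eigenvalues, negative
eigenvalues being listed but carrying no axes; the headline "variance
explained" is the cumulative percent of axes 1–2, matching the standard
two-axis ordination figure. For Euclidean-embeddable matrices the
coordinates reproduce the input distances to numerical tolerance and the
reconstruction error is always reported, never hidden.

**AMOVA** partitions variance among a-priori groups, among populations
within groups, and within populations (Excoffier-style components with
the usual unequal-size coefficients). F~CT~ is tested by permuting whole
populations among groups; a group containing a single population makes
that permutation space degenerate and triggers a warning rather than
silent nonsense. The two-level specialization equals the pairwise F~ST~
on the same pair, which is tested as a cross-module consistency property.

## Mixed stock analysis

The many-to-many MSA treats each foraging aggregation (mixture) $m$ as a
finite mixture over rookeries $r = 1..R$:

* contribution vectors $\theta_m \sim \mathrm{Dirichlet}(\alpha_m)$ with
  $\alpha_{m,r} = c\,N_r / \sum_{r'} N_{r'}$ under size-weighted priors
  ($N_r$ = nester abundance) or $c/R$ under uniform priors; the total
  prior mass is $c = 1$ by default — one pseudo-individual per mixture,
  weakly informative but enough to keep the prior proper;
* rookery haplotype frequencies
  $\pi_r \sim \mathrm{Dirichlet}(\beta, \ldots, \beta)$ updated by the
  baseline counts, with $\beta = 1/H$ per haplotype. This bounds the
  total prior mass added to a baseline at one individual regardless of
  how many haplotypes are in play, while keeping "orphan" haplotypes
  (observed only in mixtures) assignable to any rookery;
* each mixture individual with haplotype $h$ carries a latent source
  $z$ with $P(z = r) \propto \theta_{m,r}\,\pi_{r,h}$.

The Gibbs sampler alternates the multinomial split of each mixture's
haplotype counts over sources with the Dirichlet full conditionals of
$\pi$ and $\theta$. The inner loop is implemented in C++ (Rcpp) using R's
RNG, so a single `set.seed` governs full determinism. Chains start
overdispersed: $\theta_m$ from its prior, $\pi_r$ from
$\mathrm{Dirichlet}(\beta + X_r)$ (a draw consistent with the baseline
data; starting $\pi$ from the bare prior can place essentially zero mass
on haplotypes the mixtures contain, which only delays burn-in without
changing the target).

The run length convention — iterations are **per chain**, default
**50,000**, with **4 chains**, **50% burn-in** and no thinning — is a
package choice exposed in `msa_config()`; the convergence criterion is
the Gelman–Rubin shrink factor
$\hat R = \sqrt{\{(n-1)/n \cdot W + B/n\}/W}$ below **1.2** for every
parameter. A non-converged run is returned with a prominent flag rather
than discarded, mirroring diagnose-then-decide practice. Rookery-centric
shares $\phi_{r,m} = \theta_{m,r} S_m / \sum_{m'} \theta_{m',r} S_{m'}$
are derived per draw with mixture weights $S_m$ defaulting to sample
sizes (a user-supplied abundance column overrides).

The mixture-centric parameterization (one Dirichlet per mixture) was
chosen because published results of this kind are mixture-centric; the
alternative joint rookery-centric parameterization satisfies the same
recovery properties but yields different posteriors under weak data, and
would be the natural extension if source-centric estimands became the
focus.

**Immature filtering.** Foraging samples are restricted to immature
individuals before MSA: the adult threshold is the mean nesting-female
curved carapace length minus two standard deviations (sample SD), with
CCL below the threshold kept. By construction about 2.3% of true adults
fall below such a threshold; the filter trades that contamination for
never discarding genuine juveniles far below the adult range. Missing
CCL values are kept with a warning.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, with stored
truth: a library with one dominant haplotype family carrying `.1/.3`
extended variants (identical short windows, one difference beyond them)
and further families differing inside the short window; mtSTR sequences
`anchor1 (AT)^{r_1} \ldots anchor4 (AT)^{r_4}` varying only at loci 1–2
with loci 3–4 fixed at 4 repeats; rookery frequency vectors with a shared
dominant haplotype of mean frequency 0.75 (the regional pattern this
mirrors runs at roughly 74–75% dominance) and sparse-Dirichlet rare
haplotypes; finite mixtures with known $\theta$; heteroplasmy on every
profile with a chosen fraction pushed below the dominance threshold
(unclear by construction); and normal CCL classes, defaulting to nesting
females at 112 ± 5 cm and juveniles at 65 ± 10 cm.

One master seed fans out to per-component seeds through a fixed affine
counter (`derive_seed`), so partial reruns reproduce exactly and the
whole pipeline is byte-reproducible.

Deliberately *not* modelled: coalescent genealogies (frequencies are
free parameters, not products of shared history), sequencing error
beyond the substitution used to create novel-candidate test cases,
indels or alignment ambiguity, mtSTR homoplasy, and any spatial or
oceanographic structure. Passing tests therefore demonstrate that the
estimators and samplers are correct for the data-generating model the
methods themselves assume — multinomial sampling from fixed frequency
baselines — not that real Atlantic data meet that model.

## Numerical conventions and test scales

Tie-breaks and degenerate cases are fixed as follows: permutation
p-values use $(b+1)/(m+1)$ with "as extreme" meaning
$\ge$ observed $- 10^{-12}$; a statistic whose variance components are
all zero is reported as 0; $\hat R$ of constant identical chains is 1 and
of constant differing chains is $+\infty$; a heteroplasmy dominance
fraction exactly at the threshold resolves as clear; percentages round
half-up to one decimal.

Test problem sizes are chosen to exercise each property at meaningful
resolution: exhaustive two-population enumerations plus randomized
instances up to 4 populations × 5 haplotypes × n ≤ 12 against a
brute-force distance-matrix oracle at $10^{-12}$; permutation-test
calibration over 500 null pairs of n = 50 at 199 permutations; MSA
recovery over 20 seeded replicates of R = 3 rookeries, 6 haplotypes,
baseline and mixture sizes of 500, at 4 × 50,000 iterations; and a
byte-reproducibility run of the full pipeline at cohort sizes of 60–80.

## Known limitations

* Atlantic-wide differentiation matrices, ordination percentages and
  hierarchical AMOVA values for the real multi-study dataset require the
  combined published baselines of many rookeries, which are not bundled;
  the package ships only the single-rookery count table it can carry and
  validates the statistics by construction and by oracle instead.
* Φ~ST~ uses raw site differences; model-corrected distances are a
  config extension point, not implemented.
* The MSA has no "unsampled rookery" sink component: contributions are
  forced onto the characterized baselines.
* Exact-match D-loop calling treats any novel variant, sequencing error
  included, as a novel candidate; it performs no error correction.
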