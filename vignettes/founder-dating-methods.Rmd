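---
title: "Dating founder mutations from linkage-disequilibrium decay: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating founder mutations from linkage-disequilibrium decay: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderage)
```

## The problem

A recessive mutation that is common in one region but rare elsewhere —
here, the *TGM1* mutations behind the exceptional prevalence of autosomal
recessive congenital ichthyosis in Galicia — usually descends from a
single founder. All present-day disease chromosomes then carry a
haplotype inherited from that founder, progressively shortened by
recombination. Two dates are of interest and are *not* the same:

* the **TMRCA** of the sampled disease chromosomes, which is what
  linkage-disequilibrium (LD) decay measures, and
* the **age of the mutation**, which is at least as old and can be much
  older when the population later passed through a bottleneck.

`founderage` estimates the first from marker data, corrects it toward the
second under a growth model, and ships a simulator in which both are
known, so the whole chain of reasoning can be checked against truth.

## From physical distance to recombination fraction

Marker positions are given as unsigned distances from the disease locus
in Mb with a side flag (published study tables usually print unsigned
distances only; the estimators depend only on |d|). Physical distance is
converted at a constant sex-averaged rate, by default 1.64 cM/Mb — the
value estimated for the 14q11 region from control chromosomes in the
study this package grew out of. The rate is a per-run (and per-marker)
parameter, and a supplied `cM` column always overrides the conversion,
because regional recombination-rate estimation itself is out of scope
here. Map distances become recombination fractions through the Kosambi
function θ = tanh(2d)/2 (d in Morgans), which allows moderate crossover
interference; the package also provides its exact inverse, and the pair
round-trips to 1e-10 relative error. Other map functions can be applied
upstream by supplying θ-equivalent `cM` values, but Kosambi is the only
built-in.

## Haplotypes, the conserved region, and the founder allele

Phasing is deliberately limited to the deterministic Mendelian core: a
trio marker is phased when at least one parent is homozygous, the child
is homozygous, or an allele occurs in only one parent; anything else is
flagged unresolved, never guessed, and Mendelian inconsistencies are
errors naming the marker and the incompatible parent. Statistical
phasing belongs to dedicated software and phased input is accepted
as-is. For an ungenotyped affected individual, `infer_unsampled_haplotypes()`
reconstructs the disease haplotypes from the parents and a genotyped
unaffected sibling by elimination, which assumes no recombination between
marker and locus in those two meioses.

The conserved ancestral region is the maximal run of consecutive markers
around the locus at which all disease chromosomes agree. The scan grows
outward from the locus on each side, so the region always contains the
locus; a marker with missing calls extends the region only if all
non-missing calls agree and is then flagged `partial_support`. Removing
haplotypes can only widen the region (anti-monotonicity), which the test
suite checks against a brute-force interval scan.

Outside the region, the founder allele at each marker is taken as the
modal allele among disease chromosomes — the standard recipe when the
true ancestral state is unobservable. Ties are broken toward the
smallest allele label, deterministically and with a warning; published
analyses never report ties, but a reproducible pipeline must not leave
the choice to hash order. Frequencies are always computed over
non-missing calls; a haplotype-frequency query counts a control
chromosome with a missing call as a non-match, since it cannot be shown
to carry the haplotype.

## The moment estimators

With Q the proportion of disease chromosomes still carrying the founder
allele at a marker with recombination fraction θ, a star genealogy gives
E[Q] = (1 − θ)^g after g generations, hence g = ln Q / ln(1 − θ).
The estimators differ in Q:

* **Excess sharing (Risch-type):** Q = δ = (p_d − p_n)/(1 − p_n), where
  p_d and p_n are the founder-allele frequencies on disease and control
  chromosomes. δ discounts chance carriage of the founder allele on
  recombinant chromosomes and is the better-calibrated choice when a
  control panel exists.
* **Ancestral proportion (Bergman-type):** Q = p_d, with no control
  correction (`variant = "proportion"`, the default reading of that
  method; `variant = "excess"` is available). Background carriage
  inflates p_d, so this variant reads systematically younger at markers
  whose founder allele is common in controls. The per-marker values in
  the source study's table are mutually consistent with neither variant
  at every marker (its exact implementation is unpublished), which is why
  the variant sits behind an explicit argument rather than a guess baked
  in.

A marker is screened out, with a machine-readable reason, when it cannot
inform the estimate: δ ≤ 0 (founder allele not enriched on disease
chromosomes) for the excess form; p_d ≤ p_n for the proportion form;
θ = 0 (inside the conserved region); and, for the excess form, when a
marker's founder-allele disease frequency equals that of its neighbour
nearer the locus — the distal marker then witnesses no additional
recombination and would double-count the nearer one. Study-specific
exclusions that no numeric rule captures are forced through
`overrides = "MARKER:ESTIMATOR:REASON"` and carried into the report. One
such case in the source data: a founder allele with p_d = 0.25 against
p_n = 0.16 is numerically informative for the proportion estimator, yet
the original analysis excluded it (its prose calls 0.25 "less common"
than 0.16, contradicting the numbers); the package follows the numeric
rule and leaves the exclusion to an override.

Per-marker estimates are combined as an unweighted arithmetic mean with
a 95% CI of mean ± 1.96·SE, SE from the sample standard deviation
(n − 1). This exact rule regenerates, after rounding, three of the four
reproducible summary intervals printed in the source study and the lower
bound and mean of the fourth; no consistent alternative (population SD,
t quantiles, inward rounding) regenerates all four, so the remaining
printed upper bound (25, where the rule gives 25.7 → 26) is documented
as not reproducible rather than special-cased. Rounding is half-up and
happens only in the report layer; all stored values are unrounded.

## The growth correction

In a growing mutant population the genealogy is not a star: a sampled
lineage shares an initial stretch of ancestry with the founder line and
only evolves independently for L = G − T generations, where T is its
divergence time from the founder line. The moment estimators therefore
date something between the TMRCA and the mutation age G. The default
correction models T with density proportional to e^{−pt} on (0, G) —
coalescence intensity inversely proportional to the mutant population
size N(t) ∝ e^{pt}, the same approximation the simulator uses — giving a
closed form for E[(1 − θ)^{G−T}], and solves

E[(1 − θ)^{G−T}] = (1 − θ)^{ĝ}

for G by root-finding (monotone in G; tolerance 1e-9, search capped at
10,000 generations). The corrected age always exceeds the raw estimate
for p > 0, which reproduces the ordering of every corrected/uncorrected
pair in the source study's table at its growth rate p = 0.107.

Two consequences of this model are worth stating plainly. First,
`growth_rate = 0` is treated as asserting the star genealogy and returns
the estimate unchanged; the constant-size coalescent limit (T uniform)
would instead give the *largest* correction, so p = 0 is a modelling
convention, not a continuity limit. Second, within this model the
correction *shrinks* as p grows — faster growth makes the genealogy more
star-like — so the correction is deliberately not claimed to be monotone
increasing in p. The correction is pluggable (`correction =` any
function of g, θ, p) for users who prefer a different genealogy model.

The growth rate itself comes from a census pair through N = N₀·e^{gp}
with g rounded to whole generations: the bundled Galician defaults
(2,796,089 in 2011 against 629,336 in 1591, 30-year generations) give
g = 14 and p = 0.1065 ≈ 0.107. The present-census year is a parameter
defaulting to 2011, the figure contemporaneous with the study.

## The composite-likelihood age estimator

As a cross-check that uses every chromosome and marker jointly,
`composite_likelihood_age()` maximises
Σ log P(observed allele | g) with
P(founder allele) = (1 − θ)^g + (1 − (1 − θ)^g)·p_n and
P(other allele a) = (1 − (1 − θ)^g)·p_n(a),
over g ∈ (0, g_max], g_max = 500 by default, optimisation tolerance 1e-6
generations after a 2,000-point grid pass. The interval is a profile
interval at the 1.92 log-likelihood drop, and an optional user prior
turns the grid into a normalised posterior. This is **not** the
Rannala–Reeve intra-allelic coalescent behind DMLE-class software:
independence is assumed across markers and chromosomes, so the interval
understates uncertainty when markers are correlated. It reduces exactly
to the moment estimator in the single-marker case with the founder
allele absent from controls (g = ln(k/n)/ln(1 − θ)), and a fully
ancestral panel yields a boundary estimate at 0 with a warning.
Control-unseen alleles receive a floor frequency of 1/402 (one
observation beyond a 200-chromosome panel, Laplace-style) to keep the
likelihood finite.

## What the simulator emulates — and what it does not

`founder_sim_config()` defaults describe the study design the package
grew out of: a microsatellite panel at 1.98, 2.52, 3.32, 3.34, 4.54 and
8.7 Mb mirrored on both sides of the locus at 1.64 cM/Mb, 200 control
chromosomes, an 8-allele control spectrum (0.30, 0.20, 0.15, 0.10, 0.10,
0.05, 0.05, 0.05; heterozygosity ≈ 0.81, typical of dinucleotide
microsatellites), a true age of 30 generations, and disease-panel sizes
set per experiment (the study itself had 3–11 disease chromosomes per
mutation; recovery experiments default to 50 to separate estimator bias
from small-sample noise).

Controls are drawn at linkage equilibrium — the simplest null. Disease
chromosomes descend from one ancestral haplotype drawn from the same
process; each carries a per-side nearest recombination breakpoint,
exponential with rate L in the transformed coordinate u = −ln(1 − θ(d)).
In that coordinate, per-marker retention is *exactly* (1 − θ)^L — the
quantity the estimators invert — while for small distances u coincides
with the map distance in Morgans, recovering the classical
exponential-breakpoint model. (Placing the breakpoint exponentially in
raw map distance instead would make simulated retention e^{−Ld}, which
at the 8.7 Mb marker differs detectably from (1 − θ_Kosambi)^L; the
package prefers internal consistency between simulator and estimator,
and records breakpoints in both coordinates in the truth record.)
Lineage lengths are L = G under the star genealogy; under
`exponential_growth`, L = G − T with T drawn from the truncated
exponential above, i.i.d. across lineages — an approximation to the
intra-allelic coalescent that is adequate for sign-of-bias questions but
does not model the correlation structure of a real genealogy. Optional
stepwise microsatellite mutation moves retained integer allele labels
±1 with a per-generation rate (default 0).

Passing tests on these simulations shows the estimators invert the decay
model they assume, and that growth-genealogy data yield TMRCA-style
underestimates of the mutation age. It does *not* show robustness to
background LD among controls (real control haplotypes are correlated),
marker-map misspecification, mutation-rate misspecification, or
ascertainment of disease chromosomes through pedigrees — all realities
of applied founder dating.

## Reproducibility and problem sizes

Every simulation takes an integer seed; identical config and seed give
byte-identical output (controls and disease panels consume separate
seed streams derived by fixed offsets, and replicate r of a recovery
experiment uses seed + 7919·r). The validation suite runs the
inversion-identity grid (g up to 200, θ up to 0.3, 1e-9 tolerance),
10,000-lineage retention checks against (1 − θ)^30 at 3 binomial
standard errors, 200-replicate recovery experiments at 50 disease
chromosomes (mean within 20% of truth for the star genealogy; one-sided
t-test of underestimation for the growth genealogy), and
Kolmogorov–Smirnov agreement of breakpoint draws with their exponential
law — sizes chosen so the full suite completes in a few minutes on one
CPU while keeping each stochastic check several standard errors away
from its threshold.

## Known limitations

* The moment estimators assume a correct marker map; recombination-rate
  error translates linearly into age error.
* The growth correction and the simulator share one genealogy
  approximation; agreement between them validates the implementation,
  not the approximation.
* The composite-likelihood interval ignores inter-marker correlation and
  is anti-conservative.
* Founder-allele calling by modal allele degrades at distal markers and
  small panels (the mode drifts to the background mode), which is why
  informativeness screening precedes averaging.
* The demographic calculators take census figures at face value;
  historical censuses carry errors that propagate into p and hence into
  corrected ages.
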