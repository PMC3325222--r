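# founderage

Dating founder mutations from the decay of linkage disequilibrium.

When a recessive disease mutation reaches unusual frequency in a regional
population through a founder effect — as the *TGM1* mutations causing
autosomal recessive congenital ichthyosis did in Galicia (NW Spain) — the
chromosomes carrying it share a haplotype inherited from the founder.
Recombination erodes that haplotype at a known rate, so the fraction of
disease chromosomes still carrying the ancestral allele at a flanking
marker dates the most recent common ancestor (TMRCA) of the sampled
chromosomes. `founderage` implements that analysis end to end for
geneticists working with microsatellite/SNP panels around a disease locus:

* **Haplotypes** — deterministic Mendelian trio phasing, detection of the
  conserved ancestral region among disease chromosomes, founder-allele
  calling (modal allele outside the shared region), allele and haplotype
  frequencies against a control panel.
* **Genetic map** — physical-to-genetic conversion (default 1.64 cM/Mb,
  overridable; a supplied map wins) and the Kosambi map function
  θ = tanh(2d)/2 with its exact inverse.
* **Age estimators** — per-marker moment estimators inverting the decay
  law Q = (1 − θ)^g: the excess-allele-sharing form with
  δ = (p_d − p_n)/(1 − p_n) (Risch-type), the
  proportion-of-ancestral-haplotypes form Q = p_d (Bergman-type), a
  coalescent correction for exponential population growth (Labuda-type),
  informativeness screening with machine-readable reason codes,
  across-marker averaging with 95% CI (mean ± 1.96·SE), and a
  composite-likelihood age estimator as a simplified, clearly-labelled
  stand-in for DMLE-style Bayesian dating.
* **Demography** — census-pair growth rate from N = N₀·e^{gp},
  Hardy–Weinberg allele frequencies from homozygote counts, 1:K
  prevalence, sampled-chromosome proportions, generation/year conversion.
* **Simulator** — a forward founder-event generator (star or
  growth-coalescent intra-allelic genealogy, per-side recombination
  breakpoints, optional stepwise microsatellite mutation) with full truth
  records, so every estimator is testable against known ages.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_decay()` figures.

## Worked example

Reproduce the across-marker summaries from published per-marker
generation counts (the "table" entry mode, for when a study prints
per-marker estimates but not the underlying allele frequencies):

```r
library(founderage)

gens <- readr::read_tsv(
  founderage_example("tgm1_reported_generations.tsv"),
  show_col_types = FALSE)
estimate_from_generations(gens)
#> TMRCA summary (generations):
#>    c.1223_1227delACACA bergman 19 (14-24)
#>     c.1223_1227delACACA labuda 36 (29-42)
#>      c.1223_1227delACACA risch 23 (21-26)
#>              c.2278C>T bergman 35 (18-51)
#>               c.2278C>T labuda 30 (17-44)
#>                c.2278C>T risch 20 (11-30)
```

For c.2278C>T the chromosomes coalesce roughly 20–35 generations ago
(600–1,050 years at 30 y/generation) depending on the estimator; the
growth-corrected (labuda) values exceed the uncorrected (risch) ones
because, in a growing population, lineages share part of their ancestry
with the founder line and the raw moment estimate dates the (younger)
TMRCA rather than the mutation.

The demographic calculators behind the growth correction:

```r
growth_rate()           # Galician census pair, 1591 -> 2011
#>   n_present n_reference generations  rate
#> 1   2796089      629336          14 0.107
prevalence(23, 2796089)$label
#> [1] "1:122,000"
100 * hwe_allele_freq(4, 2796089)    # % allele frequency from 4 homozygotes
#> [1] 0.1196064
```

A simulated founder event analysed blind, with a marker geometry like the
study's (two intragenic SNP-like markers plus flanking microsatellites),
six disease chromosomes and 200 controls:

```r
mm <- marker_map(
  marker = c("D14S1032", "TGM1_5p", "TGM1_3p", "D14S275",
             "D14S742", "D14S72", "D14S1042", "D14S1060"),
  distance_mb = c(0.4, 0.05, 0.05, 1.98, 2.52, 3.32, 4.54, 8.7),
  side = c(-1, -1, 1, 1, 1, 1, 1, 1))
cfg <- founder_sim_config(markers = mm,
                          allele_spectra = default_allele_spectra(mm),
                          true_age = 30, n_disease = 6, n_control = 200,
                          seed = 7)
sim  <- simulate_founder_panel(cfg)
ctrl <- simulate_controls(cfg)

conserved_region(sim$panel, mm)
#> Conserved ancestral region: 3 marker(s), 0.74 cM, 6 disease chromosomes

founder_allele_table(sim$panel, ctrl, mm) |>
  estimate_marker_ages(growth_rate = 0.107) |>
  summarize_tmrca()
#> TMRCA summary (generations):
#>    bergman 8 (2-15)
#>      risch 19 (-18-55)
#>     labuda 24 (-23-71)
```

With only six chromosomes the intervals are wide — exactly the situation
of a real founder-mutation study — but the excess-sharing estimate (19)
sits near the simulated truth of 30, and `recovery_experiment()` shows it
is well calibrated on average (mean ≈ 30.5 over 200 replicates at 50
chromosomes).

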