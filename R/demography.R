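#' Per-generation exponential growth rate from a census pair
#'
#' Solves N = N0 * exp(g * p) for the growth rate p, where g is the number
#' of generations separating the two censuses (rounded to the nearest
#' whole generation). The defaults are the censuses used to calibrate the
#' growth correction for the Galician population: 2,796,089 inhabitants
#' (Galician Statistical Institute, 2011) against 629,336 in the 1591
#' census, which with 30-year generations gives g = 14 and p ~ 0.107.
#'
#' @param n_present,n_reference Census population counts (> 0).
#' @param year_present,year_reference Calendar years of the two censuses.
#' @param generation_time Years per generation (default 30).
#' @return A one-row tibble: `n_present`, `n_reference`, `generations`,
#'   `rate`.
#' @export
#' @examples
#' growth_rate()   # the Galician calibration, p ~ 0.107
growth_rate <- function(n_present = 2796089, n_reference = 629336,
                        year_present = 2011, year_reference = 1591,
                        generation_time = 30) {
  if (n_present <= 0 || n_reference <= 0) {
    abort("Census counts must be positive.", class = "founderage_domain_error")
  }
  g <- round_half_up((year_present - year_reference) / generation_time)
  if (g <= 0) {
    abort("The present census must postdate the reference census by at least one generation.",
          class = "founderage_domain_error")
  }
  tibble::tibble(
    n_present = n_present, n_reference = n_reference,
    generations = as.integer(g),
    rate = log(n_present / n_reference) / g
  )
}

#' Allele frequency of a recessive mutation from homozygote counts
#'
#' Under Hardy-Weinberg equilibrium the frequency of homozygotes for an
#' allele of frequency q is q^2, so q = sqrt(cases / population). Used to
#' turn the census count of affected homozygotes into a carrier-chromosome
#' frequency.
#'
#' @param n_homozygotes Number of homozygous individuals observed.
#' @param population Population size the count refers to (> 0).
#' @return Allele frequency q in `[0, 1]`.
#' @export
#' @examples
#' 100 * hwe_allele_freq(4, 2796089)   # percent
hwe_allele_freq <- function(n_homozygotes, population) {
  if (any(population <= 0)) {
    abort("`population` must be positive.", class = "founderage_domain_error")
  }
  if (any(n_homozygotes < 0 | n_homozygotes > population)) {
    abort("`n_homozygotes` must lie in [0, population].",
          class = "founderage_domain_error")
  }
  sqrt(n_homozygotes / population)
}

#' Disease prevalence as a 1:K ratio
#'
#' @param n_cases Number of identified cases (>= 1).
#' @param population Population size.
#' @param round_to Precision of the reported denominator (default nearest
#'   1,000).
#' @return A one-row tibble: `k` (rounded denominator) and `label`
#'   (e.g. `"1:122,000"`).
#' @export
#' @examples
#' prevalence(23, 2796089)
prevalence <- function(n_cases, population, round_to = 1000) {
  if (n_cases < 1) {
    abort("Prevalence is undefined without cases.",
          class = "founderage_domain_error")
  }
  k <- round_half_up(population / n_cases / round_to) * round_to
  tibble::tibble(
    k = k,
    label = paste0("1:", format(k, big.mark = ",", scientific = FALSE))
  )
}

#' Proportion of mutation-carrying chromosomes sampled
#'
#' Input required by DMLE-style Bayesian dating. The default method is the
#' direct reading: sampled disease chromosomes divided by the expected
#' total number of mutant chromosomes in the population, n / (q * 2 * N).
#' Alternative conventions are kept behind `method` so a report can state
#' which was used; results using the default are flagged accordingly.
#'
#' @param n_sampled Number of mutation-carrying chromosomes genotyped.
#' @param q Population allele frequency of the mutation (e.g. from
#'   [hwe_allele_freq()]).
#' @param population Census population size.
#' @param method `"chromosomes"` (default, n / (2Nq)) or `"individuals"`
#'   (n / (2N q (2 - q)) ~ carriers-based denominator).
#' @return The sampled fraction, with attributes `method` and `default`
#'   recording the convention.
#' @export
#' @examples
#' sampled_proportion(11, hwe_allele_freq(4, 2796089), 2796089)
sampled_proportion <- function(n_sampled, q, population,
                               method = c("chromosomes", "individuals")) {
  method <- match.arg(method)
  if (q <= 0) {
    abort("`q` must be positive.", class = "founderage_domain_error")
  }
  if (n_sampled < 0 || population <= 0) {
    abort("Counts must be non-negative and the population positive.",
          class = "founderage_domain_error")
  }
  denom <- switch(method,
    chromosomes = q * 2 * population,
    individuals = 2 * population * q * (2 - q) / 2
  )
  structure(n_sampled / denom, method = method,
            default = method == "chromosomes")
}

#' Convert generations to calendar years
#'
#' @param g Generations (>= 0).
#' @param generation_time Years per generation (default 30).
#' @return Years.
#' @export
#' @examples
#' generations_to_years(20)    # 600
generations_to_years <- function(g, generation_time = 30) {
  if (any(g < 0, na.rm = TRUE)) {
    abort("`g` must be non-negative.", class = "founderage_domain_error")
  }
  g * generation_time
}
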