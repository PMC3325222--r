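#' Default marker panel for founder-event simulations
#'
#' Mirrors the geometry of the microsatellite panel used to date the
#' Galician TGM1 mutations: markers at 1.98, 2.52, 3.32, 3.34, 4.54 and
#' 8.7 Mb from the locus, mirrored on both sides, converted at 1.64 cM/Mb.
#'
#' @param distances_mb Unsigned distances to mirror on both sides.
#' @param cm_per_mb Conversion rate.
#' @return A marker-map tibble ([marker_map()]).
#' @export
default_marker_panel <- function(distances_mb = c(1.98, 2.52, 3.32, 3.34,
                                                  4.54, 8.7),
                                 cm_per_mb = 1.64) {
  marker_map(
    marker = c(paste0("L", rev(seq_along(distances_mb))),
               paste0("R", seq_along(distances_mb))),
    distance_mb = c(rev(distances_mb), distances_mb),
    side = rep(c(-1L, 1L), each = length(distances_mb)),
    cm_per_mb = cm_per_mb
  )
}

#' Default microsatellite allele-frequency spectrum
#'
#' A moderately polymorphic 8-allele spectrum (heterozygosity ~0.81)
#' typical of the dinucleotide microsatellites used in founder-dating
#' panels; applied to every marker unless per-marker spectra are given.
#'
#' @param markers Marker map.
#' @return Named list of per-marker named frequency vectors.
#' @export
default_allele_spectra <- function(markers) {
  base <- c(`1` = 0.30, `2` = 0.20, `3` = 0.15, `4` = 0.10,
            `5` = 0.10, `6` = 0.05, `7` = 0.05, `8` = 0.05)
  setNames(rep(list(base), nrow(markers)), markers$marker)
}

#' Configuration of a founder-event simulation
#'
#' Bundles and validates everything the simulator needs: the marker panel,
#' per-marker control allele spectra, the true mutation age, the
#' intra-allelic genealogy model (star, or coalescent under exponential
#' growth), sample sizes and seed. The defaults emulate the study design
#' of the Galician TGM1 analysis: a microsatellite panel spanning ~12 Mb
#' around the locus and 200 control chromosomes.
#'
#' @param markers Marker map ([marker_map()]; default
#'   [default_marker_panel()]).
#' @param allele_spectra Named list (by marker) of named numeric vectors of
#'   control allele frequencies, each summing to 1 (a degenerate
#'   single-allele spectrum is allowed and yields monomorphic controls);
#'   default [default_allele_spectra()].
#' @param true_age Generations since the mutation arose (>= 0; 0 is the
#'   degenerate no-decay edge).
#' @param genealogy `"star"` (every lineage independent of the founder for
#'   the full age) or `"exponential_growth"` (lineages diverge from the
#'   founder line at coalescent times under growth, so realised lineage
#'   lengths are shorter than the mutation age).
#' @param growth_rate Per-generation growth rate p for the coalescent
#'   genealogy (study default 0.107).
#' @param n_disease,n_control Numbers of disease and control chromosomes
#'   sampled.
#' @param microsat_mutation_rate Per-generation probability of a stepwise
#'   (+/-1 label) microsatellite mutation along each lineage (default 0).
#' @param seed Integer seed; simulations with the same config and seed are
#'   identical.
#' @return A validated list of class `founder_sim_config`.
#' @export
founder_sim_config <- function(markers = default_marker_panel(),
                               allele_spectra = default_allele_spectra(markers),
                               true_age = 30,
                               genealogy = c("star", "exponential_growth"),
                               growth_rate = 0.107,
                               n_disease = 50, n_control = 200,
                               microsat_mutation_rate = 0,
                               seed = NULL) {
  genealogy <- match.arg(genealogy)
  if (true_age < 0) abort("`true_age` must be >= 0.")
  if (n_disease < 1) abort("`n_disease` must be >= 1.")
  if (n_control < 0) abort("`n_control` must be >= 0.")
  if (growth_rate < 0) abort("`growth_rate` must be >= 0.")
  if (microsat_mutation_rate < 0 || microsat_mutation_rate > 1) {
    abort("`microsat_mutation_rate` must be a probability.")
  }
  if (!all(markers$marker %in% names(allele_spectra))) {
    abort("`allele_spectra` must name every marker in the map.")
  }
  for (m in markers$marker) {
    s <- allele_spectra[[m]]
    if (is.null(names(s)) || any(s < 0) || abs(sum(s) - 1) > 1e-12) {
      abort(sprintf("Spectrum for marker '%s' must be named, non-negative and sum to 1.", m))
    }
  }
  structure(
    list(markers = markers, allele_spectra = allele_spectra,
         true_age = true_age, genealogy = genealogy,
         growth_rate = growth_rate, n_disease = n_disease,
         n_control = n_control,
         microsat_mutation_rate = microsat_mutation_rate, seed = seed),
    class = "founder_sim_config"
  )
}

with_config_seed <- function(config, offset, code) {
  if (is.null(config$seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer((config$seed + offset) %% 2147483647L), code)
  }
}

draw_background <- function(config, n) {
  mm <- config$markers
  cols <- lapply(mm$marker, function(m) {
    s <- config$allele_spectra[[m]]
    sample(names(s), n, replace = TRUE, prob = s)
  })
  names(cols) <- mm$marker
  tibble::as_tibble(cols)
}

#' Simulate a control chromosome panel
#'
#' Control chromosomes are drawn marker by marker from the configured
#' allele spectra at linkage equilibrium — the simplest null background
#' against which founder linkage disequilibrium is measured.
#'
#' @param config A [founder_sim_config()].
#' @return A haplotype panel tibble with `group = "control"`.
#' @export
simulate_controls <- function(config) {
  stopifnot(inherits(config, "founder_sim_config"))
  with_config_seed(config, 1L, {
    if (config$n_control == 0L) {
      return(haplotype_panel(
        as.data.frame(matrix(character(), 0, nrow(config$markers),
                             dimnames = list(NULL, config$markers$marker))),
        id = character(), group = character()))
    }
    haplotype_panel(draw_background(config, config$n_control),
                    id = sprintf("ctrl%03d", seq_len(config$n_control)),
                    group = "control", markers = config$markers)
  })
}

#' Simulate the disease-chromosome panel of a founder event
#'
#' One ancestral haplotype is drawn from the control process. Each sampled
#' disease chromosome descends from the founder through a lineage of
#' length L generations: L = true_age under the star genealogy, or
#' L = true_age - T under exponential growth, where the divergence time T
#' of the lineage from the founder line has density proportional to
#' exp(-p t) on (0, true_age) (coalescence intensity inversely
#' proportional to the growing mutant population size). On each side of
#' the locus the nearest recombination breakpoint is exponential with rate
#' L in the map coordinate u = -ln(1 - theta(d)), so each marker retains
#' the ancestral allele with probability exactly (1 - theta)^L; in the
#' small-distance regime u is the map distance in Morgans and this is the
#' classical exponential-breakpoint model. Markers beyond the breakpoint
#' receive alleles from a fresh control haplotype. Optionally, retained
#' microsatellite alleles mutate stepwise (+/-1) with the configured
#' per-generation rate.
#'
#' @param config A [founder_sim_config()].
#' @return A list: `panel` (disease haplotype panel) and `truth` (list
#'   with `ancestral` named allele vector, `true_age`, `lineage_lengths`,
#'   and `breakpoints` tibble with per-chromosome per-side breakpoint
#'   positions in the `u` coordinate and in cM).
#' @export
simulate_founder_panel <- function(config) {
  stopifnot(inherits(config, "founder_sim_config"))
  mm <- config$markers
  with_config_seed(config, 2L, {
    ancestral <- unlist(draw_background(config, 1)[1, ])
    n <- config$n_disease
    G <- config$true_age
    L <- if (config$genealogy == "star" || G == 0) {
      rep(G, n)
    } else {
      p <- config$growth_rate
      if (p == 0) {
        G - runif(n) * G                       # uniform divergence times
      } else {
        u <- runif(n)
        G - (-log(1 - u * (1 - exp(-p * G))) / p)
      }
    }
    u_marker <- -log(1 - mm$theta)             # retention coordinate
    side <- mm$side
    bp <- tibble::tibble(
      chromosome = rep(seq_len(n), each = 2L),
      side = rep(c(-1L, 1L), n),
      u = stats::rexp(2L * n, rate = pmax(rep(L, each = 2L), 1e-300))
    )
    bp$u[rep(L, each = 2L) == 0] <- Inf
    # u = -ln(1 - theta)  =>  theta = 1 - exp(-u); breakpoints with
    # u >= ln 2 lie beyond any finite Kosambi distance and are reported Inf
    theta_bp <- 1 - exp(-bp$u)
    bp$cM <- ifelse(is.finite(bp$u) & theta_bp < 0.5,
                    kosambi_distance(pmin(theta_bp, 0.5 - 1e-12)), Inf)
    hap <- matrix(NA_character_, n, nrow(mm), dimnames = list(NULL, mm$marker))
    for (i in seq_len(n)) {
      bg <- draw_background(config, 2)        # one fresh background per side
      u_left <- bp$u[bp$chromosome == i & bp$side == -1L]
      u_right <- bp$u[bp$chromosome == i & bp$side == 1L]
      keep <- ifelse(side < 0, u_marker < u_left, u_marker < u_right)
      row <- ifelse(keep, ancestral,
                    ifelse(side < 0, unlist(bg[1, ]), unlist(bg[2, ])))
      if (config$microsat_mutation_rate > 0 && L[i] > 0) {
        ms <- mm$kind == "microsatellite" & keep
        if (any(ms)) {
          steps <- rbinom(sum(ms), size = round(L[i]),
                          prob = config$microsat_mutation_rate)
          jump <- vapply(steps, function(k) {
            if (k == 0) 0L else sum(sample(c(-1L, 1L), k, replace = TRUE))
          }, integer(1))
          lab <- suppressWarnings(as.integer(row[ms]))
          row[ms] <- ifelse(is.na(lab), row[ms], as.character(lab + jump))
        }
      }
      hap[i, ] <- row
    }
    panel <- haplotype_panel(hap, id = sprintf("dis%03d", seq_len(n)),
                             group = "disease", markers = mm)
    list(
      panel = panel,
      truth = list(ancestral = ancestral, true_age = G,
                   lineage_lengths = L, breakpoints = bp)
    )
  })
}

#' Run the full estimation pipeline on one simulated data set
#'
#' Convenience wrapper: simulate controls and disease panel, detect the
#' conserved region, call founder alleles, compute p_d / p_n, and average
#' the per-marker estimates.
#'
#' @param config A [founder_sim_config()].
#' @param growth_rate Growth rate handed to the corrected estimator
#'   (defaults to the config's rate when the genealogy models growth,
#'   else 0).
#' @return A list: `inputs` (founder-allele table), `estimates`
#'   (per-marker tibble), `summary` ([summarize_tmrca()] output), `truth`.
#' @export
simulate_and_estimate <- function(config, growth_rate = NULL) {
  ctrl <- simulate_controls(config)
  sim <- simulate_founder_panel(config)
  growth_rate <- growth_rate %||%
    if (config$genealogy == "exponential_growth") config$growth_rate else 0
  inputs <- founder_allele_table(sim$panel, ctrl, config$markers)
  estimates <- estimate_marker_ages(inputs, growth_rate = growth_rate)
  list(inputs = inputs, estimates = estimates,
       summary = summarize_tmrca(estimates), truth = sim$truth)
}

#' Parameter-recovery experiment for the age estimators
#'
#' Repeatedly simulates founder events at a known age and pushes each
#' replicate through the full analysis pipeline (founder-allele calling on
#' the simulated data, not the recorded truth), summarising how well the
#' chosen estimator recovers the truth.
#'
#' @param config A [founder_sim_config()]; its `seed` anchors the
#'   replicate seeds.
#' @param n_replicates Number of simulated data sets.
#' @param estimator `"risch"`, `"bergman"` or `"labuda"`.
#' @return A list with `replicates` (tibble: `replicate`, `estimate`,
#'   `n_markers`, `ci_lower`, `ci_upper`, `covered`) and `summary` (one
#'   row: `true_age`, `mean_estimate`, `bias`, `rmse`, `ci_coverage`,
#'   `n_failed`).
#' @export
recovery_experiment <- function(config, n_replicates = 200,
                                estimator = c("risch", "bergman", "labuda")) {
  stopifnot(inherits(config, "founder_sim_config"))
  estimator <- match.arg(estimator)
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  base_seed <- config$seed %||% 1L
  rows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- (base_seed + 7919L * r) %% 2147483647L
    res <- suppressWarnings(simulate_and_estimate(cfg))
    s <- res$summary[res$summary$estimator == estimator, , drop = FALSE]
    if (nrow(s) == 0L) {
      return(tibble::tibble(replicate = r, estimate = NA_real_,
                            n_markers = 0L, ci_lower = NA_real_,
                            ci_upper = NA_real_, covered = NA))
    }
    tibble::tibble(
      replicate = r, estimate = s$mean_g, n_markers = s$n,
      ci_lower = s$ci_lower, ci_upper = s$ci_upper,
      covered = !is.na(s$ci_lower) &
        s$ci_lower <= config$true_age & config$true_age <= s$ci_upper
    )
  })
  est <- rows$estimate[!is.na(rows$estimate)]
  summary <- tibble::tibble(
    estimator = estimator,
    true_age = config$true_age,
    n_replicates = n_replicates,
    mean_estimate = mean(est),
    bias = mean(est) - config$true_age,
    rmse = sqrt(mean((est - config$true_age)^2)),
    ci_coverage = mean(rows$covered, na.rm = TRUE),
    n_failed = sum(is.na(rows$estimate))
  )
  list(replicates = rows, summary = summary)
}
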