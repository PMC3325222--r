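#' Excess founder-allele frequency on disease chromosomes
#'
#' delta = (p_d - p_n) / (1 - p_n): the proportion of disease chromosomes
#' carrying the founder allele by descent rather than by chance, the
#' quantity whose geometric decay at rate (1 - theta) per generation the
#' moment estimators invert.
#'
#' @param p_d Founder-allele frequency on disease chromosomes, in `(0, 1]`.
#' @param p_n The same allele's frequency on control chromosomes, `[0, 1)`.
#' @return delta (vectorised). Negative values mean the allele is more
#'   common in controls than on disease chromosomes.
#' @export
#' @examples
#' p_excess(0.8, 0.16)
p_excess <- function(p_d, p_n) {
  if (any(p_n >= 1, na.rm = TRUE)) {
    abort("`p_n` must be < 1.", class = "founderage_domain_error")
  }
  (p_d - p_n) / (1 - p_n)
}

#' Moment estimators of generations since the founder
#'
#' Both estimators invert the single-marker decay law Q = (1 - theta)^g,
#' g = ln(Q) / ln(1 - theta), under a star genealogy; they differ in what
#' is taken as the surviving ancestral proportion Q. `risch_g()` uses the
#' excess allele sharing delta = (p_d - p_n)/(1 - p_n), which corrects for
#' chance carriage of the founder allele on recombinant chromosomes.
#' `bergman_g()` uses, by default (`variant = "proportion"`), the raw
#' proportion p_d of disease chromosomes carrying the founder allele, with
#' `variant = "excess"` available to fall back to delta.
#'
#' Non-informative inputs (delta <= 0, i.e. the founder allele is not
#' enriched on disease chromosomes) return `NA`; see
#' [informativeness_filter()] for the reason codes.
#'
#' @param delta Excess founder-allele frequency, from [p_excess()].
#' @param theta Recombination fraction between marker and locus, `(0, 0.5)`.
#' @param p_d,p_n Founder-allele frequencies on disease and control
#'   chromosomes.
#' @param variant Which ancestral proportion `bergman_g()` inverts.
#' @return Estimated generations back to the most recent common ancestor
#'   (vectorised); `NA` where non-informative.
#' @export
#' @examples
#' risch_g(p_excess(0.8, 0.16), kosambi_theta(5.4448))
#' bergman_g(0.8, 0.16, kosambi_theta(5.4448))
risch_g <- function(delta, theta) {
  check_theta(theta)
  n <- max(length(delta), length(theta))
  delta <- rep_len(delta, n); theta <- rep_len(theta, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(delta) & delta > 0 & delta <= 1
  out[ok] <- log(delta[ok]) / log(1 - theta[ok])
  out
}

#' @rdname risch_g
#' @export
bergman_g <- function(p_d, p_n, theta, variant = c("proportion", "excess")) {
  variant <- match.arg(variant)
  check_theta(theta)
  q <- switch(variant, proportion = p_d, excess = p_excess(p_d, p_n))
  n <- max(length(q), length(theta), length(p_d))
  q <- rep_len(q, n); theta <- rep_len(theta, n)
  p_d <- rep_len(p_d, n); p_n <- rep_len(p_n, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(q) & !is.na(p_d) & !is.na(p_n) & p_d > p_n & q > 0 & q <= 1
  out[ok] <- log(q[ok]) / log(1 - theta[ok])
  out[!is.na(p_d) & p_d == 1] <- 0
  out
}

check_theta <- function(theta) {
  if (any(theta <= 0 | theta >= 0.5, na.rm = TRUE)) {
    abort("`theta` must lie in (0, 0.5) for age estimation.",
          class = "founderage_domain_error")
  }
  invisible(theta)
}

#' Growth correction of a moment age estimate
#'
#' Under a star genealogy every sampled lineage is independent of the
#' founder for the full mutation age, and the moment estimators are
#' calibrated. In a finite, exponentially growing mutant population,
#' lineages share an initial stretch of ancestry with the founder line, so
#' the average independent lineage length L is shorter than the true age G
#' and the raw estimate is biased downward. The default correction models
#' the divergence time T of a sampled lineage from the founder line as
#' having density proportional to exp(-p t) over (0, G) (coalescence
#' intensity inversely proportional to the mutant population size
#' N(t) = exp(p t)), and solves
#'
#'   E\[(1 - theta)^(G - T)\] = (1 - theta)^g_hat
#'
#' for G. The corrected age always satisfies G >= g_hat for p > 0. A
#' growth rate of 0 asserts the star model and returns the estimate
#' unchanged. The correction is pluggable: any function of
#' `(g, theta, growth_rate)` returning a corrected generation count can be
#' supplied.
#'
#' @param g Uncorrected generation estimate(s), e.g. from [risch_g()].
#' @param theta Recombination fraction(s), recycled against `g`.
#' @param growth_rate Per-generation exponential growth rate p (>= 0).
#' @param correction Optional replacement correction function.
#' @param g_max Upper search bound for the corrected age.
#' @return Corrected generation estimate(s); `NA` inputs propagate.
#' @export
#' @examples
#' labuda_correct(20, kosambi_theta(mb_to_cm(1.98)), growth_rate = 0.107)
labuda_correct <- function(g, theta, growth_rate,
                           correction = NULL, g_max = 10000) {
  if (length(growth_rate) != 1L || growth_rate < 0) {
    abort("`growth_rate` must be a single non-negative rate.",
          class = "founderage_domain_error")
  }
  if (!is.null(correction)) {
    return(correction(g, theta, growth_rate))
  }
  if (growth_rate == 0) {
    return(g)
  }
  check_theta(theta)
  n <- max(length(g), length(theta))
  g <- rep_len(g, n); theta <- rep_len(theta, n)
  vapply(seq_len(n), function(i) {
    if (is.na(g[i]) || is.na(theta[i])) return(NA_real_)
    if (g[i] <= 0) return(g[i])
    solve_growth_age(g[i], theta[i], growth_rate, g_max)
  }, numeric(1))
}

# E[(1-theta)^(G-T)] with T ~ p exp(-p t) / (1 - exp(-p G)) on (0, G)
mean_retention_under_growth <- function(G, a, p) {
  # a = -log(1 - theta); closed form of the truncated-exponential mixture
  if (abs(a - p) < 1e-12) {
    p * G * exp(-p * G) / (1 - exp(-p * G))
  } else {
    p * (exp(-p * G) - exp(-a * G)) / ((a - p) * (1 - exp(-p * G)))
  }
}

solve_growth_age <- function(g_hat, theta, p, g_max) {
  a <- -log(1 - theta)
  target <- exp(-a * g_hat)
  f <- function(G) mean_retention_under_growth(G, a, p) - target
  # E[(1-theta)^L] > (1-theta)^G, so the root lies at G >= g_hat
  if (f(g_max) > 0) return(g_max)
  uniroot(f, lower = g_hat, upper = g_max, tol = 1e-9)$root
}

#' Informativeness screen for per-marker age estimation
#'
#' Implements the exclusion rules applied before averaging: a marker is
#' dropped (i) for the excess-sharing (Risch-type) estimator when
#' delta <= 0, and for the proportion (Bergman-type) estimator when the
#' founder allele is no more common on disease than on control chromosomes
#' (p_d <= p_n); (ii) for the excess-sharing estimator when its
#' founder-allele disease frequency equals that of its neighbour nearer
#' the locus, since the marker then adds no recombination information;
#' (iii) always, when theta = 0 (markers inside the conserved region carry
#' no decay signal). Study-specific exclusions can be forced through
#' `overrides` (e.g. a marker the original analysis dropped on grounds the
#' numeric rule does not capture).
#'
#' @param data A tibble with columns `marker`, `p_d`, `p_n`, `theta` (and
#'   optionally `distance_mb` / `cM`, used to order markers by distance).
#' @param estimator `"risch"` or `"bergman"`.
#' @param overrides Character vector of `"MARKER:ESTIMATOR:REASON"`
#'   entries (ESTIMATOR `risch`, `bergman` or `all`) forcing exclusions.
#' @return `data` with logical `included` and character `reason`
#'   (`NA` when included) columns appended.
#' @export
informativeness_filter <- function(data, estimator = c("risch", "bergman"),
                                   overrides = NULL) {
  estimator <- match.arg(estimator)
  ord <- if ("distance_mb" %in% names(data)) {
    order(abs(data$distance_mb))
  } else {
    order(data$theta)
  }
  data <- data[ord, , drop = FALSE]
  n <- nrow(data)
  reason <- rep(NA_character_, n)
  delta <- p_excess(data$p_d, data$p_n)
  zero_theta <- data$theta <= 0
  reason[zero_theta] <- "inside_conserved_region"
  if (estimator == "risch") {
    reason[is.na(reason) & delta <= 0] <- "allele_not_enriched_in_disease"
    prev_pd <- dplyr::lag(data$p_d)
    dup <- !is.na(prev_pd) & data$p_d == prev_pd
    reason[is.na(reason) & dup] <- "no_added_recombination_information"
  } else {
    reason[is.na(reason) & data$p_d <= data$p_n] <- "allele_not_enriched_in_disease"
  }
  for (ov in overrides %||% character()) {
    parts <- strsplit(ov, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      abort("Overrides must be 'MARKER:ESTIMATOR:REASON' strings.")
    }
    if (parts[2] %in% c(estimator, "all")) {
      hit <- data$marker == parts[1]
      reason[hit & is.na(reason)] <- paste0("override:", parts[3])
    }
  }
  data$delta <- delta
  data$included <- is.na(reason)
  data$reason <- reason
  data
}

#' Per-marker age estimates for a founder mutation
#'
#' Takes the per-marker inputs (founder-allele frequencies on disease and
#' control chromosomes, recombination fraction) and returns the
#' generation estimates of each moment estimator together with the growth
#' correction and informativeness screens.
#'
#' @inheritParams informativeness_filter
#' @param growth_rate Per-generation population growth rate used by the
#'   corrected estimator (see [labuda_correct()]); the study default for
#'   the Galician population is 0.107.
#' @param variant Ancestral proportion used by [bergman_g()].
#' @param overrides Forced per-marker exclusions (see
#'   [informativeness_filter()]).
#' @return A tibble with one row per marker: the inputs, `delta`, the
#'   estimates `bergman_g`, `risch_g`, `labuda_g` (`NA` where excluded)
#'   and per-estimator inclusion flags and reason codes.
#' @export
#' @examples
#' estimate_marker_ages(
#'   tibble::tibble(marker = c("A", "B"), p_d = c(0.8, 0.6),
#'                  p_n = c(0.16, 0.3),
#'                  theta = kosambi_theta(mb_to_cm(c(1.98, 4.54)))),
#'   growth_rate = 0.107
#' )
estimate_marker_ages <- function(data, growth_rate = 0,
                                 variant = c("proportion", "excess"),
                                 overrides = NULL) {
  variant <- match.arg(variant)
  need <- c("marker", "p_d", "p_n", "theta")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns: %s.", paste(need, collapse = ", ")))
  }
  ri <- informativeness_filter(data, "risch", overrides = overrides)
  be <- informativeness_filter(data, "bergman", overrides = overrides)
  out <- ri
  out$risch_included <- ri$included
  out$risch_reason <- ri$reason
  out$bergman_included <- be$included[match(out$marker, be$marker)]
  out$bergman_reason <- be$reason[match(out$marker, be$marker)]
  out$included <- NULL
  out$reason <- NULL
  safe_theta <- ifelse(out$theta > 0, out$theta, NA_real_)
  out$bergman_g <- ifelse(
    out$bergman_included,
    bergman_g(out$p_d, out$p_n, safe_theta, variant = variant),
    NA_real_
  )
  out$risch_g <- ifelse(
    out$risch_included,
    risch_g(out$delta, safe_theta),
    NA_real_
  )
  out$labuda_g <- labuda_correct(out$risch_g, safe_theta, growth_rate)
  out
}

#' Across-marker average of per-marker generation estimates
#'
#' The per-marker estimates are combined by their arithmetic mean; the
#' 95% confidence interval is mean +/- 1.96 standard errors, with the
#' standard error computed from the sample standard deviation (n - 1
#' denominator). Values are kept unrounded; rounding to whole generations
#' happens only at the report layer ([format()]).
#'
#' @param g Numeric vector of per-marker generation estimates (`NA`s are
#'   dropped).
#' @param generation_time Years per generation (default 30).
#' @param estimator Optional estimator label carried into the output.
#' @return A one-row tibble of class `tmrca_summary`: `estimator`, `n`,
#'   `mean_g`, `se`, `ci_lower`, `ci_upper`, `mean_years`,
#'   `ci_lower_years`, `ci_upper_years`. With a single marker the CI is
#'   `NA`.
#' @export
#' @examples
#' average_tmrca(c(40, 65, 29, 20, 19))   # mean 34.6, CI (18.0, 51.2)
average_tmrca <- function(g, generation_time = 30, estimator = NA_character_) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) {
    abort("No informative marker estimates to average.")
  }
  n <- length(g)
  m <- mean(g)
  se <- if (n >= 2L) sd(g) / sqrt(n) else NA_real_
  lo <- m - 1.96 * se
  hi <- m + 1.96 * se
  out <- tibble::tibble(
    estimator = estimator, n = n, mean_g = m, se = se,
    ci_lower = lo, ci_upper = hi,
    mean_years = m * generation_time,
    ci_lower_years = lo * generation_time,
    ci_upper_years = hi * generation_time
  )
  class(out) <- c("tmrca_summary", class(out))
  out
}

#' Summarise all estimators over the informative markers
#'
#' @param estimates Output of [estimate_marker_ages()].
#' @param generation_time Years per generation.
#' @return A `tmrca_summary` tibble with one row per estimator
#'   (`bergman`, `risch`, `labuda`); estimators with no informative marker
#'   are dropped.
#' @export
summarize_tmrca <- function(estimates, generation_time = 30) {
  pieces <- list(
    bergman = estimates$bergman_g,
    risch = estimates$risch_g,
    labuda = estimates$labuda_g
  )
  rows <- purrr::imap(pieces, function(v, nm) {
    if (all(is.na(v))) NULL else average_tmrca(v, generation_time, estimator = nm)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tmrca_summary", class(out))
  out
}

#' Display a TMRCA summary the way study tables print it
#'
#' @param x A `tmrca_summary` tibble.
#' @param ... Unused.
#' @return Character vector like `"35 (18-51)"`, one per row (mean and CI
#'   rounded half-up to whole generations).
#' @export
format.tmrca_summary <- function(x, ...) {
  ifelse(
    is.na(x$se),
    sprintf("%d (n=1)", round_half_up(x$mean_g)),
    sprintf("%d (%d-%d)", round_half_up(x$mean_g),
            round_half_up(x$ci_lower), round_half_up(x$ci_upper))
  )
}

#' @export
print.tmrca_summary <- function(x, ...) {
  if (!all(c("mean_g", "se") %in% names(x))) {
    return(NextMethod())
  }
  cat("TMRCA summary (generations):\n")
  lab <- if ("estimator" %in% names(x)) x$estimator else rep("", nrow(x))
  if ("mutation" %in% names(x)) lab <- paste(x$mutation, lab)
  cat(paste0("  ", formatC(lab, width = max(nchar(lab)) + 1), " ", format(x),
             collapse = "\n"), "\n")
  invisible(x)
}

# ---- composite-likelihood age estimator -----------------------------------

#' Composite-likelihood estimate of mutation age
#'
#' A deliberately simple likelihood-based age estimator over all disease
#' chromosomes and markers jointly, provided as a cross-check on the
#' moment estimators. Each observed allele contributes independently:
#'
#'   P(founder allele | g) = (1 - theta)^g + (1 - (1 - theta)^g) p_n
#'   P(other allele a | g) = (1 - (1 - theta)^g) p_n(a)
#'
#' and the log composite likelihood is maximised over g on `(0, g_max]`.
#' This is NOT the Rannala-Reeve intra-allelic coalescent model behind
#' DMLE-style Bayesian dating: independence is assumed across markers and
#' across chromosomes, so the interval is a composite-likelihood profile
#' interval, not a posterior. With a single marker and a founder allele
#' absent from controls it reduces analytically to [risch_g()] with
#' delta = k/n.
#'
#' @param disease Haplotype panel of disease chromosomes.
#' @param founder Founder-allele table ([founder_allele_table()]) or any
#'   tibble with `marker`, `allele`, `theta` columns; markers with
#'   `theta <= 0` are ignored.
#' @param control_freqs Long tibble of control allele frequencies with
#'   columns `marker`, `allele`, `freq` (e.g. from [allele_frequency()]
#'   per marker); alleles absent from it get frequency `freq_floor`.
#' @param g_max Upper bound of the age search (default 500 generations).
#' @param prior Optional function of g giving a prior density; when
#'   supplied, a normalised grid posterior over `(0, g_max]` is returned
#'   alongside the profile interval.
#' @param freq_floor Frequency assigned to control-unseen alleles.
#' @return An object of class `founder_age_fit`: list with `estimate`
#'   (MLE in generations), `ci` (profile interval at 1.92 log-lik drop),
#'   `loglik` (function), `profile` (tibble `g`, `loglik`), `posterior`
#'   (tibble or NULL), `n_chromosomes`, `n_markers`, `boundary` flag.
#' @export
composite_likelihood_age <- function(disease, founder, control_freqs,
                                     g_max = 500, prior = NULL,
                                     freq_floor = 1 / 402) {
  disease <- disease[disease$group == "disease", , drop = FALSE]
  if (nrow(disease) == 0L) {
    abort("Need at least one disease chromosome.")
  }
  founder <- founder[founder$theta > 0, , drop = FALSE]
  if (nrow(founder) == 0L) {
    abort("Need at least one marker with theta > 0.")
  }
  obs <- panel_matrix(disease, founder$marker)
  lookup <- function(m, a) {
    hit <- control_freqs$freq[control_freqs$marker == m & control_freqs$allele == a]
    if (length(hit)) hit[1] else freq_floor
  }
  pn_founder <- vapply(seq_len(nrow(founder)),
                       function(j) lookup(founder$marker[j], founder$allele[j]),
                       numeric(1))
  pn_obs <- matrix(0, nrow(obs), ncol(obs))
  is_founder <- matrix(FALSE, nrow(obs), ncol(obs))
  for (j in seq_len(ncol(obs))) {
    is_founder[, j] <- !is.na(obs[, j]) & obs[, j] == founder$allele[j]
    pn_obs[, j] <- vapply(obs[, j], function(a) {
      if (is.na(a)) NA_real_ else lookup(founder$marker[j], a)
    }, numeric(1))
  }
  theta <- founder$theta
  loglik <- function(g) {
    q <- matrix(rep((1 - theta)^g, each = nrow(obs)), nrow(obs))
    pf <- matrix(rep(pn_founder, each = nrow(obs)), nrow(obs))
    p <- ifelse(is_founder, q + (1 - q) * pf, (1 - q) * pn_obs)
    sum(log(pmax(p, 1e-300)), na.rm = TRUE)
  }
  all_ancestral <- all(is_founder | is.na(obs))
  grid <- seq(g_max / 2000, g_max, length.out = 2000)
  prof <- vapply(grid, loglik, numeric(1))
  if (all_ancestral) {
    estimate <- 0
    boundary <- TRUE
    warn("All disease chromosomes fully ancestral: age estimate at the 0 boundary.")
  } else {
    coarse <- grid[which.max(prof)]
    w <- g_max / 2000 * 4
    opt <- optimize(loglik, lower = max(1e-8, coarse - w),
                    upper = min(g_max, coarse + w),
                    maximum = TRUE, tol = 1e-6)
    estimate <- opt$maximum
    boundary <- FALSE
  }
  llmax <- if (boundary) loglik(1e-8) else loglik(estimate)
  keep <- grid[prof >= llmax - qnorm(0.975)^2 / 2]
  ci <- if (length(keep)) range(keep) else c(NA_real_, NA_real_)
  posterior <- NULL
  if (!is.null(prior)) {
    lp <- prof + log(pmax(vapply(grid, prior, numeric(1)), 1e-300))
    lp <- lp - max(lp)
    w <- exp(lp); w <- w / sum(w)
    posterior <- tibble::tibble(g = grid, density = w / diff(grid[1:2]))
  }
  structure(
    list(estimate = estimate, ci = ci, loglik = loglik,
         profile = tibble::tibble(g = grid, loglik = prof),
         posterior = posterior,
         n_chromosomes = nrow(obs), n_markers = ncol(obs),
         boundary = boundary, g_max = g_max),
    class = "founder_age_fit"
  )
}

#' @export
print.founder_age_fit <- function(x, ...) {
  cat(sprintf(
    "Composite-likelihood mutation age: %.1f generations (profile interval %.1f-%.1f)\n",
    x$estimate, x$ci[1], x$ci[2]))
  cat(sprintf("  %d chromosomes, %d markers%s\n", x$n_chromosomes, x$n_markers,
              if (x$boundary) " [boundary estimate]" else ""))
  invisible(x)
}

#' Tidiers for composite-likelihood age fits
#'
#' @param x A `founder_age_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per quantity (estimate and interval bounds).
#'   `glance()`: a one-row model summary.
#' @exportS3Method generics::tidy
tidy.founder_age_fit <- function(x, ...) {
  tibble::tibble(
    term = "age_generations",
    estimate = x$estimate,
    conf.low = x$ci[1],
    conf.high = x$ci[2]
  )
}

#' @rdname tidy.founder_age_fit
#' @exportS3Method generics::glance
glance.founder_age_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik(max(x$estimate, 1e-8)),
    n_chromosomes = x$n_chromosomes,
    n_markers = x$n_markers,
    boundary = x$boundary,
    g_max = x$g_max
  )
}
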