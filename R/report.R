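#' Summarise published per-marker generation estimates
#'
#' The "table" entry mode: when only per-marker generation counts are
#' available (as in a published study table, where the underlying allele
#' frequencies are not reported), this reproduces the across-marker
#' summary rows directly with [average_tmrca()].
#'
#' @param generations A tibble with columns `mutation`, `estimator`,
#'   `marker`, `generations` (`NA` = marker excluded for that estimator),
#'   e.g. read from the bundled
#'   `founderage_example("tgm1_reported_generations.tsv")`.
#' @param generation_time Years per generation.
#' @return A `tmrca_summary` tibble with one row per mutation x estimator,
#'   plus a `display` column in the printed `"35 (18-51)"` style.
#' @export
#' @examples
#' gens <- readr::read_tsv(
#'   founderage_example("tgm1_reported_generations.tsv"),
#'   show_col_types = FALSE
#' )
#' estimate_from_generations(gens)
estimate_from_generations <- function(generations, generation_time = 30) {
  need <- c("mutation", "estimator", "marker", "generations")
  if (!all(need %in% names(generations))) {
    abort(sprintf("`generations` must have columns: %s.",
                  paste(need, collapse = ", ")))
  }
  out <- generations |>
    dplyr::group_by(.data$mutation, .data$estimator) |>
    dplyr::group_modify(function(d, key) {
      g <- d$generations[!is.na(d$generations)]
      if (length(g) == 0L) return(tibble::tibble())
      average_tmrca(g, generation_time = generation_time)[-1]
    }) |>
    dplyr::ungroup()
  class(out) <- c("tmrca_summary", class(out))
  out$display <- format(out)
  out
}

#' Run the founder-mutation dating pipeline end to end
#'
#' Orchestrates the analysis from files or in-memory tables: conserved
#' region detection, founder-allele calling against controls, per-marker
#' moment estimates with informativeness screening, growth-corrected and
#' composite-likelihood ages, demographic calculators, and a report bundle
#' (TSV tables plus a JSON summary and run manifest) written under
#' `out_dir`. The run is deterministic given its inputs and seed.
#'
#' @param markers Marker map tibble or path to a marker-map TSV.
#' @param haplotypes Haplotype panel tibble (disease and control rows) or
#'   path to a haplotype TSV.
#' @param growth_rate Per-generation growth rate for the corrected
#'   estimator; `NULL` computes it from `census` via [growth_rate()].
#' @param census Optional named list
#'   (`n_present`, `n_reference`, `year_present`, `year_reference`) for
#'   the demography block.
#' @param generation_time Years per generation.
#' @param variant Ancestral proportion for [bergman_g()].
#' @param overrides Forced exclusions, `"MARKER:ESTIMATOR:REASON"`.
#' @param composite Also fit [composite_likelihood_age()]?
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed matters when simulation steps are added).
#' @return A list of class `founderage_run`: `region`, `inputs`,
#'   `estimates`, `summary`, `fit` (or NULL), `demography`, `manifest`.
#' @export
run_analysis <- function(markers, haplotypes,
                         growth_rate = NULL, census = NULL,
                         generation_time = 30,
                         variant = "proportion", overrides = NULL,
                         composite = TRUE,
                         out_dir = NULL, seed = 1L) {
  if (is.character(markers)) markers <- read_marker_map(markers)
  if (is.character(haplotypes)) haplotypes <- read_haplotypes(haplotypes, markers)
  disease <- haplotypes[haplotypes$group == "disease", , drop = FALSE]
  control <- haplotypes[haplotypes$group == "control", , drop = FALSE]
  if (nrow(disease) == 0L) {
    abort("No disease chromosomes in the input panel.")
  }
  demo <- if (is.null(census)) growth_rate() else {
    do.call(growth_rate, census)
  }
  p <- if (is.null(growth_rate)) demo$rate else growth_rate
  region <- if (nrow(disease) >= 2L) conserved_region(disease, markers) else NULL
  inputs <- founder_allele_table(disease, control, markers)
  estimates <- estimate_marker_ages(inputs, growth_rate = p,
                                    variant = variant, overrides = overrides)
  summary <- summarize_tmrca(estimates, generation_time = generation_time)
  fit <- NULL
  if (composite && any(inputs$theta > 0)) {
    ctrl_freqs <- purrr::map_dfr(markers$marker, function(m) {
      f <- tryCatch(allele_frequency(control, m), error = function(e) NULL)
      if (is.null(f)) NULL else dplyr::mutate(f, marker = m, .before = 1)
    })
    fit <- composite_likelihood_age(disease, inputs, ctrl_freqs)
  }
  res <- structure(
    list(region = region, inputs = inputs, estimates = estimates,
         summary = summary, fit = fit, demography = demo,
         manifest = list(
           package_version = as.character(utils::packageVersion("founderage")),
           n_disease = nrow(disease), n_control = nrow(control),
           n_markers = nrow(markers), growth_rate = p,
           generation_time = generation_time, variant = variant,
           overrides = overrides, seed = seed,
           timestamp = format(Sys.time(), tz = "UTC")
         )),
    class = "founderage_run"
  )
  if (!is.null(out_dir)) write_run_report(res, out_dir)
  res
}

#' Write the report bundle of a pipeline run
#'
#' @param run A `founderage_run` object from [run_analysis()].
#' @param out_dir Directory to create and write into.
#' @return `run`, invisibly. Writes `marker_estimates.tsv`,
#'   `tmrca_summary.tsv`, `conserved_region.tsv`, `demography.tsv`,
#'   `summary.json` (unrounded values alongside display strings) and
#'   `manifest.json`.
#' @export
write_run_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$estimates, file.path(out_dir, "marker_estimates.tsv"),
                   progress = FALSE)
  summ <- run$summary
  summ$display <- format(summ)
  readr::write_tsv(summ, file.path(out_dir, "tmrca_summary.tsv"),
                   progress = FALSE)
  if (!is.null(run$region)) {
    readr::write_tsv(run$region$region,
                     file.path(out_dir, "conserved_region.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(run$demography, file.path(out_dir, "demography.tsv"),
                   progress = FALSE)
  json <- list(
    summary = summ,
    conserved_region_cm = if (is.null(run$region)) NULL else run$region$length_cm,
    composite_age = if (is.null(run$fit)) NULL else
      list(estimate = run$fit$estimate, ci = run$fit$ci),
    demography = run$demography
  )
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(run)
}

#' @export
print.founderage_run <- function(x, ...) {
  cat("Founder-mutation dating run\n")
  cat(sprintf("  %d disease / %d control chromosomes, %d markers\n",
              x$manifest$n_disease, x$manifest$n_control, x$manifest$n_markers))
  if (!is.null(x$region)) {
    cat(sprintf("  conserved region: %d markers, %.2f cM\n",
                nrow(x$region$region), x$region$length_cm))
  }
  print(x$summary)
  if (!is.null(x$fit)) {
    cat(sprintf("  composite-likelihood age: %.1f (%.1f-%.1f) generations\n",
                x$fit$estimate, x$fit$ci[1], x$fit$ci[2]))
  }
  invisible(x)
}
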