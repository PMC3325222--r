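#' Plot a conserved ancestral region
#'
#' Tile plot of the disease haplotypes over the marker panel, colouring
#' each call by whether it matches the shared (ancestral) allele at that
#' marker; the detected conserved region is framed.
#'
#' @param object A `conserved_region` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.conserved_region <- function(object, ...) {
  mm <- object$markers
  long <- object$panel |>
    tidyr::pivot_longer(dplyr::all_of(mm$marker),
                        names_to = "marker", values_to = "allele") |>
    dplyr::left_join(object$region[, c("marker", "allele")],
                     by = "marker", suffix = c("", "_shared")) |>
    dplyr::mutate(
      marker = factor(.data$marker, levels = mm$marker),
      status = dplyr::case_when(
        is.na(.data$allele) ~ "missing",
        !is.na(.data$allele_shared) & .data$allele == .data$allele_shared ~ "ancestral",
        TRUE ~ "other"
      )
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$id,
                                     fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$allele), size = 2.6) +
    ggplot2::scale_fill_manual(values = c(ancestral = "#74add1",
                                          other = "grey92",
                                          missing = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = sprintf("Conserved ancestral region: %.2f cM",
                                  object$length_cm)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the profile of a composite-likelihood age fit
#'
#' @param object A `founder_age_fit`.
#' @param ... Unused.
#' @return A ggplot of the composite log-likelihood over candidate ages,
#'   with the point estimate and profile interval marked.
#' @exportS3Method ggplot2::autoplot
autoplot.founder_age_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$g, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "#d73027") +
    ggplot2::geom_vline(xintercept = object$ci, colour = "#d73027",
                        linetype = "dashed") +
    ggplot2::labs(x = "Mutation age (generations)",
                  y = "Composite log-likelihood") +
    ggplot2::theme_minimal()
}

#' Plot per-marker linkage-disequilibrium decay
#'
#' Founder-allele retention against recombination fraction for each
#' marker, overlaid with the decay curves (1 - theta)^g implied by the
#' across-marker mean of each estimator.
#'
#' @param estimates Output of [estimate_marker_ages()].
#' @param summary Optional [summarize_tmrca()] output supplying the mean
#'   ages whose decay curves are drawn.
#' @return A ggplot.
#' @export
plot_decay <- function(estimates, summary = NULL) {
  pts <- estimates[estimates$theta > 0, , drop = FALSE]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$theta, y = .data$delta)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$risch_included), size = 2) +
    ggplot2::labs(x = expression(theta), y = expression(delta),
                  shape = "informative") +
    ggplot2::theme_minimal()
  if (!is.null(summary)) {
    th <- seq(1e-4, max(pts$theta) * 1.05, length.out = 200)
    curves <- purrr::map_dfr(seq_len(nrow(summary)), function(i) {
      tibble::tibble(estimator = summary$estimator[i], theta = th,
                     delta = (1 - th)^summary$mean_g[i])
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$theta, y = .data$delta,
                   colour = .data$estimator))
  }
  p
}
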