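#' Convert physical distance to genetic map distance
#'
#' Physical distances around the disease locus are converted to map
#' distances with a constant sex-averaged recombination rate. The default,
#' 1.64 cM/Mb, is the rate estimated for the 14q11 region around TGM1 from
#' control chromosomes; it can be overridden per run, and a supplied
#' genetic map always takes precedence over the conversion (see
#' [marker_map()]).
#'
#' @param d_mb Physical distance in megabases (non-negative, vectorised).
#' @param rate Recombination rate in cM per Mb (positive scalar).
#' @return Genetic distance in centimorgans.
#' @export
#' @examples
#' mb_to_cm(3.32)           # 5.4448 cM
#' mb_to_cm(8.7, rate = 1.64)
mb_to_cm <- function(d_mb, rate = 1.64) {
  if (!is.numeric(d_mb) || any(d_mb < 0, na.rm = TRUE)) {
    abort("`d_mb` must be a non-negative physical distance in Mb.",
          class = "founderage_distance_error")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort("`rate` must be a single positive cM/Mb value.",
          class = "founderage_distance_error")
  }
  d_mb * rate
}

#' Kosambi map function and its inverse
#'
#' `kosambi_theta()` translates a map distance into a recombination
#' fraction with the Kosambi map function, theta = tanh(2 d) / 2 with d in
#' Morgans, which allows for moderate crossover interference.
#' `kosambi_distance()` is the exact inverse, d = ln((1 + 2 theta) /
#' (1 - 2 theta)) / 4. The two round-trip to numerical precision.
#'
#' @param d_cm Map distance in centimorgans (non-negative, vectorised).
#' @param theta Recombination fraction in `[0, 0.5)` (vectorised).
#' @return `kosambi_theta()`: recombination fraction in `[0, 0.5)`.
#'   `kosambi_distance()`: map distance in centimorgans.
#' @export
#' @examples
#' kosambi_theta(5.4448)
#' kosambi_distance(kosambi_theta(5.4448))
kosambi_theta <- function(d_cm) {
  if (!is.numeric(d_cm) || any(d_cm < 0, na.rm = TRUE)) {
    abort("`d_cm` must be a non-negative map distance in cM.",
          class = "founderage_distance_error")
  }
  0.5 * tanh(2 * d_cm / 100)
}

#' @rdname kosambi_theta
#' @export
kosambi_distance <- function(theta) {
  if (!is.numeric(theta) || any(theta < 0 | theta >= 0.5, na.rm = TRUE)) {
    abort("`theta` must lie in [0, 0.5).",
          class = "founderage_distance_error")
  }
  100 * 0.25 * log((1 + 2 * theta) / (1 - 2 * theta))
}

#' Build a marker map around a disease locus
#'
#' A marker map is a tibble describing the genotyped loci flanking the
#' disease mutation: identifier, marker type, unsigned physical distance
#' from the locus and which side of the locus the marker lies on. Genetic
#' distance and recombination fraction are derived (constant cM/Mb rate,
#' then Kosambi) unless a genetic distance is supplied, in which case the
#' supplied map is authoritative.
#'
#' Rows are sorted by signed position (side times distance), so the locus
#' sits between the negative- and positive-position markers. Estimators
#' depend only on the unsigned distance; the side matters for ordering and
#' conserved-region detection.
#'
#' @param marker Character vector of marker names (unique).
#' @param distance_mb Unsigned physical distance from the disease locus, Mb.
#' @param kind `"microsatellite"` or `"SNP"` (recycled).
#' @param side `+1` (distal) or `-1` (proximal) relative to the locus
#'   (recycled; default all `+1` as printed study tables give unsigned
#'   distances only).
#' @param cM Optional genetic distance in cM; when supplied it overrides
#'   the cM/Mb conversion for that marker.
#' @param cm_per_mb Conversion rate used where `cM` is not supplied.
#' @return A tibble with columns `marker`, `kind`, `distance_mb`, `side`,
#'   `position_mb`, `cM`, `theta`, sorted by `position_mb`.
#' @export
#' @examples
#' marker_map(c("D14S275", "D14S1060"), c(1.98, 8.7))
marker_map <- function(marker, distance_mb,
                       kind = "microsatellite",
                       side = 1L, cM = NULL, cm_per_mb = 1.64) {
  if (anyDuplicated(marker)) {
    abort("Marker names must be unique.")
  }
  n <- length(marker)
  kind <- rep_len(as.character(kind), n)
  side <- rep_len(as.integer(side), n)
  if (!all(kind %in% c("microsatellite", "SNP"))) {
    abort("`kind` must be 'microsatellite' or 'SNP'.")
  }
  if (!all(side %in% c(-1L, 1L))) {
    abort("`side` must be -1 (proximal) or +1 (distal).")
  }
  derived <- mb_to_cm(distance_mb, cm_per_mb)
  cm <- if (is.null(cM)) derived else dplyr::coalesce(rep_len(cM, n), derived)
  if (any(cm < 0, na.rm = TRUE)) {
    abort("Genetic distances must be non-negative.",
          class = "founderage_distance_error")
  }
  tibble::tibble(
    marker = as.character(marker),
    kind = kind,
    distance_mb = as.numeric(distance_mb),
    side = side,
    position_mb = side * as.numeric(distance_mb),
    cM = cm,
    theta = kosambi_theta(cm)
  ) |>
    dplyr::arrange(.data$position_mb, .data$marker)
}

#' Read a marker map from a tab-separated file
#'
#' Expects a header with columns `marker`, `kind` and either `distance_mb`
#' or `position_mb` (signed, relative to the locus) or `position_mb` plus a
#' separate `locus_mb`. An optional `cM` column supplies an authoritative
#' genetic map; an optional `side` column gives the side flag.
#'
#' @param path Path to a TSV file ('.' decimal separator, UTF-8).
#' @inheritParams marker_map
#' @param locus_mb Physical position of the disease locus, used when the
#'   file carries absolute `position_mb` coordinates.
#' @return A marker-map tibble (see [marker_map()]).
#' @export
read_marker_map <- function(path, cm_per_mb = 1.64, locus_mb = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"marker" %in% names(raw)) {
    abort(sprintf("Marker map '%s' must have a 'marker' column.", path))
  }
  if ("distance_mb" %in% names(raw)) {
    dist <- raw$distance_mb
    side <- if ("side" %in% names(raw)) raw$side else 1L
  } else if ("position_mb" %in% names(raw)) {
    pos <- raw$position_mb - (locus_mb %||% 0)
    dist <- abs(pos)
    side <- ifelse(pos < 0, -1L, 1L)
  } else {
    abort(sprintf("Marker map '%s' needs 'distance_mb' or 'position_mb'.", path))
  }
  marker_map(
    marker = raw$marker,
    distance_mb = dist,
    kind = if ("kind" %in% names(raw)) raw$kind else "microsatellite",
    side = side,
    cM = if ("cM" %in% names(raw)) raw$cM else NULL,
    cm_per_mb = cm_per_mb
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
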