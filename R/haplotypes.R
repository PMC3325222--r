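#' Construct a panel of phased chromosomes
#'
#' A chromosome panel is a tibble with one row per phased chromosome
#' (haplotype): an `id` column (chromosome identifier, e.g. the
#' family.generation.individual.allele convention), a `group` column
#' (`"disease"` for mutation-carrying chromosomes, `"control"` otherwise)
#' and one column per marker holding an allele label. Allele labels are
#' opaque (microsatellite alleles are the usual integer bin labels, with no
#' repeat-length semantics assumed); `NA` marks a missing call.
#'
#' @param alleles A data frame or matrix of allele labels, one row per
#'   chromosome, one column per marker (column names = marker names).
#' @param id Chromosome identifiers (default `hap1 ... hapN`).
#' @param group `"disease"` or `"control"` (recycled).
#' @param markers Optional marker-map tibble ([marker_map()]); when given,
#'   columns are checked against it and reordered to map order.
#' @return A tibble with columns `id`, `group`, then one column per marker.
#' @export
haplotype_panel <- function(alleles, id = NULL, group = "disease",
                            markers = NULL) {
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  if (!is.null(markers)) {
    missing_cols <- setdiff(markers$marker, names(alleles))
    if (length(missing_cols)) {
      abort(sprintf("Panel lacks marker column(s): %s.",
                    paste(missing_cols, collapse = ", ")))
    }
    alleles <- alleles[, markers$marker, drop = FALSE]
  }
  n <- nrow(alleles)
  id <- id %||% paste0("hap", seq_len(n))
  group <- rep_len(as.character(group), n)
  if (!all(group %in% c("disease", "control"))) {
    abort("`group` must be 'disease' or 'control'.")
  }
  out <- tibble::as_tibble(lapply(alleles, as.character))
  dplyr::bind_cols(tibble::tibble(id = as.character(id), group = group), out)
}

panel_markers <- function(panel) setdiff(names(panel), c("id", "group"))

panel_matrix <- function(panel, markers = NULL) {
  cols <- markers %||% panel_markers(panel)
  m <- as.matrix(as.data.frame(panel)[, cols, drop = FALSE])
  rownames(m) <- panel$id
  m
}

#' Read and write phased haplotype tables
#'
#' The on-disk format is a TSV with `id` and `group` columns followed by
#' one column per marker, one row per chromosome — the same layout the
#' simulator emits.
#'
#' @param path Path to a TSV file.
#' @param markers Optional marker map used to check and order columns.
#' @param panel A haplotype panel tibble.
#' @return `read_haplotypes()`: a panel tibble. `write_haplotypes()`: the
#'   panel, invisibly.
#' @export
read_haplotypes <- function(path, markers = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("id", "group") %in% names(raw))) {
    abort(sprintf("Haplotype table '%s' must have 'id' and 'group' columns.",
                  path))
  }
  haplotype_panel(raw[setdiff(names(raw), c("id", "group"))],
                  id = raw$id, group = raw$group, markers = markers)
}

#' @rdname read_haplotypes
#' @export
write_haplotypes <- function(panel, path) {
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(panel)
}

#' Read phased SNP genotypes from a VCF file
#'
#' Convenience importer for phased SNP records: each sample contributes two
#' chromosomes (`<sample>.A`, `<sample>.B`). Only records whose GT field is
#' phased ("|") are accepted; sites listed in the marker map but absent
#' from the VCF become missing calls. Physical coordinates in the marker
#' map, not the VCF, remain authoritative for distances.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param markers Marker map whose `marker` names match VCF ID fields.
#' @param group Panel group for all imported chromosomes.
#' @return A haplotype panel tibble.
#' @export
read_snp_vcf <- function(path, markers, group = "control") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF input requires the 'vcfR' package.")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcfR::getID(vcf)
  samples <- colnames(gt)
  hap <- matrix(NA_character_, nrow = 2L * length(samples),
                ncol = length(markers$marker),
                dimnames = list(NULL, markers$marker))
  keep <- ids %in% markers$marker
  for (j in which(keep)) {
    calls <- gt[j, ]
    phased <- grepl("|", calls, fixed = TRUE)
    parts <- strsplit(ifelse(phased, calls, NA_character_), "|", fixed = TRUE)
    a <- vapply(parts, function(p) p[1] %||% NA_character_, character(1))
    b <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                character(1))
    hap[seq(1, by = 2, length.out = length(samples)), ids[j]] <- a
    hap[seq(2, by = 2, length.out = length(samples)), ids[j]] <- b
  }
  haplotype_panel(hap,
                  id = as.vector(rbind(paste0(samples, ".A"),
                                       paste0(samples, ".B"))),
                  group = group, markers = markers)
}

# ---- trio phasing ---------------------------------------------------------

#' Deterministic Mendelian phasing of a trio
#'
#' Assigns the child's alleles to paternal and maternal haplotypes wherever
#' transmission is unambiguous (a homozygous parent, a homozygous child, or
#' an allele carried by only one parent). Markers where both assignments
#' are Mendelian-consistent are flagged unresolved — never guessed — which
#' is the deterministic core of what statistical phasing software resolves
#' probabilistically.
#'
#' @param trio A tibble with columns `marker`, `child_1`, `child_2`,
#'   `father_1`, `father_2`, `mother_1`, `mother_2` (allele labels, `NA`
#'   for missing). See [trio_genotypes()].
#' @return A tibble with columns `marker`, `paternal`, `maternal`,
#'   `resolved` (logical) and `note` (`"resolved"`, `"ambiguous"`, or
#'   `"missing"`).
#' @export
#' @examples
#' trio <- trio_genotypes(
#'   marker = c("m1", "m2"),
#'   child  = list(c("1", "2"), c("1", "2")),
#'   father = list(c("1", "1"), c("1", "2")),
#'   mother = list(c("2", "2"), c("1", "2"))
#' )
#' trio_phase(trio)   # m1 forced, m2 ambiguous
trio_phase <- function(trio) {
  need <- c("marker", "child_1", "child_2", "father_1", "father_2",
            "mother_1", "mother_2")
  if (!all(need %in% names(trio))) {
    abort(sprintf("`trio` must have columns: %s.", paste(need, collapse = ", ")))
  }
  purrr::pmap_dfr(trio[need], function(marker, child_1, child_2,
                                       father_1, father_2,
                                       mother_1, mother_2) {
    phase_one_marker(marker, c(child_1, child_2), c(father_1, father_2),
                     c(mother_1, mother_2))
  })
}

#' Assemble trio genotypes
#'
#' @param marker Marker names.
#' @param child,father,mother Lists of length-2 character vectors (the
#'   unordered allele pair of each individual at each marker; `NA`s allowed).
#' @return A trio-genotype tibble suitable for [trio_phase()].
#' @export
trio_genotypes <- function(marker, child, father, mother) {
  as_pair <- function(x, who) {
    m <- do.call(rbind, lapply(x, function(g) {
      g <- as.character(g)
      if (length(g) != 2L) {
        abort(sprintf("Each %s genotype must be an allele pair.", who))
      }
      g
    }))
    m
  }
  cg <- as_pair(child, "child"); fg <- as_pair(father, "father")
  mg <- as_pair(mother, "mother")
  tibble::tibble(
    marker = as.character(marker),
    child_1 = cg[, 1], child_2 = cg[, 2],
    father_1 = fg[, 1], father_2 = fg[, 2],
    mother_1 = mg[, 1], mother_2 = mg[, 2]
  )
}

phase_one_marker <- function(marker, child, father, mother) {
  out <- function(pat, mat, resolved, note) {
    tibble::tibble(marker = marker, paternal = pat, maternal = mat,
                   resolved = resolved, note = note)
  }
  if (anyNA(child)) {
    return(out(NA_character_, NA_character_, FALSE, "missing"))
  }
  # candidate ordered (paternal, maternal) assignments of the child pair
  cand <- unique(list(child, rev(child)))
  ok <- purrr::keep(cand, function(pm) {
    pat_ok <- anyNA(father) || pm[1] %in% father
    mat_ok <- anyNA(mother) || pm[2] %in% mother
    pat_ok && mat_ok
  })
  if (length(ok) == 0L) {
    bad_side <- if (!anyNA(father) && !any(child %in% father)) "father" else "mother"
    abort(
      sprintf("Mendelian inconsistency at marker '%s' (%s incompatible with child).",
              marker, bad_side),
      class = "founderage_mendel_error"
    )
  }
  assignments <- unique(lapply(ok, identity))
  if (length(assignments) == 1L) {
    out(assignments[[1]][1], assignments[[1]][2], TRUE, "resolved")
  } else {
    out(NA_character_, NA_character_, FALSE, "ambiguous")
  }
}

#' Infer the disease haplotypes of an unsampled affected individual
#'
#' When the affected individual could not be genotyped, the two disease
#' chromosomes can be partially reconstructed from the parents and a
#' genotyped non-affected sibling: the sibling's trio is phased by
#' Mendelian logic, and at markers where a parent is heterozygous the
#' affected individual is assumed to have received the parental haplotype
#' complementary to the one transmitted to the mutation-negative sibling
#' (elimination, valid in the absence of recombination between marker and
#' locus in these two meioses). Homozygous parental markers are copied
#' directly; everything else is flagged unresolved rather than guessed.
#'
#' @param sibling_trio Trio genotypes ([trio_genotypes()]) with the
#'   non-affected sibling in the child role.
#' @param complement Logical flags `c(paternal = , maternal = )`: on which
#'   sides the sibling is known to carry the mutation-negative parental
#'   haplotype (default both).
#' @return A tibble with columns `marker`, `paternal`, `maternal`,
#'   `paternal_resolved`, `maternal_resolved`.
#' @export
infer_unsampled_haplotypes <- function(sibling_trio,
                                       complement = c(paternal = TRUE,
                                                      maternal = TRUE)) {
  phased <- trio_phase(sibling_trio)
  res <- dplyr::left_join(sibling_trio, phased, by = "marker")
  one_side <- function(par1, par2, transmitted, resolved, flip) {
    parent <- c(par1, par2)
    if (anyNA(parent)) {
      return(c(NA_character_, FALSE))
    }
    if (par1 == par2) {
      return(c(par1, TRUE))           # homozygous parent: side is forced
    }
    if (!resolved || is.na(transmitted)) {
      return(c(NA_character_, FALSE))
    }
    if (flip) {
      c(setdiff(parent, transmitted)[1], TRUE)
    } else {
      c(transmitted, TRUE)
    }
  }
  rows <- purrr::pmap(res, function(...) {
    r <- list(...)
    p <- one_side(r$father_1, r$father_2, r$paternal, r$resolved,
                  complement[["paternal"]])
    m <- one_side(r$mother_1, r$mother_2, r$maternal, r$resolved,
                  complement[["maternal"]])
    tibble::tibble(marker = r$marker,
                   paternal = p[1], maternal = m[1],
                   paternal_resolved = as.logical(p[2]),
                   maternal_resolved = as.logical(m[2]))
  })
  dplyr::bind_rows(rows)
}

# ---- conserved region -----------------------------------------------------

#' Detect the conserved ancestral region around the disease locus
#'
#' Scans outward from the disease locus for the maximal run of consecutive
#' markers at which all disease chromosomes carry the identical allele —
#' the footprint of the founder haplotype not yet broken up by
#' recombination. Markers with missing calls still extend the region when
#' all non-missing calls agree, but are flagged `partial_support`.
#'
#' @param disease A haplotype panel of disease chromosomes (at least 2).
#' @param markers Marker map covering the panel's marker columns.
#' @return An object of class `conserved_region`: a list with `region` (a
#'   tibble of the conserved markers with `marker`, `allele`,
#'   `position_mb`, `cM`, `partial_support`), `length_cm` (genetic span),
#'   `n_haplotypes`, and the `panel` scanned. An empty `region` means only
#'   the locus itself is shared.
#' @export
conserved_region <- function(disease, markers) {
  disease <- disease[disease$group == "disease", , drop = FALSE]
  if (nrow(disease) < 2L) {
    abort("Conserved-region detection needs at least 2 disease haplotypes.")
  }
  mm <- dplyr::arrange(markers, .data$position_mb)
  mat <- panel_matrix(disease, mm$marker)
  share <- apply(mat, 2, function(a) {
    a <- a[!is.na(a)]
    if (length(a) == 0L) return(c(NA, NA))
    c(if (length(unique(a)) == 1L) a[1] else NA, length(a))
  })
  shared_allele <- share[1, ]
  n_called <- as.integer(share[2, ])
  is_shared <- !is.na(shared_allele)
  # grow outward from the locus (position 0): left = position < 0 scanned
  # inward-out, right = position >= 0 likewise
  left_idx <- rev(which(mm$position_mb < 0))
  right_idx <- which(mm$position_mb >= 0)
  run <- function(idx) idx[cumall(is_shared[idx])]
  keep <- sort(c(run(left_idx), run(right_idx)))
  region <- tibble::tibble(
    marker = mm$marker[keep],
    allele = unname(shared_allele[keep]),
    position_mb = mm$position_mb[keep],
    cM = mm$cM[keep],
    side = mm$side[keep],
    partial_support = n_called[keep] < nrow(disease)
  )
  length_cm <- if (nrow(region) == 0L) 0 else {
    max(c(0, region$cM[region$side > 0])) + max(c(0, region$cM[region$side < 0]))
  }
  structure(
    list(region = region, length_cm = length_cm,
         n_haplotypes = nrow(disease), markers = mm, panel = disease),
    class = "conserved_region"
  )
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

#' @export
print.conserved_region <- function(x, ...) {
  cat(sprintf("Conserved ancestral region: %d marker(s), %.2f cM, %d disease chromosomes\n",
              nrow(x$region), x$length_cm, x$n_haplotypes))
  if (nrow(x$region)) print(x$region)
  invisible(x)
}

# ---- allele and haplotype frequencies -------------------------------------

#' Allele frequencies at one marker
#'
#' Frequencies are computed over non-missing calls only and sum to one.
#'
#' @param panel A haplotype panel.
#' @param marker Marker name (a panel column).
#' @return A tibble with columns `allele`, `count`, `freq`, sorted by
#'   decreasing frequency then allele label.
#' @export
allele_frequency <- function(panel, marker) {
  if (!marker %in% names(panel)) {
    abort(sprintf("Marker '%s' is not in the panel.", marker))
  }
  a <- panel[[marker]]
  a <- a[!is.na(a)]
  if (length(a) == 0L) {
    abort(sprintf("All calls missing at marker '%s'.", marker))
  }
  tab <- sort(table(a), decreasing = TRUE)
  tibble::tibble(
    allele = names(tab),
    count = as.integer(tab),
    freq = as.numeric(tab) / length(a)
  ) |>
    dplyr::arrange(dplyr::desc(.data$freq), allele_order(.data$allele))
}

# numeric-aware ordering of opaque allele labels (ties broken numerically
# when labels are integer bins, lexicographically otherwise)
allele_order <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (anyNA(num)) rank(x) else rank(num)
}

#' Founder-allele call at one marker
#'
#' Outside the conserved region the founder (ancestral) allele is taken to
#' be the most frequent allele among disease chromosomes; inside it, the
#' shared allele. Ties are broken deterministically toward the smallest
#' allele label, with a warning, and flagged ambiguous.
#'
#' @param panel A haplotype panel (disease rows are used).
#' @param marker Marker name.
#' @return A one-row tibble: `marker`, `allele`, `p_d` (frequency among
#'   non-missing disease calls), `n_called`, `ambiguous`.
#' @export
founder_allele <- function(panel, marker) {
  disease <- panel[panel$group == "disease", , drop = FALSE]
  freq <- allele_frequency(disease, marker)
  top <- freq[freq$freq == max(freq$freq), , drop = FALSE]
  ambiguous <- nrow(top) > 1L
  pick <- top$allele[order(allele_order(top$allele))][1]
  if (ambiguous) {
    warn(sprintf(
      "Modal founder allele tie at marker '%s' (%s); taking smallest label '%s'.",
      marker, paste(top$allele, collapse = ", "), pick))
  }
  tibble::tibble(
    marker = marker,
    allele = pick,
    p_d = top$freq[top$allele == pick],
    n_called = sum(freq$count),
    ambiguous = ambiguous
  )
}

#' Founder alleles and disease/control frequencies across a panel
#'
#' Applies [founder_allele()] at every marker of the map and looks the
#' chosen allele up in the control panel, yielding the per-marker inputs
#' (`p_d`, `p_n`, `theta`) the age estimators consume.
#'
#' @param disease,control Haplotype panels.
#' @param markers Marker map.
#' @return A tibble with one row per marker: `marker`, `distance_mb`,
#'   `cM`, `theta`, `allele`, `p_d`, `p_n`, `n_disease`, `ambiguous`.
#' @export
founder_allele_table <- function(disease, control, markers) {
  purrr::map_dfr(markers$marker, function(m) {
    fa <- founder_allele(disease, m)
    ctrl <- tryCatch(allele_frequency(control, m), error = function(e) NULL)
    p_n <- if (is.null(ctrl)) NA_real_ else {
      hit <- ctrl$freq[ctrl$allele == fa$allele]
      if (length(hit)) hit else 0
    }
    row <- markers[markers$marker == m, ]
    tibble::tibble(
      marker = m, distance_mb = row$distance_mb, cM = row$cM,
      theta = row$theta, allele = fa$allele, p_d = fa$p_d, p_n = p_n,
      n_disease = fa$n_called, ambiguous = fa$ambiguous
    )
  })
}

#' Frequency of a haplotype in a control panel
#'
#' Exact-match frequency of an allele vector over a marker interval among
#' control chromosomes; a missing call in a control chromosome counts as a
#' mismatch (the chromosome cannot be shown to carry the haplotype).
#'
#' @param haplotype Named character vector (names = markers) or a
#'   single-row panel slice giving the allele at each interval marker.
#' @param control A haplotype panel.
#' @return Matching fraction in `[0, 1]`.
#' @export
haplotype_frequency <- function(haplotype, control) {
  if (is.data.frame(haplotype)) {
    haplotype <- unlist(haplotype[1, setdiff(names(haplotype), c("id", "group"))])
  }
  mk <- names(haplotype)
  if (length(mk) == 0L) {
    abort("Empty marker interval.")
  }
  if (!all(mk %in% names(control))) {
    abort("Interval markers missing from the control panel.")
  }
  if (nrow(control) == 0L) {
    abort("Control panel is empty.")
  }
  mat <- panel_matrix(control, mk)
  hits <- apply(mat, 1, function(row) all(!is.na(row) & row == haplotype))
  mean(hits)
}
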