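# Small fixture builders shared across test files.

# marker map with the study's distance geometry on one side of the locus
fixture_map <- function() {
  marker_map(
    marker = c("D14S275", "D14S742", "D14S72", "D14S1043", "D14S1042", "D14S1060"),
    distance_mb = c(1.98, 2.52, 3.32, 3.34, 4.54, 8.7)
  )
}

# a tiny two-sided map for conserved-region scans
two_sided_map <- function(n_side = 4) {
  d <- seq(0.5, by = 0.5, length.out = n_side)
  marker_map(
    marker = c(paste0("L", n_side:1), paste0("R", 1:n_side)),
    distance_mb = c(rev(d), d),
    side = rep(c(-1L, 1L), each = n_side)
  )
}

# build a disease panel from a matrix of allele labels over a map
panel_from_rows <- function(rows, markers, group = "disease") {
  m <- do.call(rbind, lapply(rows, as.character))
  colnames(m) <- markers$marker
  haplotype_panel(m, group = group, markers = markers)
}

# brute-force conserved-region oracle: test every contiguous interval that
# contains the locus (position 0 boundary) for full allele sharing, return
# the widest
oracle_conserved <- function(panel, markers) {
  mm <- markers[order(markers$position_mb), ]
  mat <- as.matrix(as.data.frame(panel)[, mm$marker, drop = FALSE])
  shared <- vapply(seq_len(ncol(mat)), function(j) {
    a <- mat[, j][!is.na(mat[, j])]
    length(a) > 0 && length(unique(a)) == 1
  }, logical(1))
  best <- integer(0)
  for (i in seq_len(ncol(mat))) {
    for (j in i:ncol(mat)) {
      idx <- i:j
      # interval must touch the locus: no skipped marker between it and 0
      left_ok <- all(mm$position_mb[seq_len(i - 1)] < 0)
      right_ok <- all(mm$position_mb[setdiff(seq_len(ncol(mat)), seq_len(j))] > 0)
      if (left_ok && right_ok && all(shared[idx]) && length(idx) > length(best)) {
        best <- idx
      }
    }
  }
  mm$marker[best]
}
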