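test_that("trio phasing resolves forced transmissions and flags ambiguity", {
  trio <- trio_genotypes(
    marker = c("m1", "m2", "m3", "m4"),
    child  = list(c(1, 2), c(1, 1), c(1, 2), c(NA, NA)),
    father = list(c(1, 1), c(1, 2), c(1, 2), c(1, 2)),
    mother = list(c(2, 2), c(1, 2), c(1, 2), c(1, 2))
  )
  ph <- trio_phase(trio)
  expect_equal(ph$paternal[1], "1")      # forced by homozygous parents
  expect_equal(ph$maternal[1], "2")
  expect_equal(ph$paternal[2], "1")      # homozygous child
  expect_equal(ph$maternal[2], "1")
  expect_false(ph$resolved[3])           # all three heterozygous: ambiguous
  expect_equal(ph$note[3], "ambiguous")
  expect_equal(ph$note[4], "missing")
})

test_that("trio phasing resolves alleles carried by only one parent", {
  trio <- trio_genotypes("m", child = list(c(1, 3)),
                         father = list(c(1, 2)), mother = list(c(3, 4)))
  ph <- trio_phase(trio)
  expect_true(ph$resolved)
  expect_equal(ph$paternal, "1")
  expect_equal(ph$maternal, "3")
})

test_that("Mendelian inconsistency errors name the marker and member", {
  trio <- trio_genotypes("m7", child = list(c(1, 2)),
                         father = list(c(3, 3)), mother = list(c(1, 2)))
  expect_error(trio_phase(trio), "m7", class = "founderage_mendel_error")
  expect_error(trio_phase(trio), "father")
})

test_that("phasing never invents alleles and resolves all forced markers", {
  set.seed(41)
  for (rep in 1:25) {
    n <- 12
    fa <- replicate(n, sample(1:4, 2, replace = TRUE), simplify = FALSE)
    mo <- replicate(n, sample(1:4, 2, replace = TRUE), simplify = FALSE)
    ch <- purrr::map2(fa, mo, function(f, m) c(sample(f, 1), sample(m, 1)))
    trio <- trio_genotypes(paste0("m", 1:n), ch, fa, mo)
    ph <- trio_phase(trio)
    for (i in seq_len(n)) {
      if (ph$resolved[i]) {
        expect_setequal(c(ph$paternal[i], ph$maternal[i]), as.character(ch[[i]]))
        expect_true(ph$paternal[i] %in% as.character(fa[[i]]))
        expect_true(ph$maternal[i] %in% as.character(mo[[i]]))
      }
    }
    both_hom <- purrr::map2_lgl(fa, mo, function(f, m) {
      f[1] == f[2] && m[1] == m[2]
    })
    expect_true(all(ph$resolved[both_hom]))
  }
})

test_that("unsampled disease haplotypes are inferred by elimination", {
  # parent het, sibling received the mutation-negative allele: the affected
  # individual carries the other one; homozygous parents are copied
  trio <- trio_genotypes(
    marker = c("m1", "m2", "m3"),
    child  = list(c(2, 2), c(1, 1), c(1, 2)),
    father = list(c(1, 2), c(1, 1), c(1, 2)),
    mother = list(c(2, 3), c(1, 2), c(1, 2))
  )
  inf <- infer_unsampled_haplotypes(trio)
  expect_equal(inf$paternal[1], "1")     # sibling got 2 from father
  expect_equal(inf$maternal[1], "3")     # sibling got 2 from mother
  expect_equal(inf$paternal[2], "1")     # homozygous father forced
  expect_false(inf$maternal_resolved[3]) # ambiguous transmission
  bad <- trio_genotypes("m1", child = list(c(4, 4)),
                        father = list(c(1, 2)), mother = list(c(1, 2)))
  expect_error(infer_unsampled_haplotypes(bad),
               class = "founderage_mendel_error")
})

test_that("conserved region equals the brute-force interval scan", {
  mm <- two_sided_map(4)
  # shared at L2..R3, discordant at L4, L3 and R4
  anc <- rep("5", 8)
  h1 <- anc
  h2 <- anc; h2[1] <- "1"; h2[2] <- "2"; h2[8] <- "9"
  h3 <- anc; h3[2] <- "3"; h3[8] <- "7"
  panel <- panel_from_rows(list(h1, h2, h3), mm)
  cr <- conserved_region(panel, mm)
  expect_equal(cr$region$marker, oracle_conserved(panel, mm))
  expect_equal(cr$region$marker, c("L2", "L1", "R1", "R2", "R3"))
  expect_equal(unique(cr$region$allele), "5")
  # genetic length spans from L2 to R3
  expect_equal(cr$length_cm, 1.0 * 1.64 + 1.5 * 1.64)
})

test_that("conserved region handles the trivial extremes", {
  mm <- two_sided_map(2)
  same <- panel_from_rows(list(rep("1", 4), rep("1", 4)), mm)
  expect_equal(nrow(conserved_region(same, mm)$region), 4)
  diff_all <- panel_from_rows(list(c("1", "1", "1", "1"),
                                   c("2", "2", "2", "2")), mm)
  cr <- conserved_region(diff_all, mm)
  expect_equal(nrow(cr$region), 0)
  expect_equal(cr$length_cm, 0)
  expect_error(conserved_region(panel_from_rows(list(rep("1", 4)), mm), mm),
               "at least 2")
})

test_that("conserved region matches the oracle on random panels and never shrinks when haplotypes are dropped", {
  set.seed(99)
  mm <- two_sided_map(5)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    anc <- as.character(sample(1:4, 10, replace = TRUE))
    rows <- lapply(seq_len(n), function(i) {
      h <- anc
      k <- sample(0:6, 1)
      if (k > 0) {
        idx <- sample(10, k)
        h[idx] <- as.character(sample(5:9, k, replace = TRUE))
      }
      h
    })
    panel <- panel_from_rows(rows, mm)
    cr <- conserved_region(panel, mm)
    expect_equal(cr$region$marker, oracle_conserved(panel, mm))
    sub <- panel[seq_len(n - 1), , drop = FALSE]
    if (nrow(sub) >= 2) {
      cr_sub <- conserved_region(sub, mm)
      expect_true(all(cr$region$marker %in% cr_sub$region$marker))
    }
  }
})

test_that("markers with missing calls extend the region with partial support", {
  mm <- two_sided_map(2)
  panel <- panel_from_rows(list(c("1", "2", "3", NA), c("1", "2", "3", "4"),
                                c(NA, "2", "3", "4")), mm)
  cr <- conserved_region(panel, mm)
  expect_equal(cr$region$marker, c("L2", "L1", "R1", "R2"))
  expect_equal(cr$region$partial_support, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("allele frequencies are computed over non-missing calls and sum to 1", {
  mm <- two_sided_map(1)
  panel <- panel_from_rows(
    list(c("5", "1"), c("5", "2"), c("2", NA), c("5", "1"), c("2", "1")), mm,
    group = "control")
  f <- allele_frequency(panel, "L1")
  expect_equal(sum(f$freq), 1, tolerance = 1e-12)
  expect_equal(f$freq[f$allele == "5"], 0.6)
  f2 <- allele_frequency(panel, "R1")
  expect_equal(sum(f2$freq), 1, tolerance = 1e-12)
  expect_equal(f2$freq[f2$allele == "1"], 0.75)
  one <- panel_from_rows(list(c("7", "7")), mm, group = "control")
  expect_equal(allele_frequency(one, "L1")$freq, 1)
  empty <- panel_from_rows(list(c(NA, NA)), mm, group = "control")
  expect_error(allele_frequency(empty, "L1"), "missing")
})

test_that("frequencies are invariant to haplotype order", {
  mm <- two_sided_map(1)
  rows <- list(c("1", "2"), c("2", "2"), c("1", "3"), c("1", "2"))
  p1 <- panel_from_rows(rows, mm)
  p2 <- panel_from_rows(rev(rows), mm)
  expect_equal(allele_frequency(p1, "L1"), allele_frequency(p2, "L1"))
})

test_that("founder allele is the disease-chromosome mode with deterministic tie-break", {
  mm <- two_sided_map(1)
  panel <- panel_from_rows(list(c("5", "1"), c("5", "1"), c("5", "1"),
                                c("2", "1"), c("5", "1")), mm)
  fa <- founder_allele(panel, "L1")
  expect_equal(fa$allele, "5")
  expect_equal(fa$p_d, 0.8)
  tied <- panel_from_rows(list(c("5", "1"), c("5", "1"), c("2", "1"),
                               c("2", "1")), mm)
  expect_warning(fa2 <- founder_allele(tied, "L1"), "tie")
  expect_equal(fa2$allele, "2")           # smallest label wins
  expect_true(fa2$ambiguous)
})

test_that("haplotype frequency is the exact-match fraction with missing as mismatch", {
  mm <- two_sided_map(2)
  target <- c(L2 = "1", L1 = "2")
  ctrl_rows <- c(replicate(4, c("1", "2", "9", "9"), simplify = FALSE),
                 replicate(195, c("3", "4", "9", "9"), simplify = FALSE),
                 list(c(NA, "2", "9", "9")))
  ctrl <- panel_from_rows(ctrl_rows, mm, group = "control")
  expect_equal(haplotype_frequency(target, ctrl), 4 / 200)
  expect_equal(haplotype_frequency(c(L2 = "7", L1 = "7"), ctrl), 0)
  copies <- panel_from_rows(replicate(10, c("1", "2", "9", "9"),
                                      simplify = FALSE), mm, group = "control")
  expect_equal(haplotype_frequency(target, copies), 1)
  expect_error(haplotype_frequency(character(0), ctrl), "Empty")
})

test_that("haplotype panels round-trip through TSV", {
  mm <- two_sided_map(2)
  panel <- panel_from_rows(list(c("1", "2", NA, "4"), c("1", "2", "3", "4")), mm)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes(panel, path)
  back <- read_haplotypes(path, markers = mm)
  expect_equal(as.data.frame(back), as.data.frame(panel))
})
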