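test_that("excess founder-allele frequency follows (p_d - p_n)/(1 - p_n)", {
  expect_equal(p_excess(1, 0.2), 1)
  expect_equal(p_excess(0.5, 0.5), 0)
  expect_equal(p_excess(0.8, 0.16), 0.64 / 0.84)
  expect_lt(p_excess(0.25, 0.4), 0)
  expect_error(p_excess(0.5, 1), class = "founderage_domain_error")
})

test_that("decay inversion identity holds for both moment estimators", {
  for (g in c(1, 5, 25, 80, 200)) {
    for (theta in c(0.001, 0.01, 0.05, 0.15, 0.3)) {
      q <- (1 - theta)^g
      expect_equal(risch_g(q, theta), g, tolerance = 1e-9)
      expect_equal(bergman_g(q, 0, theta), g, tolerance = 1e-9)
      expect_equal(bergman_g(q, 0, theta, variant = "excess"),
                   g, tolerance = 1e-9)
    }
  }
  # excess variant with a non-zero control frequency chosen so delta = Q
  q <- (1 - 0.05)^25
  expect_equal(bergman_g(0.9, (0.9 - q) / (1 - q), 0.05, variant = "excess"),
               25, tolerance = 1e-6)
  expect_equal(risch_g(1, 0.2), 0)        # no decay observed
  expect_equal(bergman_g(1, 0.3, 0.2), 0)
})

test_that("non-informative inputs yield NA, not errors", {
  expect_true(is.na(risch_g(-0.1, 0.05)))
  expect_true(is.na(risch_g(0, 0.05)))
  expect_true(is.na(bergman_g(0.16, 0.25, 0.05)))   # not enriched in disease
  expect_error(risch_g(0.5, 0), class = "founderage_domain_error")
  expect_error(risch_g(0.5, 0.5), class = "founderage_domain_error")
})

test_that("closed-form decay matches a Bernoulli retention simulation", {
  # a lineage retains the ancestral allele after g generations iff no
  # recombination occurred in any generation: Q = (1 - theta)^g
  withr::with_seed(7, {
    theta <- 0.054234
    g <- 12
    n <- 2e5
    retained <- rbinom(n, size = 1, prob = (1 - theta)^g)
    delta_hat <- mean(retained)
    expect_equal(risch_g(delta_hat, theta), g, tolerance = 0.02)
  })
})

test_that("growth correction is identity at p = 0 and inflates ages for p > 0", {
  theta <- kosambi_theta(mb_to_cm(1.98))
  expect_identical(labuda_correct(20, theta, growth_rate = 0), 20)
  corrected <- labuda_correct(20, theta, growth_rate = 0.107)
  expect_gt(corrected, 20)
  expect_true(is.na(labuda_correct(NA_real_, theta, growth_rate = 0.107)))
  expect_identical(labuda_correct(0, theta, growth_rate = 0.107), 0)
  expect_error(labuda_correct(20, theta, growth_rate = -1),
               class = "founderage_domain_error")
})

test_that("growth correction exceeds the uncorrected estimate across the input grid", {
  for (theta in c(0.01, 0.03, 0.07, 0.14)) {
    for (g in c(2, 7, 20, 50)) {
      for (p in c(0.02, 0.107, 0.5)) {
        expect_gt(labuda_correct(g, theta, p), g)
      }
    }
  }
})

test_that("growth correction is self-consistent with its genealogy model", {
  # simulate lineage lengths L = G - T with T ~ truncated Exp(p), compute
  # the naive moment estimate from mean retention, and check the
  # correction recovers the true age
  withr::with_seed(11, {
    G <- 40; p <- 0.107; theta <- 0.05
    u <- runif(2e5)
    T <- -log(1 - u * (1 - exp(-p * G))) / p
    L <- G - T
    q_hat <- mean((1 - theta)^L)
    g_naive <- log(q_hat) / log(1 - theta)
    expect_lt(g_naive, G)
    expect_equal(labuda_correct(g_naive, theta, p), G, tolerance = 0.02)
  })
})

test_that("pluggable correction contract is honoured", {
  doubling <- function(g, theta, p) 2 * g
  expect_equal(labuda_correct(15, 0.05, 0.107, correction = doubling), 30)
})

test_that("informativeness filter excludes unenriched and redundant markers", {
  d <- tibble::tibble(
    marker = c("near", "mid", "dup", "far"),
    distance_mb = c(1, 2, 3, 4),
    p_d = c(0.8, 0.6, 0.6, 0.2),
    p_n = c(0.2, 0.2, 0.2, 0.4),
    theta = kosambi_theta(mb_to_cm(c(1, 2, 3, 4)))
  )
  ri <- informativeness_filter(d, "risch")
  expect_equal(ri$included, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ri$reason[3], "no_added_recombination_information")
  expect_equal(ri$reason[4], "allele_not_enriched_in_disease")
  be <- informativeness_filter(d, "bergman")
  expect_equal(be$included, c(TRUE, TRUE, TRUE, FALSE))
  all_ok <- informativeness_filter(d[1:2, ], "risch")
  expect_true(all(all_ok$included))
})

test_that("explicit per-marker overrides force exclusion with a recorded reason", {
  d <- tibble::tibble(
    marker = c("a", "b"), distance_mb = c(1, 2),
    p_d = c(0.8, 0.25), p_n = c(0.2, 0.16),
    theta = c(0.02, 0.05)
  )
  # numerically informative (0.25 > 0.16) but excludable by study decision
  be <- informativeness_filter(d, "bergman",
                               overrides = "b:bergman:study_exclusion")
  expect_false(be$included[be$marker == "b"])
  expect_match(be$reason[be$marker == "b"], "override:study_exclusion")
  ri <- informativeness_filter(d, "risch",
                               overrides = "b:bergman:study_exclusion")
  expect_true(ri$included[ri$marker == "b"])   # override is estimator-scoped
})

test_that("markers inside the conserved region are excluded from estimation", {
  d <- tibble::tibble(marker = c("in", "out"), distance_mb = c(0, 2),
                      p_d = c(1, 0.7), p_n = c(0.1, 0.2),
                      theta = c(0, 0.03))
  est <- estimate_marker_ages(d, growth_rate = 0.107)
  expect_equal(est$risch_reason[est$marker == "in"], "inside_conserved_region")
  expect_true(is.na(est$risch_g[est$marker == "in"]))
  expect_false(is.na(est$risch_g[est$marker == "out"]))
  expect_gt(est$labuda_g[est$marker == "out"], est$risch_g[est$marker == "out"])
})

test_that("across-marker averaging reproduces published summary cells", {
  # published per-marker values, proportion estimator: mean 34.6 -> 35,
  # CI (17.96, 51.24) -> 18-51
  s <- average_tmrca(c(40, 65, 29, 20, 19))
  expect_equal(s$mean_g, 34.6)
  expect_equal(format(s), "35 (18-51)")
  expect_equal(s$mean_years, 34.6 * 30)
  s2 <- average_tmrca(c(33, 29, 20, 13, 7))
  expect_equal(format(s2), "20 (11-30)")
  s3 <- average_tmrca(c(52, 37, 31, 21, 11))
  expect_equal(format(s3), "30 (17-44)")
})

test_that("a single marker gives a mean but no interval; empty input errors", {
  s <- average_tmrca(42)
  expect_equal(s$mean_g, 42)
  expect_true(is.na(s$se))
  expect_match(format(s), "n=1")
  expect_error(average_tmrca(numeric(0)), "No informative")
  expect_error(average_tmrca(c(NA_real_, NA_real_)), "No informative")
})

test_that("composite likelihood reduces to the moment estimator for one clean marker", {
  mm <- marker_map("m1", 3)
  k <- 12; n <- 20
  alleles <- matrix(c(rep("A", k), rep("B", n - k)), ncol = 1,
                    dimnames = list(NULL, "m1"))
  panel <- haplotype_panel(alleles, group = "disease")
  founder <- tibble::tibble(marker = "m1", allele = "A", theta = mm$theta)
  ctrl <- tibble::tibble(marker = "m1", allele = c("A", "B"), freq = c(0, 1))
  fit <- composite_likelihood_age(panel, founder, ctrl)
  expect_equal(fit$estimate, risch_g(k / n, mm$theta), tolerance = 1e-4)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(tidy(fit)$estimate, fit$estimate)
  expect_true(glance(fit)$n_chromosomes == n)
})

test_that("composite likelihood hits the zero boundary for fully ancestral panels", {
  mm <- marker_map(c("m1", "m2"), c(2, 4))
  alleles <- matrix("A", nrow = 8, ncol = 2,
                    dimnames = list(NULL, mm$marker))
  panel <- haplotype_panel(alleles, group = "disease")
  founder <- tibble::tibble(marker = mm$marker, allele = "A", theta = mm$theta)
  ctrl <- tibble::tibble(marker = rep(mm$marker, each = 2),
                         allele = rep(c("A", "B"), 2),
                         freq = rep(c(0.001, 0.999), 2))
  expect_warning(fit <- composite_likelihood_age(panel, founder, ctrl),
                 "boundary")
  expect_equal(fit$estimate, 0)
  expect_true(fit$boundary)
})

test_that("composite likelihood recovers a known age on a simulated panel", {
  cfg <- founder_sim_config(true_age = 30, n_disease = 80, n_control = 400,
                            seed = 2024)
  ctrl <- simulate_controls(cfg)
  sim <- simulate_founder_panel(cfg)
  founder <- tibble::tibble(
    marker = cfg$markers$marker,
    allele = unname(sim$truth$ancestral[cfg$markers$marker]),
    theta = cfg$markers$theta
  )
  ctrl_freqs <- purrr::map_dfr(cfg$markers$marker, function(m) {
    dplyr::mutate(allele_frequency(ctrl, m), marker = m, .before = 1)
  })
  fit <- composite_likelihood_age(sim$panel, founder, ctrl_freqs)
  expect_gt(fit$estimate, 15)
  expect_lt(fit$estimate, 45)
  expect_true(fit$ci[1] < fit$estimate && fit$estimate < fit$ci[2])
})
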