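test_that("HWE chi-square matches hand-computed values", {
  expect_equal(hwe_test(25, 50, 25), 1)          # exact HWE proportions
  # (30, 40, 30): p = 0.5, expected (25, 50, 25), chi2 = 1 + 2 + 1 = 4
  expect_equal(hwe_test(30, 40, 30), pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(hwe_test(30, 40, 30), 4), 0.0455)
  expect_equal(hwe_test(100, 0, 0), 1)           # monomorphic convention
  expect_error(hwe_test(0, 0, 0), "zero")
  # exact test agrees with chi-square at large balanced counts
  expect_lt(abs(hwe_test(300, 500, 200, method = "exact") -
                  hwe_test(300, 500, 200)), 0.05)
})

test_that("HWE test is calibrated under Hardy-Weinberg sampling", {
  # 10,000 sites x 500 samples at common AFs (chi-square validity range);
  # type-I error at alpha = 0.05 within 3 binomial s.e.
  af <- withr::with_seed(88, runif(10000, 0.1, 0.9))
  g <- simulate_hwe_genotypes(af, 500, seed = 89)
  p <- vapply(seq_len(ncol(g)), function(j)
    hwe_test(sum(g[, j] == 0), sum(g[, j] == 1), sum(g[, j] == 2)),
    numeric(1))
  rej <- mean(p < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("Watterson estimator follows the harmonic-number arithmetic", {
  expect_equal(watterson_theta(0, 50)$theta, 0)
  w <- watterson_theta(11, 4)     # a_4 = 1 + 1/2 + 1/3
  expect_equal(w$a_n, 11 / 6, tolerance = 1e-12)
  expect_equal(w$theta, 6)
  expect_error(watterson_theta(-1, 10), "K")
})

test_that("mutation-rate projection is algebraically exact", {
  z <- sv_mutation_rate(0, 10000)
  expect_equal(z$per_generation, 0)
  expect_equal(z$ci, c(0, 0))
  expect_equal(sv_mutation_rate(4 * 5000, 5000)$mu_haploid, 1)
  expect_error(sv_mutation_rate(10, -1), "Ne")
  r <- sv_mutation_rate(watterson_theta(500, 1000), 10000, seed = 1)
  expect_true(r$ci[1] < r$per_generation & r$per_generation < r$ci[2])
})

test_that("SV share of rare pLoF reproduces the published arithmetic", {
  expect_equal(round(sv_share_of_plof(5.5, 1.3, 16.3, TRUE), 1), 29.4)
  expect_equal(round(sv_share_of_plof(5.5, 1.3, 16.3, FALSE), 1), 25.2)
  expect_equal(sv_share_of_plof(3, 0, 0, FALSE), 100)
  expect_error(sv_share_of_plof(0, 0, 0, FALSE), "denominator")
})

test_that("per-genome burden matches manual enumeration and is additive", {
  gm <- toy_gene_models()
  # 3 samples, 4 SVs: del1 pLoF (rare singleton), dup1 copy_gain,
  # ins1 pLoF common, bnd1 ignored
  ch <- toy_cohort()
  ann <- annotate_cohort(ch, gm)
  b <- per_genome_burden(ch, ann, rare_af = 0.2)
  per <- b$per_sample
  # s1 carries del1 (pLoF geneA) + dup1 (copy_gain); s2 dup1 + ins1 hom;
  # s3 ins1 het
  expect_equal(per$genes_pLoF, c(1, 1, 1))
  expect_equal(per$genes_copy_gain, c(1, 1, 0))
  expect_equal(per$genes_IED, c(0, 0, 0))
  expect_equal(per$genes_total, per$genes_pLoF + per$genes_copy_gain)
  expect_equal(per$n_sv, c(2, 2, 1))
  # del1 af = 1/6 < 0.2 qualifies as rare; ins1 af = 3/6 does not
  expect_equal(per$genes_pLoF_rare, c(1, 0, 0))
  expect_equal(per$genes_pLoF_hom, c(0, 1, 0))

  zero <- per[per$sample_id == "s3", ]
  expect_equal(zero$genes_copy_gain, 0)

  # additivity over disjoint site subsets
  first <- svpopgen:::subset_sites(ch, 1:2)
  rest <- svpopgen:::subset_sites(ch, 3:4)
  b1 <- per_genome_burden(first, annotate_cohort(first, gm), 0.2)
  b2 <- per_genome_burden(rest, annotate_cohort(rest, gm), 0.2)
  expect_equal(b1$per_sample$n_sv + b2$per_sample$n_sv, per$n_sv)
})

test_that("Mendelian logic flags impossible child genotypes", {
  sites <- data.frame(id = c("v1", "v2"), chrom = "chr1",
                      start = c(100L, 300L), end = c(200L, 400L),
                      svtype = "DEL", svlen = 100, filter = "PASS")
  # trio: child consistent at v1 (0/1 from 0/1 x 0/0),
  # violation + de novo candidate at v2 (1/1 from 0/0 x 0/0)
  gt <- rbind(c(1L, 0L), c(0L, 0L), c(1L, 2L))
  samples <- data.frame(
    sample_id = c("fa", "mo", "kid"), population = "EUR", sex = "F",
    father_id = c(NA, NA, "fa"), mother_id = c(NA, NA, "mo"),
    is_unrelated = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  ch <- sv_cohort(sites, gt, samples)
  mc <- mendelian_check(ch)
  expect_equal(mc$per_trio$violation_rate, 0.5)
  expect_equal(mc$per_trio$de_novo_rate, 0)  # 1/1 child is not a de novo het
})

test_that("trio violation rate grows monotonically with genotyping error", {
  rates <- vapply(c(0, 0.05, 0.2), function(e) {
    sim <- simulate_cohort(small_sim(seed = 61, genotyping_error = e))
    mendelian_check(sim$cohort)$median_violation_rate
  }, numeric(1))
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) > 0))
})

test_that("LD R^2 equals the squared dosage correlation", {
  expect_equal(ld_r2(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)), 1)
  # hand covariance: second vector mirrors the first, cov = 0
  expect_equal(ld_r2(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 2, 1, 0)), 0)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_error(ld_r2(1:4, 1:5), "unequal")
})

test_that("size-AF profile is flat without size selection and CIs shrink with n", {
  flat <- data.frame(svlen = exp(runif(2000, 4, 10)), af = 0.25)
  r <- size_af_relationship(flat, seed = 3)
  expect_true(all(abs(r$table$mean_af - 0.25) < 1e-12))
  expect_true(all(r$table$ci_lo <= 0.25 & r$table$ci_hi >= 0.25))

  withr::with_seed(4, {
    small <- data.frame(svlen = exp(runif(500, 4, 10)),
                        af = runif(500, 0, 0.5))
    big <- data.frame(svlen = small$svlen[rep(1:500, 4)],
                      af = sample(small$af, 2000, replace = TRUE))
  })
  rs <- size_af_relationship(small, n_size_bins = 4, seed = 5)
  rb <- size_af_relationship(big, n_size_bins = 4, seed = 6)
  ws <- mean(rs$table$ci_hi - rs$table$ci_lo)
  wb <- mean(rb$table$ci_hi - rb$table$ci_lo)
  # 4x the sites per bin should roughly halve the bootstrap CI width
  expect_equal(ws / wb, 2, tolerance = 0.35)
})

test_that("larger SVs are rarer when selection strength grows with size", {
  cfg <- small_sim(seed = 71, size_selection = 0.6)
  sim <- simulate_cohort(cfg)
  ss <- site_stats(sim$cohort)
  r <- size_af_relationship(ss[ss$svtype == "DEL", ], n_size_bins = 5,
                            seed = 7)
  expect_lt(r$spearman$estimate, 0)
})

test_that("PCA coordinates are deterministic and label-blind under panmixia", {
  withr::with_seed(5, {
    d <- matrix(rbinom(100 * 60, 2, 0.3), nrow = 60)
    d[2, ] <- d[1, ]                      # identical samples
  })
  p <- pca_structure(d)
  expect_equal(p$coords[1, ], p$coords[2, ])
  expect_identical(p$coords, pca_structure(d)$coords)
  labels <- rep(c("A", "B"), each = 30)   # arbitrary split, no structure
  sil <- svpopgen:::label_silhouette(p$coords, labels)
  expect_lt(abs(sil), 0.1)
  expect_error(pca_structure(d[, 1:2], 3), "n_components")
})
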