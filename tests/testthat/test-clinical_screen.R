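test_that("Clopper-Pearson intervals match beta-quantile oracles", {
  # frozen from qbeta: binom.test(5, 100) / binom.test(2, 10)
  r <- binomial_ci(5, 100)
  expect_equal(round(c(r$lower, r$upper), 4), c(0.0164, 0.1128))
  r2 <- binomial_ci(2, 10)
  expect_equal(round(c(r2$lower, r2$upper), 4), c(0.0252, 0.5561))
  expect_equal(binomial_ci(0, 50)$lower, 0)
  expect_equal(binomial_ci(50, 50)$upper, 1)
  expect_error(binomial_ci(1, 0), "n")
  # agreement with stats::binom.test across a grid
  for (k in c(0, 1, 7, 20)) {
    bt <- binom.test(k, 20)$conf.int
    ci <- binomial_ci(k, 20)
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-9)
  }
})

make_screen_cohort <- function(gt_del, gt_dup) {
  n <- length(gt_del)
  sites <- data.frame(
    id = c("del_gd", "dup_gd", "small"),
    chrom = "chr1",
    start = c(1000000L, 1100000L, 5000000L),
    end = c(2500000L, 2400000L, 5000500L),
    svtype = c("DEL", "DUP", "DEL"),
    svlen = c(1500000, 1300000, 500), filter = "PASS",
    stringsAsFactors = FALSE)
  gt <- cbind(gt_del, gt_dup, rep(0L, n))
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n),
                        population = rep(c("EUR", "AFR"), length.out = n),
                        sex = "F", father_id = NA_character_,
                        mother_id = NA_character_, is_unrelated = TRUE,
                        stringsAsFactors = FALSE)
  sv_cohort(sites, gt, samples)
}

test_that("genomic-disorder carriers respect dosage direction and coverage", {
  ch <- make_screen_cohort(gt_del = c(1L, 1L, rep(0L, 8)),
                           gt_dup = c(0L, 0L, 1L, rep(0L, 7)))
  loci <- data.frame(locus_id = "GD1", chrom = "chr1",
                     start = 1200000L, end = 2200000L, direction = "DEL",
                     stringsAsFactors = FALSE)
  res <- gd_carrier_frequencies(ch, loci)
  all_row <- res[res$population == "ALL", ]
  # 2 DEL carriers of 10; the DUP carrier never counts at a DEL locus
  expect_equal(all_row$carriers, 2)
  expect_equal(all_row$frequency, 0.2)
  expect_equal(round(c(all_row$ci_lo, all_row$ci_hi), 4),
               c(0.0252, 0.5561))

  # coverage below min_coverage disqualifies
  narrow <- loci; narrow$start <- 0L; narrow$end <- 6000000L
  res2 <- gd_carrier_frequencies(ch, narrow)
  expect_equal(res2$carriers[res2$population == "ALL"], 0)

  off <- data.frame(locus_id = "GDX", chrom = "chr9", start = 1L,
                    end = 100L, direction = "DEL")
  expect_warning(res3 <- gd_carrier_frequencies(ch, off), "absent")
  expect_equal(res3$frequency[res3$population == "ALL"], 0)
})

test_that("gene-list carrier rate counts qualifying samples exactly", {
  gm <- toy_gene_models()
  n <- 20
  sites <- data.frame(
    id = c("plof_rare", "plof_common", "benign"),
    chrom = "chr1", start = c(2900L, 5100L, 40000L),
    end = c(3100L, 5300L, 41000L),
    svtype = "DEL", svlen = c(200, 200, 1000), filter = "PASS",
    stringsAsFactors = FALSE)
  gt <- cbind(c(rep(1L, 3), rep(0L, 17)),     # 3 carriers of the rare pLoF
              c(rep(1L, 10), rep(0L, 10)),    # common pLoF: disqualified
              rep(0L, n))
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n),
                        population = "EUR", sex = "F",
                        father_id = NA_character_,
                        mother_id = NA_character_,
                        is_unrelated = TRUE, stringsAsFactors = FALSE)
  ch <- sv_cohort(sites, gt, samples)
  ann <- annotate_cohort(ch, gm)
  r <- gene_list_carrier_rate(ch, ann, "geneA", af_threshold = 0.1)
  expect_equal(r$rate, 0.15)
  expect_equal(r$carriers, 3)
  # monotone in the AF threshold
  r2 <- gene_list_carrier_rate(ch, ann, "geneA", af_threshold = 0.5)
  expect_gte(r2$rate, r$rate)
  # disjoint list
  expect_equal(gene_list_carrier_rate(ch, ann, "nosuch")$rate, 0)
  expect_error(gene_list_carrier_rate(ch, ann, character(0)), "empty")
})

test_that("large rare SV carrier rate and balanced fraction by enumeration", {
  n <- 10
  sites <- data.frame(
    id = c("bigdel", "biginv", "smalldel", "bigcommon"),
    chrom = "chr1",
    start = c(1e6, 10e6, 20e6, 30e6), end = c(2.2e6, 11.5e6, 20.01e6,
                                              31.5e6),
    svtype = c("DEL", "INV", "DEL", "DUP"),
    svlen = c(1.2e6, 1.5e6, 1e4, 1.5e6), filter = "PASS",
    stringsAsFactors = FALSE)
  gt <- cbind(c(1L, rep(0L, 9)),            # 1 carrier
              c(0L, 1L, 1L, rep(0L, 7)),    # 2 carriers
              c(rep(1L, 5), rep(0L, 5)),    # small, never counts
              rep(1L, 10))                  # large but common
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n),
                        population = "EUR", sex = "F",
                        father_id = NA_character_,
                        mother_id = NA_character_, is_unrelated = TRUE,
                        stringsAsFactors = FALSE)
  ch <- sv_cohort(sites, gt, samples)
  r <- large_rare_carrier_rate(ch, af_threshold = 0.25)
  # carriers: s1 (bigdel), s2 + s3 (biginv) -> 3/10
  expect_equal(r$rate, 0.3)
  expect_equal(r$qualifying_sites, 2)
  expect_equal(r$balanced_complex_fraction, 0.5)
  # raising min_size can only lower the rate
  r2 <- large_rare_carrier_rate(ch, min_size = 1.4e6, af_threshold = 0.25)
  expect_lte(r2$rate, r$rate)
  # no qualifying SVs at all
  r3 <- large_rare_carrier_rate(ch, min_size = 1e9)
  expect_equal(r3$rate, 0)
})
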