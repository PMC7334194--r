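test_that("gene-overlap decision table matches hand-enumerated placements", {
  tg <- toy_gene()
  # (svtype, start, end, expected) — labels worked out by hand against
  # the toy gene: span [1000, 11000), exons at 1000-1200, 3000-3200,
  # 5000-5200, 7000-7200, 10800-11000, promoter [-1000, 1000)
  cases <- list(
    list("DEL", 2900, 3100, "pLoF"),          # clips exon 2
    list("DEL", 900, 1100, "pLoF"),           # clips exon 1 from outside
    list("DEL", 3300, 4900, "intronic"),
    list("DEL", 200, 800, "promoter"),
    list("DEL", 20000, 21000, "intergenic"),
    list("DUP", 500, 12000, "copy_gain"),     # spans whole transcript
    list("DUP", 2900, 3300, "IED"),           # exon 2 fully inside
    list("DUP", 3100, 3150, "utr_partial"),   # partial-exon duplication
    list("DUP", 3300, 3500, "intronic"),
    list("DUP", 500, 3100, "utr_partial"),    # one breakpoint inside
    list("DUP", 500, 2000, "utr_partial"),
    list("INV", 500, 12000, "whole_gene_inversion"),
    list("INV", 500, 3100, "pLoF"),           # one breakpoint inside
    list("INV", 3300, 4900, "intronic"),      # intron-contained
    list("INV", 2900, 5300, "pLoF"),          # inverts exons 2-3
    list("INS", 3100, 3100, "pLoF"),
    list("INS", 4000, 4000, "intronic"),
    list("INS", 500, 500, "promoter"),
    list("INS", 15000, 15000, "intergenic"),
    list("CTX", 5000, 30000, "pLoF"),
    list("CTX", 20000, 30000, "intergenic"))
  for (cs in cases) {
    sv <- make_sv(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(classify_gene_overlap(sv, tg$gene, tg$exons), cs[[4]],
                 label = paste(cs[[1]], cs[[2]], cs[[3]]))
  }
})

test_that("promoter window is strand-aware", {
  plus <- toy_gene("+"); minus <- toy_gene("-")
  sv <- make_sv("DEL", 11500, 12000)
  expect_equal(classify_gene_overlap(sv, minus$gene, minus$exons),
               "promoter")
  expect_equal(classify_gene_overlap(sv, plus$gene, plus$exons),
               "intergenic")
})

test_that("CPX consequences come from constituent segments, worst wins", {
  tg <- toy_gene()
  # delINV with the deletion clipping exon 2: pLoF through the DEL segment
  s <- "DEL_chr1:3001-3400,INV_chr1:3401-4000"
  sv <- make_sv("CPX", 3000, 4000, cpx_structure = s)
  expect_equal(classify_gene_overlap(sv, tg$gene, tg$exons), "pLoF")
  # same structure fully inside one intron
  s2 <- "DEL_chr1:3301-3500,INV_chr1:3501-3900"
  sv2 <- make_sv("CPX", 3300, 3900, cpx_structure = s2)
  expect_equal(classify_gene_overlap(sv2, tg$gene, tg$exons), "intronic")
})

test_that("malformed genes and BND records are rejected", {
  tg <- toy_gene()
  bad <- tg$exons[c(2, 1, 3, 4, 5), ]
  sv <- make_sv("DEL", 2900, 3100)
  expect_error(classify_gene_overlap(sv, tg$gene, bad), "sorted")
  expect_error(classify_gene_overlap(make_sv("BND", 3000, 3000),
                                     tg$gene, tg$exons), "BND")
})

test_that("copy_gain flips away when a DUP end enters the transcript", {
  tg <- toy_gene()
  full <- classify_gene_overlap(make_sv("DUP", 500, 12000), tg$gene,
                                tg$exons)
  expect_equal(full, "copy_gain")
  # sweep the right end from outside to inside the span: once inside,
  # the label can never be copy_gain again
  ends <- seq(12000, 9000, by = -250)
  labels <- vapply(ends, function(e)
    classify_gene_overlap(make_sv("DUP", 500, e), tg$gene, tg$exons),
    character(1))
  inside <- ends < 11000
  expect_true(all(labels[!inside] == "copy_gain"))
  expect_true(all(labels[inside] != "copy_gain"))
})

test_that("element coverage classification is containment-based", {
  el <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(classify_element_overlap(make_sv("DEL", 50, 300), el),
               "full")
  expect_equal(classify_element_overlap(make_sv("DEL", 150, 300), el),
               "partial")
  expect_equal(classify_element_overlap(make_sv("DEL", 300, 400), el),
               "none")
  expect_error(classify_element_overlap(make_sv("INV", 50, 300), el),
               "DEL/DUP")
})

test_that("annotate_cohort is order-invariant and handles intergenic cohorts", {
  gm <- toy_gene_models()
  sites <- data.frame(
    id = c("a", "b", "c"), chrom = "chr1",
    start = c(2900, 50000, 500), end = c(3100, 51000, 12000),
    svtype = c("DEL", "DEL", "DUP"), svlen = c(200, 1000, 11500),
    filter = "PASS", stringsAsFactors = FALSE)
  gt <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L), nrow = 2)
  samples <- data.frame(sample_id = c("x", "y"), population = "EUR",
                        is_unrelated = TRUE)
  ch <- sv_cohort(sites, gt, samples)
  ann <- annotate_cohort(ch, gm)
  expect_equal(unname(ann$worst[c("a", "b", "c")]),
               c("pLoF", "intergenic", "copy_gain"))

  perm <- sv_cohort(sites[c(3, 1, 2), ],
                                   gt[, c(3, 1, 2)], samples)
  ann2 <- annotate_cohort(perm, gm)
  expect_equal(ann$worst[sort(names(ann$worst))],
               ann2$worst[sort(names(ann2$worst))])

  lone <- sv_cohort(sites[2, ], gt[, 2, drop = FALSE], samples)
  ann3 <- annotate_cohort(lone, gm)
  expect_equal(nrow(ann3$gene_pairs), 0)
  expect_equal(unname(ann3$worst), "intergenic")

  dup_gene <- gm
  dup_gene$genes <- rbind(gm$genes, gm$genes)
  expect_error(annotate_cohort(ch, dup_gene), "duplicate gene ids")
})

test_that("annotation recovers the simulator's truth labels", {
  gm <- simulate_gene_models(400, seed = 55)
  sim <- simulate_cohort(small_sim(seed = 56, gene_target_frac = 0.35),
                         genes = gm)
  ann <- annotate_cohort(filter_analysis_sites(sim$cohort), gm,
                         gm$elements)
  tr <- sim$truth
  gene_truth <- tr[!is.na(tr$gene_id), ]
  key <- paste(ann$gene_pairs$sv_id, ann$gene_pairs$gene_id)
  got <- ann$gene_pairs$category[match(paste(gene_truth$id,
                                             gene_truth$gene_id), key)]
  agree <- mean(got == gene_truth$true_category, na.rm = TRUE)
  expect_gte(agree, 0.99)

  el_truth <- tr[!is.na(tr$element_id), ]
  ekey <- paste(ann$element_pairs$sv_id, ann$element_pairs$element_id)
  egot <- ann$element_pairs$coverage[match(paste(el_truth$id,
                                                 el_truth$element_id),
                                           ekey)]
  want <- sub("element_", "", el_truth$true_category)
  expect_gte(mean(egot == want, na.rm = TRUE), 0.99)
})
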