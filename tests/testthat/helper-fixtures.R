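# Hand-built fixtures shared across test files. Everything is constructed
# in code; coordinates are internal 0-based half-open.

# one gene on chr1: span [1000, 11000), '+' strand, 5 exons
toy_gene <- function(strand = "+") {
  list(
    gene = data.frame(gene_id = "geneA", chrom = "chr1", start = 1000,
                      end = 11000, strand = strand,
                      tss = if (strand == "+") 1000 else 11000,
                      stringsAsFactors = FALSE),
    exons = data.frame(start = c(1000, 3000, 5000, 7000, 10800),
                       end = c(1200, 3200, 5200, 7200, 11000)))
}

toy_gene_models <- function() {
  tg <- toy_gene()
  g <- tg$gene
  g$n_exons <- 5L
  g$coding_bp <- sum(tg$exons$end - tg$exons$start)
  g$segdup <- FALSE
  g$constraint_rank <- 1L
  list(genes = g,
       exons = cbind(gene_id = "geneA", chrom = "chr1", tg$exons))
}

make_sv <- function(svtype, start, end, chrom = "chr1",
                    cpx_structure = NA_character_) {
  data.frame(svtype = svtype, chrom = chrom, start = start, end = end,
             cpx_structure = cpx_structure, stringsAsFactors = FALSE)
}

# 3 samples x 4 sites, hand-enumerated genotypes
toy_cohort <- function() {
  sites <- data.frame(
    id = c("del1", "dup1", "ins1", "bnd1"),
    chrom = "chr1",
    start = c(1000L, 500L, 5100L, 9000L),
    end = c(2000L, 12000L, 5100L, 9000L),
    svtype = c("DEL", "DUP", "INS", "BND"),
    svlen = c(1000, 11500, 300, NA),
    filter = "PASS", stringsAsFactors = FALSE)
  gt <- matrix(c(1L, 0L, 0L,    # del1: singleton in s1
                 1L, 1L, 0L,    # dup1
                 0L, 2L, 1L,    # ins1
                 NA, NA, NA),   # bnd1
               nrow = 3)
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        population = c("EUR", "EUR", "AFR"),
                        sex = "F", father_id = NA_character_,
                        mother_id = NA_character_, is_unrelated = TRUE,
                        stringsAsFactors = FALSE)
  sv_cohort(sites, gt, samples)
}

default_arm_map <- function() {
  read_arm_map(system.file("extdata", "arm_map_synthetic.tsv",
                           package = "svpopgen"))
}

small_sim <- function(seed = 11, n_samples = 100L, n_trios = 10L, ...) {
  sim_config(n_samples = n_samples, n_trios = n_trios,
             theta = c(DEL = 150, DUP = 50, INS = 110, INV = 3, CPX = 12,
                       MCNV = 8, CTX = 2),
             seed = seed, ...)
}
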