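#' Simulation configuration
#'
#' Builds the parameter set for [simulate_cohort()]. Defaults describe a
#' desk-scale cohort with the statistical structure the downstream analyses
#' assume: a neutral 1/i site-frequency spectrum per SV class (roughly half
#' of segregating sites appear as singletons at this sample size),
#' Hardy-Weinberg genotypes within populations, Balding-Nichols
#' differentiation between continental populations, mobile-element
#' insertion size peaks near 300 bp / 2.1 kb / 6 kb, telomeric enrichment
#' of biallelic deletions and duplications and centromeric enrichment of
#' multiallelic CNVs, Mendelian trios perturbed by a genotyping error rate,
#' and category-specific purifying selection injected as an allele-count
#' down-shift.
#'
#' @param n_samples number of unrelated diploid samples (default 500).
#' @param pop_props named population proportions (sum to 1).
#' @param pop_f named Balding-Nichols differentiation parameter per
#'   population (F = 0 disables structure).
#' @param n_trios number of parent-parent-child trios appended to the
#'   cohort; parents are drawn from the unrelated set, children are marked
#'   related.
#' @param theta named population-scaled mutation parameter per SV class;
#'   expected segregating sites per class = `theta * a_n` with
#'   `a_n = sum(1/i, i < n_chromosomes)`.
#' @param size_model per-class size distributions; see defaults in the
#'   function body. `INS` is a 3-component log-normal mixture.
#' @param selection_map named allele-count down-shift strength `s` per true
#'   functional category; a selected site's allele count is redrawn with
#'   probability proportional to `i^-(1+s)` (s = 0 is neutral).
#' @param size_selection additional shift per log10(bp) above ~300 bp,
#'   producing the inverse size-frequency relationship.
#' @param positional_bias data.frame-like list of per-class telomeric and
#'   centromeric density weights (1 = uniform along the arm).
#' @param gene_target_frac fraction of DEL/DUP/INV/INS sites deliberately
#'   placed on gene models (when supplied) with a known truth category.
#' @param constraint_coupling exponent linking gene choice to the
#'   synthetic constraint rank (higher rank = more constrained = fewer
#'   functional SVs placed); 0 decouples placement from constraint.
#' @param element_target_frac fraction of DEL/DUP sites placed on noncoding
#'   elements (full or partial coverage, recorded in truth).
#' @param conservation_selection extra shift per unit conservation-sum
#'   percentile (0-1) for element-targeted CNVs; 0 disables.
#' @param genotyping_error probability that a trio child's genotype is
#'   replaced by a different random genotype (default 0.04, chosen so the
#'   Mendelian violation rate lands on the few-percent scale reported for
#'   short-read SV trios).
#' @param bnd_rate fraction of additional unresolved breakend records
#'   (quarantined from all analyses).
#' @param arm_map chromosome-arm map (see [read_arm_map()]); default is the
#'   synthetic arm map shipped with the package.
#' @param seed integer seed; mandatory.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 500L,
                       pop_props = c(AFR = 0.35, AMR = 0.15, EAS = 0.15,
                                     EUR = 0.30, OTH = 0.05),
                       pop_f = c(AFR = 0.02, AMR = 0.015, EAS = 0.02,
                                 EUR = 0.015, OTH = 0.01),
                       n_trios = 50L,
                       theta = c(DEL = 1200, DUP = 420, INS = 900,
                                 INV = 13, CPX = 80, MCNV = 55, CTX = 5),
                       size_model = NULL,
                       selection_map = c(pLoF = 0.5, IED = 0.3,
                                         copy_gain = 0.2,
                                         whole_gene_inversion = 0.1,
                                         promoter = 0.1, intronic = 0.02,
                                         intergenic = 0,
                                         element_full = 0.25,
                                         element_partial = 0.05),
                       size_selection = 0.1,
                       positional_bias = NULL,
                       gene_target_frac = 0.25,
                       constraint_coupling = 1,
                       element_target_frac = 0.10,
                       conservation_selection = 0,
                       genotyping_error = 0.04,
                       bnd_rate = 0.02,
                       arm_map = NULL,
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory in sim_config()")
  if (abs(sum(pop_props) - 1) > 1e-8) stop("pop_props must sum to 1")
  if (any(pop_props < 0) || any(pop_f < 0) || any(theta < 0) ||
      genotyping_error < 0 || bnd_rate < 0 || size_selection < 0)
    stop("all rates must be >= 0")
  if (!setequal(names(pop_props), names(pop_f)))
    stop("pop_props and pop_f must name the same populations")
  if (is.null(size_model)) size_model <- default_size_model()
  if (is.null(positional_bias)) positional_bias <- default_positional_bias()
  if (is.null(arm_map))
    arm_map <- read_arm_map(system.file("extdata", "arm_map_synthetic.tsv",
                                        package = "svpopgen"))
  structure(list(
    n_samples = as.integer(n_samples), pop_props = pop_props, pop_f = pop_f,
    n_trios = as.integer(n_trios), theta = theta, size_model = size_model,
    selection_map = selection_map, size_selection = size_selection,
    positional_bias = positional_bias, gene_target_frac = gene_target_frac,
    constraint_coupling = constraint_coupling,
    element_target_frac = element_target_frac,
    conservation_selection = conservation_selection,
    genotyping_error = genotyping_error, bnd_rate = bnd_rate,
    arm_map = arm_map, seed = as.integer(seed)), class = "sim_config")
}

# log-normal size models per class; INS is an Alu/SVA/LINE1-like mixture
default_size_model <- function() {
  list(
    DEL = list(kind = "lnorm", meanlog = log(600), sdlog = 1.3),
    DUP = list(kind = "lnorm", meanlog = log(4000), sdlog = 1.3),
    INS = list(kind = "mix", w = c(0.55, 0.25, 0.20),
               meanlog = log(c(300, 2100, 6000)),
               sdlog = c(0.15, 0.12, 0.20)),
    INV = list(kind = "lnorm", meanlog = log(5000), sdlog = 1.5),
    CPX = list(kind = "lnorm", meanlog = log(3000), sdlog = 1.2),
    MCNV = list(kind = "lnorm", meanlog = log(15000), sdlog = 1.0),
    CTX = list(kind = "fixed", value = 1000))
}

default_positional_bias <- function() {
  data.frame(
    svtype = c("DEL", "DUP", "INS", "INV", "CPX", "MCNV", "CTX"),
    telomeric = c(1.5, 1.5, 1, 1, 1, 1, 1),
    centromeric = c(1, 1, 1, 1, 1, 3, 1),
    stringsAsFactors = FALSE)
}

#' Simulate a neutral (or down-shifted) site-frequency spectrum
#'
#' Under the infinite-sites neutral model the number of segregating sites
#' is `K ~ Poisson(theta * a_n)` with `a_n = sum(1/i, i = 1..n-1)`, and a
#' site's alternate allele count `i` has probability `(1/i)/a_n`. The
#' expected singleton fraction is `1/a_n`. A down-shift strength `s > 0`
#' reweights the spectrum to `i^-(1+s)` (more singletons, lower AF),
#' emulating purifying selection.
#'
#' @param theta population-scaled mutation parameter (>= 0).
#' @param n_chromosomes number of sampled chromosomes (>= 2).
#' @param seed optional seed.
#' @param shift selection down-shift strength `s` (default 0 = neutral).
#' @return integer vector of per-site alternate allele counts (length K).
#' @export
simulate_sfs <- function(theta, n_chromosomes, seed = NULL, shift = 0) {
  if (n_chromosomes < 2) stop("n_chromosomes must be >= 2")
  if (theta < 0) stop("theta must be >= 0")
  draw <- function() {
    an <- sum(1 / seq_len(n_chromosomes - 1))
    k <- stats::rpois(1, theta * an)
    if (k == 0) return(integer(0))
    i <- seq_len(n_chromosomes - 1)
    sample(i, k, replace = TRUE, prob = i^(-(1 + shift)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Hardy-Weinberg genotypes at given allele frequencies
#'
#' Draws diploid dosages `rbinom(n, 2, p)` per site: the exact
#' Hardy-Weinberg sampling model, used both inside [simulate_cohort()]
#' (within populations) and directly for HWE-test calibration.
#'
#' @param af vector of allele frequencies.
#' @param n_samples samples per site.
#' @param seed optional seed.
#' @return integer matrix `n_samples x length(af)`.
#' @export
simulate_hwe_genotypes <- function(af, n_samples, seed = NULL) {
  draw <- function() {
    matrix(stats::rbinom(n_samples * length(af), 2L,
                         rep(af, each = n_samples)),
           nrow = n_samples)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a pair of SV/SNV dosage vectors in linkage disequilibrium
#'
#' Haplotype pairs are drawn with `P(1,1) = pa*pb + rho*sqrt(pa qa pb qb)`
#' so the haplotypic (and dosage) correlation targets `rho`; diploid
#' dosages are sums of two independent haplotypes.
#'
#' @param n samples. @param rho target correlation. @param p_a,p_b allele
#'   frequencies. @param seed optional seed.
#' @return list with integer vectors `a` and `b` of length `n`.
#' @export
simulate_ld_pair <- function(n, rho, p_a = 0.3, p_b = 0.3, seed = NULL) {
  d <- rho * sqrt(p_a * (1 - p_a) * p_b * (1 - p_b))
  p11 <- p_a * p_b + d
  p10 <- p_a - p11; p01 <- p_b - p11
  p00 <- 1 - p11 - p10 - p01
  if (min(p11, p10, p01, p00) < 0)
    stop("rho not attainable at these allele frequencies")
  draw <- function() {
    h <- sample(4, 2 * n, replace = TRUE, prob = c(p00, p01, p10, p11))
    a_hap <- as.integer(h %in% c(3L, 4L))
    b_hap <- as.integer(h %in% c(2L, 4L))
    list(a = a_hap[1:n] + a_hap[(n + 1):(2 * n)],
         b = b_hap[1:n] + b_hap[(n + 1):(2 * n)])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate gene models, noncoding elements and a conservation track
#'
#' Genes have 2-30 sorted non-overlapping exons inside their span, strand
#' and TSS; a synthetic SNV-constraint rank (permutation of `1..n_genes`)
#' stands in for LOEUF/pLI rank. Noncoding elements fall into
#' `n_element_classes` classes with a conserved subset. The conservation
#' track (BedGraph-like) is elevated over exons and conserved elements with
#' low-level background noise elsewhere; gaps score 0.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed.
#' @param arm_map arm map (default: shipped synthetic map).
#' @param n_elements number of noncoding elements.
#' @param n_element_classes number of element classes (default 14, matching
#'   a typical noncoding annotation panel).
#' @return list with `genes` (one row per gene: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`, `n_exons`, `coding_bp`, `segdup`,
#'   `constraint_rank`), `exons` (`gene_id`, `chrom`, `start`, `end`),
#'   `elements` (`element_id`, `chrom`, `start`, `end`, `class`,
#'   `conserved`) and `conservation` (`chrom`, `start`, `end`, `score`).
#' @export
simulate_gene_models <- function(n_genes, seed, arm_map = NULL,
                                 n_elements = 2000L,
                                 n_element_classes = 14L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (is.null(arm_map))
    arm_map <- read_arm_map(system.file("extdata", "arm_map_synthetic.tsv",
                                        package = "svpopgen"))
  withr::with_seed(seed, {
    span <- pmin(pmax(round(stats::rlnorm(n_genes, log(3e4), 0.8)), 2000),
                 500000)
    pos <- sample_arm_positions(n_genes, arm_map, telo_w = 1, cen_w = 1)
    start <- pmax(pos$arm_start, pos$pos - span %/% 2)
    end <- pmin(pos$arm_end, start + span)
    start <- pmax(pos$arm_start, end - span)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    n_ex <- sample(2:30, n_genes, replace = TRUE, prob = 0.88^(2:30))
    exons <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      k <- n_ex[g]
      seg <- floor(seq(start[g], end[g], length.out = k + 1))
      elen <- pmin(round(stats::runif(k, 80, 350)),
                   pmax(diff(seg) - 2L, 10L))
      off <- floor(stats::runif(k) * (diff(seg) - elen - 1))
      es <- seg[seq_len(k)] + off
      exons[[g]] <- data.frame(gene_id = sprintf("gene%05d", g),
                               chrom = pos$chrom[g], start = es,
                               end = es + elen, stringsAsFactors = FALSE)
    }
    exons <- do.call(rbind, exons)
    genes <- data.frame(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      chrom = pos$chrom, start = start, end = end, strand = strand,
      tss = ifelse(strand == "+", start, end),
      n_exons = n_ex,
      coding_bp = as.numeric(tapply(exons$end - exons$start, exons$gene_id,
                                    sum)[sprintf("gene%05d",
                                                 seq_len(n_genes))]),
      segdup = stats::runif(n_genes) < 0.1,
      constraint_rank = sample(n_genes),
      stringsAsFactors = FALSE)

    epos <- sample_arm_positions(n_elements, arm_map, 1, 1)
    elen <- round(stats::runif(n_elements, 200, 2000))
    estart <- pmax(epos$arm_start, epos$pos - elen %/% 2)
    elements <- data.frame(
      element_id = sprintf("elem%05d", seq_len(n_elements)),
      chrom = epos$chrom, start = estart, end = estart + elen,
      class = sprintf("class%02d",
                      sample(n_element_classes, n_elements, replace = TRUE)),
      conserved = stats::runif(n_elements) < 0.4,
      stringsAsFactors = FALSE)

    cons <- rbind(
      data.frame(chrom = exons$chrom, start = exons$start, end = exons$end,
                 score = round(stats::runif(nrow(exons), 0.5, 1), 4)),
      with(elements[elements$conserved, ],
           data.frame(chrom = chrom, start = start, end = end,
                      score = round(stats::runif(sum(elements$conserved),
                                                 0.4, 0.9), 4))))
    bgn <- 3000L
    bpos <- sample_arm_positions(bgn, arm_map, 1, 1)
    cons <- rbind(cons, data.frame(
      chrom = bpos$chrom, start = bpos$pos, end = bpos$pos + 1000L,
      score = round(stats::runif(bgn, 0, 0.3), 4)))
    cons <- cons[order(cons$chrom, cons$start), ]
    list(genes = genes, exons = exons, elements = elements,
         conservation = cons)
  })
}

# Sample n genomic positions on an arm map with telomeric/centromeric
# density weights: density = telo_w in the outer 10% of each arm, cen_w in
# the 10% nearest the centromere, 1 in the interstitial 80%.
sample_arm_positions <- function(n, arm_map, telo_w = 1, cen_w = 1) {
  arm <- sample(nrow(arm_map), n, replace = TRUE, prob = arm_map$arm_len)
  z <- 0.8 + 0.1 * telo_w + 0.1 * cen_w
  zone <- sample(3, n, replace = TRUE,
                 prob = c(0.8, 0.1 * telo_w, 0.1 * cen_w) / z)
  # d = fractional distance from the centromere along the arm
  d <- stats::runif(n, c(0.1, 0.9, 0)[zone], c(0.9, 1, 0.1)[zone])
  a <- arm_map[arm, ]
  pos <- ifelse(a$arm == "p", a$end - d * a$arm_len, a$start + d * a$arm_len)
  data.frame(chrom = a$chrom, pos = as.integer(round(pos)),
             arm_start = a$start, arm_end = a$end,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort SV callset with known truth
#'
#' Draws per-class segregating sites from the neutral spectrum, injects
#' category-specific selection (allele-count down-shift), places sites with
#' class-specific positional bias (or deliberately on supplied gene/element
#' models so truth categories are unambiguous), draws Hardy-Weinberg
#' genotypes within Balding-Nichols-differentiated populations, transmits
#' trios Mendelian-exactly and then perturbs the children by the genotyping
#' error rate. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param genes optional output of [simulate_gene_models()]; enables
#'   truth-labelled functional placement and conservation-coupled
#'   selection.
#' @param out_dir optional directory; when given, VCF, BED, sample-table
#'   TSV and truth TSV are written there.
#' @return list with `cohort` (an [sv_cohort()]) and `truth` (one row per
#'   emitted site: `id`, `svtype`, `true_category`, `sel_shift`,
#'   `global_af`, `gene_id`, `element_id`, `cpx_label`).
#' @export
simulate_cohort <- function(config, genes = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "cohort"), {
    res <- .simulate_cohort_impl(config, genes)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sv_vcf(res$cohort, file.path(out_dir, "cohort.vcf"))
    write_sites_bed(res$cohort, file.path(out_dir, "sites.bed"))
    write_sample_table(res$cohort$samples, file.path(out_dir, "samples.tsv"))
    data.table::fwrite(res$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
  }
  res
}

.simulate_cohort_impl <- function(config, genes) {
  n_unrel <- config$n_samples
  n_chrom <- 2L * n_unrel
  pops <- names(config$pop_props)
  cnt <- diff(round(cumsum(c(0, config$pop_props)) * n_unrel))
  pop_of <- sample(rep(pops, times = cnt))
  classes <- names(config$theta)

  # --- site skeleton: class, allele count, size -------------------------
  site_list <- lapply(classes, function(cl) {
    i <- simulate_sfs(config$theta[[cl]], n_chrom)
    if (!length(i)) return(NULL)
    data.frame(svtype = cl, i = i, svlen = draw_sizes(
      config$size_model[[cl]], length(i)), stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  ns <- nrow(sites)
  sites$id <- sprintf("sv%06d", seq_len(ns))
  sites$true_category <- NA_character_
  sites$gene_id <- NA_character_
  sites$element_id <- NA_character_
  sites$cpx_label <- NA_character_
  sites$chrom <- NA_character_
  sites$start <- NA_integer_
  sites$end <- NA_integer_
  sites$cpx_structure <- NA_character_

  # --- placement --------------------------------------------------------
  targeted <- rep(FALSE, ns)
  if (!is.null(genes)) {
    sites <- place_gene_targets(sites, genes, config$gene_target_frac,
                                config$constraint_coupling)
    sites <- place_element_targets(sites, genes$elements,
                                   config$element_target_frac)
    targeted <- !is.na(sites$true_category)
  }
  for (cl in classes) {
    idx <- which(sites$svtype == cl & !targeted)
    if (!length(idx)) next
    pb <- config$positional_bias
    w <- pb[pb$svtype == cl, ]
    pp <- sample_arm_positions(length(idx), config$arm_map,
                               telo_w = w$telomeric, cen_w = w$centromeric)
    len <- ifelse(cl == "INS", 0, round(sites$svlen[idx]))
    st <- pmax(pp$arm_start, pp$pos - len %/% 2)
    en <- pmin(pp$arm_end, st + len)
    st <- pmax(pp$arm_start, en - len)
    sites$chrom[idx] <- pp$chrom
    sites$start[idx] <- st
    sites$end[idx] <- en
  }
  cpx_idx <- which(sites$svtype == "CPX")
  if (length(cpx_idx)) sites <- attach_cpx_structures(sites, cpx_idx)

  # --- selection: redraw allele counts with weight i^-(1+s) -------------
  shift <- unname(ifelse(is.na(sites$true_category), 0,
                         config$selection_map[sites$true_category]))
  shift[is.na(shift)] <- 0
  shift <- shift + config$size_selection *
    pmax(0, log10(pmax(sites$svlen, 50)) - log10(300))
  if (config$conservation_selection > 0 && !is.null(genes)) {
    elem_idx <- which(!is.na(sites$element_id))
    if (length(elem_idx)) {
      cs <- conservation_sum(sites[elem_idx, ], genes$conservation)
      shift[elem_idx] <- shift[elem_idx] +
        config$conservation_selection * rank(cs) / length(cs)
    }
  }
  resel <- which(shift > 0)
  iseq <- seq_len(n_chrom - 1L)
  for (j in resel)
    sites$i[j] <- sample(iseq, 1, prob = iseq^(-(1 + shift[j])))
  sites$sel_shift <- shift
  sites$global_af <- sites$i / n_chrom

  # --- genotypes: Balding-Nichols + HWE within populations --------------
  bial <- sites$svtype != "MCNV"
  gt <- matrix(NA_integer_, n_unrel, ns,
               dimnames = list(NULL, sites$id))
  if (all(config$pop_f == 0)) {
    # no structure: place exactly i alternate alleles on the 2N sampled
    # chromosomes (the coalescent sample itself), so the realized SFS is
    # the drawn SFS and genotype counts follow the Hardy-Weinberg
    # conditional (Levene) distribution
    odd <- seq(1L, n_chrom, 2L); even <- odd + 1L
    for (j in which(bial)) {
      z <- integer(n_chrom)
      z[sample.int(n_chrom, sites$i[j])] <- 1L
      gt[, j] <- z[odd] + z[even]
    }
  } else for (pk in pops) {
    rows <- which(pop_of == pk)
    if (!length(rows)) next
    f <- config$pop_f[[pk]]
    p <- sites$global_af
    paf <- if (f > 0)
      stats::rbeta(ns, p * (1 - f) / f, (1 - p) * (1 - f) / f) else p
    paf[!bial] <- 0
    gt[rows, ] <- matrix(
      stats::rbinom(length(rows) * ns, 2L, rep(paf, each = length(rows))),
      nrow = length(rows))
  }
  gt[, !bial] <- NA_integer_

  # --- MCNV copy numbers ------------------------------------------------
  cn <- NULL
  mc <- which(!bial)
  if (length(mc)) {
    cn <- matrix(NA_integer_, n_unrel, length(mc),
                 dimnames = list(NULL, sites$id[mc]))
    for (k in seq_along(mc)) {
      q <- stats::rbeta(1, 0.8, 3)
      alt_states <- sample(c(0L, 2L, 3L, 4L), 2)
      qs <- q * c(0.6, 0.4)
      hap <- function(m) sample(c(1L, alt_states), m, replace = TRUE,
                                prob = c(1 - sum(qs), qs))
      cn[, k] <- hap(n_unrel) + hap(n_unrel)
    }
  }

  # --- trios ------------------------------------------------------------
  samp <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n_unrel)), population = pop_of,
    sex = sample(c("M", "F"), n_unrel, replace = TRUE),
    father_id = NA_character_, mother_id = NA_character_,
    is_unrelated = TRUE, stringsAsFactors = FALSE)
  if (config$n_trios > 0) {
    kid_gt <- matrix(NA_integer_, config$n_trios, ns)
    kid_rows <- vector("list", config$n_trios)
    used <- c()
    for (t in seq_len(config$n_trios)) {
      pool <- setdiff(seq_len(n_unrel), used)
      pool_pop <- pop_of[pool]
      pk <- sample(names(which(table(pool_pop) >= 2)), 1)
      pair <- sample(pool[pool_pop == pk], 2)
      used <- c(used, pair)
      fa <- gt[pair[1], ]; mo <- gt[pair[2], ]
      miss <- is.na(fa) | is.na(mo)
      child <- stats::rbinom(ns, 1L, ifelse(miss, 0, fa) / 2) +
        stats::rbinom(ns, 1L, ifelse(miss, 0, mo) / 2)
      child[miss] <- NA_integer_
      if (config$genotyping_error > 0) {
        err <- which(stats::runif(ns) < config$genotyping_error &
                       !is.na(child))
        if (length(err))
          child[err] <- (child[err] + sample(1:2, length(err),
                                             replace = TRUE)) %% 3L
      }
      kid_gt[t, ] <- child
      kid_rows[[t]] <- data.frame(
        sample_id = sprintf("child%03d", t), population = pk, sex = "F",
        father_id = samp$sample_id[pair[1]],
        mother_id = samp$sample_id[pair[2]],
        is_unrelated = FALSE, stringsAsFactors = FALSE)
    }
    samp <- rbind(samp, do.call(rbind, kid_rows))
    gt <- rbind(gt, kid_gt)
    if (!is.null(cn))
      cn <- rbind(cn, matrix(NA_integer_, config$n_trios, ncol(cn)))
  }

  # --- BND quarantine records ------------------------------------------
  n_bnd <- stats::rpois(1, config$bnd_rate * ns)
  if (n_bnd > 0) {
    bp <- sample_arm_positions(n_bnd, config$arm_map, 1, 1)
    bnd <- sites[rep(1, n_bnd), ]
    bnd$id <- sprintf("bnd%05d", seq_len(n_bnd))
    bnd$svtype <- "BND"; bnd$chrom <- bp$chrom
    bnd$start <- bp$pos; bnd$end <- bp$pos
    bnd$svlen <- NA_real_; bnd$i <- NA_integer_
    bnd$true_category <- NA; bnd$gene_id <- NA; bnd$element_id <- NA
    bnd$cpx_label <- NA; bnd$cpx_structure <- NA
    bnd$sel_shift <- 0; bnd$global_af <- NA_real_
    sites <- rbind(sites, bnd)
    gt <- cbind(gt, matrix(NA_integer_, nrow(gt), n_bnd,
                           dimnames = list(NULL, bnd$id)))
  }

  sites$filter <- "PASS"
  site_cols <- data.frame(
    id = sites$id, chrom = sites$chrom, start = sites$start,
    end = sites$end, svtype = sites$svtype, svlen = sites$svlen,
    filter = sites$filter, cpx_structure = sites$cpx_structure,
    stringsAsFactors = FALSE)
  colnames(gt) <- sites$id
  cohort <- sv_cohort(site_cols, gt, samp, cn)

  # drop sites monomorphic in the realized cohort (not segregating)
  seg <- cohort$sites$svtype == "BND" | cohort$sites$svtype == "MCNV" |
    cohort$sites$ac > 0
  cohort <- subset_sites(cohort, which(seg))
  truth <- sites[match(cohort$sites$id, sites$id),
                 c("id", "svtype", "true_category", "sel_shift",
                   "global_af", "gene_id", "element_id", "cpx_label")]
  rownames(truth) <- NULL
  list(cohort = cohort, truth = truth)
}

draw_sizes <- function(model, n) {
  out <- switch(model$kind,
    lnorm = stats::rlnorm(n, model$meanlog, model$sdlog),
    fixed = rep(model$value, n),
    mix = {
      comp <- sample(length(model$w), n, replace = TRUE, prob = model$w)
      stats::rlnorm(n, model$meanlog[comp], model$sdlog[comp])
    },
    stop("unknown size model kind: ", model$kind))
  pmax(round(out), 50)
}

# deliberate placement of a fraction of sites onto gene models so the
# functional truth category is unambiguous
place_gene_targets <- function(sites, genes, frac, coupling = 1) {
  g <- genes$genes; ex <- genes$exons
  eligible <- which(sites$svtype %in% c("DEL", "DUP", "INV", "INS"))
  take <- eligible[stats::runif(length(eligible)) < frac]
  # constrained genes (high rank) accumulate fewer functional SVs:
  # per-gene depletion increases with the synthetic constraint rank
  gene_w <- (nrow(g) + 1 - g$constraint_rank)^coupling
  for (j in take) {
    gi <- sample(nrow(g), 1, prob = gene_w)
    gene <- g[gi, ]
    gex <- ex[ex$gene_id == gene$gene_id, ]
    len <- round(sites$svlen[j])
    cat <- NULL
    if (sites$svtype[j] == "DEL") {
      e <- gex[sample(nrow(gex), 1), ]
      st <- round(stats::runif(1, e$start - len + 1, e$end - 1))
      cat <- "pLoF"
    } else if (sites$svtype[j] == "INS") {
      e <- gex[sample(nrow(gex), 1), ]
      st <- round(stats::runif(1, e$start + 1, e$end - 1))
      len <- 0
      cat <- "pLoF"
    } else if (sites$svtype[j] == "DUP") {
      span <- gene$end - gene$start
      if (stats::runif(1) < 0.5 || span + 2000 > len * 2) {
        len <- max(len, span + round(stats::runif(1, 200, 2000)))
        st <- gene$start - round(stats::runif(1, 100, len - span - 100))
        cat <- "copy_gain"
      } else {
        e <- gex[sample(nrow(gex), 1), ]
        elen <- e$end - e$start
        len <- min(max(len, elen + 200), span - 2)
        if (len < elen + 2) next   # exon cannot be contained; skip target
        lo <- max(gene$start + 1, e$end - len)
        hi <- min(e$start - 1, gene$end - 1 - len)
        if (lo > hi) next
        st <- round(stats::runif(1, lo, hi))
        st <- min(max(st, lo), hi)
        cat <- "IED"
      }
    } else if (sites$svtype[j] == "INV") {
      span <- gene$end - gene$start
      if (stats::runif(1) < 0.5) {
        len <- max(len, span + 1000)
        st <- gene$start - round(stats::runif(1, 100, len - span - 100))
        cat <- "whole_gene_inversion"
      } else {
        st <- round(stats::runif(1, gene$start + 1, gene$end - 1))
        # force the second breakpoint past the transcript end so exactly
        # one breakpoint falls inside
        len <- max(len, gene$end - st + round(stats::runif(1, 100, 1000)))
        cat <- "pLoF"
      }
    }
    if (is.null(cat)) next
    sites$chrom[j] <- gene$chrom
    sites$start[j] <- max(0, st)
    sites$end[j] <- max(0, st) + len
    sites$svlen[j] <- max(len, if (sites$svtype[j] == "INS")
      sites$svlen[j] else 50)
    sites$true_category[j] <- cat
    sites$gene_id[j] <- gene$gene_id
  }
  sites
}

place_element_targets <- function(sites, elements, frac) {
  eligible <- which(sites$svtype %in% c("DEL", "DUP") &
                      is.na(sites$true_category))
  take <- eligible[stats::runif(length(eligible)) < frac]
  for (j in take) {
    e <- elements[sample(nrow(elements), 1), ]
    len <- round(sites$svlen[j])
    elen <- e$end - e$start
    if (len > elen + 2 && stats::runif(1) < 0.5) {
      st <- round(stats::runif(1, e$end - len + 1, e$start - 1))
      cat <- "element_full"
    } else {
      # one breakpoint strictly inside the element: overlap, never
      # containment of the element
      en <- round(stats::runif(1, e$start + 1, e$end - 1))
      st <- en - len
      cat <- "element_partial"
    }
    sites$chrom[j] <- e$chrom
    sites$start[j] <- max(0, st)
    sites$end[j] <- max(0, st) + len
    sites$true_category[j] <- cat
    sites$element_id[j] <- e$element_id
  }
  sites
}

attach_cpx_structures <- function(sites, cpx_idx) {
  labels <- c("delINV", "INVdel", "dupINV", "INVdup", "delINVdel",
              "dupINVdup", "delINVdup", "dupINVdel", "dDUP", "dDUP_iDEL",
              "INS_iDEL")
  # dup-flanked inversions and dispersed duplications dominate; weights
  # put the inversion-involving fraction near three quarters of complex
  # SVs (dispersed duplications are inverted half the time)
  wts <- c(2, 2, 2.5, 2.5, 1.5, 0.5, 0.5, 0.5, 5, 1, 2.4)
  for (j in cpx_idx) {
    lab <- sample(labels, 1, prob = wts)
    st <- simulate_cpx_structure(lab, chrom = sites$chrom[j],
                                 start = sites$start[j],
                                 total_len = max(round(sites$svlen[j]), 300))
    sites$cpx_label[j] <- lab
    sites$cpx_structure[j] <- structure_to_string(st)
    span <- range(c(st$start[st$chrom == sites$chrom[j]],
                    st$end[st$chrom == sites$chrom[j]]), na.rm = TRUE)
    sites$start[j] <- span[1]
    sites$end[j] <- span[2]
    sites$svlen[j] <- max(span[2] - span[1], 50)
  }
  sites
}

# sum of conservation scores overlapped by each SV interval (gaps = 0)
conservation_sum <- function(svs, track) {
  q <- GenomicRanges::GRanges(svs$chrom,
                              IRanges::IRanges(svs$start + 1L, svs$end))
  s <- GenomicRanges::GRanges(track$chrom,
                              IRanges::IRanges(track$start + 1L, track$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  ov <- GenomicRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                  s[S4Vectors::subjectHits(hits)])
  contrib <- GenomicRanges::width(ov) *
    track$score[S4Vectors::subjectHits(hits)]
  out <- numeric(nrow(svs))
  agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- agg
  out
}
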