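#' Clopper-Pearson binomial confidence interval
#'
#' Exact interval for a carrier proportion; the lower bound is exactly 0
#' at k = 0 and the upper bound exactly 1 at k = n.
#'
#' @param k carriers (0 <= k <= n). @param n samples (> 0).
#' @param level confidence level (default 0.95).
#' @return list with `proportion`, `lower`, `upper`, `k`, `n`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  list(proportion = k / n, lower = lower, upper = upper, k = k, n = n)
}

#' Genomic-disorder carrier frequencies
#'
#' A sample carries a genomic-disorder locus if it has at least one CNV of
#' the locus's pathogenic dosage direction (DEL or DUP) covering at least
#' `min_coverage` of the critical region. Frequencies are reported per
#' population and overall, with Clopper-Pearson 95% intervals.
#'
#' @param cohort an [sv_cohort()].
#' @param loci data.frame (`locus_id`, `chrom`, `start`, `end`,
#'   `direction` in DEL/DUP).
#' @param min_coverage minimum fraction of the critical region covered
#'   (default 0.5).
#' @return data.frame, one row per locus x population (plus `ALL`):
#'   `locus_id`, `direction`, `population`, `carriers`, `n`, `frequency`,
#'   `ci_lo`, `ci_hi`.
#' @export
gd_carrier_frequencies <- function(cohort, loci, min_coverage = 0.5) {
  sites <- cohort$sites
  st <- cohort$samples
  unrel <- which(st$is_unrelated)
  pops <- unique(st$population[unrel])
  out <- list()
  for (r in seq_len(nrow(loci))) {
    loc <- loci[r, ]
    if (!loc$chrom %in% sites$chrom)
      warning("locus ", loc$locus_id, " on chromosome absent from callset")
    cand <- which(sites$svtype == loc$direction & sites$chrom == loc$chrom)
    ovl <- pmin(sites$end[cand], loc$end) - pmax(sites$start[cand],
                                                 loc$start)
    cand <- cand[ovl >= min_coverage * (loc$end - loc$start)]
    carrier <- rep(FALSE, nrow(st))
    if (length(cand))
      carrier <- rowSums(!is.na(cohort$gt[, cand, drop = FALSE]) &
                           cohort$gt[, cand, drop = FALSE] > 0) > 0
    groups <- c(list(ALL = unrel),
                setNames(lapply(pops, function(p)
                  unrel[st$population[unrel] == p]), pops))
    for (g in names(groups)) {
      idx <- groups[[g]]
      ci <- binomial_ci(sum(carrier[idx]), length(idx))
      out[[length(out) + 1]] <- data.frame(
        locus_id = loc$locus_id, direction = loc$direction,
        population = g, carriers = ci$k, n = ci$n,
        frequency = ci$proportion, ci_lo = ci$lower, ci_hi = ci$upper,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Carrier rate of rare pLoF SVs in a gene list
#'
#' Fraction of unrelated samples carrying at least one SV that (a) is
#' annotated pLoF for a gene in the list and (b) has allele frequency
#' below `af_threshold` (default 0.1%, the "very rare" stratum).
#'
#' @param cohort an [sv_cohort()].
#' @param annotations output of [annotate_cohort()].
#' @param gene_list nonempty character vector of gene ids.
#' @param af_threshold qualifying AF (default 0.001).
#' @return list with `rate`, `ci` (Clopper-Pearson), `carriers`, `n`,
#'   `qualifying_sites`.
#' @export
gene_list_carrier_rate <- function(cohort, annotations, gene_list,
                                   af_threshold = 0.001) {
  if (!length(gene_list)) stop("empty gene list")
  gp <- annotations$gene_pairs
  qual_sv <- unique(gp$sv_id[gp$category == "pLoF" &
                               gp$gene_id %in% gene_list])
  sites <- cohort$sites
  qual_sv <- qual_sv[sites$af[match(qual_sv, sites$id)] < af_threshold]
  unrel <- which(cohort$samples$is_unrelated)
  carrier <- if (length(qual_sv)) {
    g <- cohort$gt[unrel, qual_sv, drop = FALSE]
    rowSums(!is.na(g) & g > 0) > 0
  } else rep(FALSE, length(unrel))
  ci <- binomial_ci(sum(carrier), length(unrel))
  list(rate = ci$proportion, ci = c(ci$lower, ci$upper),
       carriers = ci$k, n = ci$n, qualifying_sites = length(qual_sv))
}

#' Carrier rate of very large rare SVs
#'
#' Fraction of unrelated samples carrying at least one autosomal SV of
#' size >= `min_size` with AF < `af_threshold`, with the fraction of those
#' qualifying SVs that are balanced or complex (INV, CTX, CPX).
#'
#' @param cohort an [sv_cohort()].
#' @param min_size minimum SV size (default 1e6).
#' @param af_threshold rare threshold (default 0.01).
#' @return list with `rate`, `ci`, `carriers`, `n`, `qualifying_sites`,
#'   `balanced_complex_fraction`.
#' @export
large_rare_carrier_rate <- function(cohort, min_size = 1e6,
                                    af_threshold = 0.01) {
  sites <- cohort$sites
  qual <- which(sites$svtype != "BND" & !is.na(sites$svlen) &
                  sites$svlen >= min_size & !is.na(sites$af) &
                  sites$af < af_threshold)
  unrel <- which(cohort$samples$is_unrelated)
  bal_cx <- mean(sites$svtype[qual] %in% c("INV", "CTX", "CPX"))
  bial <- qual[sites$svtype[qual] != "MCNV"]
  carrier <- if (length(bial)) {
    g <- cohort$gt[unrel, sites$id[bial], drop = FALSE]
    rowSums(!is.na(g) & g > 0) > 0
  } else rep(FALSE, length(unrel))
  if (!is.null(cohort$cn)) {
    mc <- intersect(sites$id[qual[sites$svtype[qual] == "MCNV"]],
                    colnames(cohort$cn))
    for (id in mc) {
      cnx <- cohort$cn[unrel, id]
      tab <- table(cnx)
      modal <- as.integer(names(tab)[which.max(tab)])
      carrier <- carrier | (!is.na(cnx) & cnx != modal)
    }
  }
  ci <- binomial_ci(sum(carrier), length(unrel))
  list(rate = ci$proportion, ci = c(ci$lower, ci$upper), carriers = ci$k,
       n = ci$n, qualifying_sites = length(qual),
       balanced_complex_fraction = if (length(qual)) bal_cx else NA_real_)
}
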