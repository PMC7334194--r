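#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the 1-df chi-square test against expected counts
#' `(n p^2, 2 n p q, n q^2)` at the observed allele frequency; monomorphic
#' sites return p = 1 by convention. The exact (conditional-on-allele-count)
#' test is available for small or rare-variant counts where the chi-square
#' approximation is poor.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (>= 0, total > 0).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return p-value.
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt,
                     method = c("chisq", "exact")) {
  method <- match.arg(method)
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be >= 0")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  p <- (2 * n_hom_ref + n_het) / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (method == "chisq") {
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((counts - expected)^2 / expected)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # exact: distribution of het count conditional on the minor allele count
  n_minor <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    homm <- (n_minor - h) / 2
    homM <- n - h - homm
    h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(homm) -
      lfactorial(homM)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Watterson estimator of the scaled mutation parameter
#'
#' `theta_hat = K / a_n` with `a_n = sum(1/i, i = 1..n-1)` the harmonic
#' number and `K` the number of segregating sites.
#'
#' @param n_segregating_sites K (>= 0).
#' @param n_chromosomes sampled chromosomes (>= 2).
#' @return list with `theta`, `a_n`, `K`, `n_chromosomes`.
#' @export
watterson_theta <- function(n_segregating_sites, n_chromosomes) {
  if (n_segregating_sites < 0) stop("K must be >= 0")
  if (n_chromosomes < 2) stop("n_chromosomes must be >= 2")
  a_n <- sum(1 / seq_len(n_chromosomes - 1))
  list(theta = n_segregating_sites / a_n, a_n = a_n,
       K = n_segregating_sites, n_chromosomes = n_chromosomes)
}

#' Project a de novo SV mutation rate from Watterson theta
#'
#' Under `theta = 4 Ne mu`, the per-haploid-genome per-generation rate is
#' `mu = theta / (4 Ne)` and the expected de novo SVs per diploid birth is
#' `2 mu`. The confidence interval treats K as Poisson (the neutral
#' sampling model of the segregating-site count) and resamples it; it
#' requires `n_chromosomes` to recover K from theta. Ne is a required,
#' explicitly logged modelling choice — the projection is only as good as
#' that number.
#'
#' @param theta Watterson estimate (or a [watterson_theta()] result).
#' @param effective_population_size diploid Ne (> 0), default 10000.
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param n_chromosomes needed for the CI; taken from `theta` when a
#'   [watterson_theta()] result is passed.
#' @param seed optional seed for the bootstrap.
#' @return list with `mu_haploid`, `per_generation` (diploid), `ci`
#'   (95%, on the diploid scale), `Ne`, `K`, `n_chromosomes`.
#' @export
sv_mutation_rate <- function(theta, effective_population_size = 10000,
                             n_bootstrap = 100, n_chromosomes = NULL,
                             seed = NULL) {
  ne <- effective_population_size
  if (ne <= 0) stop("Ne must be > 0")
  if (is.list(theta)) {
    n_chromosomes <- theta$n_chromosomes
    theta <- theta$theta
  }
  mu <- theta / (4 * ne)
  per_gen <- 2 * mu
  ci <- c(NA_real_, NA_real_)
  K <- NA_real_
  if (theta == 0) {
    ci <- c(0, 0)
  } else if (!is.null(n_chromosomes)) {
    a_n <- sum(1 / seq_len(n_chromosomes - 1))
    K <- theta * a_n
    boot <- function() {
      kb <- stats::rpois(n_bootstrap, K)
      stats::quantile(2 * (kb / a_n) / (4 * ne), c(0.025, 0.975),
                      names = FALSE)
    }
    ci <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  }
  list(mu_haploid = mu, per_generation = per_gen, ci = ci, Ne = ne, K = K,
       n_chromosomes = n_chromosomes)
}

#' Share of rare gene-inactivating events contributed by SVs
#'
#' Given per-genome means of rare pLoF SVs, rare IED SVs and rare pLoF
#' short variants (SNVs/indels), returns the SV percentage of all rare
#' heterozygous gene-inactivation events: `100 (sv + ied)/(sv + ied + snv)`
#' including IEDs, or conservatively `100 sv/(sv + snv)` excluding them.
#'
#' @param rare_plof_sv_mean,rare_ied_sv_mean,rare_plof_snv_mean per-genome
#'   means (>= 0).
#' @param include_ied include intragenic exonic duplications (default TRUE).
#' @return percentage.
#' @export
sv_share_of_plof <- function(rare_plof_sv_mean, rare_ied_sv_mean,
                             rare_plof_snv_mean, include_ied = TRUE) {
  stopifnot(rare_plof_sv_mean >= 0, rare_ied_sv_mean >= 0,
            rare_plof_snv_mean >= 0)
  num <- rare_plof_sv_mean + if (include_ied) rare_ied_sv_mean else 0
  den <- num + rare_plof_snv_mean
  if (den == 0) stop("all-zero denominator")
  100 * num / den
}

#' Per-genome SV and altered-gene burden
#'
#' Counts, per sample: non-reference biallelic SVs (plus non-modal MCNV
#' carriers), and genes altered per functional category (a gene counts
#' once per sample per category if any carried allele hits it), in an
#' all-AF and a rare (AF < 1%) stratum, plus homozygous-pLoF gene counts.
#'
#' @param cohort an [sv_cohort()].
#' @param annotations output of [annotate_cohort()].
#' @param rare_af rare-stratum frequency threshold (default 0.01).
#' @return list with `per_sample` (one row per sample) and `summary`
#'   (cohort mean and median per cell). `genes_total*` columns are the sum
#'   of the pLoF, copy_gain and IED cells by construction.
#' @export
per_genome_burden <- function(cohort, annotations, rare_af = 0.01) {
  sites <- cohort$sites
  bial <- sites$svtype != "BND" & sites$svtype != "MCNV"
  gt <- cohort$gt
  if (is.null(gt) || nrow(gt) != nrow(cohort$samples))
    stop("cohort genotype matrix does not match the sample table")
  carrier <- !is.na(gt) & gt > 0
  rare <- !is.na(sites$af) & sites$af < rare_af

  n_sv <- rowSums(carrier[, bial, drop = FALSE])
  n_sv_rare <- rowSums(carrier[, bial & rare, drop = FALSE])
  mc_ids <- sites$id[sites$svtype == "MCNV"]
  if (length(mc_ids) && !is.null(cohort$cn)) {
    for (id in intersect(mc_ids, colnames(cohort$cn))) {
      cnx <- cohort$cn[, id]
      tab <- table(cnx[cohort$samples$is_unrelated])
      modal <- as.integer(names(tab)[which.max(tab)])
      extra <- !is.na(cnx) & cnx != modal
      n_sv <- n_sv + extra
      if (!is.na(sites$af[match(id, sites$id)]) &&
          sites$af[match(id, sites$id)] < rare_af)
        n_sv_rare <- n_sv_rare + extra
    }
  }

  gp <- annotations$gene_pairs
  if (!all(gp$sv_id %in% sites$id))
    stop("annotations refer to sites absent from the cohort")
  count_genes <- function(cat, site_keep, hom = FALSE) {
    sel <- gp$category == cat & gp$sv_id %in% sites$id[site_keep]
    if (!any(sel)) return(numeric(nrow(gt)))
    sv_i <- match(gp$sv_id[sel], sites$id)
    gene_f <- factor(gp$gene_id[sel])
    inc <- Matrix::sparseMatrix(i = sv_i, j = as.integer(gene_f), x = 1,
                                dims = c(nrow(sites), nlevels(gene_f)))
    carry <- if (hom) (!is.na(gt) & gt == 2L) else carrier
    hits <- (carry * 1) %*% inc
    Matrix::rowSums(hits > 0)
  }
  cats <- c("pLoF", "copy_gain", "IED")
  per <- data.frame(sample_id = cohort$samples$sample_id,
                    n_sv = n_sv, n_sv_rare = n_sv_rare,
                    stringsAsFactors = FALSE)
  for (cat in cats) {
    per[[paste0("genes_", cat)]] <- count_genes(cat, bial)
    per[[paste0("genes_", cat, "_rare")]] <- count_genes(cat, bial & rare)
  }
  per$genes_total <- per$genes_pLoF + per$genes_copy_gain + per$genes_IED
  per$genes_total_rare <- per$genes_pLoF_rare + per$genes_copy_gain_rare +
    per$genes_IED_rare
  per$genes_pLoF_hom <- count_genes("pLoF", bial, hom = TRUE)

  num_cols <- setdiff(names(per), "sample_id")
  summary <- data.frame(
    metric = num_cols,
    mean = vapply(per[num_cols], mean, numeric(1)),
    median = vapply(per[num_cols], median, numeric(1)),
    row.names = NULL)
  list(per_sample = per, summary = summary)
}

#' Trio Mendelian consistency check
#'
#' For every complete trio in the cohort, the fraction of biallelic sites
#' (all three members genotyped) where the child genotype is impossible
#' given the parents, and the apparent de novo rate (child heterozygous,
#' both parents homozygous reference). Cohort medians are reported.
#'
#' @param cohort an [sv_cohort()] whose sample table links children to
#'   parents.
#' @return list with `per_trio` (child_id, n_sites, violation_rate,
#'   de_novo_rate) and `median_violation_rate`, `median_de_novo_rate`.
#' @export
mendelian_check <- function(cohort) {
  st <- cohort$samples
  kids <- which(!is.na(st$father_id) & !is.na(st$mother_id))
  if (!length(kids)) stop("no complete trios in the sample table")
  bial <- cohort$sites$svtype %in% c("DEL", "DUP", "INS", "INV", "CPX",
                                     "CTX")
  res <- lapply(kids, function(k) {
    fa <- match(st$father_id[k], st$sample_id)
    mo <- match(st$mother_id[k], st$sample_id)
    if (is.na(fa) || is.na(mo)) stop("broken trio links for ",
                                     st$sample_id[k])
    f <- cohort$gt[fa, bial]; m <- cohort$gt[mo, bial]
    cc <- cohort$gt[k, bial]
    ok <- !is.na(f) & !is.na(m) & !is.na(cc)
    f <- f[ok]; m <- m[ok]; cc <- cc[ok]
    viol <- (f == 0 & m == 0 & cc > 0) | (f == 2 & m == 2 & cc < 2) |
      (f == 0 & cc == 2) | (m == 0 & cc == 2) |
      (f == 2 & cc == 0) | (m == 2 & cc == 0)
    dn <- cc == 1 & f == 0 & m == 0
    data.frame(child_id = st$sample_id[k], n_sites = length(cc),
               violation_rate = mean(viol), de_novo_rate = mean(dn),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, res)
  list(per_trio = per,
       median_violation_rate = median(per$violation_rate),
       median_de_novo_rate = median(per$de_novo_rate))
}

#' Squared dosage correlation (linkage disequilibrium R^2)
#'
#' @param dosage_a,dosage_b equal-length dosage vectors (pairs with a
#'   missing value are dropped; >= 2 complete pairs and nonzero variance
#'   required).
#' @return squared Pearson correlation.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) stop("unequal lengths")
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(a) < 2) stop("fewer than 2 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: site is monomorphic in the compared samples")
  stats::cor(a, b)^2
}

#' Allele frequency as a function of SV size
#'
#' Mean AF per log-spaced size bin with a bootstrap-over-sites 95%
#' confidence interval, plus the Spearman correlation of bin midpoint size
#' against mean AF.
#'
#' @param sites data.frame with `svlen` and `af` (biallelic sites).
#' @param n_size_bins number of log-spaced bins (default 10).
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param seed optional seed.
#' @return list with `table` (`bin`, `size_lo`, `size_hi`, `n`, `mean_af`,
#'   `ci_lo`, `ci_hi`; empty bins have NA) and `spearman` (htest).
#' @export
size_af_relationship <- function(sites, n_size_bins = 10,
                                 n_bootstrap = 100, seed = NULL) {
  s <- sites[!is.na(sites$svlen) & !is.na(sites$af) & sites$svlen > 0, ]
  breaks <- exp(seq(log(min(s$svlen)), log(max(s$svlen) + 1),
                    length.out = n_size_bins + 1))
  bin <- cut(s$svlen, breaks, include.lowest = TRUE, labels = FALSE)
  mean_by_bin <- function(af, bin) {
    out <- rep(NA_real_, n_size_bins)
    m <- tapply(af, bin, mean)
    out[as.integer(names(m))] <- m
    out
  }
  obs <- mean_by_bin(s$af, bin)
  boot <- function() {
    reps <- replicate(n_bootstrap, {
      idx <- sample(nrow(s), replace = TRUE)
      mean_by_bin(s$af[idx], bin[idx])
    })
    apply(reps, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }
  ci <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  tab <- data.frame(bin = seq_len(n_size_bins),
                    size_lo = breaks[-length(breaks)], size_hi = breaks[-1],
                    n = as.integer(tabulate(bin, n_size_bins)),
                    mean_af = obs, ci_lo = ci[1, ], ci_hi = ci[2, ])
  ok <- !is.na(tab$mean_af)
  sp <- if (sum(ok) >= 3)
    suppressWarnings(stats::cor.test(sqrt(tab$size_lo * tab$size_hi)[ok],
                                     tab$mean_af[ok], method = "spearman"))
  else NULL
  list(table = tab, spearman = sp)
}

#' Principal components of common-site genotype dosages
#'
#' Column-centers the dosage matrix (missing values imputed to the column
#' mean) and returns the top sample coordinates. Signs are fixed by
#' convention: the largest-magnitude loading of each component is
#' positive, making the decomposition fully deterministic.
#'
#' @param dosage samples x sites matrix of common-site dosages (use
#'   AF > 1% sites).
#' @param n_components number of components (default 3; must not exceed
#'   the number of sites or samples).
#' @return list with `coords` (samples x components), `var_explained`.
#' @export
pca_structure <- function(dosage, n_components = 3) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) < n_components || nrow(dosage) < n_components)
    stop("need at least n_components sites and samples")
  cm <- colMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(idx)) dosage[idx] <- cm[idx[, 2]]
  x <- sweep(dosage, 2, colMeans(dosage))
  sv <- svd(x, nu = n_components, nv = n_components)
  for (j in seq_len(n_components)) {
    flip <- sign(sv$v[which.max(abs(sv$v[, j])), j])
    if (flip < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(coords) <- rownames(dosage)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coords = coords,
       var_explained = sv$d[seq_len(n_components)]^2 / sum(sv$d^2))
}
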