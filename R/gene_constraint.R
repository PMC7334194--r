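#' Fit per-gene expected rare-SV counts
#'
#' Poisson regression (log link) of observed rare functional SV counts per
#' gene on gene covariates: log10 transcript span, exon count, log10 total
#' intron length and a genomic-context flag. Fitted per functional
#' category. With an intercept, the Poisson maximum-likelihood fit
#' reproduces the total observed count exactly, so aggregate O/E is 1 by
#' construction under the null.
#'
#' @param genes gene table ([simulate_gene_models()] layout: `gene_id`,
#'   `start`, `end`, `n_exons`, `coding_bp`, `segdup`); >= 500 genes.
#' @param observed_counts named list or data.frame of per-gene counts, one
#'   element/column per functional category (rows aligned with `genes`).
#' @return a `gene_expectation_model`: per-category coefficients and a
#'   per-gene table with `observed`, `expected`, `oe`, `depletion`
#'   (`1 - O/E`) and `uninformative` flag (expected < 0.1).
#' @export
fit_expected_counts <- function(genes, observed_counts) {
  if (nrow(genes) < 500)
    stop("need >= 500 genes to fit the expectation model")
  if (is.data.frame(observed_counts))
    observed_counts <- as.list(observed_counts)
  covs <- data.frame(
    log_span = log10(genes$end - genes$start),
    n_exons = genes$n_exons,
    log_intron = log10(pmax(genes$end - genes$start - genes$coding_bp, 1)),
    segdup = as.numeric(genes$segdup))
  keep <- names(covs)[vapply(covs, function(x) length(unique(x)) > 1,
                             logical(1))]
  models <- list(); tables <- list()
  for (cat in names(observed_counts)) {
    y <- observed_counts[[cat]]
    stopifnot(length(y) == nrow(genes), all(y >= 0))
    if (sum(y) == 0) {
      # nothing observed in this category: no model to fit
      tables[[cat]] <- data.frame(
        gene_id = genes$gene_id, category = cat, observed = y,
        expected = 0, oe = NA_real_, depletion = NA_real_,
        uninformative = TRUE, stringsAsFactors = FALSE)
      models[[cat]] <- list(coefficients = NULL, covariates = keep,
                            deviance = NA_real_)
      next
    }
    dat <- cbind(covs, y = y)
    form <- if (length(keep))
      stats::as.formula(paste("y ~", paste(keep, collapse = " + ")))
    else y ~ 1
    # sparse categories can fit near-zero rates for some genes; that is
    # expected at desk scale and surfaces through the uninformative flag
    fit <- suppressWarnings(stats::glm(form, family = stats::poisson(),
                                       data = dat))
    if (!fit$converged)
      stop("Poisson expectation model did not converge for ", cat,
           "; deviance = ", signif(fit$deviance, 6))
    expected <- unname(fitted(fit))
    tables[[cat]] <- data.frame(
      gene_id = genes$gene_id, category = cat, observed = y,
      expected = expected, oe = y / expected, depletion = 1 - y / expected,
      uninformative = expected < 0.1, stringsAsFactors = FALSE)
    models[[cat]] <- list(coefficients = coef(fit),
                          covariates = keep,
                          deviance = fit$deviance)
  }
  structure(list(models = models, per_gene = do.call(rbind, tables),
                 n_genes = nrow(genes)),
            class = "gene_expectation_model")
}

#' Constraint-rank correlation of rare-SV depletion
#'
#' Genes are ranked by an external SNV-constraint metric (LOEUF/pLI rank;
#' higher rank = more constrained) and grouped into approximately equal bins
#' (about 175 genes each at genome scale, i.e. ~100 bins). Per-bin
#' depletion is `1 - sum(observed)/sum(expected)` (ratio of sums — robust
#' to genes with tiny expectations), the bin-index association is tested
#' with a two-sided Spearman correlation, and a 21-point rolling mean is
#' returned for display. Bins with zero expected count are excluded with a
#' warning.
#'
#' @param per_gene per-gene table (one category) from
#'   [fit_expected_counts()].
#' @param snv_constraint_rank integer rank per gene (aligned with
#'   `per_gene`; larger = more constrained).
#' @param n_bins target number of bins (default 100; reduced when there
#'   are fewer genes than `2 * n_bins`).
#' @param rolling rolling-mean window (default 21).
#' @return list with `per_bin` (`bin`, `n`, `mean_rank`, `observed`,
#'   `expected`, `depletion`, `rolling_depletion`), `spearman` (htest),
#'   `bin_size`.
#' @export
binned_constraint_correlation <- function(per_gene, snv_constraint_rank,
                                          n_bins = 100, rolling = 21) {
  stopifnot(length(snv_constraint_rank) == nrow(per_gene))
  n <- nrow(per_gene)
  n_bins <- max(2L, min(n_bins, n %/% 2L))
  o <- order(snv_constraint_rank)
  bin <- ceiling(seq_len(n) / (n / n_bins))
  per_bin <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- o[bin == b]
    data.frame(bin = b, n = length(i),
               mean_rank = mean(snv_constraint_rank[i]),
               observed = sum(per_gene$observed[i]),
               expected = sum(per_gene$expected[i]))
  }))
  zero <- per_bin$expected == 0
  if (any(zero)) {
    warning(sum(zero), " bin(s) with zero expected count excluded")
    per_bin <- per_bin[!zero, ]
  }
  per_bin$depletion <- 1 - per_bin$observed / per_bin$expected
  per_bin$rolling_depletion <- rolling_mean(per_bin$depletion, rolling)
  sp <- suppressWarnings(stats::cor.test(per_bin$bin, per_bin$depletion,
                                         method = "spearman"))
  list(per_bin = per_bin, spearman = sp,
       bin_size = round(n / length(unique(bin))))
}

#' Simulate per-gene rare-SV counts from a known log-linear model
#'
#' Generates `observed ~ Poisson(mu_g * (1 - depletion_g))` with
#' `log(mu_g)` linear in the gene covariates — the generative model that
#' [fit_expected_counts()] assumes, used for parameter-recovery and
#' calibration tests. The returned truth includes the per-gene depletion
#' factor.
#'
#' @param genes gene table.
#' @param coefs named coefficients (`intercept`, `log_span`, `n_exons`,
#'   `log_intron`, `segdup`); defaults give a few expected events per
#'   gene.
#' @param depletion numeric vector in `[0, 1)` per gene (default 0 = null).
#' @param seed integer seed.
#' @return list with `counts` (integer vector), `mu` (undepleted means),
#'   `depletion`.
#' @export
simulate_gene_counts <- function(genes,
                                 coefs = c(intercept = -3.5,
                                           log_span = 1.0,
                                           n_exons = 0.02,
                                           log_intron = 0, segdup = 0.3),
                                 depletion = 0, seed = 1) {
  depletion <- rep_len(depletion, nrow(genes))
  stopifnot(all(depletion >= 0), all(depletion < 1))
  eta <- coefs[["intercept"]] +
    coefs[["log_span"]] * log10(genes$end - genes$start) +
    coefs[["n_exons"]] * genes$n_exons +
    coefs[["log_intron"]] *
      log10(pmax(genes$end - genes$start - genes$coding_bp, 1)) +
    coefs[["segdup"]] * as.numeric(genes$segdup)
  mu <- exp(eta)
  counts <- withr::with_seed(seed,
                             stats::rpois(nrow(genes),
                                          mu * (1 - depletion)))
  list(counts = counts, mu = mu, depletion = depletion)
}
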