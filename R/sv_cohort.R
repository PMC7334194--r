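#' Construct an SV cohort object
#'
#' The central container of the package: a set of SV sites, diploid genotype
#' dosages for biallelic sites, integer copy numbers for multiallelic CNV
#' (MCNV) sites, and the sample table. Internal coordinates are 0-based
#' half-open; VCF I/O converts to/from 1-based inclusive.
#'
#' Allele counts (`ac`), allele numbers (`an`) and allele frequencies (`af`)
#' are always computed over the unrelated sample subset. Breakend (`BND`)
#' records are retained in `sites` but quarantined: every analysis function
#' in the package excludes them. For MCNV sites `af` is the carrier
#' frequency (fraction of unrelated samples whose diploid copy number
#' differs from the cohort mode) and `ac = round(af * an)`; MCNVs never
#' enter biallelic statistics (SFS, HWE, APS, LD).
#'
#' @param sites data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `svtype` (DEL, DUP, MCNV, INS, INV, CPX, CTX, BND), `svlen`, `filter`
#'   and optionally `cpx_structure` (token string, see
#'   [parse_cpx_intervals()]).
#' @param gt integer matrix, samples x sites, values 0/1/2/NA; MCNV and BND
#'   columns should be NA.
#' @param samples data.frame with `sample_id`, `population`, `sex`,
#'   `father_id`, `mother_id`, `is_unrelated`.
#' @param cn optional integer matrix, samples x MCNV sites (diploid copy
#'   number), column names matching MCNV site ids.
#' @return An object of class `sv_cohort` with components `sites`, `gt`,
#'   `cn`, `samples`. `sites` gains recomputed `ac`, `an`, `af`,
#'   `is_singleton` columns.
#' @export
sv_cohort <- function(sites, gt, samples, cn = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "start", "end", "svtype", "svlen",
                  "filter") %in% names(sites)))
  if (anyDuplicated(sites$id)) stop("duplicate site ids")
  if (is.null(sites$cpx_structure)) sites$cpx_structure <- NA_character_
  bad <- !is.na(sites$end) & sites$end < sites$start
  if (any(bad)) stop("end < start for site(s): ",
                     paste(head(sites$id[bad]), collapse = ", "))
  nonbnd <- sites$svtype != "BND"
  if (any(nonbnd & (is.na(sites$svlen) | sites$svlen <= 0)))
    stop("svlen must be > 0 for all non-BND records")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "population", "is_unrelated") %in%
                  names(samples)))
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    stopifnot(nrow(gt) == nrow(samples), ncol(gt) == nrow(sites))
    rownames(gt) <- samples$sample_id
    colnames(gt) <- sites$id
  }
  .check_trio_links(samples)
  obj <- structure(list(sites = sites, gt = gt, cn = cn, samples = samples),
                   class = "sv_cohort")
  obj$sites <- .recompute_allele_stats(obj)
  obj
}

.check_trio_links <- function(samples) {
  for (col in c("father_id", "mother_id")) {
    if (is.null(samples[[col]])) next
    ref <- samples[[col]]
    ref <- ref[!is.na(ref) & ref != ""]
    missing <- setdiff(ref, samples$sample_id)
    if (length(missing))
      stop("trio links reference unknown samples: ",
           paste(head(missing), collapse = ", "))
  }
  invisible(TRUE)
}

# ac/an/af over unrelated samples; MCNV af = non-modal carrier frequency
.recompute_allele_stats <- function(cohort) {
  sites <- cohort$sites
  unrel <- which(cohort$samples$is_unrelated)
  g <- cohort$gt[unrel, , drop = FALSE]
  nonmiss <- colSums(!is.na(g))
  ac <- as.integer(colSums(g, na.rm = TRUE))
  an <- as.integer(2L * nonmiss)
  af <- ifelse(an > 0, ac / an, NA_real_)
  mc <- which(sites$svtype == "MCNV")
  if (length(mc) && !is.null(cohort$cn)) {
    for (j in mc) {
      cnj <- cohort$cn[unrel, sites$id[j]]
      cnj <- cnj[!is.na(cnj)]
      if (!length(cnj)) next
      tab <- table(cnj)
      modal <- as.integer(names(tab)[which.max(tab)])
      an[j] <- 2L * length(cnj)
      af[j] <- mean(cnj != modal)
      ac[j] <- as.integer(round(af[j] * an[j]))
    }
  }
  sites$ac <- ac
  sites$an <- an
  sites$af <- af
  sites$is_singleton <- !is.na(ac) & ac == 1L & sites$svtype != "MCNV"
  sites
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat("sv_cohort:", nrow(x$sites), "sites x", nrow(x$samples), "samples (",
      sum(x$samples$is_unrelated), "unrelated )\n")
  print(table(x$sites$svtype))
  invisible(x)
}

#' Restrict a cohort to analysis-ready sites
#'
#' Keeps PASS, non-BND records (the analysis set used throughout).
#' Idempotent. Allele statistics are recomputed on the retained columns
#' (they are unchanged by site filtering, but the invariant is re-asserted).
#'
#' @param cohort an [sv_cohort()].
#' @param pass_only drop non-PASS records (default TRUE).
#' @return filtered `sv_cohort`.
#' @export
filter_analysis_sites <- function(cohort, pass_only = TRUE) {
  keep <- cohort$sites$svtype != "BND"
  if (pass_only) keep <- keep & cohort$sites$filter == "PASS"
  subset_sites(cohort, which(keep))
}

# subset a cohort to a site index vector, preserving genotype/cn alignment
subset_sites <- function(cohort, idx) {
  sites <- cohort$sites[idx, , drop = FALSE]
  gt <- if (!is.null(cohort$gt)) cohort$gt[, idx, drop = FALSE]
  cn <- cohort$cn
  if (!is.null(cn)) {
    keep_cn <- intersect(colnames(cn), sites$id)
    cn <- if (length(keep_cn)) cn[, keep_cn, drop = FALSE] else NULL
  }
  sv_cohort(sites, gt, cohort$samples, cn)
}

#' Per-site summary statistics
#'
#' One row per biallelic, non-BND site: allele counts, singleton flag and
#' Hardy-Weinberg p-value over the unrelated subset.
#'
#' @param cohort an [sv_cohort()].
#' @param hwe_method `"chisq"` (default) or `"exact"`; see [hwe_test()].
#' @return data.frame with `id`, `svtype`, `svlen`, `ac`, `an`, `af`,
#'   `is_singleton`, `hwe_p`.
#' @export
site_stats <- function(cohort, hwe_method = c("chisq", "exact")) {
  hwe_method <- match.arg(hwe_method)
  keep <- cohort$sites$svtype != "BND" & cohort$sites$svtype != "MCNV"
  sites <- cohort$sites[keep, , drop = FALSE]
  unrel <- which(cohort$samples$is_unrelated)
  g <- cohort$gt[unrel, keep, drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    gj <- gj[!is.na(gj)]
    if (!length(gj)) return(NA_real_)
    hwe_test(sum(gj == 0L), sum(gj == 1L), sum(gj == 2L),
             method = hwe_method)
  }, numeric(1))
  data.frame(id = sites$id, svtype = sites$svtype, svlen = sites$svlen,
             ac = sites$ac, an = sites$an, af = sites$af,
             is_singleton = sites$is_singleton, hwe_p = hwe_p,
             stringsAsFactors = FALSE)
}
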