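#' Prepare APS covariates for a site table
#'
#' Adds `log10_size` and coerces `svtype` to factor. Extra logical/numeric
#' columns named in `extra` are passed through as technical covariates
#' (e.g. segmental-duplication or simple-repeat overlap flags,
#' distance-to-telomere class).
#'
#' @param sites data.frame with at least `svtype`, `svlen`, `is_singleton`.
#' @param extra character vector of additional covariate columns.
#' @return data.frame ready for [fit_singleton_model()].
#' @export
aps_covariates <- function(sites, extra = character(0)) {
  out <- data.frame(is_singleton = as.logical(sites$is_singleton),
                    svtype = factor(sites$svtype),
                    log10_size = log10(pmax(sites$svlen, 1)),
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- sites[[col]]
  out
}

#' Fit the singleton-proportion calibration model
#'
#' Binomial regression (logit link by default) of the singleton indicator
#' on SV class, log10 size and any extra technical covariates, fitted on a
#' neutral reference stratum — intergenic, biallelic, PASS sites. The
#' maximum-likelihood intercept guarantees that the mean in-sample
#' prediction equals the observed singleton fraction, so the reference
#' stratum has APS = 0 exactly by construction.
#'
#' @param reference_sites covariate data.frame from [aps_covariates()]
#'   (>= 200 rows).
#' @param link `"logit"` (default) or `"cloglog"`.
#' @return an `aps_model`: coefficients, covariate schema (column names
#'   and factor levels), link, and fit diagnostics.
#' @export
fit_singleton_model <- function(reference_sites, link = c("logit",
                                                          "cloglog")) {
  link <- match.arg(link)
  if (nrow(reference_sites) < 200)
    stop("need >= 200 reference sites to calibrate the singleton model")
  covs <- setdiff(names(reference_sites), "is_singleton")
  # drop covariates with a single observed value (no information)
  covs <- covs[vapply(reference_sites[covs],
                      function(x) length(unique(x)) > 1, logical(1))]
  form <- if (length(covs))
    stats::as.formula(paste("is_singleton ~", paste(covs, collapse = " + ")))
  else is_singleton ~ 1
  fit <- stats::glm(form, family = stats::binomial(link = link),
                    data = reference_sites)
  if (!fit$converged)
    stop("singleton model did not converge; diagnostics: deviance = ",
         signif(fit$deviance, 6), ", iter = ", fit$iter)
  structure(list(
    coefficients = coef(fit), link = link, covariates = covs,
    xlevels = fit$xlevels,
    diagnostics = list(deviance = fit$deviance,
                       null_deviance = fit$null.deviance,
                       n = nrow(reference_sites),
                       observed_singleton_fraction =
                         mean(reference_sites$is_singleton))),
    class = "aps_model")
}

#' Predicted singleton probability under an APS model
#'
#' @param model an `aps_model`.
#' @param sites covariate data.frame ([aps_covariates()] layout).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_singleton <- function(model, sites) {
  eta <- rep(model$coefficients[["(Intercept)"]], nrow(sites))
  for (cv in model$covariates) {
    x <- sites[[cv]]
    if (is.null(x)) stop("covariate schema mismatch: missing column ", cv)
    if (cv %in% names(model$xlevels)) {
      lev <- model$xlevels[[cv]]
      x <- as.character(x)
      if (any(!x %in% lev))
        stop("covariate schema mismatch: unseen level(s) in ", cv, ": ",
             paste(unique(setdiff(x, lev)), collapse = ", "))
      for (l in lev[-1]) {
        cf <- model$coefficients[[paste0(cv, l)]]
        eta <- eta + ifelse(x == l, cf, 0)
      }
    } else {
      eta <- eta + model$coefficients[[cv]] * as.numeric(x)
    }
  }
  if (model$link == "logit") stats::plogis(eta) else 1 - exp(-exp(eta))
}

#' Adjusted proportion of singletons (APS) of a query variant set
#'
#' `APS = observed singleton proportion - mean model-predicted
#' proportion`; zero corresponds to singleton behaviour comparable to the
#' neutral (intergenic) calibration stratum, positive values indicate an
#' excess of singletons consistent with purifying selection. The 95%
#' confidence interval comes from bootstrap resampling of query sites; the
#' one-tailed p-value from a t-test of site-level residuals
#' (observed - predicted) against zero.
#'
#' @param query_sites covariate data.frame carrying the model's schema.
#' @param model an `aps_model` from [fit_singleton_model()].
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param seed optional seed for the bootstrap.
#' @param label optional query-set label carried into the result.
#' @return an `aps_result` list: `label`, `n`, `observed`, `expected`,
#'   `aps`, `ci` (95%), `p_one_tailed`, `degenerate` (TRUE when the query
#'   is too small for a meaningful CI).
#' @export
aps <- function(query_sites, model, n_bootstrap = 100, seed = NULL,
                label = NA_character_) {
  if (!nrow(query_sites)) stop("empty query set")
  pred <- predict_singleton(model, query_sites)
  obs <- as.numeric(query_sites$is_singleton)
  point <- mean(obs) - mean(pred)
  degenerate <- nrow(query_sites) < 2 || stats::sd(obs - pred) == 0
  ci <- c(NA_real_, NA_real_); pval <- NA_real_
  if (!degenerate) {
    pval <- stats::t.test(obs - pred, alternative = "greater")$p.value
  }
  if (!degenerate && n_bootstrap >= 1) {
    boot <- function() {
      reps <- replicate(n_bootstrap, {
        idx <- sample(length(obs), replace = TRUE)
        mean(obs[idx]) - mean(pred[idx])
      })
      stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    }
    ci <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  }
  structure(list(label = label, n = length(obs), observed = mean(obs),
                 expected = mean(pred), aps = point, ci = ci,
                 p_one_tailed = pval, degenerate = degenerate),
            class = "aps_result")
}

#' Paired full-versus-partial element coverage comparison
#'
#' For each noncoding element class, computes APS separately for CNVs that
#' fully cover elements of the class and CNVs that only partially cover
#' them, then runs a two-tailed paired t-test across classes on the
#' (full - partial) APS differences.
#'
#' @param site_covariates covariate data.frame for all candidate CNV sites
#'   (rownames or an `sv_id` column identifying sites).
#' @param element_pairs `element_pairs` data.frame from
#'   [annotate_cohort()] (`sv_id`, `class`, `coverage`).
#' @param model an `aps_model`.
#' @param min_sites minimum sites per (class, coverage) cell (default 5).
#' @return list with `per_class` (class, n_full, n_partial, aps_full,
#'   aps_partial, diff), `t_statistic`, `p_two_tailed`, `n_classes`.
#' @export
aps_full_vs_partial <- function(site_covariates, element_pairs, model,
                                min_sites = 5) {
  sv_id <- site_covariates$sv_id
  if (is.null(sv_id)) sv_id <- rownames(site_covariates)
  rows <- lapply(unique(element_pairs$class), function(cl) {
    full_ids <- unique(element_pairs$sv_id[element_pairs$class == cl &
                                             element_pairs$coverage == "full"])
    part_ids <- setdiff(
      unique(element_pairs$sv_id[element_pairs$class == cl &
                                   element_pairs$coverage == "partial"]),
      full_ids)
    fi <- which(sv_id %in% full_ids); pi <- which(sv_id %in% part_ids)
    if (length(fi) < min_sites || length(pi) < min_sites) return(NULL)
    af <- aps(site_covariates[fi, ], model, n_bootstrap = 0,
              label = paste0(cl, ":full"))
    ap <- aps(site_covariates[pi, ], model, n_bootstrap = 0,
              label = paste0(cl, ":partial"))
    data.frame(class = cl, n_full = length(fi), n_partial = length(pi),
               aps_full = af$aps, aps_partial = ap$aps,
               diff = af$aps - ap$aps, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  if (is.null(per_class) || nrow(per_class) < 2)
    stop("need >= 2 element classes with both full and partial strata")
  tt <- stats::t.test(per_class$aps_full, per_class$aps_partial,
                      paired = TRUE)
  list(per_class = per_class, t_statistic = unname(tt$statistic),
       p_two_tailed = tt$p.value, n_classes = nrow(per_class))
}

#' APS against conservation percentile for noncoding CNVs
#'
#' Each CNV is scored by the sum of conservation-track values it overlaps
#' (track gaps count 0, with a logged warning), CNVs are sorted into
#' `n_bins` percentile bins of that sum, per-bin APS is computed, and the
#' bin rank vs APS association is tested with a two-sided Spearman
#' correlation; a 21-point rolling mean of the bin series is returned for
#' display.
#'
#' @param noncoding_cnvs site data.frame (`chrom`, `start`, `end` plus the
#'   covariate columns of the model and `is_singleton`).
#' @param conservation_track data.frame (`chrom`, `start`, `end`,
#'   `score`).
#' @param model an `aps_model`.
#' @param n_bins percentile bins (default 100).
#' @param rolling rolling-mean window (default 21).
#' @return list with `per_bin` (bin, n, mean_conservation, aps,
#'   rolling_aps), `spearman` (htest or NULL), `flag` (NA or
#'   "constant_conservation").
#' @export
aps_conservation_correlation <- function(noncoding_cnvs,
                                         conservation_track, model,
                                         n_bins = 100, rolling = 21) {
  cs <- conservation_sum(noncoding_cnvs, conservation_track)
  if (any(cs == 0))
    message(sum(cs == 0), " CNV(s) had no conservation-track coverage; ",
            "gaps scored 0")
  if (length(unique(cs)) == 1)
    return(list(per_bin = NULL, spearman = NULL,
                flag = "constant_conservation"))
  bin <- ceiling(rank(cs, ties.method = "first") / length(cs) * n_bins)
  pred <- predict_singleton(model, noncoding_cnvs)
  obs <- as.numeric(noncoding_cnvs$is_singleton)
  per_bin <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(bin = b, n = sum(i), mean_conservation = mean(cs[i]),
               aps = mean(obs[i]) - mean(pred[i]))
  }))
  per_bin$rolling_aps <- rolling_mean(per_bin$aps, rolling)
  sp <- suppressWarnings(stats::cor.test(per_bin$bin, per_bin$aps,
                                         method = "spearman"))
  list(per_bin = per_bin, spearman = sp, flag = NA_character_)
}

#' Serialize / restore an APS model as JSON
#'
#' @param model an `aps_model`. @param path JSON file path.
#' @return `write_aps_model`: `path` invisibly; `read_aps_model`: the
#'   model.
#' @export
write_aps_model <- function(model, path) {
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients), link = model$link,
         covariates = model$covariates, xlevels = model$xlevels,
         diagnostics = model$diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aps_model
#' @export
read_aps_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(j$coefficients), link = j$link,
                 covariates = j$covariates,
                 xlevels = lapply(j$xlevels, as.character),
                 diagnostics = j$diagnostics),
            class = "aps_model")
}
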