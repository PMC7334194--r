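#' Run the full SV population-genetics pipeline
#'
#' Orchestrates every analysis stage over a simulated or loaded cohort and
#' writes a deterministic report bundle: per-stage TSV tables plus a
#' single JSON summary. Given the same configuration and seed, two runs
#' produce byte-identical outputs.
#'
#' @param config list with fields:
#'   \describe{
#'     \item{seed}{integer, required.}
#'     \item{simulate}{TRUE to generate the cohort with
#'       [simulate_cohort()]; FALSE to read `vcf` / `sample_table`.}
#'     \item{sim}{optional list of [sim_config()] overrides.}
#'     \item{n_genes}{genes to simulate (default 2000).}
#'     \item{vcf, sample_table}{input paths when `simulate = FALSE`.}
#'     \item{genes}{gene models (list as from [simulate_gene_models()])
#'       when not simulating.}
#'     \item{stages}{subset of `c("annotate", "popgen", "aps",
#'       "constraint", "metachrom", "cpx", "clinical")` (default: all).}
#'     \item{Ne}{effective population size for mutation-rate projection
#'       (default 10000, logged in the report).}
#'     \item{snv_rare_plof_mean}{per-genome mean of rare pLoF short
#'       variants used for the SV-share calculation (default 16.3, the
#'       companion short-variant estimate scale).}
#'     \item{gd_loci}{optional genomic-disorder locus data.frame.}
#'   }
#' @param out_dir output directory (created); NULL to skip file output.
#' @return the report bundle (list), invisibly when writing files.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.null(config$seed)) stop("config$seed is required")
  stages_all <- c("annotate", "popgen", "aps", "constraint", "metachrom",
                  "cpx", "clinical")
  stages <- if (is.null(config$stages)) stages_all else config$stages
  if (any(c("aps", "constraint", "clinical") %in% stages))
    stages <- union(stages, "annotate")   # downstream stages need it
  ne <- if (is.null(config$Ne)) 10000 else config$Ne
  snv_mean <- if (is.null(config$snv_rare_plof_mean)) 16.3
              else config$snv_rare_plof_mean
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(config = list(seed = config$seed,
                               simulate = isTRUE(config$simulate),
                               stages = stages, Ne = ne,
                               snv_rare_plof_mean = snv_mean))

  # ---- input ------------------------------------------------------------
  genes <- NULL
  need_genes <- any(c("annotate", "aps", "constraint", "clinical") %in%
                      stages)
  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", {
      n_genes <- if (is.null(config$n_genes)) 2000L else config$n_genes
      if (need_genes)
        genes <- simulate_gene_models(n_genes,
                                      seed = derive_seed(config$seed,
                                                         "genes"))
      cfg <- do.call(sim_config, c(config[["sim"]], list(seed = config$seed)))
      simulate_cohort(cfg, genes = genes)
    })
    cohort <- sim$cohort; truth <- sim$truth
  } else {
    cohort <- stage("load", {
      if (is.null(config$vcf)) stop("missing input: vcf")
      read_sv_vcf(config$vcf, config$sample_table)
    })
    genes <- config$genes
    truth <- NULL
  }
  if (need_genes && is.null(genes))
    stop("stage(s) ", paste(intersect(stages,
                                      c("annotate", "constraint")),
                            collapse = "/"),
         " requested but gene models are missing from the configuration")
  analysis <- filter_analysis_sites(cohort)
  n_unrel <- sum(cohort$samples$is_unrelated)
  n_chrom <- 2L * n_unrel
  report$cohort <- list(
    n_sites = nrow(cohort$sites),
    n_analysis_sites = nrow(analysis$sites),
    n_samples = nrow(cohort$samples), n_unrelated = n_unrel,
    class_counts = as.list(table(analysis$sites$svtype)))

  ann <- NULL
  if ("annotate" %in% stages) {
    ann <- stage("annotate", annotate_cohort(analysis, genes,
                                             genes$elements))
    report$annotate <- list(
      n_gene_pairs = nrow(ann$gene_pairs),
      worst_category_counts = as.list(ann$category_counts))
  }

  if ("popgen" %in% stages) {
    report$popgen <- stage("popgen", {
      ss <- site_stats(analysis)
      rare <- mean(ss$af < 0.01)
      very_rare <- mean(ss$af < 0.001)
      singleton <- mean(ss$is_singleton)
      hwe_frac <- mean(ss$hwe_p >= 0.05, na.rm = TRUE)
      per_class <- lapply(split(ss, ss$svtype), function(s) {
        wt <- watterson_theta(nrow(s), n_chrom)
        mr <- sv_mutation_rate(wt, ne,
                               seed = derive_seed(config$seed, "mu"))
        list(K = nrow(s), theta = wt$theta,
             mu_per_generation = mr$per_generation,
             mu_ci = mr$ci)
      })
      wt_all <- watterson_theta(nrow(ss), n_chrom)
      mr_all <- sv_mutation_rate(wt_all, ne,
                                 seed = derive_seed(config$seed, "muall"))
      saf <- size_af_relationship(ss, seed = derive_seed(config$seed,
                                                         "sizeaf"))
      common <- ss$id[ss$af > 0.01]
      pca <- NULL
      if (length(common) >= 10) {
        unrel_idx <- which(cohort$samples$is_unrelated)
        coords <- pca_structure(cohort$gt[unrel_idx, common,
                                          drop = FALSE])$coords
        sil <- if (length(unique(cohort$samples$population[unrel_idx])) > 1)
          label_silhouette(coords,
                           cohort$samples$population[unrel_idx])
        else NA_real_
        pca <- list(n_common_sites = length(common),
                    pc1_silhouette = sil)
      }
      mend <- if (any(!cohort$samples$is_unrelated))
        mendelian_check(cohort) else NULL
      list(singleton_proportion = singleton, pct_rare = 100 * rare,
           pct_very_rare = 100 * very_rare, hwe_fraction = hwe_frac,
           watterson = per_class,
           theta_all = wt_all$theta,
           mu_all_per_generation = mr_all$per_generation,
           mu_all_ci = mr_all$ci,
           size_af_spearman_rho =
             if (!is.null(saf$spearman)) unname(saf$spearman$estimate)
             else NA_real_,
           pca = pca,
           median_mendelian_violation_rate =
             if (!is.null(mend)) mend$median_violation_rate else NA_real_,
           median_de_novo_rate =
             if (!is.null(mend)) mend$median_de_novo_rate else NA_real_)
    })
  }

  burden <- NULL
  if ("annotate" %in% stages) {
    burden <- stage("burden", per_genome_burden(analysis, ann))
    sm <- setNames(burden$summary$mean, burden$summary$metric)
    md <- setNames(burden$summary$median, burden$summary$metric)
    report$burden <- list(
      median_svs_per_genome = unname(md["n_sv"]),
      mean_genes_altered = unname(sm["genes_total"]),
      mean_genes_pLoF = unname(sm["genes_pLoF"]),
      mean_genes_copy_gain = unname(sm["genes_copy_gain"]),
      mean_genes_IED = unname(sm["genes_IED"]),
      mean_rare_genes_altered = unname(sm["genes_total_rare"]),
      sv_share_of_rare_plof_pct = sv_share_of_plof(
        unname(sm["genes_pLoF_rare"]), unname(sm["genes_IED_rare"]),
        snv_mean, include_ied = TRUE),
      sv_share_excl_ied_pct = sv_share_of_plof(
        unname(sm["genes_pLoF_rare"]), unname(sm["genes_IED_rare"]),
        snv_mean, include_ied = FALSE))
  }

  aps_model <- NULL
  if ("aps" %in% stages) {
    report$aps <- stage("aps", {
      ss <- site_stats(analysis)
      cov <- aps_covariates(ss)
      cov$sv_id <- ss$id
      ref <- cov[ann$worst[ss$id] == "intergenic", ]
      aps_model <- fit_singleton_model(ref[setdiff(names(ref), "sv_id")])
      by_cat <- lapply(c("pLoF", "IED", "copy_gain", "intronic",
                         "promoter"), function(cat) {
        q <- cov[ann$worst[ss$id] == cat, ]
        if (nrow(q) < 10) return(NULL)
        r <- aps(q[setdiff(names(q), "sv_id")], aps_model,
                 seed = derive_seed(config$seed, paste0("aps", cat)),
                 label = cat)
        list(label = cat, n = r$n, aps = r$aps, ci = r$ci,
             p_one_tailed = r$p_one_tailed)
      })
      ref_res <- aps(ref[setdiff(names(ref), "sv_id")], aps_model,
                     seed = derive_seed(config$seed, "apsref"),
                     label = "intergenic")
      fp <- tryCatch(
        aps_full_vs_partial(cov, ann$element_pairs, aps_model),
        error = function(e) NULL)
      list(reference_aps = ref_res$aps,
           by_category = Filter(Negate(is.null), by_cat),
           full_vs_partial = if (!is.null(fp))
             list(n_classes = fp$n_classes, t = fp$t_statistic,
                  p = fp$p_two_tailed) else NULL)
    })
  }

  if ("constraint" %in% stages) {
    report$constraint <- stage("constraint", {
      sites <- analysis$sites
      rare_ids <- sites$id[!is.na(sites$af) & sites$af < 0.01]
      gp <- ann$gene_pairs[ann$gene_pairs$sv_id %in% rare_ids, ]
      counts <- lapply(c("pLoF", "copy_gain", "IED"), function(cat) {
        tab <- table(gp$gene_id[gp$category == cat])
        v <- integer(nrow(genes$genes))
        v[match(names(tab), genes$genes$gene_id)] <- as.integer(tab)
        v
      })
      names(counts) <- c("pLoF", "copy_gain", "IED")
      gem <- fit_expected_counts(genes$genes, counts)
      pg <- gem$per_gene[gem$per_gene$category == "pLoF", ]
      bc <- binned_constraint_correlation(pg, genes$genes$constraint_rank)
      list(aggregate_oe = sum(pg$observed) / sum(pg$expected),
           spearman_rho = unname(bc$spearman$estimate),
           spearman_p = bc$spearman$p.value, bin_size = bc$bin_size)
    })
  }

  if ("metachrom" %in% stages) {
    report$metachrom <- stage("metachrom", {
      arm_map <- if (isTRUE(config$simulate)) {
        cfg <- do.call(sim_config, c(config[["sim"]],
                                     list(seed = config$seed)))
        cfg$arm_map
      } else read_arm_map(system.file("extdata", "arm_map_synthetic.tsv",
                                      package = "svpopgen"))
      prof <- profile_enrichment(analysis$sites, arm_map)
      pt <- positional_tests(prof)
      sig <- pt$tests[!is.na(pt$tests$significant) &
                        pt$tests$significant, ]
      list(k = pt$k, adjusted_threshold = pt$adjusted_threshold,
           n_significant = nrow(sig),
           significant = if (nrow(sig))
             paste(sig$svtype, sig$positional_class, sep = ":") else list())
    })
  }

  if ("cpx" %in% stages) {
    report$cpx <- stage("cpx", {
      cpx_sites <- analysis$sites[analysis$sites$svtype == "CPX" &
                                    !is.na(analysis$sites$cpx_structure), ]
      if (!nrow(cpx_sites)) return(list(n = 0))
      cls <- lapply(cpx_sites$cpx_structure, function(s)
        classify_cpx(parse_cpx_intervals(s)))
      labels <- vapply(cls, `[[`, character(1), "label")
      invf <- vapply(cls, `[[`, logical(1), "involves_inversion")
      summ <- subclass_summary(labels, invf, svlen = cpx_sites$svlen,
                               af = cpx_sites$af)
      list(n = nrow(cpx_sites),
           inversion_fraction = summ$inversion_fraction,
           subclass_counts = setNames(as.list(summ$table$n),
                                      summ$table$subclass))
    })
  }

  if ("clinical" %in% stages) {
    report$clinical <- stage("clinical", {
      lr <- large_rare_carrier_rate(analysis)
      gl <- NULL
      if (!is.null(genes)) {
        # stand-in clinical panel: the most SNV-constrained genes
        # (higher rank = more constrained)
        panel <- genes$genes$gene_id[
          genes$genes$constraint_rank > nrow(genes$genes) - 200]
        g <- gene_list_carrier_rate(analysis, ann, panel)
        gl <- list(rate_pct = 100 * g$rate, carriers = g$carriers,
                   n = g$n, qualifying_sites = g$qualifying_sites)
      }
      gd <- NULL
      if (!is.null(config$gd_loci)) {
        gdf <- gd_carrier_frequencies(analysis, config$gd_loci)
        gd <- list(n_loci = length(unique(gdf$locus_id)))
      }
      list(large_rare_carrier_pct = 100 * lr$rate,
           large_rare_ci_pct = 100 * lr$ci,
           balanced_complex_fraction = lr$balanced_complex_fraction,
           constrained_panel = gl, genomic_disorders = gd)
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sv_vcf(cohort, file.path(out_dir, "cohort.vcf"))
    write_sites_bed(cohort, file.path(out_dir, "sites.bed"),
                    worst = if (!is.null(ann)) ann$worst)
    write_sample_table(cohort$samples, file.path(out_dir, "samples.tsv"))
    if (!is.null(truth))
      data.table::fwrite(truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", na = "NA", quote = FALSE)
    if (!is.null(burden))
      data.table::fwrite(burden$per_sample,
                         file.path(out_dir, "burden_per_sample.tsv"),
                         sep = "\t", quote = FALSE)
    if (!is.null(aps_model))
      write_aps_model(aps_model, file.path(out_dir, "aps_model.json"))
    jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
    return(invisible(report))
  }
  report
}
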