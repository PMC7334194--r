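# synthetic reference stratum with a known singleton-probability model
make_ref_sites <- function(n, seed, beta_size = -0.6, base = 0.6) {
  withr::with_seed(seed, {
    svtype <- sample(c("DEL", "DUP", "INS"), n, replace = TRUE)
    svlen <- round(exp(runif(n, log(60), log(5e4))))
    eta <- qlogis(base) + beta_size * (log10(svlen) - 3) +
      ifelse(svtype == "DUP", -0.3, 0)
    data.frame(svtype = svtype, svlen = svlen,
               is_singleton = runif(n) < plogis(eta))
  })
}

test_that("the calibration stratum has APS exactly zero in-sample", {
  ref <- aps_covariates(make_ref_sites(2000, seed = 10))
  model <- fit_singleton_model(ref)
  r <- aps(ref, model, seed = 11)
  expect_equal(r$aps, 0, tolerance = 1e-8)  # ML intercept identity
  expect_true(r$ci[1] <= 0 && r$ci[2] >= 0)
})

test_that("constant covariates collapse to the intercept model", {
  sites <- data.frame(svtype = "DEL", svlen = 1000,
                      is_singleton = rep(c(TRUE, FALSE), c(120, 280)))
  model <- fit_singleton_model(aps_covariates(sites))
  expect_equal(unname(model$coefficients["(Intercept)"]),
               qlogis(0.3), tolerance = 1e-6)
  expect_error(fit_singleton_model(aps_covariates(sites[1:50, ])),
               ">= 200")
})

test_that("the fitted size coefficient recovers the generative value", {
  ref <- aps_covariates(make_ref_sites(20000, seed = 12,
                                       beta_size = -0.6))
  model <- fit_singleton_model(ref)
  # generative: -0.6 per log10 bp
  expect_equal(unname(model$coefficients["log10_size"]), -0.6,
               tolerance = 0.15)
})

test_that("an injected singleton excess of 0.2 is recovered within the CI", {
  ref <- aps_covariates(make_ref_sites(4000, seed = 13))
  model <- fit_singleton_model(ref)
  query <- make_ref_sites(1500, seed = 14)
  qc <- aps_covariates(query)
  pred <- predict_singleton(model, qc)
  keep <- pred + 0.2 < 0.98
  qc <- qc[keep, ]
  qc$is_singleton <- withr::with_seed(15,
                                      runif(nrow(qc)) < pred[keep] + 0.2)
  r <- aps(qc, model, seed = 16)
  expect_lt(abs(r$aps - 0.2), 0.05)
  expect_true(r$ci[1] <= 0.2 + 0.03 && r$ci[2] >= 0.2 - 0.03)
  expect_lt(r$p_one_tailed, 0.001)
})

test_that("degenerate single-site queries are flagged, arithmetic still exact", {
  ref <- aps_covariates(make_ref_sites(1000, seed = 17))
  model <- fit_singleton_model(ref)
  one <- ref[1, ]
  one$is_singleton <- TRUE
  r <- aps(one, model)
  expect_true(r$degenerate)
  expect_equal(r$aps, 1 - predict_singleton(model, one))
  expect_error(aps(ref[0, ], model), "empty")
})

test_that("APS is invariant to query order and id relabelling", {
  ref <- aps_covariates(make_ref_sites(3000, seed = 18))
  model <- fit_singleton_model(ref)
  q <- aps_covariates(make_ref_sites(800, seed = 19))
  a1 <- aps(q, model, n_bootstrap = 0)
  a2 <- aps(q[sample(nrow(q)), ], model, n_bootstrap = 0)
  expect_equal(a1$aps, a2$aps)
})

test_that("schema mismatches are refused at scoring time", {
  ref <- aps_covariates(make_ref_sites(1000, seed = 20))
  model <- fit_singleton_model(ref)
  q <- aps_covariates(data.frame(svtype = "MCNV", svlen = 5000,
                                 is_singleton = FALSE))
  expect_error(aps(q, model), "schema mismatch")
})

test_that("stronger injected selection gives larger APS (monotonicity)", {
  ref <- aps_covariates(make_ref_sites(4000, seed = 21))
  model <- fit_singleton_model(ref)
  aps_at_shift <- function(shift, seed) {
    q <- aps_covariates(make_ref_sites(1200, seed = seed))
    pred <- predict_singleton(model, q)
    keep <- pred + shift < 0.98
    q <- q[keep, ]
    q$is_singleton <- withr::with_seed(seed + 1,
                                       runif(nrow(q)) < pred[keep] + shift)
    aps(q, model, n_bootstrap = 0)$aps
  }
  reps <- vapply(1:20, function(r)
    aps_at_shift(0.25, 1000 + 2 * r) - aps_at_shift(0.1, 2000 + 2 * r),
    numeric(1))
  expect_gt(mean(reps), 0.1)
  expect_gt(mean(reps > 0), 0.9)
})

test_that("full-versus-partial element comparison behaves under null and signal", {
  ref <- aps_covariates(make_ref_sites(3000, seed = 22))
  model <- fit_singleton_model(ref)
  # identical full/partial strata: paired t cannot find a difference
  q <- aps_covariates(make_ref_sites(700, seed = 23))
  q$sv_id <- sprintf("s%04d", seq_len(nrow(q)))
  pairs <- do.call(rbind, lapply(1:14, function(cl) {
    idx <- ((cl - 1) * 50 + 1):(cl * 50)
    data.frame(sv_id = q$sv_id[idx],
               element_id = "e", class = sprintf("class%02d", cl),
               coverage = rep(c("full", "partial"), each = 25))
  }))
  r <- aps_full_vs_partial(q, pairs, model)
  expect_equal(r$n_classes, 14)
  expect_gt(r$p_two_tailed, 0.05)

  # inflate singletons of full-coverage sites: significant positive diff
  qsig <- q
  full_ids <- pairs$sv_id[pairs$coverage == "full"]
  boost <- qsig$sv_id %in% full_ids
  qsig$is_singleton[boost] <- withr::with_seed(24,
    runif(sum(boost)) < pmin(predict_singleton(model, qsig[boost, ]) +
                               0.3, 0.99))
  rs <- aps_full_vs_partial(qsig, pairs, model)
  expect_lt(rs$p_two_tailed, 0.01)
  expect_gt(mean(rs$per_class$diff), 0)
  expect_error(aps_full_vs_partial(q, pairs[pairs$class == "class01", ],
                                   model), ">= 2")
})

test_that("conservation-coupled selection yields a positive Spearman trend", {
  arm <- default_arm_map()
  withr::with_seed(25, {
    n <- 3000
    pos <- svpopgen:::sample_arm_positions(n, arm, 1, 1)
    svlen <- round(exp(runif(n, log(500), log(5000))))
    cnvs <- data.frame(chrom = pos$chrom, start = pos$pos,
                       end = pos$pos + svlen, svtype = "DEL",
                       svlen = svlen, is_singleton = FALSE)
    track <- data.frame(chrom = pos$chrom, start = pos$pos,
                        end = pos$pos + svlen,
                        score = runif(n))
  })
  ref <- aps_covariates(make_ref_sites(3000, seed = 26))
  model <- fit_singleton_model(ref)
  cs <- svpopgen:::conservation_sum(cnvs, track)
  qc <- aps_covariates(cnvs)
  pred <- predict_singleton(model, qc)
  qc$is_singleton <- withr::with_seed(27,
    runif(n) < pmin(pred + 0.3 * rank(cs) / n, 0.99))
  qc <- cbind(qc, cnvs[c("chrom", "start", "end")])
  r <- aps_conservation_correlation(qc, track, model)
  expect_gt(r$spearman$estimate, 0)
  expect_lt(r$spearman$p.value, 0.05)
  expect_equal(nrow(r$per_bin), 100)

  # constant track: correlation undefined, flagged instead of computed
  flat <- track; flat$score <- 0.5
  qc2 <- qc
  # make every CNV cover the same single track interval
  same <- aps_conservation_correlation(
    transform(qc, start = 0, end = 10, chrom = "chrX"),
    data.frame(chrom = "chrX", start = 0, end = 10, score = 1), model)
  expect_equal(same$flag, "constant_conservation")
})

test_that("rolling mean of a constant series is constant", {
  expect_equal(svpopgen:::rolling_mean(rep(0.3, 50), 21), rep(0.3, 50))
})

test_that("APS models survive a JSON round trip", {
  ref <- aps_covariates(make_ref_sites(1000, seed = 28))
  model <- fit_singleton_model(ref)
  path <- tempfile(fileext = ".json")
  write_aps_model(model, path)
  back <- read_aps_model(path)
  expect_equal(predict_singleton(back, ref[1:50, ]),
               predict_singleton(model, ref[1:50, ]), tolerance = 1e-12)
})
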