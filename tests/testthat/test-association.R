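test_that("robust regression: exact fit, OLS agreement, invariances", {
  x <- seq(-1, 1, length.out = 20)
  r <- robust_regress(2 * x, x)
  expect_equal(r$beta, 2, tolerance = 1e-8)
  expect_lt(r$p, 1e-20)
  expect_equal(r$n, 20)

  set.seed(4)
  x <- rnorm(100); y <- 1 + 0.5 * x + rnorm(100, 0, 0.01)
  ols <- coef(lm(y ~ x))[["x"]]
  expect_lt(abs(robust_regress(y, x)$beta - ols), 1e-3)

  base <- robust_regress(y, x)
  shifted <- robust_regress(y + 10, x)
  expect_equal(shifted$beta, base$beta, tolerance = 1e-8)
  expect_equal(shifted$beta0, base$beta0 + 10, tolerance = 1e-6)
  scaled <- robust_regress(3 * y, x)
  expect_equal(scaled$beta, 3 * base$beta, tolerance = 1e-6)

  expect_error(robust_regress(y, rep(1, 100)), "constant")
  expect_error(robust_regress(y[1:3], x[1:3]), "at least 4")
})

test_that("robust-regression p-values are uniform on independent data", {
  set.seed(91)
  p <- replicate(400, robust_regress(rnorm(20), rnorm(20))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("FDR selection is correct at the edges and monotone", {
  res <- data.frame(transcript_id = sprintf("T%04d", 1:1000),
                    p = rep(1, 1000), stringsAsFactors = FALSE)
  expect_length(fdr_select(res), 0)
  res$p[17] <- 1e-9
  expect_identical(fdr_select(res), "T0017")
  set.seed(2)
  res$p <- runif(1000)^1.5
  sel_loose <- fdr_select(res, 0.1)
  sel_tight <- fdr_select(res, 0.01)
  expect_true(all(sel_tight %in% sel_loose))
  expect_error(fdr_select(res, 1.5), "q_threshold")
})

test_that("signal-proportion estimator hits both extremes", {
  set.seed(8)
  expect_lt(estimate_signal_proportion(runif(5000)), 0.05)
  expect_gt(estimate_signal_proportion(runif(5000, 0, 0.001)), 0.99)
  expect_error(estimate_signal_proportion(runif(50)), "at least 100")
  expect_error(estimate_signal_proportion(c(runif(200), 1.5)), "\\[0, 1\\]")
})

test_that("dose-response bins partition observations and track dosage", {
  ## direct bin checks
  tx <- data.frame(transcript_id = c("A", "B"), chrom = "chr1",
                   start = c(100L, 5000L), end = c(2000L, 9000L),
                   unique_alignment = TRUE, stringsAsFactors = FALSE)
  tcn <- structure(list(
    info = data.frame(transcript_id = c("A", "B"), chrom = "chr1",
                      rule = "overlap5", n_snps = 5L, snp_ids = "",
                      stringsAsFactors = FALSE),
    cn = matrix(c(1.0, 4.5, 0.4, 1.5), 2, 2,
                dimnames = list(c("A", "B"), c("S1", "S2"))),
    window_bp = 250000, min_snps = 5), class = "transcript_cn")
  expr <- matrix(0, 2, 2, dimnames = dimnames(tcn$cn))
  dr <- dose_response(expr, tcn)
  expect_equal(dr$n[dr$bin == "no_change"], 1L)
  expect_equal(dr$n[dr$bin == "high_amplification"], 1L)
  expect_equal(dr$n[dr$bin == "high_deletion"], 1L)
  expect_equal(dr$n[dr$bin == "low_amplification"], 1L)
  expect_equal(sum(dr$n), 4L)

  ## with slope 1 everywhere, the high-amplification bin mean exceeds the
  ## no-change bin mean by about the bin's mean log2 ratio
  lay <- simulate_layout(2, 800, 300, seed = 21)
  sim <- simulate_copy_number(lay, 12, noise_sd = 0, seed = 21)
  prof <- cn_profile(lay$snps, log2(sim$truth$snp_ratio),
                     segmented = log2(sim$truth$snp_ratio))
  tcn2 <- infer_transcript_cn(lay, prof)
  ex <- simulate_expression(lay, sim$truth, tcn2, dosage_fraction = 1,
                            beta_mean = 1, noise_sd = 0.05, seed = 21,
                            unexpressed_fraction = 0)
  dr2 <- dose_response(ex$expression, tcn2)
  ratio_all <- tcn2$cn[!is.na(tcn2$cn)]
  expected_gap <- mean(log2(ratio_all[ratio_all > 4])) -
    mean(log2(ratio_all[ratio_all > 0.93 & ratio_all <= 1.07]))
  gap <- dr2$mean[dr2$bin == "high_amplification"] -
    dr2$mean[dr2$bin == "no_change"]
  expect_equal(gap, expected_gap, tolerance = 0.15)
})

test_that("fold-change presentation matches the log2 arithmetic", {
  f <- log2fc_to_fold(-0.8)
  expect_equal(f$fold, 1.7)
  expect_identical(f$direction, "lower")
  expect_equal(log2fc_to_fold(0)$fold, 1.0)
  expect_identical(log2fc_to_fold(0)$direction, "none")
  f2 <- log2fc_to_fold(1.6)
  expect_equal(f2$fold, 3.0)
  expect_identical(f2$direction, "higher")
  expect_equal(log2fc_to_fold(0.7)$fold, 1.6)
})

test_that("genome scan: Bonferroni line and clustered-region detection", {
  ## threshold arithmetic at small M
  start <- seq(1000L, by = 50000L, length.out = 10)
  tx <- data.frame(transcript_id = sprintf("T%02d", 1:10), chrom = "chr1",
                   start = start, end = start + 10000L,
                   unique_alignment = TRUE, stringsAsFactors = FALSE)
  lay <- toy_layout(c(5L, 10L), tx, chrom_len = 1e7)
  res <- data.frame(transcript_id = tx$transcript_id, p = rep(0.5, 10),
                    stringsAsFactors = FALSE)
  rep10 <- genome_scan_report(res, lay, alpha = 0.01)
  expect_equal(rep10$threshold_p, 0.001)
  expect_equal(nrow(rep10$regions), 0)

  ## eight consecutive super-threshold transcripts flanked by nulls
  n <- 30
  start <- seq(1000L, by = 40000L, length.out = n)
  tx <- data.frame(transcript_id = sprintf("T%02d", 1:n), chrom = "chr1",
                   start = start, end = start + 5000L,
                   unique_alignment = TRUE, stringsAsFactors = FALSE)
  lay <- toy_layout(c(5L, 10L), tx, chrom_len = 3e6)
  p <- rep(0.4, n)
  p[11:18] <- 1e-8
  res <- data.frame(transcript_id = tx$transcript_id, p = p,
                    stringsAsFactors = FALSE)
  rep30 <- genome_scan_report(res, lay, alpha = 0.01, cluster_k = 5)
  expect_equal(nrow(rep30$regions), 1)
  expect_identical(rep30$regions$first_transcript, "T11")
  expect_identical(rep30$regions$last_transcript, "T18")
  expect_equal(rep30$regions$n_transcripts, 8L)
})
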