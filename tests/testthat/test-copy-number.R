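test_that("log2 transform is exact and flags bad entries by name", {
  m <- matrix(c(1, 2, 1.07, 0.5), 2, 2,
              dimnames = list(c("SNP1", "SNP2"), c("A", "B")))
  lg <- to_log2_ratio(m)
  expect_equal(lg["SNP1", "A"], 0)
  expect_equal(lg["SNP2", "A"], 1)
  expect_equal(lg["SNP1", "B"], log2(1.07), tolerance = 1e-12)
  expect_equal(round(lg["SNP1", "B"], 4), 0.0976)
  m[2, 2] <- -1
  expect_error(to_log2_ratio(m), "SNP2.*B")
})

test_that("fused lasso: penalty limits and step-signal behavior", {
  y <- c(0.1, -0.2, 0.15, 0.02, -0.1)
  expect_equal(fused_lasso_1d(y, 0, 0), y)
  expect_equal(tv_denoise(rep(2, 10), 100), rep(2, 10))
  ## large fusion penalty fuses everything to the mean
  expect_equal(tv_denoise(y, 100), rep(mean(y), 5), tolerance = 1e-12)
  expect_error(fused_lasso_1d(y, -1, 0), ">= 0")
  expect_error(fused_lasso_1d(y, 0, -1), ">= 0")

  ## 12-point two-level step: matches the generic convex oracle
  set.seed(1)
  y12 <- c(rnorm(6, 0, 0.1), rnorm(6, 1, 0.1))
  for (l2 in c(0.2, 0.5)) for (l1 in c(0, 0.1)) {
    ours <- fused_lasso_1d(y12, l1, l2)
    orac <- fused_lasso_bfgs_oracle(y12, l1, l2)
    expect_lt(abs(fused_lasso_objective(y12, ours, l1, l2) -
                  fused_lasso_objective(y12, orac, l1, l2)), 1e-6)
  }
})

test_that("TV fit is piecewise constant, fuses monotonically, keeps the mean", {
  set.seed(7)
  for (rep in 1:20) {
    y <- rnorm(sample(5:40, 1), sample(c(0, 1), 1), 0.5)
    lams <- sort(runif(3, 0, 2))
    n_levels <- vapply(lams, function(l)
      length(unique(round(tv_denoise(y, l), 9))), numeric(1))
    expect_true(all(n_levels <= length(y)))
    expect_true(all(diff(n_levels) <= 0))        # fewer levels as l2 grows
    expect_equal(mean(tv_denoise(y, lams[2])), mean(y), tolerance = 1e-9)
  }
})

test_that("breakpoints of strong steps are recovered within one SNP", {
  ## step of 4x the noise SD at a known position
  hit <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 60; bp <- 30; sd <- 0.2
    y <- c(rnorm(bp, 0, sd), rnorm(n - bp, 4 * sd, sd))
    lam <- 0.2 * sqrt(2 * log(n)) # sigma known in this construction
    fit <- tv_denoise(y, lam)
    jumps <- which(abs(diff(fit)) > sd)
    if (length(jumps) >= 1 && any(abs(jumps - bp) <= 1)) hit <- hit + 1
  }
  expect_gte(hit, 95)
})

test_that("segment_fused_lasso works per chromosome and sample", {
  lay <- simulate_layout(2, 200, 10, seed = 1)
  sim <- simulate_copy_number(lay, 3, noise_sd = 0.2, seed = 1)
  prof <- cn_profile(lay$snps, to_log2_ratio(sim$ratios))
  seg <- segment_fused_lasso(prof)
  expect_identical(dim(seg$segmented), dim(seg$log2_ratios))
  ## chromosomes are independent: segmenting one chromosome alone agrees
  idx <- which(lay$snps$chrom == "chr1")
  sub_lay_snps <- lay$snps[idx, ]
  sub <- cn_profile(sub_lay_snps, prof$log2_ratios[idx, , drop = FALSE])
  seg_sub <- segment_fused_lasso(sub)
  expect_equal(seg_sub$segmented, seg$segmented[idx, , drop = FALSE])
  expect_error(segment_fused_lasso(prof, lambda_sparsity = -1), ">= 0")
})

test_that("gain/loss calls follow the ratio thresholds of both presets", {
  snps <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(0L, 10L, 20L), stringsAsFactors = FALSE)
  seg <- matrix(log2(c(1.0, 0.5, 1.2)), 3, 1,
                dimnames = list(snps$snp_id, "S1"))
  prof <- cn_profile(snps, seg, segmented = seg)

  low <- call_cna(prof, 0.93, 1.07)
  expect_equal(unname(low$calls[, 1]), c("neutral", "loss", "gain"))
  str <- do.call(call_cna, c(list(prof), as.list(cna_thresholds("stringent"))))
  expect_equal(unname(str$calls[, 1]), c("neutral", "loss", "neutral"))
  expect_error(call_cna(prof, 1.2, 1.07), "lower")
  expect_error(call_cna(cn_profile(snps, seg), 0.93, 1.07), "not segmented")
})

test_that("genome altered fraction: limits and recovery of planted burden", {
  snps <- data.frame(snp_id = sprintf("s%d", 1:4), chrom = "chr1",
                     pos = c(0L, 5L, 10L, 15L), stringsAsFactors = FALSE)
  mk <- function(v) {
    m <- matrix(log2(v), 4, 1, dimnames = list(snps$snp_id, "S1"))
    call_cna(cn_profile(snps, m, segmented = m))
  }
  expect_equal(unname(genome_altered_fraction(mk(rep(1, 4)))), 0)
  expect_equal(unname(genome_altered_fraction(mk(rep(3, 4)))), 1)

  ## planted 40% altered genome, low noise
  lay <- simulate_layout(2, 1000, 10, seed = 4)
  sim <- simulate_copy_number(lay, 4, segment_rate = 0.15, noise_sd = 0.1,
                              seed = 4,
                              level_values = c(0.5, 1, 2),
                              level_probs = c(0.2, 0.6, 0.2))
  truth_altered <- colMeans(sim$truth$snp_ratio != 1)
  prof <- segment_fused_lasso(cn_profile(lay$snps, to_log2_ratio(sim$ratios)))
  est <- genome_altered_fraction(call_cna(prof))
  expect_true(all(abs(est - truth_altered) <= 0.05))
})
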