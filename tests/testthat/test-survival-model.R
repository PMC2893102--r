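test_that("PC summary: variance, orthogonality, eigen oracle, sign fix", {
  ## rank-1 matrix: first component explains essentially all variance
  set.seed(3)
  u <- rnorm(12); v <- rnorm(6)
  m1 <- outer(v, u) + matrix(rnorm(72, 0, 1e-6), 6, 12)
  dimnames(m1) <- list(sprintf("T%d", 1:6), sprintf("S%02d", 1:12))
  pc1 <- pc_scores(m1, rownames(m1), 2)
  expect_gt(pc1$var_explained[1], 0.999)
  expect_lt(abs(sum(pc1$loadings[, 1] * pc1$loadings[, 2])), 1e-10)
  expect_true(all(abs(colMeans(pc1$scores)) < 1e-9))

  ## brute-force eigendecomposition oracle on a 6 x 4 toy
  m <- matrix(rnorm(24), 6, 4,
              dimnames = list(sprintf("T%d", 1:6), sprintf("S%d", 1:4)))
  pc <- pc_scores(m, rownames(m), 2)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x) / (nrow(x) - 1))
  for (k in 1:2) {
    w <- ev$vectors[, k]
    w <- w * sign(w[which.max(abs(w))])     # same sign convention
    expect_equal(unname(pc$loadings[, k]), unname(w), tolerance = 1e-8)
    expect_equal(unname(pc$scores[, k]), unname(as.vector(x %*% w)),
                 tolerance = 1e-8)
  }
  ## sign convention: largest-magnitude loading element is positive
  expect_true(all(apply(pc$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  expect_error(pc_scores(m, rownames(m)[1], 2), "rank|exceeds")
})

test_that("Cox fits: recovery, CI coverage under the null, degeneracies", {
  ## planted stage effect with HR = 2 per stage unit
  cl <- simulate_clinical(150, 0, transcript_ids = "T1", seed = 42,
                          stage_hr = 2, censor_rate = 0.01, de_shift = 0,
                          nonspecific_death_frac = 0)
  cases <- cl$clinical[cl$clinical$case == 1, ]
  d <- data.frame(time = cases$followup_months, event = cases$oscc_death,
                  stage = cases$stage, noise = rnorm(150))
  fit <- fit_cox(d, "stage")
  expect_true(abs(fit$table$coef - log(2)) <= 2 * fit$table$se)
  expect_true(all(fit$table$hr > 0))
  expect_equal(fit$table$hr_lo, exp(fit$table$coef - 1.96 * fit$table$se))

  ## null covariate: 95% CI covers HR = 1 in most replicates
  covers <- 0
  for (s in 1:40) {
    cs <- simulate_clinical(100, 0, transcript_ids = "T1", seed = 100 + s,
                            censor_rate = 0.02, de_shift = 0)
    cc <- cs$clinical[cs$clinical$case == 1, ]
    dd <- data.frame(time = cc$followup_months, event = cc$oscc_death,
                     x = rnorm(100))
    tab <- fit_cox(dd, "x")$table
    if (tab$hr_lo <= 1 && tab$hr_hi >= 1) covers <- covers + 1
  }
  expect_gte(covers, 33)   # about 95%, with binomial slack at 40 replicates

  d0 <- d; d0$event <- 0
  expect_error(fit_cox(d0, "stage"), "no events")
  dconst <- d; dconst$stage <- 2
  expect_error(fit_cox(dconst, "stage"), "degenerate|constant")
})

test_that("jackknife risk scores equal direct leave-one-out refits", {
  set.seed(9)
  n <- 12
  d <- data.frame(time = round(rexp(n, 0.05), 1) + 1,
                  event = rbinom(n, 1, 0.7),
                  stage = sample(1:4, n, TRUE), x = rnorm(n))
  sc <- jackknife_risk_scores(d, c("stage", "x"))
  expect_length(sc, n)
  for (i in seq_len(n)) {
    refit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ stage + x,
                      data = d[-i, ], ties = "efron"))
    expect_equal(unname(sc[i]),
                 sum(coef(refit) * c(d$stage[i], d$x[i])),
                 tolerance = 1e-10)
  }
  ## permutation invariance up to subject order
  perm <- sample(n)
  sc_perm <- jackknife_risk_scores(d[perm, ], c("stage", "x"))
  expect_equal(unname(sc_perm), unname(sc[perm]), tolerance = 1e-10)
  expect_error(jackknife_risk_scores(d[1:5, ], "x"), "at least 10")
})

test_that("time-dependent ROC: limits and the uncensored empirical oracle", {
  set.seed(21)
  n <- 80
  time <- rexp(n, 0.05); event <- rep(1, n)
  ## null score
  roc0 <- time_dependent_roc(rnorm(n), time, event, 15)
  expect_gt(roc0$auc, 0.3); expect_lt(roc0$auc, 0.7)
  ## a score that perfectly orders event times
  roc1 <- time_dependent_roc(-time, time, event, 15)
  expect_equal(roc1$auc, 1, tolerance = 1e-9)

  ## uncensored toy: equals the empirical ROC of cases vs controls
  t10 <- c(3, 8, 12, 20, 26, 31, 7, 15, 40, 22)
  s10 <- c(2.5, 1.9, 1.2, 0.3, -0.5, -1, 2.2, 0.8, -2, 0.1)
  r <- time_dependent_roc(s10, t10, rep(1, 10), landmark = 24)
  expect_equal(r$auc, empirical_roc_auc(s10, t10 <= 24), tolerance = 1e-9)

  ## invariant under strictly increasing transforms of the score
  r2 <- time_dependent_roc(exp(s10), t10, rep(1, 10), landmark = 24)
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)

  expect_error(time_dependent_roc(s10, t10 + 100, rep(1, 10), landmark = 24),
               "no events")
})

test_that("internal Kaplan-Meier evaluator matches survival::survfit", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 40
    time <- round(rexp(n, 0.04), 1) + 0.1
    event <- rbinom(n, 1, 0.6)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    for (t in c(5, 12, 30)) {
      s_ref <- summary(sf, times = t, extend = TRUE)$surv
      expect_equal(cnexpress:::km_surv_at(time, event, t), s_ref,
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC comparison: self-comparison, determinism, informative score", {
  set.seed(55)
  n <- 100
  risk <- rnorm(n)
  time <- rexp(n, 0.04 * exp(1.2 * risk)); event <- rbinom(n, 1, 0.9)
  self <- compare_auc(risk, risk, time, event, landmark = 15, B_boot = 200,
                      seed = 3)
  expect_equal(self$diff, 0)
  expect_equal(self$p, 1)
  ## determinism under a fixed seed
  set.seed(999); noise <- rnorm(n)
  c1 <- compare_auc(risk, noise, time, event, 15, B_boot = 300, seed = 7)
  c2 <- compare_auc(risk, noise, time, event, 15, B_boot = 300, seed = 7)
  expect_identical(c1, c2)
  ## a strongly informative score beats noise
  expect_gt(c1$auc_a, c1$auc_b)
  expect_lt(c1$p, 0.05)
  expect_error(compare_auc(risk[1:10], risk, time, event, 15), "same subjects")
})
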