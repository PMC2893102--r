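test_that("case/control Z equals the regression t-statistic exactly", {
  ## hand-checkable toy: Z^2 must equal the lm F-statistic on 1 df
  expr <- rbind(T1 = c(0.1, -0.2, 0.05, 1.1, 0.9, 1.3),
                T2 = c(5, 5.2, 4.9, 5.1, 5.0, 5.05))
  status <- c(0, 0, 0, 1, 1, 1)
  scr <- casecontrol_screen(expr, status, z_cutoff = 2)
  for (i in 1:2) {
    fit <- lm(expr[i, ] ~ status)
    tval <- summary(fit)$coefficients["status", "t value"]
    expect_equal(scr$cc_z[i], tval, tolerance = 1e-10)
    expect_equal(scr$cc_z[i]^2, summary(fit)$fstatistic[["value"]],
                 tolerance = 1e-8)
  }
  expect_true(scr$cc_flag[1])
  expect_false(scr$cc_flag[2])

  ## identical group distributions give Z near zero
  set.seed(10)
  e0 <- matrix(rnorm(600), 3, 200,
               dimnames = list(c("A", "B", "C"), sprintf("S%d", 1:200)))
  z0 <- casecontrol_screen(e0, rep(c(0, 1), each = 100))$cc_z
  expect_true(all(abs(z0) < 4))
  expect_error(casecontrol_screen(e0, rep(1, 200)), "both")
})

test_that("survival screen: null calibration, cohort rule, degeneracies", {
  set.seed(14)
  n <- 150
  ids <- sprintf("P%03d", 1:n)
  expr <- matrix(rnorm(150 * n), 150, n,
                 dimnames = list(sprintf("T%03d", 1:150), ids))
  clinical <- data.frame(
    sample_id = ids, age = round(runif(n, 30, 80)),
    sex = rbinom(n, 1, 0.5),
    followup_months = round(rexp(n, 0.04) + 0.5, 1),
    oscc_death = rbinom(n, 1, 0.4), stringsAsFactors = FALSE)

  scr <- survival_screen(expr, clinical)
  ## expression is independent of survival: Z approximately N(0, 1)
  expect_lt(abs(mean(scr$surv_z)), 0.2)
  expect_gt(sd(scr$surv_z), 0.8)
  expect_lt(sd(scr$surv_z), 1.2)
  ## the follow-up rule drops short-follow-up subjects
  expect_equal(attr(scr, "n_used"),
               sum(clinical$followup_months >= 4))

  none <- clinical; none$oscc_death <- 0
  expect_error(survival_screen(expr, none), "no cause-specific events")
  flat <- clinical; flat$followup_months <- 12; flat$oscc_death <- 0
  expect_error(survival_screen(expr, flat), "events|degenerate")
})

test_that("survival screen recovers a planted hazard ratio", {
  ## single risk transcript with true log-HR = log(2)
  covered <- 0
  for (s in 1:60) {
    cl <- simulate_clinical(150, 0, transcript_ids = c("R1", "N1"),
                            risk_transcripts = "R1", hr_per_unit = 2,
                            censor_rate = 0.01, seed = s, de_shift = 0,
                            stage_hr = 1, nonspecific_death_frac = 0)
    cases <- cl$clinical[cl$clinical$case == 1, ]
    d <- data.frame(time = cases$followup_months, event = cases$oscc_death,
                    x = cl$expression["R1", cases$sample_id],
                    age = cases$age, sex = cases$sex)
    fit <- survival::coxph(survival::Surv(time, event) ~ x + age + sex,
                           data = d, ties = "efron")
    est <- coef(fit)[["x"]]
    se <- sqrt(diag(vcov(fit)))[["x"]]
    if (abs(est - log(2)) <= 2 * se) covered <- covered + 1
  }
  expect_gte(covered, 54)  # 90% of replicates
})

test_that("permutation enrichment: edge cases and exhaustive agreement", {
  set.seed(6)
  z <- setNames(rnorm(40), sprintf("T%02d", 1:40))
  top <- names(sort(abs(z), decreasing = TRUE))[1:5]
  B <- 1000
  enr <- permutation_enrichment(top, z, B = B, statistic = "mean_abs",
                                seed = 1)
  expect_equal(enr$empirical_p, 1 / (B + 1))

  ## tiny universe: compare against complete enumeration of all 56 subsets
  z8 <- setNames(c(3.2, 2.8, 2.5, 0.1, -0.2, 0.4, -0.5, 0.3),
                 sprintf("G%d", 1:8))
  cand <- c("G1", "G2", "G3")
  combos <- combn(names(z8), 3)
  null_all <- apply(combos, 2, function(s) mean(abs(z8[s])))
  obs <- mean(abs(z8[cand]))
  p_exact <- mean(null_all >= obs)
  enr8 <- permutation_enrichment(cand, z8, B = 4000, statistic = "mean_abs",
                                 seed = 2)
  expect_lt(abs(enr8$empirical_p - p_exact), 0.05)

  ## p is never zero and candidate relabeling outside the set is irrelevant
  expect_gt(enr8$empirical_p, 0)
  z_relab <- z8
  names(z_relab)[4:8] <- sprintf("H%d", 1:5)
  enr_relab <- permutation_enrichment(cand, z_relab, B = 4000,
                                      statistic = "mean_abs", seed = 2)
  expect_equal(enr_relab$empirical_p, enr8$empirical_p)

  expect_error(permutation_enrichment(sprintf("G%d", 1:9), z8, B = 100),
               "larger|missing")
  expect_error(permutation_enrichment(cand, z8, B = 50), "at least 100")
  expect_error(permutation_enrichment(cand, unname(z8), B = 100), "named")
})

test_that("enrichment p is uniform when the candidate set is random", {
  set.seed(77)
  z <- setNames(rnorm(300), sprintf("T%03d", 1:300))
  p <- replicate(200, {
    cand <- sample(names(z), 30)
    permutation_enrichment(cand, z, B = 199, statistic = "mean_abs",
                           seed = sample.int(1e6, 1))$empirical_p
  })
  ## the +1-corrected p lives on a grid of 200 values, so ties are expected
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})
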