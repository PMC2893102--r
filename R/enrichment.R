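## Screening of copy-number-associated transcripts in an independent
## case/control cohort: differential-expression Z-scores, age/sex-adjusted
## survival Z-scores, and permutation enrichment against random same-size
## transcript sets.

#' Case/control differential-expression Z-scores
#'
#' Per transcript, the Z-score of the slope from least-squares regression of
#' expression on the 0/1 case indicator (identical to the pooled-variance
#' two-sample t-statistic). Computed in closed form for all transcripts at
#' once.
#'
#' @param expr expression matrix (transcripts x samples).
#' @param status 0/1 case indicator per sample (both classes non-empty).
#' @param z_cutoff flag threshold (default 6).
#' @param signed if `FALSE` (default) the flag uses `|Z| > z_cutoff`; if
#'   `TRUE`, only over-expression in cases (`Z > z_cutoff`) is flagged.
#' @return data frame: transcript_id, cc_z, cc_flag.
#' @export
casecontrol_screen <- function(expr, status, z_cutoff = 6, signed = FALSE) {
  stopifnot(is.matrix(expr), length(status) == ncol(expr))
  status <- as.numeric(status)
  if (length(unique(status)) < 2L)
    stop_arg("both cases and controls are required")
  n <- length(status)
  xc <- status - mean(status)
  sxx <- sum(xc^2)
  beta <- as.vector(expr %*% xc) / sxx
  yc <- expr - rowMeans(expr)
  syy <- rowSums(yc^2)
  s2 <- pmax(syy - beta^2 * sxx, 0) / (n - 2)
  se <- sqrt(s2 / sxx)
  z <- ifelse(se > 0, beta / se, 0)
  flag <- if (signed) z > z_cutoff else abs(z) > z_cutoff
  data.frame(transcript_id = rownames(expr), cc_z = z, cc_flag = flag,
             stringsAsFactors = FALSE)
}

#' Survival Z-scores adjusted for age and sex
#'
#' Restricts the cohort to subjects with at least `min_followup` months of
#' follow-up (removing early deaths likelier to reflect co-morbidity than
#' tumor biology) and, per transcript, fits a Cox proportional-hazards model
#' of cause-specific survival on expression, age and a sex dummy. Deaths
#' from other causes are censored.
#'
#' @param expr expression matrix (transcripts x samples).
#' @param clinical data frame with sample_id, age, sex, followup_months,
#'   oscc_death for the samples to screen (cases only).
#' @param min_followup months of follow-up required (default 4).
#' @param z_cutoff flag threshold on `|Z|` (default 1.96).
#' @return data frame: transcript_id, surv_z, surv_flag; the subset size and
#'   event count are attached as attributes `n_used` and `n_events`.
#' @export
survival_screen <- function(expr, clinical, min_followup = 4,
                            z_cutoff = 1.96) {
  stopifnot(is.matrix(expr))
  cl <- clinical[clinical$sample_id %in% colnames(expr), , drop = FALSE]
  cl <- cl[!is.na(cl$followup_months) & cl$followup_months >= min_followup, ,
           drop = FALSE]
  if (nrow(cl) == 0L) stop_arg("no subjects with sufficient follow-up")
  ev <- cl$oscc_death
  if (sum(ev) == 0L)
    stop_arg("no cause-specific events after follow-up filtering; screen aborted")
  if (length(unique(cl$followup_months)) == 1L && all(ev == 0))
    stop_arg("all subjects censored at the same time: degenerate cohort")
  e <- expr[, cl$sample_id, drop = FALSE]
  surv <- survival::Surv(cl$followup_months, ev)
  z <- vapply(seq_len(nrow(e)), function(i) {
    fit <- tryCatch(
      survival::coxph(surv ~ e[i, ] + cl$age + cl$sex, ties = "efron"),
      error = function(err) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(surv ~ e[i, ] + cl$age + cl$sex,
                                         ties = "efron"))
      })
    if (is.null(fit)) return(NA_real_)
    s <- summary(fit)$coefficients
    s[1, "z"]
  }, numeric(1))
  out <- data.frame(transcript_id = rownames(e), surv_z = z,
                    surv_flag = !is.na(z) & abs(z) > z_cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "n_used") <- nrow(cl)
  attr(out, "n_events") <- sum(ev)
  out
}

#' Permutation enrichment of a transcript set against screen Z-scores
#'
#' Compares a candidate set's Z-score distribution with that of `B` random
#' transcript sets of the same size drawn without replacement from the
#' screened universe. The default statistic counts set members whose `|Z|`
#' exceeds `cutoff` (matching the downstream cutoff-based selections);
#' `"mean_abs"` and `"ks"` (Kolmogorov-Smirnov distance between the set and
#' its complement) are alternatives. The empirical p-value uses the +1
#' correction and is therefore never zero.
#'
#' @param candidate character vector of transcript ids (subset of
#'   `names(all_z)`).
#' @param all_z named vector of screen Z-scores for the whole universe.
#' @param B number of random sets (>= 100; default 1000).
#' @param statistic `"count_exceed"`, `"mean_abs"` or `"ks"`.
#' @param cutoff `|Z|` cutoff for `"count_exceed"` (default 6).
#' @param seed integer seed.
#' @return list of class `enrichment_test`: observed statistic, null
#'   statistics, empirical p and settings.
#' @export
permutation_enrichment <- function(candidate, all_z, B = 1000,
                                   statistic = c("count_exceed", "mean_abs",
                                                 "ks"),
                                   cutoff = 6, seed = 1) {
  statistic <- match.arg(statistic)
  B <- check_count(B, "B")
  if (B < 100L) stop_arg("`B` must be at least 100")
  universe <- names(all_z)
  if (is.null(universe)) stop_arg("`all_z` must be a named vector")
  if (!all(candidate %in% universe))
    stop_arg("candidate transcripts missing from the screened universe")
  m <- length(candidate)
  if (m > length(universe)) stop_arg("candidate set larger than the universe")
  keep <- !is.na(all_z)
  all_z <- all_z[keep]
  universe <- names(all_z)
  candidate <- intersect(candidate, universe)
  m <- length(candidate)

  stat_fun <- switch(statistic,
    count_exceed = function(z_set, z_rest) sum(abs(z_set) > cutoff),
    mean_abs = function(z_set, z_rest) mean(abs(z_set)),
    ks = function(z_set, z_rest)
      suppressWarnings(stats::ks.test(z_set, z_rest)$statistic))

  observed <- stat_fun(all_z[candidate], all_z[setdiff(universe, candidate)])
  set.seed(derive_seed(seed, 5L))
  null_stats <- vapply(seq_len(B), function(b) {
    s <- sample(universe, m)
    stat_fun(all_z[s], all_z[setdiff(universe, s)])
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (B + 1)
  structure(list(statistic = statistic, observed = unname(observed),
                 null_statistics = unname(null_stats), empirical_p = p,
                 set_size = m, B = B, cutoff = cutoff),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("enrichment_test (%s): observed %.4g, empirical p = %.4g (B = %d, set size %d)\n",
              x$statistic, x$observed, x$empirical_p, x$B, x$set_size))
  invisible(x)
}
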