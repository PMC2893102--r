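## PC-summary risk scores over a transcript set, Cox models, jackknife
## leave-one-out risk scores, and 2-year time-dependent ROC comparison.

#' Principal-component scores over a transcript set
#'
#' PCA of the samples x selected-transcripts matrix after per-transcript
#' centering. The sign of each loading vector is fixed so that its
#' largest-magnitude element is positive, making the decomposition
#' deterministic.
#'
#' @param expr expression matrix (transcripts x samples).
#' @param transcript_set ids of the transcripts to summarize.
#' @param n_components number of components to keep (default 2).
#' @return object of class `pc_summary`: loadings (transcripts x components),
#'   scores (samples x components, centered), variance explained.
#' @export
pc_scores <- function(expr, transcript_set, n_components = 2) {
  n_components <- check_count(n_components, "n_components")
  missing <- setdiff(transcript_set, rownames(expr))
  if (length(missing))
    stop_arg("transcripts not in expression matrix: %s",
             paste(utils::head(missing, 3), collapse = ", "))
  x <- t(expr[transcript_set, , drop = FALSE])   # samples x transcripts
  if (n_components > min(dim(x)))
    stop_arg("`n_components` exceeds the matrix rank bound")
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pca$rotation[, seq_len(n_components), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(pca$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(transcript_set = transcript_set, loadings = load,
                 scores = scores,
                 var_explained = ve[seq_len(n_components)]),
            class = "pc_summary")
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximization with Efron handling of ties. AJCC stage,
#' when used, is coded as a continuous integer 1-4.
#'
#' @param clinical data frame with columns `time`, `event` and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @return list with `fit` (the coxph object) and `table` (term, coef, se,
#'   z, p, hr and 95% CI).
#' @export
fit_cox <- function(clinical, covariates) {
  if (!all(c("time", "event") %in% names(clinical)))
    stop_arg("`clinical` must contain `time` and `event` columns")
  if (sum(clinical$event) < 1) stop_arg("no events: cannot fit a Cox model")
  const <- covariates[vapply(covariates, function(v)
    length(unique(clinical[[v]])) < 2L, logical(1))]
  if (length(const))
    stop_arg("degenerate covariate(s) constant across subjects: %s",
             paste(const, collapse = ", "))
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = clinical, ties = "efron")
  if (any(is.na(stats::coef(fit))))
    warning("collinear covariates: some coefficients are NA", call. = FALSE)
  s <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(s), coef = s[, "coef"],
                    se = s[, "se(coef)"], z = s[, "z"],
                    p = s[, "Pr(>|z|)"], hr = exp(s[, "coef"]),
                    hr_lo = exp(s[, "coef"] - 1.96 * s[, "se(coef)"]),
                    hr_hi = exp(s[, "coef"] + 1.96 * s[, "se(coef)"]),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(fit = fit, table = tab)
}

#' Jackknife leave-one-out risk scores
#'
#' For each subject, the Cox model is refit on all other subjects and the
#' held-out subject's risk score is the linear predictor
#' `sum(coef * covariates)` under that fit (NA coefficients from degenerate
#' refits contribute zero). Exactly one score per subject.
#'
#' @param clinical data frame with `time`, `event` and covariates.
#' @param covariates character vector of covariate column names.
#' @return numeric vector of risk scores, named by rownames of `clinical`
#'   (or sample_id when present).
#' @export
jackknife_risk_scores <- function(clinical, covariates) {
  n <- nrow(clinical)
  if (n < 10L) stop_arg("need at least 10 subjects for the jackknife")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  x <- as.matrix(clinical[, covariates, drop = FALSE])
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      suppressWarnings(survival::coxph(f, data = clinical[-i, , drop = FALSE],
                                       ties = "efron")),
      error = function(e)
        stop_arg("leave-one-out Cox fit failed when holding out subject %d: %s",
                 i, conditionMessage(e)))
    b <- stats::coef(fit)
    b[is.na(b)] <- 0
    scores[i] <- sum(b * x[i, ])
  }
  nm <- if ("sample_id" %in% names(clinical)) clinical$sample_id
        else rownames(clinical)
  stats::setNames(scores, nm)
}

#' Time-dependent (cumulative/dynamic) ROC at a landmark time
#'
#' Kaplan-Meier-based estimator of the cumulative-case / dynamic-control ROC
#' of Heagerty, Lumley and Pepe (2000, Biometrics), without nearest-neighbor
#' smoothing: at landmark `t`, sensitivity at cutpoint `c` is
#' `(1 - S(t | score > c)) P(score > c) / (1 - S(t))` and the false-positive
#' rate is `S(t | score > c) P(score > c) / S(t)`, with the conditional
#' survival estimated by Kaplan-Meier within `score > c`. With no censoring
#' this reduces to the empirical ROC of subjects with events by `t` against
#' subjects event-free beyond `t`. AUC is the trapezoid rule over the curve.
#'
#' @param scores per-subject risk scores (higher = riskier).
#' @param time,event follow-up time and event indicator.
#' @param landmark evaluation time (same units as `time`).
#' @return list with `roc` (data frame: cutoff, fpr, tpr) and `auc`.
#' @export
time_dependent_roc <- function(scores, time, event, landmark) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  if (!any(event > 0 & time <= landmark))
    stop_arg("no events before the landmark time")
  s_marg <- km_surv_at(time, event, landmark)
  if (s_marg >= 1 || s_marg <= 0)
    stop_arg("marginal survival at the landmark is degenerate")
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- numeric(length(cuts))
  fpr <- numeric(length(cuts))
  for (k in seq_along(cuts)) {
    sel <- scores > cuts[k]
    if (!any(sel)) { tpr[k] <- 0; fpr[k] <- 0; next }
    pc <- mean(sel)
    s_c <- km_surv_at(time[sel], event[sel], landmark)
    tpr[k] <- (1 - s_c) * pc / (1 - s_marg)
    fpr[k] <- s_c * pc / s_marg
  }
  roc <- data.frame(cutoff = c(Inf, cuts, -Inf),
                    fpr = pmin(pmax(c(0, fpr, 1), 0), 1),
                    tpr = pmin(pmax(c(0, tpr, 1), 0), 1))
  roc <- roc[order(roc$fpr, roc$tpr), ]
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Compare two models' landmark AUCs by paired bootstrap
#'
#' Resamples subjects with replacement, recomputes both time-dependent AUCs
#' on each bootstrap sample, and reports the observed AUC difference
#' (a - b) with a two-sided +1-corrected p-value from the fraction of
#' bootstrap differences crossing zero.
#'
#' @param scores_a,scores_b risk scores for the same subjects.
#' @param time,event follow-up and event indicator.
#' @param landmark evaluation time.
#' @param B_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return list with `auc_a`, `auc_b`, `diff`, `p`, `B_used`.
#' @export
compare_auc <- function(scores_a, scores_b, time, event, landmark,
                        B_boot = 2000, seed = 1) {
  if (length(scores_a) != length(scores_b))
    stop_arg("score vectors must cover the same subjects")
  n <- length(time)
  auc_a <- time_dependent_roc(scores_a, time, event, landmark)$auc
  auc_b <- time_dependent_roc(scores_b, time, event, landmark)$auc
  set.seed(derive_seed(seed, 6L))
  diffs <- rep(NA_real_, B_boot)
  for (b in seq_len(B_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (!any(event[idx] > 0 & time[idx] <= landmark)) next
    if (km_surv_at(time[idx], event[idx], landmark) <= 0) next
    da <- time_dependent_roc(scores_a[idx], time[idx], event[idx], landmark)$auc
    db <- time_dependent_roc(scores_b[idx], time[idx], event[idx], landmark)$auc
    diffs[b] <- da - db
  }
  diffs <- diffs[!is.na(diffs)]
  B_used <- length(diffs)
  if (B_used < 10L) stop_arg("too few valid bootstrap replicates")
  p <- min(1, 2 * (1 + min(sum(diffs <= 0), sum(diffs >= 0))) / (B_used + 1))
  list(auc_a = auc_a, auc_b = auc_b, diff = auc_a - auc_b, p = p,
       B_used = B_used)
}
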