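## Per-transcript dosage testing: robust regression of expression on log2
## copy number, FDR selection, signal-proportion estimation, dose-response
## bins and genome-scan reporting.

#' Robust regression of expression on copy number for one transcript
#'
#' Fits `Y = b0 + b*X + e` by iteratively reweighted least squares with the
#' Huber psi (tuning constant 1.345) and MAD re-estimation of scale, as in
#' [MASS::rlm()]. The two-sided p-value for `b = 0` uses the t-statistic with
#' `N - 2` degrees of freedom. The plain Pearson correlation of `x` and `y`
#' is reported alongside.
#'
#' @param y expression vector; @param x copy-number vector (log2 scale).
#' @return one-row data frame: beta0, beta, se, t, p, r, n.
#' @export
robust_regress <- function(y, x) {
  n <- length(y)
  if (length(x) != n) stop_arg("`y` and `x` must have the same length")
  if (n < 4L) stop_arg("need at least 4 paired observations")
  if (stats::sd(x) == 0) stop_arg("`x` is constant: degenerate predictor")
  fit <- suppressWarnings(
    MASS::rlm(x = cbind(1, x), y = y, psi = MASS::psi.huber, k = 1.345,
              scale.est = "MAD", maxit = 50, acc = 1e-8))
  beta <- unname(stats::coef(fit))
  ## se of coefficients from the IRLS fit, as summary.rlm computes it
  sm <- summary(fit, method = "XtX")
  se <- sm$coefficients[2, "Std. Error"]
  tstat <- beta[2] / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  data.frame(beta0 = beta[1], beta = beta[2], se = se, t = tstat, p = p,
             r = stats::cor(x, y), n = n)
}

#' Dosage test for every transcript
#'
#' Runs [robust_regress()] of each transcript's (renormalized) expression on
#' its log2 copy-number ratio and appends Benjamini-Hochberg q-values.
#' Transcripts without copy number (unmapped) or with a constant predictor
#' are returned with NA statistics.
#'
#' @param expr expression matrix (transcripts x samples).
#' @param tcn a `transcript_cn` object on the same samples.
#' @return data frame (one row per transcript): transcript_id, beta, se, t,
#'   p, q, r, n.
#' @export
associate_all <- function(expr, tcn) {
  stopifnot(inherits(tcn, "transcript_cn"))
  ids <- intersect(rownames(expr), rownames(tcn$cn))
  samples <- intersect(colnames(expr), colnames(tcn$cn))
  if (length(samples) < 4L) stop_arg("need at least 4 shared samples")
  res <- lapply(ids, function(id) {
    xr <- tcn$cn[id, samples]
    if (anyNA(xr) || stats::sd(xr) == 0)
      return(data.frame(beta0 = NA_real_, beta = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, r = NA_real_,
                        n = length(samples)))
    robust_regress(expr[id, samples], log2(xr))
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(transcript_id = ids, stringsAsFactors = FALSE), out)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  out
}

#' Select transcripts at a target false discovery rate
#'
#' Benjamini-Hochberg step-up selection: transcripts whose BH-adjusted
#' p-value is at most `q_threshold`.
#'
#' @param results data frame with columns transcript_id and p.
#' @param q_threshold FDR level in (0, 1); default 0.01.
#' @return character vector of selected transcript ids.
#' @export
fdr_select <- function(results, q_threshold = 0.01) {
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold >= 1)
    stop_arg("`q_threshold` must lie in (0, 1)")
  ok <- !is.na(results$p)
  q <- stats::p.adjust(results$p[ok], method = "BH")
  results$transcript_id[ok][q <= q_threshold]
}

#' Estimate the proportion of transcripts with a real dosage signal
#'
#' Uses the upper tail of the p-value histogram: `pi0 = #{p > lambda} /
#' (M * (1 - lambda))` with `lambda = 0.5`; the signal proportion is
#' `1 - pi0`, clipped to [0, 1].
#'
#' @param p_values vector of at least 100 p-values in [0, 1].
#' @param lambda tail threshold (default 0.5).
#' @return scalar signal proportion.
#' @export
estimate_signal_proportion <- function(p_values, lambda = 0.5) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100L) stop_arg("need at least 100 p-values")
  if (any(p_values < 0 | p_values > 1)) stop_arg("p-values must lie in [0, 1]")
  pi0 <- sum(p_values > lambda) / (length(p_values) * (1 - lambda))
  min(max(1 - pi0, 0), 1)
}

## Dose-response bins on the copy-number ratio scale: half-open,
## upper-inclusive intervals partitioning (0, Inf).
DOSE_BIN_EDGES <- c(0, 0.5, 0.93, 1.07, 2, 4, Inf)
DOSE_BIN_LABELS <- c("high_deletion", "low_deletion", "no_change",
                     "low_amplification", "medium_amplification",
                     "high_amplification")

#' Dose-response summary of expression by copy-number ratio bin
#'
#' Assigns every (transcript, sample) observation to one of six bins of the
#' copy-number ratio -- high deletion (<= 0.5), low deletion (0.5-0.93], no
#' change (0.93-1.07], low (1.07-2], medium (2-4] and high (> 4)
#' amplification -- and summarizes the log2 expression in each: count,
#' quartiles, mean, and mean difference from the no-change bin with its
#' fold-change equivalent.
#'
#' @param expr expression matrix (transcripts x samples, log2 scale).
#' @param tcn a `transcript_cn` with ratios for the same transcripts/samples.
#' @return data frame, one row per bin.
#' @export
dose_response <- function(expr, tcn) {
  stopifnot(inherits(tcn, "transcript_cn"))
  ids <- intersect(rownames(expr), rownames(tcn$cn))
  samples <- intersect(colnames(expr), colnames(tcn$cn))
  ratio <- tcn$cn[ids, samples, drop = FALSE]
  e <- expr[ids, samples, drop = FALSE]
  keep <- !is.na(ratio)
  if (any(ratio[keep] <= 0)) stop_arg("non-positive copy-number ratio")
  bin <- cut(ratio[keep], DOSE_BIN_EDGES, labels = DOSE_BIN_LABELS,
             right = TRUE)
  vals <- split(e[keep], bin)
  ref_mean <- mean(vals[["no_change"]])
  out <- do.call(rbind, lapply(DOSE_BIN_LABELS, function(b) {
    v <- vals[[b]]
    if (length(v) == 0L)
      return(data.frame(bin = b, n = 0L, q25 = NA_real_, median = NA_real_,
                        q75 = NA_real_, mean = NA_real_,
                        diff_vs_no_change = NA_real_, fold = NA_real_,
                        direction = NA_character_, stringsAsFactors = FALSE))
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    d <- mean(v) - ref_mean
    f <- log2fc_to_fold(d)
    data.frame(bin = b, n = length(v), q25 = qs[1], median = qs[2],
               q75 = qs[3], mean = mean(v), diff_vs_no_change = d,
               fold = f$fold, direction = f$direction,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Convert a log2 expression difference to a fold change
#'
#' `2^|delta|`, reported to one decimal with a direction flag, e.g. a log2
#' difference of -0.8 is a 1.7-fold decrease and +1.6 a 3.0-fold increase.
#'
#' @param delta_log2 log2 difference.
#' @return list with `fold` (one-decimal rounding), `fold_exact` and
#'   `direction` ("higher", "lower" or "none").
#' @export
log2fc_to_fold <- function(delta_log2) {
  fold <- 2^abs(delta_log2)
  list(fold = round(fold, 1), fold_exact = fold,
       direction = if (delta_log2 > 0) "higher"
                   else if (delta_log2 < 0) "lower" else "none")
}

#' Genome-wide scan report with Bonferroni line and clustered regions
#'
#' Computes `-log10(p)` per transcript against the Bonferroni threshold
#' `alpha / M` (M = number of tested transcripts) and lists clustered
#' regions: maximal runs of at least `cluster_k` consecutive transcripts on
#' one chromosome all exceeding the threshold.
#'
#' @param results data frame from [associate_all()].
#' @param layout a `genome_layout` providing transcript coordinates.
#' @param alpha family-wise error target (default 0.01).
#' @param cluster_k minimum run length for a clustered region (default 5).
#' @return list with `m` (number of tests), `threshold_p`,
#'   `neglog10_cutoff` (two decimals), `scan` (per-transcript table sorted by
#'   position with neglog10_p and above-threshold flag) and `regions`.
#' @export
genome_scan_report <- function(results, layout, alpha = 0.01, cluster_k = 5) {
  tested <- results[!is.na(results$p), , drop = FALSE]
  m <- nrow(tested)
  if (m == 0L) stop_arg("no tested transcripts")
  threshold_p <- alpha / m
  tr <- layout$transcripts
  scan <- merge(tested, tr[, c("transcript_id", "chrom", "start", "end")],
                by = "transcript_id")
  scan <- scan[order(match(scan$chrom, layout$chromosomes$name), scan$start), ]
  scan$neglog10_p <- -log10(scan$p)
  scan$above <- scan$p < threshold_p

  regions <- list()
  for (ck in unique(scan$chrom)) {
    sub <- scan[scan$chrom == ck, ]
    r <- rle(sub$above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= cluster_k)
    for (h in hit) {
      blk <- sub[starts[h]:ends[h], ]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ck, start = min(blk$start), end = max(blk$end),
        n_transcripts = nrow(blk),
        first_transcript = blk$transcript_id[1],
        last_transcript = blk$transcript_id[nrow(blk)],
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(chrom = character(0), start = integer(0),
                             end = integer(0), n_transcripts = integer(0),
                             first_transcript = character(0),
                             last_transcript = character(0))
  list(m = m, threshold_p = threshold_p,
       neglog10_cutoff = round(-log10(threshold_p), 2),
       scan = scan, regions = regions)
}
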