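## Synthetic cohorts with recorded ground truth: segmental copy number,
## dosage-responsive expression, and a case/control cohort with
## proportional-hazards survival. Defaults emulate a heavily rearranged
## squamous-cell tumor genome profiled on mid-2000s SNP/expression arrays.

#' Simulate per-SNP copy-number ratios with segmental aberrations
#'
#' Draws, for every sample and chromosome, breakpoints from a Poisson process
#' (`segment_rate` per Mb) and assigns each segment a true cancer/normal
#' copy-number ratio from a categorical distribution spanning high-level
#' deletion through high-level amplification. Observed per-SNP ratios are the
#' segment ratio times multiplicative log-normal noise
#' (`ratio * 2^rnorm(0, noise_sd)`), which keeps ratios positive.
#'
#' @param layout a `genome_layout`.
#' @param n_samples number of tumor samples.
#' @param segment_rate expected breakpoints per Mb per chromosome.
#' @param noise_sd standard deviation of the log2-scale multiplicative noise;
#'   0 gives noise-free ratios equal to the segment truth.
#' @param seed integer seed.
#' @param level_values,level_probs categorical distribution of true segment
#'   ratios. Defaults span the six dose-response bins used downstream
#'   (high deletion < 0.5 up to high amplification > 4) with roughly half the
#'   genome copy-neutral.
#' @return list with `ratios` (SNPs x samples matrix of observed positive
#'   ratios) and `truth` (a `truth_table` holding per-sample segment ratios and
#'   the noise-free per-SNP ratio matrix).
#' @export
simulate_copy_number <- function(layout, n_samples, segment_rate = 0.2,
                                 noise_sd = 0.25, seed = 1,
                                 level_values = c(0.3, 0.7, 1, 1.5, 3, 5),
                                 level_probs = c(0.05, 0.18, 0.50, 0.18, 0.06, 0.03)) {
  validate_layout(layout)
  if (nrow(layout$snps) == 0L) stop_arg("layout has no SNPs")
  n_samples <- check_count(n_samples, "n_samples")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_arg("`noise_sd` must be >= 0")
  if (segment_rate < 0) stop_arg("`segment_rate` must be >= 0")
  if (any(level_values <= 0)) stop_arg("true copy-number ratios must be positive")
  level_probs <- level_probs / sum(level_probs)

  set.seed(derive_seed(seed, 2L))
  snps <- layout$snps
  samples <- sprintf("S%03d", seq_len(n_samples))
  n_snp <- nrow(snps)
  true_ratio <- matrix(NA_real_, n_snp, n_samples,
                       dimnames = list(snps$snp_id, samples))
  seg_rows <- list()
  for (j in seq_len(n_samples)) {
    for (k in seq_len(nrow(layout$chromosomes))) {
      ck <- layout$chromosomes$name[k]
      L <- layout$chromosomes$length[k]
      idx <- which(snps$chrom == ck)
      n_bp <- stats::rpois(1, segment_rate * L / 1e6)
      bp <- sort(stats::runif(n_bp, 0, L))
      bounds <- c(0, bp, L)
      levels_k <- sample(level_values, length(bounds) - 1L, replace = TRUE,
                         prob = level_probs)
      if (length(idx)) {
        seg_of_snp <- findInterval(snps$pos[idx], bounds,
                                   rightmost.closed = FALSE)
        true_ratio[idx, j] <- levels_k[seg_of_snp]
      }
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        sample = samples[j], chrom = ck,
        start = bounds[-length(bounds)], end = bounds[-1L],
        ratio = levels_k, stringsAsFactors = FALSE)
    }
  }
  noise <- if (noise_sd > 0)
    matrix(2^stats::rnorm(n_snp * n_samples, 0, noise_sd), n_snp, n_samples)
  else 1
  ratios <- true_ratio * noise
  dimnames(ratios) <- dimnames(true_ratio)

  truth <- structure(list(
    segment_truth = do.call(rbind, seg_rows),
    snp_ratio = true_ratio,
    dosage = NULL, casecontrol = NULL, survival = NULL),
    class = "truth_table")
  list(ratios = ratios, truth = truth)
}

#' Simulate log2 expression with a planted copy-number dosage effect
#'
#' A fraction of transcripts is designated dosage-responsive: their log2
#' expression is `baseline + beta * log2(copy-number ratio) + noise`. All
#' other transcripts have slope zero. Unmapped transcripts (no copy number)
#' can never be responsive.
#'
#' @param layout a `genome_layout`.
#' @param truth `truth_table` from [simulate_copy_number()]; returned updated
#'   with the per-transcript dosage truth.
#' @param transcript_cn a `transcript_cn` object giving the per-transcript,
#'   per-sample copy-number ratio that drives expression (typically inferred
#'   from the noise-free truth profile).
#' @param dosage_fraction proportion of transcripts that respond to dosage.
#' @param beta_mean slope (log2 expression per log2 copy-ratio unit) given to
#'   every responsive transcript.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd distribution of per-transcript baseline
#'   log2 expression (defaults keep typical values well above the detection
#'   filter threshold of 3).
#' @param unexpressed_fraction proportion of transcripts drawn as unexpressed
#'   (baseline near log2 = 1.5, below the detection filter), emulating array
#'   probes for genes silent in the tissue.
#' @return list with `expression` (transcripts x samples log2 matrix) and the
#'   updated `truth`.
#' @export
simulate_expression <- function(layout, truth, transcript_cn,
                                dosage_fraction = 0.3, beta_mean = 1,
                                noise_sd = 0.3, seed = 1,
                                baseline_mean = 6, baseline_sd = 1,
                                unexpressed_fraction = 0.3) {
  validate_layout(layout)
  dosage_fraction <- check_proportion(dosage_fraction, "dosage_fraction")
  if (noise_sd < 0) stop_arg("`noise_sd` must be >= 0")
  tids <- layout$transcripts$transcript_id
  if (!setequal(tids, transcript_cn$info$transcript_id))
    stop_arg("transcript sets of `layout` and `transcript_cn` differ")

  set.seed(derive_seed(seed, 3L))
  samples <- colnames(transcript_cn$cn)
  n_t <- length(tids)
  mapped <- transcript_cn$info$transcript_id[transcript_cn$info$rule != "unmapped"]
  n_resp <- round(dosage_fraction * n_t)
  responsive <- character(0)
  if (n_resp > 0) {
    if (n_resp > length(mapped)) n_resp <- length(mapped)
    responsive <- sample(mapped, n_resp)
  }
  beta <- stats::setNames(rep(0, n_t), tids)
  beta[responsive] <- beta_mean

  unexpressed_fraction <- check_proportion(unexpressed_fraction,
                                           "unexpressed_fraction")
  baseline <- stats::rnorm(n_t, baseline_mean, baseline_sd)
  n_off <- round(unexpressed_fraction * n_t)
  if (n_off > 0) {
    off <- sample.int(n_t, n_off)
    baseline[off] <- stats::rnorm(n_off, 1.5, 0.7)
  }
  expr <- matrix(baseline, n_t, length(samples),
                 dimnames = list(tids, samples))
  cn <- transcript_cn$cn[tids, , drop = FALSE]
  log2cn <- log2(cn)
  log2cn[is.na(log2cn)] <- 0           # unmapped: no dosage term
  expr <- expr + beta * log2cn
  if (noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd),
                          nrow(expr), ncol(expr))

  truth$dosage <- data.frame(transcript_id = tids, beta = unname(beta),
                             responsive = tids %in% responsive,
                             stringsAsFactors = FALSE)
  list(expression = expr, truth = truth)
}

#' Simulate an independent case/control cohort with survival follow-up
#'
#' Emulates a testing cohort of primary-tumor cases and normal-mucosa
#' controls: per-sample expression for the supplied transcripts, a planted
#' case/control mean shift for designated transcripts, and case survival
#' times drawn from a proportional-hazards model whose log-hazard is linear
#' in the mean expression of the designated risk transcripts plus AJCC stage
#' (coded 1-4, continuous). Age is uniform on 23-84 years, sex Bernoulli(1/2).
#'
#' @param n_cases,n_controls cohort sizes (cases must be >= 1).
#' @param transcript_ids transcript universe for the cohort expression matrix.
#' @param risk_transcripts ids whose expression drives the hazard.
#' @param hr_per_unit hazard ratio per unit of (centered) expression of each
#'   designated risk transcript; 1 plants no survival signal.
#' @param censor_rate rate (per month) of independent exponential censoring;
#'   0 means every subject's event time is observed.
#' @param seed integer seed.
#' @param de_transcripts ids differentially expressed in cases (defaults to
#'   `risk_transcripts`).
#' @param de_shift mean log2 expression shift in cases for `de_transcripts`.
#' @param risk_cor_sd standard deviation of a latent per-sample factor shared
#'   by all risk transcripts, emulating a co-regulated signature; 0 leaves
#'   risk transcripts mutually independent.
#' @param stage_hr hazard ratio per stage unit.
#' @param baseline_hazard baseline exponential hazard per month.
#' @param nonspecific_death_frac fraction of deaths attributed to causes other
#'   than the tumor (kept as deaths but not cause-specific events).
#' @return list with `clinical` (data frame: sample_id, case, age, sex, stage,
#'   followup_months, dead, oscc_death), `expression` (transcripts x samples),
#'   and `truth` (per-transcript case/control shift and log hazard ratio).
#' @export
simulate_clinical <- function(n_cases, n_controls, transcript_ids,
                              risk_transcripts = character(0),
                              hr_per_unit = 1, censor_rate = 0.02, seed = 1,
                              de_transcripts = risk_transcripts,
                              de_shift = 1, risk_cor_sd = 0.3, stage_hr = 2,
                              baseline_hazard = 0.03,
                              nonspecific_death_frac = 0.1) {
  n_cases <- check_count(n_cases, "n_cases")
  if (!is.numeric(n_controls) || n_controls < 0)
    stop_arg("`n_controls` must be a non-negative count")
  n_controls <- as.integer(n_controls)
  hr_per_unit <- check_positive(hr_per_unit, "hr_per_unit")
  if (censor_rate < 0) stop_arg("`censor_rate` must be >= 0")
  if (!all(risk_transcripts %in% transcript_ids))
    stop_arg("`risk_transcripts` must be a subset of `transcript_ids`")
  if (!all(de_transcripts %in% transcript_ids))
    stop_arg("`de_transcripts` must be a subset of `transcript_ids`")

  set.seed(derive_seed(seed, 4L))
  n <- n_cases + n_controls
  ids <- sprintf("P%03d", seq_len(n))
  case <- c(rep(1L, n_cases), rep(0L, n_controls))
  n_t <- length(transcript_ids)

  baseline <- stats::rnorm(n_t, 6, 1)
  expr <- matrix(baseline, n_t, n, dimnames = list(transcript_ids, ids)) +
    matrix(stats::rnorm(n_t * n, 0, 1), n_t, n)
  if (length(de_transcripts))
    expr[de_transcripts, case == 1L] <-
      expr[de_transcripts, case == 1L, drop = FALSE] + de_shift
  if (length(risk_transcripts) > 1L && risk_cor_sd > 0) {
    u <- stats::rnorm(n, 0, risk_cor_sd)
    expr[risk_transcripts, ] <- expr[risk_transcripts, , drop = FALSE] +
      rep(u, each = length(risk_transcripts))
  }

  age <- round(stats::runif(n, 23, 84))
  sex <- stats::rbinom(n, 1, 0.5)
  stage <- ifelse(case == 1L, sample(1:4, n, replace = TRUE,
                                     prob = c(0.1, 0.2, 0.3, 0.4)), NA_integer_)

  followup <- rep(NA_real_, n)
  dead <- rep(NA_integer_, n)
  oscc_death <- rep(NA_integer_, n)
  ci <- which(case == 1L)
  lp <- log(stage_hr) * (stage[ci] - mean(stage[ci]))
  if (length(risk_transcripts)) {
    rx <- expr[risk_transcripts, ci, drop = FALSE]
    rx <- rx - rowMeans(rx)
    lp <- lp + log(hr_per_unit) * colSums(rx)
  }
  t_event <- stats::rexp(length(ci), rate = baseline_hazard * exp(lp))
  t_cens <- if (censor_rate > 0) stats::rexp(length(ci), censor_rate) else Inf
  obs <- pmin(t_event, t_cens)
  ev <- as.integer(t_event <= t_cens)
  nonspec <- ev == 1L & stats::runif(length(ci)) < nonspecific_death_frac
  followup[ci] <- round(obs, 1)
  followup[ci][followup[ci] <= 0] <- 0.1
  dead[ci] <- ev
  oscc_death[ci] <- as.integer(ev == 1L & !nonspec)

  clinical <- data.frame(sample_id = ids, case = case, age = age, sex = sex,
                         stage = stage, followup_months = followup,
                         dead = dead, oscc_death = oscc_death,
                         stringsAsFactors = FALSE)
  truth <- list(
    casecontrol = data.frame(
      transcript_id = transcript_ids,
      shift = ifelse(transcript_ids %in% de_transcripts, de_shift, 0),
      stringsAsFactors = FALSE),
    survival = data.frame(
      transcript_id = transcript_ids,
      log_hr = ifelse(transcript_ids %in% risk_transcripts,
                      log(hr_per_unit), 0),
      stringsAsFactors = FALSE))
  list(clinical = clinical, expression = expr, truth = truth)
}
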