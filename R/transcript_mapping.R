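## Per-transcript copy number from nearby SNPs, by a three-rule precedence:
## (1) mean over >= `min_snps` SNPs overlapping the transcript; else
## (2) mean over the `min_snps` closest SNPs within `window_bp`; else
## (3) mean over the 1..(min_snps-1) SNPs within the window; else unmapped.

## Distance from a SNP position to a 0-based half-open interval [start, end):
## 0 if inside, else the gap to the nearer boundary.
snp_interval_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos >= end, pos - end + 1L, 0L))
}

#' Infer per-transcript copy number from a segmented SNP profile
#'
#' For each transcript the inferred copy number per sample is the arithmetic
#' mean, on the ratio scale, of the segmented (denoised) copy-number ratios
#' of the SNPs selected by the first applicable rule. SNPs overlapping the
#' transcript have distance 0 and are therefore always among the closest
#' candidates for rule 2. Ties at the `min_snps`-th smallest distance are
#' broken by (position, snp_id) order so the selection is deterministic.
#'
#' @param layout a `genome_layout` (or any list with a `transcripts` data
#'   frame: transcript_id, chrom, start, end).
#' @param profile a segmented `cn_profile`.
#' @param window_bp neighborhood radius in bp (default 250 kb).
#' @param min_snps SNP count required for rules 1 and 2 (default 5).
#' @return object of class `transcript_cn`: list with `info` (transcript_id,
#'   chrom, rule, n_snps, snp_ids) and `cn` (transcripts x samples matrix of
#'   copy-number ratios; NA rows for unmapped transcripts), plus the window
#'   and min-SNP settings used.
#' @export
infer_transcript_cn <- function(layout, profile, window_bp = 250000,
                                min_snps = 5) {
  stopifnot(inherits(profile, "cn_profile"))
  if (is.null(profile$segmented))
    stop_arg("profile is not segmented; run segment_fused_lasso() first")
  window_bp <- check_positive(window_bp, "window_bp")
  min_snps <- check_count(min_snps, "min_snps")
  tr <- layout$transcripts
  if (any(tr$start >= tr$end))
    stop_arg("malformed transcript interval (start >= end): %s",
             tr$transcript_id[which(tr$start >= tr$end)[1]])

  seg_ratio <- 2^profile$segmented
  samples <- colnames(seg_ratio)
  n_t <- nrow(tr)
  cn <- matrix(NA_real_, n_t, length(samples),
               dimnames = list(tr$transcript_id, samples))
  rule <- character(n_t)
  n_used <- integer(n_t)
  used_ids <- character(n_t)

  by_chrom <- split(seq_len(nrow(profile$snps)), profile$snps$chrom)
  for (i in seq_len(n_t)) {
    idx <- by_chrom[[tr$chrom[i]]]
    if (is.null(idx)) { rule[i] <- "unmapped"; next }
    pos <- profile$snps$pos[idx]
    d <- snp_interval_distance(pos, tr$start[i], tr$end[i])
    overlap <- idx[d == 0]
    if (length(overlap) >= min_snps) {
      chosen <- overlap
      rule[i] <- "overlap5"
    } else {
      in_win <- d <= window_bp
      cand <- idx[in_win]
      if (length(cand) >= min_snps) {
        ## closest min_snps; ties broken by (distance, position, snp_id)
        ord <- order(d[in_win], pos[in_win], profile$snps$snp_id[cand])
        chosen <- cand[ord[seq_len(min_snps)]]
        rule[i] <- "closest5"
      } else if (length(cand) >= 1L) {
        chosen <- cand
        rule[i] <- "all_in_window"
      } else {
        rule[i] <- "unmapped"
        next
      }
    }
    n_used[i] <- length(chosen)
    used_ids[i] <- paste(profile$snps$snp_id[chosen], collapse = ",")
    cn[i, ] <- colMeans(seg_ratio[chosen, , drop = FALSE])
  }

  structure(list(
    info = data.frame(transcript_id = tr$transcript_id, chrom = tr$chrom,
                      rule = rule, n_snps = n_used, snp_ids = used_ids,
                      stringsAsFactors = FALSE),
    cn = cn, window_bp = window_bp, min_snps = min_snps),
    class = "transcript_cn")
}

#' @export
print.transcript_cn <- function(x, ...) {
  tab <- table(factor(x$info$rule,
                      c("overlap5", "closest5", "all_in_window", "unmapped")))
  cat(sprintf("transcript_cn: %d transcripts x %d samples\n",
              nrow(x$cn), ncol(x$cn)))
  print(tab)
  invisible(x)
}

#' Summarize transcript copy-number mapping
#'
#' Counts transcripts per mapping rule and reports the percentage of mapped
#' transcripts whose copy number was inferred from at least `min_snps` SNPs
#' (rules 1 and 2), rounded to one decimal place.
#'
#' @param tcn a `transcript_cn` object.
#' @return list with `counts` (named integer vector over the four rules),
#'   `n_total`, `n_mapped`, and `pct_ge_min_snps` (NA with an explanatory
#'   `note` when no transcript is mapped).
#' @export
mapping_summary <- function(tcn) {
  stopifnot(inherits(tcn, "transcript_cn"))
  rules <- c("overlap5", "closest5", "all_in_window", "unmapped")
  counts <- table(factor(tcn$info$rule, rules))
  counts <- stats::setNames(as.integer(counts), rules)
  n_total <- sum(counts)
  n_mapped <- n_total - counts[["unmapped"]]
  if (n_mapped == 0L)
    return(list(counts = counts, n_total = n_total, n_mapped = 0L,
                pct_ge_min_snps = NA_real_, note = "no mapped transcripts"))
  list(counts = counts, n_total = n_total, n_mapped = n_mapped,
       pct_ge_min_snps = percent1(counts[["overlap5"]] + counts[["closest5"]],
                                  n_mapped),
       note = NULL)
}
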