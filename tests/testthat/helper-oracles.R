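## Independent oracles used across the suite. Each is deliberately written
## with a different algorithm than the implementation it checks.

## Generic convex-optimization oracle for the fused-lasso objective:
## graduated smoothing of the absolute values plus BFGS, warm-started across
## smoothing levels. Independent of the direct taut-string solver.
fused_lasso_bfgs_oracle <- function(y, l1, l2) {
  b <- y
  for (eps in c(1e-6, 1e-9, 1e-12, 1e-15, 1e-16)) {
    f <- function(b) 0.5 * sum((y - b)^2) + l1 * sum(sqrt(b^2 + eps)) +
      l2 * sum(sqrt(diff(b)^2 + eps))
    g <- function(b) {
      d <- diff(b)
      gr <- (b - y) + l1 * b / sqrt(b^2 + eps)
      tv <- d / sqrt(d^2 + eps)
      gr[-length(b)] <- gr[-length(b)] - l2 * tv
      gr[-1] <- gr[-1] + l2 * tv
      gr
    }
    for (r in 1:2)
      b <- stats::optim(b, f, g, method = "BFGS",
                        control = list(maxit = 10000, reltol = 1e-16))$par
  }
  b
}

## Brute-force transcript mapping oracle: scans every SNP distance
## explicitly and applies the three-rule precedence with no indexing tricks.
map_transcript_brute <- function(tx, snps, seg_ratio, window_bp = 250000,
                                 min_snps = 5) {
  on_chrom <- snps[snps$chrom == tx$chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0L) return(list(rule = "unmapped"))
  d <- vapply(seq_len(nrow(on_chrom)), function(i) {
    p <- on_chrom$pos[i]
    if (p >= tx$start && p < tx$end) 0
    else if (p < tx$start) tx$start - p
    else p - tx$end + 1
  }, numeric(1))
  overlap <- on_chrom$snp_id[d == 0]
  if (length(overlap) >= min_snps) {
    chosen <- overlap; rule <- "overlap5"
  } else {
    win <- which(d <= window_bp)
    if (length(win) >= min_snps) {
      ord <- win[order(d[win], on_chrom$pos[win], on_chrom$snp_id[win])]
      chosen <- on_chrom$snp_id[ord[seq_len(min_snps)]]
      rule <- "closest5"
    } else if (length(win) >= 1L) {
      chosen <- on_chrom$snp_id[win]; rule <- "all_in_window"
    } else return(list(rule = "unmapped"))
  }
  list(rule = rule, snp_ids = sort(chosen),
       value = colMeans(seg_ratio[chosen, , drop = FALSE]))
}

## Empirical ROC of cases vs controls (no censoring): classical
## rank/threshold construction plus Mann-Whitney AUC.
empirical_roc_auc <- function(scores, is_case) {
  x <- scores[is_case]; y <- scores[!is_case]
  w <- 0
  for (xi in x) w <- w + sum(xi > y) + 0.5 * sum(xi == y)
  w / (length(x) * length(y))
}

## A tiny hand-built layout for mapping and pipeline toys.
toy_layout <- function(snp_pos, tx, chrom_len = 1e7, chrom = "chr1") {
  snps <- data.frame(snp_id = sprintf("SNP%03d", seq_along(snp_pos)),
                     chrom = chrom, pos = as.integer(snp_pos),
                     stringsAsFactors = FALSE)
  structure(list(
    chromosomes = data.frame(name = chrom, length = chrom_len,
                             stringsAsFactors = FALSE),
    snps = snps, transcripts = tx), class = "genome_layout")
}

## Segmented profile with given per-SNP log2 values (matrix or vector).
toy_profile <- function(layout, log2_values) {
  m <- if (is.matrix(log2_values)) log2_values
       else matrix(log2_values, ncol = 1,
                   dimnames = list(NULL, "S001"))
  rownames(m) <- layout$snps$snp_id
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  cn_profile(layout$snps, m, segmented = m)
}
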