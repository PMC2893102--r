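## Copy-number estimation: log2 transform, exact fused-lasso segmentation
## (direct total-variation denoising + soft-thresholding), gain/loss calls
## and genome-altered burden.

#' Construct a per-SNP copy-number profile
#'
#' @param snps data frame with columns snp_id, chrom, pos (0-based), sorted by
#'   (chromosome, position).
#' @param log2_ratios matrix (SNPs x samples) of log2 cancer/normal ratios
#'   with rownames matching `snps$snp_id`.
#' @param segmented optional same-shape matrix of fitted piecewise-constant
#'   log2 values.
#' @return an object of class `cn_profile`.
#' @export
cn_profile <- function(snps, log2_ratios, segmented = NULL) {
  stopifnot(is.data.frame(snps),
            all(c("snp_id", "chrom", "pos") %in% names(snps)))
  if (!is.matrix(log2_ratios) || nrow(log2_ratios) != nrow(snps))
    stop_arg("`log2_ratios` must be a matrix with one row per SNP")
  if (is.null(rownames(log2_ratios)))
    rownames(log2_ratios) <- snps$snp_id
  if (!identical(rownames(log2_ratios), snps$snp_id))
    stop_arg("rownames of `log2_ratios` must match `snps$snp_id` in order")
  ord <- order(match(snps$chrom, unique(snps$chrom)), snps$pos)
  if (!identical(ord, seq_len(nrow(snps))))
    stop_arg("SNPs must be sorted by (chromosome, position)")
  if (!is.null(segmented) && !identical(dim(segmented), dim(log2_ratios)))
    stop_arg("`segmented` must have the same shape as `log2_ratios`")
  structure(list(snps = snps, log2_ratios = log2_ratios,
                 segmented = segmented), class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile: %d SNPs x %d samples (%s)\n",
              nrow(x$log2_ratios), ncol(x$log2_ratios),
              if (is.null(x$segmented)) "unsegmented" else "segmented"))
  invisible(x)
}

#' Log2-transform a matrix of copy-number ratios
#'
#' The copy-number ratio is tumor copy number over the two copies expected in
#' a diploid normal cell; a neutral locus has ratio 1 and log2 ratio 0.
#'
#' @param raw_ratio_matrix matrix of positive ratios.
#' @return matrix of elementwise base-2 logarithms.
#' @export
to_log2_ratio <- function(raw_ratio_matrix) {
  m <- as.matrix(raw_ratio_matrix)
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rn <- rownames(m); cn <- colnames(m)
    stop_arg("non-positive copy-number ratio at SNP %s, sample %s",
             if (is.null(rn)) bad[1, 1] else rn[bad[1, 1]],
             if (is.null(cn)) bad[1, 2] else cn[bad[1, 2]])
  }
  log2(m)
}

#' Exact 1-D total-variation denoising
#'
#' Solves `argmin_x 1/2 sum (y_i - x_i)^2 + lambda * sum |x_i - x_{i-1}|`
#' exactly by Condat's direct (taut-string equivalent) algorithm. The
#' solution is piecewise constant and, because the fusion penalty involves
#' only differences, preserves the mean of `y`.
#'
#' @param y numeric vector.
#' @param lambda non-negative fusion penalty.
#' @return numeric vector of the same length.
#' @export
tv_denoise <- function(y, lambda) {
  n <- length(y)
  if (lambda < 0) stop_arg("`lambda` must be >= 0")
  if (n <= 1L || lambda == 0) return(y)
  x <- numeric(n)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1] - lambda; vmax <- y[1] + lambda
  umin <- lambda; umax <- -lambda
  repeat {
    if (k == n) { x[n] <- vmin + umin; return(x) }
    repeat {                                           # forward scan
      if (y[k + 1L] + umin < vmin - lambda) {          # negative jump
        x[k0:km] <- vmin
        k <- k0 <- km <- kp <- km + 1L
        vmin <- y[k]; vmax <- y[k] + 2 * lambda
        umin <- lambda; umax <- -lambda
      } else if (y[k + 1L] + umax > vmax + lambda) {   # positive jump
        x[k0:kp] <- vmax
        k <- k0 <- km <- kp <- kp + 1L
        vmin <- y[k] - 2 * lambda; vmax <- y[k]
        umin <- lambda; umax <- -lambda
      } else {                                         # extend current segment
        k <- k + 1L
        umin <- umin + y[k] - vmin
        umax <- umax + y[k] - vmax
        if (umin >= lambda) {
          vmin <- vmin + (umin - lambda) / (k - k0 + 1)
          umin <- lambda; km <- k
        }
        if (umax <= -lambda) {
          vmax <- vmax + (umax + lambda) / (k - k0 + 1)
          umax <- -lambda; kp <- k
        }
      }
      if (k >= n) break
    }
    ## end of signal reached: settle the last segment, possibly backtracking
    if (umin < 0) {
      x[k0:km] <- vmin
      k <- k0 <- km <- km + 1L
      vmin <- y[k]; umin <- lambda
      umax <- y[k] + lambda - vmax
    } else if (umax > 0) {
      x[k0:kp] <- vmax
      k <- k0 <- kp <- kp + 1L
      vmax <- y[k]; umax <- -lambda
      umin <- y[k] - lambda - vmin
    } else {
      x[k0:n] <- vmin + umin / (k - k0 + 1)
      return(x)
    }
  }
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' Fused-lasso objective value
#'
#' `1/2 sum (y-b)^2 + l1 sum |b| + l2 sum |b_i - b_{i-1}|`; used to compare
#' the direct solver against generic convex-optimization oracles.
#'
#' @param y data vector; @param beta candidate fit.
#' @param lambda_sparsity,lambda_fusion penalties.
#' @return scalar objective value.
#' @export
fused_lasso_objective <- function(y, beta, lambda_sparsity, lambda_fusion) {
  0.5 * sum((y - beta)^2) + lambda_sparsity * sum(abs(beta)) +
    lambda_fusion * sum(abs(diff(beta)))
}

#' Solve the 1-D fused lasso exactly
#'
#' Minimizes the fused-lasso objective (see [fused_lasso_objective()]) by
#' exact total-variation denoising with the fusion penalty followed by
#' soft-thresholding at the sparsity penalty -- an exact composition for this
#' objective (Friedman et al. 2007, "Pathwise coordinate optimization").
#'
#' @param y numeric vector.
#' @param lambda_sparsity,lambda_fusion non-negative penalties.
#' @return the minimizing piecewise-constant vector.
#' @export
fused_lasso_1d <- function(y, lambda_sparsity, lambda_fusion) {
  if (lambda_sparsity < 0 || lambda_fusion < 0)
    stop_arg("penalties must be >= 0")
  soft_threshold(tv_denoise(y, lambda_fusion), lambda_sparsity)
}

## Default fusion penalty: universal threshold sigma * sqrt(2 log n) with
## sigma estimated from the median absolute successive difference.
default_lambda_fusion <- function(y) {
  n <- length(y)
  if (n < 3L) return(0)
  sigma <- stats::median(abs(diff(y))) / (sqrt(2) * stats::qnorm(0.75))
  sigma * sqrt(2 * log(n))
}

#' Segment a copy-number profile with the fused lasso
#'
#' Fits, independently per chromosome and sample, a piecewise-constant
#' profile to the log2 ratios. The default fusion penalty is the universal
#' threshold `sigma * sqrt(2 log n)` with `sigma` from the median absolute
#' successive difference of the data (robust to true copy-number steps); the
#' sparsity penalty defaults to 0 so neutral regions are not shrunk away from
#' their observed level.
#'
#' @param profile a `cn_profile`.
#' @param lambda_sparsity non-negative sparsity penalty (default 0).
#' @param lambda_fusion non-negative fusion penalty, or `NULL` to use the
#'   per-chromosome universal threshold.
#' @return the profile with `segmented` filled.
#' @export
segment_fused_lasso <- function(profile, lambda_sparsity = 0,
                                lambda_fusion = NULL) {
  stopifnot(inherits(profile, "cn_profile"))
  if (lambda_sparsity < 0 || (!is.null(lambda_fusion) && lambda_fusion < 0))
    stop_arg("penalties must be >= 0")
  y <- profile$log2_ratios
  seg <- y
  for (ck in unique(profile$snps$chrom)) {
    idx <- which(profile$snps$chrom == ck)
    for (j in seq_len(ncol(y))) {
      l2 <- if (is.null(lambda_fusion)) default_lambda_fusion(y[idx, j])
            else lambda_fusion
      seg[idx, j] <- fused_lasso_1d(y[idx, j], lambda_sparsity, l2)
    }
  }
  profile$segmented <- seg
  profile
}

#' Gain/loss presets on the copy-number ratio scale
#'
#' `"low"` calls any departure beyond ratios 0.93/1.07 an aberration;
#' `"stringent"` requires ratios below 0.7 or above 1.4.
#'
#' @param preset `"low"` or `"stringent"`.
#' @return numeric c(lower, upper).
#' @export
cna_thresholds <- function(preset = c("low", "stringent")) {
  switch(match.arg(preset), low = c(0.93, 1.07), stringent = c(0.7, 1.4))
}

#' Call copy-number gains and losses from a segmented profile
#'
#' Thresholds are applied on the ratio scale to the fitted (segmented)
#' values: loss below `lower`, gain above `upper`, neutral otherwise.
#'
#' @param profile a segmented `cn_profile`.
#' @param lower,upper ratio thresholds with `0 < lower < 1 < upper`.
#' @return object of class `cna_calls`: list with `calls` (character matrix
#'   in {loss, neutral, gain}), the thresholds and the SNP table.
#' @export
call_cna <- function(profile, lower = 0.93, upper = 1.07) {
  stopifnot(inherits(profile, "cn_profile"))
  if (is.null(profile$segmented))
    stop_arg("profile is not segmented; run segment_fused_lasso() first")
  if (!(lower > 0 && lower < 1 && upper > 1))
    stop_arg("thresholds must satisfy 0 < lower < 1 < upper")
  ratio <- 2^profile$segmented
  calls <- matrix("neutral", nrow(ratio), ncol(ratio),
                  dimnames = dimnames(ratio))
  calls[ratio < lower] <- "loss"
  calls[ratio > upper] <- "gain"
  structure(list(calls = calls, lower = lower, upper = upper,
                 snps = profile$snps), class = "cna_calls")
}

#' Per-sample fraction of the genome with a copy-number aberration
#'
#' By default each SNP counts equally; with `weight = "bp"` each SNP is
#' weighted by the genomic interval it represents (half the distance to each
#' neighboring SNP on the same chromosome).
#'
#' @param calls a `cna_calls` object.
#' @param weight `"snp"` or `"bp"`.
#' @return named numeric vector of per-sample altered fractions in [0, 1].
#' @export
genome_altered_fraction <- function(calls, weight = c("snp", "bp")) {
  stopifnot(inherits(calls, "cna_calls"))
  weight <- match.arg(weight)
  m <- calls$calls
  if (length(m) == 0L) stop_arg("empty call set")
  altered <- m != "neutral"
  if (weight == "snp") return(colMeans(altered))
  w <- numeric(nrow(m))
  for (ck in unique(calls$snps$chrom)) {
    idx <- which(calls$snps$chrom == ck)
    p <- calls$snps$pos[idx]
    if (length(p) == 1L) { w[idx] <- 1; next }
    gaps <- diff(p)
    w[idx] <- (c(gaps[1], gaps) + c(gaps, gaps[length(gaps)])) / 2
  }
  colSums(altered * w) / sum(w)
}
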