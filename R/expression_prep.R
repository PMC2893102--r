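## Transcript filtering and the second (median-based) normalization applied
## before dosage testing.

SEX_CHROMS <- c("x", "y")
MITO_CHROMS <- c("mt", "m")

chrom_class <- function(chrom) {
  c <- tolower(sub("^chr", "", as.character(chrom)))
  ifelse(is.na(c) | c == "", "unknown",
         ifelse(c %in% SEX_CHROMS, "sex",
                ifelse(c %in% MITO_CHROMS, "mito", "autosome")))
}

#' Inter-quartile range with linear-interpolation quantiles
#'
#' Q3 - Q1 using type-7 (linear interpolation) quantiles, the convention the
#' detection filter applies to log2 expression.
#'
#' @param values numeric vector of at least 4 values.
#' @return non-negative scalar.
#' @export
iqr <- function(values) {
  if (length(values) < 4L)
    stop_arg("`values` must contain at least 4 observations")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Filter transcripts before copy-number association
#'
#' Removes transcripts that (1) have no alignment information or no unique
#' alignment to the genome; (2) lie on a sex chromosome or mitochondrial DNA;
#' (3) never reach log2 expression above `min_log2` in at least `min_samples`
#' samples; or (4) have an inter-quartile range of expression below
#' `min_iqr`. Rules are applied in this order and the removal log records
#' each discarded transcript with the first rule it failed; the retained set
#' passes all four regardless of order.
#'
#' @param expr log2 expression matrix (transcripts x samples, rownames are
#'   transcript ids).
#' @param annot data frame with transcript_id, chrom and (optionally)
#'   unique_alignment; a transcript absent from `annot` counts as rule-1.
#' @param min_log2,min_samples,min_iqr filter thresholds (defaults 3, 3, 0.1).
#' @return list with `expr` (retained matrix) and `removed` (data frame:
#'   transcript_id, rule, detail).
#' @export
filter_transcripts <- function(expr, annot, min_log2 = 3, min_samples = 3,
                               min_iqr = 0.1) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  ids <- rownames(expr)
  m <- match(ids, annot$transcript_id)
  uniq <- if ("unique_alignment" %in% names(annot)) annot$unique_alignment
          else rep(TRUE, nrow(annot))
  cls <- chrom_class(annot$chrom)

  rule <- rep(NA_character_, length(ids))
  detail <- rep(NA_character_, length(ids))
  fail1 <- is.na(m) | !uniq[m] | cls[m] == "unknown"
  rule[fail1] <- "no_alignment"
  detail[fail1] <- ifelse(is.na(m[fail1]), "missing annotation",
                          "no unique alignment")
  fail2 <- is.na(rule) & cls[m] %in% c("sex", "mito")
  rule[fail2] <- "sex_or_mito"
  detail[fail2] <- annot$chrom[m][fail2]
  n_detected <- rowSums(expr > min_log2)
  fail3 <- is.na(rule) & n_detected < min_samples
  rule[fail3] <- "low_expression"
  detail[fail3] <- sprintf("> %g in %d of %d samples (need %d)", min_log2,
                           n_detected[fail3], ncol(expr), min_samples)
  iqrs <- apply(expr, 1, iqr)
  fail4 <- is.na(rule) & iqrs < min_iqr
  rule[fail4] <- "low_iqr"
  detail[fail4] <- sprintf("IQR %.4g < %g", iqrs[fail4], min_iqr)

  removed <- data.frame(transcript_id = ids[!is.na(rule)],
                        rule = rule[!is.na(rule)],
                        detail = detail[!is.na(rule)],
                        stringsAsFactors = FALSE)
  list(expr = expr[is.na(rule), , drop = FALSE], removed = removed)
}

## Center a vector at its median and scale by the median absolute deviation
## about the median (no consistency constant). Degenerate scale (0) leaves
## the vector centered only.
median_standardize <- function(y) {
  ctr <- y - stats::median(y)
  s <- stats::median(abs(ctr))
  if (s == 0) list(values = ctr, degenerate = TRUE)
  else list(values = ctr / s, degenerate = FALSE)
}

#' Median-based renormalization of a filtered expression matrix
#'
#' Transforms each sample (column) to `(Y - median(Y)) / median(|Y -
#' median(Y)|)` and then each transcript (row) likewise, so that medians are
#' near zero with comparable variation across samples and transcripts. A
#' column or row whose median absolute deviation is zero is centered only and
#' reported with a warning. The per-vector transform is idempotent: applying
#' the column pass to an already column-standardized matrix is the identity.
#'
#' @param expr log2 expression matrix.
#' @param order `"sample_first"` (default) standardizes columns then rows;
#'   `"transcript_first"` the reverse.
#' @return matrix of the same shape.
#' @export
renormalize <- function(expr, order = c("sample_first", "transcript_first")) {
  order <- match.arg(order)
  stopifnot(is.matrix(expr))
  pass <- function(m, margin, label) {
    degenerate <- character(0)
    res <- apply(m, margin, function(v) {
      s <- median_standardize(v)
      s$values
    })
    ## apply() returns vectors along `margin` as columns; restore orientation
    out <- if (margin == 2) res else t(res)
    dimnames(out) <- dimnames(m)
    degen <- if (margin == 2) {
      which(apply(m, 2, function(v) stats::median(abs(v - stats::median(v)))) == 0)
    } else {
      which(apply(m, 1, function(v) stats::median(abs(v - stats::median(v)))) == 0)
    }
    if (length(degen))
      warning(sprintf("%d %s(s) with zero median absolute deviation: centered only",
                      length(degen), label), call. = FALSE)
    out
  }
  if (order == "sample_first") {
    out <- pass(expr, 2, "sample")
    out <- pass(out, 1, "transcript")
  } else {
    out <- pass(expr, 1, "transcript")
    out <- pass(out, 2, "sample")
  }
  out
}
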