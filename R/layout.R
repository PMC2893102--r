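## Synthetic genome layout: chromosomes, SNP probe positions, transcript
## intervals. Coordinates are 0-based half-open internally; writers emit
## 1-based inclusive coordinates (see io.R).

#' Simulate a genome layout of SNP probes and transcript intervals
#'
#' Builds an artificial genome whose SNP and transcript geometry exercises
#' every branch of the transcript copy-number mapping rules: by construction
#' the layout contains transcripts that overlap at least five SNPs,
#' transcripts with only one to four SNPs inside the 250 kb neighborhood, and
#' (when `n_transcripts >= 3`) at least one transcript with no SNP within
#' 250 kb at all. Each chromosome carries a dense SNP region, a sparse region
#' with three isolated SNPs spaced megabases apart, and a terminal SNP desert.
#'
#' @param n_chrom number of (autosomal) chromosomes.
#' @param n_snps total number of SNP probes across the genome.
#' @param n_transcripts total number of transcript intervals.
#' @param seed integer seed; identical arguments and seed give identical
#'   layouts.
#' @param chrom_length_bp length of every chromosome in bp (default 60 Mb).
#' @return an object of class `genome_layout`: a list with data frames
#'   `chromosomes` (name, length), `snps` (snp_id, chrom, pos; sorted, strictly
#'   increasing positions per chromosome) and `transcripts` (transcript_id,
#'   chrom, start, end, unique_alignment).
#' @export
simulate_layout <- function(n_chrom, n_snps, n_transcripts, seed,
                            chrom_length_bp = 6e7) {
  n_chrom <- check_count(n_chrom, "n_chrom")
  n_snps <- check_count(n_snps, "n_snps")
  n_transcripts <- check_count(n_transcripts, "n_transcripts")
  L <- check_positive(chrom_length_bp, "chrom_length_bp")
  if (L < 1e7) stop_arg("`chrom_length_bp` must be at least 10 Mb")

  set.seed(derive_seed(seed, 1L))
  chroms <- paste0("chr", seq_len(n_chrom))

  ## SNP quota per chromosome, as even as possible
  quota <- rep(n_snps %/% n_chrom, n_chrom)
  extra <- n_snps %% n_chrom
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L

  snp_list <- vector("list", n_chrom)
  sparse_pos <- vector("list", n_chrom)  # isolated SNPs, >= 3 Mb apart
  for (k in seq_len(n_chrom)) {
    nk <- quota[k]
    if (nk == 0L) next
    n_sparse <- min(3L, max(0L, nk - 5L))
    n_dense <- nk - n_sparse
    dense <- sort(sample.int(floor(0.60 * L), n_dense)) - 1L
    sp <- integer(0)
    if (n_sparse > 0) {
      anchors <- floor(L * c(0.66, 0.70, 0.74))[seq_len(n_sparse)]
      sp <- anchors + sample(-10000:10000, n_sparse, replace = TRUE)
    }
    pos <- sort(unique(c(dense, sp)))
    ## resolve rare collisions so the per-chromosome count is exact
    while (length(pos) < nk) {
      pos <- sort(unique(c(pos, sample.int(floor(0.60 * L), nk - length(pos)) - 1L)))
    }
    snp_list[[k]] <- data.frame(chrom = chroms[k], pos = pos,
                                stringsAsFactors = FALSE)
    sparse_pos[[k]] <- sp
  }
  snps <- do.call(rbind, snp_list)
  snps <- snps[order(match(snps$chrom, chroms), snps$pos), , drop = FALSE]
  snps <- data.frame(snp_id = sprintf("SNP%06d", seq_len(nrow(snps))),
                     snps, stringsAsFactors = FALSE)
  rownames(snps) <- NULL

  ## Transcript class quotas (per genome)
  n_desert <- if (n_transcripts >= 3L) max(1L, floor(0.01 * n_transcripts)) else 0L
  n_sparse_t <- if (n_transcripts >= 4L) max(1L, floor(0.05 * n_transcripts)) else 0L
  n_rest <- n_transcripts - n_desert - n_sparse_t
  n_wide <- if (n_rest >= 1L) max(1L, floor(0.5 * n_rest)) else 0L
  n_free <- n_rest - n_wide

  classes <- c(rep("desert", n_desert), rep("sparse", n_sparse_t),
               rep("wide", n_wide), rep("free", n_free))
  tx_chrom <- chroms[((seq_len(n_transcripts) - 1L) %% n_chrom) + 1L]

  start <- integer(n_transcripts)
  end <- integer(n_transcripts)
  for (i in seq_len(n_transcripts)) {
    cl <- classes[i]
    ck <- tx_chrom[i]
    cpos <- snps$pos[snps$chrom == ck]
    if (cl == "desert") {
      lo <- floor(0.80 * L) + 260000
      w <- sample(5000:50000, 1L)
      start[i] <- sample(seq.int(lo, floor(L) - w - 1L), 1L)
      end[i] <- start[i] + w
    } else if (cl == "sparse") {
      sp <- sparse_pos[[match(ck, chroms)]]
      if (length(sp) == 0L) { cl <- "free"; classes[i] <- "free" } else {
        anchor <- sp[sample.int(length(sp), 1L)]
        w <- sample(5000:20000, 1L)
        start[i] <- anchor + 40000L   # near one isolated SNP, no overlap
        end[i] <- start[i] + w
      }
    }
    if (cl == "wide") {
      if (length(cpos) >= 5L) {
        j <- sample.int(length(cpos) - 4L, 1L)
        start[i] <- max(0L, cpos[j] - sample(100:2000, 1L))
        end[i] <- cpos[j + 4L] + sample(100:2000, 1L)
      } else cl <- classes[i] <- "free"
    }
    if (cl == "free") {
      w <- round(stats::rlnorm(1, log(30000), 0.8))
      w <- max(1000L, min(w, floor(0.1 * L)))
      start[i] <- sample.int(floor(0.60 * L) - w, 1L) - 1L
      end[i] <- start[i] + w
    }
  }

  transcripts <- data.frame(
    transcript_id = sprintf("T%05d", seq_len(n_transcripts)),
    chrom = tx_chrom, start = start, end = end,
    unique_alignment = TRUE, stringsAsFactors = FALSE)

  layout <- structure(list(
    chromosomes = data.frame(name = chroms, length = rep(floor(L), n_chrom),
                             stringsAsFactors = FALSE),
    snps = snps, transcripts = transcripts), class = "genome_layout")
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  s <- layout$snps
  tr <- layout$transcripts
  len <- stats::setNames(layout$chromosomes$length, layout$chromosomes$name)
  if (any(s$pos < 0) || any(s$pos >= len[s$chrom]))
    stop_arg("SNP positions must lie within [0, chromosome length)")
  for (ck in unique(s$chrom)) {
    p <- s$pos[s$chrom == ck]
    if (any(diff(p) <= 0)) stop_arg("SNP positions must be strictly increasing on %s", ck)
  }
  if (any(tr$start >= tr$end)) stop_arg("transcript start must be < end")
  if (anyDuplicated(tr$transcript_id)) stop_arg("duplicated transcript ids")
  invisible(layout)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %d SNPs, %d transcripts\n",
              nrow(x$chromosomes), nrow(x$snps), nrow(x$transcripts)))
  invisible(x)
}
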