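## Plain-text readers and writers. Annotation files are 1-based inclusive on
## disk (the array-annotation convention) and converted to the package's
## 0-based half-open internal coordinates on read.

#' Write a genome layout to annotation files
#'
#' Emits `chromosomes.tsv` (name, length), `snp_annotation.tsv` (snp_id,
#' chrom, pos; 1-based) and `transcript_annotation.tsv` (transcript_id,
#' chrom, start, end, unique_alignment; 1-based inclusive).
#'
#' @param layout a `genome_layout`; @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_layout <- function(layout, dir) {
  validate_layout(layout)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "chromosomes.tsv")
  p2 <- file.path(dir, "snp_annotation.tsv")
  p3 <- file.path(dir, "transcript_annotation.tsv")
  utils::write.table(layout$chromosomes, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- layout$snps
  s$pos <- s$pos + 1L
  utils::write.table(s, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- layout$transcripts
  tr$start <- tr$start + 1L     # end is exclusive internally == inclusive end
  utils::write.table(tr, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a genome layout from annotation files
#'
#' @param dir directory containing the files written by [write_layout()].
#' @return a `genome_layout`.
#' @export
read_layout <- function(dir) {
  ch <- utils::read.delim(file.path(dir, "chromosomes.tsv"),
                          stringsAsFactors = FALSE)
  s <- utils::read.delim(file.path(dir, "snp_annotation.tsv"),
                         stringsAsFactors = FALSE)
  tr <- utils::read.delim(file.path(dir, "transcript_annotation.tsv"),
                          stringsAsFactors = FALSE)
  s$pos <- s$pos - 1L
  tr$start <- tr$start - 1L
  if (!"unique_alignment" %in% names(tr)) tr$unique_alignment <- TRUE
  layout <- structure(list(chromosomes = ch, snps = s, transcripts = tr),
                      class = "genome_layout")
  validate_layout(layout)
}

#' Write / read a numeric matrix as TSV with an id column
#'
#' @param m matrix with rownames; @param path file path; @param id_col name
#'   of the first column holding rownames.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read the clinical table as CSV
#'
#' Columns: sample_id, case, age, sex, stage, followup_months, dead,
#' oscc_death.
#'
#' @param clinical data frame; @param path file path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the simulation ground truth as JSON
#'
#' Serializes the recorded truth of a simulated study: per-sample segment
#' ratios, per-transcript dosage slopes, case/control shifts and log hazard
#' ratios. The noise-free per-SNP ratio matrix is omitted (it is implied by
#' the segment table).
#'
#' @param truth a `truth_table` (optionally with casecontrol/survival truth
#'   attached, as returned by [simulate_study()]).
#' @param path output file path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(segment_truth = truth$segment_truth,
              dosage = truth$dosage,
              casecontrol = truth$casecontrol,
              survival = truth$survival)
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
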