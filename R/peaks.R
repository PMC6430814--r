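#' Read peak intervals from a BED6 / narrowPeak file
#'
#' Reads the first six columns of a BED file into a tibble of stranded
#' intervals. Coordinates stay 0-based half-open, as in the file. The strand
#' column is mandatory because every downstream step (read-start collection,
#' sequence context, allele counting) is strand-specific.
#'
#' Lines whose interval is inverted (`start >= end`) are rejected
#' individually and reported with their line numbers; a file with no valid
#' line returns an empty tibble with a warning.
#'
#' @param path Path to a BED6 or narrowPeak file (only the first six columns
#'   are used).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, in file order.
#' @export
read_peak_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character())
  if (length(lines) == 0 || all(lines == "")) {
    warn(sprintf("'%s' contains no peak records.", path))
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf(
      "BED line(s) %s have fewer than 6 columns; a strand column is required.",
      paste(head(which(nf < 6), 5), collapse = ", ")))
  }
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  peaks <- tibble(
    chrom = mat[, 1],
    start = suppressWarnings(as.integer(mat[, 2])),
    end = suppressWarnings(as.integer(mat[, 3])),
    name = mat[, 4],
    score = suppressWarnings(as.numeric(mat[, 5])),
    strand = mat[, 6]
  )
  check_strand(peaks$strand)
  bad <- which(is.na(peaks$start) | is.na(peaks$end) |
                 peaks$start < 0 | peaks$start >= peaks$end)
  if (length(bad) > 0) {
    warn(sprintf("Rejected %d malformed BED line(s): %s",
                 length(bad), paste(head(bad, 10), collapse = ", ")))
    peaks <- peaks[-bad, ]
  }
  if (nrow(peaks) == 0) warn(sprintf("'%s' contains no valid peak records.", path))
  peaks
}

#' Library size in millions of usable reads
#'
#' The per-replicate scaling factor used both for peak retention
#' (reads-per-million coverage) and allelic count normalisation. "Usable"
#' reads are the deduplicated, uniquely mapped reads produced by the upstream
#' mapping pipeline; when given a BAM path the count excludes unmapped,
#' secondary, supplementary and QC-fail records and, for paired data,
#' counts only second-in-pair mates (the mate whose 5' end marks the
#' crosslink site).
#'
#' @param x Either a single numeric read count or the path to an indexed BAM
#'   file.
#' @param paired_end Only used for BAM input: when `TRUE` (default) count
#'   read-2 mates only; when `FALSE` every usable read counts.
#' @param mapq_min Minimum mapping quality for BAM input.
#' @return Usable reads divided by 1e6.
#' @export
library_size_millions <- function(x, paired_end = TRUE, mapq_min = 10) {
  if (is.numeric(x) && length(x) == 1) {
    n <- x
  } else if (is.character(x) && length(x) == 1) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      abort("Counting reads in a BAM file requires the Rsamtools package.")
    }
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE,
      isSecondMateRead = if (paired_end) TRUE else NA)
    n <- Rsamtools::countBam(
      x, param = Rsamtools::ScanBamParam(
        flag = flag, mapqFilter = mapq_min))$records
  } else {
    abort("`x` must be a read count or a BAM path.")
  }
  if (n <= 0) abort("Zero usable reads: library-size normalization is undefined.")
  n / 1e6
}

#' Retain peaks enriched over the size-matched input
#'
#' A peak is kept when its library-normalised (reads-per-million) coverage in
#' at least one eCLIP replicate is at least `fold` times the normalised
#' coverage of the same region in the SMInput control. The threshold is
#' inclusive, and a peak with SMInput coverage 0 but any eCLIP coverage is
#' always kept (the fold change is effectively infinite).
#'
#' @param peaks Tibble of peaks carrying one column per replicate coverage
#'   (names given by `rep_cols`, default every column matching `^rep_`) and an
#'   `input_coverage` column, all raw read counts over the peak interval.
#' @param rep_library_sizes Numeric vector, usable reads (millions) per
#'   replicate, in the order of `rep_cols`.
#' @param input_library_size Usable reads (millions) in the SMInput library.
#' @param fold Enrichment threshold (default 4).
#' @param rep_cols Names of the replicate coverage columns.
#' @return The retained subset of `peaks` (row order preserved), with an
#'   `"attrition"` attribute tibble (`n_in`, `n_retained`, `n_dropped`,
#'   `fold`) retrievable with [attrition()].
#' @export
retain_peaks <- function(peaks, rep_library_sizes, input_library_size,
                         fold = 4, rep_cols = grep("^rep_", names(peaks), value = TRUE)) {
  stopifnot(length(rep_cols) >= 1, "input_coverage" %in% names(peaks))
  if (length(rep_library_sizes) != length(rep_cols)) {
    abort("One library size per replicate coverage column is required.")
  }
  if (any(rep_library_sizes <= 0) || input_library_size <= 0) {
    abort("Library sizes must be positive.")
  }
  rep_rpm <- sweep(as.matrix(peaks[rep_cols]), 2, rep_library_sizes, "/")
  input_rpm <- peaks$input_coverage / input_library_size
  keep <- rowSums(rep_rpm >= fold * input_rpm & rep_rpm > 0) > 0
  out <- peaks[keep, , drop = FALSE]
  attr(out, "attrition") <- tibble(
    n_in = nrow(peaks), n_retained = sum(keep),
    n_dropped = sum(!keep), fold = fold)
  out
}

#' Retrieve the attrition report attached to a filtered object
#' @param x An object returned by [retain_peaks()] or [apply_filter_chain()].
#' @return The attrition tibble, or `NULL` if none is attached.
#' @export
attrition <- function(x) attr(x, "attrition")
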