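#' Call allele-specific binding from tabular eCLIP inputs
#'
#' End-to-end orchestration over the package's tabular containers: call
#' heterozygous SNVs from pooled SMInput counts (optionally merged with a
#' user list), assign each SNV its offset to the nearest crosslink site,
#' bias-normalise the replicate counts, fit the variance trend, run the
#' empirical Gaussian test and adjust with Benjamini-Hochberg. BAM/VCF/FASTA
#' inputs are converted to these tables at the boundary with
#' [count_alleles_bam()], [read_snv_vcf()] and [read_genome_fasta()].
#'
#' @param counts Long tibble of per-replicate allelic counts: `snv_id`,
#'   `chrom`, `pos`, `strand`, `ref`, `alt`, `replicate`, `y_ref`, `y_alt`.
#' @param sminput_counts Pooled SMInput counts per SNV: `snv_id`, `y_ref`,
#'   `y_alt`.
#' @param crosslink_sites Tibble `chrom`, `pos`, `strand` of called
#'   crosslink sites (used for offsets); `NULL` places every SNV outside
#'   the bias window.
#' @param bias `bias_table` estimated from the SMInput (see
#'   [estimate_bias_table()]); `NULL` falls back to the uniform table (no
#'   sequence correction, per-million scaling only).
#' @param library_sizes Named numeric vector of replicate library sizes in
#'   millions.
#' @param user_snvs Optional user heterozygous SNVs merged via
#'   [merge_with_user_snvs()]; identified by `chrom`/`pos`.
#' @param het_min_cov,het_ratio_low,het_ratio_high Heterozygous-call
#'   thresholds (see [call_heterozygous()]).
#' @param fdr_threshold ASB significance threshold (default 0.10).
#' @param span LOESS span for the variance trend.
#' @param trend Optional pre-fitted `variance_trend` (useful when the tested
#'   subset is too small to train one).
#' @return An `asb_result` (see [asb_test()]) carrying `chrom`, `pos`,
#'   `ref`, `alt` columns, restricted to heterozygous SNVs.
#' @export
asb_call <- function(counts, sminput_counts, crosslink_sites = NULL,
                     bias = NULL, library_sizes = 1, user_snvs = NULL,
                     het_min_cov = 10, het_ratio_low = 0.25,
                     het_ratio_high = 0.75, fdr_threshold = 0.10,
                     span = 0.75, trend = NULL) {
  het <- sminput_counts$snv_id[
    call_heterozygous(sminput_counts$y_ref, sminput_counts$y_alt,
                      het_min_cov, het_ratio_low, het_ratio_high)]
  snvs <- distinct(counts, .data$snv_id, .data$chrom, .data$pos,
                   .data$strand, .data$ref, .data$alt)
  keep <- snvs$snv_id %in% het
  if (!is.null(user_snvs)) {
    keep <- keep | paste(snvs$chrom, snvs$pos) %in%
      paste(user_snvs$chrom, user_snvs$pos)
  }
  snvs <- snvs[keep, , drop = FALSE]
  if (nrow(snvs) == 0) abort("No heterozygous SNV passes the SMInput thresholds.")
  offsets <- rep(NA_integer_, nrow(snvs))
  if (!is.null(crosslink_sites) && nrow(crosslink_sites) > 0) {
    for (i in seq_len(nrow(snvs))) {
      sites <- crosslink_sites[crosslink_sites$chrom == snvs$chrom[i], ]
      offsets[i] <- assign_offset(snvs$pos[i], sites$pos, snvs$strand[i])
    }
  }
  snvs$offset <- offsets
  work <- counts |>
    filter(.data$snv_id %in% snvs$snv_id) |>
    left_join(snvs[c("snv_id", "offset")], by = "snv_id") |>
    normalize_allelic_counts(bias %||% uniform_bias_table(), library_sizes)
  res <- asb_test(work, trend = trend, span = span, fdr_threshold = fdr_threshold)
  left_join(snvs[c("snv_id", "chrom", "pos", "ref", "alt", "offset")],
            res, by = "snv_id") |>
    structure(trend = attr(res, "trend"),
              fdr_threshold = fdr_threshold,
              class = c("asb_result", class(snvs)))
}

#' Write / read the ASB result table
#'
#' Tab-separated, one row per tested SNV, deterministically ordered by
#' `chrom`, `pos` and (when present) `rbp`. The genomic position is printed
#' 1-based in the `pos` column for human readability and converted back on
#' reading; numeric columns round-trip to at least 12 significant digits.
#'
#' @param records An `asb_result` or compatible tibble with `chrom`, `pos`
#'   (0-based internally).
#' @param path Output path.
#' @return `write_asb_table()` returns `records` invisibly;
#'   `read_asb_table()` returns a tibble with 0-based `pos`.
#' @export
write_asb_table <- function(records, path) {
  out <- as_tibble(records)
  out$pos <- out$pos + 1L
  sort_cols <- intersect(c("chrom", "pos", "rbp"), names(out))
  out <- arrange(out, across(dplyr::all_of(sort_cols)))
  readr::write_tsv(out, path)
  invisible(records)
}

#' @rdname write_asb_table
#' @export
read_asb_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  out$pos <- out$pos - 1L
  out
}

#' Read eCLIP read alignments from a BAM file into a tibble
#'
#' Applies the usable-read filters (mapped, primary, non-supplementary,
#' QC-pass, MAPQ threshold) and restricts to second-in-pair mates for
#' paired data, since the read-2 5' end marks the crosslink site.
#'
#' @param bam Path to an indexed BAM file.
#' @param paired_end Keep read-2 mates only (default `TRUE`); `FALSE`
#'   treats every read as marking the truncation (single-end protocol).
#' @param mapq_min Minimum mapping quality (default 10).
#' @return Tibble with `chrom`, `start` (0-based), `end` (exclusive),
#'   `strand` — the fragment strand of the read.
#' @export
read_eclip_reads <- function(bam, paired_end = TRUE, mapq_min = 10) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Reading BAM requires the Rsamtools package.")
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE,
    isSecondMateRead = if (paired_end) TRUE else NA)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = flag, mapqFilter = mapq_min,
      what = c("rname", "pos", "qwidth", "strand", "cigar")))[[1]]
  width <- GenomicAlignments_width(res$cigar, res$qwidth)
  tibble(chrom = as.character(res$rname),
         start = res$pos - 1L,
         end = res$pos - 1L + width,
         strand = as.character(res$strand))
}

# reference-spanning width from CIGAR (M/D/N/=/X consume reference)
GenomicAlignments_width <- function(cigar, qwidth) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg)) return(qwidth[i])
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    lens <- regmatches(cg, gregexpr("[0-9]+", cg))[[1]]
    kinds <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(lens)[kinds %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}
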