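#' Count alleles at an SNV from per-base pileup calls
#'
#' Tallies reference, alternative and other base calls at a candidate SNV,
#' discarding calls below the base-quality threshold. Deletions and
#' reference skips must already be absent from `bases` (they carry no base
#' call). Third-allele ("other") reads are counted but excluded from allelic
#' ratios downstream.
#'
#' @param bases Tibble of pileup calls at the SNV with columns `base` and
#'   `qual` (numeric, Phred scale).
#' @param ref,alt Reference and alternative allele (single bases, distinct).
#' @param min_base_quality Minimum base quality (default 10). Raw base
#'   qualities are used unless the upstream pipeline stored realigned
#'   (BAQ-adjusted) qualities, in which case those are honoured transparently.
#' @return One-row tibble with `y_ref`, `y_alt`, `y_other`.
#' @export
count_alleles <- function(bases, ref, alt, min_base_quality = 10) {
  stopifnot(ref %in% DNA_BASES, alt %in% DNA_BASES, ref != alt)
  keep <- bases$qual >= min_base_quality
  b <- bases$base[keep]
  tibble(y_ref = sum(b == ref), y_alt = sum(b == alt),
         y_other = sum(b != ref & b != alt))
}

#' Count alleles at candidate SNVs from a BAM file
#'
#' Pileup-based allele counting over an indexed BAM, applying the usable-read
#' filters (mapped, primary, non-supplementary, QC-pass, MAPQ and base
#' quality thresholds) and, for paired data, restricting to read-2 mates.
#'
#' @param bam Path to an indexed BAM file.
#' @param snvs Tibble with columns `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param min_base_quality Minimum base quality (default 10).
#' @param mapq_min Minimum mapping quality (default 10).
#' @param paired_end Restrict to second-in-pair mates (default `TRUE`); set
#'   `FALSE` for single-end libraries where every read marks the truncation.
#' @return `snvs` with columns `y_ref`, `y_alt`, `y_other` added.
#' @export
count_alleles_bam <- function(bam, snvs, min_base_quality = 10, mapq_min = 10,
                              paired_end = TRUE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("BAM pileup counting requires the Rsamtools package.")
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE,
    isSecondMateRead = if (paired_end) TRUE else NA)
  which <- GenomicRanges::GRanges(snvs$chrom,
                                  IRanges::IRanges(snvs$pos + 1L, snvs$pos + 1L))
  pu <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(flag = flag, which = which,
                                           mapqFilter = mapq_min),
    pileupParam = Rsamtools::PileupParam(
      min_base_quality = min_base_quality, min_mapq = mapq_min,
      distinguish_strands = FALSE, include_deletions = FALSE,
      include_insertions = FALSE, max_depth = 1e6))
  out <- snvs
  out$y_ref <- out$y_alt <- out$y_other <- 0L
  for (i in seq_len(nrow(snvs))) {
    rows <- pu[pu$seqnames == snvs$chrom[i] & pu$pos == snvs$pos[i] + 1L, ]
    counts <- stats::setNames(rows$count, as.character(rows$nucleotide))
    y <- function(b) sum(counts[names(counts) == b])
    out$y_ref[i] <- y(snvs$ref[i])
    out$y_alt[i] <- y(snvs$alt[i])
    out$y_other[i] <- sum(counts) - out$y_ref[i] - out$y_alt[i]
  }
  out
}

#' Call heterozygous SNVs from pooled SMInput counts
#'
#' A candidate site is declared heterozygous when the pooled SMInput
#' coverage (`y_ref + y_alt`) reaches `min_cov` and the reference allelic
#' ratio lies within `[ratio_low, ratio_high]` (bounds inclusive). Third
#' alleles do not enter the ratio.
#'
#' @param y_ref,y_alt Integer vectors of pooled SMInput allele counts.
#' @param min_cov Minimum total coverage (default 10).
#' @param ratio_low,ratio_high Inclusive bounds on the reference ratio
#'   (defaults 0.25 and 0.75).
#' @return Logical vector.
#' @export
call_heterozygous <- function(y_ref, y_alt, min_cov = 10,
                              ratio_low = 0.25, ratio_high = 0.75) {
  total <- y_ref + y_alt
  ratio <- ifelse(total > 0, y_ref / total, NA_real_)
  !is.na(ratio) & total >= min_cov & ratio >= ratio_low & ratio <= ratio_high
}

#' Read candidate or genotyped SNVs from a VCF
#'
#' Bi-allelic SNVs only; indels and multi-allelic records are skipped with a
#' warning. With `het_only = TRUE` the first sample's genotype must be
#' heterozygous (0/1, 0|1 or 1|0).
#'
#' @param path VCF (v4.x) path.
#' @param het_only Keep only heterozygous genotypes (requires a genotype
#'   column).
#' @param source Source tag stored with each record (default `"user"`).
#' @return Tibble with `chrom`, `pos` (0-based), `ref`, `alt`, `source`.
#' @export
read_snv_vcf <- function(path, het_only = FALSE, source = "user") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  if (any(!keep)) {
    warn(sprintf("Skipped %d non-bi-allelic-SNV record(s).", sum(!keep)))
  }
  if (het_only) {
    gt <- vcfR::extract.gt(v, element = "GT")[, 1]
    keep <- keep & gt %in% c("0/1", "0|1", "1|0")
  }
  tibble(chrom = fix$CHROM[keep],
         pos = as.integer(fix$POS[keep]) - 1L,
         ref = fix$REF[keep], alt = fix$ALT[keep],
         source = source)
}

#' Merge called heterozygous SNVs with a user-provided list
#'
#' Union keyed on `(chrom, pos)`. Where both lists carry the same position,
#' the user record wins; if its alleles disagree with the called record a
#' warning is raised.
#'
#' @param called Tibble of SMInput-called heterozygous SNVs (`chrom`, `pos`,
#'   `ref`, `alt`, `source`).
#' @param user Tibble of user heterozygous SNVs, same columns.
#' @return Combined tibble, sorted by `chrom`, `pos`.
#' @export
merge_with_user_snvs <- function(called, user) {
  key <- function(d) paste(d$chrom, d$pos)
  dup <- key(called) %in% key(user)
  if (any(dup)) {
    conf <- merge(called[dup, c("chrom", "pos", "ref", "alt")],
                  user[, c("chrom", "pos", "ref", "alt")],
                  by = c("chrom", "pos"), suffixes = c("_called", "_user"))
    n_conflict <- sum(conf$ref_called != conf$ref_user | conf$alt_called != conf$alt_user)
    if (n_conflict > 0) {
      warn(sprintf("%d position(s) with conflicting alleles; user records kept.",
                   n_conflict))
    }
  }
  arrange(bind_rows(user, called[!dup, , drop = FALSE]), .data$chrom, .data$pos)
}
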