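# internal helpers ----------------------------------------------------------

# coerce a genome to a named character vector of chromosome sequences;
# accepts a named character vector or a Biostrings::DNAStringSet
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      abort("`genome` must be a *named* character vector of chromosome sequences.")
    }
    return(toupper(genome))
  }
  if (inherits(genome, "DNAStringSet")) {
    return(toupper(stats::setNames(as.character(genome), names(genome))))
  }
  abort("`genome` must be a named character vector or a DNAStringSet.")
}

#' Read a genome FASTA into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; sequence names are
#' truncated at the first whitespace so they match BED/VCF chromosome names.
#'
#' @param path Path to an (optionally gzipped) FASTA file.
#' @return Named character vector of upper-case chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Reading FASTA requires the Biostrings package.")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_genome(seqs)
}

# reverse complement of upper-case DNA strings (vectorised)
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

# strand-aware substring extraction: returns the window [start, end] (1-based,
# inclusive, genomic orientation) of `chrom`, reverse-complemented on "-"
genome_window <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(sprintf("Chromosome '%s' not present in the genome.", chrom))
  }
  s <- substr(genome[[chrom]], start, end)
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' (eCLIP analysis is strand-specific).")
  }
  invisible(strand)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}
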