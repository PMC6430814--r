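#' Collect read-start pileups within a peak
#'
#' Reverse transcription truncates at the protein-RNA crosslink, so the
#' biological 5' end of a read-2 mate marks the crosslink site. For reads on
#' the `+` strand that is the leftmost aligned base; on the `-` strand the
#' rightmost. Only reads on the peak strand contribute.
#'
#' @param reads Tibble of usable read-2 alignments with columns `start`
#'   (0-based), `end` (0-based exclusive) and `strand`.
#' @param peak A single-row tibble or list with `start`, `end`, `strand`.
#' @return Tibble with columns `pos` (0-based genomic coordinate) and `m`
#'   (number of reads starting there); positions with no read start are
#'   omitted.
#' @export
collect_read_starts <- function(reads, peak) {
  check_strand(peak$strand)
  reads <- reads[reads$strand == peak$strand, , drop = FALSE]
  starts <- if (identical(peak$strand, "+")) reads$start else reads$end - 1L
  starts <- starts[starts >= peak$start & starts < peak$end]
  if (length(starts) == 0) return(tibble(pos = integer(), m = integer()))
  tab <- table(starts)
  tibble(pos = as.integer(names(tab)), m = as.integer(tab))
}

#' Call crosslink sites by permutation FDR
#'
#' Candidate sites are positions whose read-start count `m` is improbably
#' large under a null in which the peak's read starts fall uniformly at
#' random over the peak. For each observed count threshold `m`, the empirical
#' FDR is the permutation mean of the number of positions reaching `m`
#' divided by the observed number; sites with FDR at or below `max_fdr` are
#' called. A peak may yield several sites (read-through of a 3' crosslink can
#' create secondary truncation points).
#'
#' @param start_counts Tibble from [collect_read_starts()] (`pos`, `m`).
#' @param peak_length Peak width in nucleotides.
#' @param n_perm Number of permutations (default 1000).
#' @param max_fdr Maximum empirical FDR for a called site (default 0.001).
#' @return Tibble with columns `pos`, `m`, `fdr`, restricted to called sites
#'   and sorted by position.
#' @export
call_crosslink_sites <- function(start_counts, peak_length, n_perm = 1000,
                                 max_fdr = 0.001) {
  if (peak_length < 1) abort("`peak_length` must be at least 1.")
  if (n_perm < 100) abort("Use at least 100 permutations for a stable FDR.")
  if (nrow(start_counts) == 0) {
    return(tibble(pos = integer(), m = integer(), fdr = double()))
  }
  n_reads <- sum(start_counts$m)
  thresholds <- sort(unique(start_counts$m))
  exceed <- matrix(0, n_perm, length(thresholds))
  for (b in seq_len(n_perm)) {
    counts <- tabulate(sample.int(peak_length, n_reads, replace = TRUE),
                       nbins = peak_length)
    counts <- counts[counts > 0]
    for (t in seq_along(thresholds)) {
      exceed[b, t] <- sum(counts >= thresholds[t])
    }
  }
  obs <- vapply(thresholds, function(m) sum(start_counts$m >= m), numeric(1))
  fdr_by_thr <- colMeans(exceed) / obs
  # FDR is monotone non-increasing in the count threshold
  fdr_by_thr <- rev(cummin(rev(pmin(fdr_by_thr, 1))))
  fdr <- fdr_by_thr[match(start_counts$m, thresholds)]
  out <- start_counts
  out$fdr <- fdr
  arrange(out[out$fdr <= max_fdr, , drop = FALSE], .data$pos)
}

# bias table -----------------------------------------------------------------

new_bias_table <- function(q, n_sites, flank = 25) {
  stopifnot(is.matrix(q), nrow(q) == 4, ncol(q) == 2 * flank + 1)
  dimnames(q) <- list(DNA_BASES, as.character(-flank:flank))
  structure(q, n_sites = n_sites, class = c("bias_table", class(q)))
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf("<bias_table> crosslink sequence propensity q(a, d), %d offsets, %s sites\n",
              ncol(x), format(attr(x, "n_sites"))))
  print(round(unclass(x)[, c(1, 2, 25, 26, 27, 50, 51)], 3))
  invisible(x)
}

#' Estimate the crosslinking sequence propensity from SMInput sites
#'
#' For every offset `d` in `[-flank, flank]` around each crosslink site
#' called in the SMInput sample, counts the strand-oriented reference base and
#' converts the counts to relative frequencies `q(a, d)`. Sites on the `-`
#' strand contribute their reverse-complemented context. Sites whose window
#' leaves the chromosome, or whose window contains a non-ACGT base, are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param sites Tibble with columns `chrom`, `pos` (0-based), `strand`.
#' @param genome Named character vector of chromosome sequences or a
#'   `DNAStringSet` (see [read_genome_fasta()]).
#' @param flank Window half-width (default 25).
#' @return A `bias_table`: 4 x (2*flank+1) matrix of `q(a, d)` with rows
#'   A, C, G, T and columns `-flank ... flank`; every column sums to 1.
#' @export
estimate_bias_table <- function(sites, genome, flank = 25) {
  genome <- as_genome(genome)
  if (nrow(sites) == 0) abort("No crosslink sites supplied.")
  check_strand(sites$strand)
  width <- 2 * flank + 1
  contexts <- character(0)
  n_skipped <- 0
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(genome)) abort(sprintf("Chromosome '%s' not in genome.", chrom))
    lo <- sites$pos[i] - flank + 1L  # 1-based window start
    hi <- sites$pos[i] + flank + 1L
    if (lo < 1 || hi > nchar(genome[[chrom]])) {
      n_skipped <- n_skipped + 1
      next
    }
    ctx <- genome_window(genome, chrom, lo, hi, sites$strand[i])
    if (grepl("[^ACGT]", ctx)) {
      n_skipped <- n_skipped + 1
      next
    }
    contexts <- c(contexts, ctx)
  }
  if (length(contexts) == 0) abort("No usable crosslink sites (all windows skipped).")
  mat <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  counts <- apply(mat, 2, function(col) tabulate(factor(col, DNA_BASES), 4))
  q <- counts / length(contexts)
  out <- new_bias_table(q, n_sites = length(contexts), flank = flank)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Uniform (bias-free) propensity table
#' @param flank Window half-width (default 25).
#' @return A `bias_table` with `q(a, d) = 0.25` everywhere.
#' @export
uniform_bias_table <- function(flank = 25) {
  new_bias_table(matrix(0.25, 4, 2 * flank + 1), n_sites = 0, flank = flank)
}

#' Synthetic crosslink propensity table for simulation
#'
#' A smooth, uridine-enriched propensity mimicking the shape seen in eCLIP
#' SMInput data: T (U on the RNA) peaks at the crosslink site and decays to
#' the neutral 0.25 away from it, the other three bases sharing the
#' remainder equally.
#'
#' @param t_peak Excess T propensity at offset 0 (default 0.30, i.e.
#'   `q(T, 0) = 0.55`).
#' @param decay Exponential decay length in nucleotides (default 4).
#' @param flank Window half-width (default 25).
#' @return A `bias_table`.
#' @export
synthetic_bias_table <- function(t_peak = 0.30, decay = 4, flank = 25) {
  stopifnot(t_peak >= 0, t_peak < 0.75, decay > 0)
  d <- -flank:flank
  tq <- 0.25 + t_peak * exp(-abs(d) / decay)
  q <- rbind((1 - tq) / 3, (1 - tq) / 3, (1 - tq) / 3, tq)
  new_bias_table(q, n_sites = 0, flank = flank)
}

#' Write / read a bias table as TSV
#'
#' The on-disk format is a 4 x (2*flank+1) grid with a header row of offsets
#' and a leading `base` column.
#'
#' @param bias A `bias_table`.
#' @param path File path.
#' @return `write_bias_table()` returns `bias` invisibly; `read_bias_table()`
#'   returns a `bias_table`.
#' @export
write_bias_table <- function(bias, path) {
  df <- data.frame(base = rownames(bias), unclass(bias), check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(bias)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  q <- as.matrix(df[, -1])
  flank <- (ncol(q) - 1) / 2
  new_bias_table(q[match(DNA_BASES, df$base), , drop = FALSE],
                 n_sites = NA_integer_, flank = flank)
}

#' Strand-oriented offset of an SNV to its nearest crosslink site
#'
#' Returns the offset `d` used to look up `q(a, d)`: the signed,
#' strand-oriented distance from the nearest called crosslink site to the
#' SNV. Ties between two equidistant sites are broken towards the 5' site.
#' When the peak has no site, or the nearest site is farther than `flank`,
#' `NA` is returned ("outside" the bias window, where `q` defaults to 0.25).
#'
#' @param snv_pos Integer vector of SNV positions (0-based).
#' @param site_pos Integer vector of crosslink site positions in the same
#'   peak (0-based).
#' @param strand Peak strand, `"+"` or `"-"`.
#' @param flank Bias window half-width (default 25).
#' @return Integer vector of offsets, `NA` for "outside".
#' @export
assign_offset <- function(snv_pos, site_pos, strand = "+", flank = 25) {
  check_strand(strand)
  if (length(site_pos) == 0) return(rep(NA_integer_, length(snv_pos)))
  vapply(snv_pos, function(p) {
    d_genomic <- p - site_pos
    dist <- abs(d_genomic)
    nearest <- which(dist == min(dist))
    if (length(nearest) > 1) {
      # 5' site: smaller coordinate on "+", larger on "-"
      pick <- if (identical(strand, "+")) which.min(site_pos[nearest])
              else which.max(site_pos[nearest])
      nearest <- nearest[pick]
    }
    d <- if (identical(strand, "+")) d_genomic[nearest] else -d_genomic[nearest]
    if (abs(d) > flank) NA_integer_ else as.integer(d)
  }, integer(1))
}

#' Look up the crosslink propensity q(a, d)
#'
#' Offsets outside the window (`NA` or |d| > flank) return the neutral 0.25.
#' Propensities of exactly zero (an allele base never observed at that offset
#' in the SMInput) are floored at `q_floor` with a warning: a finite-sample
#' zero would otherwise make the normalised count infinite.
#'
#' @param bias A `bias_table`.
#' @param allele Character vector of bases (A/C/G/T).
#' @param offset Integer vector of offsets (`NA` = outside window).
#' @param q_floor Lower floor applied to zero propensities (default 0.005).
#' @return Numeric vector of propensities.
#' @export
bias_propensity <- function(bias, allele, offset, q_floor = 0.005) {
  stopifnot(inherits(bias, "bias_table"))
  if (!all(allele %in% DNA_BASES)) abort("Alleles must be A, C, G or T.")
  flank <- (ncol(bias) - 1) / 2
  q <- rep(0.25, length(allele))
  inside <- !is.na(offset) & abs(offset) <= flank
  if (any(inside)) {
    q[inside] <- unclass(bias)[cbind(allele[inside], as.character(offset[inside]))]
  }
  if (any(q == 0)) {
    warn(sprintf("%d zero propensity value(s) floored at %g.", sum(q == 0), q_floor))
    q[q == 0] <- q_floor
  }
  q
}

#' Bias-normalise allelic read counts
#'
#' Applies the crosslink-bias and library-size correction
#' `x = y / (q(a, d) * R)` to the raw allelic counts of every record, where
#' `q` is the propensity of the allele base at the record's offset from the
#' nearest crosslink site and `R` the replicate's usable reads in millions.
#'
#' @param counts Tibble with columns `ref`, `alt` (allele bases), `offset`
#'   (integer or `NA`), `replicate`, and raw counts `y_ref`, `y_alt`.
#' @param bias A `bias_table`.
#' @param library_sizes Named numeric vector of library sizes (millions),
#'   names matching `counts$replicate`; or a single number used for all.
#' @param q_floor Passed to [bias_propensity()].
#' @return `counts` with columns `x_ref` and `x_alt` added.
#' @export
normalize_allelic_counts <- function(counts, bias, library_sizes, q_floor = 0.005) {
  if (length(library_sizes) == 1 && is.null(names(library_sizes))) {
    R <- rep(library_sizes, nrow(counts))
  } else {
    R <- unname(library_sizes[as.character(counts$replicate)])
    if (any(is.na(R))) abort("Every replicate needs a library size.")
  }
  if (any(R <= 0)) abort("Library sizes must be positive.")
  q_ref <- bias_propensity(bias, counts$ref, counts$offset, q_floor)
  q_alt <- bias_propensity(bias, counts$alt, counts$offset, q_floor)
  mutate(counts,
         x_ref = .data$y_ref / (q_ref * R),
         x_alt = .data$y_alt / (q_alt * R))
}
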