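# Posterior quality filters applied to ASB candidates on real data.
# Each filter is a pure keep/remove predicate over a candidate table with
# columns chrom, pos (0-based) and, where needed, rbp / gene / ratio.

#' Homopolymer filter
#'
#' Removes candidates lying inside a run of five or more identical
#' reference bases (the run counts the candidate position itself and may be
#' longer than five). Single-nucleotide evidence inside homopolymers is
#' unreliable for the same reasons as in RNA-editing detection.
#'
#' @param candidates Tibble with `chrom`, `pos` (0-based).
#' @param genome Named character vector or `DNAStringSet`.
#' @param min_run Minimum run length (default 5).
#' @return Logical keep vector.
#' @export
filter_homopolymer <- function(candidates, genome, min_run = 5) {
  genome <- as_genome(genome)
  vapply(seq_len(nrow(candidates)), function(i) {
    chrom <- candidates$chrom[i]
    p1 <- candidates$pos[i] + 1L  # 1-based
    len <- nchar(genome[[chrom]])
    lo <- max(1L, p1 - (min_run - 1L))
    hi <- min(len, p1 + (min_run - 1L))
    window <- strsplit(substr(genome[[chrom]], lo, hi), "", fixed = TRUE)[[1]]
    centre <- p1 - lo + 1L
    if (length(window) < min_run) return(TRUE)
    # any window of min_run consecutive identical bases containing the centre?
    first <- max(1L, centre - min_run + 1L)
    last <- min(centre, length(window) - min_run + 1L)
    if (first > last) return(TRUE)
    for (s in first:last) {
      if (length(unique(window[s:(s + min_run - 1L)])) == 1) return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Microsatellite filter
#'
#' Removes candidates overlapping annotated microsatellite intervals
#' (0-based half-open overlap, so a position equal to an interval's `end` is
#' kept).
#'
#' @param candidates Tibble with `chrom`, `pos`.
#' @param microsatellites Tibble with `chrom`, `start`, `end` (may be empty).
#' @return Logical keep vector.
#' @export
filter_microsatellite <- function(candidates, microsatellites) {
  if (nrow(microsatellites) == 0) return(rep(TRUE, nrow(candidates)))
  vapply(seq_len(nrow(candidates)), function(i) {
    ms <- microsatellites[microsatellites$chrom == candidates$chrom[i], ]
    !any(candidates$pos[i] >= ms$start & candidates$pos[i] < ms$end)
  }, logical(1))
}

#' Mappability filter
#'
#' Removes candidates whose 101-nt centred sequence has a best off-target
#' identity of at least `max_identity` elsewhere in the genome. The
#' similarity source is pluggable: supply a precomputed per-SNV table (from
#' any aligner) with columns `chrom`, `pos`, `identity`. Candidates absent
#' from the table are kept with a warning (set `strict = TRUE` to drop
#' them instead).
#'
#' @param candidates Tibble with `chrom`, `pos`.
#' @param similarity Tibble `chrom`, `pos`, `identity` (fractions in [0,1]).
#' @param max_identity Inclusive removal threshold (default 0.95).
#' @param strict Drop candidates missing from the table (default `FALSE`).
#' @return Logical keep vector.
#' @export
filter_mappability <- function(candidates, similarity, max_identity = 0.95,
                               strict = FALSE) {
  key <- paste(candidates$chrom, candidates$pos)
  skey <- paste(similarity$chrom, similarity$pos)
  idx <- match(key, skey)
  missing <- is.na(idx)
  if (any(missing)) {
    warn(sprintf("%d candidate(s) missing from the similarity table: %s.",
                 sum(missing), if (strict) "removed" else "kept"))
  }
  keep <- rep(TRUE, nrow(candidates))
  keep[!missing] <- similarity$identity[idx[!missing]] < max_identity
  keep[missing] <- !strict
  keep
}

#' Detect allele-specific-expression (ASE) genes from RNA-Seq allelic counts
#'
#' Within one RNA-Seq data set a gene is ASE when it has at least
#' `min_snvs` testable heterozygous SNVs (total count >= `min_reads`) and
#' every testable SNV is allelically biased at BH FDR < `fdr` (exact
#' binomial test against 0.5, adjusted across all testable SNVs of the data
#' set). A gene is a confirmed ASE gene when it is ASE in at least
#' `n_datasets` data sets and, in each of those, the reference allele
#' frequency of all its testable SNVs is outside `[ratio_bounds[1],
#' ratio_bounds[2]]`.
#'
#' @param rna Tibble with columns `dataset`, `gene`, `snv_id`, `y_ref`,
#'   `y_alt`.
#' @param min_snvs,min_reads,fdr,n_datasets,ratio_bounds See description.
#' @return Character vector of confirmed ASE gene names.
#' @export
detect_ase_genes <- function(rna, min_snvs = 2, min_reads = 10, fdr = 0.05,
                             n_datasets = 2, ratio_bounds = c(0.40, 0.60)) {
  per_ds <- rna |>
    mutate(total = .data$y_ref + .data$y_alt,
           testable = .data$total >= min_reads) |>
    filter(.data$testable)
  if (nrow(per_ds) == 0) return(character(0))
  per_ds <- per_ds |>
    group_by(.data$dataset) |>
    mutate(p_bias = purrr::map2_dbl(.data$y_ref, .data$total,
                                    ~ stats::binom.test(.x, .y, 0.5)$p.value),
           fdr_bias = stats::p.adjust(.data$p_bias, "BH"),
           ratio = .data$y_ref / .data$total) |>
    ungroup()
  gene_ds <- per_ds |>
    group_by(.data$dataset, .data$gene) |>
    summarise(n_testable = n(),
              all_biased = all(.data$fdr_bias < fdr),
              all_extreme = all(.data$ratio < ratio_bounds[1] |
                                  .data$ratio > ratio_bounds[2]),
              .groups = "drop") |>
    filter(.data$n_testable >= min_snvs, .data$all_biased)
  confirmed <- gene_ds |>
    group_by(.data$gene) |>
    summarise(n_ds = n(), extreme_everywhere = all(.data$all_extreme),
              .groups = "drop") |>
    filter(.data$n_ds >= n_datasets, .data$extreme_everywhere)
  confirmed$gene
}

#' ASE filter
#'
#' Removes candidates located in confirmed ASE genes: gene-level allelic
#' expression bias masquerades as binding bias but reflects transcription,
#' not protein-RNA interaction.
#'
#' @param candidates Tibble with a `gene` column.
#' @param ase_genes Character vector from [detect_ase_genes()].
#' @return Logical keep vector.
#' @export
filter_ase <- function(candidates, ase_genes) {
  if (!"gene" %in% names(candidates)) {
    warn("Candidates carry no `gene` column; ASE filter keeps everything.")
    return(rep(TRUE, nrow(candidates)))
  }
  !(candidates$gene %in% ase_genes)
}

#' Mean and SD of SMInput allelic ratios at known heterozygous SNVs
#'
#' @param y_ref,y_alt SMInput allele counts at known heterozygous SNVs.
#' @return Tibble with `theta` (mean reference ratio) and `sigma` (SD).
#' @export
reference_ratio_stats <- function(y_ref, y_alt) {
  total <- y_ref + y_alt
  ratio <- y_ref[total > 0] / total[total > 0]
  tibble(theta = mean(ratio), sigma = stats::sd(ratio))
}

#' Reference-mapping-bias filter
#'
#' Alignment to the reference genome favours reference alleles; a candidate
#' whose allelic ratio sits close to the bulk SMInput ratio distribution is
#' indistinguishable from that bias. The filter keeps candidates with
#' `z = |ratio - theta| / sigma >= min_z`.
#'
#' @param ratio Candidate reference allelic ratios.
#' @param theta,sigma Mean and SD of the SMInput ratio distribution (see
#'   [reference_ratio_stats()]); `sigma` must be positive.
#' @param min_z Minimum Z-score (default 1).
#' @return Logical keep vector.
#' @export
filter_reference_bias <- function(ratio, theta, sigma, min_z = 1) {
  if (!is.finite(sigma) || sigma <= 0) {
    abort("Degenerate SMInput ratio distribution (sigma must be > 0).")
  }
  abs(ratio - theta) / sigma >= min_z
}

#' Hotspot filter
#'
#' eCLIP occasionally produces promiscuous "hotspot" regions pulled down by
#' many unrelated proteins. The genome is binned into non-overlapping
#' windows of `window` nucleotides; within each window the SNV positions
#' that are ASB candidates for more than `rbp_threshold` distinct RBPs are
#' counted. Windows whose count significantly exceeds the background (the
#' Poisson upper tail against the mean over non-empty windows, BH FDR <
#' `max_fdr`, with a hard floor of `min_count` such positions) are flagged
#' and all candidates inside them are removed.
#'
#' @param candidates Tibble with `chrom`, `pos`, `rbp`.
#' @param window Window width in nucleotides (default 2000).
#' @param rbp_threshold A position counts only when shared by strictly more
#'   than this many RBPs (default 4).
#' @param max_fdr BH FDR threshold on the Poisson tail (default 0.01).
#' @param min_count Hard floor on the multi-RBP count of a flagged window
#'   (default 3), guarding tiny data sets.
#' @return Logical keep vector, with the flagged windows attached as the
#'   `"hotspots"` attribute (tibble `chrom`, `window_start`, `n_multi`).
#' @export
filter_hotspot <- function(candidates, window = 2000, rbp_threshold = 4,
                           max_fdr = 0.01, min_count = 3) {
  win <- (candidates$pos %/% window) * window
  # every window containing a candidate contributes to the background, with
  # a multi-RBP count of zero when no position is shared widely enough
  multi <- candidates |>
    mutate(window_start = win) |>
    group_by(.data$chrom, .data$window_start, .data$pos) |>
    summarise(n_rbp = dplyr::n_distinct(.data$rbp), .groups = "drop") |>
    group_by(.data$chrom, .data$window_start) |>
    summarise(n_multi = sum(.data$n_rbp > rbp_threshold), .groups = "drop")
  keep <- rep(TRUE, nrow(candidates))
  flagged <- multi[0, ]
  if (nrow(multi) > 0) {
    lambda <- mean(multi$n_multi)
    p <- stats::ppois(multi$n_multi - 1, lambda, lower.tail = FALSE)
    flag <- stats::p.adjust(p, "BH") < max_fdr & multi$n_multi >= min_count
    flagged <- multi[flag, , drop = FALSE]
    if (nrow(flagged) > 0) {
      bad <- paste(flagged$chrom, flagged$window_start)
      keep <- !(paste(candidates$chrom, win) %in% bad)
    }
  }
  attr(keep, "hotspots") <- flagged
  keep
}

#' Apply the posterior filter chain
#'
#' Runs the six quality filters in their fixed order — homopolymer,
#' microsatellite, mappability, ASE, reference-bias, hotspot — skipping any
#' filter whose resource is missing (with a warning for the ASE filter,
#' whose absence is easy to overlook), and records per-step attrition. A
#' candidate failing several filters is counted at the first failing step
#' only.
#'
#' @param candidates Tibble with `chrom`, `pos`, `rbp` and, as needed,
#'   `gene` and `ratio` columns.
#' @param genome Genome for the homopolymer filter, or `NULL` to skip.
#' @param microsatellites Microsatellite intervals, or `NULL` to skip.
#' @param similarity Off-target identity table, or `NULL` to skip.
#' @param rna RNA-Seq allelic counts for [detect_ase_genes()], or `NULL` to
#'   skip (warns).
#' @param ratio_stats One-row tibble `theta`, `sigma` from
#'   [reference_ratio_stats()], or `NULL` to skip.
#' @param hotspot Run the hotspot filter (default `TRUE`).
#' @param ... Tuning parameters forwarded to the individual filters, named
#'   `homopolymer_min_run`, `mappability_max_identity`, `ase_fdr`,
#'   `reference_min_z`, `hotspot_window`, `hotspot_rbp_threshold`.
#' @return The surviving candidates, with the per-step report attached as
#'   attribute `"attrition"` (columns `step`, `filter`, `n_in`,
#'   `n_removed`, `n_out`, `pct_removed`); retrieve it with [attrition()].
#' @export
apply_filter_chain <- function(candidates, genome = NULL,
                               microsatellites = NULL, similarity = NULL,
                               rna = NULL, ratio_stats = NULL,
                               hotspot = TRUE, ...) {
  dots <- list(...)
  opt <- function(name, default) dots[[name]] %||% default
  report <- list()
  step <- 0L
  run <- function(cand, name, keep) {
    step <<- step + 1L
    report[[step]] <<- tibble(
      step = step, filter = name, n_in = nrow(cand),
      n_removed = sum(!keep), n_out = sum(keep),
      pct_removed = if (nrow(cand) > 0) 100 * sum(!keep) / nrow(cand) else 0)
    cand[keep, , drop = FALSE]
  }
  out <- candidates
  if (!is.null(genome)) {
    out <- run(out, "homopolymer",
               filter_homopolymer(out, genome, opt("homopolymer_min_run", 5)))
  }
  if (!is.null(microsatellites)) {
    out <- run(out, "microsatellite", filter_microsatellite(out, microsatellites))
  }
  if (!is.null(similarity)) {
    out <- run(out, "mappability",
               filter_mappability(out, similarity,
                                  opt("mappability_max_identity", 0.95)))
  }
  if (!is.null(rna)) {
    ase <- detect_ase_genes(rna, fdr = opt("ase_fdr", 0.05))
    out <- run(out, "ase", filter_ase(out, ase))
  } else {
    warn("No RNA-Seq allelic tables supplied: ASE filter skipped.")
  }
  if (!is.null(ratio_stats)) {
    out <- run(out, "reference_bias",
               filter_reference_bias(out$ratio, ratio_stats$theta,
                                     ratio_stats$sigma,
                                     opt("reference_min_z", 1)))
  }
  if (isTRUE(hotspot)) {
    out <- run(out, "hotspot",
               filter_hotspot(out, window = opt("hotspot_window", 2000),
                              rbp_threshold = opt("hotspot_rbp_threshold", 4)))
  }
  attr(out, "attrition") <- bind_rows(report)
  out
}
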