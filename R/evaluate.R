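#' Chi-square test of allelic imbalance on combined counts
#'
#' One-degree-of-freedom goodness-of-fit of the replicate-combined
#' (major, minor) counts against a balanced 50/50 expectation, without
#' continuity correction. This is the standard count comparator that ignores
#' replicate variability and crosslink bias; it is provided for
#' benchmarking, not for calling ASB.
#'
#' @param major,minor Non-negative integer vectors of combined counts.
#' @return Vector of p-values; `NA` where `major + minor == 0`.
#' @export
chi2_imbalance_test <- function(major, minor) {
  n <- major + minor
  stat <- ifelse(n > 0, (major - minor)^2 / n, NA_real_)
  ifelse(is.na(stat), NA_real_, stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric tail summation: with margins
#' fixed, every table whose probability does not exceed that of the observed
#' table contributes. Implemented directly with [stats::dhyper()] so that
#' millions of small tables can be tested quickly; it agrees with
#' [stats::fisher.test()] to numerical precision.
#'
#' @param a,b,c,d Cell counts, row-wise: the observed table is
#'   `rbind(c(a, b), c(c, d))`. Vectors are recycled to a common length.
#' @return Vector of two-sided p-values; an all-zero table gives 1.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, len); b <- rep_len(b, len)
  c <- rep_len(c, len); d <- rep_len(d, len)
  if (any(c(a, b, c, d) < 0)) abort("Cell counts must be non-negative.")
  vapply(seq_len(len), function(i) {
    m <- a[i] + b[i]          # row 1 total
    n2 <- c[i] + d[i]         # row 2 total
    k <- a[i] + c[i]          # column 1 total
    if (m + n2 == 0) return(1)
    lo <- max(0, k - n2); hi <- min(k, m)
    x <- lo:hi
    probs <- stats::dhyper(x, m, n2, k)
    p_obs <- probs[x == a[i]]
    # relative tolerance guards against ties broken by floating error
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Fisher's exact comparator on combined allelic counts
#'
#' Contrasts the observed (major, minor) combined counts with the balanced
#' expectation of the same total split evenly (rounded):
#' `rbind(c(major, minor), c(round(n/2), n - round(n/2)))`. The 2x2
#' construction is a benchmark design choice; it affects this comparator
#' only, never the empirical Gaussian test.
#'
#' @inheritParams chi2_imbalance_test
#' @return Vector of two-sided p-values (degenerate zero-total tables give 1).
#' @export
fisher_imbalance_test <- function(major, minor) {
  n <- major + minor
  e1 <- round(n / 2)
  fisher_exact_2x2(major, minor, e1, n - e1)
}

#' Precision-recall curve and area under it
#'
#' Threshold sweep over the unique scores (larger = more ASB-like; use
#' `-log(p)` for p-values), collapsing tied scores to a single operating
#' point. The area is the trapezoidal integral of precision over recall,
#' with the curve anchored at recall 0 using the first operating point's
#' precision.
#'
#' @param scores Numeric vector of scores.
#' @param labels Logical vector of truth labels (`TRUE` = positive).
#' @return A `pr_curve` tibble with `threshold`, `recall`, `precision` and
#'   attribute `"auc"`; see [pr_auc()].
#' @export
precision_recall <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    abort("Both positive and negative labels are required.")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  last_of_tie <- !duplicated(s, fromLast = TRUE)
  tp <- tp[last_of_tie]; fp <- fp[last_of_tie]
  recall <- tp / sum(labels)
  precision <- tp / (tp + fp)
  curve <- tibble(threshold = s[last_of_tie], recall = recall,
                  precision = precision)
  auc <- sum(diff(c(0, recall)) *
               (c(precision[1], head(precision, -1)) + precision) / 2)
  structure(curve, auc = auc, class = c("pr_curve", class(curve)))
}

#' Area under the precision-recall curve
#' @inheritParams precision_recall
#' @return The PR-AUC as a single number.
#' @export
pr_auc <- function(scores, labels) {
  attr(precision_recall(scores, labels), "auc")
}

#' Sensitivity and specificity at 95% operating points
#'
#' Sweeps call thresholds over the unique scores (calling everything at or
#' above the threshold) plus the empty call set, and reports SEN95 (maximum
#' sensitivity among thresholds with specificity >= 0.95) and SPE95
#' (maximum specificity among thresholds with sensitivity >= 0.95).
#' Specificity is `TN / (TN + FP)`. Unattainable operating points yield 0.
#'
#' @inheritParams precision_recall
#' @return Tibble with columns `sen95` and `spe95`.
#' @export
sen_spe_at_operating_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    abort("Both positive and negative labels are required.")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  last_of_tie <- !duplicated(s, fromLast = TRUE)
  tp <- c(0, tp[last_of_tie]); fp <- c(0, fp[last_of_tie])  # 0 = call nothing
  np <- sum(l); nn <- sum(!l)
  sens <- tp / np
  spec <- (nn - fp) / nn
  sen95 <- if (any(spec >= 0.95)) max(sens[spec >= 0.95]) else 0
  spe95 <- if (any(sens >= 0.95)) max(spec[sens >= 0.95]) else 0
  tibble(sen95 = sen95, spe95 = spe95)
}

#' Percentage of ASB calls per coverage bin
#'
#' The overdispersion diagnostic: in the absence of overdispersion-driven
#' false positives the fraction of significant calls among testable SNVs is
#' independent of read coverage.
#'
#' @param coverage Mean read coverage of each SNV across replicates.
#' @param significant Logical significance flags (FDR below threshold).
#' @param bin_edges Left-closed bin edges (default
#'   `c(10, 20, 50, 100, 200, 500, Inf)`).
#' @return Tibble with `bin`, `n_testable`, `n_significant`, `pct_asb`
#'   (percentage; `NA` for empty bins, which are reported, not silently
#'   dropped). Values below the first bin edge fall outside the testable
#'   range and are excluded.
#' @export
percent_asb_by_coverage <- function(coverage, significant,
                                    bin_edges = c(10, 20, 50, 100, 200, 500, Inf)) {
  stopifnot(length(coverage) == length(significant))
  bin <- cut(coverage, bin_edges, right = FALSE)
  counts <- tibble(bin = bin, sig = as.logical(significant)) |>
    filter(!is.na(.data$bin)) |>
    group_by(.data$bin, .drop = FALSE) |>
    summarise(n_testable = n(), n_significant = sum(.data$sig), .groups = "drop")
  counts$pct_asb <- ifelse(counts$n_testable > 0,
                           100 * counts$n_significant / counts$n_testable,
                           NA_real_)
  counts
}

#' Benchmark imbalance tests on simulated data
#'
#' Runs the empirical Gaussian test (with bias correction when `bias` is
#' given) and the chi-square and Fisher comparators on combined replicate
#' counts, for every experiment of a simulated data set, and computes
#' PR-AUC, SEN95 and SPE95 against the embedded truth labels.
#'
#' @param data Long tibble from [simulate_asb_study()].
#' @param bias Optional `bias_table` used to normalise counts for the
#'   empirical Gaussian test (the comparators never see it). Use the table
#'   that generated the data to benchmark a correctly specified correction,
#'   or `NULL` for uncorrected (plain per-million) scaling.
#' @param methods Subset of `c("asb", "chi2", "fisher")`.
#' @param library_size Library size in millions applied to every replicate
#'   (simulated counts are not library-scaled, default 1).
#' @param fdr_threshold Significance threshold (default 0.10).
#' @param span LOESS span for the variance trend.
#' @param min_coverage An SNV is testable — for every method alike — only
#'   when its total count reaches this value in each replicate (default 10).
#' @return List with `metrics` (one row per experiment x method: `pr_auc`,
#'   `sen95`, `spe95`) and `per_snv` (per-SNV `p_value`, `fdr`,
#'   `significant`, `coverage`, `is_asb` per method).
#' @export
benchmark_asb_methods <- function(data, bias = NULL,
                                  methods = c("asb", "chi2", "fisher"),
                                  library_size = 1, fdr_threshold = 0.10,
                                  span = 0.75, min_coverage = 10) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!"is_asb" %in% names(data)) abort("Truth labels (`is_asb`) are required.")
  norm_bias <- bias %||% uniform_bias_table()
  per_snv <- list(); metrics <- list()
  for (e in unique(data$experiment)) {
    d <- data[data$experiment == e, , drop = FALSE]
    testable_ids <- d |>
      group_by(.data$snv_id) |>
      summarise(ok = min(.data$major_count + .data$minor_count) >= min_coverage,
                .groups = "drop")
    d <- d[d$snv_id %in% testable_ids$snv_id[testable_ids$ok], , drop = FALSE]
    truth <- d |> distinct(.data$snv_id, .data$is_asb)
    covg <- d |> group_by(.data$snv_id) |>
      summarise(coverage = mean(.data$major_count + .data$minor_count),
                .groups = "drop")
    res_e <- list()
    if ("asb" %in% methods) {
      counts <- tibble(snv_id = d$snv_id, replicate = d$replicate,
                       ref = d$major_base, alt = d$minor_base,
                       offset = d$offset,
                       y_ref = d$major_count, y_alt = d$minor_count) |>
        normalize_allelic_counts(norm_bias, library_size)
      fit <- asb_test(counts, span = span, fdr_threshold = fdr_threshold)
      res_e$asb <- tibble(snv_id = fit$snv_id, p_value = fit$p_value,
                          fdr = fit$fdr, significant = fit$significant)
    }
    if (any(c("chi2", "fisher") %in% methods)) {
      comb <- d |> group_by(.data$snv_id) |>
        summarise(major = sum(.data$major_count),
                  minor = sum(.data$minor_count), .groups = "drop")
      if ("chi2" %in% methods) {
        p <- chi2_imbalance_test(comb$major, comb$minor)
        res_e$chi2 <- tibble(snv_id = comb$snv_id, p_value = p,
                             fdr = stats::p.adjust(p, "BH"))
        res_e$chi2$significant <- res_e$chi2$fdr < fdr_threshold
      }
      if ("fisher" %in% methods) {
        p <- fisher_imbalance_test(comb$major, comb$minor)
        res_e$fisher <- tibble(snv_id = comb$snv_id, p_value = p,
                               fdr = stats::p.adjust(p, "BH"))
        res_e$fisher$significant <- res_e$fisher$fdr < fdr_threshold
      }
    }
    for (m in names(res_e)) {
      r <- res_e[[m]] |>
        left_join(truth, by = "snv_id") |>
        left_join(covg, by = "snv_id")
      r$method <- m; r$experiment <- e
      per_snv[[length(per_snv) + 1]] <- r
      ok <- !is.na(r$p_value)
      score <- -log10(pmax(r$p_value[ok], 1e-300))
      metrics[[length(metrics) + 1]] <- dplyr::bind_cols(
        tibble(experiment = e, method = m,
               pr_auc = pr_auc(score, r$is_asb[ok])),
        sen_spe_at_operating_points(score, r$is_asb[ok]))
    }
  }
  list(metrics = bind_rows(metrics), per_snv = bind_rows(per_snv))
}
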