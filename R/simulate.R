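#' Default variance target for simulated allelic counts
#'
#' Between-replicate variance of an allelic count as a function of its mean:
#' Poisson noise plus a multiplicative overdispersion term whose CV2 plateau
#' (default 0.05) mimics the high-count asymptote of the mean-CV2 trend seen
#' in eCLIP replicates.
#'
#' @param mean Mean allelic count.
#' @param cv2_plateau Asymptotic squared coefficient of variation.
#' @return Target variance `mean + cv2_plateau * mean^2`.
#' @export
default_var_target <- function(mean, cv2_plateau = 0.05) {
  mean + cv2_plateau * mean^2
}

#' Zero-truncated negative binomial moments
#'
#' Moments of the zero-truncated distribution obtained by conditioning a
#' negative binomial with untruncated mean `mean` and variance `variance` on
#' being at least 1. Used as the oracle for the sampler's moment recovery.
#'
#' @param mean,variance Untruncated NB mean and variance (`variance > mean`).
#' @return Tibble with `p0` (untruncated mass at zero), `mean_zt`, `var_zt`.
#' @export
ztnb_moments <- function(mean, variance) {
  stopifnot(all(variance > mean))
  size <- mean^2 / (variance - mean)
  p0 <- stats::dnbinom(0, size = size, mu = mean)
  mean_zt <- mean / (1 - p0)
  var_zt <- (variance + mean^2) / (1 - p0) - mean_zt^2
  tibble(p0 = p0, mean_zt = mean_zt, var_zt = var_zt)
}

#' Sample zero-truncated negative binomial counts
#'
#' Negative binomial parameterised by its untruncated mean and variance
#' (`size = mean^2 / (variance - mean)`), truncated at zero by exact
#' rejection resampling. When the requested variance does not exceed the
#' mean (no negative-binomial overdispersion) a zero-truncated Poisson is
#' drawn instead, with a warning.
#'
#' @param n Number of draws.
#' @param mean,variance Untruncated target mean and variance (recycled).
#' @return Integer vector of counts, all >= 1.
#' @export
rztnb <- function(n, mean, variance) {
  mean <- rep_len(mean, n); variance <- rep_len(variance, n)
  stopifnot(all(mean > 0))
  x <- integer(n)
  nb <- variance > mean
  if (any(!nb)) {
    warn(sprintf("%d draw(s) with variance <= mean: zero-truncated Poisson fallback.",
                 sum(!nb)))
  }
  draw <- function(idx) {
    out <- integer(length(idx))
    todo <- seq_along(idx)
    while (length(todo) > 0) {
      i <- idx[todo]
      y <- integer(length(i))
      y[nb[i]] <- stats::rnbinom(sum(nb[i]),
                                 size = mean[i][nb[i]]^2 /
                                   (variance[i][nb[i]] - mean[i][nb[i]]),
                                 mu = mean[i][nb[i]])
      y[!nb[i]] <- stats::rpois(sum(!nb[i]), mean[i][!nb[i]])
      out[todo] <- y
      todo <- todo[y == 0]
    }
    out
  }
  x <- draw(seq_len(n))
  x
}

#' Sample per-SNV total read coverage
#'
#' Resamples an empirical coverage distribution when one is supplied,
#' otherwise draws from a log-normal fallback; values below `min_coverage`
#' are excluded (testing allelic imbalance requires a minimum per-replicate
#' coverage of 10).
#'
#' @param n Number of draws.
#' @param source Optional numeric vector of empirical coverages to resample
#'   (e.g. read from a one-column file).
#' @param meanlog,sdlog Log-normal fallback parameters (defaults give a
#'   median coverage of about 55).
#' @param min_coverage Floor enforced by resampling (default 10).
#' @return Integer vector of coverages, all >= `min_coverage`.
#' @export
sample_total_coverage <- function(n, source = NULL, meanlog = log(55),
                                  sdlog = 1, min_coverage = 10) {
  if (!is.null(source)) {
    if (length(source) == 0) abort("Empirical coverage source is empty.")
    source <- source[source >= min_coverage]
    if (length(source) == 0) {
      abort(sprintf("No empirical coverage value reaches the minimum of %d.",
                    min_coverage))
    }
    return(as.integer(sample(source, n, replace = TRUE)))
  }
  x <- integer(0)
  while (length(x) < n) {
    y <- round(stats::rlnorm(n, meanlog, sdlog))
    x <- c(x, y[y >= min_coverage])
  }
  as.integer(x[seq_len(n)])
}

#' Inject crosslinking sequence bias into simulated counts
#'
#' Rescales each simulated allelic count by the ratio of the allele base's
#' crosslink propensity at the SNV's offset to the neutral 0.25, rounding to
#' the nearest integer with a floor of 1. SNVs outside the bias window
#' (offset `NA` or beyond the table's flank) are untouched. This is the
#' inverse of the correction applied by [normalize_allelic_counts()], so a
#' biased data set analysed with the same table recovers the unbiased
#' counts up to rounding.
#'
#' @param data Simulated data set from [simulate_asb_study()] (long tibble
#'   with `major_count`, `minor_count`, `major_base`, `minor_base`,
#'   `offset`).
#' @param bias A `bias_table`.
#' @return `data` with the count columns rescaled.
#' @export
inject_crosslink_bias <- function(data, bias) {
  stopifnot(inherits(bias, "bias_table"))
  flank <- (ncol(bias) - 1) / 2
  inside <- !is.na(data$offset) & abs(data$offset) <= flank
  scale_for <- function(base) {
    s <- rep(1, nrow(data))
    s[inside] <- unclass(bias)[cbind(base[inside],
                                     as.character(data$offset[inside]))] / 0.25
    s
  }
  mutate(data,
         major_count = pmax(round(.data$major_count * scale_for(.data$major_base)), 1),
         minor_count = pmax(round(.data$minor_count * scale_for(.data$minor_base)), 1))
}

#' Push simulated SNVs into the high-variance regime
#'
#' Re-spreads each SNV's per-replicate total counts symmetrically about
#' their mean until the between-replicate standard deviation exceeds the
#' 95th percentile of `reference_sd` (the SD distribution of a baseline
#' simulation), preserving each SNV's mean total within 10%. Allelic counts
#' within a replicate are scaled proportionally. SNVs whose counts are too
#' small to reach the target without a zero count are dropped with a
#' warning.
#'
#' @param data Simulated data set (long tibble, `k = 2` replicates).
#' @param reference_sd Numeric vector of baseline between-replicate SDs of
#'   SNV total counts.
#' @return `data` with counts perturbed (possibly fewer SNVs).
#' @export
make_high_variance <- function(data, reference_sd) {
  target <- stats::quantile(reference_sd, 0.95, names = FALSE)
  out <- data |>
    group_by(.data$experiment, .data$snv_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != 2) abort("High-variance perturbation expects k = 2 replicates.")
      tot <- d$major_count + d$minor_count
      m <- mean(tot)
      delta <- ceiling((target * sqrt(2) - abs(diff(tot))) / 2)
      delta <- max(delta, 0) + 1  # strictly exceed the target
      lo <- which.min(tot); hi <- setdiff(1:2, lo)
      new_tot <- tot
      new_tot[lo] <- tot[lo] - delta
      new_tot[hi] <- tot[hi] + delta
      if (new_tot[lo] < 2 || abs(mean(new_tot) - m) > 0.1 * m) {
        return(d[0, , drop = FALSE])  # unattainable at tiny counts
      }
      scale <- new_tot / tot
      d$major_count <- pmax(round(d$major_count * scale), 1)
      d$minor_count <- pmax(round(d$minor_count * scale), 1)
      d
    }) |>
    ungroup()
  dropped <- dplyr::n_distinct(paste(data$experiment, data$snv_id)) -
    dplyr::n_distinct(paste(out$experiment, out$snv_id))
  if (dropped > 0) {
    warn(sprintf("%d SNV(s) dropped: high-variance target unattainable.", dropped))
  }
  out
}

#' Simulate allele-specific eCLIP read counts
#'
#' Generates synthetic per-SNV, per-replicate allelic counts with the
#' statistical structure of eCLIP data: a per-SNV total coverage drawn from
#' an empirical or log-normal distribution, allelic counts drawn from a
#' zero-truncated negative binomial whose variance matches the observed
#' between-replicate variance as a function of the mean, a fraction of SNVs
#' carrying true allele-specific binding at major-allele ratio `r_true`, and
#' (optionally) multiplicative crosslinking sequence bias.
#'
#' Each SNV is assigned a random offset to its nearest crosslink site
#' (uniform over the bias window plus an "outside" mass) and two distinct
#' random allele bases, so that bias injection and correction can be
#' exercised even when `bias = NULL`.
#'
#' @param n_experiments Number of independent experiments (default 1).
#' @param n_snvs Heterozygous SNVs per experiment (default 5000).
#' @param frac_asb Fraction of SNVs with true ASB (default 0.10).
#' @param r_true Expected major-allele ratio of ASB SNVs, in (0.5, 1)
#'   (default 0.8; null SNVs use 0.5).
#' @param k Replicates (default 2).
#' @param coverage_source Optional empirical coverage vector (see
#'   [sample_total_coverage()]).
#' @param meanlog,sdlog Log-normal coverage fallback parameters.
#' @param min_coverage Per-replicate coverage floor (default 10).
#' @param var_target Function mapping a mean count to its target
#'   between-replicate variance (default [default_var_target()]).
#' @param shared_coverage When `TRUE` (default) one total coverage is drawn
#'   per SNV and shared by all replicates, so replicate-to-replicate
#'   variability comes entirely from the count noise; `FALSE` redraws the
#'   coverage independently per replicate.
#' @param bias Optional `bias_table` injected via [inject_crosslink_bias()].
#' @param frac_outside Fraction of SNVs placed outside the bias window
#'   (default 0.1).
#' @param seed Optional integer seed; recorded in the output's `"seed"`
#'   attribute.
#' @return Long tibble, one row per experiment x SNV x replicate:
#'   `experiment`, `snv_id`, `replicate`, `coverage`, `major_count`,
#'   `minor_count`, `offset`, `major_base`, `minor_base`, `is_asb`,
#'   `r_true`. The configuration is attached as attribute `"config"`.
#' @export
simulate_asb_study <- function(n_experiments = 1, n_snvs = 5000,
                               frac_asb = 0.10, r_true = 0.8, k = 2,
                               coverage_source = NULL, meanlog = log(55),
                               sdlog = 1, min_coverage = 10,
                               var_target = default_var_target,
                               shared_coverage = TRUE, bias = NULL,
                               frac_outside = 0.1, seed = NULL) {
  stopifnot(frac_asb >= 0, frac_asb < 1, r_true > 0.5, r_true < 1, k >= 2)
  if (!is.null(seed)) set.seed(seed)
  flank <- if (is.null(bias)) 25 else (ncol(bias) - 1) / 2
  one <- function(e) {
    n_asb <- round(n_snvs * frac_asb)
    is_asb <- rep(c(TRUE, FALSE), c(n_asb, n_snvs - n_asb))
    r <- ifelse(is_asb, r_true, 0.5)
    if (shared_coverage) {
      C <- matrix(sample_total_coverage(n_snvs, coverage_source, meanlog,
                                        sdlog, min_coverage), n_snvs, k)
    } else {
      C <- matrix(sample_total_coverage(n_snvs * k, coverage_source, meanlog,
                                        sdlog, min_coverage), n_snvs, k)
    }
    maj_mean <- r * C; min_mean <- (1 - r) * C
    maj <- matrix(rztnb(n_snvs * k, maj_mean, var_target(maj_mean)), n_snvs, k)
    mn <- matrix(rztnb(n_snvs * k, min_mean, var_target(min_mean)), n_snvs, k)
    offset <- sample(-flank:flank, n_snvs, replace = TRUE)
    offset[stats::runif(n_snvs) < frac_outside] <- NA_integer_
    major_base <- sample(DNA_BASES, n_snvs, replace = TRUE)
    minor_base <- vapply(major_base,
                         function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
    tibble(
      experiment = e,
      snv_id = rep(sprintf("snv%05d", seq_len(n_snvs)), k),
      replicate = rep(paste0("rep", seq_len(k)), each = n_snvs),
      coverage = as.vector(C),
      major_count = as.vector(maj), minor_count = as.vector(mn),
      offset = rep(offset, k),
      major_base = rep(major_base, k), minor_base = rep(minor_base, k),
      is_asb = rep(is_asb, k), r_true = rep(r, k))
  }
  out <- purrr::map_dfr(seq_len(n_experiments), one)
  if (!is.null(bias)) out <- inject_crosslink_bias(out, bias)
  attr(out, "config") <- list(
    n_experiments = n_experiments, n_snvs = n_snvs, frac_asb = frac_asb,
    r_true = r_true, k = k, meanlog = meanlog, sdlog = sdlog,
    min_coverage = min_coverage, shared_coverage = shared_coverage,
    biased = !is.null(bias), frac_outside = frac_outside, seed = seed)
  out
}

#' Write / read a simulated data set as TSV
#'
#' The seed and generator settings are echoed in `#`-prefixed header lines.
#'
#' @param data Tibble from [simulate_asb_study()].
#' @param path File path.
#' @return `write_sim_dataset()` returns `data` invisibly;
#'   `read_sim_dataset()` returns the tibble (header comments dropped).
#' @export
write_sim_dataset <- function(data, path) {
  cfg <- attr(data, "config")
  hdr <- if (is.null(cfg)) character(0) else {
    sprintf("# %s", paste(names(cfg), unlist(lapply(cfg, format)),
                          sep = "=", collapse = " "))
  }
  readr::write_lines(hdr, path)
  readr::write_tsv(data, path, append = TRUE, col_names = TRUE)
  invisible(data)
}

#' @rdname write_sim_dataset
#' @export
read_sim_dataset <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
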