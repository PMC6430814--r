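#' Per-allele summary of normalised counts across replicates
#'
#' @param x Numeric matrix of normalised counts, one row per allele record
#'   and one column per replicate (k >= 2 columns).
#' @return Tibble with `mu` (arithmetic mean), `s2` (unbiased, k-1
#'   denominator variance), `cv2` (`s2 / mu^2`, 0 where `mu == 0`) and `k`.
#' @export
summarize_alleles <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2) abort("At least two replicates are required.")
  if (any(x < 0)) abort("Normalised counts must be non-negative.")
  mu <- rowMeans(x)
  s2 <- rowSums((x - mu)^2) / (k - 1)
  tibble(mu = mu, s2 = s2, cv2 = ifelse(mu > 0, s2 / mu^2, 0), k = k)
}

#' Fit the mean-CV2 variance-moderation trend
#'
#' Locally weighted (LOESS) regression of the squared coefficient of
#' variation of normalised allelic counts on the log2 mean, pooled over both
#' alleles of every testable SNV in the experiment. The fitted curve replaces
#' the noisy per-SNV sample variance in the imbalance test: with only a
#' handful of replicates the per-SNV variance is a poor estimator, while the
#' global mean-variance relationship is stable.
#'
#' Predictions outside the training range of log2 means are clamped to the
#' boundary fits, and all fitted values are floored at `cv2_floor`.
#'
#' @param mu Numeric vector of per-allele means of normalised counts (only
#'   entries with `mu > 0` train the fit).
#' @param cv2 Matching vector of squared coefficients of variation.
#' @param span LOESS span (default 0.75).
#' @param degree Local polynomial degree (default 1).
#' @param min_points Minimum training points (default 30); fewer is an error
#'   suggesting the experiment be pooled with others or a parametric
#'   fallback `cv2 = a + b/mu` be fitted by hand.
#' @param cv2_floor Lower floor on fitted CV2 (default 1e-6).
#' @return An object of class `variance_trend` with `predict()`, `tidy()`,
#'   `glance()` and `autoplot()` methods.
#' @export
fit_variance_trend <- function(mu, cv2, span = 0.75, degree = 1,
                               min_points = 30, cv2_floor = 1e-6) {
  ok <- is.finite(mu) & mu > 0 & is.finite(cv2)
  mu <- mu[ok]; cv2 <- cv2[ok]
  if (length(mu) < min_points) {
    abort(sprintf(paste(
      "Only %d usable training points (< %d). Pool alleles across",
      "experiments, or fit the parametric fallback cv2 = a + b/mu."),
      length(mu), min_points))
  }
  lmu <- log2(mu)
  fit <- stats::loess(cv2 ~ lmu, span = span, degree = degree,
                      family = "gaussian")
  structure(
    list(fit = fit, range = range(lmu), span = span, degree = degree,
         n = length(mu), floor = cv2_floor),
    class = "variance_trend")
}

#' Moderated CV2 at given mean counts
#'
#' @param object A `variance_trend`.
#' @param mu Numeric vector of mean normalised counts (> 0).
#' @param ... Unused.
#' @return Fitted CV2 values, clamped to the training range and floored.
#' @export
predict.variance_trend <- function(object, mu, ...) {
  if (any(mu <= 0)) abort("`mu` must be positive.")
  lmu <- pmin(pmax(log2(mu), object$range[1]), object$range[2])
  unname(pmax(stats::predict(object$fit, data.frame(lmu = lmu)), object$floor))
}

#' @export
print.variance_trend <- function(x, ...) {
  cat(sprintf(
    "<variance_trend> LOESS(span = %g, degree = %d), %d training alleles, log2-mean range [%.2f, %.2f]\n",
    x$span, x$degree, x$n, x$range[1], x$range[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Grid of the fitted mean-CV2 trend
#'
#' @param x A `variance_trend`.
#' @param n Number of grid points across the training range (default 101).
#' @param ... Unused.
#' @return Tibble with `log2_mu`, `mu`, `cv2`, suitable for diagnostics or
#'   serialisation.
#' @export
tidy.variance_trend <- function(x, n = 101, ...) {
  lmu <- seq(x$range[1], x$range[2], length.out = n)
  tibble(log2_mu = lmu, mu = 2^lmu, cv2 = predict(x, 2^lmu))
}

#' @rdname tidy.variance_trend
#' @export
glance.variance_trend <- function(x, ...) {
  tibble(n = x$n, span = x$span, degree = x$degree,
         log2_mu_min = x$range[1], log2_mu_max = x$range[2],
         cv2_floor = x$floor)
}

#' Expected variance of normalised counts at a mean
#'
#' The moderated variance used by the imbalance test:
#' `sigma2_hat = cv2_hat(mu) * mu^2`.
#'
#' @param trend A `variance_trend`.
#' @param mu Mean normalised count (> 0).
#' @return Expected variance (always positive thanks to the CV2 floor).
#' @export
expected_variance <- function(trend, mu) {
  predict(trend, mu) * mu^2
}

#' Empirical Gaussian allelic-imbalance p-value
#'
#' The allele with the higher mean normalised count across replicates is the
#' major allele M, the other the minor allele m. The posterior for the mean
#' of the count-generating distribution of M given its k replicate
#' observations (flat prior limit) is `N(mu_M, sigma2_hat_M / k)` with the
#' moderated variance from [expected_variance()]. The two-sided p-value is
#' twice the posterior mass at or below the minor mean:
#' `p = 2 * Phi((mu_m - mu_M) / sqrt(sigma2_hat_M / k))`, capped at 1 (an
#' exact tie gives p = 1 with the reference allele kept as major).
#'
#' @param x_ref,x_alt Numeric matrices of normalised counts (rows = SNVs,
#'   columns = the k replicates).
#' @param trend A fitted `variance_trend`.
#' @return Tibble with one row per SNV: `mean_ref`, `mean_alt`,
#'   `major_allele` ("ref"/"alt"), `mean_major`, `mean_minor`,
#'   `var_major` (moderated), `k`, `p_value`, and `testable` (both allele
#'   means positive; untestable rows carry `NA` p-values).
#' @export
asb_pvalue <- function(x_ref, x_alt, trend) {
  x_ref <- as.matrix(x_ref); x_alt <- as.matrix(x_alt)
  stopifnot(identical(dim(x_ref), dim(x_alt)))
  k <- ncol(x_ref)
  mean_ref <- rowMeans(x_ref)
  mean_alt <- rowMeans(x_alt)
  testable <- mean_ref > 0 & mean_alt > 0
  major_is_ref <- mean_ref >= mean_alt
  mean_major <- pmax(mean_ref, mean_alt)
  mean_minor <- pmin(mean_ref, mean_alt)
  var_major <- rep(NA_real_, length(mean_major))
  p <- rep(NA_real_, length(mean_major))
  if (any(testable)) {
    var_major[testable] <- expected_variance(trend, mean_major[testable])
    z <- (mean_minor[testable] - mean_major[testable]) /
      sqrt(var_major[testable] / k)
    p[testable] <- pmin(2 * stats::pnorm(z), 1)
  }
  tibble(mean_ref = mean_ref, mean_alt = mean_alt,
         major_allele = ifelse(major_is_ref, "ref", "alt"),
         mean_major = mean_major, mean_minor = mean_minor,
         var_major = var_major, k = k, p_value = p, testable = testable)
}

#' Test allelic imbalance across an experiment
#'
#' High-level wrapper: summarises both alleles of every SNV, fits (or
#' reuses) the mean-CV2 trend on the pooled allele summaries, computes the
#' empirical Gaussian p-value per SNV and adjusts for multiple testing with
#' Benjamini-Hochberg across all testable SNVs of the experiment.
#'
#' @param counts Long tibble with columns `snv_id`, `replicate` and the
#'   normalised counts `x_ref`, `x_alt` (see
#'   [normalize_allelic_counts()]); one row per SNV x replicate.
#' @param trend Optional pre-fitted `variance_trend`; fitted from `counts`
#'   when `NULL`.
#' @param span,min_trend_points,cv2_floor Passed to [fit_variance_trend()]
#'   when the trend is fitted here.
#' @param fdr_threshold Significance threshold on the BH-adjusted p-value
#'   (default 0.10).
#' @return An `asb_result` tibble: one row per SNV with the columns of
#'   [asb_pvalue()] plus `snv_id`, `fdr` and `significant`; the trend is
#'   attached as attribute `"trend"`.
#' @export
asb_test <- function(counts, trend = NULL, span = 0.75, min_trend_points = 30,
                     cv2_floor = 1e-6, fdr_threshold = 0.10) {
  needed <- c("snv_id", "replicate", "x_ref", "x_alt")
  if (!all(needed %in% names(counts))) {
    abort(sprintf("`counts` must have columns %s.", paste(needed, collapse = ", ")))
  }
  wide_ref <- tidyr::pivot_wider(counts[c("snv_id", "replicate", "x_ref")],
                                 names_from = "replicate", values_from = "x_ref")
  wide_alt <- tidyr::pivot_wider(counts[c("snv_id", "replicate", "x_alt")],
                                 names_from = "replicate", values_from = "x_alt")
  stopifnot(identical(wide_ref$snv_id, wide_alt$snv_id))
  x_ref <- as.matrix(wide_ref[-1])
  x_alt <- as.matrix(wide_alt[-1])
  if (anyNA(x_ref) || anyNA(x_alt)) {
    abort("Every SNV needs a count in every replicate.")
  }
  if (is.null(trend)) {
    sm <- summarize_alleles(rbind(x_ref, x_alt))
    trend <- fit_variance_trend(sm$mu, sm$cv2, span = span,
                                min_points = min_trend_points,
                                cv2_floor = cv2_floor)
  }
  res <- asb_pvalue(x_ref, x_alt, trend)
  res <- dplyr::bind_cols(tibble(snv_id = wide_ref$snv_id), res)
  res$fdr <- NA_real_
  res$fdr[res$testable] <- stats::p.adjust(res$p_value[res$testable], method = "BH")
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_threshold
  attr(res, "trend") <- trend
  attr(res, "fdr_threshold") <- fdr_threshold
  class(res) <- c("asb_result", class(res))
  res
}

#' Summary of an allelic-imbalance test
#'
#' @param x An `asb_result` from [asb_test()].
#' @param ... Unused.
#' @return One-row tibble: number of SNVs, testable SNVs, significant calls,
#'   the FDR threshold and the trend's training size.
#' @export
glance.asb_result <- function(x, ...) {
  tibble(n_snvs = nrow(x), n_testable = sum(x$testable),
         n_significant = sum(x$significant),
         fdr_threshold = attr(x, "fdr_threshold"),
         trend_n = attr(x, "trend")$n)
}
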