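test_that("chi-square comparator matches the 1-df goodness-of-fit closed form", {
  expect_equal(chi2_imbalance_test(30, 30), 1)
  # (75-50)^2/50 + (25-50)^2/50 = 25
  expect_equal(chi2_imbalance_test(75, 25), pchisq(25, 1, lower.tail = FALSE))
  expect_equal(chi2_imbalance_test(75, 25), chi2_imbalance_test(25, 75))
  expect_true(is.na(chi2_imbalance_test(0, 0)))
  # cross-check against stats::chisq.test without continuity correction
  for (tab in list(c(40, 20), c(13, 5), c(101, 99))) {
    expect_equal(chi2_imbalance_test(tab[1], tab[2]),
                 suppressWarnings(chisq.test(tab, p = c(0.5, 0.5)))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact_2x2 agrees with fisher.test and exhaustive enumeration", {
  # independent oracle 1: stats::fisher.test
  tables <- list(c(30, 30, 30, 30), c(75, 25, 50, 50), c(5, 5, 5, 5),
                 c(12, 3, 4, 9), c(1, 9, 11, 3), c(0, 5, 7, 2))
  for (tb in tables) {
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 fisher.test(matrix(tb, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-12)
  }
  # independent oracle 2: brute-force enumeration over margin-fixed tables
  enum_fisher <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
    xs <- max(0, k - r2):min(k, r1)
    pr <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
    sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
  }
  set.seed(51)
  for (i in 1:30) {
    tb <- rpois(4, 8)
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 enum_fisher(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-12)
  }
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
})

test_that("the Fisher comparator contrasts counts with a balanced split", {
  expect_equal(fisher_imbalance_test(30, 30), 1)
  expect_equal(fisher_imbalance_test(75, 25),
               fisher.test(matrix(c(75, 25, 50, 50), 2, 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_imbalance_test(0, 0), 1)
  # odd totals round the expectation deterministically
  expect_equal(fisher_imbalance_test(7, 4),
               fisher.test(matrix(c(7, 4, 6, 5), 2, 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
})

test_that("precision-recall machinery handles perfect, null and degenerate scores", {
  labels <- rep(c(TRUE, FALSE), c(20, 180))
  perfect <- c(seq(2, 3, length.out = 20), seq(0, 1, length.out = 180))
  expect_equal(pr_auc(perfect, labels), 1.0)
  # reversing the orientation destroys the ranking
  expect_lte(pr_auc(-perfect, labels), 0.1 + 0.02)
  # null scores: PR-AUC equals prevalence
  set.seed(52)
  lab2 <- rep(c(TRUE, FALSE), c(1000, 9000))
  expect_lt(abs(pr_auc(runif(10000), lab2) - 0.10), 0.02)
  # recall is non-decreasing along the sweep
  curve <- precision_recall(runif(500), rep(c(TRUE, FALSE), 250))
  expect_true(all(diff(curve$recall) >= 0))
  expect_error(pr_auc(1:5, rep(TRUE, 5)), "positive and negative")
})

test_that("SEN95/SPE95 operating points behave at the extremes", {
  labels <- rep(c(TRUE, FALSE), c(20, 180))
  perfect <- c(seq(2, 3, length.out = 20), seq(0, 1, length.out = 180))
  op <- sen_spe_at_operating_points(perfect, labels)
  expect_equal(op$sen95, 1)
  expect_equal(op$spe95, 1)
  # constant scores: all-or-nothing calls, specificity 0.95 unattainable
  op2 <- sen_spe_at_operating_points(rep(1, 200), labels)
  expect_equal(op2$sen95, 0)
  # label-independent scores: sensitivity at 95% specificity is about 5%
  set.seed(53)
  lab3 <- rep(c(TRUE, FALSE), c(5000, 5000))
  op3 <- sen_spe_at_operating_points(runif(10000), lab3)
  expect_lt(abs(op3$sen95 - 0.05), 0.02)
})

test_that("coverage bins partition testable SNVs and report empty bins as NA", {
  cov <- c(15, 25, 75, 75, 130)
  sig <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  out <- percent_asb_by_coverage(cov, sig)
  expect_equal(sum(out$n_testable), 5)
  expect_equal(out$pct_asb[out$bin == "[50,100)"], 50)
  expect_true(is.na(out$pct_asb[out$bin == "[200,500)"]))
  expect_equal(out$pct_asb[out$bin == "[10,20)"], 100)
})

test_that("the benchmark harness scores all three methods against the truth", {
  sim <- simulate_asb_study(n_experiments = 2, n_snvs = 400, r_true = 0.9,
                            seed = 12)
  bench <- benchmark_asb_methods(sim)
  expect_equal(sort(unique(bench$metrics$method)), c("asb", "chi2", "fisher"))
  expect_equal(nrow(bench$metrics), 6)  # 2 experiments x 3 methods
  expect_true(all(bench$metrics$pr_auc >= 0 & bench$metrics$pr_auc <= 1))
  expect_true(all(bench$metrics$pr_auc > 0.5))  # r = 0.9 is easy
  per <- bench$per_snv
  # one row per method for every SNV testable at min per-replicate total 10
  n_testable <- sim |>
    dplyr::group_by(experiment, snv_id) |>
    dplyr::summarise(ok = min(major_count + minor_count) >= 10,
                     .groups = "drop") |>
    dplyr::pull(ok) |>
    sum()
  expect_equal(nrow(per), 3 * n_testable)
  expect_true(all(c("p_value", "fdr", "significant", "coverage", "is_asb")
                  %in% names(per)))
  # single-method run
  solo <- benchmark_asb_methods(sim, methods = "chi2")
  expect_equal(unique(solo$metrics$method), "chi2")
  expect_error(benchmark_asb_methods(dplyr::select(sim, -is_asb)), "Truth labels")
})
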