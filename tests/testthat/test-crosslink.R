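test_that("collect_read_starts takes the biological 5' end on each strand", {
  peak_plus <- list(start = 0L, end = 100L, strand = "+")
  reads <- tibble::tibble(start = c(10L, 50L, 50L, 50L, 10L),
                          end = c(40L, 80L, 80L, 80L, 40L),
                          strand = c("+", "+", "+", "+", "-"))
  out <- collect_read_starts(reads, peak_plus)
  expect_equal(out$pos, c(10L, 50L))
  expect_equal(out$m, c(1L, 3L))  # the "-" read is off-strand

  peak_minus <- list(start = 0L, end = 100L, strand = "-")
  out <- collect_read_starts(tibble::tibble(start = 10L, end = 40L, strand = "-"),
                             peak_minus)
  expect_equal(out$pos, 39L)  # rightmost base of [10, 40)

  none <- collect_read_starts(reads[0, ], peak_plus)
  expect_equal(nrow(none), 0)
})

test_that("permutation FDR calls a stacked position and not a uniform pileup", {
  set.seed(11)
  # 200 reads all on one position of a 100 nt peak: no permutation of 200
  # uniform reads ever stacks them, FDR 0
  stacked <- tibble::tibble(pos = 37L, m = 200L)
  sites <- call_crosslink_sites(stacked, peak_length = 100, n_perm = 500)
  expect_equal(sites$pos, 37L)
  expect_equal(sites$fdr, 0)

  # one read per position is exactly the null: nothing called at FDR 0.001
  flat <- tibble::tibble(pos = 0:99, m = 1L)
  expect_equal(nrow(call_crosslink_sites(flat, 100, n_perm = 300)), 0)

  expect_equal(nrow(call_crosslink_sites(flat[0, ], 100)), 0)
  expect_error(call_crosslink_sites(stacked, peak_length = 0), "peak_length")
})

test_that("empirical FDR is monotone non-increasing in the count threshold", {
  set.seed(12)
  counts <- tibble::tibble(pos = 0:19, m = c(rep(1L, 15), 3L, 4L, 6L, 9L, 30L))
  out <- call_crosslink_sites(counts, peak_length = 60, n_perm = 300, max_fdr = 1)
  out <- out[order(out$m), ]
  expect_true(all(diff(out$fdr) <= 1e-12))
})

test_that("bias table estimation recovers base frequencies and respects strand", {
  # all sites share one context: point mass at each offset
  genome <- c(chrZ = paste0(strrep("C", 25), "T", strrep("G", 25),
                            strrep("A", 60)))
  sites <- tibble::tibble(chrom = "chrZ", pos = 25L, strand = "+")
  bias <- estimate_bias_table(sites, genome)
  expect_equal(unname(bias["T", "0"]), 1)
  expect_equal(unname(bias["C", "-10"]), 1)
  expect_equal(unname(bias["G", "10"]), 1)

  # "-" strand context is the reverse complement: C at -10 becomes G at +10
  bias_m <- estimate_bias_table(
    tibble::tibble(chrom = "chrZ", pos = 25L, strand = "-"), genome)
  expect_equal(unname(bias_m["A", "0"]), 1)
  expect_equal(unname(bias_m["G", "10"]), 1)

  # sites at the chromosome edge are skipped, zero usable sites is an error
  edge <- tibble::tibble(chrom = "chrZ", pos = 3L, strand = "+")
  expect_error(estimate_bias_table(edge, genome), "No usable")

  # column normalisation holds on mixed real-ish input
  set.seed(13)
  g2 <- c(chrR = uniform_random_genome(20000))
  s2 <- tibble::tibble(chrom = "chrR",
                       pos = sample(30:19970, 300),
                       strand = sample(c("+", "-"), 300, TRUE))
  b2 <- estimate_bias_table(s2, g2)
  expect_equal(unname(colSums(unclass(b2))), rep(1, 51), tolerance = 1e-9)
  # order invariance
  b3 <- estimate_bias_table(s2[sample(nrow(s2)), ], g2)
  expect_equal(unclass(b2), unclass(b3))
})

test_that("uniform random genome gives near-uniform propensities (Monte Carlo)", {
  set.seed(14)
  g <- c(chrR = uniform_random_genome(60000, seed = 403))
  sites <- tibble::tibble(chrom = "chrR", pos = sample(30:59970, 10000),
                          strand = "+")
  bias <- estimate_bias_table(sites, g)
  expect_true(all(abs(unclass(bias) - 0.25) < 0.02))
})

test_that("offset assignment picks the nearest site with 5' tie-breaking", {
  expect_equal(assign_offset(60L, c(50L, 80L), "+"), 10L)
  expect_equal(assign_offset(65L, c(50L, 80L), "+"), 15L)   # tie -> 5' site 50
  expect_equal(assign_offset(65L, c(50L, 80L), "-"), 15L)  # 5' site on "-" is 80
  expect_equal(assign_offset(60L, integer(0), "+"), NA_integer_)
  expect_equal(assign_offset(10L, c(80L, 50L), "+"), NA_integer_)  # |d| = 40 > 25
  # strand orientation flips the sign
  expect_equal(assign_offset(60L, 50L, "-"), -10L)
})

test_that("count normalisation follows x = y / (q R) with the outside-window rule", {
  bias <- uniform_bias_table()
  counts <- tibble::tibble(
    ref = c("A", "C", "T"), alt = c("G", "T", "A"),
    offset = c(0L, 0L, NA), replicate = "rep1",
    y_ref = c(10, 10, 7), y_alt = c(0, 4, 2))
  out <- normalize_allelic_counts(counts, bias, library_sizes = c(rep1 = 1))
  expect_equal(out$x_ref, c(40, 40, 28))  # q = 0.25 inside and outside alike

  # non-uniform q and R = 2
  b2 <- unclass(synthetic_bias_table())
  q <- b2["T", "0"]
  counts2 <- tibble::tibble(ref = "T", alt = "A", offset = 0L,
                            replicate = "rep1", y_ref = 10, y_alt = 0)
  out2 <- normalize_allelic_counts(counts2, synthetic_bias_table(),
                                   library_sizes = c(rep1 = 2))
  expect_equal(out2$x_ref, 10 / (q * 2))

  # round trip: multiplying unbiased counts by q R then normalising recovers them
  set.seed(15)
  b <- synthetic_bias_table()
  n <- 200
  tab <- tibble::tibble(
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = "A", offset = sample(c(-25:25, NA), n, TRUE),
    replicate = "rep1", y_alt = 0)
  x0 <- runif(n, 1, 100)
  qv <- bias_propensity(b, tab$ref, tab$offset)
  tab$y_ref <- x0 * qv * 3.7
  out3 <- normalize_allelic_counts(tab, b, library_sizes = c(rep1 = 3.7))
  expect_equal(out3$x_ref, x0, tolerance = 1e-9)
})

test_that("zero propensities are floored with a warning", {
  q <- matrix(0.25, 4, 51)
  q[, 26] <- c(0, 0.4, 0.3, 0.3)
  bias <- asbind:::new_bias_table(q, n_sites = 10)
  expect_warning(v <- bias_propensity(bias, "A", 0L), "floored")
  expect_equal(v, 0.005)
})

test_that("under uniform q, normalisation never changes allelic ratios", {
  set.seed(16)
  counts <- tibble::tibble(
    ref = sample(c("A", "C"), 50, TRUE), alt = sample(c("G", "T"), 50, TRUE),
    offset = sample(c(-25:25, NA), 50, TRUE), replicate = "rep1",
    y_ref = rpois(50, 40) + 1, y_alt = rpois(50, 40) + 1)
  out <- normalize_allelic_counts(counts, uniform_bias_table(),
                                  library_sizes = c(rep1 = 2.5))
  expect_equal(out$x_ref / out$x_alt, counts$y_ref / counts$y_alt,
               tolerance = 1e-12)
})

test_that("bias tables round-trip through TSV", {
  b <- synthetic_bias_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bias_table(b, path)
  b2 <- read_bias_table(path)
  expect_equal(unclass(b2), unclass(b), tolerance = 1e-12,
               ignore_attr = "n_sites")
})
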