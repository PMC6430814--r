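# The toy genome (helper-synthetic.R) carries an AAAAA run at chrT:150-154
# and a (CT)x10 stretch at chrT:170-189.

test_that("homopolymer filter removes SNVs inside runs of five or more", {
  genome <- toy_genome()
  cand <- tibble::tibble(chrom = "chrT", pos = c(152L, 150L, 154L, 149L, 155L))
  keep <- filter_homopolymer(cand, genome)
  # inside the run (150..154) removed; positions flanking it depend on their
  # own base: 149 and 155 are kept unless they extend the run, which the
  # fixture precludes by construction only at 149
  expect_false(keep[1]); expect_false(keep[2]); expect_false(keep[3])
  expect_equal(substr(genome[["chrT"]], 151, 155), "AAAAA")
  # a kept position: max run 2 around a mixed context
  cand2 <- tibble::tibble(chrom = "chrT", pos = 170L)  # CTCT... no run of 5
  expect_true(filter_homopolymer(cand2, genome))
})

test_that("microsatellite overlap is 0-based half-open", {
  ms <- tibble::tibble(chrom = "chrT", start = 90L, end = 110L)
  cand <- tibble::tibble(chrom = "chrT", pos = c(100L, 110L, 89L, 90L))
  expect_equal(filter_microsatellite(cand, ms), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(filter_microsatellite(cand, ms[0, ])))
  # other chromosome untouched
  expect_true(filter_microsatellite(tibble::tibble(chrom = "chrU", pos = 100L), ms))
})

test_that("mappability filter removes >=95% off-target identity, inclusive", {
  sim <- tibble::tibble(chrom = "chrT", pos = c(1L, 2L, 3L),
                        identity = c(0.97, 0.80, 0.95))
  cand <- tibble::tibble(chrom = "chrT", pos = c(1L, 2L, 3L, 4L))
  expect_warning(keep <- filter_mappability(cand, sim), "missing")
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE))
  expect_warning(strict <- filter_mappability(cand, sim, strict = TRUE))
  expect_false(strict[4])
})

test_that("ASE genes need two concordantly biased testable SNVs in two data sets", {
  biased <- tidyr::expand_grid(dataset = c("d1", "d2"),
                               snv_id = c("s1", "s2")) |>
    dplyr::mutate(gene = "gA", y_ref = 50L, y_alt = 10L)
  balanced <- tidyr::expand_grid(dataset = c("d1", "d2"),
                                 snv_id = c("s3", "s4")) |>
    dplyr::mutate(gene = "gB", y_ref = c(30L, 12L, 30L, 12L),
                  y_alt = c(30L, 10L, 30L, 10L))
  lonely <- tibble::tibble(dataset = c("d1", "d2"), snv_id = "s5", gene = "gC",
                           y_ref = 60L, y_alt = 5L)
  rna <- dplyr::bind_rows(biased, balanced, lonely)
  ase <- detect_ase_genes(rna)
  expect_equal(ase, "gA")   # gB unbiased, gC has one testable SNV only

  # one data set is not enough
  expect_equal(detect_ase_genes(biased[biased$dataset == "d1", ]), character(0))

  cand <- tibble::tibble(chrom = "chrT", pos = 1:3, gene = c("gA", "gB", "gC"))
  expect_equal(filter_ase(cand, ase), c(FALSE, TRUE, TRUE))
})

test_that("reference-bias Z-score keeps only ratios one SD away from the bulk", {
  expect_equal(filter_reference_bias(c(0.55, 0.75, 0.5), theta = 0.5, sigma = 0.1),
               c(FALSE, TRUE, FALSE))
  expect_error(filter_reference_bias(0.6, 0.5, 0), "sigma")
  stats <- reference_ratio_stats(y_ref = c(40, 60, 50), y_alt = c(60, 40, 50))
  expect_equal(stats$theta, 0.5)
  expect_gt(stats$sigma, 0)
})

test_that("hotspot windows need more than rbp_threshold RBPs and Poisson excess", {
  # 6 multi-RBP positions in one window, sparse singletons elsewhere
  hot <- tidyr::expand_grid(pos = seq(24000L, 24500L, by = 100L),
                            rbp = paste0("RBP", 1:5)) |>
    dplyr::mutate(chrom = "chr14")
  cold <- tibble::tibble(chrom = "chr14",
                         pos = seq(100000L, 400000L, by = 2000L)[1:100],
                         rbp = "RBP1")
  cand <- dplyr::bind_rows(hot, cold)
  keep <- filter_hotspot(cand)
  flagged <- attr(keep, "hotspots")
  expect_equal(flagged$window_start, 24000L)
  expect_true(all(!keep[cand$pos < 26000]))
  expect_true(all(keep[cand$pos >= 100000]))

  # exactly four RBPs do not count ("more than four")
  four <- tidyr::expand_grid(pos = seq(24000L, 24500L, by = 100L),
                             rbp = paste0("RBP", 1:4)) |>
    dplyr::mutate(chrom = "chr14")
  keep4 <- filter_hotspot(dplyr::bind_rows(four, cold))
  expect_equal(nrow(attr(keep4, "hotspots")), 0)
  expect_true(all(keep4))

  # homogeneous singleton landscape: nothing flagged
  keep0 <- filter_hotspot(cold)
  expect_true(all(keep0))
})

test_that("the filter chain is ordered, order-independent and self-consistent", {
  genome <- toy_genome()
  ms <- tibble::tibble(chrom = "chrT", start = 170L, end = 190L)
  set.seed(61)
  cand <- tibble::tibble(
    chrom = "chrT",
    pos = c(152L, 175L, 300L, 320L, 340L, 360L),
    rbp = "RBP1", gene = "gX",
    ratio = c(0.9, 0.9, 0.52, 0.9, 0.48, 0.85))
  stats <- tibble::tibble(theta = 0.5, sigma = 0.1)
  expect_warning(
    out <- apply_filter_chain(cand, genome = genome, microsatellites = ms,
                              ratio_stats = stats),
    "ASE filter skipped")
  rep <- attrition(out)
  # homopolymer removes pos 152, microsatellite removes 175, Z-score removes
  # the two near-0.5 ratios; a candidate failing two filters counts once
  expect_equal(rep$filter, c("homopolymer", "microsatellite", "reference_bias",
                             "hotspot"))
  expect_equal(rep$n_removed, c(1, 1, 2, 0))
  expect_equal(sum(rep$n_removed), nrow(cand) - nrow(out))
  expect_equal(rep$n_out, c(5, 4, 2, 2))
  expect_equal(sort(out$pos), c(320L, 360L))

  # pure predicates: re-running the chain on its own output removes nothing
  expect_warning(
    again <- apply_filter_chain(out, genome = genome, microsatellites = ms,
                                ratio_stats = stats))
  expect_equal(attrition(again)$n_removed, rep(0, 4))

  # input order never changes the surviving set
  expect_warning(
    shuf <- apply_filter_chain(cand[sample(nrow(cand)), ], genome = genome,
                               microsatellites = ms, ratio_stats = stats))
  expect_equal(sort(shuf$pos), sort(out$pos))

  # all filters disabled: identity with an empty report
  expect_warning(none <- apply_filter_chain(cand, hotspot = FALSE))
  expect_equal(nrow(none), nrow(cand))
  expect_equal(nrow(attrition(none)), 0)
})
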