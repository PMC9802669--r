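# Context assignment, methylcytosine calling, methylome summaries.

test_that("assign_context follows the strand-aware two-base rule", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACGTT"))
  expect_equal(assign_context(g, "chr1", 3, "+"), "CG")
  # palindromic CG: minus-strand C at the reference G position
  expect_equal(assign_context(g, "chr1", 4, "-"), "CG")
  g2 <- Biostrings::DNAStringSet(c(c1 = "ACTGA", c2 = "ACTTA", c3 = "AAC"))
  expect_equal(assign_context(g2, "c1", 2, "+"), "CHG")
  expect_equal(assign_context(g2, "c2", 2, "+"), "CHH")
  expect_true(is.na(assign_context(g2, "c3", 3, "+")))
  # errors: not a cytosine on the given strand
  expect_error(assign_context(g, "chr1", 1, "+"), "not a cytosine")
  expect_error(assign_context(g, "chr1", 3, "-"), "not a cytosine")
  expect_error(assign_context(g, "chr1", 99, "+"), "out of range")
})

test_that("enumerate_cytosines partitions every C into one context or NA", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  sites <- enumerate_cytosines(g)
  chars <- strsplit(s, "")[[1]]
  expect_equal(nrow(sites), sum(chars == "C") + sum(chars == "G"))
  # recompute independently with assign_context for a sample of rows
  idx <- sample(nrow(sites), 300)
  expect_equal(sites$context[idx],
               assign_context(g, sites$chrom[idx], sites$pos[idx], sites$strand[idx]))
  # exactly one context per covered site; NA only at chromosome edges
  expect_true(all(sites$context %in% c("CG", "CHG", "CHH") | is.na(sites$context)))
  expect_true(all(sites$pos[is.na(sites$context)] %in% c(1, 2, 2999, 3000)))
})

test_that("caller enforces coverage in all samples and the binomial rule", {
  s1 <- make_report(c(10, 20, 30), m = c(0, 9, 5), u = c(10, 1, 0))
  s2 <- make_report(c(10, 20, 30), m = c(2, 8, 1), u = c(8, 2, 2))  # site 30: n=3
  calls <- call_methylcytosines(list(a = s1, b = s2), error_rate = 0.01)
  # site 30 dropped everywhere: n = 3 < 4 in sample b
  expect_equal(calls$a$pos, c(10, 20))
  expect_equal(calls$b$pos, c(10, 20))
  expect_equal(attr(calls, "n_excluded"), 1L)
  # m = 0 -> p = 1, never methylated
  expect_equal(calls$a[pos == 10, p_value], 1)
  expect_false(calls$a[pos == 10, is_methylated])
  # m = 9, n = 10, e = 0.01 -> p ~ 9.3e-17, methylated
  expect_equal(calls$a[pos == 20, p_value], oracle_binom_tail(9, 10, 0.01),
               tolerance = 1e-12)
  expect_true(calls$a[pos == 20, is_methylated])
  expect_equal(calls$a[pos == 20, level], 0.9)
  expect_error(call_methylcytosines(list(s1), error_rate = 1.2), "error_rate")
})

test_that("null-site call rate respects the discrete test size", {
  # scaled-down version of the calibration criterion (full size in
  # test-acceptance.R): 1e5 null sites at coverage 15
  set.seed(6)
  n <- rpois(1e5, 15)
  rep0 <- data.table::data.table(chrom = "c", pos = seq_along(n), strand = "+",
                                 m = rbinom(length(n), n, 0.01), u = NA_integer_,
                                 context = "CG")
  rep0[, u := n - m]
  calls <- call_methylcytosines(rep0, error_rate = 0.01)[[1]]
  frac <- mean(calls$is_methylated)
  sizes <- vapply(4:60, function(nn) {
    k <- which(binom_upper_tail(0:nn, nn, 0.01) < 1e-4)[1] - 1L
    if (is.na(k)) 0 else binom_upper_tail(k, nn, 0.01)
  }, numeric(1))
  wts <- dpois(4:60, 15) / sum(dpois(4:60, 15))
  size <- sum(sizes * wts)
  expect_lt(size, 1e-4)
  expect_lte(frac, qbinom(0.999, nrow(calls), size) / nrow(calls))
})

test_that("summaries: context means, mC fractions, window rule", {
  calls <- data.table::data.table(
    chrom = "chr1", pos = c(100, 200, 300), strand = "+",
    context = c("CG", "CG", "CHH"),
    m = c(1, 2, 0), u = c(1, 0, 2), n = 2, level = c(0.5, 1.0, 0.0),
    p_value = 0.5, is_methylated = c(TRUE, TRUE, FALSE))
  sm <- summarize_methylome(calls, c(chr1 = 1000))
  expect_equal(sm$context[context == "CG", mean_level], 0.75)
  expect_equal(sm$context[context == "CG", mc_fraction], 1)
  # mC fractions normalise to 1
  calls2 <- data.table::data.table(
    chrom = "chr1", pos = 1:100, strand = "+",
    context = rep(c("CG", "CHG", "CHH"), c(20, 30, 50)),
    m = 5, u = 0, n = 5, level = 1, p_value = 0, is_methylated = TRUE)
  sm2 <- summarize_methylome(calls2, c(chr1 = 1000))
  expect_equal(sm2$context[order(context), mc_fraction], c(0.2, 0.3, 0.5))
  expect_equal(sum(sm2$context$mc_fraction), 1, tolerance = 1e-12)
  # window enumeration on a 2 Mb chromosome: starts every 200 kb below the
  # length (10 windows), 6 of them full 1 Mb anchors, the rest clipped
  w <- window_mean_track(data.table::data.table(chrom = "chr1", pos = 1, value = 0.5),
                         c(chr1 = 2e6))
  expect_equal(nrow(w), 10)
  expect_equal(w$start, seq(0, 1.8e6, by = 2e5))
  expect_equal(sum(w$end - w$start == 1e6), 6)
  expect_equal(max(w$end), 2e6)
  # empty windows are NA (missing), not zero
  expect_true(all(is.na(w$mean_level[-1])))
  expect_equal(w$mean_level[1], 0.5)
})
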