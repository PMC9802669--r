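# DMR scanning, interdependent merging, location classification.

# five shared CG sites: A pooled 40/10, B pooled 10/40 per the crafted case
crafted_pair <- function() {
  pos <- c(100, 120, 140, 160, 180)
  list(a = make_report(pos, m = 8, u = 2),
       b = make_report(pos, m = 2, u = 8))
}

test_that("scan emits a candidate for a strong 5-site difference", {
  cp <- crafted_pair()
  cand <- scan_dmr_candidates(cp$a, cp$b, "CG")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 180)
  expect_equal(cand$n_sites, 5L)
  expect_equal(cand$level_a, 0.8)
  expect_equal(cand$level_b, 0.2)
  expect_equal(cand$p_value, oracle_fisher_2x2(40, 10, 10, 40), tolerance = 1e-10)
  expect_lt(cand$p_value, 5e-9)
})

test_that("scan rejects no-difference and exact-cutoff windows", {
  pos <- c(100, 120, 140, 160, 180)
  same <- make_report(pos, m = 5, u = 5)
  expect_equal(nrow(scan_dmr_candidates(same, same, "CG")), 0)
  # diff exactly 0.10 fails the strict inequality
  a <- make_report(pos, m = 6, u = 4)   # pooled 30/50 = 0.6
  b <- make_report(pos, m = 5, u = 5)   # pooled 25/50 = 0.5
  expect_equal(nrow(scan_dmr_candidates(a, b, "CG")), 0)
})

test_that("scan excludes sites under-covered in either sample", {
  pos <- c(100, 120, 140, 160, 180, 200)
  a <- make_report(pos, m = 8, u = 2)
  b <- make_report(pos, m = c(2, 2, 2, 2, 2, 1), u = c(8, 8, 8, 8, 8, 1))
  cand <- scan_dmr_candidates(a, b, "CG")
  expect_equal(cand$end, 180)  # site 200 (n=2 in b) never enters a window
})

test_that("empty context yields empty result with a warning", {
  cp <- crafted_pair()
  expect_warning(cand <- scan_dmr_candidates(cp$a, cp$b, "CHH"), "fewer than")
  expect_equal(nrow(cand), 0)
})

test_that("interdependent candidates join; independent ones stay separate", {
  # neutral middle drags the spanning diff below 0.1 -> two DMRs
  fx <- merge_fixture()
  dmrs <- call_dmrs(fx$a, fx$b, contexts = "CG")
  expect_equal(nrow(dmrs), 2)
  expect_true(all(dmrs$merged_from == 1L))
  # spanning region recomputed by hand: fails the join cutoff
  ma <- 2 * 45 + 40 * 25; na <- 2 * 50 + 40 * 50
  mb <- 2 * 5 + 40 * 25;  nb <- na
  expect_lt(abs(ma / na - mb / nb), 0.1)
  # short neutral stretch -> spanning region passes -> one merged DMR
  fx2 <- merge_fixture(gap_sites = 4)
  dmrs2 <- call_dmrs(fx2$a, fx2$b, contexts = "CG")
  expect_equal(nrow(dmrs2), 1)
  expect_gte(dmrs2$merged_from, 2L)
  expect_equal(dmrs2$n_sites, 14L)
  expect_gt(abs(dmrs2$diff), 0.1)
  expect_lte(dmrs2$p_value, 0.05)
})

test_that("merging is idempotent and keeps single candidates unchanged", {
  fx <- merge_fixture(gap_sites = 4)
  a <- pool_calls(fx$a); b <- pool_calls(fx$b)
  sites <- methexpr:::shared_context_sites(a, b, "CG")
  cand <- scan_dmr_candidates(fx$a, fx$b, "CG")
  m1 <- merge_interdependent(cand, sites)
  m2 <- merge_interdependent(m1, sites)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  # single candidate passes through with merged_from = 1
  cp <- crafted_pair()
  one <- scan_dmr_candidates(cp$a, cp$b, "CG")
  sites1 <- methexpr:::shared_context_sites(pool_calls(cp$a), pool_calls(cp$b), "CG")
  mo <- merge_interdependent(one, sites1)
  expect_equal(nrow(mo), 1)
  expect_equal(mo$merged_from, 1L)
  expect_equal(mo$start, one$start)
  expect_equal(mo$direction, "hyper")
})

test_that("swapping samples flips direction and preserves p-values", {
  cfg <- tiny_config(seed = 21)
  gg <- simulate_genome(cfg)
  tr <- plant_truth(cfg, gg$genome, gg$genes)
  meth <- simulate_methylomes(cfg, gg$genome, gg$genes, tr)
  calls <- call_methylcytosines(meth[c("W245_R5_m1", "Z16_R5_m1")], 0.01)
  ab <- call_dmrs(calls[[1]], calls[[2]], contexts = "CG")
  ba <- call_dmrs(calls[[2]], calls[[1]], contexts = "CG")
  expect_equal(ab$start, ba$start)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)
  expect_equal(ab$direction, ifelse(ba$direction == "hyper", "hypo", "hyper"))
  # every emitted DMR satisfies the stated thresholds
  expect_true(all(abs(ab$diff) > 0.1))
  expect_true(all(ab$p_value <= 0.05))
  expect_true(all(ab$n_sites >= 5))
})

test_that("DMR location: body overlap, strand-aware upstream, complement", {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(1100, 5000), end = c(2000, 6000),
    strand = c("+", "-"), length = c(901L, 1001L))
  dmrs <- data.table::data.table(
    dmr_id = c("d1", "d2", "d3"), chrom = "chr1",
    start = c(1000, 6100, 9500), end = c(1200, 6150, 9600),
    context = "CG", direction = "hyper")
  res <- classify_dmr_location(dmrs, genes, c(chr1 = 10000))
  expect_equal(res$dmrs$location, c("genic", "genic", "intergenic"))
  expect_equal(res$fractions$genic_fraction, 2 / 3)
})
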