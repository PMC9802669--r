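# DMR-gene association, enrichment statistics, cross-tabs, window
# correlation, term enrichment.

test_that("DMR-gene association: body, clipped upstream, complement", {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(1000, 30), end = c(2000, 600), strand = "+",
    length = c(1001L, 571L))
  dmrs <- data.table::data.table(
    dmr_id = c("d1", "d2", "d3"), chrom = "chr1",
    start = c(900, 1, 8000), end = c(1100, 50, 8100), context = "CG")
  res <- associate_dmrs(dmrs, genes, c(chr1 = 10000))
  p <- res$pairs
  # d1 overlaps g1's body and, incidentally, its upstream stretch
  expect_equal(p[dmr_id == "d1" & gene_id == "g1", where], "both")
  # upstream of g2 clipped to [1, 29]; d2 spans both upstream and body
  expect_equal(p[dmr_id == "d2" & gene_id == "g2", where], "both")
  expect_false("d3" %in% p$dmr_id)  # 3 kb from everything: unassociated
  expect_setequal(res$genes, c("g1", "g2"))
  expect_warning(associate_dmrs(data.table::data.table(
    dmr_id = "x", chrom = "chrZ", start = 1, end = 5, context = "CG"),
    genes, c(chr1 = 10000)), "absent")
})

test_that("upstream regions are strand-aware and never overlap the body", {
  genes <- data.table::data.table(
    gene_id = c("p", "m"), chrom = "c1", start = c(5000, 5000),
    end = c(6000, 6000), strand = c("+", "-"), length = 1001L)
  reg <- gene_regions(genes, c(c1 = 7000))
  up_p <- reg[gene_id == "p" & part == "upstream"]
  up_m <- reg[gene_id == "m" & part == "upstream"]
  expect_equal(c(up_p$start, up_p$end), c(3000, 4999))
  expect_equal(c(up_m$start, up_m$end), c(6001, 7000))  # clipped at chrom end
  expect_true(all(reg[part == "upstream", end < 5000 | start > 6000]))
})

test_that("fold enrichment closed forms and hypergeometric tail", {
  e <- deg_dmr_enrichment(1000, 200, 100, 50)
  expect_equal(e$fold_enrichment, 2.5)
  expect_equal(e$p_value, oracle_hyper_tail(50, 200, 1000, 100), tolerance = 1e-12)
  # k = n*K/N exactly -> fold 1
  expect_equal(deg_dmr_enrichment(1000, 200, 100, 20)$fold_enrichment, 1)
  # N=20, K=5, n=5, k=4 against the enumeration oracle
  e2 <- deg_dmr_enrichment(20, 5, 5, 4)
  expect_equal(e2$p_value, oracle_hyper_tail(4, 5, 20, 5), tolerance = 1e-12)
  expect_error(deg_dmr_enrichment(100, 0, 10, 0), "undefined")
  expect_error(deg_dmr_enrichment(100, 10, 0, 0), "undefined")
  expect_error(deg_dmr_enrichment(100, 10, 5, 7), "inconsistent")
})

crosstab_fixture <- function(dirs_dmr, dirs_deg) {
  n <- length(dirs_dmr)
  dmrs <- data.table::data.table(dmr_id = sprintf("d%d", 1:n), context = "CG",
                                 direction = dirs_dmr)
  degs <- data.table::data.table(gene_id = sprintf("g%d", 1:n),
                                 direction = ifelse(dirs_deg == "up", "up_in_a",
                                                    "down_in_a"),
                                 is_deg = TRUE)
  assoc <- data.table::data.table(gene_id = sprintf("g%d", 1:n),
                                  dmr_id = sprintf("d%d", 1:n), where = "body")
  list(dmrs = dmrs, degs = degs, assoc = assoc)
}

test_that("hyper/hypo cross-tab: degenerate case and focal-swap symmetry", {
  fx <- crosstab_fixture(rep("hyper", 6), rep(c("up", "down"), 3))
  tab <- hyper_hypo_crosstab(fx$dmrs, fx$degs, fx$assoc)
  expect_equal(tab$hyper_fraction, c(1, 1))  # all-hyper: fraction 1 everywhere
  # mixed directions; swapping the focal sample flips f -> 1 - f
  fx2 <- crosstab_fixture(c("hyper", "hyper", "hypo", "hyper", "hypo", "hypo"),
                          c("up", "up", "up", "down", "down", "down"))
  t1 <- hyper_hypo_crosstab(fx2$dmrs, fx2$degs, fx2$assoc)
  fx2s <- fx2
  fx2s$dmrs$direction <- ifelse(fx2$dmrs$direction == "hyper", "hypo", "hyper")
  fx2s$degs$direction <- ifelse(fx2$degs$direction == "up_in_a", "down_in_a",
                                "up_in_a")
  t2 <- hyper_hypo_crosstab(fx2s$dmrs, fx2s$degs, fx2s$assoc)
  m <- merge(t1, t2, by = c("context", "deg_direction"))
  # swapped focal sample also swaps which DEG class is which
  expect_equal(t1[deg_direction == "up", hyper_fraction],
               1 - t2[deg_direction == "down", hyper_fraction])
  expect_equal(t1[deg_direction == "down", hyper_fraction],
               1 - t2[deg_direction == "up", hyper_fraction])
})

test_that("window correlation: perfect anti-correlation and input guards", {
  w <- data.table::data.table(chrom = "c1", start = seq(0, 9e5, 1e5),
                              end = seq(1e5, 1e6, 1e5))
  meth <- data.table::copy(w)[, mean_level := seq(0.1, 1, 0.1)]
  expr <- data.table::copy(w)[, mean_level := 5 - seq(0.1, 1, 0.1)]
  res <- methylation_expression_correlation(meth, expr)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_equal(res$n_windows, 10)
  expect_error(methylation_expression_correlation(meth[1:2], expr[1:2]),
               "fewer than 3")
})

test_that("window expression track anchors genes by body midpoint", {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "c1", start = c(100, 250100),
    end = c(1100, 251100), strand = "+", length = 1001L)
  fv <- c(g1 = 9.99, g2 = 99.99)
  tr <- window_expression_track(fv, genes, c(c1 = 6e5), window_size = 2e5,
                                step = 2e5, eps = 0.01)
  expect_equal(tr$mean_level, c(1, 2, NA), tolerance = 1e-10)
})

test_that("term enrichment: maximal overlap ranks first, k = 0 gives p = 1", {
  ann <- data.table::data.table(
    gene_id = c(sprintf("g%02d", 1:40), "g01", "g02", "g03"),
    term_id = c(rep("BIG", 40), rep("SMALL", 3)))
  res <- term_enrichment(c("g01", "g02", "g03"), ann)
  expect_equal(res$term_id[1], "SMALL")
  expect_equal(res[term_id == "SMALL", n_overlap], 3L)
  expect_equal(res[term_id == "SMALL", p_value],
               oracle_hyper_tail(3, 3, 40, 3), tolerance = 1e-12)
  # a term with no overlap: P(X >= 0) = 1
  ann2 <- rbind(ann, data.table::data.table(gene_id = c("g38", "g39"),
                                            term_id = "NONE"))
  res2 <- term_enrichment(c("g01", "g02", "g03"), ann2)
  expect_equal(res2[term_id == "NONE", p_value], 1)
  expect_error(term_enrichment("g01", ann[0]), "empty background")
})

test_that("null gene sets are enriched at roughly the nominal rate", {
  set.seed(51)
  genes <- sprintf("g%03d", 1:200)
  ann <- data.table::rbindlist(lapply(1:40, function(i)
    data.table::data.table(gene_id = sample(genes, 25), term_id = sprintf("T%02d", i))))
  hits <- replicate(25, {
    res <- term_enrichment(sample(genes, 30), ann)
    mean(res$p_value < 0.05)
  })
  expect_lt(mean(hits), 0.12)  # ~5% nominal, generous Monte Carlo margin
})
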