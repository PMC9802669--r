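# Synthetic-data generator: determinism, placement, realized effects.

test_that("genome simulation is deterministic and honours gene constraints", {
  cfg <- tiny_config(seed = 61)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))
  # n_genes = 0: valid genome, empty gene table
  g0 <- simulate_genome(tiny_config(seed = 61, n_genes = 0L))
  expect_equal(nrow(g0$genes), 0)
  expect_equal(length(g0$genome), 2)
  # genes that cannot fit raise the placement constraint
  expect_error(simulate_genome(tiny_config(seed = 61, chrom_length = 5e3,
                                           n_genes = 40L)),
               "non-overlapping")
})

test_that("placed genes are disjoint and inside chromosomes (interval sweep)", {
  cfg <- tiny_config(seed = 62, chrom_length = 1e6, n_genes = 200L,
                     gene_length_range = c(1000L, 5000L))
  gg <- simulate_genome(cfg)
  expect_equal(nrow(gg$genes), 200)
  for (ch in unique(gg$genes$chrom)) {
    g <- gg$genes[chrom == ch][order(start)]
    expect_true(all(g$start >= 1))
    expect_true(all(g$end <= 1e6))
    expect_true(all(g$end - g$start + 1 == g$length))
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
})

test_that("emitted methylome context equals recomputation from the genome", {
  cfg <- tiny_config(seed = 63, chrom_length = 2e4, n_genes = 5L,
                     n_planted_degs = 2L)
  gg <- simulate_genome(cfg)
  tr <- plant_truth(cfg, gg$genome, gg$genes)
  meth <- simulate_methylomes(cfg, gg$genome, gg$genes, tr)
  dt <- meth[[1]]
  idx <- sample(nrow(dt), 400)
  expect_equal(dt$context[idx],
               assign_context(gg$genome, dt$chrom[idx], dt$pos[idx], dt$strand[idx]))
  # determinism: same config reproduces the identical file
  meth2 <- simulate_methylomes(cfg, gg$genome, gg$genes, tr)
  expect_identical(as.data.frame(meth[[1]]), as.data.frame(meth2[[1]]))
})

test_that("observed CG level matches the configured baseline", {
  # ~1e5 CG sites outside DMRs; error floor raises 0.8 to 0.8 + 0.01 * 0.2
  cfg <- tiny_config(seed = 64, n_chromosomes = 2L, chrom_length = 4e5,
                     n_genes = 0L, n_planted_dmrs = 0L,
                     anticorrelation_fraction = 0, n_planted_degs = 0L,
                     n_modules = 0L, landscape_amplitude = 0,
                     context_base_levels = c(CG = 0.8, CHG = 0.7, CHH = 0.1))
  gg <- simulate_genome(cfg)
  tr <- plant_truth(cfg, gg$genome, gg$genes)
  meth <- simulate_methylomes(cfg, gg$genome, gg$genes, tr)
  dt <- meth[[1]][context == "CG" & m + u > 0]
  expect_gt(nrow(dt), 9e4)
  expect_equal(mean(dt$m / (dt$m + dt$u)), 0.8 + 0.01 * 0.2, tolerance = 0.01)
})

test_that("coverage_mean = 0 gives empty coverage everywhere", {
  cfg <- tiny_config(seed = 65, chrom_length = 1e4, n_genes = 2L,
                     coverage_mean = 0, n_planted_degs = 0L)
  gg <- simulate_genome(cfg)
  tr <- plant_truth(cfg, gg$genome, gg$genes)
  meth <- simulate_methylomes(cfg, gg$genome, gg$genes, tr)
  expect_true(all(meth[[1]]$m + meth[[1]]$u == 0))
  calls <- call_methylcytosines(meth[[1]], 0.01)
  expect_equal(nrow(calls[[1]]), 0)
})

test_that("planted CG-DMRs realise their effect in pooled levels", {
  cfg <- tiny_config(seed = 66, chrom_length = 3e5, n_planted_dmrs = 25L,
                     dmr_effect = 0.4, coverage_mean = 30)
  gg <- simulate_genome(cfg)
  tr <- plant_truth(cfg, gg$genome, gg$genes)
  meth <- simulate_methylomes(cfg, gg$genome, gg$genes, tr)
  a <- pool_calls(meth[["W245_R5_m1"]]); b <- pool_calls(meth[["Z16_R5_m1"]])
  pl <- tr$planted_dmrs[kind == "planted" & context == "CG"]
  diffs <- vapply(seq_len(nrow(pl)), function(i) {
    sa <- a[chrom == pl$chrom[i] & pos >= pl$start[i] & pos <= pl$end[i] &
              context == "CG"]
    sb <- b[chrom == pl$chrom[i] & pos >= pl$start[i] & pos <= pl$end[i] &
              context == "CG"]
    sum(sa$m) / sum(sa$n) - sum(sb$m) / sum(sb$n)
  }, numeric(1))
  signs <- ifelse(pl$direction == "hyper", 1, -1)
  # every planted DMR clears the 0.1 call cutoff; the mean realized |diff|
  # reaches ~0.3 (hyper CG truncates at level 1: 0.7 + 0.4 -> 1.0)
  expect_true(all(diffs * signs > 0.1))
  expect_gte(mean(abs(diffs)), 0.3)
  # matched null regions recorded alongside, same shape
  expect_equal(nrow(tr$planted_dmrs[kind == "null" & context == "CG"]), 25)
})

test_that("fold-1 genes have equal group means at n = 50 replicates", {
  genes <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
    start = seq(1000, by = 3000, length.out = 30),
    end = seq(1000, by = 3000, length.out = 30) + 1999L,
    strand = "+", length = 2000L)
  cfg <- tiny_config(seed = 67, n_genes = 30L, n_replicates = 50L,
                     n_planted_degs = 0L, anticorrelation_fraction = 0,
                     n_modules = 0L, stages = "R5")
  tr <- plant_truth(cfg, NULL, genes)
  ex <- simulate_expression(cfg, genes, tr)
  sh <- ex$sample_sheet
  pvals <- apply(ex$counts, 1, function(x)
    t.test(log1p(x[sh[genotype == "W245", sample_id]]),
           log1p(x[sh[genotype == "Z16", sample_id]]))$p.value)
  expect_gt(mean(pvals > 0.01), 0.9)
  # determinism of the count matrix
  ex2 <- simulate_expression(cfg, genes, tr)
  expect_identical(ex$counts, ex2$counts)
})

test_that("module genes are more correlated within than between modules", {
  cfg <- tiny_config(seed = 68, n_genes = 60L, n_modules = 2L,
                     module_size = 15L, anticorrelation_fraction = 0,
                     n_planted_degs = 0L)
  gg <- simulate_genome(cfg)
  tr <- plant_truth(cfg, gg$genome, gg$genes)
  ex <- simulate_expression(cfg, gg$genes, tr)
  x <- log2(ex$counts + 1)
  cc <- cor(t(x))
  m1 <- tr$modules[module == 1, gene_id]
  m2 <- tr$modules[module == 2, gene_id]
  within <- c(cc[m1, m1][upper.tri(diag(length(m1)))],
              cc[m2, m2][upper.tri(diag(length(m2)))])
  between <- as.vector(cc[m1, m2])
  expect_gt(mean(within), mean(between) + 0.3)
})

test_that("planted DEG folds are realised within 25%", {
  genes <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
    start = seq(1000, by = 2500, length.out = 100),
    end = seq(1000, by = 2500, length.out = 100) + 1999L,
    strand = "+", length = 2000L)
  cfg <- tiny_config(seed = 69, n_genes = 100L, n_replicates = 50L,
                     n_planted_degs = 10L, deg_fold_change = 4,
                     anticorrelation_fraction = 0, n_modules = 0L,
                     stages = "R5", chrom_length = 2.5e5 + 5e3)
  tr <- plant_truth(cfg, NULL, genes)
  ex <- simulate_expression(cfg, genes, tr)
  sh <- ex$sample_sheet
  ma <- rowMeans(ex$counts[, sh[genotype == "W245", sample_id]])
  mb <- rowMeans(ex$counts[, sh[genotype == "Z16", sample_id]])
  pd <- tr$planted_degs
  realized <- ifelse(pd$direction == "up", ma[pd$gene_id] / mb[pd$gene_id],
                     mb[pd$gene_id] / ma[pd$gene_id])
  expect_true(all(abs(realized - 4) / 4 < 0.25))
})
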