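library(data.table)  # data.table semantics for [ in test code

# Independent enumeration oracles (choose()-based, no stats:: tail
# functions) and small fixture builders shared across the test files.

# two-sided Fisher exact: sum of probabilities of all tables at fixed
# margins no more probable than the observed one
oracle_fisher_2x2 <- function(ma, ua, mb, ub) {
  na <- ma + ua; nb <- mb + ub; K <- ma + mb; N <- na + nb
  lo <- max(0, K - nb); hi <- min(K, na)
  pr <- vapply(lo:hi, function(x) choose(na, x) * choose(nb, K - x), numeric(1)) /
    choose(N, K)
  dobs <- pr[ma - lo + 1]
  min(1, sum(pr[pr <= dobs * (1 + 1e-7)]))
}

# binomial upper tail by direct term summation
oracle_binom_tail <- function(m, n, p) {
  if (m > n) return(0)
  sum(vapply(m:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), numeric(1)))
}

# hypergeometric upper tail by direct term summation
oracle_hyper_tail <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) choose(K, i) * choose(N - K, n - i), numeric(1))) /
    choose(N, n)
}

# TOM by triple loop from an adjacency matrix (diagonal ignored)
oracle_tom <- function(a) {
  a <- as.matrix(a); diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# cytosine-report table builder (one chromosome, plus strand, one context)
make_report <- function(pos, m, u, context = "CG", chrom = "chr1", strand = "+") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
                         m = as.integer(m), u = as.integer(u), context = context)
}

# two strong 5-site clusters around a deeply covered neutral stretch; with
# a long stretch the spanning region fails the join test, with a short one
# it passes (used by the merge unit tests and acceptance criterion 4)
merge_fixture <- function(gap_sites = 40) {
  p1 <- seq(100, 108, by = 2)
  pm <- seq(120, 120 + 2 * (gap_sites - 1), by = 2)
  p2 <- max(pm) + c(10, 12, 14, 16, 18)
  a <- make_report(c(p1, pm, p2),
                   m = c(rep(9, 5), rep(25, gap_sites), rep(9, 5)),
                   u = c(rep(1, 5), rep(25, gap_sites), rep(1, 5)))
  b <- make_report(c(p1, pm, p2),
                   m = c(rep(1, 5), rep(25, gap_sites), rep(1, 5)),
                   u = c(rep(9, 5), rep(25, gap_sites), rep(9, 5)))
  list(a = a, b = b)
}

# tiny deterministic sim config for fast tests
tiny_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_chromosomes = 2L, chrom_length = 1e5,
               n_genes = 40L, gene_length_range = c(800L, 2000L),
               n_planted_dmrs = 4L, n_planted_degs = 8L,
               n_modules = 2L, module_size = 8L, meth_replicates = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
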