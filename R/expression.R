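# Expression quantification, differential expression, and profile
# clustering. Counts are a genes x samples integer matrix; FPKM is
# 1e9 * C / (N_s * L_g) with N_s the sample's counted-fragment total.
#
# The differential test is a deliberate transparent substitute for the
# published package the study delegated to: an exact two-proportion
# binomial test on pooled counts (the gene's share of each pooled group
# library), Benjamini-Hochberg adjusted. It operates on the same inputs
# and thresholds (fold change >= 2, adjusted p <= 0.001, FPKM >= 1 in at
# least one sample).

#' Fragments per kilobase of transcript per million mapped reads
#'
#' fpkm[g, s] = 1e9 * C[g, s] / (N_s * L_g), with N_s the column sum of
#' `counts`.
#'
#' @param counts genes x samples non-negative matrix (rownames = gene ids).
#' @param gene_lengths named vector of gene lengths in bp (> 0).
#' @return FPKM matrix of the same shape.
#' @examples
#' compute_fpkm(matrix(100, 1, 1, dimnames = list("g", "s")) * 1,
#'              c(g = 2000))  # with N = 100; see tests for the closed form
#' @export
compute_fpkm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  L <- gene_lengths[rownames(counts)]
  if (any(is.na(L))) stop("gene_lengths missing for some genes")
  if (any(L <= 0)) stop("zero or negative gene length")
  N <- colSums(counts)
  fpkm <- sweep(counts, 2, pmax(N, 1), "/")
  fpkm <- sweep(fpkm, 1, as.numeric(L), "/") * 1e9
  fpkm
}

#' Call differentially expressed genes between two groups
#'
#' Genes are first filtered to FPKM >= `fpkm_filter` in at least one sample
#' of the two compared groups; counts are then pooled within each group and
#' each gene's share of the pooled libraries compared by an exact two-sided
#' two-proportion binomial test (conditioning on the gene's total count,
#' the group-A count is Binomial with probability N_A / (N_A + N_B) under
#' the null). P-values are Benjamini-Hochberg adjusted over tested genes.
#' The fold change is the ratio of group mean FPKM with floor `fpkm_floor`.
#'
#' @param counts genes x samples count matrix.
#' @param gene_lengths named gene lengths (bp).
#' @param samples_a,samples_b column names of the two groups.
#' @param fc_cutoff fold-change threshold (>= 2 means |log2FC| >= 1).
#' @param adj_p_cutoff BH-adjusted p threshold (0.001).
#' @param fpkm_filter expression filter (>= 1 in at least one sample).
#' @param fpkm_floor pseudo-value floor for the fold-change ratio (0.01).
#' @return data.table(gene_id, group_a_mean, group_b_mean, log2_fold_change,
#'   p_value, adjusted_p, direction, is_deg); attribute `n_excluded` counts
#'   genes dropped by the expression filter.
#' @export
call_degs <- function(counts, gene_lengths, samples_a, samples_b,
                      fc_cutoff = 2, adj_p_cutoff = 0.001,
                      fpkm_filter = 1, fpkm_floor = 0.01) {
  counts <- as.matrix(counts)
  if (!length(samples_a) || !length(samples_b)) stop("empty comparison group")
  miss <- setdiff(c(samples_a, samples_b), colnames(counts))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ","))
  sub <- counts[, c(samples_a, samples_b), drop = FALSE]
  fpkm <- compute_fpkm(sub, gene_lengths)
  expressed <- apply(fpkm, 1, max) >= fpkm_filter
  n_excluded <- sum(!expressed)
  sub <- sub[expressed, , drop = FALSE]
  fpkm <- fpkm[expressed, , drop = FALSE]

  ca <- rowSums(sub[, samples_a, drop = FALSE])
  cb <- rowSums(sub[, samples_b, drop = FALSE])
  Na <- sum(counts[, samples_a]); Nb <- sum(counts[, samples_b])
  p <- binom_two_sided(as.integer(ca), as.integer(ca + cb), Na / (Na + Nb))
  adj <- stats::p.adjust(p, method = "BH")

  mean_a <- rowMeans(fpkm[, samples_a, drop = FALSE])
  mean_b <- rowMeans(fpkm[, samples_b, drop = FALSE])
  lfc <- log2(pmax(mean_a, fpkm_floor) / pmax(mean_b, fpkm_floor))
  out <- data.table::data.table(
    gene_id = rownames(sub),
    group_a_mean = mean_a, group_b_mean = mean_b,
    log2_fold_change = lfc, p_value = p, adjusted_p = adj,
    direction = ifelse(lfc > 0, "up_in_a", "down_in_a"),
    is_deg = abs(lfc) >= log2(fc_cutoff) & adj <= adj_p_cutoff)
  attr(out, "n_excluded") <- n_excluded
  out[]
}

# per-gene z-score of log2(FPKM + 1); constant profiles become all-zero
normalize_profiles <- function(fpkm) {
  x <- log2(as.matrix(fpkm) + 1)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z
}

#' K-means clustering of expression profiles
#'
#' Profiles are per-gene z-scores of log2(FPKM + 1); Lloyd's algorithm with
#' k-means++ seeding under a fixed seed, `n_init` restarts keeping the best
#' within-cluster sum of squares (Euclidean distance throughout). Ties in
#' assignment go to the lowest cluster index; an emptied cluster is
#' re-seeded from the point farthest from its centre.
#'
#' @param fpkm genes x samples FPKM matrix, pre-filtered to expressed genes
#'   (FPKM >= 1 in at least one sample) unless `filter = FALSE`.
#' @param k number of clusters (default 9).
#' @param seed RNG seed for seeding/restarts.
#' @param n_init restarts (default 5).
#' @param max_iter Lloyd iteration cap.
#' @param filter apply the FPKM >= 1 expression filter (default TRUE).
#' @return list(assignment = named integer vector, centers = k x samples
#'   matrix, inertia, inertia_trace of the winning run).
#' @export
kmeans_cluster <- function(fpkm, k = 9L, seed = 1L, n_init = 5L,
                           max_iter = 100L, filter = TRUE) {
  fpkm <- as.matrix(fpkm)
  if (filter) fpkm <- fpkm[apply(fpkm, 1, max) >= 1, , drop = FALSE]
  if (k > nrow(fpkm)) stop("k exceeds the number of genes (", nrow(fpkm), ")")
  z <- normalize_profiles(fpkm)
  set.seed(seed)
  best <- NULL
  for (run in seq_len(n_init)) {
    fit <- lloyd_kmeans(z, k, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  names(best$assignment) <- rownames(z)
  best
}

# k-means++ seeding followed by Lloyd iterations
lloyd_kmeans <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  ci <- sample.int(n, 1)
  centers[1, ] <- x[ci, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    ci <- sample.int(n, 1, prob = prob)
    centers[j, ] <- x[ci, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  assign <- integer(n)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dmat <- dist_to_centers(x, centers)
    assign_new <- max.col(-dmat, ties.method = "first")  # lowest index on ties
    for (j in seq_len(k)) {
      if (!any(assign_new == j)) {
        far <- which.max(dmat[cbind(seq_len(n), assign_new)])
        assign_new[far] <- j
      }
    }
    inertia <- sum(dist_to_centers(x, centers)[cbind(seq_len(n), assign_new)])
    trace <- c(trace, inertia)
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
    if (iter > 1 && identical(assign_new, assign)) { assign <- assign_new; break }
    assign <- assign_new
  }
  final <- sum(dist_to_centers(x, centers)[cbind(seq_len(n), assign)])
  list(assignment = assign, centers = centers, inertia = final,
       inertia_trace = c(trace, final))
}

# squared Euclidean distances of rows of x to rows of centers
dist_to_centers <- function(x, centers) {
  xc <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xc, cc, "+") - 2 * x %*% t(centers)
}

#' Sample-level overview: hierarchical clustering and PCA
#'
#' Samples are clustered on 1 - Pearson correlation of log2(FPKM + 1)
#' profiles with average linkage; PCA runs on the same normalised matrix
#' (samples as observations, centred).
#'
#' @param fpkm genes x samples FPKM matrix (>= 2 samples).
#' @return list(hclust, pca = samples x PC coordinate matrix,
#'   variance_explained fractions summing to 1 over all components).
#' @export
profile_overview <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (ncol(fpkm) < 2) stop("need at least two samples")
  x <- log2(fpkm + 1)
  keep <- apply(x, 1, stats::sd) > 0
  cc <- stats::cor(x[keep, , drop = FALSE])
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(hclust = hc, pca = pc$x, variance_explained = ve)
}
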