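# Integration of DMRs with gene models, DEGs, expression tracks and term
# annotations: DMR-gene association over body + 2 kb upstream, DEG
# enrichment among DMR-associated genes (hypergeometric), hyper/hypo by
# up/down cross-tabulation, windowed methylation-expression correlation,
# and flat term enrichment.

#' Associate DMRs with genes by body or 2 kb upstream overlap
#'
#' A gene is DMR-associated when its genic region (body or strand-aware
#' 2 kb upstream, clipped to the chromosome) overlaps a DMR by at least
#' `min_overlap` bp. One DMR may associate with several genes and vice
#' versa; each pair is annotated with where the overlap fell.
#'
#' @param dmrs DMR data.table (needs dmr_id, chrom, start, end).
#' @param genes gene-model data.table.
#' @param chrom_len named chromosome lengths.
#' @param upstream upstream extent in bp (2000).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return list(pairs = data.table(gene_id, dmr_id, where in
#'   body/upstream/both), genes = DMR-associated gene ids). Warns when
#'   chromosome name sets disagree.
#' @export
associate_dmrs <- function(dmrs, genes, chrom_len, upstream = 2000L,
                           min_overlap = 1L) {
  mism <- setdiff(unique(dmrs$chrom), unique(genes$chrom))
  if (length(mism))
    warning(length(mism), " DMR chromosome(s) absent from gene models: ",
            paste(mism, collapse = ","))
  if (!nrow(dmrs) || !nrow(genes))
    return(list(pairs = data.table::data.table(gene_id = character(),
                                               dmr_id = character(),
                                               where = character()),
                genes = character()))
  reg <- gene_regions(genes, chrom_len, upstream)
  q <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(dmrs$start, dmrs$end))
  r <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start, reg$end))
  # chromosome-set disagreement is already reported above; silence the
  # GRanges seqlevel notice it would duplicate
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, r, minoverlap = min_overlap))
  pairs <- data.table::data.table(
    dmr_id = dmrs$dmr_id[S4Vectors::queryHits(ov)],
    gene_id = reg$gene_id[S4Vectors::subjectHits(ov)],
    part = reg$part[S4Vectors::subjectHits(ov)])
  pairs <- pairs[, .(where = if (all(c("body", "upstream") %in% part)) "both"
                     else part[1]),
                 by = .(gene_id, dmr_id)]
  data.table::setorder(pairs, gene_id, dmr_id)
  list(pairs = pairs[], genes = sort(unique(pairs$gene_id)))
}

#' Fold enrichment of DEGs among DMR-associated genes
#'
#' fold = (k/n) / (K/N) with N total genes, K DMR-associated genes, n total
#' DEGs and k DMR-associated DEGs; significance is the hypergeometric upper
#' tail P(X >= k).
#'
#' @param n_total_genes N.
#' @param n_dmr_assoc_genes K.
#' @param n_total_degs n.
#' @param n_dmr_assoc_degs k.
#' @return list(fold_enrichment, p_value).
#' @examples
#' deg_dmr_enrichment(1000, 200, 100, 50)$fold_enrichment  # 2.5
#' @export
deg_dmr_enrichment <- function(n_total_genes, n_dmr_assoc_genes,
                               n_total_degs, n_dmr_assoc_degs) {
  N <- n_total_genes; K <- n_dmr_assoc_genes
  n <- n_total_degs; k <- n_dmr_assoc_degs
  if (k > min(K, n) || K > N || n > N) stop("inconsistent enrichment counts")
  if (K == 0 || n == 0)
    stop("fold enrichment undefined: no DMR-associated genes or no DEGs")
  list(fold_enrichment = (k / n) / (K / N),
       p_value = hyper_upper_tail(k, K, N, n))
}

#' Hyper/hypo by up/down cross-tabulation of DEG-overlapping DMRs
#'
#' Among DMRs associated with up-regulated (resp. down-regulated) DEGs,
#' reports the hyper fraction hyper / (hyper + hypo) per context (and per
#' stage when the DEG table carries a `stage` column). DMR and DEG
#' directions must refer to the same focal sample A. Each (DMR, DEG) pair
#' counts once; empty classes give an NA fraction, not zero.
#'
#' @param dmrs DMR data.table (dmr_id, context, direction).
#' @param degs DEG data.table from [call_degs()] restricted or not; only
#'   rows with is_deg == TRUE are used. Optional `stage` column.
#' @param association the `pairs` table from [associate_dmrs()].
#' @return data.table(context[, stage], deg_direction, n_hyper, n_hypo,
#'   hyper_fraction).
#' @export
hyper_hypo_crosstab <- function(dmrs, degs, association) {
  degs <- data.table::as.data.table(degs)[is_deg == TRUE]
  keys <- c("context", if ("stage" %in% names(degs)) "stage", "deg_direction")
  j <- merge(association, dmrs[, .(dmr_id, context, dmr_direction = direction)],
             by = "dmr_id")
  j <- merge(j, degs[, c("gene_id", "direction",
                         intersect("stage", names(degs))), with = FALSE],
             by = "gene_id")
  data.table::setnames(j, "direction", "deg_direction")
  j[, deg_direction := ifelse(deg_direction == "up_in_a", "up", "down")]
  tab <- j[, .(n_hyper = sum(dmr_direction == "hyper"),
               n_hypo = sum(dmr_direction == "hypo")), by = keys]
  tab[, hyper_fraction := ifelse(n_hyper + n_hypo > 0,
                                 n_hyper / (n_hyper + n_hypo), NA_real_)]
  data.table::setorderv(tab, keys)
  tab[]
}

#' Per-window mean expression track
#'
#' Genes are anchored by body midpoint; each window's value is the mean of
#' log10(FPKM + eps) over anchored genes, using the same window geometry as
#' the methylation track. Empty windows are NA.
#'
#' @param fpkm_values named per-gene expression values (e.g. one sample's
#'   FPKM, or a group mean).
#' @param genes gene-model data.table.
#' @param chrom_len named chromosome lengths.
#' @param window_size,step window geometry in bp (1 Mb / 200 kb).
#' @param eps pseudo-value inside the log10 (0.01).
#' @return data.table(chrom, start, end, mean_level, n_sites) where
#'   mean_level is mean log10(FPKM + eps) and n_sites counts genes.
#' @export
window_expression_track <- function(fpkm_values, genes, chrom_len,
                                    window_size = 1e6, step = 2e5, eps = 0.01) {
  v <- fpkm_values[genes$gene_id]
  if (any(is.na(v))) stop("fpkm_values missing for some genes")
  track <- data.table::data.table(
    chrom = genes$chrom,
    pos = as.integer((genes$start + genes$end) / 2),
    value = log10(v + eps))
  window_mean_track(track, chrom_len, window_size, step)
}

#' Correlate windowed methylation with windowed expression
#'
#' Pearson correlation over windows where both tracks are defined, with the
#' two-sided p-value from the t transform.
#'
#' @param meth_windows,expr_windows window tables (chrom, start, end,
#'   mean_level) on the same geometry, e.g. from
#'   [summarize_methylome()]`$windows` and [window_expression_track()].
#' @return list(r, p_value, n_windows).
#' @export
methylation_expression_correlation <- function(meth_windows, expr_windows) {
  j <- merge(meth_windows[, .(chrom, start, end, meth = mean_level)],
             expr_windows[, .(chrom, start, end, expr = mean_level)],
             by = c("chrom", "start", "end"))
  j <- j[!is.na(meth) & !is.na(expr)]
  if (nrow(j) < 3) stop("fewer than 3 windows with both tracks defined")
  ct <- stats::cor.test(j$meth, j$expr, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_windows = nrow(j))
}

#' Flat term over-representation by the hypergeometric test
#'
#' For each term: N = annotated background genes, K = the term's genes,
#' n = genes of the query set present in the background, k = the term's
#' genes in the query set; p is the upper tail P(X >= k) with a BH-adjusted
#' q-value column.
#'
#' @param gene_set query gene ids.
#' @param annotation data.table(gene_id, term_id) background annotation
#'   (taken as flat; no ontology propagation).
#' @return data.table(term_id, n_term, n_overlap, fold_enrichment, p_value,
#'   q_value) sorted by p.
#' @export
term_enrichment <- function(gene_set, annotation) {
  annotation <- unique(data.table::as.data.table(annotation)[, .(gene_id, term_id)])
  if (!nrow(annotation)) stop("empty background annotation")
  bg <- unique(annotation$gene_id)
  N <- length(bg)
  set <- intersect(unique(gene_set), bg)
  n <- length(set)
  tab <- annotation[, .(n_term = .N, n_overlap = sum(gene_id %in% set)),
                    by = term_id]
  tab[, fold_enrichment := ifelse(n > 0, (n_overlap / n) / (n_term / N), NA_real_)]
  tab[, p_value := hyper_upper_tail(n_overlap, n_term, N, n)]
  tab[, q_value := stats::p.adjust(p_value, method = "BH")]
  data.table::setorder(tab, p_value, term_id)
  tab[]
}
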