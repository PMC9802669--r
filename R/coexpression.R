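# Co-expression network: unsigned soft-threshold adjacency and the
# topological overlap matrix (TOM), used to select genes co-expressed with
# a seed set at a similarity threshold.
#
#   a_ij   = |cor(x_i, x_j)|^beta          (a_ii treated as 0)
#   k_i    = sum_{j != i} a_ij
#   TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij),  TOM_ii = 1

#' Build an unsigned co-expression network with TOM similarity
#'
#' Pearson correlation on log2(FPKM + 1) profiles, soft-thresholded to the
#' adjacency `|r|^beta`, then converted to topological overlap. Genes with
#' constant profiles (undefined correlation) are dropped with a warning.
#'
#' @param fpkm genes x samples FPKM matrix (>= 3 samples); pre-filter to
#'   expressed genes before calling.
#' @param beta soft-threshold power (default 6).
#' @return list(genes, adjacency (zero diagonal), tom (unit diagonal),
#'   connectivity) of class `methexpr_network`.
#' @export
build_network <- function(fpkm, beta = 6) {
  fpkm <- as.matrix(fpkm)
  if (ncol(fpkm) < 3) stop("need at least three samples")
  x <- log2(fpkm + 1)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene profile(s) dropped")
    x <- x[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  a <- abs(r)^beta
  diag(a) <- 0
  structure(c(list(genes = rownames(x)), tom_from_adjacency(a)),
            class = "methexpr_network")
}

#' Topological overlap from an adjacency matrix
#'
#' @param a symmetric adjacency in `[0,1]` (diagonal ignored).
#' @return list(adjacency, tom, connectivity).
#' @export
tom_from_adjacency <- function(a) {
  a <- as.matrix(a)
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(a)
  list(adjacency = a, tom = tom, connectivity = k)
}

#' Select genes co-expressed with a seed set
#'
#' A gene is selected when its TOM similarity to at least one seed gene
#' reaches `threshold`; the edge list and per-seed interaction counts
#' (degree, for "top co-expressed" rankings) are returned alongside.
#'
#' @param network a [build_network()] result.
#' @param seed_genes seed gene ids (must all be in the network).
#' @param threshold similarity cutoff (default 0.2, `>=`).
#' @param use either "tom" (default) or "adjacency" as the similarity.
#' @return list(selected gene ids, edges = data.table(seed, gene, similarity)
#'   over gene != seed pairs, seed_degree = data.table(seed, degree)).
#' @export
select_coexpressed <- function(network, seed_genes, threshold = 0.2,
                               use = c("tom", "adjacency")) {
  use <- match.arg(use)
  genes <- network$genes
  bad <- setdiff(seed_genes, genes)
  if (length(bad)) stop("unknown seed gene(s): ", paste(bad, collapse = ","))
  sim <- if (use == "tom") network$tom else network$adjacency
  rownames(sim) <- colnames(sim) <- genes
  s <- sim[seed_genes, , drop = FALSE]
  if (use == "tom") for (g in seed_genes) s[g, g] <- 1 else for (g in seed_genes) s[g, g] <- 0
  selected <- colnames(s)[apply(s, 2, max) >= threshold]
  edges <- data.table::rbindlist(lapply(seed_genes, function(sg) {
    v <- sim[sg, ]
    hit <- names(v)[v >= threshold & names(v) != sg]
    if (!length(hit)) return(NULL)
    data.table::data.table(seed = sg, gene = hit, similarity = v[hit])
  }))
  if (!nrow(edges))
    edges <- data.table::data.table(seed = character(), gene = character(),
                                    similarity = numeric())
  deg <- edges[, .(degree = .N), by = seed]
  missing_seeds <- setdiff(seed_genes, deg$seed)
  if (length(missing_seeds))
    deg <- rbind(deg, data.table::data.table(seed = missing_seeds, degree = 0L))
  data.table::setorder(deg, -degree, seed)
  list(selected = selected, edges = edges[], seed_degree = deg[])
}
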