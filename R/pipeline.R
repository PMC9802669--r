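# Pipeline orchestration: a validated config (YAML round-trip), staged
# subcommands over the module interface files, a JSON run manifest with
# checksums, and stderr logging. Exit-code conventions for the CLI script
# (inst/cli/methexpr-cli.R): 0 ok, 2 config error, 3 missing input,
# 4 runtime failure.

config_error <- function(...) stop(errorCondition(paste0(...), class = "methexpr_config_error"))
missing_input <- function(...) stop(errorCondition(paste0(...), class = "methexpr_missing_input"))

log_msg <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

#' Pipeline configuration
#'
#' Holds input paths and every analysis threshold; defaults are the
#' pipeline's canonical values (coverage >= 4, binomial p < 1e-4, >= 5 DMR
#' sites, level difference > 0.1, Fisher p <= 0.05, fold change >= 2,
#' adjusted p <= 0.001, FPKM filter >= 1, nine clusters, soft power 6,
#' similarity >= 0.2, 1 Mb windows sliding 200 kb) so a bare run applies
#' the standard rules.
#'
#' @param outdir output directory for all stages.
#' @param genome genome FASTA path.
#' @param genes gene models (GFF3 or BED) path.
#' @param meth_sheet TSV (sample_id, path, genotype, stage) locating the
#'   per-sample cytosine reports.
#' @param counts,gene_lengths,sample_sheet expression inputs (TSV).
#' @param annotation optional gene-to-term TSV for enrichment.
#' @param seed_genes optional seed gene ids for co-expression selection.
#' @param focal_genotype focal sample A; defaults to the first genotype of
#'   the sample sheet.
#' @param error_rate bisulfite non-conversion/error rate for the caller.
#' @param min_coverage,mc_p methylcytosine caller thresholds.
#' @param dmr_min_sites,dmr_diff,dmr_p,dmr_window_sites,merge_gap DMR
#'   thresholds.
#' @param fc,deg_adj_p,fpkm_filter DEG thresholds.
#' @param k,beta,tom_threshold clustering / network parameters.
#' @param window,step window geometry in bp.
#' @param max_network_genes cap on network size (most-variable genes kept).
#' @param seed RNG seed for every stochastic stage.
#' @param simulation optional list of [sim_config()] overrides; enables the
#'   `simulate` stage.
#' @return config object (class `methexpr_config`).
#' @export
pipeline_config <- function(outdir = "methexpr_out",
                            genome = NULL, genes = NULL, meth_sheet = NULL,
                            counts = NULL, gene_lengths = NULL,
                            sample_sheet = NULL, annotation = NULL,
                            seed_genes = NULL, focal_genotype = NULL,
                            error_rate = 0.01, min_coverage = 4L, mc_p = 1e-4,
                            dmr_min_sites = 5L, dmr_diff = 0.1, dmr_p = 0.05,
                            dmr_window_sites = 5L, merge_gap = 100L,
                            fc = 2, deg_adj_p = 0.001, fpkm_filter = 1,
                            k = 9L, beta = 6, tom_threshold = 0.2,
                            window = 1e6, step = 2e5,
                            max_network_genes = 2000L, seed = 1L,
                            simulation = NULL) {
  cfg <- as.list(environment())
  chk <- function(ok, what) if (!ok) config_error("invalid config: ", what)
  chk(error_rate >= 0 && error_rate < 1, "error_rate in [0,1)")
  chk(mc_p > 0 && mc_p < 1, "mc_p in (0,1)")
  chk(min_coverage >= 1, "min_coverage >= 1")
  chk(dmr_min_sites >= 1 && dmr_window_sites >= dmr_min_sites ||
        dmr_window_sites >= 1, "dmr window sites >= 1")
  chk(dmr_diff > 0 && dmr_diff < 1, "dmr_diff in (0,1)")
  chk(dmr_p > 0 && dmr_p <= 1, "dmr_p in (0,1]")
  chk(fc >= 1, "fc >= 1")
  chk(deg_adj_p > 0 && deg_adj_p <= 1, "deg_adj_p in (0,1]")
  chk(fpkm_filter >= 0, "fpkm_filter >= 0")
  chk(k >= 1, "k >= 1")
  chk(beta >= 1, "beta >= 1")
  chk(tom_threshold >= 0, "tom_threshold >= 0")
  chk(window > 0 && step > 0 && step <= window, "step <= window, both > 0")
  chk(merge_gap >= 0, "merge_gap >= 0")
  int_fields <- c("min_coverage", "dmr_min_sites", "dmr_window_sites",
                  "merge_gap", "k", "max_network_genes", "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  num_fields <- c("error_rate", "mc_p", "dmr_diff", "dmr_p", "fc", "deg_adj_p",
                  "fpkm_filter", "beta", "tom_threshold", "window", "step")
  for (f in num_fields) cfg[[f]] <- as.numeric(cfg[[f]])
  if (!is.null(cfg$simulation)) cfg$simulation <- lapply(cfg$simulation, identity)
  structure(cfg, class = "methexpr_config")
}

#' Read / write a pipeline config as YAML
#' @param path YAML file path.
#' @return for `read_pipeline_config`, a validated `methexpr_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) missing_input("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) config_error("unknown config field(s): ", paste(bad, collapse = ","))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `methexpr_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

need_file <- function(path, what) {
  if (is.null(path)) missing_input("config does not set the ", what, " input")
  if (!file.exists(path)) missing_input(what, " input not found: ", path,
                                        " (run the producing stage first)")
  path
}

read_meth_sheet <- function(config) {
  p <- need_file(config$meth_sheet, "meth_sheet")
  sheet <- data.table::fread(p)
  stopifnot(all(c("sample_id", "path", "genotype", "stage") %in% names(sheet)))
  sheet
}

read_counts_inputs <- function(config) {
  cdt <- data.table::fread(need_file(config$counts, "counts"))
  counts <- as.matrix(cdt[, -1]); rownames(counts) <- cdt[[1]]
  gl <- data.table::fread(need_file(config$gene_lengths, "gene_lengths"))
  sheet <- data.table::fread(need_file(config$sample_sheet, "sample_sheet"))
  list(counts = counts, gene_lengths = stats::setNames(gl$length, gl$gene_id),
       sample_sheet = sheet)
}

genotype_pair <- function(config, sheet) {
  gts <- unique(sheet$genotype)
  focal <- if (!is.null(config$focal_genotype)) config$focal_genotype else gts[1]
  if (!focal %in% gts) config_error("focal_genotype ", focal, " not in sample sheet")
  c(focal, setdiff(gts, focal)[1])
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Stages read and write only their module's interface files under
#' `config$outdir`; `all` chains them and a JSON manifest (config hash,
#' package version, seed, per-stage row counts, output checksums) is
#' written at the end of every invocation. Progress is logged to stderr.
#'
#' @param name one of simulate, callmc, dmr, deg, cluster, network,
#'   integrate, all.
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @return invisibly, the manifest list.
#' @export
run_subcommand <- function(name = c("simulate", "callmc", "dmr", "deg",
                                    "cluster", "network", "integrate", "all"),
                           config) {
  name <- match.arg(name)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "methexpr_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (name == "all") {
    c(if (!is.null(config$simulation)) "simulate",
      "callmc", "dmr", "deg", "cluster", "network", "integrate")
  } else name
  manifest <- list(package_version = as.character(utils::packageVersion("methexpr")),
                   seed = config$seed, stages = list())
  for (st in stages) {
    log_msg("stage ", st, " started")
    t0 <- proc.time()[["elapsed"]]
    res <- switch(st,
      simulate = stage_simulate(config),
      callmc = stage_callmc(config),
      dmr = stage_dmr(config),
      deg = stage_deg(config),
      cluster = stage_cluster(config),
      network = stage_network(config),
      integrate = stage_integrate(config))
    if (st == "simulate") config <- res$config
    log_msg("stage ", st, " done in ",
            sprintf("%.1fs", proc.time()[["elapsed"]] - t0))
    manifest$stages[[st]] <- res$counts
  }
  cfg_path <- file.path(config$outdir, "config_used.yaml")
  write_pipeline_config(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  outs <- setdiff(list.files(config$outdir, full.names = TRUE),
                  file.path(config$outdir, "manifest.json"))
  outs <- outs[!dir.exists(outs)]
  manifest$checksums <- as.list(tools::md5sum(outs))
  names(manifest$checksums) <- basename(outs)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config) {
  sim_over <- config$simulation
  if (is.null(sim_over$seed)) sim_over$seed <- config$seed
  if (!is.null(sim_over$context_base_levels))
    sim_over$context_base_levels <- unlist(sim_over$context_base_levels)
  if (!is.null(sim_over$gene_length_range))
    sim_over$gene_length_range <- unlist(sim_over$gene_length_range)
  scfg <- do.call(sim_config, sim_over)
  simdir <- file.path(config$outdir, "sim")
  paths <- simulate_dataset(scfg, simdir)
  # meth sheet from the simulated sample naming <genotype>_<stage>_m<rep>
  mpaths <- unlist(paths$methylomes)
  ids <- sub("^meth_(.*)\\.tsv$", "\\1", basename(mpaths))
  parts <- data.table::tstrsplit(ids, "_")
  msheet <- data.table::data.table(sample_id = ids, path = mpaths,
                                   genotype = parts[[1]], stage = parts[[2]])
  msheet_path <- file.path(simdir, "meth_sheet.tsv")
  data.table::fwrite(msheet, msheet_path, sep = "\t")
  config$genome <- paths$genome
  config$genes <- paths$genes_gff3
  config$meth_sheet <- msheet_path
  config$counts <- paths$counts
  config$gene_lengths <- paths$gene_lengths
  config$sample_sheet <- paths$sample_sheet
  config$annotation <- paths$annotation
  list(config = config, counts = list(n_meth_samples = nrow(msheet)))
}

stage_callmc <- function(config) {
  sheet <- read_meth_sheet(config)
  reports <- lapply(sheet$path, function(p) read_cytosine_report(need_file(p, "cytosine report")))
  names(reports) <- sheet$sample_id
  calls <- call_methylcytosines(reports, error_rate = config$error_rate,
                                min_coverage = config$min_coverage,
                                p_threshold = config$mc_p)
  for (sid in names(calls))
    data.table::fwrite(calls[[sid]], file.path(config$outdir, paste0("calls_", sid, ".tsv")),
                       sep = "\t", na = "NA", quote = FALSE)
  list(counts = list(n_sites_tested = nrow(calls[[1]]),
                     n_excluded = attr(calls, "n_excluded")))
}

read_calls <- function(config, sheet) {
  lapply(stats::setNames(sheet$sample_id, sheet$sample_id), function(sid)
    data.table::fread(need_file(file.path(config$outdir, paste0("calls_", sid, ".tsv")),
                                paste0("calls for ", sid)),
                      na.strings = c("NA", "")))
}

stage_dmr <- function(config) {
  sheet <- read_meth_sheet(config)
  calls <- read_calls(config, sheet)
  genes <- read_gene_models(need_file(config$genes, "gene models"))
  clen <- fasta_lengths(need_file(config$genome, "genome"))
  gts <- genotype_pair(config, sheet)
  counts <- list()
  for (stg in unique(sheet$stage)) {
    ids_a <- sheet[genotype == gts[1] & stage == stg, sample_id]
    ids_b <- sheet[genotype == gts[2] & stage == stg, sample_id]
    if (!length(ids_a) || !length(ids_b)) next
    dmrs <- call_dmrs(calls[ids_a], calls[ids_b],
                      min_sites = config$dmr_min_sites,
                      diff_cutoff = config$dmr_diff, p_cutoff = config$dmr_p,
                      window_sites = config$dmr_window_sites,
                      min_coverage = config$min_coverage,
                      max_gap = config$merge_gap)
    loc <- classify_dmr_location(dmrs, genes, clen)
    write_dmrs(loc$dmrs, file.path(config$outdir, paste0("dmrs_", stg, ".tsv")))
    data.table::fwrite(loc$fractions,
                       file.path(config$outdir, paste0("dmr_location_", stg, ".tsv")),
                       sep = "\t")
    counts[[stg]] <- nrow(dmrs)
  }
  list(counts = counts)
}

fasta_lengths <- function(path) chrom_lengths(Biostrings::readDNAStringSet(path))

stage_deg <- function(config) {
  ex <- read_counts_inputs(config)
  gts <- genotype_pair(config, ex$sample_sheet)
  counts <- list()
  for (stg in unique(ex$sample_sheet$stage)) {
    ids_a <- ex$sample_sheet[genotype == gts[1] & stage == stg, sample_id]
    ids_b <- ex$sample_sheet[genotype == gts[2] & stage == stg, sample_id]
    if (!length(ids_a) || !length(ids_b)) next
    degs <- call_degs(ex$counts, ex$gene_lengths, ids_a, ids_b,
                      fc_cutoff = config$fc, adj_p_cutoff = config$deg_adj_p,
                      fpkm_filter = config$fpkm_filter)
    data.table::fwrite(degs, file.path(config$outdir, paste0("degs_", stg, ".tsv")),
                       sep = "\t")
    counts[[stg]] <- sum(degs$is_deg)
  }
  list(counts = counts)
}

stage_cluster <- function(config) {
  ex <- read_counts_inputs(config)
  fpkm <- compute_fpkm(ex$counts, ex$gene_lengths)
  km <- kmeans_cluster(fpkm, k = config$k, seed = config$seed,
                       filter = config$fpkm_filter > 0)
  data.table::fwrite(data.table::data.table(gene_id = names(km$assignment),
                                            cluster = km$assignment),
                     file.path(config$outdir, "clusters.tsv"), sep = "\t")
  ov <- profile_overview(fpkm)
  pca <- data.table::data.table(sample_id = rownames(ov$pca))
  pca <- cbind(pca, data.table::as.data.table(ov$pca))
  data.table::fwrite(pca, file.path(config$outdir, "pca_coordinates.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    component = seq_along(ov$variance_explained),
    variance_explained = ov$variance_explained),
    file.path(config$outdir, "pca_variance.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(order = ov$hclust$order,
                                            sample_id = ov$hclust$labels[ov$hclust$order]),
                     file.path(config$outdir, "sample_dendrogram_order.tsv"), sep = "\t")
  list(counts = list(n_clustered = length(km$assignment)))
}

stage_network <- function(config) {
  ex <- read_counts_inputs(config)
  fpkm <- compute_fpkm(ex$counts, ex$gene_lengths)
  fpkm <- fpkm[apply(fpkm, 1, max) >= config$fpkm_filter, , drop = FALSE]
  if (nrow(fpkm) > config$max_network_genes) {
    v <- apply(log2(fpkm + 1), 1, stats::var)
    fpkm <- fpkm[order(-v)[seq_len(config$max_network_genes)], , drop = FALSE]
    log_msg("network restricted to the ", config$max_network_genes,
            " most variable genes")
  }
  net <- suppressWarnings(build_network(fpkm, beta = config$beta))
  saved_edges <- which(net$tom >= config$tom_threshold & upper.tri(net$tom),
                       arr.ind = TRUE)
  edges <- data.table::data.table(gene_a = net$genes[saved_edges[, 1]],
                                  gene_b = net$genes[saved_edges[, 2]],
                                  tom = net$tom[saved_edges])
  data.table::setorder(edges, gene_a, gene_b)
  data.table::fwrite(edges, file.path(config$outdir, "network_edges.tsv"), sep = "\t")
  if (!is.null(config$seed_genes)) {
    sel <- select_coexpressed(net, intersect(config$seed_genes, net$genes),
                              threshold = config$tom_threshold)
    data.table::fwrite(data.table::data.table(gene_id = sel$selected),
                       file.path(config$outdir, "coexpressed_selection.tsv"), sep = "\t")
  }
  list(counts = list(n_network_genes = length(net$genes), n_edges = nrow(edges)))
}

stage_integrate <- function(config) {
  sheet <- read_meth_sheet(config)
  calls <- read_calls(config, sheet)
  genes <- read_gene_models(need_file(config$genes, "gene models"))
  clen <- fasta_lengths(need_file(config$genome, "genome"))
  ex <- read_counts_inputs(config)
  fpkm <- compute_fpkm(ex$counts, ex$gene_lengths)
  gts <- genotype_pair(config, ex$sample_sheet)
  enrich <- list(); cts <- list()
  crosstabs <- list()
  for (stg in unique(sheet$stage)) {
    dpath <- need_file(file.path(config$outdir, paste0("dmrs_", stg, ".tsv")),
                       paste0("DMR table for stage ", stg))
    dmrs <- data.table::fread(dpath)
    dmrs[, start := start + 1L]  # back to 1-based inclusive
    degs <- data.table::fread(need_file(file.path(config$outdir, paste0("degs_", stg, ".tsv")),
                                        paste0("DEG table for stage ", stg)))
    assoc <- associate_dmrs(dmrs, genes, clen)
    data.table::fwrite(assoc$pairs,
                       file.path(config$outdir, paste0("dmr_gene_pairs_", stg, ".tsv")),
                       sep = "\t")
    N <- nrow(genes)
    n_deg <- sum(degs$is_deg)
    K <- length(assoc$genes)
    k <- length(intersect(assoc$genes, degs[is_deg == TRUE, gene_id]))
    enrich[[stg]] <- if (K > 0 && n_deg > 0)
      c(list(stage = stg, N = N, K = K, n = n_deg, k = k),
        deg_dmr_enrichment(N, K, n_deg, k)) else
      list(stage = stg, N = N, K = K, n = n_deg, k = k)
    ct <- hyper_hypo_crosstab(dmrs, degs, assoc$pairs)
    ct[, stage := stg]
    crosstabs[[stg]] <- ct
    cts[[stg]] <- list(n_assoc_genes = K, n_assoc_degs = k)
  }
  data.table::fwrite(data.table::rbindlist(crosstabs, fill = TRUE),
                     file.path(config$outdir, "hyper_hypo_crosstab.tsv"), sep = "\t")
  jsonlite::write_json(enrich, file.path(config$outdir, "deg_dmr_enrichment.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  # windowed methylation-expression correlation per methylome sample
  corr <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    mw <- summarize_methylome(calls[[sid]], clen, config$window, config$step)$windows
    ids <- ex$sample_sheet[genotype == sheet$genotype[i] & stage == sheet$stage[i],
                           sample_id]
    if (!length(ids)) next
    fv <- rowMeans(fpkm[, ids, drop = FALSE])
    ew <- window_expression_track(fv, genes, clen, config$window, config$step)
    r <- methylation_expression_correlation(mw, ew)
    corr[[sid]] <- c(list(sample_id = sid), r)
  }
  data.table::fwrite(data.table::rbindlist(corr),
                     file.path(config$outdir, "window_correlation.tsv"), sep = "\t")
  if (!is.null(config$annotation)) {
    ann <- data.table::fread(need_file(config$annotation, "annotation"))
    data.table::setnames(ann, seq_len(2L), c("gene_id", "term_id"))
    all_degs <- unique(unlist(lapply(unique(sheet$stage), function(stg) {
      d <- data.table::fread(file.path(config$outdir, paste0("degs_", stg, ".tsv")))
      d[is_deg == TRUE, gene_id]
    })))
    if (length(all_degs)) {
      te <- term_enrichment(all_degs, ann)
      data.table::fwrite(te, file.path(config$outdir, "deg_term_enrichment.tsv"),
                         sep = "\t")
    }
  }
  list(counts = cts)
}
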