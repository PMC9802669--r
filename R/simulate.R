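# Synthetic-data generator: genomes, gene models, per-cytosine methylomes
# and RNA-seq count matrices for a two-genotype x two-stage design, with
# planted DMRs, DEGs, co-expression modules and promoter-methylation /
# expression anti-correlation recorded in truth tables. Every downstream
# stage of the pipeline can therefore be scored against known truth.
#
# All randomness flows from config$seed; each emitted methylome file uses
# its own counter-derived stream so files are individually reproducible.

#' Simulation configuration
#'
#' Defaults describe the emulated study design: a wild ("W245") and a
#' cultivated ("Z16") genotype sampled at two seed stages (R5, R8) with
#' three RNA-seq replicates, plant-typical context methylation baselines,
#' and planted effects chosen to be detectable by the pipeline's own rules
#' (DMR effect 0.4 > the 0.1 call cutoff; DEG fold 4 >= the 2x cutoff).
#'
#' @param seed integer RNG seed; every output derives from it.
#' @param n_chromosomes,chrom_length genome shape (uniform chromosome size, bp).
#' @param n_genes,gene_length_range non-overlapping gene count and length (bp).
#' @param n_replicates RNA-seq replicates per genotype x stage group.
#' @param meth_replicates bisulfite samples per genotype x stage group.
#' @param coverage_mean mean reads per cytosine (Poisson).
#' @param bisulfite_error non-conversion/error rate in `[0,1)`; the binomial
#'   caller's null probability.
#' @param context_base_levels named baseline methylation levels for CG, CHG, CHH.
#' @param n_planted_dmrs planted DMRs per context (an equal number of matched
#'   null regions is also recorded).
#' @param dmr_sites same-context cytosines per planted DMR (>= 5 so truth is
#'   detectable by the >= 5-site rule).
#' @param dmr_effect absolute methylation-level shift of planted DMRs (> 0.1).
#' @param n_planted_degs,deg_fold_change planted DEG count and fold (>= 2).
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param anticorrelation_fraction fraction of genes whose promoter
#'   methylation and expression are shifted in opposite directions between
#'   genotypes.
#' @param n_modules,module_size planted co-expression modules.
#' @param module_factor_sd sd of the shared latent log-factor within a module.
#' @param landscape_amplitude,landscape_cycles amplitude and per-chromosome
#'   period count of the sinusoidal methylation landscape shared by both
#'   genotypes (heterochromatin-like domains).
#' @param landscape_slope damping of baseline expression with the local
#'   landscape value (mu is scaled by exp(-slope * landscape at the gene
#'   midpoint)); this plants the genome-scale windowed
#'   methylation-expression anti-correlation.
#' @param base_expression_meanlog,base_expression_sdlog lognormal baseline
#'   mean counts per gene.
#' @param libsize_factor_sd lognormal sd of per-sample library-size factors.
#' @param genotypes,stages group labels; the first genotype is the focal
#'   (wild) sample in which planted shifts are applied.
#' @return validated config object (class `methexpr_sim_config`).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 2e6,
                       n_genes = 400L,
                       gene_length_range = c(1000L, 5000L),
                       n_replicates = 3L,
                       meth_replicates = 3L,
                       coverage_mean = 30,
                       bisulfite_error = 0.01,
                       context_base_levels = c(CG = 0.70, CHG = 0.35, CHH = 0.08),
                       n_planted_dmrs = 100L,
                       dmr_sites = 8L,
                       dmr_effect = 0.4,
                       n_planted_degs = 40L,
                       deg_fold_change = 4,
                       nb_dispersion = 0.05,
                       anticorrelation_fraction = 0.2,
                       n_modules = 5L,
                       module_size = 25L,
                       module_factor_sd = 0.6,
                       landscape_amplitude = 0.15,
                       landscape_cycles = 2,
                       landscape_slope = 6,
                       base_expression_meanlog = log(100),
                       base_expression_sdlog = 1,
                       libsize_factor_sd = 0.05,
                       genotypes = c("W245", "Z16"),
                       stages = c("R5", "R8")) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$genotypes) == 2L, length(cfg$stages) >= 1L)
  if (cfg$bisulfite_error < 0 || cfg$bisulfite_error >= 1)
    stop("bisulfite_error must be in [0, 1)")
  if (any(cfg$context_base_levels < 0) || any(cfg$context_base_levels > 1))
    stop("context_base_levels must be in [0, 1]")
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$context_base_levels)))
    stop("context_base_levels needs CG, CHG and CHH entries")
  if (cfg$dmr_effect <= 0.1 || cfg$dmr_effect > 1)
    stop("dmr_effect must be in (0.1, 1] so planted DMRs clear the 0.1 call cutoff")
  if (cfg$n_planted_degs > 0 && cfg$deg_fold_change < 2)
    stop("deg_fold_change must be >= 2 for planted DEGs to be detectable")
  if (cfg$dmr_sites < 5L)
    stop("dmr_sites must be >= 5 (the DMR caller's minimum site rule)")
  if (cfg$anticorrelation_fraction < 0 || cfg$anticorrelation_fraction > 1)
    stop("anticorrelation_fraction must be in [0, 1]")
  if (cfg$coverage_mean < 0 || cfg$nb_dispersion < 0)
    stop("coverage_mean and nb_dispersion must be non-negative")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "methexpr_sim_config")
}

# derived stream seed per output unit, kept inside 32-bit range
stream_seed <- function(seed, index) as.integer((as.numeric(seed) + 7919 * index) %% 2147483647)

#' Simulate a genome and non-overlapping gene models
#'
#' Chromosomes are uniform-random A/C/G/T; genes are placed without overlap
#' with random strands, deterministically for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list(genome = DNAStringSet, genes = data.table(gene_id, chrom,
#'   start, end, strand, length)).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "methexpr_sim_config"))
  set.seed(stream_seed(config$seed, 1L))
  nchr <- config$n_chromosomes
  len <- as.integer(config$chrom_length)
  chroms <- sprintf("chr%d", seq_len(nchr))
  bases <- charToRaw("ACGT")
  seqs <- vapply(chroms, function(ch)
    rawToChar(bases[sample.int(4L, len, replace = TRUE)]), character(1))
  genome <- Biostrings::DNAStringSet(seqs)

  n_genes <- as.integer(config$n_genes)
  per_chr <- diff(floor(seq(0, n_genes, length.out = nchr + 1L)))
  glist <- vector("list", nchr)
  for (i in seq_len(nchr)) {
    k <- per_chr[i]
    if (k == 0L) next
    lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]), k,
                   replace = TRUE)
    free <- len - sum(lens)
    if (free < 0)
      stop("cannot place ", k, " non-overlapping genes of total length ",
           sum(lens), " on a chromosome of ", len, " bp")
    off <- sort(sample.int(free + 1L, k, replace = TRUE)) - 1L
    starts <- off + c(0L, cumsum(lens)[-k]) + 1L
    glist[[i]] <- data.table::data.table(
      chrom = chroms[i], start = starts, end = starts + lens - 1L,
      strand = sample(c("+", "-"), k, replace = TRUE), length = lens)
  }
  genes <- data.table::rbindlist(glist)
  if (nrow(genes)) {
    data.table::setorder(genes, chrom, start)
    genes[, gene_id := sprintf("G%05d", .I)]
    data.table::setcolorder(genes, c("gene_id", "chrom", "start", "end", "strand", "length"))
  } else {
    genes <- data.table::data.table(gene_id = character(), chrom = character(),
                                    start = integer(), end = integer(),
                                    strand = character(), length = integer())
  }
  list(genome = genome, genes = genes[])
}

# landscape value at positions (vectorised); phases per chromosome from truth
landscape_at <- function(truth, chrom, pos) {
  ls <- truth$landscape
  i <- match(chrom, ls$chrom)
  ls$amplitude[i] * sin(2 * pi * pos / ls$chrom_length[i] * ls$cycles[i] + ls$phase[i])
}

#' Plant the ground truth for a simulated dataset
#'
#' Chooses planted DMR intervals (runs of `dmr_sites` consecutive
#' same-context cytosines) plus matched null regions, anticorrelated genes
#' (promoter methylation up & expression down in the focal genotype, or the
#' reverse), planted DEGs, co-expression module assignments, per-gene
#' baseline expression, and the per-chromosome methylation landscape.
#'
#' @param config a [sim_config()].
#' @param genome DNAStringSet, or NULL for an expression-only truth (no
#'   planted DMR intervals).
#' @param genes gene-model data.table.
#' @return truth object (class `methexpr_truth`): planted_dmrs (kind =
#'   planted/null), anticorrelated, planted_degs, modules, base_mean,
#'   landscape.
#' @export
plant_truth <- function(config, genome, genes) {
  stopifnot(inherits(config, "methexpr_sim_config"))
  set.seed(stream_seed(config$seed, 2L))
  chroms <- if (!is.null(genome)) names(as_dss(genome)) else unique(genes$chrom)
  landscape <- data.table::data.table(
    chrom = chroms,
    chrom_length = as.numeric(config$chrom_length),
    amplitude = config$landscape_amplitude,
    cycles = config$landscape_cycles,
    phase = stats::runif(length(chroms), 0, 2 * pi))

  # anticorrelated genes: promoter methylation and expression move oppositely
  n_ac <- round(config$anticorrelation_fraction * nrow(genes))
  ac_ids <- if (n_ac > 0) sample(genes$gene_id, n_ac) else character()
  anticorrelated <- data.table::data.table(
    gene_id = ac_ids,
    direction = rep(c("hyper_down", "hypo_up"), length.out = n_ac))

  # planted DMRs + matched null regions, avoiding anticorrelated promoters
  planted <- data.table::data.table(
    truth_id = character(), chrom = character(), start = integer(),
    end = integer(), context = character(), direction = character(),
    n_sites = integer(), kind = character())
  if (!is.null(genome) && config$n_planted_dmrs > 0) {
    sites <- enumerate_cytosines(genome)
    clen <- chrom_lengths(genome)
    avoid <- if (nrow(anticorrelated)) {
      reg <- gene_regions(genes[gene_id %in% ac_ids], clen)
      reg[, .(chrom, start, end)]
    } else data.table::data.table(chrom = character(), start = integer(), end = integer())
    planted <- place_truth_regions(sites, config, avoid)
  }

  # baseline expression and planted DEGs on safely-expressed genes
  base_mean <- data.table::data.table(
    gene_id = genes$gene_id,
    base_mean = stats::rlnorm(nrow(genes), config$base_expression_meanlog,
                              config$base_expression_sdlog))
  eligible <- setdiff(base_mean[base_mean >= 20, gene_id], ac_ids)
  n_deg <- min(config$n_planted_degs, length(eligible))
  if (n_deg < config$n_planted_degs)
    warning("only ", n_deg, " genes eligible for planted DEGs")
  deg_ids <- if (n_deg > 0) sample(eligible, n_deg) else character()
  planted_degs <- data.table::data.table(
    gene_id = deg_ids,
    stage = if (n_deg) sample(config$stages, n_deg, replace = TRUE) else character(),
    direction = rep(c("up", "down"), length.out = n_deg),
    fold = rep(config$deg_fold_change, n_deg))

  # co-expression modules on the remaining genes
  pool <- setdiff(genes$gene_id, c(ac_ids, deg_ids))
  n_mod_genes <- min(config$n_modules * config$module_size, length(pool))
  mod_ids <- if (n_mod_genes > 0) sample(pool, n_mod_genes) else character()
  modules <- data.table::data.table(
    gene_id = mod_ids,
    module = if (n_mod_genes) rep(seq_len(config$n_modules),
                                  length.out = n_mod_genes) else integer())
  data.table::setorder(modules, module, gene_id)

  structure(list(planted_dmrs = planted, anticorrelated = anticorrelated,
                 planted_degs = planted_degs, modules = modules,
                 base_mean = base_mean, landscape = landscape),
            class = "methexpr_truth")
}

# choose non-overlapping runs of dmr_sites consecutive same-context sites;
# 2x n_planted_dmrs per context (planted + matched null), padded 300 bp apart
place_truth_regions <- function(sites, config, avoid, max_width = 1500L, pad = 300L) {
  k <- config$dmr_sites
  need_per_ctx <- 2L * config$n_planted_dmrs
  out <- list()
  acc_chrom <- character(); acc_start <- numeric(); acc_end <- numeric()
  if (nrow(avoid)) {
    acc_chrom <- avoid$chrom; acc_start <- avoid$start; acc_end <- avoid$end
  }
  for (ctx in c("CG", "CHG", "CHH")) {
    cs <- sites[context %in% ctx]
    data.table::setorder(cs, chrom, pos)
    n <- nrow(cs)
    if (n < k) stop("fewer than ", k, " ", ctx, " sites in the genome")
    i2 <- seq_len(n - k + 1L)
    same <- cs$chrom[i2] == cs$chrom[i2 + k - 1L]
    width_ok <- (cs$pos[i2 + k - 1L] - cs$pos[i2]) <= max_width
    cand <- i2[same & width_ok]
    cand <- sample(cand)
    got <- 0L
    rows <- vector("list", need_per_ctx)
    for (ci in cand) {
      s <- cs$pos[ci]; e <- cs$pos[ci + k - 1L]; ch <- cs$chrom[ci]
      hit <- acc_chrom == ch & acc_start <= e + pad & acc_end >= s - pad
      if (any(hit)) next
      got <- got + 1L
      rows[[got]] <- list(chrom = ch, start = s, end = e)
      acc_chrom <- c(acc_chrom, ch); acc_start <- c(acc_start, s); acc_end <- c(acc_end, e)
      if (got == need_per_ctx) break
    }
    if (got < need_per_ctx)
      stop("could not place ", need_per_ctx, " disjoint ", k, "-site ", ctx,
           " regions; enlarge the genome or reduce n_planted_dmrs")
    dt <- data.table::rbindlist(rows)
    dt[, context := ctx]
    dt[, n_sites := k]
    dt[, kind := rep(c("planted", "null"), each = config$n_planted_dmrs)]
    dt[, direction := ifelse(kind == "planted",
                             rep(c("hyper", "hypo"), length.out = .N), NA_character_)]
    out[[ctx]] <- dt
  }
  res <- data.table::rbindlist(out)
  res[, truth_id := sprintf("%s_%s_%03d", kind, context, seq_len(.N)), by = .(kind, context)]
  data.table::setcolorder(res, c("truth_id", "chrom", "start", "end", "context",
                                 "direction", "n_sites", "kind"))
  data.table::setorder(res, chrom, start)
  res[]
}

# true methylation level per site for one genotype: context baseline +
# landscape (zeroed inside truth regions so the planted effect is exact),
# +/- dmr_effect in planted DMRs and anticorrelated promoters of the focal
# genotype, clamped to [0, 1]
true_levels <- function(config, sites, truth, genes, genotype) {
  base <- config$context_base_levels
  lev <- ifelse(is.na(sites$context), 0, base[sites$context])
  lev <- lev + landscape_at(truth, sites$chrom, sites$pos)
  td <- truth$planted_dmrs
  if (nrow(td)) {
    inreg <- overlap_flag(sites, td)
    # remove the landscape inside planted and matched-null intervals
    lev[inreg] <- ifelse(is.na(sites$context[inreg]), 0, base[sites$context[inreg]])
  }
  if (genotype == config$genotypes[1]) {
    if (nrow(td)) {
      pl <- td[kind == "planted"]
      for (dir in c("hyper", "hypo")) {
        sel <- pl[direction == dir]
        if (!nrow(sel)) next
        hit <- overlap_flag_ctx(sites, sel)  # context-matched shift only
        lev[hit] <- lev[hit] + ifelse(dir == "hyper", config$dmr_effect, -config$dmr_effect)
      }
    }
    ac <- truth$anticorrelated
    if (nrow(ac)) {
      clen <- stats::setNames(rep(as.numeric(config$chrom_length),
                                  nrow(truth$landscape)), truth$landscape$chrom)
      reg <- gene_regions(genes[gene_id %in% ac$gene_id], clen)
      reg <- reg[part == "upstream"]
      reg <- merge(reg, ac, by = "gene_id")
      for (dir in c("hyper_down", "hypo_up")) {
        sel <- reg[direction == dir]
        if (!nrow(sel)) next
        hit <- overlap_flag(sites, sel)
        lev[hit] <- lev[hit] + ifelse(dir == "hyper_down", config$dmr_effect,
                                      -config$dmr_effect)
      }
    }
  }
  pmin(pmax(lev, 0), 1)
}

# logical: site falls inside any interval of `regions` (chrom, start, end)
overlap_flag <- function(sites, regions) {
  if (!nrow(regions)) return(rep(FALSE, nrow(sites)))
  q <- data.table::data.table(chrom = sites$chrom, start = sites$pos, end = sites$pos)
  r <- data.table::data.table(chrom = regions$chrom,
                              start = as.integer(regions$start),
                              end = as.integer(regions$end))
  data.table::setkey(r, chrom, start, end)
  ov <- data.table::foverlaps(q, r, type = "within", which = TRUE, nomatch = NULL)
  flag <- rep(FALSE, nrow(sites))
  flag[unique(ov$xid)] <- TRUE
  flag
}

# as overlap_flag but requiring the site context to match the region context
overlap_flag_ctx <- function(sites, regions) {
  flag <- rep(FALSE, nrow(sites))
  for (ctx in unique(regions$context)) {
    f <- overlap_flag(sites, regions[context == ctx])
    flag <- flag | (f & !is.na(sites$context) & sites$context == ctx)
  }
  flag
}

#' Simulate per-sample cytosine methylation reports
#'
#' Every genomic cytosine (both strands) receives a true level from the
#' context baseline, the shared landscape, and the genotype-specific planted
#' shifts; observed counts are drawn as n ~ Poisson(coverage_mean) and
#' methylated ~ Binomial(n, level + bisulfite_error * (1 - level)). The
#' emitted context column is the one recomputed from the genome.
#'
#' @param config a [sim_config()].
#' @param genome DNAStringSet from [simulate_genome()].
#' @param genes gene-model data.table.
#' @param truth a [plant_truth()] object.
#' @param outdir if non-NULL, one TSV per sample is written there
#'   (`meth_<sample>.tsv`) and paths are returned; otherwise a named list of
#'   data.tables.
#' @return named list of data.tables (chrom, pos, strand, m, u, context) or
#'   of file paths.
#' @export
simulate_methylomes <- function(config, genome, genes, truth, outdir = NULL) {
  stopifnot(inherits(config, "methexpr_sim_config"), inherits(truth, "methexpr_truth"))
  sites <- enumerate_cytosines(genome)
  levs <- lapply(config$genotypes, function(g) true_levels(config, sites, truth, genes, g))
  names(levs) <- config$genotypes
  samples <- expand.grid(replicate = seq_len(config$meth_replicates),
                         stage = config$stages, genotype = config$genotypes,
                         stringsAsFactors = FALSE)
  out <- vector("list", nrow(samples))
  names(out) <- sprintf("%s_%s_m%d", samples$genotype, samples$stage, samples$replicate)
  for (i in seq_len(nrow(samples))) {
    set.seed(stream_seed(config$seed, 100L + i))
    lev <- levs[[samples$genotype[i]]]
    p_obs <- lev + config$bisulfite_error * (1 - lev)
    n <- stats::rpois(nrow(sites), config$coverage_mean)
    m <- stats::rbinom(nrow(sites), n, p_obs)
    dt <- data.table::data.table(chrom = sites$chrom, pos = sites$pos,
                                 strand = sites$strand, m = m, u = n - m,
                                 context = sites$context)
    if (is.null(outdir)) {
      out[[i]] <- dt
    } else {
      path <- file.path(outdir, paste0("meth_", names(out)[i], ".tsv"))
      write_cytosine_report(dt, path)
      out[[i]] <- path
    }
  }
  out
}

#' Simulate an RNA-seq count matrix with planted structure
#'
#' Counts are negative binomial around a per-gene baseline damped by the
#' methylation landscape at the gene midpoint (the planted genome-scale
#' anti-correlation); planted DEGs and anticorrelated genes receive their
#' fold between genotypes in the focal genotype's columns; module genes
#' share a per-sample latent log-factor.
#'
#' @param config a [sim_config()].
#' @param genes gene-model data.table (ids and lengths are used; positions
#'   only for the landscape damping).
#' @param truth a [plant_truth()] object.
#' @param outdir if non-NULL, writes counts.tsv, gene_lengths.tsv and
#'   sample_sheet.tsv there.
#' @return list(counts = integer matrix genes x samples, gene_lengths named
#'   vector, sample_sheet data.table), plus `paths` when written.
#' @export
simulate_expression <- function(config, genes, truth, outdir = NULL) {
  stopifnot(inherits(config, "methexpr_sim_config"), inherits(truth, "methexpr_truth"))
  set.seed(stream_seed(config$seed, 3L))
  sheet <- expand.grid(replicate = seq_len(config$n_replicates),
                       stage = config$stages, genotype = config$genotypes,
                       stringsAsFactors = FALSE)
  sheet <- data.table::as.data.table(sheet)[, .(sample_id = sprintf("%s_%s_r%d", genotype, stage, replicate),
                                               genotype, stage, replicate)]
  ns <- nrow(sheet)
  ng <- nrow(genes)
  bm <- truth$base_mean[match(genes$gene_id, gene_id), base_mean]
  mid <- (genes$start + genes$end) / 2
  damp <- exp(-config$landscape_slope * landscape_at(truth, genes$chrom, mid))
  mu <- matrix(bm * damp, nrow = ng, ncol = ns,
               dimnames = list(genes$gene_id, sheet$sample_id))
  focal <- sheet$genotype == config$genotypes[1]
  ac <- truth$anticorrelated
  if (nrow(ac)) {
    f <- config$deg_fold_change
    i_dn <- match(ac[direction == "hyper_down", gene_id], genes$gene_id)
    i_up <- match(ac[direction == "hypo_up", gene_id], genes$gene_id)
    mu[i_dn, focal] <- mu[i_dn, focal] / f
    mu[i_up, focal] <- mu[i_up, focal] * f
  }
  pd <- truth$planted_degs
  if (nrow(pd)) {
    for (j in seq_len(nrow(pd))) {
      gi <- match(pd$gene_id[j], genes$gene_id)
      cols <- focal & sheet$stage == pd$stage[j]
      mu[gi, cols] <- mu[gi, cols] *
        if (pd$direction[j] == "up") pd$fold[j] else 1 / pd$fold[j]
    }
  }
  md <- truth$modules
  if (nrow(md)) {
    fac <- matrix(stats::rnorm(config$n_modules * ns, 0, config$module_factor_sd),
                  nrow = config$n_modules)
    gi <- match(md$gene_id, genes$gene_id)
    mu[gi, ] <- mu[gi, ] * exp(fac[md$module, , drop = FALSE])
  }
  lib <- stats::rlnorm(ns, 0, config$libsize_factor_sd)
  mu <- sweep(mu, 2, lib, `*`)
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu, size = 1 / max(config$nb_dispersion, 1e-8)),
                   nrow = ng, dimnames = dimnames(mu))
  gene_lengths <- stats::setNames(genes$length, genes$gene_id)
  res <- list(counts = counts, gene_lengths = gene_lengths, sample_sheet = sheet)
  if (!is.null(outdir)) {
    cdt <- data.table::data.table(gene_id = rownames(counts))
    cdt <- cbind(cdt, data.table::as.data.table(counts))
    paths <- c(counts = file.path(outdir, "counts.tsv"),
               gene_lengths = file.path(outdir, "gene_lengths.tsv"),
               sample_sheet = file.path(outdir, "sample_sheet.tsv"))
    data.table::fwrite(cdt, paths["counts"], sep = "\t")
    data.table::fwrite(data.table::data.table(gene_id = names(gene_lengths),
                                              length = gene_lengths),
                       paths["gene_lengths"], sep = "\t")
    data.table::fwrite(sheet, paths["sample_sheet"], sep = "\t")
    res$paths <- paths
  }
  res
}

#' Simulate a gene-to-term annotation table
#'
#' Each planted co-expression module becomes one term (MOD<k>); additional
#' random terms of 5-50 genes provide a null background for enrichment.
#'
#' @param config a [sim_config()].
#' @param genes gene-model data.table.
#' @param truth a [plant_truth()] object.
#' @param n_random_terms number of random background terms.
#' @return data.table(gene_id, term_id).
#' @export
simulate_annotation <- function(config, genes, truth, n_random_terms = 20L) {
  set.seed(stream_seed(config$seed, 4L))
  parts <- list()
  if (nrow(truth$modules))
    parts$mod <- truth$modules[, .(gene_id, term_id = sprintf("MOD%d", module))]
  rnd <- lapply(seq_len(n_random_terms), function(i) {
    sz <- sample(5:50, 1)
    data.table::data.table(gene_id = sample(genes$gene_id, min(sz, nrow(genes))),
                           term_id = sprintf("T%03d", i))
  })
  out <- data.table::rbindlist(c(parts, rnd))
  data.table::setorder(out, term_id, gene_id)
  unique(out)
}

#' Simulate and write a complete dataset
#'
#' Orchestrates [simulate_genome()], [plant_truth()],
#' [simulate_methylomes()], [simulate_expression()] and
#' [simulate_annotation()], writing genome FASTA, GFF3/BED gene models,
#' per-sample cytosine reports, count matrices, sample sheet, annotation and
#' truth tables under `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return named list of file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gg <- simulate_genome(config)
  truth <- plant_truth(config, gg$genome, gg$genes)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                genes_gff3 = file.path(outdir, "genes.gff3"),
                genes_bed = file.path(outdir, "genes.bed"))
  Biostrings::writeXStringSet(gg$genome, paths$genome)
  write_gene_models(gg$genes, gff3 = paths$genes_gff3, bed = paths$genes_bed)
  meth <- simulate_methylomes(config, gg$genome, gg$genes, truth, outdir = outdir)
  paths$methylomes <- unlist(meth)
  expr <- simulate_expression(config, gg$genes, truth, outdir = outdir)
  paths <- c(paths, as.list(expr$paths))
  ann <- simulate_annotation(config, gg$genes, truth)
  paths$annotation <- file.path(outdir, "annotation.tsv")
  data.table::fwrite(ann, paths$annotation, sep = "\t")
  for (tab in c("planted_dmrs", "anticorrelated", "planted_degs", "modules",
                "base_mean", "landscape")) {
    p <- file.path(outdir, paste0("truth_", tab, ".tsv"))
    data.table::fwrite(truth[[tab]], p, sep = "\t")
    paths[[paste0("truth_", tab)]] <- p
  }
  lapply(paths, unname)
}
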