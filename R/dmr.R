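# Differentially methylated region (DMR) detection between two samples.
#
# Candidate windows are runs of `window_sites` consecutive shared
# same-context cytosines (step one site); a window passes when the pooled
# level difference exceeds `diff_cutoff` (strict) AND the two-sided Fisher
# exact p on the pooled 2x2 read-count table is <= `p_cutoff`. Overlapping
# passing windows on one site run are collapsed into a single candidate;
# nearby candidates are then joined when the full spanning region passes
# the same two criteria ("interdependent" DMRs), repeated to a fixed point.

#' Pool replicate call tables into one sample
#'
#' Sums methylated/unmethylated read counts by (chrom, pos, strand),
#' keeping the context column. Used to pool biological replicates per group
#' before the two-sample comparison.
#'
#' @param samples a call/report data.table or list of them.
#' @return data.table(chrom, pos, strand, context, m, u, n).
#' @export
pool_calls <- function(samples) {
  if (data.table::is.data.table(samples) || is.data.frame(samples))
    samples <- list(samples)
  dt <- data.table::rbindlist(lapply(samples, function(s)
    data.table::as.data.table(s)[, .(chrom, pos, strand, context, m, u)]))
  out <- dt[, .(m = sum(m), u = sum(u), context = context[1]),
            by = .(chrom, pos, strand)]
  out[, n := m + u]
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

# shared covered same-context sites between two pooled samples
shared_context_sites <- function(pooled_a, pooled_b, ctx, min_coverage = 4L) {
  a <- pooled_a[context %in% ctx, .(chrom, pos, strand, context, m_a = m, n_a = n)]
  b <- pooled_b[context %in% ctx, .(chrom, pos, strand, m_b = m, n_b = n)]
  s <- merge(a, b, by = c("chrom", "pos", "strand"))
  s <- s[n_a >= min_coverage & n_b >= min_coverage]
  data.table::setorder(s, chrom, pos, strand)
  s[]
}

# pooled stats over a site index range, from per-chromosome cumsums
span_stats_cum <- function(cum, i1, i2) {
  csum <- function(cs) cs[i2] - if (i1 > 1L) cs[i1 - 1L] else 0
  ma <- csum(cum$cma); na <- csum(cum$cna)
  mb <- csum(cum$cmb); nb <- csum(cum$cnb)
  la <- ma / na; lb <- mb / nb
  list(n_sites = i2 - i1 + 1L, m_a = ma, n_a = na, m_b = mb, n_b = nb,
       level_a = la, level_b = lb, diff = la - lb,
       p_value = fisher_test_2x2(ma, na - ma, mb, nb - mb))
}

#' Scan for DMR candidates between two samples in one context
#'
#' @param calls_a,calls_b call/report tables (replicates pooled; see
#'   [pool_calls()]) for the focal sample A and comparator B.
#' @param context one of "CG", "CHG", "CHH".
#' @param min_sites minimum shared context sites required genome-wide
#'   (scan warns and returns empty below this).
#' @param diff_cutoff pooled level difference threshold, strict `>` (0.1).
#' @param p_cutoff two-sided Fisher exact p threshold, `<=` (0.05).
#' @param window_sites consecutive shared sites per window (5, step 1 site).
#' @param min_coverage per-site coverage floor applied to both samples (4).
#' @return data.table of candidates: chrom, start, end, context, n_sites,
#'   pooled counts, level_a, level_b, diff, p_value (1-based inclusive
#'   interval spanning first to last member site).
#' @export
scan_dmr_candidates <- function(calls_a, calls_b, context,
                                min_sites = 5L, diff_cutoff = 0.1,
                                p_cutoff = 0.05, window_sites = 5L,
                                min_coverage = 4L) {
  a <- pool_calls(calls_a); b <- pool_calls(calls_b)
  sites <- shared_context_sites(a, b, context, min_coverage)
  if (nrow(sites) < min_sites) {
    warning("fewer than ", min_sites, " shared ", context, " sites; empty scan")
    return(empty_candidates())
  }
  scan_sites(sites, context, diff_cutoff, p_cutoff, window_sites)
}

empty_candidates <- function() {
  data.table::data.table(chrom = character(), start = integer(), end = integer(),
                         context = character(), n_sites = integer(),
                         m_a = numeric(), n_a = numeric(), m_b = numeric(),
                         n_b = numeric(), level_a = numeric(), level_b = numeric(),
                         diff = numeric(), p_value = numeric())
}

# windowed scan over a shared-site table (single context, all chromosomes)
scan_sites <- function(sites, context, diff_cutoff, p_cutoff, window_sites) {
  w <- as.integer(window_sites)
  res <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[chrom == ch]
    n <- nrow(s)
    if (n < w) next
    cum <- list(cma = cumsum(s$m_a), cna = cumsum(s$n_a),
                cmb = cumsum(s$m_b), cnb = cumsum(s$n_b))
    i <- seq_len(n - w + 1L)
    wsum <- function(cs) cs[i + w - 1L] - c(0, cs)[i]
    ma <- wsum(cum$cma); na <- wsum(cum$cna)
    mb <- wsum(cum$cmb); nb <- wsum(cum$cnb)
    diff <- ma / na - mb / nb
    pass1 <- which(is.finite(diff) & abs(diff) > diff_cutoff)
    if (!length(pass1)) next
    p <- fisher_test_2x2(ma[pass1], na[pass1] - ma[pass1],
                         mb[pass1], nb[pass1] - mb[pass1])
    ws <- pass1[p <= p_cutoff]
    if (!length(ws)) next
    # greedily union overlapping passing windows, validating each union
    cands <- vector("list", length(ws))
    nc <- 0L
    lo <- ws[1]; hi <- ws[1] + w - 1L
    cur <- span_stats_cum(cum, lo, hi)
    for (j in ws[-1]) {
      if (j <= hi) {
        st2 <- span_stats_cum(cum, lo, max(hi, j + w - 1L))
        if (abs(st2$diff) > diff_cutoff && st2$p_value <= p_cutoff) {
          hi <- max(hi, j + w - 1L); cur <- st2
          next
        }
      }
      nc <- nc + 1L
      cands[[nc]] <- c(list(start = s$pos[lo], end = s$pos[hi]), cur)
      lo <- j; hi <- j + w - 1L
      cur <- span_stats_cum(cum, lo, hi)
    }
    nc <- nc + 1L
    cands[[nc]] <- c(list(start = s$pos[lo], end = s$pos[hi]), cur)
    dt <- data.table::rbindlist(cands[seq_len(nc)])
    dt[, `:=`(chrom = ch, context = context)]
    res[[length(res) + 1L]] <- dt
  }
  if (!length(res)) return(empty_candidates())
  out <- data.table::rbindlist(res)
  data.table::setcolorder(out, c("chrom", "start", "end", "context", "n_sites",
                                 "m_a", "n_a", "m_b", "n_b", "level_a",
                                 "level_b", "diff", "p_value"))
  data.table::setorder(out, chrom, start)
  out[]
}

#' Join interdependent DMR candidates
#'
#' Two nearby candidates (gap <= `max_gap` bp) are joined into one
#' continuous DMR when the full spanning region - all shared covered
#' context sites from the upstream candidate's start to the downstream
#' candidate's end - again shows |pooled level difference| > `diff_cutoff`
#' with Fisher p <= `p_cutoff`; otherwise they stay independent. Joining is
#' repeated left-to-right until a fixed point, so the operation is
#' idempotent.
#'
#' @param candidates output of [scan_dmr_candidates()] (one context).
#' @param sites the shared-site table the candidates were scanned from
#'   (available via [call_dmrs()] or [scan_dmr_candidates()]'s inputs).
#' @param diff_cutoff,p_cutoff join criteria (same as the scan's).
#' @param max_gap maximum bp between candidate ends to attempt a join (100).
#' @return data.table of DMRs: candidate columns + direction
#'   ("hyper"/"hypo" relative to sample A) and merged_from.
#' @export
merge_interdependent <- function(candidates, sites, diff_cutoff = 0.1,
                                 p_cutoff = 0.05, max_gap = 100L) {
  dmrs <- data.table::copy(candidates)
  if (!"merged_from" %in% names(dmrs)) dmrs[, merged_from := 1L]
  data.table::setorder(dmrs, chrom, start)
  # per-chromosome cumulative counts for O(log n) spanning-region stats
  sites <- data.table::as.data.table(sites)
  data.table::setorder(sites, chrom, pos)
  bych <- lapply(split(sites, sites$chrom), function(s)
    list(pos = s$pos, cma = cumsum(s$m_a), cna = cumsum(s$n_a),
         cmb = cumsum(s$m_b), cnb = cumsum(s$n_b)))
  span <- function(ch, s, e) {
    o <- bych[[ch]]
    i1 <- findInterval(s - 0.5, o$pos) + 1L
    i2 <- findInterval(e, o$pos)
    csum <- function(cs) cs[i2] - if (i1 > 1L) cs[i1 - 1L] else 0
    ma <- csum(o$cma); na <- csum(o$cna); mb <- csum(o$cmb); nb <- csum(o$cnb)
    la <- ma / na; lb <- mb / nb
    list(n_sites = i2 - i1 + 1L, m_a = ma, n_a = na, m_b = mb, n_b = nb,
         level_a = la, level_b = lb, diff = la - lb,
         p_value = fisher_test_2x2(ma, na - ma, mb, nb - mb))
  }
  repeat {
    joined <- FALSE
    i <- 1L
    while (i < nrow(dmrs)) {
      same <- dmrs$chrom[i] == dmrs$chrom[i + 1L]
      gap <- dmrs$start[i + 1L] - dmrs$end[i] - 1L
      if (same && gap <= max_gap) {
        st <- span(dmrs$chrom[i], dmrs$start[i], dmrs$end[i + 1L])
        if (abs(st$diff) > diff_cutoff && st$p_value <= p_cutoff) {
          dmrs[i, `:=`(end = dmrs$end[i + 1L], n_sites = st$n_sites,
                       m_a = st$m_a, n_a = st$n_a, m_b = st$m_b, n_b = st$n_b,
                       level_a = st$level_a, level_b = st$level_b,
                       diff = st$diff, p_value = st$p_value,
                       merged_from = dmrs$merged_from[i] + dmrs$merged_from[i + 1L])]
          dmrs <- dmrs[-(i + 1L)]
          joined <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!joined) break
  }
  dmrs[, direction := ifelse(diff > 0, "hyper", "hypo")]
  dmrs[]
}

#' Detect DMRs between two samples across contexts
#'
#' Convenience wrapper: pools replicates per group, scans each context,
#' joins interdependent candidates, and assigns hyper/hypo direction
#' relative to sample A.
#'
#' @param samples_a,samples_b call/report data.tables or lists of replicate
#'   tables for the focal sample A and comparator B.
#' @param contexts contexts to scan (default all three).
#' @inheritParams scan_dmr_candidates
#' @inheritParams merge_interdependent
#' @return data.table of DMRs across contexts with dmr_id.
#' @export
call_dmrs <- function(samples_a, samples_b, contexts = c("CG", "CHG", "CHH"),
                      min_sites = 5L, diff_cutoff = 0.1, p_cutoff = 0.05,
                      window_sites = 5L, min_coverage = 4L, max_gap = 100L) {
  a <- pool_calls(samples_a); b <- pool_calls(samples_b)
  res <- lapply(contexts, function(ctx) {
    sites <- shared_context_sites(a, b, ctx, min_coverage)
    if (nrow(sites) < min_sites) {
      warning("fewer than ", min_sites, " shared ", ctx, " sites; skipped")
      return(NULL)
    }
    cand <- scan_sites(sites, ctx, diff_cutoff, p_cutoff, window_sites)
    if (!nrow(cand)) return(NULL)
    merge_interdependent(cand, sites, diff_cutoff, p_cutoff, max_gap)
  })
  out <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  if (!nrow(out)) {
    out <- empty_candidates()
    out[, `:=`(merged_from = integer(), direction = character(), dmr_id = character())]
    return(out[])
  }
  data.table::setorder(out, chrom, start)
  out[, dmr_id := sprintf("DMR_%s_%05d", context, seq_len(.N)), by = context]
  out[]
}

#' Label DMRs as genic or intergenic
#'
#' A DMR is genic when it overlaps at least one bp of any gene body or its
#' strand-aware 2 kb upstream region.
#'
#' @param dmrs DMR data.table from [call_dmrs()].
#' @param genes gene-model data.table.
#' @param chrom_len named chromosome lengths (clips upstream regions).
#' @param upstream upstream extent in bp (2000).
#' @return list(dmrs = input + `location` column, fractions =
#'   data.table(context, n_dmrs, n_genic, genic_fraction)).
#' @export
classify_dmr_location <- function(dmrs, genes, chrom_len, upstream = 2000L) {
  dmrs <- data.table::copy(dmrs)
  if (!nrow(dmrs)) {
    dmrs[, location := character()]
    return(list(dmrs = dmrs[], fractions = data.table::data.table(
      context = character(), n_dmrs = integer(), n_genic = integer(),
      genic_fraction = numeric())))
  }
  reg <- gene_regions(genes, chrom_len, upstream)
  q <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(dmrs$start, dmrs$end))
  r <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start, reg$end))
  hit <- IRanges::overlapsAny(q, r)
  dmrs[, location := ifelse(hit, "genic", "intergenic")]
  fr <- dmrs[, .(n_dmrs = .N, n_genic = sum(location == "genic")), by = context]
  fr[, genic_fraction := n_genic / n_dmrs]
  list(dmrs = dmrs[], fractions = fr[])
}

#' Write DMRs as a BED-like TSV (0-based half-open)
#' @param dmrs DMR data.table (1-based inclusive internally).
#' @param path output path.
#' @export
write_dmrs <- function(dmrs, path) {
  out <- data.table::copy(dmrs)
  out[, start := start - 1L]  # half-open: end stays
  cols <- intersect(c("chrom", "start", "end", "context", "n_sites", "level_a",
                      "level_b", "diff", "p_value", "direction", "merged_from",
                      "dmr_id", "location"), names(out))
  data.table::fwrite(out[, cols, with = FALSE], path, sep = "\t", quote = FALSE)
  invisible(path)
}
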