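# Methylcytosine calling and methylome summaries.
#
# Cytosine reports are 6-column TSVs: chrom, pos (1-based), strand, m
# (methylated reads), u (unmethylated reads), context. Calls add p_value,
# is_methylated and level. A site is tested only when covered by at least
# `min_coverage` reads in every compared sample; the null is
# Binomial(n, error_rate) where error_rate is the bisulfite
# non-conversion/error rate.

#' Read a per-cytosine methylation report
#'
#' @param path TSV with columns chrom, pos, strand, m, u, context (header
#'   optional; recognised by name when present).
#' @return data.table(chrom, pos, strand, m, u, context).
#' @export
read_cytosine_report <- function(path) {
  dt <- data.table::fread(path, na.strings = c("NA", ""))
  if (!all(c("chrom", "pos") %in% names(dt)))
    data.table::setnames(dt, seq_len(6L), c("chrom", "pos", "strand", "m", "u", "context"))
  if (is.logical(dt$context)) dt[, context := as.character(context)]
  dt[]
}

#' Write a per-cytosine methylation report
#' @param sites data.table with chrom, pos, strand, m, u, context.
#' @param path output TSV path.
#' @export
write_cytosine_report <- function(sites, path) {
  data.table::fwrite(sites[, c("chrom", "pos", "strand", "m", "u", "context"),
                           with = FALSE],
                     path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Call methylcytosines by binomial test across compared samples
#'
#' Sites keyed by (chrom, pos, strand) are kept only when covered by at
#' least `min_coverage` reads in every sample of `samples`; each kept site
#' is then tested per sample with the upper-tail binomial probability
#' P(X >= m | n, error_rate) and called methylated when p < `p_threshold`.
#' The methylation level is m/n.
#'
#' @param samples named list of cytosine-report data.tables (or a single
#'   data.table, treated as one sample).
#' @param error_rate bisulfite non-conversion/error rate in `[0,1)`. If a
#'   designated unmethylated control is available its mean level can be used
#'   here (see [estimate_error_rate()]).
#' @param min_coverage minimum reads required in all compared samples
#'   (default 4).
#' @param p_threshold binomial p-value cutoff (default 1e-4, strict `<`).
#' @return named list of call data.tables (chrom, pos, strand, context, m,
#'   u, n, level, p_value, is_methylated); attribute `n_excluded` carries
#'   the number of candidate sites dropped by the coverage rule.
#' @export
call_methylcytosines <- function(samples, error_rate = 0.01, min_coverage = 4L,
                                 p_threshold = 1e-4) {
  if (data.table::is.data.table(samples) || is.data.frame(samples))
    samples <- list(sample1 = data.table::as.data.table(samples))
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  for (s in samples)
    if (any(s$m < 0) || any(s$u < 0)) stop("negative read counts")

  keytab <- data.table::rbindlist(lapply(samples, function(s)
    data.table::as.data.table(s)[, .(chrom, pos, strand, ok = (m + u) >= min_coverage)]))
  agg <- keytab[, .(n_ok = sum(ok), n_samp = .N), by = .(chrom, pos, strand)]
  n_universe <- nrow(agg)
  shared <- agg[n_ok == length(samples) & n_samp == length(samples),
                .(chrom, pos, strand)]
  data.table::setkey(shared, chrom, pos, strand)
  out <- lapply(samples, function(s) {
    s <- data.table::as.data.table(s)
    data.table::setkey(s, chrom, pos, strand)
    s <- s[shared, nomatch = NULL]
    s[, n := m + u]
    s[, level := ifelse(n > 0, m / n, NA_real_)]
    s[, p_value := binom_upper_tail(m, n, error_rate)]
    s[, is_methylated := p_value < p_threshold]
    data.table::setorder(s, chrom, pos, strand)
    s[]
  })
  attr(out, "n_excluded") <- n_universe - nrow(shared)
  attr(out, "error_rate") <- error_rate
  out
}

#' Estimate the bisulfite error rate from an unmethylated control
#'
#' The pooled level (sum m / sum n) over a user-designated unmethylated
#' control sequence (e.g. chloroplast or lambda spike-in) estimates the
#' non-conversion plus sequencing error rate used as the binomial null.
#'
#' @param report cytosine-report data.table.
#' @param control_chroms chromosome names of the control sequence.
#' @return scalar estimate in `[0, 1)`.
#' @export
estimate_error_rate <- function(report, control_chroms) {
  ctl <- report[chrom %in% control_chroms]
  if (!nrow(ctl) || sum(ctl$m + ctl$u) == 0)
    stop("no covered control cytosines on ", paste(control_chroms, collapse = ","))
  sum(ctl$m) / sum(ctl$m + ctl$u)
}

#' Summarise a methylome: context averages, mC fractions, sliding windows
#'
#' Per-context average level is the mean of per-site levels over covered
#' sites (region-level pooled statistics live in the DMR stage); the mC
#' fraction is each context's share of all methylated cytosines; window
#' means use windows of `window_size` bp sliding by `step` bp, with
#' windows holding no covered site reported as NA (missing, not zero).
#' Sites with NA context are excluded from context-stratified statistics
#' and counted in `n_context_na`.
#'
#' @param calls one call data.table from [call_methylcytosines()].
#' @param chrom_len named vector of chromosome lengths.
#' @param window_size,step window geometry in bp (defaults 1 Mb / 200 kb).
#' @return list(context = data.table(context, mean_level, pooled_level,
#'   n_sites, n_mc, mc_fraction), overall_level, n_context_na, windows =
#'   data.table(chrom, start, end, mean_level, n_sites); start 0-based
#'   half-open for BEDGRAPH compatibility).
#' @export
summarize_methylome <- function(calls, chrom_len, window_size = 1e6, step = 2e5) {
  calls <- data.table::as.data.table(calls)
  covered <- calls[n > 0]
  ctx <- covered[!is.na(context),
                 .(mean_level = mean(level), pooled_level = sum(m) / sum(n),
                   n_sites = .N, n_mc = sum(is_methylated)),
                 by = context]
  data.table::setorder(ctx, context)
  total_mc <- sum(ctx$n_mc)
  ctx[, mc_fraction := if (total_mc > 0) n_mc / total_mc else NA_real_]
  windows <- window_mean_track(covered[, .(chrom, pos, value = level)],
                               chrom_len, window_size, step)
  list(context = ctx[],
       overall_level = mean(covered$level),
       n_context_na = nrow(covered[is.na(context)]),
       windows = windows)
}

#' Sliding-window mean of a positional track
#'
#' Window starts are 0, step, 2*step, ... below the chromosome length; each
#' window spans `window_size` bp clipped at the chromosome end. The window
#' mean averages `value` over positions falling inside; empty windows are NA.
#'
#' @param track data.table(chrom, pos, value), 1-based positions.
#' @param chrom_len named chromosome lengths.
#' @param window_size,step geometry in bp.
#' @return data.table(chrom, start, end, mean_value -> mean_level, n_sites);
#'   start is 0-based, end exclusive.
#' @export
window_mean_track <- function(track, chrom_len, window_size = 1e6, step = 2e5) {
  res <- lapply(names(chrom_len), function(ch) {
    len <- chrom_len[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window_size, len)
    tr <- track[chrom == ch]
    mean_level <- rep(NA_real_, length(starts))
    n_sites <- integer(length(starts))
    if (nrow(tr)) {
      for (i in seq_along(starts)) {
        v <- tr$value[tr$pos > starts[i] & tr$pos <= ends[i]]
        n_sites[i] <- length(v)
        if (length(v)) mean_level[i] <- mean(v)
      }
    }
    data.table::data.table(chrom = ch, start = starts, end = ends,
                           mean_level = mean_level, n_sites = n_sites)
  })
  data.table::rbindlist(res)[]
}

#' Write a window track as BEDGRAPH (0-based half-open)
#' @param windows data.table from [window_mean_track()].
#' @param path output path; NA windows are skipped.
#' @export
write_bedgraph <- function(windows, path) {
  w <- windows[!is.na(mean_level), .(chrom, start = as.integer(start),
                                     end = as.integer(end), mean_level)]
  data.table::fwrite(w, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
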