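# Genome sequence access, cytosine context classification, and gene-model
# I/O. Sequences are Biostrings::DNAStringSet; gene models travel as a plain
# data.table (gene_id, chrom, start, end, strand, length; 1-based inclusive)
# with GFF3/BED round-trips through rtracklayer.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify the sequence context of cytosines
#'
#' Plant cytosine methylation is analysed in three sequence contexts: CG,
#' CHG and CHH, where H is A, T or C. The context of a cytosine is read from
#' the two bases downstream in its strand's 5'->3' direction; on the minus
#' strand the reference shows G and downstream means decreasing coordinates,
#' complemented. `NA` is returned where the two-base window runs off the
#' chromosome end (a single downstream G still resolves to CG).
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector).
#' @param chrom chromosome names, recycled against `pos`.
#' @param pos 1-based positions of the cytosines on the reference.
#' @param strand "+" or "-" per position.
#' @return character vector in {"CG","CHG","CHH", NA}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACGTT"))
#' assign_context(g, "chr1", 3, "+")  # "CG"
#' assign_context(g, "chr1", 4, "-")  # "CG"
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  genome <- as_dss(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stop("unknown chromosome: ", ch)
    s <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    len <- length(s)
    idx <- which(chrom == ch)
    p <- pos[idx]
    if (any(p < 1L | p > len))
      stop("position out of range on ", ch, ": ",
           paste(p[p < 1L | p > len], collapse = ","))
    plus <- strand[idx] == "+"
    refbase <- s[p]
    bad <- (plus & refbase != "C") | (!plus & refbase != "G")
    if (any(bad))
      stop("not a cytosine on the given strand at ", ch, ":",
           paste(paste0(p[bad], strand[idx][bad]), collapse = ","))
    b1 <- ifelse(plus, ifelse(p + 1L <= len, s[pmin(p + 1L, len)], NA),
                       ifelse(p - 1L >= 1L, COMPLEMENT[s[pmax(p - 1L, 1L)]], NA))
    b2 <- ifelse(plus, ifelse(p + 2L <= len, s[pmin(p + 2L, len)], NA),
                       ifelse(p - 2L >= 1L, COMPLEMENT[s[pmax(p - 2L, 1L)]], NA))
    ctx <- ifelse(!is.na(b1) & b1 == "G", "CG",
           ifelse(is.na(b1) | is.na(b2), NA_character_,
           ifelse(b2 == "G", "CHG", "CHH")))
    out[idx] <- ctx
  }
  out
}

#' Enumerate every cytosine of a genome with its context
#'
#' Walks both strands (plus-strand C, minus-strand G) and classifies each
#' site. This is the site universe used by the simulator and by context
#' consistency checks.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @return data.table with columns chrom, pos (1-based), strand, context
#'   (NA at chromosome-end sites), sorted by (chrom, pos, strand).
#' @export
enumerate_cytosines <- function(genome) {
  genome <- as_dss(genome)
  res <- lapply(names(genome), function(ch) {
    s <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    len <- length(s)
    pp <- which(s == "C")
    pm <- which(s == "G")
    ctx_p <- context_plus(s, pp, len)
    ctx_m <- context_minus(s, pm)
    data.table::data.table(
      chrom = ch,
      pos = c(pp, pm),
      strand = rep(c("+", "-"), c(length(pp), length(pm))),
      context = c(ctx_p, ctx_m))
  })
  dt <- data.table::rbindlist(res)
  data.table::setorder(dt, chrom, pos, strand)
  dt[]
}

# context of plus-strand cytosines at positions pp in char vector s
context_plus <- function(s, pp, len) {
  b1 <- ifelse(pp + 1L <= len, s[pmin(pp + 1L, len)], NA)
  b2 <- ifelse(pp + 2L <= len, s[pmin(pp + 2L, len)], NA)
  ifelse(!is.na(b1) & b1 == "G", "CG",
  ifelse(is.na(b1) | is.na(b2), NA_character_,
  ifelse(b2 == "G", "CHG", "CHH")))
}

# context of minus-strand cytosines (reference G) at positions pm
context_minus <- function(s, pm) {
  b1 <- ifelse(pm - 1L >= 1L, s[pmax(pm - 1L, 1L)], NA)  # complement later
  b2 <- ifelse(pm - 2L >= 1L, s[pmax(pm - 2L, 1L)], NA)
  # downstream base is G iff reference base is C
  ifelse(!is.na(b1) & b1 == "C", "CG",
  ifelse(is.na(b1) | is.na(b2), NA_character_,
  ifelse(b2 == "C", "CHG", "CHH")))
}

as_dss <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) return(Biostrings::DNAStringSet(genome))
  stop("genome must be a DNAStringSet or named character vector")
}

chrom_lengths <- function(genome) {
  genome <- as_dss(genome)
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read gene models from GFF3 or BED
#'
#' @param path a GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file. GFF3 rows are
#'   filtered to feature type "gene".
#' @return data.table(gene_id, chrom, start, end, strand, length), 1-based
#'   inclusive coordinates.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE) && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else if ("name" %in% names(S4Vectors::mcols(gr))) as.character(gr$name)
         else paste0("gene", seq_along(gr))
  dt <- data.table::data.table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  dt[, length := end - start + 1L]
  data.table::setorder(dt, chrom, start)
  dt[]
}

#' Write gene models as GFF3 and BED6
#'
#' @param genes gene-model data.table (see [read_gene_models()]).
#' @param gff3 optional GFF3 output path (1-based inclusive).
#' @param bed optional BED6 output path (0-based half-open).
#' @return invisibly, the paths written.
#' @export
write_gene_models <- function(genes, gff3 = NULL, bed = NULL) {
  gr <- genes_to_granges(genes)
  if (!is.null(gff3)) {
    gr2 <- gr
    gr2$type <- "gene"
    gr2$ID <- genes$gene_id
    gr2$source <- "methexpr"
    rtracklayer::export(gr2, gff3, format = "gff3")
  }
  if (!is.null(bed)) {
    gr2 <- gr
    gr2$name <- genes$gene_id
    gr2$score <- 0L
    rtracklayer::export(gr2, bed, format = "bed")
  }
  invisible(c(gff3 = gff3, bed = bed))
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
}

#' Strand-aware gene regions: body and 2 kb upstream
#'
#' The genic region used throughout DMR-gene association is the gene body
#' plus 2 kb upstream of the transcription start: `[start-2000, start-1]` on
#' the plus strand, `[end+1, end+2000]` on the minus strand, clipped to the
#' chromosome.
#'
#' @param genes gene-model data.table.
#' @param chrom_len named vector of chromosome lengths (for clipping).
#' @param upstream upstream extent in bp (default 2000).
#' @return data.table(gene_id, chrom, start, end, strand, part) with one
#'   "body" row per gene and one "upstream" row where the upstream interval
#'   is non-empty after clipping.
#' @export
gene_regions <- function(genes, chrom_len, upstream = 2000L) {
  body <- data.table::data.table(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = genes$start, end = genes$end, strand = genes$strand, part = "body")
  up_start <- ifelse(genes$strand == "+", genes$start - upstream, genes$end + 1L)
  up_end   <- ifelse(genes$strand == "+", genes$start - 1L, genes$end + upstream)
  up_start <- pmax(up_start, 1L)
  up_end <- pmin(up_end, chrom_len[genes$chrom])
  keep <- up_start <= up_end
  up <- data.table::data.table(
    gene_id = genes$gene_id[keep], chrom = genes$chrom[keep],
    start = as.integer(up_start[keep]), end = as.integer(up_end[keep]),
    strand = genes$strand[keep], part = "upstream")
  out <- data.table::rbindlist(list(body, up))
  data.table::setorder(out, chrom, start)
  out[]
}
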