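# Weighted methylation levels over gene regions and binned metaprofiles.
#
# All levels are pooled-count ratios: sum(methylated) / sum(coverage) over
# the qualifying cytosines of a region and context. Gene coordinates are
# 0-based half-open internally; GFF3 (1-based inclusive) is converted at
# the IO boundary only.

REGIONS <- c("upstream", "body", "downstream")

#' Read gene models from a GFF3 file
#'
#' Imports `gene` features and converts them to the package's internal
#' 0-based half-open convention. The transcription start site (TSS) is the
#' 5' end on the gene's strand.
#'
#' @param path GFF3 file.
#' @return data.table with `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (!length(gr)) stop("no gene features in ", path)
  dt <- data.table(
    gene_id = as.character(gr$ID),
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    strand  = as.character(GenomicRanges::strand(gr)),
    start   = GenomicRanges::start(gr) - 1L,
    end     = GenomicRanges::end(gr))
  if (anyNA(dt$gene_id)) stop("gene feature without ID attribute in ", path)
  if (any(!dt$strand %in% c("+", "-")))
    stop("gene feature without explicit strand in ", path)
  setorder(dt, chrom, start)
  dt[]
}

#' Write gene models to GFF3
#'
#' @param genes gene table as returned by [read_genes()].
#' @param path output file.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, source = "allelomethyl") {
  genes <- as.data.table(genes)
  gr <- granges0(genes$chrom, genes$start, genes$end, genes$strand)
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.check_genes <- function(genes) {
  genes <- as.data.table(genes)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (any(!genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in gene table")
  genes
}

#' Strand-aware gene regions (upstream flank, body, downstream flank)
#'
#' Upstream is 5' of the TSS on the gene's own strand; flanks are truncated
#' at chromosome ends when `chrom_lens` is supplied.
#'
#' @param genes gene table (0-based half-open).
#' @param flank flank width in bp (default 2000).
#' @param chrom_lens optional named vector of chromosome lengths.
#' @return data.table `gene_id`, `region`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_regions <- function(genes, flank = 2000, chrom_lens = NULL) {
  genes <- .check_genes(genes)
  up <- genes[, .(gene_id, region = "upstream", chrom, strand,
                  start = ifelse(strand == "+", start - flank, end),
                  end   = ifelse(strand == "+", start, end + flank))]
  body <- genes[, .(gene_id, region = "body", chrom, strand, start, end)]
  dn <- genes[, .(gene_id, region = "downstream", chrom, strand,
                  start = ifelse(strand == "+", end, start - flank),
                  end   = ifelse(strand == "+", end + flank, start))]
  reg <- rbindlist(list(up, body, dn))
  reg[, start := pmax(start, 0L)]
  if (!is.null(chrom_lens)) {
    reg[, end := pmin(end, chrom_lens[chrom])]
  }
  reg <- reg[start < end]
  setorder(reg, chrom, start, gene_id)
  reg[]
}

# Collapse duplicate site rows (same chrom/pos/strand/context) by summing
# counts, so that levels are invariant to how reads were split across rows,
# and drop ambiguous-context sites.
.aggregate_sites <- function(calls) {
  calls <- as.data.table(calls)
  need <- c("chrom", "pos", "strand", "context", "coverage", "methylated")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("call table missing column(s): ", paste(miss, collapse = ", "))
  calls[context %in% CONTEXTS,
        .(coverage = sum(coverage), methylated = sum(methylated)),
        by = .(chrom, pos, strand, context)]
}

#' Weighted methylation level per gene region and context
#'
#' For each gene x region (`upstream`, `body`, `downstream`) x context, the
#' level is the pooled-count ratio sum(methylated)/sum(coverage) over sites
#' with coverage at least `min_cov`. Regions with no qualifying site get a
#' missing level with `n_sites = 0`.
#'
#' @param calls methylation call table (`chrom`, `pos`, `strand`, `context`,
#'   `coverage`, `methylated`); duplicate site rows are pooled first.
#' @param genes gene table (0-based half-open).
#' @param flank flank width in bp (default 2000).
#' @param min_cov minimum site coverage (default 4).
#' @param chrom_lens optional chromosome lengths for flank truncation.
#' @return data.table `gene_id`, `region`, `context`, `level`, `n_sites`,
#'   `total_coverage`, one row per gene x region x context.
#' @export
region_levels <- function(calls, genes, flank = 2000, min_cov = 4,
                          chrom_lens = NULL) {
  genes <- .check_genes(genes)
  sites <- .aggregate_sites(calls)[coverage >= min_cov]
  reg <- gene_regions(genes, flank = flank, chrom_lens = chrom_lens)

  grid <- CJ(gene_id = genes$gene_id, region = REGIONS, context = CONTEXTS)
  if (nrow(sites) && nrow(reg)) {
    hits <- GenomicRanges::findOverlaps(
      granges0(sites$chrom, sites$pos, sites$pos + 1L),
      granges0(reg$chrom, reg$start, reg$end), ignore.strand = TRUE)
    ov <- data.table(sites[S4Vectors::queryHits(hits),
                           .(context, coverage, methylated)],
                     reg[S4Vectors::subjectHits(hits), .(gene_id, region)])
    agg <- ov[, .(level = sum(methylated) / sum(coverage), n_sites = .N,
                  total_coverage = sum(coverage)),
              by = .(gene_id, region, context)]
    out <- merge(grid, agg, by = c("gene_id", "region", "context"), all.x = TRUE)
  } else {
    out <- grid[, `:=`(level = NA_real_, n_sites = NA_integer_,
                       total_coverage = NA_real_)]
  }
  out[is.na(n_sites), `:=`(n_sites = 0L, total_coverage = 0)]
  out[, region := factor(region, levels = REGIONS)]
  setorder(out, gene_id, region, context)
  out[, region := as.character(region)]
  out[]
}

#' Binned TSS-to-TTS methylation metaprofile
#'
#' Each flank is divided into `flank_bins` equal-width bins; the gene body
#' is rescaled to `body_bins` proportional bins. Minus-strand genes are
#' reversed so that bin 0 is always the position farthest upstream of the
#' TSS. Per gene and bin the pooled level is computed, then averaged over
#' the genes contributing data to that bin (genes shorter than `body_bins`
#' simply populate fewer body bins; they are not skipped).
#'
#' @inheritParams region_levels
#' @param flank_bins bins per flank (default 20).
#' @param body_bins bins across the gene body (default 40).
#' @param min_cov minimum site coverage (default 1).
#' @return data.table `context`, `bin`, `zone`, `mean_level`, `n_genes`
#'   with `2 * flank_bins + body_bins` bins per context.
#' @export
metaprofile <- function(calls, genes, flank = 2000, flank_bins = 20,
                        body_bins = 40, min_cov = 1) {
  genes <- .check_genes(genes)
  if (!nrow(genes)) stop("at least one gene is required")
  sites <- .aggregate_sites(calls)[coverage >= min_cov]
  nb <- 2L * flank_bins + body_bins
  zone_of <- function(bin) fifelse(bin < flank_bins, "upstream",
                            fifelse(bin < flank_bins + body_bins, "body",
                                    "downstream"))
  grid <- CJ(context = CONTEXTS, bin = 0:(nb - 1L))

  span <- genes[, .(gene_id, chrom, strand, gstart = start, gend = end,
                    start = start - flank, end = end + flank)]
  span[, start := pmax(start, 0L)]
  hits <- GenomicRanges::findOverlaps(
    granges0(sites$chrom, sites$pos, sites$pos + 1L),
    granges0(span$chrom, span$start, span$end), ignore.strand = TRUE)
  if (!length(hits)) {
    out <- grid[, .(context, bin, zone = zone_of(bin),
                    mean_level = NA_real_, n_genes = 0L)]
    return(out[])
  }
  ov <- data.table(sites[S4Vectors::queryHits(hits)],
                   span[S4Vectors::subjectHits(hits),
                        .(gene_id, gstrand = strand, gstart, gend)])
  len <- ov$gend - ov$gstart
  plus <- ov$gstrand == "+"
  # gene-oriented offset within upstream flank / body / downstream flank
  bin <- integer(nrow(ov))
  pos <- ov$pos
  in_up   <- fifelse(plus, pos < ov$gstart, pos >= ov$gend)
  in_body <- pos >= ov$gstart & pos < ov$gend
  off_up <- fifelse(plus, pos - (ov$gstart - flank), (ov$gend + flank - 1L) - pos)
  off_bd <- fifelse(plus, pos - ov$gstart, (ov$gend - 1L) - pos)
  off_dn <- fifelse(plus, pos - ov$gend, (ov$gstart - 1L) - pos)
  bin[in_up] <- pmin((off_up[in_up] * flank_bins) %/% flank, flank_bins - 1L)
  bin[in_body] <- flank_bins +
    pmin((off_bd[in_body] * body_bins) %/% len[in_body], body_bins - 1L)
  dn <- !in_up & !in_body
  bin[dn] <- flank_bins + body_bins +
    pmin((off_dn[dn] * flank_bins) %/% flank, flank_bins - 1L)
  # flank truncation at chromosome start can put minus-strand downstream /
  # plus-strand upstream offsets below 0 only if pos < 0, impossible; but a
  # site can fall in a truncated flank window of another gene. Guard anyway.
  keep <- bin >= 0L & bin < nb
  ov <- ov[keep]; ov[, bin := bin[keep]]

  per_gene <- ov[, .(level = sum(methylated) / sum(coverage)),
                 by = .(gene_id, context, bin)]
  prof <- per_gene[, .(mean_level = mean(level), n_genes = .N),
                   by = .(context, bin)]
  out <- merge(grid, prof, by = c("context", "bin"), all.x = TRUE)
  out[is.na(n_genes), n_genes := 0L]
  out[, zone := zone_of(bin)]
  setorder(out, context, bin)
  out[, .(context, bin, zone, mean_level, n_genes)][]
}
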