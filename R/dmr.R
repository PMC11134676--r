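# Sliding-window DMR calling between two methylation samples.
#
# The caller is a transparent windowed two-proportion test rather than a
# smoothed dispersion-shrinkage model: per window the methylated/total
# counts of each sample are pooled, compared with a continuity-corrected
# two-proportion z-test, corrected across windows by Benjamini-Hochberg
# (per context), and significant windows are merged and boundary-refined.

# Vectorised two-sided two-proportion z-test on pooled counts, matching
# stats::prop.test with Yates continuity correction. Zero pooled variance
# (both samples all-methylated or all-unmethylated) gives p = 1.
two_prop_p <- function(m1, n1, m2, n2, correct = TRUE) {
  p1 <- m1 / n1; p2 <- m2 / n2
  pp <- (m1 + m2) / (n1 + n2)
  v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  d <- abs(p1 - p2)
  cc <- if (correct) pmin(0.5 * (1 / n1 + 1 / n2), d) else 0
  p <- rep(1, length(d))
  pos <- v > 0
  p[pos] <- 2 * pnorm(-(d[pos] - cc[pos]) / sqrt(v[pos]))
  pmin(p, 1)
}

.joint_sites <- function(calls_a, calls_b, ctx, min_cov) {
  a <- .aggregate_sites(calls_a)[context == ctx & coverage >= min_cov]
  b <- .aggregate_sites(calls_b)[context == ctx & coverage >= min_cov]
  j <- merge(a[, .(chrom, pos, strand, m_a = methylated, n_a = coverage)],
             b[, .(chrom, pos, strand, m_b = methylated, n_b = coverage)],
             by = c("chrom", "pos", "strand"))
  setorder(j, chrom, pos, strand)
  j
}

.pool_span <- function(sites, chrom_, lo, hi) {
  s <- sites[chrom == chrom_ & pos >= lo & pos < hi]
  list(m_a = sum(s$m_a), n_a = sum(s$n_a), m_b = sum(s$m_b),
       n_b = sum(s$n_b), n_sites = nrow(s))
}

# Refine a merged window span on a fixed sub-window grid. A sub-window
# supports the region if its pooled delta has the region's sign and
# magnitude at least half the strongest same-sign sub-window delta (never
# below delta_min); anchoring the threshold to the strongest sub-window,
# not the span average, keeps it from being diluted when merged windows
# overhang the true signal. Supporting sub-windows are then grouped into
# runs: gaps of unsupported sequence longer than split_gap split the span
# into separate regions (merging can bridge two nearby DMRs through a
# quiet stretch), and single-sub-window runs are discarded as noise.
# Returns a data.table of refined (start, end) spans; falls back to the
# input span when nothing supports it.
.refine_span <- function(sites, chrom_, start, end, delta_min, refine_bp,
                         split_gap = 500L) {
  fallback <- data.table(start = start, end = end)
  s <- sites[chrom == chrom_ & pos >= start & pos < end]
  if (!nrow(s)) return(fallback)
  dlt <- sum(s$m_a) / sum(s$n_a) - sum(s$m_b) / sum(s$n_b)
  if (dlt == 0) return(fallback)
  s[, sw := (pos - start) %/% refine_bp]
  sub <- s[, .(d = sum(m_a) / sum(n_a) - sum(m_b) / sum(n_b), nst = .N,
               lo = min(pos), hi = max(pos) + 1L), by = sw]
  setorder(sub, sw)
  ref <- sub[sign(d) == sign(dlt) & nst >= 3, ]
  peak <- if (nrow(ref)) max(abs(ref$d)) else abs(dlt)
  thr <- max(delta_min, peak / 2)
  sup <- sub[sign(d) == sign(dlt) & abs(d) >= thr]
  if (!nrow(sup)) return(fallback)
  run <- cumsum(c(1L, as.integer(sup$lo[-1] - sup$hi[-nrow(sup)] > split_gap)))
  spans <- sup[, .(start = min(lo), end = max(hi), n_sub = .N), by = .(run = run)]
  spans <- spans[n_sub >= 2L]
  if (!nrow(spans)) return(fallback)
  spans[, .(start, end)]
}

#' Call differentially methylated regions between two samples
#'
#' Slides windows of `window` bp at `step` bp across each chromosome.
#' Windows with at least `min_sites` cytosines of the requested context
#' covered (`>= min_cov`) in both samples are tested by a pooled two-sided
#' two-proportion z-test with continuity correction; p-values are
#' Benjamini-Hochberg adjusted across all tested windows. Significant
#' windows (`q <= alpha`, `|delta| >= delta_min`) with the same delta sign
#' and gaps of at most `step` are merged; merged spans are then
#' boundary-refined on a `refine_bp` sub-window grid and their statistics
#' recomputed from the pooled counts of the final span, with p and q
#' reported as the minimum over member windows.
#'
#' @param calls_a,calls_b methylation call tables for the two samples on
#'   the same genome.
#' @param context one of `CG`, `CHG`, `CHH`.
#' @param window,step window width and slide step in bp (window >= step).
#' @param min_sites minimum jointly covered sites per window (default 5).
#' @param min_cov minimum per-site coverage in each sample (default 4).
#' @param delta_min minimum absolute methylation difference (default 0.1).
#' @param alpha q-value threshold (default 0.05).
#' @param refine logical; refine merged boundaries (default TRUE).
#' @param refine_bp sub-window width for refinement (default 100).
#' @return data.table of DMRs: `chrom`, `start`, `end` (0-based half-open),
#'   `context`, `mean_a`, `mean_b`, `delta = mean_a - mean_b`, `n_sites`,
#'   `p_value`, `q_value`. Attribute `windows` holds the per-window test
#'   table (`chrom`, `start`, `end`, `n_sites`, `delta`, `p_value`,
#'   `q_value`).
#' @export
call_dmrs <- function(calls_a, calls_b, context, window = 1000, step = 500,
                      min_sites = 5, min_cov = 4, delta_min = 0.1,
                      alpha = 0.05, refine = TRUE, refine_bp = 100) {
  if (window < step) stop("window must be >= step")
  context <- match.arg(context, CONTEXTS)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), mean_a = numeric(),
                      mean_b = numeric(), delta = numeric(),
                      n_sites = integer(), p_value = numeric(),
                      q_value = numeric())
  sites <- .joint_sites(calls_a, calls_b, context, min_cov)
  if (!nrow(sites)) {
    setattr(empty, "windows", data.table())
    return(empty)
  }

  # each site belongs to every window k*step with k*step <= pos < k*step+window
  kmax <- sites$pos %/% step
  kmin <- pmax(0L, (sites$pos - window) %/% step + 1L)
  reps <- kmax - kmin + 1L
  exp_idx <- rep(seq_len(nrow(sites)), reps)
  win <- sites[exp_idx]
  win[, wstart := as.integer(unlist(mapply(seq, kmin, kmax, SIMPLIFY = FALSE)) * step)]
  wt <- win[, .(n_sites = .N, m_a = sum(m_a), n_a = sum(n_a),
                m_b = sum(m_b), n_b = sum(n_b)),
            by = .(chrom, wstart)]
  wt <- wt[n_sites >= min_sites]
  if (!nrow(wt)) {
    setattr(empty, "windows", data.table())
    return(empty)
  }
  wt[, delta := m_a / n_a - m_b / n_b]
  wt[, p_value := two_prop_p(m_a, n_a, m_b, n_b)]
  wt[, q_value := p.adjust(p_value, method = "BH")]
  setorder(wt, chrom, wstart)
  win_table <- wt[, .(chrom, start = wstart, end = wstart + as.integer(window),
                      n_sites, delta, p_value, q_value)]

  sig <- wt[q_value <= alpha & abs(delta) >= delta_min]
  if (!nrow(sig)) {
    setattr(empty, "windows", win_table)
    return(empty)
  }
  sig[, wend := wstart + as.integer(window)]
  sig[, sgn := sign(delta)]
  sig[, new_run := {
    prev_end <- shift(wend); prev_chr <- shift(chrom); prev_sgn <- shift(sgn)
    as.integer(is.na(prev_end) | chrom != prev_chr | sgn != prev_sgn |
               wstart - prev_end > step)
  }]
  sig[, run := cumsum(new_run)]
  reg <- sig[, .(chrom = chrom[1], start = min(wstart), end = max(wend),
                 sgn = sgn[1], p_value = min(p_value), q_value = min(q_value)),
             by = run]

  out <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    r <- reg[i]
    spans <- if (refine)
      .refine_span(sites, r$chrom, r$start, r$end, delta_min, refine_bp)
    else data.table(start = r$start, end = r$end)
    out[[i]] <- rbindlist(lapply(seq_len(nrow(spans)), function(k) {
      pool <- .pool_span(sites, r$chrom, spans$start[k], spans$end[k])
      data.table(
        chrom = r$chrom, start = as.integer(spans$start[k]),
        end = as.integer(spans$end[k]), context = context,
        mean_a = pool$m_a / pool$n_a, mean_b = pool$m_b / pool$n_b,
        delta = pool$m_a / pool$n_a - pool$m_b / pool$n_b,
        n_sites = pool$n_sites, p_value = r$p_value, q_value = r$q_value)
    }))
  }
  res <- rbindlist(out)
  setorder(res, chrom, start)
  setattr(res, "windows", win_table)
  res[]
}

#' Annotate DMRs to promoter, gene-body or intergenic compartments
#'
#' A DMR overlapping (>= 1 bp) any strand-aware promoter (`promoter_bp`
#' upstream of a TSS) is `promoter`; otherwise overlap with any gene body
#' makes it `gene_body`; otherwise `intergenic`. Every DMR receives exactly
#' one category.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param genes gene table (0-based half-open).
#' @param promoter_bp promoter width upstream of the TSS (default 2000).
#' @return the DMR table with an `annotation` column.
#' @export
annotate_dmrs <- function(dmrs, genes, promoter_bp = 2000) {
  dmrs <- as.data.table(dmrs)
  genes <- .check_genes(genes)
  dmrs[, annotation := "intergenic"]
  if (!nrow(dmrs)) return(dmrs[])
  dgr <- granges0(dmrs$chrom, dmrs$start, dmrs$end)
  prom <- gene_regions(genes, flank = promoter_bp)[region == "upstream"]
  body <- genes
  in_body <- S4Vectors::queryHits(GenomicRanges::findOverlaps(
    dgr, granges0(body$chrom, body$start, body$end), ignore.strand = TRUE))
  dmrs[unique(in_body), annotation := "gene_body"]
  if (nrow(prom)) {
    in_prom <- S4Vectors::queryHits(GenomicRanges::findOverlaps(
      dgr, granges0(prom$chrom, prom$start, prom$end), ignore.strand = TRUE))
    dmrs[unique(in_prom), annotation := "promoter"]
  }
  dmrs[]
}

#' Per-gene summary of overlapping DMRs
#'
#' One row per gene whose promoter or gene body overlaps at least one DMR,
#' with counts per context and per direction of the methylation difference
#' (`hyper`: delta > 0, `hypo`: delta < 0).
#'
#' @inheritParams annotate_dmrs
#' @return data.table `gene_id`, `n_dmrs`, `CG`, `CHG`, `CHH`, `hyper`,
#'   `hypo`.
#' @export
dmr_gene_table <- function(dmrs, genes, promoter_bp = 2000) {
  dmrs <- as.data.table(dmrs)
  genes <- .check_genes(genes)
  empty <- data.table(gene_id = character(), n_dmrs = integer(),
                      CG = integer(), CHG = integer(), CHH = integer(),
                      hyper = integer(), hypo = integer())
  if (!nrow(dmrs)) return(empty)
  reg <- gene_regions(genes, flank = promoter_bp)[region %in% c("upstream", "body")]
  hits <- GenomicRanges::findOverlaps(
    granges0(dmrs$chrom, dmrs$start, dmrs$end),
    granges0(reg$chrom, reg$start, reg$end), ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  ov <- unique(data.table(dmr = S4Vectors::queryHits(hits),
                          gene_id = reg$gene_id[S4Vectors::subjectHits(hits)]))
  ov <- cbind(ov, dmrs[ov$dmr, .(context, delta)])
  tab <- ov[, .(n_dmrs = .N,
                CG = sum(context == "CG"), CHG = sum(context == "CHG"),
                CHH = sum(context == "CHH"),
                hyper = sum(delta > 0), hypo = sum(delta < 0)),
            by = gene_id]
  setorder(tab, gene_id)
  tab[]
}

#' Write DMRs as BED6+ text
#'
#' Columns: chrom, start, end, name (context), score (-log10 q, capped at
#' 1000), strand ("."), then mean_a, mean_b, delta, n_sites, annotation.
#'
#' @param dmrs annotated DMR table.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dmrs <- as.data.table(dmrs)
  if (!"annotation" %in% names(dmrs)) dmrs[, annotation := NA_character_]
  bed <- dmrs[, .(chrom, start, end, name = context,
                  score = round(pmin(-log10(pmax(q_value, 1e-300)), 1000), 3),
                  strand = ".", mean_a = round(mean_a, 6),
                  mean_b = round(mean_b, 6), delta = round(delta, 6),
                  n_sites, annotation)]
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
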