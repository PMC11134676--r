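# Independent oracles and small fixture builders used across the suite.

library(data.table)

# Brute-force cytosine context scanner: works directly on the sequence
# string with substring(), and derives the minus strand by classifying the
# Biostrings reverse complement and mapping coordinates back. Independent
# of the char-array logic in classify_contexts().
oracle_contexts <- function(seq_str, chrom = "chr") {
  classify_plus <- function(s) {
    n <- nchar(s)
    base <- substring(s, 1:n, 1:n)
    idx <- which(base == "C")
    if (!length(idx)) return(data.table())
    tri <- substring(s, idx, idx + 2)
    ctx <- vapply(tri, function(t) {
      if (nchar(t) < 3 || grepl("N", t)) return("ambiguous")
      if (substring(t, 2, 2) == "G") "CG"
      else if (substring(t, 3, 3) == "G") "CHG"
      else "CHH"
    }, character(1), USE.NAMES = FALSE)
    data.table(pos = idx - 1L, context = ctx)
  }
  n <- nchar(seq_str)
  plus <- classify_plus(seq_str)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_str)))
  minus <- classify_plus(rc)
  res <- rbind(
    if (nrow(plus)) data.table(chrom = chrom, pos = plus$pos, strand = "+",
                               context = plus$context),
    if (nrow(minus)) data.table(chrom = chrom, pos = n - 1L - minus$pos,
                                strand = "-", context = minus$context))
  setorder(res, chrom, pos, strand)
  res
}

random_seq <- function(n, with_n = FALSE, prob = c(0.3, 0.2, 0.2, 0.3)) {
  alph <- c("A", "C", "G", "T")
  s <- sample(alph, n, replace = TRUE, prob = prob)
  if (with_n) s[sample.int(n, max(1, n %/% 50))] <- "N"
  paste(s, collapse = "")
}

# Per-base re-computation of region levels: explicit coordinate tests per
# gene and region, no interval machinery.
oracle_region_levels <- function(calls, genes, flank, min_cov) {
  calls <- as.data.table(calls)
  agg <- calls[context %in% c("CG", "CHG", "CHH"),
               .(coverage = sum(coverage), methylated = sum(methylated)),
               by = .(chrom, pos, strand, context)]
  agg <- agg[coverage >= min_cov]
  out <- list()
  for (g in seq_len(nrow(genes))) {
    gi <- genes[g, ]
    bounds <- if (gi$strand == "+") list(
      upstream = c(gi$start - flank, gi$start),
      body = c(gi$start, gi$end),
      downstream = c(gi$end, gi$end + flank))
    else list(
      upstream = c(gi$end, gi$end + flank),
      body = c(gi$start, gi$end),
      downstream = c(gi$start - flank, gi$start))
    for (rg in names(bounds)) {
      lo <- max(bounds[[rg]][1], 0)
      hi <- bounds[[rg]][2]
      for (ctx in c("CG", "CHG", "CHH")) {
        s <- agg[chrom == gi$chrom & pos >= lo & pos < hi & context == ctx]
        out[[length(out) + 1L]] <- data.table(
          gene_id = gi$gene_id, region = rg, context = ctx,
          level = if (nrow(s)) sum(s$methylated) / sum(s$coverage) else NA_real_,
          n_sites = nrow(s))
      }
    }
  }
  res <- rbindlist(out)
  res[, region := factor(region, levels = c("upstream", "body", "downstream"))]
  setorder(res, gene_id, region, context)
  res[, region := as.character(region)]
  res[]
}

# Exhaustive maximum-score chain via bitmask enumeration (n <= 16):
# every subset is checked for strict monotonicity in both orientations
# with the rank-gap bound.
oracle_best_chain_score <- function(ra, rb, score, max_gap, min_len = 1) {
  n <- length(ra)
  stopifnot(n <= 16)
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    if (length(idx) < min_len) next
    o <- order(ra[idx])
    a <- ra[idx][o]; b <- rb[idx][o]
    if (any(diff(a) <= 0) || any(diff(a) > max_gap)) next
    ok_same <- all(diff(b) > 0) && all(diff(b) <= max_gap)
    ok_inv <- all(diff(b) < 0) && all(-diff(b) <= max_gap)
    if (ok_same || ok_inv) best <- max(best, sum(score[idx]))
  }
  best
}

# Small call-table builder: sites every `by` bp with one context, given
# per-position methylation proportion and fixed coverage (deterministic).
flat_calls <- function(from, to, by = 10, level = 0.5, cov = 20,
                       chrom = "chr1", context = "CG") {
  pos <- seq(from, to - 1, by = by)
  data.table(chrom = chrom, pos = as.integer(pos), strand = "+",
             context = context, coverage = cov,
             methylated = as.integer(round(level * cov)))
}

small_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                       start = 3000, end = 5000) {
  data.table(gene_id = gene_id, chrom = chrom, strand = strand,
             start = as.integer(start), end = as.integer(end))
}
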