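# Collinear-block chaining of homology anchors and allele pair calling.
#
# Anchors (best-homolog hits between the two haplotypes, with similarity
# scores) are chained per chromosome pair by a weighted longest-increasing
# -subsequence: chains must be strictly monotone in gene rank on both sides
# (decreasing on side B for inverted blocks) with bounded rank gaps. Genes
# inside a block are then matched one-to-one by descending score, the
# "best homolog" rule.

#' Attach chromosome and rank positions to an anchor table
#'
#' Gene rank is the 1-based order of the gene's start coordinate within its
#' chromosome.
#'
#' @param anchors data.frame with `gene_a`, `gene_b`, `score`.
#' @param genes_a,genes_b gene tables for the two haplotypes.
#' @return anchor table with `chrom_a`, `rank_a`, `chrom_b`, `rank_b` added.
#' @export
anchor_ranks <- function(anchors, genes_a, genes_b) {
  anchors <- as.data.table(anchors)
  need <- c("gene_a", "gene_b", "score")
  miss <- setdiff(need, names(anchors))
  if (length(miss)) stop("anchor table missing column(s): ", paste(miss, collapse = ", "))
  rank_tab <- function(genes) {
    g <- .check_genes(genes)
    setorder(g, chrom, start)
    g[, rank := seq_len(.N), by = chrom]
    g[, .(gene_id, chrom, rank)]
  }
  ra <- rank_tab(genes_a); rb <- rank_tab(genes_b)
  out <- merge(anchors, setnames(copy(ra), c("gene_a", "chrom_a", "rank_a")),
               by = "gene_a")
  out <- merge(out, setnames(copy(rb), c("gene_b", "chrom_b", "rank_b")),
               by = "gene_b")
  if (nrow(out) < nrow(anchors))
    stop(nrow(anchors) - nrow(out), " anchor(s) reference genes absent from the annotations")
  out[]
}

# Maximum-score chain by O(n^2) DP. Anchors must be pre-sorted by
# (rank_a, rank_b). Returns integer indices of the chain members, or
# integer(0).
.best_chain <- function(ra, rb, score, max_gap) {
  n <- length(ra)
  if (!n) return(integer())
  best <- score
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] < ra[i] && rb[j] < rb[i] &&
          ra[i] - ra[j] <= max_gap && rb[i] - rb[j] <= max_gap) {
        cand <- best[j] + score[i]
        if (cand > best[i]) { best[i] <- cand; prev[i] <- j }
      }
    }
  }
  end <- which.max(best)
  chain <- integer()
  while (end != 0L) { chain <- c(end, chain); end <- prev[end] }
  chain
}

#' Chain homology anchors into collinear blocks
#'
#' Within each chromosome pair, maximal-scoring chains are extracted
#' greedily by weighted longest-increasing-subsequence over anchor ranks;
#' both orientations are tried and each anchor may belong to at most one
#' block. Chains shorter than `min_anchors` are discarded; consecutive
#' chain members may differ by at most `max_gap` rank positions on either
#' side.
#'
#' @param anchors anchor table with `gene_a`, `gene_b`, `score` and either
#'   rank columns (`chrom_a`, `rank_a`, `chrom_b`, `rank_b`) or gene tables
#'   supplied via `genes_a`/`genes_b`.
#' @param genes_a,genes_b optional gene tables used to derive ranks.
#' @param min_anchors minimum anchors per block (default 5).
#' @param max_gap maximum rank gap between consecutive anchors (default 25).
#' @return list with `blocks` (block_id, chrom_a, chrom_b, orientation,
#'   n_anchors, score) and `anchors` (input rows plus `block_id`, `NA` for
#'   unassigned anchors).
#' @export
chain_anchors <- function(anchors, genes_a = NULL, genes_b = NULL,
                          min_anchors = 5, max_gap = 25) {
  anchors <- as.data.table(anchors)
  rank_cols <- c("chrom_a", "rank_a", "chrom_b", "rank_b")
  if (!all(rank_cols %in% names(anchors))) {
    if (is.null(genes_a) || is.null(genes_b))
      stop("anchors lack rank columns; supply genes_a and genes_b")
    anchors <- anchor_ranks(anchors, genes_a, genes_b)
  }
  if (any(anchors$score <= 0)) stop("anchor scores must be positive")
  # canonical order makes the result invariant to input row order
  setorder(anchors, chrom_a, chrom_b, rank_a, rank_b, gene_a, gene_b, score)
  anchors[, block_id := NA_integer_]
  anchors[, .row := seq_len(.N)]

  blocks <- list()
  bid <- 0L
  for (grp in split(seq_len(nrow(anchors)),
                    paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))) {
    avail <- grp
    repeat {
      if (length(avail) < min_anchors) break
      sub <- anchors[avail]
      fwd <- .best_chain(sub$rank_a, sub$rank_b, sub$score, max_gap)
      # inverted orientation: rank_b strictly decreasing; re-sort so that
      # negated rank_b is increasing alongside rank_a
      o <- order(sub$rank_a, -sub$rank_b)
      revc <- .best_chain(sub$rank_a[o], -sub$rank_b[o], sub$score[o], max_gap)
      revc <- o[revc]
      sf <- sum(sub$score[fwd]); sr <- sum(sub$score[revc])
      if (sf >= sr) { chain <- fwd; orient <- "same" } else { chain <- revc; orient <- "inverted" }
      if (length(chain) < min_anchors) break
      bid <- bid + 1L
      rows <- avail[chain]
      anchors[rows, block_id := bid]
      blocks[[bid]] <- data.table(
        block_id = bid, chrom_a = anchors$chrom_a[rows[1]],
        chrom_b = anchors$chrom_b[rows[1]], orientation = orient,
        n_anchors = length(rows), score = sum(anchors$score[rows]))
      avail <- setdiff(avail, rows)
    }
  }
  anchors[, .row := NULL]
  blocks <- if (length(blocks)) rbindlist(blocks) else
    data.table(block_id = integer(), chrom_a = character(),
               chrom_b = character(), orientation = character(),
               n_anchors = integer(), score = numeric())
  setorder(blocks, block_id)
  list(blocks = blocks[], anchors = anchors[])
}

#' Call one-to-one allelic gene pairs within collinear blocks
#'
#' Within each block, genes are paired with their highest-scoring in-block
#' anchor partner; ties are broken by smaller rank distance, then by
#' lexicographic gene id. One-to-one matching is enforced greedily in
#' descending score order; when a gene appears in several blocks the longer
#' block wins.
#'
#' @param chained result of [chain_anchors()], or its `anchors` component
#'   (an anchor table carrying `block_id`).
#' @return data.table `gene_a`, `gene_b`, `block_id`, `score`, one row per
#'   pair; each gene occurs at most once.
#' @export
call_allele_pairs <- function(chained) {
  anchors <- if (is.list(chained) && !is.data.frame(chained)) chained$anchors else chained
  anchors <- as.data.table(anchors)
  if (!"block_id" %in% names(anchors))
    stop("anchors carry no block_id; run chain_anchors() first")
  memb <- anchors[!is.na(block_id)]
  if (!nrow(memb))
    return(data.table(gene_a = character(), gene_b = character(),
                      block_id = integer(), score = numeric()))
  memb[, block_size := .N, by = block_id]
  memb[, rank_dist := abs(rank_a - rank_b)]
  setorder(memb, -block_size, block_id, -score, rank_dist, gene_a, gene_b)
  used_a <- new.env(hash = TRUE); used_b <- new.env(hash = TRUE)
  keep <- logical(nrow(memb))
  for (i in seq_len(nrow(memb))) {
    ga <- memb$gene_a[i]; gb <- memb$gene_b[i]
    if (is.null(used_a[[ga]]) && is.null(used_b[[gb]])) {
      keep[i] <- TRUE
      used_a[[ga]] <- TRUE; used_b[[gb]] <- TRUE
    }
  }
  pairs <- memb[keep, .(gene_a, gene_b, block_id, score)]
  setorder(pairs, gene_a)
  pairs[]
}

#' Percentage of allele pairs expressed in a tissue
#'
#' @param expressed number of expressed pairs.
#' @param total total number of allele pairs.
#' @return `100 * expressed / total`, rounded to 2 decimals.
#' @examples
#' pair_expression_coverage(8099, 22034) # 36.76
#' @export
pair_expression_coverage <- function(expressed, total) {
  stopifnot_scalar_count(expressed, "expressed")
  stopifnot_scalar_count(total, "total")
  if (total == 0) stop("total must be positive")
  if (expressed > total) stop("expressed cannot exceed total")
  round(100 * expressed / total, 2)
}
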