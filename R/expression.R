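# TPM filtering and allelic differential expression.
#
# Two filters precede any allelic comparison: genes with mean TPM 0 in
# every tissue are discarded as non-expressed, and genes whose replicates
# disagree by 50% or more -- (max - min) / mean >= 0.5 within any expressed
# tissue -- are dropped as irreproducible. Allelic pairs with a greater
# than two-fold difference in mean TPM are called differentially expressed.

.check_expr <- function(expr) {
  expr <- as.data.table(expr)
  need <- c("gene_id", "tissue", "replicate", "tpm")
  miss <- setdiff(need, names(expr))
  if (length(miss)) stop("expression table missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(expr$tpm)) stop("missing TPM values in expression table")
  if (any(expr$tpm < 0)) stop("negative TPM values in expression table")
  if (!nrow(expr)) return(expr)
  cnt <- expr[, .N, by = .(gene_id, tissue)]
  if (length(unique(cnt$N)) != 1L)
    stop("unbalanced replicates: every gene must have the same replicate count in every tissue")
  if (cnt$N[1] < 2L) stop("at least 2 replicates per tissue are required")
  expr
}

#' Filter genes by expression and replicate consistency
#'
#' Two rules, applied in order. Rule 2 (non-expression): genes whose mean
#' TPM is 0 in every tissue are discarded and flagged non-expressed.
#' Rule 1 (replicate consistency): for each remaining gene, in every tissue
#' with positive mean the statistic `d = (max - min) / mean` over the
#' replicates must be below `max_rep_diff`; genes violating it in any
#' expressed tissue are dropped.
#'
#' @param expr long expression table (`gene_id`, `tissue`, `replicate`,
#'   `tpm`), complete and balanced.
#' @param max_rep_diff replicate disagreement bound (default 0.5, i.e. a
#'   50% difference).
#' @return list with `retained` (character vector of gene ids) and `report`
#'   (per-gene `nonexpressed`, `max_d`, `retained`, `reason`).
#' @export
filter_genes <- function(expr, max_rep_diff = 0.5) {
  expr <- .check_expr(expr)
  per <- expr[, .(mean = mean(tpm), max = max(tpm), min = min(tpm)),
              by = .(gene_id, tissue)]
  per[, d := fifelse(mean > 0, (max - min) / mean, NA_real_)]
  rep_gene <- per[, .(
    nonexpressed = all(mean == 0),
    max_d = if (all(mean == 0)) NA_real_ else max(d, na.rm = TRUE)),
    by = gene_id]
  rep_gene[, retained := !nonexpressed & max_d < max_rep_diff]
  rep_gene[, reason := fifelse(nonexpressed, "nonexpressed",
                        fifelse(retained, "retained", "replicate_inconsistent"))]
  setorder(rep_gene, gene_id)
  list(retained = rep_gene[retained == TRUE, gene_id], report = rep_gene[])
}

#' Call allelic differential expression for one tissue
#'
#' For each allele pair, mean TPM per allele is computed over replicates of
#' the requested tissue. The fold change is
#' `r = (max + pseudo) / (min + pseudo)`; pairs with `r > fold` are classed
#' `A_high` or `B_high` by which allele is higher, pairs with both means 0
#' are `not_expressed`, and everything else is `balanced`. A pair counts as
#' expressed when at least one allele mean exceeds `expressed_min`.
#'
#' @param pairs allele pair table (`gene_a`, `gene_b`) from
#'   [call_allele_pairs()].
#' @param expr long expression table, typically restricted to genes
#'   retained by [filter_genes()].
#' @param tissue tissue label to compare.
#' @param fold fold-change threshold (default 2; calls require `r > fold`).
#' @param pseudo pseudocount stabilising ratios at low expression
#'   (default 0.1 TPM).
#' @param expressed_min expression floor for the expressed-pair count
#'   (default 0: any positive mean counts).
#' @return data.table `gene_a`, `gene_b`, `tissue`, `mean_a`, `mean_b`,
#'   `log2_ratio` (A over B, pseudocounted), `ratio` (max over min),
#'   `class`, `expressed`; attribute `coverage` lists the number of scored
#'   and expressed pairs and their percentage
#'   (via [pair_expression_coverage()]).
#' @export
call_allelic_de <- function(pairs, expr, tissue, fold = 2, pseudo = 0.1,
                            expressed_min = 0) {
  pairs <- as.data.table(pairs)
  if (!all(c("gene_a", "gene_b") %in% names(pairs)))
    stop("pairs must have gene_a and gene_b columns")
  expr <- .check_expr(expr)
  if (!tissue %in% expr$tissue)
    stop("tissue '", tissue, "' absent from expression table")
  tis <- tissue
  mt <- expr[tissue == tis, .(mean_tpm = mean(tpm)), by = gene_id]
  dt <- pairs[, .(gene_a, gene_b)]
  dt[, mean_a := mt$mean_tpm[match(gene_a, mt$gene_id)]]
  dt[, mean_b := mt$mean_tpm[match(gene_b, mt$gene_id)]]
  n_missing <- sum(is.na(dt$mean_a) | is.na(dt$mean_b))
  if (n_missing)
    message(n_missing, " pair(s) dropped: allele absent from the (filtered) expression table")
  dt <- dt[!is.na(mean_a) & !is.na(mean_b)]
  dt[, tissue := tis]
  dt[, log2_ratio := log2((mean_a + pseudo) / (mean_b + pseudo))]
  dt[, ratio := (pmax(mean_a, mean_b) + pseudo) / (pmin(mean_a, mean_b) + pseudo)]
  dt[, expressed := pmax(mean_a, mean_b) > expressed_min]
  dt[, class := fifelse(mean_a == 0 & mean_b == 0, "not_expressed",
               fifelse(ratio > fold & mean_a > mean_b, "A_high",
               fifelse(ratio > fold & mean_b > mean_a, "B_high", "balanced")))]
  setcolorder(dt, c("gene_a", "gene_b", "tissue"))
  setorder(dt, gene_a)
  n_expr <- sum(dt$expressed)
  cov <- list(n_pairs = nrow(dt), n_expressed = n_expr,
              pct_expressed = if (nrow(dt)) pair_expression_coverage(n_expr, nrow(dt)) else NA_real_)
  setattr(dt, "coverage", cov)
  dt[]
}
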