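# Joint analysis of allelic expression classes and methylation levels,
# plus the per-haplotype assembly metric report.

#' Join allelic expression calls with per-allele methylation levels
#'
#' For every differentially expressed pair (class `A_high` or `B_high`),
#' region/context methylation levels of the higher- and lower-expressed
#' allele are put side by side. The summary reports, per tissue x region x
#' context: the mean level on each side, a paired one-sided Wilcoxon
#' signed-rank p-value for "higher-expressed allele is less methylated"
#' (level_high < level_low), and the Spearman correlation between the
#' per-pair log2 expression ratio (high over low) and the methylation
#' difference (level_high - level_low). Pairs missing a level in a given
#' region/context cell are dropped from that cell only.
#'
#' @param de_calls output of [call_allelic_de()] (one or more tissues
#'   row-bound).
#' @param levels_a,levels_b region-level tables from [region_levels()] for
#'   haplotype A and B genes. For multi-tissue calls, pass lists named by
#'   tissue.
#' @return list with `records` (per pair x region x context) and `summary`
#'   (per tissue x region x context with `n_pairs`, `mean_high`,
#'   `mean_low`, `wilcox_p`, `spearman_rho`, `spearman_p`).
#' @export
integrate_methylation_expression <- function(de_calls, levels_a, levels_b) {
  de <- as.data.table(de_calls)[class %in% c("A_high", "B_high")]
  lv <- function(x, tis) {
    if (is.data.frame(x)) as.data.table(x)
    else if (is.list(x)) as.data.table(x[[tis]])
    else stop("levels must be a data.frame or a list of data.frames by tissue")
  }
  empty_records <- data.table(
    gene_a = character(), gene_b = character(), tissue = character(),
    class = character(), log2_high_low = numeric(), region = character(),
    context = character(), level_high = numeric(), level_low = numeric())
  empty_summary <- data.table(
    tissue = character(), region = character(), context = character(),
    n_pairs = integer(), mean_high = numeric(), mean_low = numeric(),
    wilcox_p = numeric(), spearman_rho = numeric(), spearman_p = numeric())
  if (!nrow(de)) {
    warning("no differentially expressed pairs; empty integration summary")
    return(list(records = empty_records, summary = empty_summary))
  }
  recs <- rbindlist(lapply(split(de, de$tissue), function(d) {
    tis <- d$tissue[1]
    la <- lv(levels_a, tis)[, .(gene = gene_id, region, context, level)]
    lb <- lv(levels_b, tis)[, .(gene = gene_id, region, context, level)]
    d <- d[, .(gene_a, gene_b, tissue, class,
               gene_high = fifelse(class == "A_high", gene_a, gene_b),
               gene_low  = fifelse(class == "A_high", gene_b, gene_a),
               log2_high_low = abs(log2_ratio))]
    both <- rbind(la, lb)
    m <- merge(d, setnames(copy(both), "level", "level_high"),
               by.x = "gene_high", by.y = "gene", allow.cartesian = TRUE)
    m <- merge(m, setnames(copy(both), "level", "level_low"),
               by.x = c("gene_low", "region", "context"),
               by.y = c("gene", "region", "context"), all.x = TRUE)
    m[, c("gene_high", "gene_low") := NULL]
    m
  }))
  records <- recs[!is.na(level_high) & !is.na(level_low)]
  setorder(records, tissue, region, context, gene_a)

  summarise_cell <- function(h, l, r) {
    wp <- tryCatch({
      if (all(h == l)) 1
      else suppressWarnings(wilcox.test(h, l, paired = TRUE,
                                        alternative = "less")$p.value)
    }, error = function(e) NA_real_)
    sp <- tryCatch({
      d <- h - l
      if (length(r) < 3 || length(unique(r)) < 2 || length(unique(d)) < 2)
        list(rho = NA_real_, p = NA_real_)
      else {
        ct <- suppressWarnings(cor.test(r, d, method = "spearman", exact = FALSE))
        list(rho = unname(ct$estimate), p = ct$p.value)
      }
    }, error = function(e) list(rho = NA_real_, p = NA_real_))
    list(n_pairs = length(h), mean_high = mean(h), mean_low = mean(l),
         wilcox_p = wp, spearman_rho = sp$rho, spearman_p = sp$p)
  }
  summary <- records[, summarise_cell(level_high, level_low, log2_high_low),
                     by = .(tissue, region, context)]
  setorder(summary, tissue, region, context)
  list(records = records[], summary = summary[])
}

#' Cross-haplotype assembly/annotation metric report
#'
#' Per metric, reports the value of each haplotype and their arithmetic
#' mean to 3 decimals -- the usual way headline assembly statistics (contig
#' and scaffold N50, gene counts, BUSCO completeness) of a pair of
#' haplotype assemblies are summarised.
#'
#' @param metrics_a,metrics_b named numeric vectors with identical names.
#' @return data.table `metric`, `hap_a`, `hap_b`, `mean`.
#' @examples
#' summarize_haplotype_metrics(c(contig_n50_mb = 15.08),
#'                             c(contig_n50_mb = 9.77))
#' @export
summarize_haplotype_metrics <- function(metrics_a, metrics_b) {
  if (is.null(names(metrics_a)) || is.null(names(metrics_b)))
    stop("metrics must be named numeric vectors")
  if (!setequal(names(metrics_a), names(metrics_b)) ||
      length(metrics_a) != length(metrics_b))
    stop("metric names differ between haplotypes")
  metrics_b <- metrics_b[names(metrics_a)]
  data.table(metric = names(metrics_a),
             hap_a = unname(metrics_a), hap_b = unname(metrics_b),
             mean = round((unname(metrics_a) + unname(metrics_b)) / 2, 3))
}
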