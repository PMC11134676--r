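# Benchmark configurations shared by the acceptance-style checks: each one
# states the study conditions for one property (null calibration, planted
# DMR recovery, planted DE recovery, methylation-expression coupling).

flat_tissue_means <- function() {
  data.table::CJ(haplotype = c("hapA", "hapB"), tissue = c("flower", "leaf"),
                 context = c("CG", "CHG", "CHH"))[
    , mean := c(CG = 0.45, CHG = 0.2, CHH = 0.3)[context]][]
}

null_dmr_config <- function(seed) {
  simulation_config(seed = seed, n_chroms = 2, chrom_len = 500000,
                    n_genes = 20, context_means = flat_tissue_means(),
                    dmr_spec = list(), meth_rho = 0, de_fraction = 0,
                    nonexpressed_fraction = 0)
}

dmr_recovery_config <- function(seed) {
  simulation_config(seed = seed, n_chroms = 2, chrom_len = 300000,
                    n_genes = 10, context_means = flat_tissue_means(),
                    coverage_mean = 30, de_fraction = 0,
                    nonexpressed_fraction = 0,
                    dmr_spec = list(list(haplotype = "hapA",
                                         sample_a = "flower",
                                         sample_b = "leaf",
                                         n = 50, length = 1000, delta = 0.3)))
}

de_recovery_config <- function(seed) {
  simulation_config(seed = seed, n_genes = 200, n_chroms = 2,
                    chrom_len = 300000, gene_len_range = c(500, 1000),
                    flank = 500, de_fraction = 0.2, tpm_sigma = 0.2,
                    dmr_spec = list())
}

integration_config <- function(seed, slope = -6) {
  simulation_config(seed = seed, n_genes = 200, n_chroms = 2,
                    chrom_len = 400000, gene_len_range = c(800, 1500),
                    flank = 1000, de_fraction = 0.4, meth_expr_slope = slope,
                    dmr_spec = list())
}

# reciprocal-overlap recovery and base-level precision of a called DMR set
# against planted truth
dmr_benchmark <- function(called, planted) {
  recip <- function(ps, pe, cs, ce) {
    ov <- pmax(0, pmin(pe, ce) - pmax(ps, cs))
    ov >= 0.5 * (pe - ps) & ov >= 0.5 * (ce - cs)
  }
  rec <- vapply(seq_len(nrow(planted)), function(i)
    any(called$chrom == planted$chrom[i] &
          recip(planted$start[i], planted$end[i], called$start, called$end)),
    logical(1))
  outside <- 0; total <- 0
  for (i in seq_len(nrow(called))) {
    p <- planted[planted$chrom == called$chrom[i], ]
    ov <- sum(pmax(0, pmin(called$end[i], p$end) - pmax(called$start[i], p$start)))
    total <- total + (called$end[i] - called$start[i])
    outside <- outside + (called$end[i] - called$start[i]) - ov
  }
  list(n_recovered = sum(rec), n_planted = nrow(planted),
       outside = outside, called_bases = total)
}

# run the allele-pairing + filtering + DE-calling chain on a bundle
de_benchmark <- function(bundle, tissue = "flower") {
  pairs <- call_allele_pairs(chain_anchors(bundle$anchors, bundle$genes$hapA,
                                           bundle$genes$hapB))
  flt <- filter_genes(bundle$expression)
  kept <- bundle$expression[bundle$expression$gene_id %in% flt$retained, ]
  de <- suppressMessages(call_allelic_de(pairs, kept, tissue))
  truth <- bundle$truth$planted_de_pairs
  m <- merge(de, truth, by = c("gene_a", "gene_b"))
  others <- de[!paste(de$gene_a, de$gene_b) %in%
                 paste(truth$gene_a, truth$gene_b), ]
  list(hits = sum(m$class == m$direction), scored = nrow(m),
       planted = nrow(truth),
       false = sum(others$class %in% c("A_high", "B_high")),
       nonde = nrow(others))
}

# full methylation x expression chain on a bundle; returns the record and
# summary tables of the integration stage
integration_benchmark <- function(bundle) {
  cfg <- bundle$config
  pairs <- call_allele_pairs(chain_anchors(bundle$anchors, bundle$genes$hapA,
                                           bundle$genes$hapB))
  flt <- filter_genes(bundle$expression)
  kept <- bundle$expression[bundle$expression$gene_id %in% flt$retained, ]
  de <- rbind(suppressMessages(call_allelic_de(pairs, kept, "flower")),
              suppressMessages(call_allelic_de(pairs, kept, "leaf")))
  lv <- function(h) lapply(setNames(cfg$tissues, cfg$tissues), function(tis)
    region_levels(bundle$calls[[h]][[tis]], bundle$genes[[h]],
                  flank = cfg$flank, min_cov = 4))
  integrate_methylation_expression(de, lv("hapA"), lv("hapB"))
}

# simulate a small dataset on disk and build a matching pipeline config
pipeline_fixture <- function(seed = 1, root = tempfile("pipe")) {
  datadir <- file.path(root, "data")
  cfg <- simulation_config(seed = seed, n_genes = 16, n_chroms = 1,
                           chrom_len = 120000, gene_len_range = c(800, 1500),
                           flank = 1200, dmr_margin = 300)
  simulate_dataset(cfg, outdir = datadir)
  list(
    root = root,
    config = list(
      seed = seed, outdir = file.path(root, "out"),
      inputs = list(
        genome_hapA = file.path(datadir, "genome_hapA.fa"),
        genome_hapB = file.path(datadir, "genome_hapB.fa"),
        genes_hapA = file.path(datadir, "genes_hapA.gff3"),
        genes_hapB = file.path(datadir, "genes_hapB.gff3"),
        calls = list(
          hapA = list(flower = file.path(datadir, "calls_hapA_flower.tsv"),
                      leaf = file.path(datadir, "calls_hapA_leaf.tsv")),
          hapB = list(flower = file.path(datadir, "calls_hapB_flower.tsv"),
                      leaf = file.path(datadir, "calls_hapB_leaf.tsv"))),
        expression = file.path(datadir, "expression.tsv"),
        anchors = file.path(datadir, "anchors.tsv")),
      params = list(flank = 1200, promoter_bp = 1200,
                    dmr = list(contexts = c("CG", "CHH")))))
}

pooled_spearman <- function(records, reg, ctx = "CG") {
  r <- records[records$region == reg & records$context == ctx, ]
  ct <- suppressWarnings(cor.test(r$log2_high_low, r$level_high - r$level_low,
                                  method = "spearman", exact = FALSE))
  list(n = nrow(r), rho = unname(ct$estimate), p = ct$p.value)
}
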