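small_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_genes = 12, n_chroms = 1,
                    chrom_len = 90000, gene_len_range = c(800, 1500),
                    flank = 1200, dmr_margin = 300, ...)
}

test_that("a fixed seed reproduces every output file byte for byte", {
  d1 <- file.path(tempdir(), "sim_run1"); d2 <- file.path(tempdir(), "sim_run2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_dataset(small_cfg(seed = 42), outdir = d1)
  simulate_dataset(small_cfg(seed = 42), outdir = d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("realized pooled context levels track the configured means and ordering", {
  cfg <- small_cfg(seed = 8, dmr_spec = list(), de_fraction = 0,
                   nonexpressed_fraction = 0)
  b <- simulate_dataset(cfg)
  cm <- cfg$context_means
  for (h in c("hapA", "hapB")) for (tis in cfg$tissues) {
    cl <- b$calls[[h]][[tis]]
    realized <- cl[, .(lvl = sum(methylated) / sum(coverage),
                       n = sum(coverage)), by = context]
    expect_true(all(realized[order(-lvl)]$context == c("CG", "CHH", "CHG")))
    for (ctx in c("CG", "CHH", "CHG")) {
      mu <- cm[cm$haplotype == h & cm$tissue == tis & cm$context == ctx, ]$mean
      r <- realized[realized$context == ctx, ]
      # within 3 binomial SE plus the per-gene offset spread
      tol <- 3 * sqrt(mu * (1 - mu) / r$n) + 0.02
      expect_lt(abs(r$lvl - mu), tol)
    }
  }
})

test_that("zero effect sizes give an empty truth table", {
  b <- simulate_dataset(small_cfg(seed = 3, dmr_spec = list(), de_fraction = 0))
  expect_equal(nrow(b$truth$planted_dmrs), 0L)
  expect_equal(nrow(b$truth$planted_de_pairs), 0L)
})

test_that("the truth bundle round-trips through TSV losslessly", {
  b <- simulate_dataset(small_cfg(seed = 9))
  d <- file.path(tempdir(), "truth_rt")
  unlink(d, recursive = TRUE)
  write_truth(b$truth, d)
  back <- read_truth(d)
  expect_equal(as.data.frame(back$planted_dmrs),
               as.data.frame(b$truth$planted_dmrs))
  expect_equal(as.data.frame(back$planted_de_pairs),
               as.data.frame(b$truth$planted_de_pairs))
  expect_equal(as.data.frame(back$gene_levels),
               as.data.frame(b$truth$gene_levels))
  expect_equal(nrow(b$truth$planted_dmrs), 16L) # default: 8 per haplotype
  # empty truth gives header-only files that still read back
  b0 <- simulate_dataset(small_cfg(seed = 3, dmr_spec = list(), de_fraction = 0))
  d0 <- file.path(tempdir(), "truth_rt0")
  unlink(d0, recursive = TRUE)
  write_truth(b0$truth, d0)
  expect_equal(nrow(read_truth(d0)$planted_dmrs), 0L)
  unlink(c(d, d0), recursive = TRUE)
})

test_that("annotation, expression table and anchors are mutually consistent", {
  b <- simulate_dataset(small_cfg(seed = 2))
  all_genes <- c(b$genes$hapA$gene_id, b$genes$hapB$gene_id)
  expect_setequal(unique(b$expression$gene_id), all_genes)
  expect_true(all(b$truth$planted_de_pairs$gene_a %in% b$anchors$gene_a))
  # every planted DMR lies within a simulated chromosome
  pd <- b$truth$planted_dmrs
  expect_true(all(pd$start >= 0 & pd$end <= b$config$chrom_len))
  # gene ids in the GFF3 written to disk match the in-memory table
  d <- file.path(tempdir(), "sim_gff")
  unlink(d, recursive = TRUE)
  simulate_dataset(small_cfg(seed = 2), outdir = d)
  g <- read_genes(file.path(d, "genes_hapA.gff3"))
  expect_equal(as.data.frame(g[, c("gene_id", "chrom", "strand", "start", "end")]),
               as.data.frame(b$genes$hapA[, c("gene_id", "chrom", "strand",
                                              "start", "end")]))
  unlink(d, recursive = TRUE)
})

test_that("sites in written call files agree with the genome contexts", {
  d <- file.path(tempdir(), "sim_ctx")
  unlink(d, recursive = TRUE)
  b <- simulate_dataset(small_cfg(seed = 13), outdir = d)
  sites <- classify_contexts(file.path(d, "genome_hapA.fa"))
  got <- load_calls(file.path(d, "calls_hapA_flower.tsv"), sites)
  expect_equal(attr(got, "n_rejected"), 0L)
  unlink(d, recursive = TRUE)
})

test_that("planted DMRs realize their configured delta at 30x coverage", {
  cfg <- simulation_config(seed = 21, n_genes = 6, n_chroms = 1,
                           chrom_len = 120000, gene_len_range = c(800, 1200),
                           flank = 1000, coverage_mean = 30,
                           dmr_spec = list(list(haplotype = "hapA",
                                                sample_a = "flower",
                                                sample_b = "leaf",
                                                n = 10, length = 1000,
                                                delta = 0.3)),
                           context_means = data.table::CJ(
                             haplotype = c("hapA", "hapB"),
                             tissue = c("flower", "leaf"),
                             context = c("CG", "CHG", "CHH"))[
                               , mean := c(CG = 0.5, CHG = 0.2, CHH = 0.3)[context]][])
  b <- simulate_dataset(cfg)
  pd <- b$truth$planted_dmrs
  fl <- b$calls$hapA$flower; lf <- b$calls$hapA$leaf
  for (i in seq_len(nrow(pd))) {
    sa <- fl[fl$chrom == pd$chrom[i] & fl$pos >= pd$start[i] & fl$pos < pd$end[i], ]
    sb <- lf[lf$chrom == pd$chrom[i] & lf$pos >= pd$start[i] & lf$pos < pd$end[i], ]
    realized <- sum(sa$methylated) / sum(sa$coverage) -
      sum(sb$methylated) / sum(sb$coverage)
    expect_lt(abs(realized - 0.3), 0.05)
  }
})

test_that("planted gene-body levels are recovered by region_levels", {
  cfg <- small_cfg(seed = 31, coverage_mean = 30)
  b <- simulate_dataset(cfg)
  lv <- region_levels(b$calls$hapA$flower, b$genes$hapA, flank = cfg$flank,
                      min_cov = 4)
  truth <- b$truth$gene_levels
  tr <- truth[truth$haplotype == "hapA" & truth$tissue == "flower", ]
  m <- merge(lv, tr, by = c("gene_id", "region", "context"))
  m <- m[!is.na(m$level) & m$n_sites >= 20, ]
  expect_gt(nrow(m), 50)
  expect_lt(max(abs(m$level - m$mu)), 0.08)
  expect_lt(mean(abs(m$level - m$mu)), 0.03)
})

test_that("invalid configurations are refused", {
  expect_error(simulation_config(n_genes = 0), "configuration error")
  expect_error(simulation_config(de_fraction = 1.5), "configuration error")
  expect_error(simulation_config(n_genes = 500, chrom_len = 100000),
               "configuration error")
  expect_error(simulation_config(gene_len_range = c(2000, 1000)),
               "configuration error")
})
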