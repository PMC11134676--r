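test_that("region level is the pooled-count ratio over qualifying sites", {
  gene <- small_gene(start = 3000, end = 5000, strand = "+")
  calls <- data.table::data.table(
    chrom = "chr1", pos = c(3100L, 3200L), strand = "+", context = "CG",
    coverage = c(10, 10), methylated = c(3, 2))
  lv <- region_levels(calls, gene, flank = 2000, min_cov = 4)
  expect_equal(lv[lv$region == "body" & lv$context == "CG", ]$level, 0.25)
  expect_equal(lv[lv$region == "body" & lv$context == "CG", ]$n_sites, 2L)
  # upstream has no covered sites: missing level, n_sites = 0
  up <- lv[lv$region == "upstream" & lv$context == "CG", ]
  expect_true(is.na(up$level))
  expect_equal(up$n_sites, 0L)
})

test_that("upstream is strand-oriented and flanks truncate at chromosome ends", {
  gene <- small_gene(start = 1000, end = 2000, strand = "-")
  # on a minus-strand gene the upstream flank lies to the right of the gene
  calls <- data.table::data.table(
    chrom = "chr1", pos = c(2500L, 500L), strand = "+", context = "CHH",
    coverage = 10, methylated = c(8, 2))
  lv <- region_levels(calls, gene, flank = 2000, min_cov = 1)
  expect_equal(lv[lv$region == "upstream" & lv$context == "CHH", ]$level, 0.8)
  expect_equal(lv[lv$region == "downstream" & lv$context == "CHH", ]$level, 0.2)
  # truncation: downstream flank would span [-1000, 1000) -> clipped at 0
  lv2 <- region_levels(calls, gene, flank = 2000, min_cov = 1,
                       chrom_lens = c(chr1 = 2600))
  expect_equal(lv2[lv2$region == "upstream" & lv2$context == "CHH", ]$level, 0.8)
})

test_that("levels are invariant to splitting a site's reads across rows", {
  set.seed(21)
  genes <- small_gene(start = 2000, end = 4000)
  calls <- flat_calls(0, 6000, by = 37, level = 0.4, cov = 12)
  split1 <- calls[, .(chrom, pos, strand, context,
                      coverage = 5L, methylated = pmin(methylated, 5L))]
  split2 <- calls[, .(chrom, pos, strand, context,
                      coverage = coverage - 5L,
                      methylated = methylated - pmin(methylated, 5L))]
  a <- region_levels(calls, genes, min_cov = 6)
  b <- region_levels(rbind(split1, split2), genes, min_cov = 6)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("region levels match a per-base brute-force recomputation", {
  set.seed(5)
  genes <- data.table::data.table(
    gene_id = paste0("g", 1:4), chrom = "chr1",
    strand = c("+", "-", "+", "-"),
    start = c(1000L, 4000L, 6500L, 8200L),
    end = c(2200L, 5100L, 7400L, 9100L))
  pos <- sort(sample(0:9999, 900))
  calls <- data.table::data.table(
    chrom = "chr1", pos = pos,
    strand = sample(c("+", "-"), 900, TRUE),
    context = sample(c("CG", "CHG", "CHH"), 900, TRUE),
    coverage = rpois(900, 8))
  calls[, methylated := rbinom(.N, coverage, 0.3)]
  got <- region_levels(calls, genes, flank = 1500, min_cov = 4)
  exp <- oracle_region_levels(calls, genes, flank = 1500, min_cov = 4)
  expect_equal(got$level, exp$level, tolerance = 1e-12)
  expect_equal(got$n_sites, exp$n_sites)
})

test_that("a flat methylome gives a flat metaprofile", {
  genes <- rbind(small_gene("g1", start = 3000, end = 5000, strand = "+"),
                 small_gene("g2", start = 9000, end = 12000, strand = "-"))
  calls <- flat_calls(0, 15000, by = 13, level = 0.5, cov = 10)
  mp <- metaprofile(calls, genes, flank = 2000, flank_bins = 10, body_bins = 20)
  cg <- mp[mp$context == "CG" & mp$n_genes > 0, ]
  expect_true(nrow(cg) > 0)
  expect_true(all(abs(cg$mean_level - 0.5) < 1e-12))
  expect_equal(nrow(mp[mp$context == "CG", ]), 40L)
})

test_that("bins without data report zero contributing genes", {
  genes <- small_gene(start = 5000, end = 7000, strand = "+")
  calls <- flat_calls(3000, 5000, by = 10)     # upstream flank only
  mp <- metaprofile(calls, genes, flank = 2000, flank_bins = 5, body_bins = 10)
  cg <- mp[mp$context == "CG", ]
  expect_true(all(cg$n_genes[cg$bin < 5] == 1L))
  expect_true(all(cg$n_genes[cg$bin >= 5] == 0L))
  expect_true(all(is.na(cg$mean_level[cg$bin >= 5])))
})

test_that("metaprofile resolves a planted flank/body methylation step", {
  genes <- rbind(small_gene("g1", start = 4000, end = 6000, strand = "+"),
                 small_gene("g2", start = 14000, end = 16500, strand = "-"))
  mk <- function(g) {
    body <- flat_calls(g$start, g$end, by = 8, level = 0.6, cov = 50)
    up <- if (g$strand == "+") flat_calls(g$start - 2000, g$start, by = 8,
                                          level = 0.2, cov = 50)
          else flat_calls(g$end, g$end + 2000, by = 8, level = 0.2, cov = 50)
    dn <- if (g$strand == "+") flat_calls(g$end, g$end + 2000, by = 8,
                                          level = 0.2, cov = 50)
          else flat_calls(g$start - 2000, g$start, by = 8, level = 0.2, cov = 50)
    rbind(body, up, dn)
  }
  calls <- rbind(mk(genes[1, ]), mk(genes[2, ]))
  mp <- metaprofile(calls, genes, flank = 2000, flank_bins = 10, body_bins = 20)
  cg <- mp[mp$context == "CG", ]
  expect_true(all(abs(cg$mean_level[cg$zone == "body"] - 0.6) < 0.05))
  expect_true(all(abs(cg$mean_level[cg$zone != "body"] - 0.2) < 0.05))
})

test_that("minus-strand genes are reversed so bin 0 is farthest upstream", {
  gene <- small_gene(start = 5000, end = 7000, strand = "-")
  # a single site 1900 bp 5' of the TSS (TSS at end-1 on minus strand)
  calls <- data.table::data.table(chrom = "chr1", pos = 8900L, strand = "+",
                                  context = "CG", coverage = 10, methylated = 10)
  mp <- metaprofile(calls, gene, flank = 2000, flank_bins = 10, body_bins = 10)
  hit <- mp[mp$n_genes > 0 & mp$context == "CG", ]
  expect_equal(hit$bin, 0L)
  expect_equal(hit$zone, "upstream")
})
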