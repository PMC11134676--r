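test_that("identical samples yield zero DMRs", {
  calls <- flat_calls(0, 20000, by = 15, level = 0.4, cov = 20)
  d <- call_dmrs(calls, calls, context = "CG")
  expect_equal(nrow(d), 0L)
})

test_that("window two-proportion p-values match stats::prop.test", {
  set.seed(9)
  for (i in 1:20) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    m1 <- rbinom(1, n1, 0.4); m2 <- rbinom(1, n2, 0.5)
    ours <- allelomethyl:::two_prop_p(m1, n1, m2, n2)
    ref <- suppressWarnings(prop.test(c(m1, m2), c(n1, n2)))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  # zero pooled variance convention
  expect_equal(allelomethyl:::two_prop_p(0, 10, 0, 12), 1)
  expect_equal(allelomethyl:::two_prop_p(10, 10, 12, 12), 1)
})

test_that("a planted methylation step is recovered with refined boundaries", {
  a <- flat_calls(0, 20000, by = 10, level = 0.2, cov = 50)
  a[pos >= 8000 & pos < 11000, methylated := as.integer(round(0.8 * coverage))]
  b <- flat_calls(0, 20000, by = 10, level = 0.2, cov = 50)
  d <- call_dmrs(a, b, context = "CG")
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$start - 8000), 150)
  expect_lt(abs(d$end - 11000), 150)
  expect_gt(d$delta, 0.5)
  expect_lt(d$q_value, 0.05)
  # direction flips with the sample order
  d2 <- call_dmrs(b, a, context = "CG")
  expect_lt(d2$delta, -0.5)
})

test_that("raising delta_min never increases the number of DMRs", {
  set.seed(31)
  pos <- seq(0L, 60000L, by = 20L)
  mk <- function(lv) data.table::data.table(
    chrom = "chr1", pos = pos, strand = "+", context = "CG",
    coverage = rpois(length(pos), 25) + 1L)[
      , methylated := rbinom(.N, coverage, lv)][]
  lv <- rep(0.3, length(pos))
  lv[pos >= 10000 & pos < 11000] <- 0.55
  lv[pos >= 30000 & pos < 31000] <- 0.45
  a <- mk(lv); b <- mk(0.3)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.3),
                   function(dm) nrow(call_dmrs(a, b, "CG", delta_min = dm)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("merged DMRs within a context never overlap", {
  set.seed(12)
  pos <- seq(0L, 80000L, by = 15L)
  lv <- rep(0.25, length(pos))
  for (s in c(5000, 12000, 40000, 41500, 70000))
    lv[pos >= s & pos < s + 1200] <- 0.7
  a <- data.table::data.table(chrom = "chr1", pos = pos, strand = "+",
                              context = "CHH",
                              coverage = rpois(length(pos), 30) + 1L)
  a[, methylated := rbinom(.N, coverage, lv)]
  b <- data.table::data.table(chrom = "chr1", pos = pos, strand = "+",
                              context = "CHH",
                              coverage = rpois(length(pos), 30) + 1L)
  b[, methylated := rbinom(.N, coverage, 0.25)]
  d <- call_dmrs(a, b, "CHH")
  expect_gt(nrow(d), 1L)
  d <- d[order(d$start), ]
  if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  expect_true(all(d$end - d$start >= 1))
  expect_true(all(abs(d$delta) >= 0.1))
  expect_true(all(d$q_value <= 0.05))
})

test_that("window must be at least as wide as the step", {
  calls <- flat_calls(0, 5000)
  expect_error(call_dmrs(calls, calls, "CG", window = 200, step = 500),
               "window")
})

test_that("DMR annotation has promoter > gene_body > intergenic priority", {
  genes <- small_gene(start = 10000, end = 14000, strand = "+")
  dmrs <- data.table::data.table(
    chrom = "chr1",
    start = c(9500L, 11000L, 30000L, 9900L),
    end = c(9800L, 11500L, 31000L, 10200L),
    context = "CG", mean_a = 0.5, mean_b = 0.2, delta = 0.3,
    n_sites = 10L, p_value = 1e-6, q_value = 1e-5)
  ann <- annotate_dmrs(dmrs, genes, promoter_bp = 2000)
  # 500 bp upstream of the TSS; inside the gene; 16 kb away; straddling the
  # TSS (promoter wins over gene_body)
  expect_equal(ann$annotation,
               c("promoter", "gene_body", "intergenic", "promoter"))
  expect_true(all(table(ann$annotation) >= 0)) # exactly one category each
  expect_equal(sum(ann$annotation %in% c("promoter", "gene_body", "intergenic")),
               nrow(ann))
})

test_that("promoter annotation is strand-aware", {
  gene_m <- small_gene(start = 10000, end = 14000, strand = "-")
  dmr <- data.table::data.table(chrom = "chr1", start = 14500L, end = 14800L,
                                context = "CG", mean_a = 0.5, mean_b = 0.2,
                                delta = 0.3, n_sites = 5L,
                                p_value = 1e-4, q_value = 1e-3)
  expect_equal(annotate_dmrs(dmr, gene_m)$annotation, "promoter")
  gene_p <- small_gene(start = 10000, end = 14000, strand = "+")
  expect_equal(annotate_dmrs(dmr, gene_p)$annotation, "intergenic")
})

test_that("per-gene DMR table counts contexts and directions", {
  genes <- small_gene(start = 10000, end = 14000, strand = "+")
  dmrs <- data.table::data.table(
    chrom = "chr1",
    start = c(10500L, 12000L, 13000L, 40000L),
    end = c(10900L, 12400L, 13400L, 41000L),
    context = c("CG", "CG", "CHH", "CG"),
    mean_a = 0.5, mean_b = 0.2, delta = c(0.3, 0.3, -0.3, 0.3),
    n_sites = 10L, p_value = 1e-6, q_value = 1e-5)
  tab <- dmr_gene_table(dmrs, genes)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$CG, 2L)
  expect_equal(tab$CHH, 1L)
  expect_equal(tab$hyper, 2L)
  expect_equal(tab$hypo, 1L)
  expect_equal(nrow(dmr_gene_table(dmrs[0, ], genes)), 0L)
})

test_that("genes overlapping planted DMRs match the gene table exactly", {
  # plant DMRs against known gene coordinates and verify via interval logic
  genes <- rbind(small_gene("g1", start = 5000, end = 8000),
                 small_gene("g2", start = 20000, end = 23000),
                 small_gene("g3", start = 40000, end = 42000))
  dmrs <- data.table::data.table(
    chrom = "chr1", start = c(6000L, 19000L), end = c(6500L, 19500L),
    context = "CG", mean_a = 0.6, mean_b = 0.2, delta = 0.4, n_sites = 8L,
    p_value = 1e-8, q_value = 1e-7)
  tab <- dmr_gene_table(dmrs, genes, promoter_bp = 2000)
  expect_setequal(tab$gene_id, c("g1", "g2")) # g2 hit via its promoter
})
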