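# Self-contained two-haplotype simulator with planted truth.
#
# The generator emulates the statistical structure the analysis assumes:
# two collinear haplotypes with the same gene order; per-context
# methylation levels ordered CG > CHH > CHG with small tissue differences
# (one haplotype slightly more methylated in flowers, the other in
# leaves); planted differentially methylated regions in intergenic space;
# allelic pairs with planted two-fold-scale expression divergence; and a
# negative coupling between promoter/gene-body methylation differences and
# the allelic log2 expression ratio. Cytosine contexts are realised from
# the actual simulated sequence, so the context caller can be validated
# against truth.

.default_context_means <- function(tissues) {
  if (length(tissues) != 2)
    stop("default context means are defined for exactly two tissues; supply context_means")
  rbindlist(list(
    data.table(haplotype = "hapA", tissue = tissues[1],
               context = c("CG", "CHH", "CHG"), mean = c(0.60, 0.30, 0.20)),
    data.table(haplotype = "hapA", tissue = tissues[2],
               context = c("CG", "CHH", "CHG"), mean = c(0.57, 0.28, 0.19)),
    data.table(haplotype = "hapB", tissue = tissues[1],
               context = c("CG", "CHH", "CHG"), mean = c(0.58, 0.26, 0.18)),
    data.table(haplotype = "hapB", tissue = tissues[2],
               context = c("CG", "CHH", "CHG"), mean = c(0.62, 0.29, 0.21))))
}

.default_dmr_spec <- function(tissues) {
  list(list(haplotype = "hapA", sample_a = tissues[1], sample_b = tissues[2],
            n = 8, length = 1000, delta = 0.25),
       list(haplotype = "hapB", sample_a = tissues[1], sample_b = tissues[2],
            n = 8, length = 1000, delta = -0.25))
}

#' Build and validate a simulation configuration
#'
#' Defaults describe a desk-scale allodiploid: two chromosomes of 350 kb
#' per haplotype, 60 collinear gene pairs, CG > CHH > CHG context means
#' with one haplotype more methylated in flowers and the other in leaves,
#' 8 planted flower-vs-leaf DMRs per haplotype (1 kb, |delta| 0.25),
#' Poisson coverage around 30x with beta-binomial overdispersion
#' rho = 0.05, three replicates of log-normally noisy TPM (sigma 0.2), 20%
#' of pairs with planted >= 2-fold allelic divergence, and a negative
#' methylation-expression coupling of -6 log2 units per methylation
#' fraction.
#'
#' @param seed RNG seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#' @param n_chroms,chrom_len chromosomes per haplotype and their length (bp).
#' @param n_genes number of collinear gene pairs.
#' @param gene_len_range min/max gene length (bp).
#' @param flank flank width (bp) reserved around every gene and used as the
#'   promoter width (default 2000).
#' @param tissues tissue labels (default flower, leaf).
#' @param context_means data.frame `haplotype`, `tissue`, `context`, `mean`
#'   of baseline methylation fractions.
#' @param dmr_spec list of planted-DMR specs, each a list with `haplotype`,
#'   `sample_a`, `sample_b` (tissues), `n`, `length` (bp) and `delta`
#'   (added to `sample_a`).
#' @param coverage_mean mean per-site read coverage (Poisson).
#' @param n_replicates RNA replicates per tissue (default 3).
#' @param de_fraction fraction of pairs with planted >= 2-fold divergence.
#' @param meth_expr_slope coupling of the allelic log2 expression ratio to
#'   the allelic promoter methylation difference (log2 units per
#'   methylation fraction; negative couples high methylation to low
#'   expression; 0 disables the coupling).
#' @param tpm_sigma log-normal replicate noise (sd on the natural log).
#' @param meth_rho beta-binomial overdispersion of methylation counts
#'   (0 = pure binomial).
#' @param decoy_fraction fraction of spurious anchors with random partners.
#' @param nonexpressed_fraction fraction of pairs silent in all tissues.
#' @param tpm_meanlog2,tpm_sdlog2 distribution of baseline log2 TPM.
#' @param dmr_margin minimum distance (bp) between planted DMRs and from
#'   gene flanks (default 1500, so distinct planted regions stay farther
#'   apart than the DMR caller's window + step resolution).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_chroms = 2, chrom_len = 350000,
                              n_genes = 60, gene_len_range = c(1000, 2500),
                              flank = 2000, tissues = c("flower", "leaf"),
                              context_means = NULL, dmr_spec = NULL,
                              coverage_mean = 30, n_replicates = 3,
                              de_fraction = 0.2, meth_expr_slope = -6,
                              tpm_sigma = 0.2, meth_rho = 0.05,
                              decoy_fraction = 0.1,
                              nonexpressed_fraction = 0.1,
                              tpm_meanlog2 = 3.5, tpm_sdlog2 = 1,
                              dmr_margin = 1500) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
              gene_len_range = as.integer(gene_len_range),
              flank = as.integer(flank), tissues = tissues,
              context_means = if (is.null(context_means))
                .default_context_means(tissues) else as.data.table(context_means),
              dmr_spec = if (is.null(dmr_spec)) .default_dmr_spec(tissues) else dmr_spec,
              coverage_mean = coverage_mean, n_replicates = as.integer(n_replicates),
              de_fraction = de_fraction, meth_expr_slope = meth_expr_slope,
              tpm_sigma = tpm_sigma, meth_rho = meth_rho,
              decoy_fraction = decoy_fraction,
              nonexpressed_fraction = nonexpressed_fraction,
              tpm_meanlog2 = tpm_meanlog2, tpm_sdlog2 = tpm_sdlog2,
              dmr_margin = as.integer(dmr_margin))
  with(cfg, {
    if (n_chroms < 1 || chrom_len < 1 || n_genes < 1 || flank < 0 ||
        coverage_mean <= 0 || n_replicates < 2 ||
        length(gene_len_range) != 2 || any(gene_len_range <= 0) ||
        gene_len_range[1] > gene_len_range[2])
      stop("configuration error: non-positive or inconsistent lengths/counts")
    fr <- c(de_fraction, meth_rho, decoy_fraction, nonexpressed_fraction,
            cfg$context_means$mean)
    if (any(fr < 0 | fr > 1)) stop("configuration error: fractions must lie in [0, 1]")
    if (tpm_sigma < 0) stop("configuration error: tpm_sigma must be >= 0")
    if (dmr_margin < 0) stop("configuration error: dmr_margin must be >= 0")
    if (length(tissues) < 2 || anyDuplicated(tissues))
      stop("configuration error: at least two distinct tissues required")
    per_chrom <- ceiling(n_genes / n_chroms)
    if (chrom_len %/% per_chrom < gene_len_range[2] + 2 * flank)
      stop("configuration error: chrom_len too small for n_genes with these gene lengths and flanks")
    need <- CJ(haplotype = c("hapA", "hapB"), tissue = tissues,
               context = CONTEXTS)
    have <- cfg$context_means[, .(haplotype, tissue, context)]
    if (nrow(fsetdiff(need, as.data.table(have))) > 0)
      stop("configuration error: context_means must cover both haplotypes, all tissues and all contexts")
    for (d in cfg$dmr_spec) {
      if (!all(c("haplotype", "sample_a", "sample_b", "n", "length", "delta") %in% names(d)))
        stop("configuration error: dmr_spec entries need haplotype, sample_a, sample_b, n, length, delta")
      if (d$n < 0 || d$length <= 0) stop("configuration error: non-positive DMR count/length")
      if (abs(d$delta) > 1) stop("configuration error: |delta| must be <= 1")
    }
  })
  class(cfg) <- "simulation_config"
  cfg
}

.random_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(0.30, 0.20, 0.20, 0.30)), collapse = "")
}

# genes are laid out chromosome by chromosome in uniform slots with
# jitter, leaving at least one flank width on each side of every gene
.simulate_genes <- function(cfg, hap, lens, strands, chrom_idx, pos_in_chrom) {
  pre <- if (hap == "hapA") "gA" else "gB"
  k_per <- tabulate(chrom_idx, nbins = cfg$n_chroms)
  starts <- integer(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    cidx <- chrom_idx[i]
    slot <- cfg$chrom_len %/% k_per[cidx]
    room <- slot - lens[i] - 2L * cfg$flank
    jitter <- if (room > 0) as.integer(floor(runif(1, 0, room + 1))) else 0L
    starts[i] <- (pos_in_chrom[i] - 1L) * slot + cfg$flank + jitter
  }
  data.table(gene_id = sprintf("%s%04d", pre, seq_len(cfg$n_genes)),
             chrom = paste0(hap, "_chr", chrom_idx),
             strand = strands, start = starts, end = starts + lens,
             pair = seq_len(cfg$n_genes))
}

.free_gaps <- function(cfg, genes, chroms) {
  occ <- genes[, .(chrom, lo = pmax(start - cfg$flank, 0L),
                   hi = pmin(end + cfg$flank, cfg$chrom_len))]
  gaps <- list()
  for (ch in chroms) {
    o <- occ[chrom == ch][order(lo)]
    starts <- c(0L, o$hi)
    ends <- c(o$lo, cfg$chrom_len)
    g <- data.table(chrom = ch, lo = starts, hi = ends)[hi - lo > 0]
    gaps[[ch]] <- g
  }
  rbindlist(gaps)
}

# margin keeps planted regions >= 2*margin apart (and away from gene
# flanks); the 1500 bp default keeps distinct planted DMRs farther apart
# than the resolution (window + step) of a window-scale caller
.plant_intervals <- function(gaps, n, len, margin = 1500L) {
  out <- list()
  for (i in seq_len(n)) {
    cand <- which(gaps$hi - gaps$lo >= len + 2L * margin)
    if (!length(cand))
      stop("configuration error: no intergenic room left for planted DMRs")
    gi <- cand[sample.int(length(cand), 1L)]
    lo <- gaps$lo[gi]; hi <- gaps$hi[gi]
    s <- lo + margin + as.integer(floor(runif(1, 0, hi - lo - len - 2L * margin + 1)))
    out[[i]] <- data.table(chrom = gaps$chrom[gi], start = s, end = s + as.integer(len))
    gaps <- rbind(gaps[-gi],
                  data.table(chrom = gaps$chrom[gi],
                             lo = c(lo, s + as.integer(len)), hi = c(s, hi)))
  }
  rbindlist(out)
}

#' Simulate a two-haplotype dataset with planted truth
#'
#' Generates, under a single RNG seed, two collinear haplotype genomes with
#' gene annotations, per-tissue per-cytosine methylation call tables,
#' a replicated TPM table, a homology anchor table (all true pairs plus
#' decoys), and a machine-readable truth bundle. See
#' [simulation_config()] for what the defaults emulate.
#'
#' @param config a [simulation_config()].
#' @param outdir optional directory; when given, all outputs are written
#'   there as FASTA / GFF3 / TSV files and the truth bundle via
#'   [write_truth()].
#' @return a list with `config`, `genomes` (named character vectors),
#'   `genes` (per haplotype), `sites` (classified cytosines per haplotype),
#'   `calls` (`calls[[haplotype]][[tissue]]`), `expression`, `anchors`,
#'   `truth` and, when `outdir` is given, `files`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  if (!inherits(config, "simulation_config"))
    stop("config must come from simulation_config()")
  cfg <- config
  set.seed(cfg$seed)
  haps <- c("hapA", "hapB")
  n <- cfg$n_genes

  # --- gene layout (shared order and lengths; per-haplotype jitter) ------
  lens <- as.integer(round(runif(n, cfg$gene_len_range[1], cfg$gene_len_range[2])))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  per_chrom <- ceiling(n / cfg$n_chroms)
  chrom_idx <- ((seq_len(n) - 1L) %/% per_chrom) + 1L
  pos_in_chrom <- unlist(lapply(tabulate(chrom_idx, cfg$n_chroms), seq_len))
  genes <- lapply(haps, function(h)
    .simulate_genes(cfg, h, lens, strands, chrom_idx, pos_in_chrom))
  names(genes) <- haps

  # --- genomes and realised cytosine contexts ---------------------------
  genomes <- lapply(haps, function(h) {
    seqs <- vapply(seq_len(cfg$n_chroms), function(i) .random_chrom(cfg$chrom_len),
                   character(1))
    names(seqs) <- paste0(h, "_chr", seq_len(cfg$n_chroms))
    seqs
  })
  names(genomes) <- haps
  sites <- lapply(genomes, classify_contexts)

  # --- pair-level expression and methylation effects --------------------
  j <- round(runif(n, -0.05, 0.05), 6)            # shared per-pair jitter
  n_de <- round(cfg$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer()
  de_dir <- sample(c(1, -1), n_de, replace = TRUE)
  de_lf <- round(runif(n_de, 1.5, 3), 6)
  rho <- numeric(n)                               # target log2 A/B ratio
  dm <- round(rnorm(n, 0, 0.03), 6)               # promoter level difference A-B
  if (cfg$meth_expr_slope != 0) {
    rho <- cfg$meth_expr_slope * dm
    rho[de_idx] <- de_dir * de_lf
    dm[de_idx] <- round(rho[de_idx] / cfg$meth_expr_slope +
                        rnorm(n_de, 0, 0.02), 6)
  } else {
    rho[de_idx] <- de_dir * de_lf
  }
  dm_body <- round(0.6 * dm, 6)

  offsets <- rbindlist(lapply(haps, function(h) {
    sgn <- if (h == "hapA") 0.5 else -0.5
    rbindlist(list(
      data.table(haplotype = h, pair = seq_len(n), region = "upstream",
                 offset = round(j + sgn * dm, 6)),
      data.table(haplotype = h, pair = seq_len(n), region = "body",
                 offset = round(j + sgn * dm_body, 6)),
      data.table(haplotype = h, pair = seq_len(n), region = "downstream",
                 offset = j)))
  }))

  # --- truth: per-gene true levels --------------------------------------
  cm <- as.data.table(cfg$context_means)
  gene_levels <- rbindlist(lapply(haps, function(h) {
    g <- genes[[h]][, .(haplotype = h, gene_id, pair)]
    grid <- g[, CJ(region = REGIONS, context = CONTEXTS,
                   tissue = cfg$tissues), by = .(haplotype, gene_id, pair)]
    grid <- merge(grid, offsets, by = c("haplotype", "pair", "region"))
    grid <- merge(grid, cm, by = c("haplotype", "tissue", "context"))
    grid[, mu := round(clamp(mean + offset, 0.02, 0.98), 6)]
    grid[, .(haplotype, gene_id, region, context, tissue, mu)]
  }))
  setorder(gene_levels, haplotype, gene_id, region, context, tissue)

  # --- planted DMRs ------------------------------------------------------
  planted <- list()
  gaps <- lapply(haps, function(h)
    .free_gaps(cfg, genes[[h]], paste0(h, "_chr", seq_len(cfg$n_chroms))))
  names(gaps) <- haps
  for (d in cfg$dmr_spec) {
    if (d$n == 0) next
    iv <- .plant_intervals(gaps[[d$haplotype]], d$n, d$length,
                           margin = cfg$dmr_margin)
    # reserve: drop used space so later specs cannot overlap these
    for (k in seq_len(nrow(iv))) {
      gp <- gaps[[d$haplotype]]
      hit <- gp$chrom == iv$chrom[k] & gp$lo < iv$end[k] & gp$hi > iv$start[k]
      if (any(hit)) {
        cut <- gp[hit]
        repl <- rbindlist(lapply(seq_len(nrow(cut)), function(m)
          data.table(chrom = cut$chrom[m],
                     lo = c(cut$lo[m], iv$end[k]),
                     hi = c(iv$start[k], cut$hi[m]))))[hi - lo > 0]
        gaps[[d$haplotype]] <- rbind(gp[!hit], repl)
      }
    }
    planted[[length(planted) + 1L]] <-
      iv[, .(haplotype = d$haplotype, chrom, start, end,
             sample_a = d$sample_a, sample_b = d$sample_b,
             delta = round(d$delta, 6))]
  }
  planted_dmrs <- if (length(planted)) rbindlist(planted) else
    data.table(haplotype = character(), chrom = character(),
               start = integer(), end = integer(), sample_a = character(),
               sample_b = character(), delta = numeric())
  setorder(planted_dmrs, haplotype, chrom, start)

  # --- methylation calls -------------------------------------------------
  calls <- list()
  for (h in haps) {
    st <- sites[[h]][context %in% CONTEXTS]
    reg <- gene_regions(genes[[h]], flank = cfg$flank,
                        chrom_lens = setNames(rep(cfg$chrom_len, cfg$n_chroms),
                                              paste0(h, "_chr", seq_len(cfg$n_chroms))))
    reg <- merge(reg, genes[[h]][, .(gene_id, pair)], by = "gene_id")
    reg <- merge(reg, offsets[haplotype == h], by = c("pair", "region"))
    hits <- GenomicRanges::findOverlaps(
      granges0(st$chrom, st$pos, st$pos + 1L),
      granges0(reg$chrom, reg$start, reg$end), ignore.strand = TRUE)
    site_off <- rep(0, nrow(st))
    site_off[S4Vectors::queryHits(hits)] <- reg$offset[S4Vectors::subjectHits(hits)]
    calls[[h]] <- list()
    for (tis in cfg$tissues) {
      base <- cm[haplotype == h & tissue == tis]
      mu <- base$mean[match(st$context, base$context)] + site_off
      # planted DMR deltas apply to sample_a of their contrast
      pd <- planted_dmrs[haplotype == h]
      if (nrow(pd)) {
        dh <- GenomicRanges::findOverlaps(
          granges0(st$chrom, st$pos, st$pos + 1L),
          granges0(pd$chrom, pd$start, pd$end), ignore.strand = TRUE)
        qi <- S4Vectors::queryHits(dh); si <- S4Vectors::subjectHits(dh)
        sel_a <- pd$sample_a[si] == tis
        mu[qi[sel_a]] <- mu[qi[sel_a]] + pd$delta[si[sel_a]]
      }
      mu <- clamp(mu, 0.02, 0.98)
      cov <- rpois(nrow(st), cfg$coverage_mean)
      p <- if (cfg$meth_rho > 0) {
        ab <- (1 - cfg$meth_rho) / cfg$meth_rho
        rbeta(nrow(st), mu * ab, (1 - mu) * ab)
      } else mu
      m <- rbinom(nrow(st), cov, p)
      cl <- st[, .(chrom, pos, strand, context)]
      cl[, `:=`(coverage = cov, methylated = m)]
      calls[[h]][[tis]] <- cl[coverage > 0]
    }
  }

  # --- expression --------------------------------------------------------
  avail <- setdiff(seq_len(n), de_idx)
  n_ne <- min(round(cfg$nonexpressed_fraction * n), length(avail))
  ne_idx <- if (n_ne > 0) sort(sample(avail, n_ne)) else integer()
  expr <- list()
  for (tis in cfg$tissues) {
    b <- rnorm(n, cfg$tpm_meanlog2, cfg$tpm_sdlog2)
    mu_a <- 2^(b + rho / 2); mu_b <- 2^(b - rho / 2)
    mu_a[ne_idx] <- 0; mu_b[ne_idx] <- 0
    for (r in seq_len(cfg$n_replicates)) {
      noise_a <- exp(rnorm(n, 0, cfg$tpm_sigma))
      noise_b <- exp(rnorm(n, 0, cfg$tpm_sigma))
      expr[[length(expr) + 1L]] <- rbind(
        data.table(gene_id = genes$hapA$gene_id, tissue = tis, replicate = r,
                   tpm = round(mu_a * noise_a, 4)),
        data.table(gene_id = genes$hapB$gene_id, tissue = tis, replicate = r,
                   tpm = round(mu_b * noise_b, 4)))
    }
  }
  expression <- rbindlist(expr)
  setorder(expression, tissue, replicate, gene_id)

  # --- anchors -----------------------------------------------------------
  anchors <- data.table(gene_a = genes$hapA$gene_id,
                        gene_b = genes$hapB$gene_id,
                        score = round(runif(n, 500, 1500), 1))
  n_dec <- round(cfg$decoy_fraction * n)
  if (n_dec > 0) {
    ia <- sample.int(n, n_dec, replace = TRUE)
    shift_by <- sample.int(n - 1L, n_dec, replace = TRUE)
    ib <- ((ia - 1L + shift_by) %% n) + 1L
    anchors <- rbind(anchors,
                     data.table(gene_a = genes$hapA$gene_id[ia],
                                gene_b = genes$hapB$gene_id[ib],
                                score = round(runif(n_dec, 50, 300), 1)))
  }

  truth <- list(
    planted_dmrs = planted_dmrs,
    planted_de_pairs = if (n_de > 0) data.table(
      pair = de_idx, gene_a = genes$hapA$gene_id[de_idx],
      gene_b = genes$hapB$gene_id[de_idx],
      direction = fifelse(de_dir > 0, "A_high", "B_high"),
      log2_fold = de_lf) else
        data.table(pair = integer(), gene_a = character(),
                   gene_b = character(), direction = character(),
                   log2_fold = numeric()),
    gene_levels = gene_levels,
    params = data.table(
      param = c("seed", "meth_expr_slope", "de_fraction", "coverage_mean",
                "meth_rho", "tpm_sigma"),
      value = as.character(c(cfg$seed, cfg$meth_expr_slope, cfg$de_fraction,
                             cfg$coverage_mean, cfg$meth_rho, cfg$tpm_sigma))))

  bundle <- list(config = cfg, genomes = genomes, genes = genes,
                 sites = sites, calls = calls, expression = expression,
                 anchors = anchors, truth = truth)
  if (!is.null(outdir)) bundle$files <- write_dataset(bundle, outdir)
  bundle
}

#' Write a simulated dataset bundle to disk
#'
#' Emits FASTA genomes (60-column wrap), GFF3 annotations, per-tissue
#' methylation TSVs, the expression and anchor TSVs, and the truth bundle.
#'
#' @param bundle result of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  for (h in names(bundle$genomes)) {
    fa <- file.path(outdir, paste0("genome_", h, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(bundle$genomes[[h]]), fa, width = 60L)
    files[paste0("genome_", h)] <- fa
    gff <- file.path(outdir, paste0("genes_", h, ".gff3"))
    write_genes(bundle$genes[[h]], gff)
    files[paste0("genes_", h)] <- gff
    for (tis in names(bundle$calls[[h]])) {
      p <- file.path(outdir, sprintf("calls_%s_%s.tsv", h, tis))
      write_tsv(bundle$calls[[h]][[tis]], p)
      files[sprintf("calls_%s_%s", h, tis)] <- p
    }
  }
  files["expression"] <- write_tsv(bundle$expression,
                                   file.path(outdir, "expression.tsv"))
  files["anchors"] <- write_tsv(bundle$anchors,
                                file.path(outdir, "anchors.tsv"))
  files <- c(files, write_truth(bundle$truth, outdir))
  invisible(files)
}

#' Write the truth bundle as TSV files
#'
#' Four files are written into `dir`: `truth_dmrs.tsv`,
#' `truth_de_pairs.tsv`, `truth_gene_levels.tsv` and `truth_params.tsv`.
#' Empty components give header-only files; the files round-trip
#' losslessly through [read_truth()].
#'
#' @param truth truth list from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(truth_dmrs = file.path(dir, "truth_dmrs.tsv"),
             truth_de_pairs = file.path(dir, "truth_de_pairs.tsv"),
             truth_gene_levels = file.path(dir, "truth_gene_levels.tsv"),
             truth_params = file.path(dir, "truth_params.tsv"))
  write_tsv(truth$planted_dmrs, paths["truth_dmrs"])
  write_tsv(truth$planted_de_pairs, paths["truth_de_pairs"])
  write_tsv(truth$gene_levels, paths["truth_gene_levels"])
  write_tsv(truth$params, paths["truth_params"])
  invisible(paths)
}

#' Read a truth bundle written by [write_truth()]
#'
#' @param dir directory holding the truth TSVs.
#' @return list with `planted_dmrs`, `planted_de_pairs`, `gene_levels`,
#'   `params`.
#' @export
read_truth <- function(dir) {
  list(
    planted_dmrs = read_tsv(file.path(dir, "truth_dmrs.tsv")),
    planted_de_pairs = read_tsv(file.path(dir, "truth_de_pairs.tsv")),
    gene_levels = read_tsv(file.path(dir, "truth_gene_levels.tsv")),
    params = read_tsv(file.path(dir, "truth_params.tsv")))
}
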