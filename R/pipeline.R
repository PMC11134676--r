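# Pipeline orchestration: structured YAML config, staged execution,
# machine-readable run manifest. Outputs are pure functions of
# (inputs, parameters, seed), so a rerun with an identical config
# reproduces byte-identical files; the manifest deliberately records no
# wall-clock information.

.default_params <- function() {
  list(flank = 2000, min_cov = 4, promoter_bp = 2000,
       profile = list(flank_bins = 20, body_bins = 40),
       dmr = list(haplotype = "hapA", sample_a = "flower", sample_b = "leaf",
                  contexts = c("CG", "CHG", "CHH"), window = 1000, step = 500,
                  min_sites = 5, delta_min = 0.1, alpha = 0.05),
       pairs = list(min_anchors = 5, max_gap = 25),
       de = list(tissues = c("flower", "leaf"), fold = 2, pseudo = 0.1,
                 expressed_min = 0))
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent list) with `seed`,
#' `outdir`, an `inputs` block (paths to the two genomes, the two GFF3
#' annotations, the per-haplotype per-tissue methylation call TSVs keyed
#' `calls: {hapA: {flower: ..., leaf: ...}, hapB: ...}`, the expression TSV
#' and the anchors TSV) and an optional `params` block overriding stage
#' defaults. Every referenced input must exist at validation time.
#'
#' @param config path to a YAML file or a list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")
  if (is.null(config$outdir)) stop("config requires an outdir")
  config$seed <- as.integer(config$seed %||% 1L)
  inp <- config$inputs
  need <- c("genome_hapA", "genome_hapB", "genes_hapA", "genes_hapB",
            "expression", "anchors", "calls")
  miss <- setdiff(need, names(inp))
  if (length(miss)) stop("config inputs missing: ", paste(miss, collapse = ", "))
  flat <- c(inp[setdiff(need, "calls")], unlist(inp$calls))
  absent <- unlist(flat)[!file.exists(unlist(flat))]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  config$params <- modifyList(.default_params(), config$params %||% list())
  pd <- config$params$dmr
  if (!pd$haplotype %in% names(inp$calls) ||
      !all(c(pd$sample_a, pd$sample_b) %in% names(inp$calls[[pd$haplotype]])))
    stop("dmr contrast names a haplotype/tissue without a calls file")
  class(config) <- "pipeline_config"
  config
}

.stage_entry <- function(name, params, inputs, outputs) {
  list(name = name, params = params,
       inputs = as.list(tools::md5sum(unlist(inputs))),
       outputs = outputs, status = "complete")
}

#' Run the full haplotype methylome / allelic expression pipeline
#'
#' Executes the six analysis stages in order -- `contexts` (cytosine
#' classification of both genomes), `profile` (region levels and
#' metaprofiles per haplotype and tissue), `dmr` (windowed DMR calling for
#' the configured contrast plus annotation), `pairs` (anchor chaining and
#' allele pairing), `allelediff` (TPM filtering and per-tissue allelic DE)
#' and `integrate` (methylation x expression join) -- writing each stage's
#' outputs and a manifest entry (parameters, input checksums, row counts)
#' into `config$outdir`. A failing stage halts the run with the stage
#' named; the manifest then marks the run incomplete.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @return the run manifest, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "pipeline.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  p <- config$params
  inp <- config$inputs
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env()
  out_path <- function(...) file.path(config$outdir, paste0(...))
  emit <- function(x, path) { write_tsv(x, path); setNames(nrow(x), basename(path)) }

  stages <- list(
    contexts = function() {
      outs <- c()
      state$sites <- list(); state$genes <- list(); state$chrom_lens <- list()
      for (h in c("hapA", "hapB")) {
        genome <- Biostrings::readDNAStringSet(inp[[paste0("genome_", h)]])
        state$chrom_lens[[h]] <- setNames(Biostrings::width(genome),
                                          sub("\\s.*$", "", names(genome)))
        state$sites[[h]] <- classify_contexts(genome)
        state$genes[[h]] <- read_genes(inp[[paste0("genes_", h)]])
        outs <- c(outs, emit(state$sites[[h]], out_path("sites_", h, ".tsv")))
      }
      .stage_entry("contexts", list(), inp[c("genome_hapA", "genome_hapB")],
                   as.list(outs))
    },
    profile = function() {
      outs <- c()
      state$calls <- list(); state$levels <- list()
      for (h in c("hapA", "hapB")) {
        state$calls[[h]] <- list(); state$levels[[h]] <- list()
        for (tis in names(inp$calls[[h]])) {
          cl <- load_calls(inp$calls[[h]][[tis]], state$sites[[h]])
          state$calls[[h]][[tis]] <- cl
          lv <- region_levels(cl, state$genes[[h]], flank = p$flank,
                              min_cov = p$min_cov,
                              chrom_lens = state$chrom_lens[[h]])
          state$levels[[h]][[tis]] <- lv
          mp <- metaprofile(cl, state$genes[[h]], flank = p$flank,
                            flank_bins = p$profile$flank_bins,
                            body_bins = p$profile$body_bins)
          outs <- c(outs,
                    emit(lv, out_path(sprintf("region_levels_%s_%s.tsv", h, tis))),
                    emit(mp, out_path(sprintf("metaprofile_%s_%s.tsv", h, tis))))
        }
      }
      .stage_entry("profile", p[c("flank", "min_cov", "profile")],
                   unlist(inp$calls), as.list(outs))
    },
    dmr = function() {
      outs <- c()
      h <- p$dmr$haplotype
      all_dmrs <- list()
      for (ctx in p$dmr$contexts) {
        d <- call_dmrs(state$calls[[h]][[p$dmr$sample_a]],
                       state$calls[[h]][[p$dmr$sample_b]], context = ctx,
                       window = p$dmr$window, step = p$dmr$step,
                       min_sites = p$dmr$min_sites, min_cov = p$min_cov,
                       delta_min = p$dmr$delta_min, alpha = p$dmr$alpha)
        d <- annotate_dmrs(d, state$genes[[h]], promoter_bp = p$promoter_bp)
        all_dmrs[[ctx]] <- d
        outs <- c(outs, emit(d, out_path("dmrs_", ctx, ".tsv")))
        write_dmr_bed(d, out_path("dmrs_", ctx, ".bed"))
      }
      state$dmrs <- rbindlist(all_dmrs)
      outs <- c(outs, emit(dmr_gene_table(state$dmrs, state$genes[[h]],
                                          promoter_bp = p$promoter_bp),
                           out_path("dmr_genes.tsv")))
      .stage_entry("dmr", p$dmr,
                   list(inp$calls[[h]][[p$dmr$sample_a]],
                        inp$calls[[h]][[p$dmr$sample_b]]), as.list(outs))
    },
    pairs = function() {
      anchors <- read_tsv(inp$anchors, required = c("gene_a", "gene_b", "score"))
      ch <- chain_anchors(anchors, state$genes$hapA, state$genes$hapB,
                          min_anchors = p$pairs$min_anchors,
                          max_gap = p$pairs$max_gap)
      state$pairs <- call_allele_pairs(ch)
      outs <- c(emit(ch$blocks, out_path("blocks.tsv")),
                emit(state$pairs, out_path("pairs.tsv")))
      .stage_entry("pairs", p$pairs, list(inp$anchors), as.list(outs))
    },
    allelediff = function() {
      expr <- read_tsv(inp$expression,
                       required = c("gene_id", "tissue", "replicate", "tpm"))
      flt <- filter_genes(expr)
      kept <- expr[gene_id %in% flt$retained]
      outs <- c(emit(flt$report, out_path("filter_report.tsv")))
      state$de <- list()
      for (tis in p$de$tissues) {
        de <- call_allelic_de(state$pairs, kept, tissue = tis,
                              fold = p$de$fold, pseudo = p$de$pseudo,
                              expressed_min = p$de$expressed_min)
        state$de[[tis]] <- de
        cov <- attr(de, "coverage")
        say(sprintf("allelediff %s: %d/%d pairs expressed (%.2f%%)",
                    tis, cov$n_expressed, cov$n_pairs, cov$pct_expressed))
        outs <- c(outs, emit(de, out_path("allelic_de_", tis, ".tsv")))
      }
      .stage_entry("allelediff", p$de, list(inp$expression), as.list(outs))
    },
    integrate = function() {
      de_all <- rbindlist(state$de)
      res <- integrate_methylation_expression(de_all, state$levels$hapA,
                                              state$levels$hapB)
      outs <- c(emit(res$records, out_path("integration_records.tsv")),
                emit(res$summary, out_path("integration_summary.tsv")))
      .stage_entry("integrate", list(), list(inp$expression), as.list(outs))
    })

  for (nm in names(stages)) {
    say("stage ", nm, ": start")
    entry <- tryCatch(stages[[nm]](), error = function(e) e)
    if (inherits(entry, "error")) {
      manifest$stages[[nm]] <- list(name = nm, status = "failed",
                                    error = conditionMessage(entry))
      manifest$status <- "incomplete"
      jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(entry))
    }
    manifest$stages[[nm]] <- entry
    say("stage ", nm, ": complete")
  }
  manifest$status <- "complete"
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
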