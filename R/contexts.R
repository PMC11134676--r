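# Cytosine sequence-context classification and methylation-call loading.
#
# Plant cytosine methylation is analysed in three sequence contexts -- CG,
# CHG and CHH (H = A, C or T) -- defined by the two bases immediately
# downstream (3') of the cytosine on its own strand. Both strands carry
# cytosines: a G on the plus strand is a C on the minus strand, whose
# downstream bases are the complements of the two plus-strand bases to its
# left. Positions are reported 0-based in plus-strand coordinates.

CONTEXTS <- c("CG", "CHG", "CHH")

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.as_seq_list <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else stop("genome must be a FASTA path, DNAStringSet or named character vector")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("genome sequences must be named")
  # FASTA descriptions: keep the first word as the chromosome name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  toupper(seqs)
}

.classify_one <- function(chars, chrom) {
  n <- length(chars)
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad))
    stop("non-nucleotide character(s) in ", chrom, ": ",
         paste(unique(chars[bad]), collapse = ", "))
  out <- list()

  # plus strand: C at i, downstream bases at i+1, i+2
  i <- which(chars == "C")
  if (length(i)) {
    b1 <- rep(NA_character_, length(i)); b2 <- b1
    s1 <- i + 1L <= n; b1[s1] <- chars[i[s1] + 1L]
    s2 <- i + 2L <= n; b2[s2] <- chars[i[s2] + 2L]
    ctx <- rep("ambiguous", length(i))
    ok <- !is.na(b1) & !is.na(b2) & b1 != "N" & b2 != "N"
    ctx[ok & b1 == "G"] <- "CG"
    ctx[ok & b1 != "G" & b2 == "G"] <- "CHG"
    ctx[ok & b1 != "G" & b2 != "G"] <- "CHH"
    out$plus <- data.table(chrom = chrom, pos = i - 1L, strand = "+", context = ctx)
  }

  # minus strand: G at j in plus coordinates is a C on the minus strand;
  # its downstream bases sit at j-1, j-2 and read as complements.
  j <- which(chars == "G")
  if (length(j)) {
    d1 <- rep(NA_character_, length(j)); d2 <- d1
    s1 <- j - 1L >= 1L; d1[s1] <- chars[j[s1] - 1L]
    s2 <- j - 2L >= 1L; d2[s2] <- chars[j[s2] - 2L]
    ctx <- rep("ambiguous", length(j))
    ok <- !is.na(d1) & !is.na(d2) & d1 != "N" & d2 != "N"
    # complement(d1) == "G" <=> d1 == "C"
    ctx[ok & d1 == "C"] <- "CG"
    ctx[ok & d1 != "C" & d2 == "C"] <- "CHG"
    ctx[ok & d1 != "C" & d2 != "C"] <- "CHH"
    out$minus <- data.table(chrom = chrom, pos = j - 1L, strand = "-", context = ctx)
  }
  rbindlist(out)
}

#' Classify cytosine sequence contexts on both strands
#'
#' Scans a genome and assigns every cytosine (on either strand) to one of
#' the three plant methylation contexts, `CG`, `CHG` or `CHH`
#' (H = A, C or T), from the two bases immediately downstream on the
#' cytosine's own strand. Cytosines whose trinucleotide runs off the end of
#' the sequence or contains an `N` are labelled `ambiguous` and are excluded
#' from all level computations downstream.
#'
#' @param genome a FASTA file path, a [Biostrings::DNAStringSet], or a named
#'   character vector of sequences over `A`, `C`, `G`, `T`, `N`.
#' @return a `data.table` with columns `chrom`, `pos` (0-based plus-strand
#'   coordinate of the cytosine), `strand` (`+`/`-`) and `context`
#'   (`CG`, `CHG`, `CHH` or `ambiguous`), sorted by chromosome and position.
#' @examples
#' classify_contexts(c(chr = "ACGTCAGCAT"))
#' @export
classify_contexts <- function(genome) {
  seqs <- .as_seq_list(genome)
  res <- rbindlist(lapply(names(seqs), function(nm) {
    .classify_one(strsplit(seqs[[nm]], "", fixed = TRUE)[[1]], nm)
  }))
  if (!nrow(res))
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character()))
  setorder(res, chrom, pos, strand)
  res[]
}

#' Load per-cytosine methylation calls and reconcile them with the genome
#'
#' Reads a bedMethyl-like TSV of per-cytosine counts (columns `chrom`,
#' `pos` 0-based, `strand`, `context`, `coverage`, `methylated`) and joins
#' each row to a genome-classified cytosine site. Rows that do not land on
#' a classified cytosine, or whose stated context disagrees with the
#' genome-derived context, are rejected and counted; more than
#' `max_mismatch` rejected rows aborts, since that indicates the calls and
#' the genome do not belong together.
#'
#' @param path TSV file of methylation calls.
#' @param sites classified sites from [classify_contexts()].
#' @param max_mismatch maximum tolerated fraction of rejected rows
#'   (default 0.01).
#' @return a `data.table` of accepted calls (`chrom`, `pos`, `strand`,
#'   `context`, `coverage`, `methylated`) with attribute `n_rejected`.
#' @export
load_calls <- function(path, sites, max_mismatch = 0.01) {
  need <- c("chrom", "pos", "strand", "context", "coverage", "methylated")
  dt <- read_tsv(path, required = need)
  bad <- which(!is.finite(dt$pos) | dt$pos < 0 | dt$pos != round(dt$pos) |
               !is.finite(dt$coverage) | dt$coverage < 0 |
               !is.finite(dt$methylated) | dt$methylated < 0 |
               dt$methylated > dt$coverage |
               !dt$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed methylation call row(s) in ", path, " at line(s) ",
         paste(head(bad + 1L, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  sites <- as.data.table(sites)[, .(chrom, pos, strand, genome_context = context)]
  dt <- merge(dt, sites, by = c("chrom", "pos", "strand"),
              all.x = TRUE, sort = FALSE)
  ok <- !is.na(dt$genome_context) & dt$genome_context == dt$context &
    dt$context %in% CONTEXTS
  n_rej <- sum(!ok)
  if (nrow(dt) > 0 && n_rej / nrow(dt) > max_mismatch)
    stop(sprintf(paste0("%d of %d call rows (%.1f%%) disagree with the ",
                        "genome-derived cytosine contexts; calls and genome ",
                        "appear mismatched"),
                 n_rej, nrow(dt), 100 * n_rej / nrow(dt)))
  out <- dt[ok, .(chrom, pos, strand, context, coverage, methylated)]
  setorder(out, chrom, pos, strand)
  setattr(out, "n_rejected", n_rej)
  out[]
}
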