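#' Extract strand-aware promoter windows around transcription starts
#'
#' For a plus-strand gene with TSS at 0-based position `t`, the window is the
#' genomic interval `[t - upstream, t + downstream)`; for a minus-strand gene
#' it is `[t - downstream + 1, t + upstream + 1)` reverse-complemented. In
#' both cases position 0 of the returned sequence is the most-upstream base,
#' and the window covers exactly `upstream + downstream` bases (the TSS base
#' falls in the downstream part). Windows running off a chromosome end are
#' clipped with a warning. Duplicate gene ids keep the first record, with a
#' warning.
#'
#' @param genome A named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param tss_table Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based), `strand` (`"+"`/`"-"`), e.g. from [read_tss_table()].
#' @param upstream,downstream Window size in bp upstream/downstream of the
#'   TSS (defaults 1000 and 100, the -1000..+100 promoter convention).
#' @return A promoter tibble: `gene_id`, `seq` (uppercase), `chrom`, `start`,
#'   `end` (0-based half-open source interval), `strand`, `upstream`,
#'   `downstream`.
#' @export
extract_promoters <- function(genome, tss_table, upstream = 1000,
                              downstream = 100) {
  chrom_seqs <- load_genome(genome)
  tss_table <- as_tibble(tss_table)
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(tss_table)))
    stop_input("`tss_table` needs columns gene_id, chrom, tss, strand")
  if (anyDuplicated(tss_table$gene_id)) {
    warn("duplicate gene ids in TSS table; keeping the first record per gene")
    tss_table <- tss_table[!duplicated(tss_table$gene_id), ]
  }
  unknown <- setdiff(unique(tss_table$chrom), names(chrom_seqs))
  if (length(unknown) > 0) {
    bad <- tss_table$gene_id[tss_table$chrom %in% unknown][1]
    stop_input(sprintf("chromosome '%s' (gene %s) not found in genome",
                       tss_table$chrom[tss_table$chrom %in% unknown][1], bad))
  }
  if (any(tss_table$tss < 0)) stop_input("TSS coordinates must be >= 0")
  if (!all(tss_table$strand %in% c("+", "-")))
    stop_input("strand must be '+' or '-'")

  chrom_len <- nchar(chrom_seqs)
  plus <- tss_table$strand == "+"
  start <- ifelse(plus, tss_table$tss - upstream,
                  tss_table$tss - downstream + 1)
  end <- ifelse(plus, tss_table$tss + downstream,
                tss_table$tss + upstream + 1)
  cl <- chrom_len[tss_table$chrom]
  start_c <- pmax(start, 0)
  end_c <- pmin(end, cl)
  if (any(start_c > start | end_c < end))
    warn(sprintf("%d promoter window(s) clipped at chromosome ends",
                 sum(start_c > start | end_c < end)))

  seqs <- toupper(substr(chrom_seqs[tss_table$chrom], start_c + 1, end_c))
  seqs[!plus] <- revcomp(seqs[!plus])

  tibble(
    gene_id = tss_table$gene_id,
    seq = unname(seqs),
    chrom = tss_table$chrom,
    start = as.integer(start_c),
    end = as.integer(end_c),
    strand = tss_table$strand,
    upstream = as.integer(upstream),
    downstream = as.integer(downstream)
  )
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop_input("`genome` must be a named character vector, DNAStringSet, or FASTA path")
}

#' Sample a reference gene set
#'
#' Draws `k` TSS records uniformly without replacement from the universe,
#' excluding a given gene set (by default the analysed cluster genes, so the
#' background never contains the foreground).
#'
#' @param universe Data frame of TSS records (`gene_id` column required).
#' @param k Number of genes to sample (default 5000).
#' @param exclude Character vector of gene ids never to sample.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return The sampled rows of `universe`, in sampled order.
#' @export
sample_reference <- function(universe, k = 5000, exclude = character(0),
                             seed = 1) {
  universe <- as_tibble(universe)
  pool <- universe[!(universe$gene_id %in% exclude), ]
  if (nrow(pool) < k)
    stop_input(sprintf(
      "universe has only %d genes after exclusions; %d requested",
      nrow(pool), k))
  idx <- with_seed(derive_seed(seed, "sample_reference"),
                   sample.int(nrow(pool), k))
  pool[idx, ]
}

#' Read a TSS table
#'
#' Accepts a 4-column TSV (`gene_id`, `chrom`, `tss`, `strand`; 0-based TSS)
#' or a BED6 file (TSS taken as `chromStart` for `+` genes and `chromEnd - 1`
#' for `-` genes).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_table <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- readr::read_tsv(path, col_names = c("gene_id", "chrom", "tss", "strand"),
                           col_types = "ccic", comment = "#")
  } else {
    bed <- readr::read_tsv(path,
                           col_names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           col_types = "ciicdc", comment = "#")
    out <- tibble(gene_id = bed$name, chrom = bed$chrom,
                  tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
                  strand = bed$strand)
  }
  out
}

#' Write a promoter set as FASTA
#'
#' @param promoters Promoter tibble (needs `gene_id` and `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- promoter_seqs(promoters)
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a promoter set from FASTA
#'
#' @param path FASTA file path.
#' @return A promoter tibble with `gene_id` and `seq` columns.
#' @export
read_promoters_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(gene_id = sub("\\s.*$", "", names(ss)),
         seq = unname(toupper(as.character(ss))))
}
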