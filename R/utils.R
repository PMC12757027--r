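# Small shared helpers: sequence arithmetic, seeded RNG scoping, FASTA/FASTQ IO.
# All internal coordinates are 0-based half-open; file formats are emitted
# 1-based per their standards.

#' Reverse-complement a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC content of DNA strings, in percent
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of GC percentages in `[0, 100]`.
#' @export
gc_percent <- function(x) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x), c("G", "C"))
  100 * rowSums(f) / nchar(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substr0 <- function(x, start, end) {
  # 0-based half-open substring
  substring(x, start + 1, end)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

#' Write simulated reads to FASTQ
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`
#'   (as produced by [simulate_long_reads()]).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path.
#' @return Tibble with `read_id`, `sequence`, `quality`, `length`,
#'   `mean_quality` (mean Phred score per read).
#' @export
read_fastq_table <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(q),
    length = unname(nchar(as.character(x))),
    mean_quality = mean_phred(q)
  )
}

mean_phred <- function(quality) {
  vapply(quality, function(s) {
    if (!nzchar(s)) return(NA_real_)
    mean(utf8ToInt(s) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write a genome to FASTA
#'
#' @param genome A `cast_genome` (or any character DNA string).
#' @param path Output path.
#' @param name Sequence name.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, name = "sim_genome") {
  seq <- if (inherits(genome, "cast_genome")) genome$sequence else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(seq, name)), path)
  invisible(path)
}

#' Write gene models to GFF3 (1-based, per the standard)
#'
#' @param genome A `cast_genome`.
#' @param path Output path.
#' @param seqid Sequence name used in column 1.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genome, path, seqid = "sim_genome") {
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tcastworks\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     seqid, g$start + 1L, g$end, g$strand, g$gene))
  writeLines(lines, path)
  invisible(path)
}

# interval overlap length for 0-based half-open intervals
overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))
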