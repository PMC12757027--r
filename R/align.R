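# Seed-and-extend local aligner (R surface over the C++ core).
#
# BLASTn is the tool a lab would normally use for span-based rules like
# these (cargo location, flank classification, off-target search). Here the
# same decisions are driven by an internal seed-and-extend aligner with
# BLASTn-like scoring
# (match +2, mismatch -3, gap open 5, extend 2) so that the package carries no
# external binary dependency; the test suite holds its accept/reject decisions
# to a full Smith-Waterman oracle.

#' Local alignment by exact-word seeding and banded extension
#'
#' Finds local alignments of `query` against `subject` on one or both strands.
#' Exact `word_size`-mers seed diagonal clusters; each cluster is extended with
#' a banded affine-gap Smith-Waterman restricted to the seeded diagonals.
#' Overlapping hits are pruned best-first.
#'
#' @param query,subject DNA strings (character scalars).
#' @param word_size Seed word length (BLASTn uses 11 by default; the guide
#'   off-target scan uses 4).
#' @param band Diagonal padding/merging width for the banded extension.
#' @param both_strands Also align the reverse complement of `query`; hit
#'   coordinates are always reported on the forward `query`/`subject`.
#' @param score_floor Minimum reported alignment score.
#' @param max_hits Maximum number of non-overlapping hits per strand.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return Tibble with one row per hit: `score`, `qstart`, `qend`, `sstart`,
#'   `send` (1-based, closed, on the forward sequences), `strand`, and
#'   `qlen`/`slen` aligned-span lengths. Sorted by decreasing score.
#' @export
local_align <- function(query, subject, word_size = 11, band = 64,
                        both_strands = TRUE, score_floor = 20, max_hits = 25,
                        match = 2, mismatch = -3, gap_open = -5, gap_ext = -2) {
  stopifnot(is.character(query), length(query) == 1,
            is.character(subject), length(subject) == 1)
  run1 <- function(q, strand) {
    h <- as_tibble(cpp_seed_extend(q, subject, word_size, band,
                                   match, mismatch, gap_open, gap_ext,
                                   score_floor, max_hits))
    if (nrow(h) == 0) return(h)
    h$strand <- strand
    if (strand == "-") {
      qlen <- nchar(query)
      qs <- qlen - h$qend + 1L
      h$qend <- qlen - h$qstart + 1L
      h$qstart <- qs
    }
    h
  }
  out <- run1(query, "+")
  if (both_strands) out <- bind_rows(out, run1(revcomp(query), "-"))
  if (nrow(out) == 0) {
    return(tibble(score = integer(), qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(), strand = character(),
                  qlen = integer(), slen = integer()))
  }
  out$qlen <- out$qend - out$qstart + 1L
  out$slen <- out$send - out$sstart + 1L
  arrange(out, desc(.data$score), .data$sstart)
}

best_hit <- function(aln) if (nrow(aln) == 0) NULL else aln[1, ]
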