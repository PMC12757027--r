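# Long-read insertion-outcome profiling.
#
# Filter chain: read QC (mean quality, minimum length), the >=10 kb analysis
# subset, cargo location with the 80% right-end coverage rule, flank
# classification (>100 bp mapped to genome/plasmid), then the insertion call:
# genomic junction, orientation (RL/LR by which transposon end is
# PAM-proximal), offset from the protospacer 3' end, on-target status within
# a 100-bp window downstream of the target 3' end, and cointegrate status
# (plasmid backbone contiguous with the cargo).

#' Quality/length filtering of long reads
#'
#' @param reads FASTQ path or a read table (as from [simulate_long_reads()]
#'   or [read_fastq_table()]).
#' @param min_quality Reads must exceed this mean Phred score.
#' @param min_length Minimum read length, bp (QC set).
#' @param analysis_min_length Reads must exceed this length to enter the
#'   analysis set (complete cargo + junction information).
#' @return List with `qc_set` and `analysis_set` tibbles and a `counts`
#'   element (`n_input`, `n_pass_qc`, `n_ge_min`).
#' @export
filter_reads <- function(reads, min_quality = 20, min_length = 150,
                         analysis_min_length = 10000) {
  stopifnot(min_quality > 0, min_length > 0, analysis_min_length > 0)
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq_table(reads)
  reads <- as_tibble(reads)
  if (!"length" %in% names(reads)) reads$length <- nchar(reads$sequence)
  if (!"mean_quality" %in% names(reads)) reads$mean_quality <- mean_phred(reads$quality)
  qc <- filter(reads, .data$mean_quality > min_quality, .data$length >= min_length)
  analysis <- filter(qc, .data$length > analysis_min_length)
  list(qc_set = qc, analysis_set = analysis,
       counts = c(n_input = nrow(reads), n_pass_qc = nrow(qc),
                  n_ge_min = nrow(analysis)))
}

#' Locate the transposon cargo on a read
#'
#' Aligns the full transposon to the read (both strands) and applies the
#' right-end coverage rule: reads whose best hit covers less than
#' `min_right_end_cov` of the annotated right-end interval are rejected.
#'
#' @param read_seq Read sequence (character scalar).
#' @param vec A `cast_vector` with annotated end intervals.
#' @param min_right_end_cov Minimum aligned fraction of the right-end
#'   interval (default 0.80).
#' @param word_size,band,score_floor Aligner parameters.
#' @return List: `found`, `reject_reason` (`NA`, `"no_cargo"` or
#'   `"right_end"`), `read_start`, `read_end` (1-based span on the read),
#'   `strand` (transposon vs read), `tn_start`, `tn_end` (span on the forward
#'   transposon), `right_end_coverage`, `left_end_found`, `score`.
#' @export
locate_cargo <- function(read_seq, vec, min_right_end_cov = 0.80,
                         word_size = 13, band = 100, score_floor = 100) {
  stopifnot(inherits(vec, "cast_vector"))
  aln <- local_align(vec$transposon, read_seq, word_size = word_size,
                     band = band, score_floor = score_floor, max_hits = 8)
  if (nrow(aln) == 0) {
    return(list(found = FALSE, reject_reason = "no_cargo"))
  }
  h <- aln[1, ]
  cov_of <- function(iv) { # iv 0-based half-open on transposon
    overlap_len(h$qstart - 1L, h$qend, iv[1], iv[2]) / diff(iv)
  }
  right_cov <- cov_of(vec$right_end)
  left_cov <- cov_of(vec$left_end)
  if (right_cov < min_right_end_cov) {
    return(list(found = FALSE, reject_reason = "right_end",
                right_end_coverage = right_cov))
  }
  list(found = TRUE, reject_reason = NA_character_,
       read_start = h$sstart, read_end = h$send, strand = h$strand,
       tn_start = h$qstart, tn_end = h$qend,
       right_end_coverage = right_cov,
       left_end_found = left_cov >= min_right_end_cov,
       score = h$score)
}

align_flank <- function(flank_seq, ref_seq, word_size, band, score_floor = 30) {
  if (nchar(flank_seq) < word_size) return(NULL)
  best_hit(local_align(flank_seq, ref_seq, word_size = word_size, band = band,
                       score_floor = score_floor, max_hits = 4))
}

#' Classify the genomic context of read flanks
#'
#' The cargo-proximal portion of each flank (up to `flank_cap` bp) is aligned
#' to the reference genome and to the plasmid backbone; a flank is `genomic`
#' or `plasmid` when more than `min_flank_bp` bases map to that reference
#' only, `both` when both do, `unmapped` otherwise.
#'
#' @param read_seq Read sequence.
#' @param cargo Result of [locate_cargo()] (with `found = TRUE`).
#' @param genome A `cast_genome` (or character genome sequence).
#' @param vec A `cast_vector` (supplies the backbone sequence).
#' @param min_flank_bp Minimum mapped bases for a genomic/plasmid label.
#' @param flank_cap Cargo-proximal flank length analysed, bp.
#' @param word_size,band Aligner parameters.
#' @return List with per-flank (`left`, `right`) elements: `label`,
#'   `genome_bp`, `plasmid_bp`, and the genome hit (`ghit`) used for
#'   junction mapping (flank-local 1-based coordinates plus `flank_offset`,
#'   the 0-based read position where the analysed flank begins).
#' @export
classify_flanks <- function(read_seq, cargo, genome, vec,
                            min_flank_bp = 100, flank_cap = 600,
                            word_size = 11, band = 100) {
  gseq <- if (inherits(genome, "cast_genome")) genome$sequence else genome
  L <- nchar(read_seq)
  one <- function(side) {
    if (side == "left") {
      from <- max(0L, cargo$read_start - 1L - flank_cap)
      to <- cargo$read_start - 1L
    } else {
      from <- cargo$read_end
      to <- min(L, cargo$read_end + flank_cap)
    }
    fl <- substr0(read_seq, from, to)
    if (nchar(fl) == 0) {
      return(list(label = "unmapped", genome_bp = 0L, plasmid_bp = 0L,
                  ghit = NULL, flank_offset = from))
    }
    gh <- align_flank(fl, gseq, word_size, band)
    ph <- align_flank(fl, vec$backbone, word_size, band)
    gbp <- if (is.null(gh)) 0L else gh$qlen
    pbp <- if (is.null(ph)) 0L else ph$qlen
    label <- if (gbp > min_flank_bp && pbp > min_flank_bp) "both"
             else if (gbp > min_flank_bp) "genomic"
             else if (pbp > min_flank_bp) "plasmid"
             else "unmapped"
    list(label = label, genome_bp = gbp, plasmid_bp = pbp,
         ghit = gh, flank_offset = from)
  }
  list(left = one("left"), right = one("right"))
}

#' Call the insertion outcome of one read
#'
#' Maps the transposon-genome junction to genome coordinates from the
#' genomic flank(s), assigns orientation (RL when the transposon right end is
#' the PAM-proximal end), computes the offset from the protospacer 3' end,
#' applies the on-target window, and flags cointegrates (any plasmid-bearing
#' flank contiguous with the cargo).
#'
#' @param read_seq Read sequence.
#' @param vec,genome,target Vector/genome/target objects.
#' @param on_target_window Window size, bp, downstream of the target 3' end.
#' @param window_mode `"downstream"` (one-sided, the default) or
#'   `"symmetric"` (+/- window around the target 3' end).
#' @param ... Passed to [locate_cargo()] / [classify_flanks()].
#' @return One-row tibble: `placed`, `reject_reason`, `junction` (1-based
#'   genomic position of the first genomic base downstream of the insertion),
#'   `orientation`, `offset_bp`, `on_target`, `cointegrate`, flank labels and
#'   `right_end_coverage`; unplaceable reads carry `placed = FALSE`.
#' @export
call_insertion <- function(read_seq, vec, genome, target,
                           on_target_window = 100,
                           window_mode = c("downstream", "symmetric"), ...) {
  window_mode <- match.arg(window_mode)
  empty <- function(reason, cargo = NULL) {
    tibble(placed = FALSE, reject_reason = reason,
           junction = NA_integer_, orientation = NA_character_,
           offset_bp = NA_integer_, on_target = NA, cointegrate = NA,
           left_flank = NA_character_, right_flank = NA_character_,
           right_end_coverage = if (is.null(cargo) ||
                                    is.null(cargo$right_end_coverage))
             NA_real_ else cargo$right_end_coverage)
  }
  dots <- list(...)
  cargo_args <- dots[names(dots) %in% c("min_right_end_cov", "score_floor")]
  flank_args <- dots[names(dots) %in% c("min_flank_bp", "flank_cap")]
  cargo <- do.call(locate_cargo, c(list(read_seq, vec), cargo_args))
  if (!cargo$found) return(empty(cargo$reject_reason, cargo))
  fl <- do.call(classify_flanks,
                c(list(read_seq, cargo, genome, vec), flank_args))
  genomic <- function(f) f$label %in% c("genomic", "both") && !is.null(f$ghit)
  # Canonicalise the read to the genome-forward frame so junction and
  # orientation logic sees a single geometry.
  strand_of <- function(f) if (genomic(f)) f$ghit$strand else NA_character_
  sg <- c(strand_of(fl$left), strand_of(fl$right))
  sg <- sg[!is.na(sg)]
  if (length(sg) == 0) return(empty("unplaceable", cargo))
  if (sg[1] == "-") {
    read_seq <- revcomp(read_seq)
    L <- nchar(read_seq)
    new_start <- L - cargo$read_end + 1L
    cargo$read_end <- L - cargo$read_start + 1L
    cargo$read_start <- new_start
    cargo$strand <- if (cargo$strand == "+") "-" else "+"
    fl <- do.call(classify_flanks,
                  c(list(read_seq, cargo, genome, vec), flank_args))
    if (!genomic(fl$left) && !genomic(fl$right)) {
      return(empty("unplaceable", cargo))
    }
  }
  # Junction: genomic coordinate (1-based) of the first genomic base
  # downstream (right) of the inserted sequence. The left flank's last
  # aligned base is the last genomic base before the insertion; the right
  # flank's first aligned base is the junction itself.
  j_left <- if (genomic(fl$left) && fl$left$ghit$strand == "+") {
    fl$left$ghit$send + 1L
  } else NA_integer_
  j_right <- if (genomic(fl$right) && fl$right$ghit$strand == "+") {
    fl$right$ghit$sstart
  } else NA_integer_
  # PAM-proximal side: upstream (left, in genome-forward frame) for a +
  # strand target, downstream for a - strand target.
  prefer_left <- target$strand == "+"
  junction <- if (prefer_left) {
    if (!is.na(j_left)) j_left else j_right
  } else {
    if (!is.na(j_right)) j_right else j_left
  }
  if (is.na(junction)) return(empty("unplaceable", cargo))
  # Orientation: in the genome-forward frame a "-" cargo hit means the
  # transposon right end faces the lower-coordinate (left) side.
  rl_faces_pam <- if (target$strand == "+") cargo$strand == "-" else cargo$strand == "+"
  orientation <- if (rl_faces_pam) "RL" else "LR"
  j0 <- junction - 1L # 0-based
  # bases between the protospacer 3' end and the insertion gap; 0 means the
  # cargo sits immediately 3' of the protospacer on the target strand
  offset <- if (target$strand == "+") {
    j0 - target$proto3p - 1L
  } else {
    target$proto3p - j0
  }
  on_target <- if (window_mode == "downstream") {
    offset >= 0L && offset <= on_target_window
  } else {
    abs(offset) <= on_target_window
  }
  cointegrate <- fl$left$label %in% c("plasmid", "both") ||
                 fl$right$label %in% c("plasmid", "both")
  tibble(placed = TRUE, reject_reason = NA_character_,
         junction = junction, orientation = orientation,
         offset_bp = as.integer(offset), on_target = on_target,
         cointegrate = cointegrate,
         left_flank = fl$left$label, right_flank = fl$right$label,
         right_end_coverage = cargo$right_end_coverage)
}

#' Profile a set of long reads end to end
#'
#' Runs [filter_reads()], then [call_insertion()] on every analysis-set read,
#' and returns the per-read call table together with the filter-chain counts.
#'
#' @param reads FASTQ path or read table.
#' @param vec,genome,target Vector/genome/target objects.
#' @param ... Passed to [filter_reads()] and [call_insertion()].
#' @return List with `calls` (placed reads; carries `event_id` when the input
#'   table has one, enabling clone-level estimates), `rejected` (read id and
#'   reason), and `counts` (named filter-chain vector).
#' @export
profile_reads <- function(reads, vec, genome, target, ...) {
  dots <- list(...)
  filt_args <- dots[names(dots) %in%
                    c("min_quality", "min_length", "analysis_min_length")]
  call_args <- dots[setdiff(names(dots), names(filt_args))]
  fr <- do.call(filter_reads, c(list(reads), filt_args))
  an <- fr$analysis_set
  calls <- list(); rejected <- list()
  for (i in seq_len(nrow(an))) {
    res <- do.call(call_insertion,
                   c(list(an$sequence[i], vec, genome, target), call_args))
    res$read_id <- an$read_id[i]
    if ("event_id" %in% names(an)) res$event_id <- an$event_id[i]
    if (res$placed) calls[[length(calls) + 1]] <- res
    else rejected[[length(rejected) + 1]] <- res
  }
  calls <- bind_rows(calls); rejected <- bind_rows(rejected)
  n_cargo <- nrow(calls) +
    (if (nrow(rejected)) sum(!rejected$reject_reason %in% c("no_cargo", "right_end")) else 0)
  counts <- c(fr$counts, n_cargo = n_cargo, n_called = nrow(calls))
  list(calls = calls, rejected = rejected, counts = counts)
}

#' Summarise insertion calls
#'
#' @param calls Call table from [profile_reads()] (placed reads).
#' @param genome_length Genome length for the position histogram.
#' @param bin_size Histogram bin width, bp.
#' @param counts Optional filter-chain counts to carry into the summary.
#' @return An `insertion_profile`: list with `n_called`, `on_target_pct`,
#'   `orientation` (fractions), `cointegrate_pct` (read-level),
#'   `cointegrate_pct_clone` (majority vote per clone, when `event_id` is
#'   available), `modal_offset`, `offset_hist` (`offset_bp`, `n`, `pct`),
#'   `genome_hist` (`bin_start`, `n`) and `counts`. Empty input returns an
#'   explicit empty sentinel (`n_called = 0`, statistics `NA`).
#' @export
summarize_insertions <- function(calls, genome_length, bin_size = 1000,
                                 counts = NULL) {
  if (is.null(calls) || nrow(calls) == 0) {
    return(structure(list(n_called = 0L, on_target_pct = NA_real_,
                          orientation = c(RL = NA_real_, LR = NA_real_),
                          cointegrate_pct = NA_real_,
                          cointegrate_pct_clone = NA_real_,
                          modal_offset = NA_integer_,
                          offset_hist = tibble(offset_bp = integer(),
                                               n = integer(), pct = numeric()),
                          genome_hist = tibble(bin_start = integer(), n = integer()),
                          counts = counts, empty = TRUE),
                     class = "insertion_profile"))
  }
  ori <- table(factor(calls$orientation, levels = c("RL", "LR")))
  off <- calls |>
    group_by(offset_bp = .data$offset_bp) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    arrange(.data$offset_bp)
  modal <- off$offset_bp[which.max(off$n)]
  bins <- tibble(bin_start = as.integer(
    bin_size * ((calls$junction - 1L) %/% bin_size))) |>
    group_by(.data$bin_start) |>
    summarise(n = n(), .groups = "drop")
  clone_pct <- NA_real_
  if ("event_id" %in% names(calls)) {
    clone <- calls |>
      group_by(.data$event_id) |>
      summarise(coint = mean(.data$cointegrate) >= 0.5, .groups = "drop")
    clone_pct <- 100 * mean(clone$coint)
  }
  if (!is.null(counts)) {
    chain <- c(counts["n_input"], counts["n_pass_qc"], counts["n_ge_min"],
               counts["n_cargo"], counts["n_called"])
    stopifnot(!is.unsorted(rev(unname(chain))))
  }
  structure(list(
    n_called = nrow(calls),
    on_target_pct = 100 * mean(calls$on_target),
    orientation = setNames(as.numeric(ori) / sum(ori), names(ori)),
    cointegrate_pct = 100 * mean(calls$cointegrate),
    cointegrate_pct_clone = clone_pct,
    modal_offset = modal,
    offset_hist = off,
    genome_hist = bins,
    counts = counts, empty = FALSE
  ), class = "insertion_profile")
}

#' @export
print.insertion_profile <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<insertion_profile> empty (no placed reads)\n")
    return(invisible(x))
  }
  cat(sprintf("<insertion_profile> %d called reads\n", x$n_called))
  cat(sprintf("  on-target:    %.1f%%\n", x$on_target_pct))
  cat(sprintf("  orientation:  RL %.1f%% / LR %.1f%%\n",
              100 * x$orientation[["RL"]], 100 * x$orientation[["LR"]]))
  cat(sprintf("  cointegrate:  %.1f%% (reads)%s\n", x$cointegrate_pct,
              if (is.na(x$cointegrate_pct_clone)) "" else
                sprintf(", %.1f%% (clones)", x$cointegrate_pct_clone)))
  cat(sprintf("  modal offset: %d bp\n", x$modal_offset))
  invisible(x)
}
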