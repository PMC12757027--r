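# Insertion-event and long-read simulation with planted ground truth.
# The generators are first-class, tested code: every event records its
# position, orientation, offset, cointegrate and on-target status, and every
# read records its source event, so profiler output can be held to the truth.

#' Simulate CAST integration events with ground truth
#'
#' On-target events are placed a configurable offset downstream of the
#' protospacer 3' end (the distance the transposase sets); off-target events
#' are placed uniformly outside the on-target window. Orientation (RL = the
#' transposon right end is PAM-proximal; LR otherwise) and cointegrate status
#' (whole vector integrated with duplicated transposon copies) are drawn
#' independently per event.
#'
#' @param genome A `cast_genome`.
#' @param target A `cast_target` from [plant_target()].
#' @param n_events Number of independent integration events (clones).
#' @param offset_mean Mean integration offset, bp downstream of the
#'   protospacer 3' end.
#' @param offset_sd Standard deviation of the offset (0 = point mass).
#' @param orientation_probs Named probabilities for `RL` and `LR`.
#' @param cointegrate_rate,off_target_rate Per-event probabilities.
#' @param on_target_window One-sided window (bp downstream of the protospacer
#'   3' end) within which an event counts as on-target.
#' @param edge_margin Events are kept this far from genome ends so that reads
#'   spanning them can be drawn.
#' @param seed Integer seed.
#' @return A `cast_truth`: list with `events` (tibble: `event_id`, `position`
#'   = 0-based junction, `orientation`, `offset_bp`, `cointegrate`,
#'   `on_target`) and the `target`.
#' @export
simulate_insertions <- function(genome, target, n_events = 200,
                                offset_mean = 49, offset_sd = 0,
                                orientation_probs = c(RL = 0.9, LR = 0.1),
                                cointegrate_rate = 0, off_target_rate = 0,
                                on_target_window = 100, edge_margin = 9000,
                                seed = NULL) {
  stopifnot(inherits(genome, "cast_genome"), inherits(target, "cast_target"))
  stopifnot(cointegrate_rate >= 0, cointegrate_rate <= 1,
            off_target_rate >= 0, off_target_rate <= 1)
  p_or <- orientation_probs[c("RL", "LR")] / sum(orientation_probs)
  with_seed(seed, {
    off <- runif(n_events) < off_target_rate
    offset <- pmax(0L, as.integer(round(rnorm(n_events, offset_mean, offset_sd))))
    j_on <- target$proto3p + 1L + offset
    win <- c(target$proto3p + 1L, target$proto3p + 1L + on_target_window)
    j <- j_on
    if (any(off)) {
      lo <- edge_margin; hi <- genome$length - edge_margin
      cand <- function(n) as.integer(round(runif(n, lo, hi)))
      jo <- cand(sum(off))
      while (any(bad <- jo >= win[1] & jo <= win[2])) jo[bad] <- cand(sum(bad))
      j[off] <- jo
    }
    events <- tibble(
      event_id = sprintf("ev%04d", seq_len(n_events)),
      position = j,
      orientation = sample(c("RL", "LR"), n_events, replace = TRUE, prob = p_or),
      offset_bp = j - target$proto3p - 1L,
      cointegrate = runif(n_events) < cointegrate_rate,
      on_target = !off
    )
    structure(list(events = events, target = target,
                   on_target_window = on_target_window),
              class = "cast_truth")
  })
}

insert_sequence <- function(event, vector) {
  tn <- vector$transposon
  ins <- if (event$cointegrate) paste0(tn, vector$backbone, tn) else tn
  # RL: right end PAM-proximal on a + strand target => insert reverse strand
  if (event$orientation == "RL") revcomp(ins) else ins
}

#' Simulate Nanopore-like long reads spanning integration events
#'
#' Each read is drawn from one event's edited allele (genomic flank,
#' integrated sequence, genomic flank), on a random strand, with iid
#' substitution/indel errors and a flat quality string. Both flanks are
#' guaranteed at least `min_flank` bp, emulating the junction-spanning subset
#' the downstream analysis uses.
#'
#' @param genome A `cast_genome`.
#' @param truth A `cast_truth` from [simulate_insertions()].
#' @param vector A `cast_vector`.
#' @param n_reads Number of reads; events are sampled with replacement, so an
#'   event (clone) can be covered by several reads.
#' @param read_length Target read length, bp. Reads whose insert is longer
#'   than `read_length - 2 * min_flank` are lengthened to fit.
#' @param per_base_error Total error rate; split 60/20/20 between
#'   substitutions, insertions and deletions.
#' @param mean_quality Phred score written uniformly to the quality string.
#' @param min_flank Minimum genomic flank retained on each side, bp.
#' @param sample_events Draw events with replacement (the default, emulating
#'   colony scrapes where clones contribute uneven read numbers); `FALSE`
#'   cycles through events so each clone is covered `n_reads / n_events`
#'   times.
#' @param seed Integer seed; fixed seed gives byte-identical reads.
#' @return Tibble (the truth table) with `read_id`, `event_id`, `sequence`,
#'   `quality`, `length`, `strand`, plus the event's `position`,
#'   `orientation`, `offset_bp`, `cointegrate`, `on_target`.
#' @export
simulate_long_reads <- function(genome, truth, vector, n_reads = 500,
                                read_length = 15000, per_base_error = 0.05,
                                mean_quality = 30, min_flank = 500,
                                sample_events = TRUE, seed = NULL) {
  stopifnot(inherits(truth, "cast_truth"), inherits(vector, "cast_vector"))
  ev <- truth$events
  with_seed(seed, {
    idx <- if (sample_events) sample(nrow(ev), n_reads, replace = TRUE)
           else rep(seq_len(nrow(ev)), length.out = n_reads)
    qchar <- intToUtf8(33L + as.integer(mean_quality))
    rows <- rep(list(NULL), n_reads)
    for (r in seq_len(n_reads)) {
      e <- ev[idx[r], ]
      ins <- insert_sequence(e, vector)
      li <- nchar(ins)
      L <- max(read_length, li + 2L * min_flank)
      j <- e$position
      left_len <- as.integer(round(runif(1, min_flank, L - li - min_flank)))
      left_len <- min(left_len, j) # rebalance flanks near genome edges
      right_len <- min(L - li - left_len, genome$length - j)
      left_len <- min(j, L - li - right_len)
      up <- substr0(genome$sequence, max(0L, j - left_len), j)
      down <- substr0(genome$sequence, j, min(genome$length, j + right_len))
      raw <- paste0(up, ins, down)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") raw <- revcomp(raw)
      seqd <- add_read_errors(raw, per_base_error)
      rows[[r]] <- tibble(
        read_id = sprintf("read%05d", r), event_id = e$event_id,
        sequence = seqd, quality = strrep(qchar, nchar(seqd)),
        length = nchar(seqd), strand = strand,
        position = e$position, orientation = e$orientation,
        offset_bp = e$offset_bp, cointegrate = e$cointegrate,
        on_target = e$on_target
      )
    }
    bind_rows(rows)
  })
}

add_read_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  n_err <- rbinom(1, n, rate)
  if (n_err == 0) return(seq)
  pos <- sample.int(n, n_err)
  kind <- sample(c("sub", "ins", "del"), n_err, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  alt <- sample(c("A", "C", "G", "T"), n_err, replace = TRUE)
  is_sub <- kind == "sub"; is_ins <- kind == "ins"
  same <- is_sub & alt == chars[pos]
  alt[same] <- chartr("ACGT", "TGCA", alt[same]) # force a real substitution
  chars[pos[is_sub]] <- alt[is_sub]
  chars[pos[is_ins]] <- paste0(alt[is_ins], chars[pos[is_ins]])
  chars[pos[kind == "del"]] <- ""
  paste(chars, collapse = "")
}
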