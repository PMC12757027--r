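# Safe-site and guide design.
#
# Safe sites are intergenic regions between converging genes (-> <-) of
# 300-600 nt that avoid mobile-element/ncRNA masks and essential-gene flanks.
# Within a site, every 5'-CN-3' PAM on either strand yields a candidate
# 32-nt protospacer immediately 3' of the PAM; candidates are filtered on GC
# content (40-60%), on the predicted insertion locus (~49 bp downstream of
# the protospacer) staying inside the site and clear of terminator masks,
# then ranked by off-target risk (seed-region complementarity first, best
# local-alignment score second) and the top k per site are selected.

#' Find candidate safe sites between converging genes
#'
#' @param genes Gene table (`gene`, `start`, `end`, `strand`; 0-based
#'   half-open), or a `cast_genome`.
#' @param genome_length Genome length (taken from the `cast_genome` if one is
#'   given).
#' @param min_len,max_len Accepted intergenic length range, nt.
#' @param masks Mask tibble (`label`, `start`, `end`) with labels among
#'   `mobile_element`, `ncRNA`, `terminator`; `essential` genes are flagged
#'   via an `essential` logical column on `genes` or an `essential` mask
#'   overlapping the flanking gene.
#' @return Tibble of every convergent gap with `site`, `start`, `end`,
#'   `length`, flanking gene ids, `exclusion_flags` (comma-joined audit
#'   trail; empty when accepted) and `accepted`.
#' @export
find_safe_sites <- function(genes, genome_length = NULL, min_len = 300,
                            max_len = 600, masks = NULL) {
  if (inherits(genes, "cast_genome")) {
    g <- genes
    if (is.null(masks)) masks <- g$masks
    genome_length <- g$length
    genes <- g$genes
  }
  genes <- as_tibble(genes)
  if (is.unsorted(genes$start)) {
    warn("gene models were not sorted by start; normalising")
    genes <- arrange(genes, .data$start)
  }
  if (is.null(masks)) masks <- tibble(label = character(), start = integer(),
                                      end = integer())
  masks <- as_tibble(masks)
  ess_flag <- if ("essential" %in% names(genes)) genes$essential else
    rep(FALSE, nrow(genes))
  # essential mask intervals mark genes they overlap
  emask <- filter(masks, .data$label == "essential")
  if (nrow(emask)) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(genes$start + 1L, genes$end),
      IRanges::IRanges(emask$start + 1L, emask$end))
    ess_flag[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  out <- list()
  for (i in seq_len(nrow(genes) - 1)) {
    a <- genes[i, ]; b <- genes[i + 1, ]
    if (!(a$strand == "+" && b$strand == "-")) next
    s <- a$end; e <- b$start
    len <- e - s
    if (len <= 0) next
    flags <- character()
    if (len < min_len) flags <- c(flags, "too_short")
    if (len > max_len) flags <- c(flags, "too_long")
    for (lab in c("mobile_element", "ncRNA")) {
      m <- filter(masks, .data$label == lab)
      if (nrow(m) && any(overlap_len(s, e, m$start, m$end) > 0)) {
        flags <- c(flags, lab)
      }
    }
    if (ess_flag[i] || ess_flag[i + 1]) flags <- c(flags, "essential_flank")
    out[[length(out) + 1]] <- tibble(
      site = length(out) + 1L, start = s, end = e, length = len,
      left_gene = a$gene, right_gene = b$gene,
      exclusion_flags = paste(flags, collapse = ","),
      accepted = length(flags) == 0)
  }
  if (length(out) == 0) {
    return(tibble(site = integer(), start = integer(), end = integer(),
                  length = integer(), left_gene = character(),
                  right_gene = character(), exclusion_flags = character(),
                  accepted = logical()))
  }
  bind_rows(out)
}

#' Scan a region for 5'-CN-3' PAMs on both strands
#'
#' A PAM is any C (read 5'->3' on either strand) together with its following
#' base. Positions are genome-frame and 0-based; `pam_start` is the
#' coordinate of the PAM's 5'-most base on its own strand.
#'
#' @param genome A `cast_genome` or character genome sequence.
#' @param start,end Region scanned, 0-based half-open (defaults to the whole
#'   sequence).
#' @return Tibble with `pam_start`, `strand`, `pam` (2-nt sequence as read on
#'   its strand). Positions whose base is not A/C/G/T are skipped with a
#'   warning.
#' @export
scan_pams <- function(genome, start = 0, end = NULL) {
  seq <- if (inherits(genome, "cast_genome")) genome$sequence else genome
  if (is.null(end)) end <- nchar(seq)
  region <- substr0(seq, start, end)
  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    warn("ambiguity codes in region; those positions are skipped")
  }
  n <- length(chars)
  fwd <- which(chars == "C" & c(chars[-1] %in% c("A", "C", "G", "T"), FALSE))
  rev_ <- which(chars == "G" & c(FALSE, chars[-n] %in% c("A", "C", "G", "T")))
  bind_rows(
    tibble(pam_start = start + fwd - 1L, strand = "+",
           pam = paste0("C", chars[fwd + 1L])),
    tibble(pam_start = start + rev_ - 1L, strand = "-",
           pam = paste0("C", chartr("ACGT", "TGCA", chars[rev_ - 1L])))
  ) |> arrange(.data$pam_start, .data$strand)
}

#' Extract candidate 32-nt guides downstream of PAMs
#'
#' The protospacer is the `guide_len` bases immediately 3' of the PAM on the
#' PAM's strand. Candidates running off the sequence are skipped.
#'
#' @param genome A `cast_genome` or character sequence.
#' @param pams Tibble from [scan_pams()].
#' @param guide_len Protospacer length (32).
#' @return Tibble with `pam_start`, `strand`, `pam`, `protospacer`,
#'   `proto_start`, `proto_end` (genome-frame, 0-based half-open), `proto3p`
#'   (0-based genomic coordinate of the protospacer's 3'-most base) and
#'   `gc_pct`.
#' @export
extract_guides <- function(genome, pams, guide_len = 32) {
  seq <- if (inherits(genome, "cast_genome")) genome$sequence else genome
  n <- nchar(seq)
  rows <- lapply(seq_len(nrow(pams)), function(i) {
    p <- pams[i, ]
    if (p$strand == "+") {
      ps <- p$pam_start + 2L; pe <- ps + guide_len
      if (pe > n) return(NULL)
      proto <- substr0(seq, ps, pe)
      p3 <- pe - 1L
    } else {
      # on the minus strand 3' of the PAM means lower genome coordinates
      pe <- p$pam_start - 1L; ps <- pe - guide_len
      if (ps < 0) return(NULL)
      proto <- revcomp(substr0(seq, ps, pe))
      p3 <- ps
    }
    tibble(pam_start = p$pam_start, strand = p$strand, pam = p$pam,
           protospacer = proto, proto_start = ps, proto_end = pe,
           proto3p = p3, gc_pct = gc_percent(proto))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(pam_start = integer(), strand = character(),
                  pam = character(), protospacer = character(),
                  proto_start = integer(), proto_end = integer(),
                  proto3p = integer(), gc_pct = numeric()))
  }
  out
}

predicted_locus <- function(guides, offset_window = c(45, 55)) {
  lo <- offset_window[1]; hi <- offset_window[2]
  s <- ifelse(guides$strand == "+",
              guides$proto3p + 1L + lo, guides$proto3p - hi)
  tibble(locus_start = as.integer(s),
         locus_end = as.integer(s + (hi - lo) + 1L))
}

#' Filter guide candidates on GC and insertion-locus placement
#'
#' @param candidates Tibble from [extract_guides()].
#' @param site One row of [find_safe_sites()] output (the hosting site).
#' @param gc_range Accepted GC range, percent.
#' @param offset_window Insertion-locus window downstream of the protospacer
#'   3' end, bp (around the ~49 bp expected integration distance).
#' @param terminator_mask Optional tibble (`start`, `end`) of terminator
#'   intervals the locus must not disrupt.
#' @return `candidates` with `locus_start`, `locus_end`, `fails`
#'   (comma-joined rule failures: `gc`, `locus_outside`, `terminator`) and
#'   `accepted`.
#' @export
filter_guides <- function(candidates, site, gc_range = c(40, 60),
                          offset_window = c(45, 55), terminator_mask = NULL) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, locus_start = integer(), locus_end = integer(),
                  fails = character(), accepted = logical()))
  }
  loc <- predicted_locus(candidates, offset_window)
  out <- bind_cols(candidates, loc)
  gc_bad <- out$gc_pct < gc_range[1] | out$gc_pct > gc_range[2]
  outside <- out$locus_start < site$start | out$locus_end > site$end
  term_bad <- rep(FALSE, nrow(out))
  if (!is.null(terminator_mask) && nrow(terminator_mask)) {
    for (k in seq_len(nrow(terminator_mask))) {
      term_bad <- term_bad | overlap_len(out$locus_start, out$locus_end,
                                         terminator_mask$start[k],
                                         terminator_mask$end[k]) > 0
    }
  }
  fails <- mapply(function(g, o, t) {
    paste(c(if (g) "gc", if (o) "locus_outside", if (t) "terminator"),
          collapse = ",")
  }, gc_bad, outside, term_bad)
  mutate(out, fails = unname(fails), accepted = !nzchar(fails))
}

#' Score a guide's genome-wide off-target potential
#'
#' BLASTn-like scan (default word size 4, no complexity filtering) of the
#' guide against both strands of the genome, excluding the on-target locus.
#' The seed region is the first `seed_len` nt of the guide (PAM-proximal
#' end); seed matches of the best hit are counted on the hit's seed diagonal.
#'
#' @param guide Guide row (needs `protospacer`, `proto_start`, `proto_end`)
#'   or a bare 32-nt character protospacer.
#' @param genome A `cast_genome` or character sequence.
#' @param word_size Seed word length (4, as in the source search).
#' @param seed_len Seed-region length, nt.
#' @param exclude_interval 0-based half-open interval masking the on-target
#'   locus (defaults to the guide's own coordinates when given a guide row).
#' @param score_floor Minimum alignment score for a counted hit (match +2,
#'   mismatch -3; 32 corresponds to a 16-bp perfect core).
#' @return One-row tibble: `best_score`, `best_hit_length`,
#'   `best_hit_identity` (matches-equivalent fraction of the aligned span),
#'   `seed_matches`, `n_hits_above_floor`.
#' @export
offtarget_scan <- function(guide, genome, word_size = 4, seed_len = 10,
                           exclude_interval = NULL, score_floor = 32) {
  seq <- if (inherits(genome, "cast_genome")) genome$sequence else genome
  if (is.character(guide)) {
    proto <- guide
  } else {
    proto <- guide$protospacer
    if (is.null(exclude_interval)) {
      exclude_interval <- c(guide$proto_start - 2L, guide$proto_end + 2L)
    }
  }
  hits <- local_align(proto, seq, word_size = word_size, band = 16,
                      score_floor = score_floor, max_hits = 200)
  if (!is.null(exclude_interval) && nrow(hits)) {
    keep <- overlap_len(hits$sstart - 1L, hits$send,
                        exclude_interval[1], exclude_interval[2]) == 0
    hits <- hits[keep, ]
  }
  if (nrow(hits) == 0) {
    return(tibble(best_score = 0L, best_hit_length = 0L,
                  best_hit_identity = 0, seed_matches = 0L,
                  n_hits_above_floor = 0L))
  }
  h <- hits[1, ]
  ident <- (h$score + 3 * h$qlen) / (5 * h$qlen) # matches-equivalent fraction
  tibble(best_score = h$score, best_hit_length = h$qlen,
         best_hit_identity = min(1, ident),
         seed_matches = seed_diag_matches(proto, seq, h, seed_len),
         n_hits_above_floor = nrow(hits))
}

# matches between the guide's first seed_len bases and the genome along the
# best hit's seed diagonal (ungapped approximation of the hit's alignment)
seed_diag_matches <- function(proto, seq, h, seed_len) {
  sl <- min(seed_len, nchar(proto))
  gchars <- function(s0, e0) strsplit(substr0(seq, max(0, s0), max(0, e0)), "")[[1]]
  pchars <- strsplit(substr(proto, 1, sl), "")[[1]]
  if (h$strand == "+") {
    s0 <- (h$sstart - 1L) - (h$qstart - 1L) # genome 0-based pos of guide base 1
    g <- gchars(s0, s0 + sl)
  } else {
    # guide base 1 pairs with the genome position opposite the hit's far end
    e0 <- (h$send - 1L) + (h$qstart - 1L)
    g <- rev(strsplit(chartr("ACGT", "TGCA",
                             substr0(seq, max(0, e0 - sl + 1L), e0 + 1L)),
                      "")[[1]])
  }
  if (length(g) < sl) return(sum(head(pchars, length(g)) == g))
  sum(pchars == head(g, sl))
}

#' Select the top-ranked guides for a safe site
#'
#' Accepted candidates are ranked ascending by seed-region complementarity of
#' their best off-target hit, then by best off-target score; full ties are
#' broken deterministically by protospacer sequence and finally by genomic
#' coordinate (the sequence tie-break keeps selection invariant under
#' reverse-complementing the genome).
#'
#' @param accepted Accepted candidates carrying off-target columns (as built
#'   by [design_guides()]).
#' @param k Guides per site (3).
#' @return `accepted`, ranked and truncated to `k` rows, with a `rank`
#'   column. Fewer than `k` accepted guides returns all with a warning.
#' @export
select_guides <- function(accepted, k = 3) {
  stopifnot(k >= 1)
  if (nrow(accepted) == 0) {
    warn("no accepted guides for this site")
    return(mutate(accepted, rank = integer()))
  }
  ranked <- accepted |>
    arrange(.data$seed_matches, .data$best_score, .data$protospacer,
            .data$pam_start) |>
    mutate(rank = row_number())
  if (nrow(ranked) < k) {
    warn(sprintf("only %d accepted guides (requested %d)", nrow(ranked), k))
  }
  head(ranked, k)
}

#' Design guides for every accepted safe site
#'
#' Full pipeline: [find_safe_sites()] -> [scan_pams()] -> [extract_guides()]
#' -> [filter_guides()] -> [offtarget_scan()] -> [select_guides()], followed
#' by a post-pipeline audit re-checking the PAM, length, GC and locus rules
#' on everything emitted.
#'
#' @param genome A `cast_genome`.
#' @param k Guides per site.
#' @param min_len,max_len,masks Safe-site parameters.
#' @param gc_range,offset_window Guide filters.
#' @param word_size,seed_len,score_floor Off-target scan parameters.
#' @return List with `sites` (audit table) and `guides` (selected guides,
#'   all sites, with off-target columns and per-site `rank`).
#' @export
design_guides <- function(genome, k = 3, min_len = 300, max_len = 600,
                          masks = NULL, gc_range = c(40, 60),
                          offset_window = c(45, 55), word_size = 4,
                          seed_len = 10, score_floor = 32) {
  sites <- find_safe_sites(genome, min_len = min_len, max_len = max_len,
                           masks = masks)
  mask_tbl <- if (!is.null(masks)) as_tibble(masks)
    else if (inherits(genome, "cast_genome")) genome$masks
    else tibble(label = character(), start = integer(), end = integer())
  term <- filter(mask_tbl, .data$label == "terminator")
  picked <- list()
  for (i in which(sites$accepted)) {
    site <- sites[i, ]
    pams <- scan_pams(genome, site$start, site$end)
    cand <- extract_guides(genome, pams)
    cand <- filter_guides(cand, site, gc_range = gc_range,
                          offset_window = offset_window,
                          terminator_mask = term)
    acc <- filter(cand, .data$accepted)
    if (nrow(acc) == 0) { warn(sprintf("site %d: no accepted guides", site$site)); next }
    ot <- bind_rows(lapply(seq_len(nrow(acc)), function(j) {
      offtarget_scan(acc[j, ], genome, word_size = word_size,
                     seed_len = seed_len, score_floor = score_floor)
    }))
    sel <- select_guides(bind_cols(acc, ot), k = k)
    sel$site <- site$site
    picked[[length(picked) + 1]] <- sel
  }
  guides <- bind_rows(picked)
  audit_guides(guides, sites, gc_range, offset_window)
  list(sites = sites, guides = guides)
}

# re-check every emitted guide against the design rules; hard failure on any
# violation so a pipeline bug cannot ship a bad guide silently
audit_guides <- function(guides, sites, gc_range, offset_window) {
  if (is.null(guides) || nrow(guides) == 0) return(invisible(TRUE))
  stopifnot(all(nchar(guides$protospacer) == 32),
            all(substr(guides$pam, 1, 1) == "C"),
            all(guides$gc_pct >= gc_range[1] & guides$gc_pct <= gc_range[2]))
  for (i in seq_len(nrow(guides))) {
    s <- sites[sites$site == guides$site[i], ]
    stopifnot(guides$locus_start[i] >= s$start, guides$locus_end[i] <= s$end)
  }
  invisible(TRUE)
}
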