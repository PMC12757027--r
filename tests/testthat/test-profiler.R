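# Long-read outcome profiling: filter rules, the right-end coverage rule,
# flank classification, junction/orientation/offset calls, truth recovery at
# 0% and 5% read error, strand symmetry, and the filter-chain monotonicity.

test_that("read filtering applies the quality, length and analysis thresholds", {
  mk <- function(id, len, q) {
    tibble::tibble(read_id = id, sequence = strrep("A", len),
                   quality = strrep(intToUtf8(33 + q), len))
  }
  reads <- dplyr::bind_rows(
    lapply(1:5, function(i) mk(paste0("lowq", i), 12000, 10)),   # fail Q20
    lapply(1:5, function(i) mk(paste0("short", i), 140, 30)),    # fail 150 bp
    lapply(1:10, function(i) mk(paste0("long", i), 15000, 30))   # pass all
  )
  fr <- filter_reads(reads)
  expect_equal(unname(fr$counts), c(20, 10, 10))
  expect_equal(nrow(fr$analysis_set), 10)
  expect_true(all(grepl("^long", fr$analysis_set$read_id)))
  # 9 kb read passes QC but not the 10 kb analysis threshold
  mid <- filter_reads(mk("mid", 9000, 30))
  expect_equal(nrow(mid$qc_set), 1)
  expect_equal(nrow(mid$analysis_set), 0)
  # 140 bp at Q30 is excluded from the QC set by length alone
  expect_equal(nrow(filter_reads(mk("x", 140, 30))$qc_set), 0)
})

test_that("cargo location enforces the 80% right-end coverage rule", {
  lx <- fix_locus()
  tn <- lx$vec$transposon
  flank <- substr(lx$genome$sequence, 2001, 5000)
  full <- paste0(flank, tn, substr(lx$genome$sequence, 5001, 8000))
  hit <- locate_cargo(full, lx$vec)
  expect_true(hit$found)
  expect_equal(hit$right_end_coverage, 1.0)
  expect_true(hit$left_end_found)
  # truncate the read so only 70% of the right end remains -> rejected
  re_len <- diff(lx$vec$right_end)
  keep <- nchar(flank) + lx$vec$right_end[1] + floor(0.7 * re_len)
  trunc <- substr(full, 1, keep)
  miss <- locate_cargo(trunc, lx$vec)
  expect_false(miss$found)
  expect_equal(miss$reject_reason, "right_end")
  expect_lt(miss$right_end_coverage, 0.8)
  # no cargo at all
  none <- locate_cargo(flank, lx$vec)
  expect_equal(none$reject_reason, "no_cargo")
})

test_that("flank classification follows the >100 bp mapped rule", {
  lx <- fix_locus()
  tn <- lx$vec$transposon
  g <- lx$genome$sequence
  mkread <- function(left, right) paste0(left, tn, right)
  # simple insertion: both flanks genomic
  r1 <- mkread(substr(g, 3001, 4000), substr(g, 4001, 5000))
  c1 <- locate_cargo(r1, lx$vec)
  f1 <- classify_flanks(r1, c1, lx$genome, lx$vec)
  expect_equal(f1$left$label, "genomic")
  expect_equal(f1$right$label, "genomic")
  # cointegrate-like read: backbone on one side
  r2 <- mkread(substr(g, 3001, 4000), lx$vec$backbone)
  c2 <- locate_cargo(r2, lx$vec)
  f2 <- classify_flanks(r2, c2, lx$genome, lx$vec)
  expect_equal(f2$right$label, "plasmid")
  # 90 genomic bp is below the threshold -> unmapped
  r3 <- mkread(substr(g, 3001, 4000), substr(g, 8001, 8090))
  c3 <- locate_cargo(r3, lx$vec)
  f3 <- classify_flanks(r3, c3, lx$genome, lx$vec)
  expect_equal(f3$right$label, "unmapped")
  expect_lte(f3$right$genome_bp, 100)
})

test_that("calls recover planted truth exactly on error-free reads", {
  lx <- fix_locus(); rc <- fix_reads_clean()
  res <- fix_profile_clean()
  expect_equal(nrow(res$calls), nrow(rc$reads))
  m <- dplyr::inner_join(res$calls,
                         rc$reads[, c("read_id", "position", "orientation",
                                      "offset_bp", "cointegrate", "on_target")],
                         by = "read_id", suffix = c("", ".true"))
  expect_equal(m$junction, m$position + 1L) # 1-based output vs 0-based truth
  expect_equal(m$orientation, m$orientation.true)
  expect_equal(m$offset_bp, m$offset_bp.true)
  expect_equal(m$cointegrate, m$cointegrate.true)
  expect_equal(m$on_target, m$on_target.true)
  # an RL event at the default offset is called (RL, 49, on-target)
  rl <- m[m$orientation.true == "RL" & m$on_target.true, ][1, ]
  expect_equal(rl$orientation, "RL")
  expect_equal(rl$offset_bp, 49L)
  expect_true(rl$on_target)
  # the mirrored LR events carry the identical offset
  lr <- m[m$orientation.true == "LR" & m$on_target.true, ]
  expect_true(all(lr$offset_bp == 49L))
})

test_that("5% read error keeps labels right and the modal offset exact", {
  lx <- fix_locus(); rn <- fix_reads_noisy()
  res <- profile_reads(rn$reads, lx$vec, lx$genome, lx$target)
  m <- dplyr::inner_join(res$calls,
                         rn$reads[, c("read_id", "orientation", "offset_bp",
                                      "cointegrate", "on_target")],
                         by = "read_id", suffix = c("", ".true"))
  expect_gte(nrow(m), 20)
  expect_equal(m$orientation, m$orientation.true)
  expect_equal(m$cointegrate, m$cointegrate.true)
  # on-target percentage within 2 points of the planted truth
  s <- summarize_insertions(res$calls, lx$genome$length, counts = res$counts)
  expect_lt(abs(s$on_target_pct - 100 * mean(m$on_target.true)), 2 + 1e-9)
  expect_equal(s$modal_offset, 49L)
})

test_that("the filter chain is monotone and the summary percentages cohere", {
  res <- fix_profile_clean()
  lx <- fix_locus()
  expect_true(all(diff(unname(res$counts)) <= 0))
  s <- summarize_insertions(res$calls, lx$genome$length, counts = res$counts)
  expect_equal(sum(s$offset_hist$pct), 100)
  expect_equal(sum(s$orientation), 1)
  expect_equal(sum(s$genome_hist$n), s$n_called)
  # empty sentinel
  s0 <- summarize_insertions(res$calls[0, ], lx$genome$length)
  expect_true(s0$empty)
  expect_equal(s0$n_called, 0)
  expect_true(is.na(s0$on_target_pct))
})

test_that("profiling is invariant under reverse-complementing the locus", {
  lx <- fix_locus(); rc <- fix_reads_clean()
  L <- lx$genome$length
  g2 <- lx$genome
  g2$sequence <- revcomp(lx$genome$sequence)
  t2 <- lx$target
  t2$strand <- "-"
  t2$proto3p <- (L - 1L) - lx$target$proto3p
  res1 <- fix_profile_clean()
  res2 <- profile_reads(rc$reads, lx$vec, g2, t2)
  m <- dplyr::inner_join(res1$calls, res2$calls, by = "read_id",
                         suffix = c(".fwd", ".rev"))
  expect_equal(nrow(m), nrow(res1$calls))
  expect_equal(m$orientation.fwd, m$orientation.rev)
  expect_equal(m$offset_bp.fwd, m$offset_bp.rev)
  expect_equal(m$on_target.fwd, m$on_target.rev)
  expect_equal(m$cointegrate.fwd, m$cointegrate.rev)
  # junctions mirror: rev 1-based position of the base just downstream on the
  # flipped strand corresponds to L - (fwd junction) + 1 shifted by one base
  expect_equal(m$junction.rev, L - m$junction.fwd + 2L)
})

test_that("clone-level and read-level cointegrate estimates agree on clean data", {
  lx <- fix_locus(); rc <- fix_reads_clean()
  res <- fix_profile_clean()
  s <- summarize_insertions(res$calls, lx$genome$length)
  truth_rate <- 100 * mean(rc$reads$cointegrate)
  expect_equal(s$cointegrate_pct, truth_rate)
  expect_false(is.na(s$cointegrate_pct_clone))
})
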