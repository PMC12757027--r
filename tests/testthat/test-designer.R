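# Guide design: safe-site audit flags, exhaustive PAM/guide enumeration
# oracles, the GC/locus/terminator filters, off-target scoring, ranking, and
# strand symmetry of the whole pipeline.

test_that("safe sites accept convergent 300-600 nt gaps and flag the rest", {
  genes <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e", "f", "g", "h"),
    start = c(0, 1400, 3000, 3250, 5000, 6000, 8000, 9000),
    end = c(1000, 2400, 3200, 4200, 5800, 6900, 8700, 9950),
    strand = c("+", "-", "+", "-", "+", "+", "+", "-"))
  # gaps: a|b = 400 (conv), c|d = 50 (conv, short), e|f tandem, g|h = 300 (conv)
  sites <- find_safe_sites(genes, min_len = 300, max_len = 600)
  expect_equal(nrow(sites), 3)
  expect_equal(sites$accepted, c(TRUE, FALSE, TRUE))
  expect_match(sites$exclusion_flags[2], "too_short")
  # an ncRNA mask overlapping the first gap knocks it out
  masks <- tibble::tibble(label = "ncRNA", start = 1100L, end = 1200L)
  s2 <- find_safe_sites(genes, min_len = 300, max_len = 600, masks = masks)
  expect_false(s2$accepted[1])
  expect_match(s2$exclusion_flags[1], "ncRNA")
  # essential flank exclusion
  genes$essential <- c(TRUE, rep(FALSE, 7))
  s3 <- find_safe_sites(genes, min_len = 300, max_len = 600)
  expect_match(s3$exclusion_flags[1], "essential_flank")
  # 250 nt gap is too short
  g4 <- tibble::tibble(gene = c("x", "y"), start = c(0, 1250),
                       end = c(1000, 2000), strand = c("+", "-"))
  expect_match(find_safe_sites(g4)$exclusion_flags, "too_short")
})

test_that("PAM scanning matches exhaustive enumeration on both strands", {
  # hand-checkable cases
  p1 <- scan_pams("ACGT")
  expect_equal(nrow(p1[p1$strand == "+", ]), 1) # the C at index 1 (0-based)
  expect_equal(p1$pam[p1$strand == "+"], "CG")
  expect_equal(nrow(scan_pams("ATATTATA")), 0)  # A/T only: no C either strand
  p2 <- scan_pams("CCGG")
  expect_true(all(c("+", "-") %in% p2$strand))
  # exhaustive regex oracle on a random sequence
  withr::local_seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  got <- scan_pams(s)
  fwd <- gregexpr("(?=C.)", s, perl = TRUE)[[1]]
  rev_ <- gregexpr("(?=.G)", s, perl = TRUE)[[1]]
  expect_equal(got$pam_start[got$strand == "+"], as.integer(fwd) - 1L)
  expect_equal(got$pam_start[got$strand == "-"], as.integer(rev_))
})

test_that("guide extraction matches an exhaustive substring oracle", {
  withr::local_seed(12)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  pams <- scan_pams(s)
  guides <- extract_guides(s, pams)
  expect_true(all(nchar(guides$protospacer) == 32))
  for (i in seq_len(nrow(guides))) {
    g <- guides[i, ]
    if (g$strand == "+") {
      expect_equal(g$protospacer, substr(s, g$pam_start + 3, g$pam_start + 34))
      expect_equal(g$proto3p, g$pam_start + 33L)
    } else {
      expect_equal(g$protospacer,
                   revcomp(substr(s, g$pam_start - 32, g$pam_start - 1)))
      expect_equal(g$proto3p, g$pam_start - 33L)
    }
    # PAM as recorded matches the sequence read on the guide's strand
    pam_seq <- if (g$strand == "+") substr(s, g$pam_start + 1, g$pam_start + 2)
               else revcomp(substr(s, g$pam_start, g$pam_start + 1))
    expect_equal(g$pam, pam_seq)
    expect_equal(substr(g$pam, 1, 1), "C")
  }
  # candidates running off the sequence end are skipped, not truncated
  tail_pams <- scan_pams(s, start = 270)
  tg <- extract_guides(s, tail_pams)
  expect_true(all(tg$proto_end <= 300 & tg$proto_start >= 0))
  # GC arithmetic: 16 G/C of 32 -> 50%
  expect_equal(gc_percent(strrep("GCAT", 8)), 50)
})

test_that("guide filters enforce GC, locus containment and terminator masks", {
  site <- tibble::tibble(site = 1L, start = 0L, end = 300L)
  cand <- tibble::tibble(
    pam_start = c(10L, 20L, 200L, 40L), strand = "+",
    pam = "CA",
    protospacer = c(strrep("GCAT", 8), strrep("G", 32), strrep("GCAT", 8),
                    strrep("GCAT", 8)),
    proto_start = c(12L, 22L, 202L, 42L),
    proto_end = c(44L, 54L, 234L, 74L),
    proto3p = c(43L, 53L, 250L, 73L),
    gc_pct = c(50, 100, 50, 50))
  term <- tibble::tibble(start = 120L, end = 140L)
  out <- filter_guides(cand, site, terminator_mask = term)
  expect_true(out$accepted[1])
  expect_match(out$fails[2], "gc")          # GC 100%
  expect_match(out$fails[3], "locus_outside") # locus beyond the region end
  expect_match(out$fails[4], "terminator")  # locus 118..129 hits the mask
})

test_that("off-target scan finds planted duplicates and respects exclusion", {
  withr::local_seed(13)
  g <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  guide <- substr(g, 5001, 5032)
  # planted verbatim at a second locus
  g2 <- paste0(substr(g, 1, 12000), guide, substr(g, 12033, 20000))
  rep_ <- offtarget_scan(guide, g2, exclude_interval = c(5000L, 5032L))
  expect_equal(rep_$best_hit_identity, 1.0)
  expect_equal(rep_$best_hit_length, 32L)
  expect_equal(rep_$seed_matches, 10L)
  expect_gte(rep_$n_hits_above_floor, 1L)
  # with the duplicate's own locus also excluded, nothing is left above floor
  rep2 <- offtarget_scan(guide, g, exclude_interval = c(5000L, 5032L))
  expect_equal(rep2$n_hits_above_floor, 0L)
  expect_lt(rep2$best_hit_length, 32L)
  # a reverse-complement copy is found on the minus strand
  g3 <- paste0(substr(g, 1, 12000), revcomp(guide), substr(g, 12033, 20000))
  rep3 <- offtarget_scan(guide, g3, exclude_interval = c(5000L, 5032L))
  expect_equal(rep3$best_hit_identity, 1.0)
  expect_equal(rep3$seed_matches, 10L)
})

test_that("guide selection ranks by seed matches then score with stable ties", {
  acc <- tibble::tibble(
    pam_start = c(30L, 10L, 20L, 40L),
    protospacer = strrep("GCAT", 8), pam = "CA", strand = "+",
    seed_matches = c(10L, 0L, 0L, 2L),
    best_score = c(64L, 20L, 20L, 20L))
  sel <- select_guides(acc, k = 3)
  expect_equal(nrow(sel), 3)
  # seed-matched off-target ranks last; tie on (0, 20) broken by coordinate
  expect_equal(sel$pam_start, c(10L, 20L, 40L))
  expect_equal(sel$rank, 1:3)
  expect_warning(select_guides(acc[1:2, ], k = 3), "only 2")
  expect_warning(select_guides(acc[0, ], k = 3), "no accepted")
})

test_that("the full design pipeline emits 3 audited guides per accepted site", {
  g <- make_genome(n_converging_pairs = 4, seed = 21)
  dg <- design_guides(g, k = 3)
  expect_true(all(dg$sites$accepted))
  expect_equal(nrow(dg$guides), 12)
  expect_equal(unname(table(dg$guides$site)), rep(3L, 4), ignore_attr = TRUE)
  expect_true(all(nchar(dg$guides$protospacer) == 32))
  expect_true(all(substr(dg$guides$pam, 1, 1) == "C"))
  expect_true(all(dg$guides$gc_pct >= 40 & dg$guides$gc_pct <= 60))
  expect_true(all(dg$sites$length <= 600))
  # locus containment re-checked from the emitted coordinates
  for (i in seq_len(nrow(dg$guides))) {
    gu <- dg$guides[i, ]
    s <- dg$sites[dg$sites$site == gu$site, ]
    expect_gte(gu$locus_start, s$start)
    expect_lte(gu$locus_end, s$end)
  }
})

test_that("designing on the reverse-complemented genome mirrors the guides", {
  g <- make_genome(n_converging_pairs = 3, seed = 22)
  L <- g$length
  g2 <- g
  g2$sequence <- revcomp(g$sequence)
  g2$genes <- tibble::tibble(
    gene = rev(g$genes$gene),
    start = rev(L - g$genes$end), end = rev(L - g$genes$start),
    strand = rev(ifelse(g$genes$strand == "+", "-", "+")))
  g2$intergenic <- tibble::tibble(
    site = g$intergenic$site,
    start = rev(L - g$intergenic$end), end = rev(L - g$intergenic$start),
    left_gene = rev(g$intergenic$right_gene),
    right_gene = rev(g$intergenic$left_gene),
    length = rev(g$intergenic$length))
  d1 <- design_guides(g, k = 3)
  d2 <- design_guides(g2, k = 3)
  expect_setequal(d1$guides$protospacer, d2$guides$protospacer)
  expect_setequal(d1$guides$pam, d2$guides$pam)
})
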