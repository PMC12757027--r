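# Fitness calling: arithmetic oracles on toy tables, planted-effect recovery,
# and the label-symmetry / invariance properties of the consistency rule.

toy_meta <- function(n = 10, gene = sprintf("g%02d", seq_len(n)), pos = 0.5) {
  tibble::tibble(barcode = sprintf("bc%02d", seq_len(n)), gene = gene,
                 fractional_position = rep(pos, length.out = n))
}

test_that("strain fitness is the centred pseudocount log-ratio", {
  meta <- toy_meta(10)
  t0 <- stats::setNames(rep(100, 10), meta$barcode)
  # identity: post == t0 -> all zero after centering
  sf0 <- strain_fitness(t0, t0, meta)
  expect_true(all(sf0$log2_ratio == 0))
  # one strain at 4x against a null background: centred ratio ~ 2
  post <- t0; post["bc01"] <- 400
  sf <- strain_fitness(t0, post, meta, pseudocount = 1)
  expect_equal(sf$log2_ratio[sf$barcode == "bc01"],
               log2(401 / 101), tolerance = 1e-12)
  expect_equal(sf$log2_ratio[sf$barcode == "bc01"], 2, tolerance = 0.01)
  # dropout strain is unusable
  t0d <- t0; t0d["bc02"] <- 0
  sfd <- strain_fitness(t0d, post, meta)
  expect_false(sfd$usable[sfd$barcode == "bc02"])
  expect_error(strain_fitness(t0, stats::setNames(1:3, c("x", "y", "z")), meta),
               "shared")
})

test_that("gene fitness averages only central-window usable strains", {
  meta <- tibble::tibble(barcode = c("a", "b", "c", "d", "e"),
                         gene = c("g1", "g1", "g1", "g2", "g2"),
                         fractional_position = c(0.05, 0.5, 0.95, 0.3, 0.6))
  t0 <- stats::setNames(rep(1000, 5), meta$barcode)
  post <- stats::setNames(c(4000, 4000, 4000, 1000, 1000), meta$barcode)
  sf <- strain_fitness(t0, post, meta, central_window = c(0.1, 0.9))
  gf <- gene_fitness(sf)
  # only the 0.5 strain of g1 contributes
  expect_equal(gf$n_usable_strains[gf$gene == "g1"], 1)
  # mean of usable fitnesses {1, 3} = 2, on a hand-built table
  sf2 <- tibble::tibble(barcode = c("x", "y"), gene = "g",
                        fractional_position = 0.5, t0_count = 10,
                        post_count = 10, log2_ratio = c(1, 3), usable = TRUE)
  expect_equal(gene_fitness(sf2)$fitness, 2)
  # zero T0 across all strains -> nd
  t0z <- stats::setNames(c(1000, 1000, 1000, 0, 0), meta$barcode)
  gfz <- gene_fitness(strain_fitness(t0z, post, meta))
  expect_false(gfz$sufficient_t0[gfz$gene == "g2"])
})

test_that("differential fitness averages replicates and propagates nd", {
  gf <- function(fit, nd = FALSE, rep = 1) {
    tibble::tibble(gene = c("g1", "g2"), fitness = fit,
                   n_usable_strains = 2, sufficient_t0 = !nd,
                   replicate = rep)
  }
  cast <- dplyr::bind_rows(gf(c(-2, 0), rep = 1), gf(c(-2, 0), rep = 2),
                           gf(c(-2, 0), rep = 3))
  mar <- dplyr::bind_rows(gf(c(0, 0), rep = 1), gf(c(0, 0), rep = 2),
                          gf(c(0, 0), rep = 3))
  d <- differential_fitness(cast, mar)
  expect_equal(d$delta[d$gene == "g1"], -2)
  expect_equal(d$delta[d$gene == "g2"], 0)
  ident <- differential_fitness(cast, cast)
  expect_true(all(ident$delta == 0))
  expect_error(differential_fitness(cast[0, ], mar), "replicates")
})

test_that("candidate calling enforces the two-screen consistency rule", {
  mk <- function(d1, d2, nd = FALSE) {
    list(tibble::tibble(gene = "g", delta = d1, nd = nd),
         tibble::tibble(gene = "g", delta = d2, nd = nd))
  }
  call1 <- function(d1, d2, nd = FALSE) {
    x <- mk(d1, d2, nd); call_candidates(x[[1]], x[[2]])$call
  }
  expect_equal(call1(1.5, 0.8), "none")    # fails consistency
  expect_equal(call1(-1.2, -2.0), "activator")
  expect_equal(call1(1.2, 2.0), "inhibitor")
  expect_equal(call1(1.2, -2.0), "none")   # sign flip
  expect_equal(call1(5, 5, nd = TRUE), "nd")
})

test_that("planted effects are recovered and sign negation swaps labels", {
  fx <- fix_screen()
  rs <- run_screen(fx$counts, fx$design$meta)
  got <- rs$calls[match(fx$planted$gene, rs$calls$gene), ]
  # delta close to the planted CAST-only effect at 1e6 depth
  expect_true(all(abs(got$delta_screen1 - fx$planted$effect_val) < 0.3))
  expect_true(all(abs(got$delta_screen2 - fx$planted$effect_val) < 0.3))
  expect_equal(got$call, c("activator", "inhibitor", "activator"))
  # negating CAST effects in the generator swaps activator and inhibitor
  eff_neg <- fx$design$effects
  eff_neg$effect <- ifelse(eff_neg$condition == "CAST",
                           -eff_neg$effect, eff_neg$effect)
  d_neg <- fx$design; d_neg$effects <- eff_neg
  rs_neg <- run_screen(simulate_barseq(d_neg, depth = 1e6, seed = 2002),
                       fx$design$meta)
  got_neg <- rs_neg$calls[match(fx$planted$gene, rs_neg$calls$gene), ]
  expect_equal(got_neg$call, c("inhibitor", "activator", "inhibitor"))
})

test_that("gene fitness is invariant to strain order and barcode relabeling", {
  fx <- fix_screen()
  t0 <- fx$counts[fx$counts$screen == 1 & fx$counts$condition == "T0", ]
  post <- fx$counts[fx$counts$screen == 1 & fx$counts$condition == "CAST" &
                    fx$counts$replicate == 1, ]
  gf1 <- gene_fitness(strain_fitness(t0, post, fx$design$meta))
  perm <- sample(nrow(fx$design$meta))
  gf2 <- gene_fitness(strain_fitness(t0, post, fx$design$meta[perm, ]))
  expect_equal(dplyr::arrange(gf1, gene), dplyr::arrange(gf2, gene))
  relabel <- function(x) { x$barcode <- sub("^bc", "BARCODE_", x$barcode); x }
  meta3 <- relabel(fx$design$meta)
  t03 <- relabel(t0)
  post3 <- relabel(post)
  gf3 <- gene_fitness(strain_fitness(t03, post3, meta3))
  expect_equal(dplyr::arrange(gf1, gene), dplyr::arrange(gf3, gene))
})

test_that("T0 QC reports dropout genes and ignores post-selection counts", {
  n <- 3744
  meta <- toy_meta(n, gene = sprintf("gene%04d", seq_len(n)))
  t0 <- stats::setNames(rep(100, n), meta$barcode)
  qc0 <- t0_qc(t0, meta)
  expect_equal(nrow(qc0), 0)
  expect_equal(attr(qc0, "fraction_pct"), 0)
  t0[1:107] <- 0
  qc <- t0_qc(t0, meta)
  expect_equal(attr(qc, "n_missing"), 107)
  expect_equal(attr(qc, "fraction_pct"), 2.9)
})

test_that("null screens control the false-positive rate and improve with depth", {
  fp_rate <- function(depth, seed) {
    d <- make_screen_design(n_genes = 300, strains_per_gene = 5,
                            null_effect_sd = 0.3, seed = seed)
    rs <- run_screen(simulate_barseq(d, depth = depth, seed = seed + 1),
                     d$meta)
    mean(rs$calls$call %in% c("activator", "inhibitor"))
  }
  shallow <- mean(vapply(1:3, function(s) fp_rate(2e4, 3000 + s), numeric(1)))
  deep <- mean(vapply(1:3, function(s) fp_rate(1e6, 3100 + s), numeric(1)))
  expect_lt(deep, 0.01)
  expect_lte(deep, shallow)
})
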