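# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 50 kb genome, target in the second convergent gap, standard vector
fix_locus <- function() {
  fixture("locus", function() {
    g <- make_genome(length = 50000, n_converging_pairs = 4, seed = 1001)
    pt <- plant_target(g, site_index = 2, seed = 1002)
    list(genome = pt$genome, target = pt$target,
         vec = make_cast_vector(seed = 1003))
  })
}

# mixed-outcome truth + error-free reads
fix_reads_clean <- function() {
  fixture("reads_clean", function() {
    lx <- fix_locus()
    truth <- simulate_insertions(lx$genome, lx$target, n_events = 30,
                                 orientation_probs = c(RL = 0.5, LR = 0.5),
                                 cointegrate_rate = 0.2, off_target_rate = 0.1,
                                 seed = 1010)
    reads <- simulate_long_reads(lx$genome, truth, lx$vec, n_reads = 24,
                                 per_base_error = 0, sample_events = FALSE,
                                 seed = 1011)
    list(truth = truth, reads = reads)
  })
}

# same event mix with 5% read error
fix_reads_noisy <- function() {
  fixture("reads_noisy", function() {
    lx <- fix_locus()
    truth <- simulate_insertions(lx$genome, lx$target, n_events = 30,
                                 orientation_probs = c(RL = 0.5, LR = 0.5),
                                 cointegrate_rate = 0.2, off_target_rate = 0.1,
                                 seed = 1010)
    reads <- simulate_long_reads(lx$genome, truth, lx$vec, n_reads = 24,
                                 per_base_error = 0.05, sample_events = FALSE,
                                 seed = 1012)
    list(truth = truth, reads = reads)
  })
}

fix_profile_clean <- function() {
  fixture("profile_clean", function() {
    lx <- fix_locus(); rc <- fix_reads_clean()
    profile_reads(rc$reads, lx$vec, lx$genome, lx$target)
  })
}

# small two-screen design with planted effects for recovery tests
fix_screen <- function() {
  fixture("screen", function() {
    planted <- tibble::tibble(
      gene = c("gene0005", "gene0010", "gene0015"),
      effect_val = c(-1.5, 2.5, -2.5))
    eff <- tidyr::expand_grid(gene = planted$gene, screen = 1:2,
                              condition = "CAST") |>
      dplyr::left_join(planted, by = "gene") |>
      dplyr::rename(effect = effect_val)
    design <- make_screen_design(n_genes = 200, strains_per_gene = 10,
                                 effects = eff, seed = 2001)
    counts <- simulate_barseq(design, depth = 1e6, seed = 2002)
    list(design = design, counts = counts, planted = planted)
  })
}
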