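# End-to-end recovery experiments at the study's conditions. Each experiment
# generates synthetic data with planted truth, runs the corresponding
# analysis, and returns both the planted truth and the recovered quantities,
# so that parameter recovery can be checked (and reported) from a single
# seeded call.

#' Two-screen host-factor recovery experiment
#'
#' Simulates the differential RB-TnSeq screen over a 3,744-gene library with
#' a planted hit set (11 activators with negative CAST effects, 4 inhibitors
#' with positive effects, magnitudes above the calling threshold in both
#' screens) among null genes with independent per-screen `N(0, 0.3)` effects,
#' then runs the full fitness pipeline and the two-screen consistency call.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_genes Gene universe size.
#' @param n_activators,n_inhibitors Planted hit counts.
#' @param effect_range Planted effect magnitudes are uniform in this range.
#' @param strains_per_gene Barcoded mutants per gene.
#' @param depth Reads per BarSeq sample.
#' @param threshold Consistency-rule threshold.
#' @return List with `calls`, `n_activators_called`, `n_inhibitors_called`,
#'   `planted` (the hit table) and `recovered` (planted hits called with the
#'   planted label).
#' @export
experiment_screen <- function(seed, n_genes = 3744, n_activators = 11,
                              n_inhibitors = 4, effect_range = c(2, 4),
                              strains_per_gene = 10, depth = 1e6,
                              threshold = 1) {
  n_hits <- n_activators + n_inhibitors
  planted <- with_seed(seed, {
    genes <- sprintf("gene%04d", sample(n_genes, n_hits))
    tibble(gene = genes,
           sign = c(rep(-1, n_activators), rep(1, n_inhibitors)),
           magnitude = runif(n_hits, effect_range[1], effect_range[2]))
  })
  eff <- tidyr::expand_grid(gene = planted$gene, screen = 1:2) |>
    mutate(condition = "CAST") |>
    left_join(planted, by = "gene") |>
    mutate(effect = .data$sign * .data$magnitude) |>
    select("gene", "screen", "condition", "effect")
  design <- make_screen_design(n_genes = n_genes,
                               strains_per_gene = strains_per_gene,
                               effects = eff, seed = seed + 1)
  counts <- simulate_barseq(design, depth = depth, seed = seed + 2)
  rs <- run_screen(counts, design$meta, threshold = threshold)
  truth <- mutate(planted,
                  label = ifelse(.data$sign < 0, "activator", "inhibitor"))
  joined <- inner_join(rs$calls, truth, by = "gene")
  list(calls = rs$calls,
       n_activators_called = sum(rs$calls$call == "activator"),
       n_inhibitors_called = sum(rs$calls$call == "inhibitor"),
       planted = truth,
       recovered = sum(joined$call == joined$label))
}

#' Time-zero dropout QC experiment
#'
#' Plants `n_dropouts` genes absent at time zero in screen 1 of an
#' `n_genes` library and reports the QC fraction.
#'
#' @param seed Integer seed.
#' @param n_genes,n_dropouts Library size and planted dropout count.
#' @return List with `n_missing` and `fraction_pct`.
#' @export
experiment_t0_qc <- function(seed, n_genes = 3744, n_dropouts = 107) {
  drop <- tibble(gene = sprintf("gene%04d", seq_len(n_dropouts)), screen = 1L)
  design <- make_screen_design(n_genes = n_genes, strains_per_gene = 2,
                               dropout_genes = drop, seed = seed)
  counts <- simulate_barseq(design, depth = 5e5, n_replicates = 1,
                            seed = seed + 1)
  t0 <- filter(counts, .data$screen == 1, .data$condition == "T0")
  qc <- t0_qc(t0, design$meta)
  list(n_missing = attr(qc, "n_missing"),
       fraction_pct = attr(qc, "fraction_pct"))
}

#' Long-read insertion-profiling recovery experiment
#'
#' Builds a 50-kb genome with a planted target, simulates integration events
#' and Nanopore-like reads over 10 kb, and profiles them end to end.
#'
#' @param seed Integer seed.
#' @param n_events Number of integration events (clones).
#' @param n_reads Number of reads (one per event when
#'   `sample_events = FALSE`).
#' @param cointegrate_rate,off_target_rate,orientation_probs Planted rates.
#' @param per_base_error Read error rate.
#' @param sample_events Passed to [simulate_long_reads()].
#' @return List with `truth`, `summary` (an `insertion_profile`), `calls`
#'   and `counts`.
#' @export
experiment_profiling <- function(seed, n_events = 500, n_reads = 500,
                                 cointegrate_rate = 0, off_target_rate = 0,
                                 orientation_probs = c(RL = 0.9, LR = 0.1),
                                 per_base_error = 0.05,
                                 sample_events = FALSE) {
  g <- make_genome(length = 50000, n_converging_pairs = 4, seed = seed)
  pt <- plant_target(g, site_index = 2, seed = seed + 1)
  vec <- make_cast_vector(seed = seed + 2)
  truth <- simulate_insertions(pt$genome, pt$target, n_events = n_events,
                               cointegrate_rate = cointegrate_rate,
                               off_target_rate = off_target_rate,
                               orientation_probs = orientation_probs,
                               seed = seed + 3)
  reads <- simulate_long_reads(pt$genome, truth, vec, n_reads = n_reads,
                               per_base_error = per_base_error,
                               sample_events = sample_events,
                               seed = seed + 4)
  res <- profile_reads(reads, vec, pt$genome, pt$target)
  s <- summarize_insertions(res$calls, pt$genome$length, counts = res$counts)
  list(truth = truth, summary = s, calls = res$calls, counts = res$counts)
}

#' Day-paired fold-change recovery experiment
#'
#' Simulates `n_days` conjugation days, each with a treatment and a same-day
#' control whose true efficiency ratio is `true_fold` (control efficiency
#' `control_efficiency` of `total_cfu` cells/ml), titers the spot plates, and
#' recovers the day-paired fold changes.
#'
#' Spots are simulated in duplicate over a 1e2..1e8 dilution series and
#' counted up to 300 colonies: the replicate spread the source experiment
#' reports implies per-titer counting noise well below what single <=30
#' colony spots could deliver, so the emulation counts denser spots.
#'
#' @param seed Integer seed.
#' @param true_fold Planted treatment/control efficiency ratio.
#' @param control_efficiency True control editing efficiency.
#' @param total_cfu True total titer, CFU/ml.
#' @param n_days Paired days (biological replicates).
#' @param n_spots Technical replicate spots per dilution.
#' @param countable_max Upper countable limit per spot.
#' @return List with `folds` (per day), `mean_fold`, and the
#'   [one_sample_t()] result against the normalised control.
#' @export
experiment_fold <- function(seed, true_fold = 55.2,
                            control_efficiency = 1e-3, total_cfu = 2.5e9,
                            n_days = 3, n_spots = 2, countable_max = 300) {
  plates <- list()
  for (d in seq_len(n_days)) {
    day <- sprintf("day%d", d)
    ctrl <- make_plate_truth(total_cfu, total_cfu * control_efficiency,
                             dilution_factors = 10^(2:8), day = day)
    trt <- make_plate_truth(total_cfu,
                            total_cfu * control_efficiency * true_fold,
                            dilution_factors = 10^(2:8), day = day)
    pc <- simulate_spot_plates(ctrl, n_spots = n_spots,
                               countable_max = countable_max,
                               seed = seed + 10 * d)
    ptr <- simulate_spot_plates(trt, n_spots = n_spots,
                                countable_max = countable_max,
                                seed = seed + 10 * d + 1)
    pc$sample <- paste0("control_", day); pc$role <- "control"
    ptr$sample <- paste0("treatment_", day); ptr$role <- "treatment"
    plates[[length(plates) + 1]] <- bind_rows(pc, ptr)
  }
  res <- efficiency_from_plates(bind_rows(plates),
                                countable_range = c(3, countable_max))
  folds <- res$folds
  tt <- one_sample_t(folds$fold_change, mu = 1, direction = "greater")
  list(folds = folds, mean_fold = mean(folds$fold_change), t_test = tt)
}
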