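# RB-TnSeq screen and spot-plate simulation.
#
# The screen generator emulates a barcoded transposon-mutant library run
# through two parallel differential screens (a CAST condition and a mariner
# transposase control, each against a shared time-zero sample), with per-gene
# true fitness effects planted per screen and per condition. The spot-plate
# generator emulates 10-fold serial-dilution titering of transconjugant and
# total populations.

#' Design a synthetic barcoded mutant library for two parallel screens
#'
#' Each gene carries `strains_per_gene` uniquely barcoded insertion mutants at
#' random fractional positions. True fitness effects are drawn per gene, per
#' screen and per condition: planted effects are taken from `effects`, every
#' other (null) gene gets an independent `N(0, null_effect_sd)` effect in the
#' CAST condition per screen; the mariner control is exactly neutral.
#'
#' @param n_genes Number of genes in the library universe.
#' @param strains_per_gene Barcoded insertion mutants per gene.
#' @param effects Optional tibble of planted effects with columns
#'   `gene`, `screen`, `condition`, `effect` (missing screen/condition
#'   combinations are filled from the null model).
#' @param null_effect_sd SD of the per-screen null CAST effects.
#' @param dropout_genes Character vector of gene ids absent at time zero, or a
#'   tibble with columns `gene`, `screen` for screen-specific dropouts.
#' @param t0_lognormal_sd SD (log scale) of per-strain time-zero abundance.
#' @param seed Integer seed.
#' @return A `screen_design`: list with `meta` (tibble `barcode`, `gene`,
#'   `fractional_position`), `effects` (tibble `gene`, `screen`, `condition`,
#'   `effect`), `dropouts` (tibble `gene`, `screen`), `t0_abundance`
#'   (per-strain relative abundance) and `genes`.
#' @export
make_screen_design <- function(n_genes = 3744, strains_per_gene = 3,
                               effects = NULL, null_effect_sd = 0.3,
                               dropout_genes = character(),
                               t0_lognormal_sd = 0.3, seed = NULL) {
  stopifnot(n_genes >= 1, strains_per_gene >= 1)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  with_seed(seed, {
    meta <- tibble(
      barcode = sprintf("bc%05d", seq_len(n_genes * strains_per_gene)),
      gene = rep(genes, each = strains_per_gene),
      fractional_position = runif(n_genes * strains_per_gene)
    )
    base <- tidyr::expand_grid(gene = genes, screen = 1:2,
                               condition = c("CAST", "mariner"))
    base$effect <- ifelse(base$condition == "CAST",
                          rnorm(nrow(base), 0, null_effect_sd), 0)
    if (!is.null(effects)) {
      effects <- as_tibble(effects)
      stopifnot(all(c("gene", "screen", "condition", "effect") %in% names(effects)))
      base <- base |>
        left_join(effects, by = c("gene", "screen", "condition"),
                  suffix = c("", ".planted")) |>
        mutate(effect = ifelse(is.na(.data$effect.planted),
                               .data$effect, .data$effect.planted)) |>
        select(-"effect.planted")
    }
    dropouts <- if (is.character(dropout_genes)) {
      tidyr::expand_grid(gene = dropout_genes, screen = 1:2)
    } else {
      as_tibble(dropout_genes)[, c("gene", "screen")]
    }
    structure(list(meta = meta, effects = base, dropouts = dropouts,
                   t0_abundance = setNames(
                     exp(rnorm(nrow(meta), 0, t0_lognormal_sd)), meta$barcode),
                   genes = genes),
              class = "screen_design")
  })
}

#' Simulate BarSeq count tables for two parallel screens
#'
#' Per screen, one pooled time-zero sample and `n_replicates` post-selection
#' replicates per condition are drawn. A strain's expected post-selection
#' share is its time-zero share multiplied by `2^effect` (plus optional
#' per-strain lognormal noise on the effect), renormalised; counts are
#' negative-binomial with dispersion `nb_size`. Strains of dropout genes get
#' zero time-zero (and post) counts in the affected screen.
#'
#' @param design A `screen_design`.
#' @param depth Expected total reads per sample.
#' @param n_replicates Post-selection replicates per condition.
#' @param nb_size Negative-binomial size (larger = closer to Poisson).
#' @param noise_sd SD of per-strain noise added to the gene effect (log2).
#' @param seed Integer seed.
#' @return Tibble with `screen`, `condition` (`T0`, `CAST`, `mariner`),
#'   `replicate` (0 for T0), `barcode`, `count`.
#' @export
simulate_barseq <- function(design, depth = 1e6, n_replicates = 3,
                            nb_size = 50, noise_sd = 0.1, seed = NULL) {
  stopifnot(inherits(design, "screen_design"), depth > 0)
  meta <- design$meta
  with_seed(seed, {
    out <- list()
    for (scr in 1:2) {
      drop <- design$dropouts$gene[design$dropouts$screen == scr]
      ab <- design$t0_abundance
      ab[meta$gene %in% drop] <- 0
      p0 <- ab / sum(ab)
      out[[length(out) + 1]] <- tibble(
        screen = scr, condition = "T0", replicate = 0L,
        barcode = meta$barcode,
        count = rnbinom(nrow(meta), mu = depth * p0, size = nb_size)
      )
      for (cond in c("CAST", "mariner")) {
        eff <- design$effects |>
          filter(.data$screen == scr, .data$condition == cond)
        gene_eff <- setNames(eff$effect, eff$gene)[meta$gene]
        for (rep_i in seq_len(n_replicates)) {
          e <- gene_eff
          if (noise_sd > 0) e <- e + rnorm(length(e), 0, noise_sd)
          w <- p0 * 2^e
          w <- if (sum(w) > 0) w / sum(w) else w
          out[[length(out) + 1]] <- tibble(
            screen = scr, condition = cond, replicate = rep_i,
            barcode = meta$barcode,
            count = rnbinom(nrow(meta), mu = depth * w, size = nb_size)
          )
        }
      }
    }
    bind_rows(out)
  })
}

#' Define ground truth for a serial-dilution spot-plate experiment
#'
#' @param total_cfu_per_ml,transconjugant_cfu_per_ml True titers
#'   (transconjugant must not exceed total).
#' @param dilution_factors Powers of 10; the lowest factor sets the detection
#'   limit (1 colony at the lowest dilution; the defaults give the
#'   1e5 CFU/ml limit of 10 ul spots diluted 1e3-fold).
#' @param spot_volume_ul Spotted volume per dilution, ul.
#' @param day Day label used for treatment/control pairing.
#' @return A `plate_truth` list.
#' @export
make_plate_truth <- function(total_cfu_per_ml, transconjugant_cfu_per_ml,
                             dilution_factors = 10^(3:8), spot_volume_ul = 10,
                             day = "day1") {
  stopifnot(transconjugant_cfu_per_ml <= total_cfu_per_ml,
            spot_volume_ul > 0)
  lf <- log10(dilution_factors)
  if (any(abs(lf - round(lf)) > 1e-8)) abort("dilution factors must be powers of 10")
  structure(list(total_cfu_per_ml = total_cfu_per_ml,
                 transconjugant_cfu_per_ml = transconjugant_cfu_per_ml,
                 dilution_factors = dilution_factors,
                 spot_volume_ul = spot_volume_ul, day = day),
            class = "plate_truth")
}

#' Simulate colony counts from 10-fold serial-dilution spot plates
#'
#' Colony counts per spot are Poisson with mean
#' `cfu_per_ml * (spot_volume_ul / 1000) / dilution_factor`; counts above
#' `countable_max` are reported as lawns (`NA` count, `lawn = TRUE`), the way
#' a plate reader would record them.
#'
#' @param truth A `plate_truth` from [make_plate_truth()].
#' @param n_spots Technical replicate spots per dilution.
#' @param countable_max Counts above this are flagged as lawns.
#' @param seed Integer seed.
#' @return Tibble with `day`, `plate` (`total`/`transconjugant`),
#'   `dilution_factor`, `spot`, `count` (`NA` for lawns), `lawn`.
#' @export
simulate_spot_plates <- function(truth, n_spots = 1, countable_max = 30,
                                 seed = NULL) {
  stopifnot(inherits(truth, "plate_truth"))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      plate = c("total", "transconjugant"),
      dilution_factor = truth$dilution_factors,
      spot = seq_len(n_spots)
    )
    cfu <- ifelse(grid$plate == "total", truth$total_cfu_per_ml,
                  truth$transconjugant_cfu_per_ml)
    mu <- cfu * (truth$spot_volume_ul / 1000) / grid$dilution_factor
    raw <- rpois(nrow(grid), mu)
    grid$lawn <- raw > countable_max
    grid$count <- ifelse(grid$lawn, NA_integer_, raw)
    grid$day <- truth$day
    grid$spot_volume_ul <- truth$spot_volume_ul
    grid[, c("day", "plate", "dilution_factor", "spot", "spot_volume_ul",
             "count", "lawn")]
  })
}
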