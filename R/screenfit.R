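# Gene-fitness calling for differential RB-TnSeq screens.
#
# Strain fitness is the pseudocounted log2 post/T0 ratio, median-centred so a
# typical (null) strain scores 0. Gene fitness is the unweighted mean over
# usable strains: insertion in the central region of the gene and enough
# time-zero reads. Per screen, the CAST condition is contrasted against the
# mariner control (replicates averaged first), and candidate regulators are
# genes whose CAST - mariner difference exceeds the threshold, with a
# consistent sign, in both independent screens: positive differences mark
# putative inhibitors (mutating the gene helps CAST), negative differences
# putative activators. Genes without sufficient time-zero abundance in a
# screen are reported "nd" and excluded from calling.

as_count_tbl <- function(x, value_name = "count") {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble(barcode = names(x), count = as.numeric(x))
  }
  x <- as_tibble(x)
  stopifnot(all(c("barcode", "count") %in% names(x)))
  x[, c("barcode", "count")]
}

#' Per-strain fitness from barcode counts
#'
#' `log2((post + pseudocount) / (t0 + pseudocount))`, median-centred over
#' strains with sufficient time-zero counts. A strain is `usable` when its
#' time-zero count reaches `min_t0` and its insertion lies in the central
#' window of the gene.
#'
#' @param t0_counts,post_counts Tibbles with `barcode`, `count` (or named
#'   numeric vectors). Barcodes are matched by key; strains missing from
#'   either table get a zero count there.
#' @param meta Strain metadata tibble: `barcode`, `gene`,
#'   `fractional_position`.
#' @param pseudocount Added to both counts before the ratio (> 0).
#' @param min_t0 Minimum time-zero reads for a usable strain.
#' @param central_window Fractional-position window (within `[0, 1]`) of
#'   insertions that report on gene function.
#' @return Tibble with `barcode`, `gene`, `fractional_position`, `t0_count`,
#'   `post_count`, `log2_ratio` (centred), `usable`.
#' @export
strain_fitness <- function(t0_counts, post_counts, meta, pseudocount = 1,
                           min_t0 = 3, central_window = c(0.1, 0.9)) {
  stopifnot(pseudocount > 0,
            central_window[1] >= 0, central_window[2] <= 1)
  t0 <- rename(as_count_tbl(t0_counts), t0_count = "count")
  post <- rename(as_count_tbl(post_counts), post_count = "count")
  if (length(intersect(t0$barcode, post$barcode)) == 0) {
    abort("no shared barcodes between t0 and post-selection counts")
  }
  meta <- as_tibble(meta)
  stopifnot(all(c("barcode", "gene", "fractional_position") %in% names(meta)))
  out <- meta |>
    left_join(t0, by = "barcode") |>
    left_join(post, by = "barcode") |>
    mutate(t0_count = ifelse(is.na(.data$t0_count), 0, .data$t0_count),
           post_count = ifelse(is.na(.data$post_count), 0, .data$post_count),
           log2_ratio = log2((.data$post_count + pseudocount) /
                             (.data$t0_count + pseudocount)),
           usable = .data$t0_count >= min_t0 &
             .data$fractional_position >= central_window[1] &
             .data$fractional_position <= central_window[2])
  keep <- out$t0_count >= min_t0
  centre <- if (any(keep)) median(out$log2_ratio[keep]) else median(out$log2_ratio)
  mutate(out, log2_ratio = .data$log2_ratio - centre)
}

#' Gene fitness by central-region averaging
#'
#' Unweighted mean of usable strains' centred log2 ratios per gene. A gene
#' with fewer than `min_strains` usable strains is flagged
#' `sufficient_t0 = FALSE` ("nd": no data) and its fitness is `NA`.
#'
#' @param strain_tbl Output of [strain_fitness()].
#' @param min_strains Minimum usable strains for a defined gene score.
#' @return Tibble with `gene`, `fitness`, `n_usable_strains`, `sufficient_t0`.
#' @export
gene_fitness <- function(strain_tbl, min_strains = 1) {
  strain_tbl |>
    group_by(.data$gene) |>
    summarise(
      fitness = ifelse(sum(.data$usable) >= min_strains,
                       mean(.data$log2_ratio[.data$usable]), NA_real_),
      n_usable_strains = sum(.data$usable),
      sufficient_t0 = sum(.data$usable) >= min_strains,
      .groups = "drop"
    )
}

#' CAST - mariner differential fitness per gene
#'
#' Replicates are averaged within each condition, then the mariner-control
#' mean is subtracted from the CAST mean. A gene that is "nd" (insufficient
#' time zero) in any replicate of either condition is "nd" for the screen.
#'
#' @param cast_fit,mariner_fit Tibbles of per-replicate gene fitness: columns
#'   of [gene_fitness()] output plus a `replicate` column (a single
#'   replicate's table, without the column, is accepted).
#' @return Tibble with `gene`, `delta` (CAST - mariner), `nd`.
#' @export
differential_fitness <- function(cast_fit, mariner_fit) {
  summarise_cond <- function(x) {
    x <- as_tibble(x)
    if (nrow(x) == 0) abort("no replicates supplied")
    x |>
      group_by(.data$gene) |>
      summarise(mean_fit = mean(.data$fitness),
                nd = any(!.data$sufficient_t0), .groups = "drop")
  }
  ca <- summarise_cond(cast_fit)
  ma <- summarise_cond(mariner_fit)
  if (!setequal(ca$gene, ma$gene)) {
    abort("CAST and mariner tables must cover the same gene universe")
  }
  inner_join(ca, ma, by = "gene", suffix = c("_cast", "_mariner")) |>
    mutate(nd = .data$nd_cast | .data$nd_mariner,
           delta = ifelse(.data$nd, NA_real_,
                          .data$mean_fit_cast - .data$mean_fit_mariner)) |>
    select("gene", "delta", "nd")
}

#' Call activator/inhibitor candidates with the two-screen consistency rule
#'
#' A gene is an inhibitor when its differential exceeds `threshold` in both
#' screens, an activator when it is below `-threshold` in both, `nd` when
#' either screen lacks data, `none` otherwise. Output is sorted by decreasing
#' absolute mean differential.
#'
#' @param delta1,delta2 Per-screen differential tables from
#'   [differential_fitness()].
#' @param threshold Positive fitness-difference threshold (default 1).
#' @return Tibble with `gene`, `delta_screen1`, `delta_screen2`, `call`.
#' @export
call_candidates <- function(delta1, delta2, threshold = 1) {
  stopifnot(threshold > 0)
  d <- inner_join(rename(delta1, delta_screen1 = "delta", nd1 = "nd"),
                  rename(delta2, delta_screen2 = "delta", nd2 = "nd"),
                  by = "gene")
  d |>
    mutate(call = case_when(
      .data$nd1 | .data$nd2 ~ "nd",
      .data$delta_screen1 > threshold & .data$delta_screen2 > threshold ~ "inhibitor",
      .data$delta_screen1 < -threshold & .data$delta_screen2 < -threshold ~ "activator",
      TRUE ~ "none"
    )) |>
    mutate(.abs = abs((.data$delta_screen1 + .data$delta_screen2) / 2)) |>
    arrange(desc(.data$.abs)) |>
    select("gene", "delta_screen1", "delta_screen2", "call")
}

#' Time-zero dropout QC
#'
#' Lists genes whose total time-zero count over all their strains falls below
#' `min_t0`; these cannot be scored and flag possible bottlenecking during
#' library propagation.
#'
#' @param t0_counts Tibble `barcode`, `count` (or named vector).
#' @param meta Strain metadata (`barcode`, `gene`).
#' @param min_t0 Minimum total time-zero reads per gene.
#' @return Tibble of missing genes (`gene`, `t0_total`), with attributes
#'   `n_genes`, `n_missing` and `fraction_pct` (percent of the gene universe,
#'   1 decimal place).
#' @export
t0_qc <- function(t0_counts, meta, min_t0 = 3) {
  t0 <- as_count_tbl(t0_counts)
  meta <- as_tibble(meta)
  tot <- meta |>
    left_join(t0, by = "barcode") |>
    mutate(count = ifelse(is.na(.data$count), 0, .data$count)) |>
    group_by(.data$gene) |>
    summarise(t0_total = sum(.data$count), .groups = "drop")
  missing <- filter(tot, .data$t0_total < min_t0)
  structure(missing,
            n_genes = nrow(tot),
            n_missing = nrow(missing),
            fraction_pct = round(100 * nrow(missing) / nrow(tot), 1))
}

#' Run the full two-screen differential fitness analysis
#'
#' Convenience driver from a [simulate_barseq()]-shaped count table to
#' candidate calls: per screen and condition, per-replicate strain and gene
#' fitness against the screen's pooled T0, replicate averaging, the CAST -
#' mariner differential, and the two-screen consistency call.
#'
#' @param counts Tibble with `screen`, `condition`, `replicate`, `barcode`,
#'   `count` (condition `T0` is the reference).
#' @param meta Strain metadata (`barcode`, `gene`, `fractional_position`).
#' @param threshold Consistency-rule threshold.
#' @param ... Passed to [strain_fitness()] (`pseudocount`, `min_t0`,
#'   `central_window`) .
#' @return List with `gene_fitness` (per screen/condition/replicate),
#'   `deltas` (per screen), `calls`, and `qc` (per-screen [t0_qc()] reports).
#' @export
run_screen <- function(counts, meta, threshold = 1, ...) {
  counts <- as_tibble(counts)
  deltas <- list(); gf_all <- list(); qc <- list()
  for (scr in sort(unique(counts$screen))) {
    t0 <- filter(counts, .data$screen == scr, .data$condition == "T0")
    fits <- list()
    for (cond in c("CAST", "mariner")) {
      reps <- filter(counts, .data$screen == scr, .data$condition == cond)
      fits[[cond]] <- bind_rows(lapply(sort(unique(reps$replicate)), function(r) {
        sf <- strain_fitness(t0, filter(reps, .data$replicate == r), meta, ...)
        mutate(gene_fitness(sf), screen = scr, condition = cond, replicate = r)
      }))
    }
    gf_all[[as.character(scr)]] <- bind_rows(fits)
    deltas[[as.character(scr)]] <- differential_fitness(fits$CAST, fits$mariner)
    qc[[as.character(scr)]] <- t0_qc(t0, meta)
  }
  list(gene_fitness = bind_rows(gf_all),
       deltas = deltas,
       calls = call_candidates(deltas[["1"]], deltas[["2"]], threshold),
       qc = qc)
}
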