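# Editing-efficiency statistics from serial-dilution spot plates.
#
# Titers come from countable spots (pooled over spots, weighted by plated
# volume); efficiency is transconjugant / total CFU per ml with censored
# ("below detection") values propagated as upper bounds, never imputed as
# zero; fold changes pair each treatment strictly with the control of the
# same day; significance against the normalised control (hypothetical mean
# 1) uses a one-sample, one-tailed t test.

#' CFU/ml titer from serial-dilution spot counts
#'
#' Each countable spot estimates `count * dilution_factor * (1000 /
#' spot_volume_ul)` CFU/ml; spots are pooled by total colonies over total
#' plated volume (a volume-weighted average, robust to spots near the
#' countable minimum). All-zero series are censored at the detection limit:
#' one colony in a spot of the least-diluted plating.
#'
#' @param counts Colony counts per spot (`NA` for lawns), parallel to
#'   `dilution_factors`; or a tibble from [simulate_spot_plates()] (one
#'   plate) with `count` and `dilution_factor` columns.
#' @param dilution_factors Dilution factor per spot (powers of 10).
#' @param spot_volume_ul Spotted volume, ul.
#' @param countable_range Counts outside `[min, max]` (or lawns) are ignored.
#' @return One-row tibble: `cfu_per_ml`, `below_detection`,
#'   `detection_limit`, `n_countable`.
#' @export
cfu_from_spots <- function(counts, dilution_factors = NULL,
                           spot_volume_ul = 10, countable_range = c(3, 30)) {
  if (is.data.frame(counts)) {
    tb <- counts
    dilution_factors <- tb$dilution_factor
    if ("spot_volume_ul" %in% names(tb)) spot_volume_ul <- tb$spot_volume_ul[1]
    counts <- tb$count
  }
  stopifnot(length(counts) == length(dilution_factors), spot_volume_ul > 0)
  vol_ml <- spot_volume_ul / 1000
  limit <- 1 * min(dilution_factors) / vol_ml
  countable <- !is.na(counts) &
    counts >= countable_range[1] & counts <= countable_range[2]
  if (!any(countable)) {
    below <- all(is.na(counts) | counts == 0 | counts < countable_range[1])
    return(tibble(cfu_per_ml = NA_real_, below_detection = below,
                  detection_limit = limit, n_countable = 0L))
  }
  est <- sum(counts[countable]) / sum(vol_ml / dilution_factors[countable])
  tibble(cfu_per_ml = est, below_detection = FALSE,
         detection_limit = limit, n_countable = sum(countable))
}

#' Editing efficiency from transconjugant and total titers
#'
#' @param transconjugant,total One-row tibbles from [cfu_from_spots()] (or
#'   bare CFU/ml numbers, taken as measured).
#' @return One-row tibble: `efficiency` (ratio; for a censored numerator this
#'   is the upper bound `detection_limit / total`), `below_detection`,
#'   `transconjugant_cfu_per_ml`, `total_cfu_per_ml`.
#' @export
editing_efficiency <- function(transconjugant, total) {
  as_est <- function(x) {
    if (is.numeric(x)) {
      tibble(cfu_per_ml = x, below_detection = FALSE,
             detection_limit = NA_real_, n_countable = NA_integer_)
    } else as_tibble(x)
  }
  tc <- as_est(transconjugant); tt <- as_est(total)
  if (isTRUE(tt$below_detection)) {
    abort("total titer below detection: efficiency undefined")
  }
  stopifnot(tt$cfu_per_ml > 0)
  if (isTRUE(tc$below_detection)) {
    return(tibble(efficiency = tc$detection_limit / tt$cfu_per_ml,
                  below_detection = TRUE,
                  transconjugant_cfu_per_ml = NA_real_,
                  total_cfu_per_ml = tt$cfu_per_ml))
  }
  tibble(efficiency = tc$cfu_per_ml / tt$cfu_per_ml,
         below_detection = FALSE,
         transconjugant_cfu_per_ml = tc$cfu_per_ml,
         total_cfu_per_ml = tt$cfu_per_ml)
}

#' Day-paired fold change in editing efficiency
#'
#' Each treatment is normalised to the control measured the same day
#' (day-to-day variation makes cross-day pooling invalid); days with several
#' controls use the day's mean control efficiency.
#'
#' @param measurements Tibble with one row per sample: `sample`, `day`,
#'   `role` (`"treatment"`/`"control"`), `efficiency` (e.g. assembled from
#'   [editing_efficiency()] rows).
#' @return Tibble with one row per treatment: `sample`, `day`,
#'   `control_efficiency`, `fold_change`.
#' @export
fold_change <- function(measurements) {
  m <- as_tibble(measurements)
  stopifnot(all(c("sample", "day", "role", "efficiency") %in% names(m)))
  ctrl <- m |>
    filter(.data$role == "control") |>
    group_by(.data$day) |>
    summarise(control_efficiency = mean(.data$efficiency), .groups = "drop")
  tr <- filter(m, .data$role == "treatment")
  missing_days <- setdiff(tr$day, ctrl$day)
  if (length(missing_days)) {
    abort(paste0("no same-day control for day(s): ",
                 paste(missing_days, collapse = ", ")))
  }
  tr |>
    left_join(ctrl, by = "day") |>
    mutate(fold_change = .data$efficiency / .data$control_efficiency) |>
    select("sample", "day", "control_efficiency", "fold_change")
}

#' One-sample, one-tailed t test against a hypothetical mean
#'
#' Tests whether normalised fold changes differ from the control value
#' (hypothetical mean 1) in the hypothesised direction.
#'
#' @param values Numeric vector (n >= 2, non-zero variance).
#' @param mu Hypothetical mean (1 = the normalised control).
#' @param direction `"greater"` (values exceed `mu`) or `"less"`.
#' @return One-row tibble: `n`, `mean`, `sd`, `t_statistic`, `df`,
#'   `p_one_tailed`, `direction`.
#' @export
one_sample_t <- function(values, mu = 1, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n < 2) abort("one_sample_t needs at least 2 values")
  s <- sd(values)
  if (s == 0) abort("zero variance: t statistic undefined")
  m <- mean(values)
  t_stat <- (m - mu) / (s / sqrt(n))
  p <- if (direction == "greater") pt(t_stat, n - 1, lower.tail = FALSE)
       else pt(t_stat, n - 1, lower.tail = TRUE)
  tibble(n = n, mean = m, sd = s, t_statistic = t_stat, df = n - 1,
         p_one_tailed = p, direction = direction)
}

#' Efficiency analysis of a spot-plate table
#'
#' Driver from a [simulate_spot_plates()]-shaped table (several samples,
#' stacked with `sample` and `role` columns) to per-sample efficiencies and
#' day-paired fold changes.
#'
#' @param plates Tibble with `sample`, `role`, `day`, `plate`
#'   (`total`/`transconjugant`), `dilution_factor`, `spot_volume_ul`,
#'   `count`, `lawn`.
#' @param countable_range Passed to [cfu_from_spots()].
#' @return List with `efficiencies` (per sample) and `folds` (per
#'   treatment).
#' @export
efficiency_from_plates <- function(plates, countable_range = c(3, 30)) {
  plates <- as_tibble(plates)
  keys <- distinct(plates, .data$sample, .data$role, .data$day)
  eff <- bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- filter(plates, .data$sample == k$sample, .data$day == k$day)
    tc <- cfu_from_spots(filter(sub, .data$plate == "transconjugant"),
                         countable_range = countable_range)
    tt <- cfu_from_spots(filter(sub, .data$plate == "total"),
                         countable_range = countable_range)
    bind_cols(k, editing_efficiency(tc, tt))
  }))
  list(efficiencies = eff, folds = fold_change(eff))
}
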