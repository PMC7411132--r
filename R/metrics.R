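#' Signed counting errors
#'
#' For specimen i and organ k the counting error is
#' `e[i,k] = predicted - true`: positive when the pipeline over-counts
#' (e.g. one flower detected as two), negative when structures are missed.
#'
#' @param truth,predicted Tidy count tibbles (`specimen_id`, `organ`,
#'   `count`) over the same specimen set.
#' @return Tibble `specimen_id`, `organ`, `true`, `predicted`, `error`.
#' @export
counting_error <- function(truth, predicted) {
  t <- as_tibble(truth); p <- as_tibble(predicted)
  for (df in list(t, p)) assert_cols(df, c("specimen_id", "organ", "count"),
                                     "counting_error")
  if (!setequal(t$specimen_id, p$specimen_id)) {
    abort("counting_error: truth and predictions cover different specimens")
  }
  t |>
    rename(true = "count") |>
    inner_join(rename(p, predicted = "count"),
               by = c("specimen_id", "organ")) |>
    mutate(error = .data$predicted - .data$true) |>
    arrange(.data$specimen_id, .data$organ)
}

#' Mean absolute counting error
#'
#' Per-organ MAE is the mean of `|error|` over specimens for that organ.
#' The `"all"` row follows the comparison-table convention: the unweighted
#' mean of the three per-organ MAEs. Set `overall = "sum_per_specimen"` for
#' the literal per-specimen-sum reading (mean over specimens of the summed
#' absolute errors across organs, i.e. three times the default when all
#' organs are present).
#'
#' @param errors Output of [counting_error()] (or any tibble with `organ`
#'   and `error`).
#' @param overall `"mean_of_organs"` (default) or `"sum_per_specimen"`.
#' @return Tibble `organ` (three organ rows plus `"all"`), `mae`, `n`.
#' @export
mae <- function(errors, overall = c("mean_of_organs", "sum_per_specimen")) {
  overall <- match.arg(overall)
  df <- as_tibble(errors)
  assert_cols(df, c("organ", "error"), "mae")
  if (nrow(df) == 0) abort("mae: empty error records")
  per_organ <- df |>
    mutate(organ = as_organ(.data$organ)) |>
    group_by(.data$organ) |>
    summarise(mae = mean(abs(.data$error)), n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(organ = factor(organ_levels(), levels = organ_levels()),
                    fill = list(mae = NA_real_, n = 0L)) |>
    arrange(.data$organ)
  all_value <- if (overall == "mean_of_organs") {
    mean(per_organ$mae)
  } else {
    if (!"specimen_id" %in% names(df)) {
      abort("mae: sum_per_specimen needs a specimen_id column")
    }
    df |>
      group_by(.data$specimen_id) |>
      summarise(e = sum(abs(.data$error)), .groups = "drop") |>
      pull(.data$e) |>
      mean()
  }
  bind_rows(mutate(per_organ, organ = as.character(.data$organ)),
            tibble(organ = "all", mae = all_value, n = nrow(df)))
}

#' Combine per-organ MAEs into the overall table entry
#'
#' The "All" column of a counting-error comparison table is the unweighted
#' mean of the per-organ MAEs.
#'
#' @param per_organ Numeric vector of per-organ MAEs.
#' @return Their mean.
#' @export
#' @examples
#' mae_overall(c(0.201, 0.507, 0.266))
mae_overall <- function(per_organ) mean(per_organ)

#' Coefficient of determination of predicted vs. true counts
#'
#' `R^2 = 1 - SS_res / SS_tot` with the mean taken over the observed counts
#' of the evaluated subset; can be negative, and is undefined (`NA`) when
#' the observed counts are constant (SS_tot = 0). Per-organ values treat
#' each specimen as one observation; the `"all"` row pools every
#' (specimen, organ) observation.
#'
#' @param errors Output of [counting_error()] (columns `organ`, `true`,
#'   `predicted`).
#' @return Tibble `organ` (three organ rows plus `"all"`), `r_squared`,
#'   `n`.
#' @export
r_squared <- function(errors) {
  df <- as_tibble(errors)
  assert_cols(df, c("organ", "true", "predicted"), "r_squared")
  rsq <- function(true, pred) {
    ss_tot <- sum((true - mean(true))^2)
    if (length(true) < 2 || ss_tot == 0) return(NA_real_)
    1 - sum((true - pred)^2) / ss_tot
  }
  per_organ <- df |>
    mutate(organ = as_organ(.data$organ)) |>
    group_by(.data$organ) |>
    summarise(r_squared = rsq(.data$true, .data$predicted), n = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$organ) |>
    mutate(organ = as.character(.data$organ))
  bind_rows(per_organ,
            tibble(organ = "all",
                   r_squared = rsq(df$true, df$predicted),
                   n = nrow(df)))
}

#' Letter-value summary of a distribution
#'
#' Successive half-sample quantiles for heavy-tailed summaries: the median
#' (depth (1 + n)/2), then fourths, eighths, and so on, each at depth
#' `(1 + floor(previous depth)) / 2`, taken symmetrically from both ends of
#' the sorted sample. Letters stop when the depth would fall below
#' `min_tail` observations or after `max_letters` letters. Values beyond
#' the outermost letter pair are reported as outliers.
#'
#' @param values Non-empty numeric vector.
#' @param max_letters Maximum number of letters (default 8:
#'   M, F, E, D, C, B, A, Z).
#' @param min_tail Smallest allowed (floored) depth (default 1).
#' @return Tibble `letter`, `depth`, `lower`, `upper`, with the outliers in
#'   attribute `"outliers"`. For the median row `lower == upper`.
#' @export
#' @examples
#' letter_values(1:8)
letter_values <- function(values, max_letters = 8, min_tail = 1) {
  if (length(values) == 0) abort("letter_values: empty input")
  x <- sort(values)
  n <- length(x)
  letters_seq <- c("M", "F", "E", "D", "C", "B", "A", "Z", "Y", "X", "W")
  at_depth <- function(d) {
    lo <- (x[floor(d)] + x[ceiling(d)]) / 2
    hi <- (x[n + 1 - floor(d)] + x[n + 1 - ceiling(d)]) / 2
    c(lo, hi)
  }
  depths <- numeric(); d <- (1 + n) / 2
  while (length(depths) < min(max_letters, length(letters_seq)) &&
         floor(d) >= min_tail) {
    depths <- c(depths, d)
    if (floor(d) == 1) break
    d <- (1 + floor(d)) / 2
  }
  vals <- t(vapply(depths, at_depth, numeric(2)))
  out <- tibble(letter = letters_seq[seq_along(depths)],
                depth = depths,
                lower = vals[, 1], upper = vals[, 2])
  last <- nrow(out)
  attr(out, "outliers") <- x[x < out$lower[last] | x > out$upper[last]]
  out
}

#' Weighted overall accuracy from prevalence and class rates
#'
#' The overall accuracy of a binary column is the prevalence-weighted mean
#' of the true-positive rate (on observed positives) and the true-negative
#' rate (on observed negatives):
#' `(prevalence * tp + (100 - prevalence) * tn) / 100`, all in percent.
#'
#' @param prevalence Observed positive rate (percent).
#' @param tp True-positive rate among observed positives (percent).
#' @param tn True-negative rate among observed negatives (percent).
#' @return Overall accuracy (percent).
#' @export
#' @examples
#' weighted_overall_accuracy(9.75, 51.66, 91.89)
weighted_overall_accuracy <- function(prevalence, tp, tn) {
  (prevalence * tp + (100 - prevalence) * tn) / 100
}

#' Presence and dominance accuracy of predicted counts
#'
#' Derives coarse phenophase indicators from counts and scores the
#' predictions against truth: presence of each organ (`count >= 1`) and two
#' dominance relations, `flowers >= buds` and `fruits >= flowers` (ties,
#' including 0 = 0, satisfy the relation). For each indicator the report
#' gives the observed prevalence, TP/FN rates as percentages of observed
#' positives, TN/FP rates as percentages of observed negatives, and the
#' prevalence-weighted overall accuracy. Columns with no observed positives
#' (or negatives) carry `NA` rates.
#'
#' @param truth,predicted Tidy count tibbles over matched specimens.
#' @return Tibble with one row per indicator: `indicator`, `prevalence`,
#'   `tp`, `tn`, `fp`, `fn`, `accuracy` (percent, unrounded).
#' @export
presence_dominance <- function(truth, predicted) {
  joined <- counting_error(truth, predicted)
  wide <- joined |>
    select("specimen_id", "organ", "true", "predicted") |>
    tidyr::pivot_wider(names_from = "organ",
                       values_from = c("true", "predicted"))
  indicator <- function(name, obs, pred) {
    npos <- sum(obs); nneg <- sum(!obs); ntot <- length(obs)
    tp <- if (npos > 0) 100 * sum(obs & pred) / npos else NA_real_
    tn <- if (nneg > 0) 100 * sum(!obs & !pred) / nneg else NA_real_
    prev <- 100 * npos / ntot
    acc <- 100 * sum(obs == pred) / ntot
    tibble(indicator = name, prevalence = prev,
           tp = tp, tn = tn,
           fp = if (is.na(tn)) NA_real_ else 100 - tn,
           fn = if (is.na(tp)) NA_real_ else 100 - tp,
           accuracy = acc)
  }
  bind_rows(
    indicator("bud_present", wide$true_bud >= 1, wide$predicted_bud >= 1),
    indicator("flower_present", wide$true_flower >= 1,
              wide$predicted_flower >= 1),
    indicator("fruit_present", wide$true_fruit >= 1,
              wide$predicted_fruit >= 1),
    indicator("flowers_ge_buds", wide$true_flower >= wide$true_bud,
              wide$predicted_flower >= wide$predicted_bud),
    indicator("fruits_ge_flowers", wide$true_fruit >= wide$true_flower,
              wide$predicted_fruit >= wide$predicted_flower))
}

#' Distribution of predicted counts per true-count value
#'
#' For every observed true-count value (per organ) the table gives the
#' Tukey box-plot summary of the matching predictions: median, hinges,
#' whiskers under the 1.5 x IQR rule, and outliers. Empty bins do not
#' appear.
#'
#' @param truth,predicted Tidy count tibbles over matched specimens.
#' @return Tibble `organ`, `true_count`, `n`, `median`, `lower_hinge`,
#'   `upper_hinge`, `whisker_low`, `whisker_high`, and list-column
#'   `outliers`.
#' @export
predicted_count_distribution <- function(truth, predicted) {
  joined <- counting_error(truth, predicted)
  joined |>
    group_by(.data$organ, true_count = .data$true) |>
    summarise(
      n = dplyr::n(),
      stats = list(grDevices::boxplot.stats(.data$predicted)),
      .groups = "drop") |>
    mutate(
      median = purrr::map_dbl(.data$stats, ~ .x$stats[3]),
      lower_hinge = purrr::map_dbl(.data$stats, ~ .x$stats[2]),
      upper_hinge = purrr::map_dbl(.data$stats, ~ .x$stats[4]),
      whisker_low = purrr::map_dbl(.data$stats, ~ .x$stats[1]),
      whisker_high = purrr::map_dbl(.data$stats, ~ .x$stats[5]),
      outliers = purrr::map(.data$stats, "out")) |>
    select(-"stats") |>
    arrange(.data$organ, .data$true_count)
}
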