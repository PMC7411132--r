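#' Per-annotator structure counts
#'
#' Counts dot markers per specimen, annotator, and organ — the raw material
#' for crowd aggregation, where each specimen is typically marked by a few
#' different crowd-sourcers.
#'
#' @param annotations Annotation tibble (typically filtered to
#'   `annotator_role == "crowd"`).
#' @return Tibble `specimen_id`, `annotator_id`, `organ`, `count` with all
#'   three organ levels per (specimen, annotator).
#' @export
annotator_counts <- function(annotations) {
  df <- as_tibble(annotations)
  assert_cols(df, c("specimen_id", "annotator_id", "organ"),
              "annotator_counts")
  pairs <- distinct(df, .data$specimen_id, .data$annotator_id)
  grid <- tidyr::expand_grid(
    pairs, organ = factor(organ_levels(), levels = organ_levels()))
  tallied <- df |>
    mutate(organ = as_organ(.data$organ)) |>
    count(.data$specimen_id, .data$annotator_id, .data$organ, name = "count")
  grid |>
    left_join(tallied, by = c("specimen_id", "annotator_id", "organ")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    arrange(.data$specimen_id, .data$annotator_id, .data$organ)
}

#' Aggregate multi-annotator counts to one count vector per specimen
#'
#' Two strategies mirror the usual comparison rows: `"average"` takes the
#' per-organ arithmetic mean over the specimen's annotators (kept
#' fractional — rounding would discard the averaging benefit), and
#' `"isolated"` keeps a single annotator per specimen, drawn by a seeded
#' rule evaluated per specimen.
#'
#' @param counts Output of [annotator_counts()].
#' @param mode `"average"` or `"isolated"`.
#' @param seed Seed for the isolated-annotator draw (required for
#'   `"isolated"`).
#' @return Tidy count tibble (`specimen_id`, `organ`, `count`); counts are
#'   fractional under `"average"`.
#' @export
aggregate_annotators <- function(counts, mode = c("average", "isolated"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  df <- as_tibble(counts)
  assert_cols(df, c("specimen_id", "annotator_id", "organ", "count"),
              "aggregate_annotators")
  if (nrow(df) == 0) abort("aggregate_annotators: empty input")
  if (mode == "average") {
    return(df |>
             group_by(.data$specimen_id, .data$organ) |>
             summarise(count = mean(.data$count), .groups = "drop") |>
             arrange(.data$specimen_id, .data$organ))
  }
  picks <- df |>
    distinct(.data$specimen_id, .data$annotator_id) |>
    group_by(.data$specimen_id) |>
    summarise(annotator_id = withr::with_seed(
      seed + sum(utf8ToInt(first(.data$specimen_id))),
      sample(sort(.data$annotator_id), 1)), .groups = "drop")
  df |>
    inner_join(picks, by = c("specimen_id", "annotator_id")) |>
    select("specimen_id", "organ", "count") |>
    arrange(.data$specimen_id, .data$organ)
}

#' Per-annotator MAE, averaged over annotators
#'
#' Scores each annotator in isolation — MAE of their counts against truth on
#' the specimens they annotated — and averages over annotators. This is how
#' an "isolated annotator" row of a source-comparison table is formed when
#' every individual annotator is allowed to contribute.
#'
#' @param counts Output of [annotator_counts()].
#' @param truth Tidy truth counts covering the annotated specimens.
#' @return Tibble `organ` (three rows plus `"all"`), `mae` (mean over
#'   annotators), `n_annotators`.
#' @export
mae_by_annotator <- function(counts, truth) {
  df <- as_tibble(counts)
  per <- df |>
    group_by(.data$annotator_id) |>
    dplyr::group_map(function(g, key) {
      errs <- counting_error(
        semi_join(truth, g, by = "specimen_id"),
        select(g, "specimen_id", "organ", "count"))
      mutate(mae(errs), annotator_id = key$annotator_id)
    }) |>
    bind_rows()
  per |>
    group_by(.data$organ) |>
    summarise(mae = mean(.data$mae, na.rm = TRUE),
              n_annotators = dplyr::n(), .groups = "drop") |>
    dplyr::slice(match(c(organ_levels(), "all"), .data$organ))
}

#' Compare the counting errors of two sources
#'
#' Pairs the two sources on specimens and applies a two-sided Wilcoxon
#' signed-rank test to the per-specimen mean absolute errors (exact when
#' the sample is small and untied, normal approximation otherwise), as
#' when asking whether a model's counts err less than a crowd's.
#'
#' @param errors_a,errors_b Outputs of [counting_error()] for the two
#'   sources over the same specimens.
#' @param names Length-2 character vector naming the sources.
#' @return One-row tibble: source names, each source's overall MAE
#'   (mean-of-organs), the signed-rank statistic, `p_value`, and `n`
#'   (paired specimens).
#' @export
compare_sources <- function(errors_a, errors_b,
                            names = c("source_a", "source_b")) {
  per_specimen <- function(e) {
    as_tibble(e) |>
      group_by(.data$specimen_id) |>
      summarise(abs_error = mean(abs(.data$error)), .groups = "drop")
  }
  a <- per_specimen(errors_a); b <- per_specimen(errors_b)
  paired <- inner_join(a, b, by = "specimen_id", suffix = c("_a", "_b"))
  if (nrow(paired) < 2) abort("compare_sources: need at least 2 paired specimens")
  if (nrow(paired) < length(union(a$specimen_id, b$specimen_id))) {
    abort("compare_sources: sources cover different specimen sets")
  }
  diffs <- paired$abs_error_a - paired$abs_error_b
  if (all(diffs == 0)) {
    test <- list(statistic = c(V = NA_real_), p.value = 1)
  } else {
    test <- suppressWarnings(
      wilcox.test(paired$abs_error_a, paired$abs_error_b,
                  paired = TRUE, exact = NULL))
  }
  tibble(source_a = names[1], source_b = names[2],
         mae_a = mae(errors_a)$mae[4],
         mae_b = mae(errors_b)$mae[4],
         statistic = unname(test$statistic),
         p_value = test$p.value,
         n = nrow(paired))
}
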