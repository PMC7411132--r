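#' Read a specimen manifest
#'
#' The manifest lists every digitized sheet in a dataset: one row per
#' specimen with its image path, pixel dimensions, and taxonomy.
#'
#' @param path Path to a CSV with columns `specimen_id`, `image_path`,
#'   `width`, `height`, `species`, `genus` (header required, UTF-8).
#' @return A tibble, one row per specimen.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("specimen manifest not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(df, c("specimen_id", "image_path", "width", "height",
                    "species", "genus"), "specimen manifest")
  if (anyDuplicated(df$specimen_id)) {
    abort("specimen manifest: duplicated specimen_id",
          class = "phenocount_schema_error")
  }
  if (any(df$width <= 0 | df$height <= 0)) {
    abort("specimen manifest: non-positive image dimensions",
          class = "phenocount_schema_error")
  }
  mutate(df, specimen_id = as.character(.data$specimen_id))
}

#' Read and validate a dot-marker annotation table
#'
#' Each row is one marked reproductive structure: a point placed by an
#' annotator at the center of a visible bud, flower, or fruit. Coordinates
#' are 0-based pixel indices in the *original* image (x rightward, y
#' downward); all rescaling happens downstream when masks are generated.
#'
#' Rows with unknown organ labels or, when a manifest is supplied,
#' out-of-bounds coordinates or unknown specimen ids are rejected with
#' row-indexed diagnostics.
#'
#' @param path Path to a CSV with columns `specimen_id`, `annotator_id`,
#'   `annotator_role` (`expert` or `crowd`), `organ` (`bud`/`flower`/
#'   `fruit`), `x`, `y`, `species`, `genus`.
#' @param specimens Optional specimen manifest (see [read_specimens()]);
#'   when given, annotations are validated against image bounds and known
#'   specimen ids.
#' @return A tibble of validated annotations with `organ` as a factor with
#'   levels `bud < flower < fruit`.
#' @export
read_annotations <- function(path, specimens = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("annotation table not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(df, c("specimen_id", "annotator_id", "annotator_role",
                    "organ", "x", "y", "species", "genus"),
              "annotation table")
  validate_annotations(df, specimens)
}

#' Validate an in-memory annotation table
#'
#' @param annotations A data frame shaped like the annotation CSV.
#' @inheritParams read_annotations
#' @return The validated tibble (organ coerced to the fixed factor).
#' @export
validate_annotations <- function(annotations, specimens = NULL) {
  df <- as_tibble(annotations)
  df$specimen_id <- as.character(df$specimen_id)
  df$annotator_id <- as.character(df$annotator_id)
  if (nrow(df) == 0) {
    df$organ <- factor(character(), levels = organ_levels())
    return(df)
  }
  bad_role <- which(!df$annotator_role %in% c("expert", "crowd"))
  if (length(bad_role) > 0) {
    abort(sprintf("annotation table: invalid annotator_role at row(s) %s",
                  paste(head(bad_role, 10), collapse = ", ")),
          class = "phenocount_schema_error")
  }
  df$organ <- as_organ(df$organ, "annotation table")
  bad_xy <- which(!is.finite(df$x) | !is.finite(df$y) | df$x < 0 | df$y < 0)
  if (length(bad_xy) > 0) {
    abort(sprintf("annotation table: negative or missing coordinates at row(s) %s",
                  paste(head(bad_xy, 10), collapse = ", ")),
          class = "phenocount_schema_error")
  }
  if (!is.null(specimens)) {
    unknown <- which(!df$specimen_id %in% specimens$specimen_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "annotation table: unknown specimen id(s) %s at row(s) %s",
        paste(unique(df$specimen_id[unknown]), collapse = ", "),
        paste(head(unknown, 10), collapse = ", ")),
        class = "phenocount_reference_error")
    }
    dims <- specimens[match(df$specimen_id, specimens$specimen_id), ]
    oob <- which(df$x >= dims$width | df$y >= dims$height)
    if (length(oob) > 0) {
      abort(sprintf(
        "annotation table: coordinates outside image bounds at row(s) %s",
        paste(head(oob, 10), collapse = ", ")),
        class = "phenocount_reference_error")
    }
  }
  df
}

#' Keep one annotator per specimen by priority
#'
#' For each specimen, retains only the annotations of the first annotator in
#' `priority` who annotated it. Specimens annotated by none of the listed
#' annotators are dropped; their ids are reported via a message and attached
#' as the `"dropped_specimens"` attribute. The operation is idempotent.
#'
#' @param annotations An annotation tibble.
#' @param priority Character vector of annotator ids, highest priority first.
#' @param quiet Suppress the drop report message.
#' @return Filtered annotation tibble with attribute `dropped_specimens`.
#' @export
select_single_annotator <- function(annotations, priority, quiet = FALSE) {
  if (length(priority) == 0) {
    abort("priority list must be non-empty")
  }
  df <- as_tibble(annotations)
  chosen <- df |>
    distinct(.data$specimen_id, .data$annotator_id) |>
    filter(.data$annotator_id %in% priority) |>
    mutate(rank = match(.data$annotator_id, priority)) |>
    group_by(.data$specimen_id) |>
    filter(.data$rank == min(.data$rank)) |>
    ungroup() |>
    select("specimen_id", "annotator_id")
  out <- inner_join(df, chosen, by = c("specimen_id", "annotator_id"))
  dropped <- setdiff(unique(df$specimen_id), chosen$specimen_id)
  if (length(dropped) > 0 && !quiet) {
    inform(sprintf(
      "select_single_annotator: dropped %d specimen(s) with no listed annotator: %s",
      length(dropped), paste(head(dropped, 10), collapse = ", ")))
  }
  attr(out, "dropped_specimens") <- dropped
  out
}

#' Split specimens into training and test sets
#'
#' The split is at the specimen level so that all annotations of a specimen
#' fall on one side. Ids are shuffled with a seeded uniform permutation and
#' the first `round(test_fraction * n)` become the test set; the split is
#' deterministic given the seed.
#'
#' @param specimens A data frame with a `specimen_id` column (typically the
#'   manifest).
#' @param test_fraction Fraction of specimens for the test side, in (0, 1).
#' @param seed Integer seed controlling the shuffle.
#' @return The input tibble with an added `split` column
#'   (`"train"`/`"test"`).
#' @export
split_specimens <- function(specimens, test_fraction, seed) {
  if (!is.numeric(test_fraction) || length(test_fraction) != 1 ||
      test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be a single number in (0, 1)")
  }
  df <- as_tibble(specimens)
  assert_cols(df, "specimen_id", "split_specimens")
  ids <- unique(df$specimen_id)
  if (length(ids) < 2) {
    abort("split_specimens needs at least 2 specimens")
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  n_test <- round(test_fraction * length(ids))
  test_ids <- shuffled[seq_len(n_test)]
  mutate(df, split = ifelse(.data$specimen_id %in% test_ids, "test", "train"))
}

#' Per-specimen, per-organ structure counts
#'
#' Counts dot markers per specimen and organ. With a manifest supplied,
#' specimens that carry no markers (sterile sheets) appear with all-zero
#' counts; otherwise only specimens present in `annotations` are returned.
#'
#' @param annotations Annotation tibble.
#' @param specimens Optional manifest used to zero-fill sterile specimens.
#' @return A tidy count tibble: `specimen_id`, `organ`, `count`, with all
#'   three organ levels per specimen.
#' @export
count_structures <- function(annotations, specimens = NULL) {
  df <- as_tibble(annotations)
  ids <- if (is.null(specimens)) unique(df$specimen_id) else
    unique(as.character(specimens$specimen_id))
  grid <- tidyr::expand_grid(
    specimen_id = ids,
    organ = factor(organ_levels(), levels = organ_levels()))
  tallied <- df |>
    mutate(organ = as_organ(.data$organ)) |>
    count(.data$specimen_id, .data$organ, name = "count")
  grid |>
    left_join(tallied, by = c("specimen_id", "organ")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    arrange(.data$specimen_id, .data$organ)
}

#' True counts from a single-annotator dataset
#'
#' The true count of organ k on specimen i is the number of dot markers of
#' that organ placed by the specimen's (single) annotator. Run
#' [select_single_annotator()] first; mixed annotators are an error because
#' they would double-count structures.
#'
#' @inheritParams count_structures
#' @return A tidy count tibble (see [count_structures()]).
#' @export
count_truth <- function(annotations, specimens = NULL) {
  df <- as_tibble(annotations)
  if (nrow(df) > 0) {
    multi <- df |>
      distinct(.data$specimen_id, .data$annotator_id) |>
      count(.data$specimen_id) |>
      filter(.data$n > 1)
    if (nrow(multi) > 0) {
      abort(sprintf(
        "count_truth: specimen(s) with multiple annotators (run select_single_annotator first): %s",
        paste(head(multi$specimen_id, 10), collapse = ", ")),
        class = "phenocount_state_error")
    }
  }
  count_structures(df, specimens)
}

#' Composition of a structure dataset
#'
#' Totals and percentages of buds, flowers, and fruits, matching the layout
#' of a pooled composition table: percentage = 100 x organ total / grand
#' total, reported to one decimal. With a grand total of zero the
#' percentages are undefined (`NA`), never NaN.
#'
#' @param counts Either a tidy count tibble (`specimen_id`, `organ`,
#'   `count`) or a numeric vector of three per-organ totals in
#'   bud/flower/fruit order.
#' @return A tibble with one row per organ: `organ`, `total`, `percent`
#'   (1 decimal), plus attributes `grand_total` and (for tibble input)
#'   `mean_per_specimen`.
#' @export
#' @examples
#' composition_summary(c(107, 1241, 240))
composition_summary <- function(counts) {
  if (is.numeric(counts)) {
    stopifnot(length(counts) == 3)
    totals <- tibble(
      organ = factor(organ_levels(), levels = organ_levels()),
      total = as.numeric(counts))
    mean_per_specimen <- NA_real_
  } else {
    df <- as_tibble(counts)
    assert_cols(df, c("specimen_id", "organ", "count"), "composition_summary")
    if (nrow(df) == 0) abort("composition_summary: empty counts")
    totals <- df |>
      mutate(organ = as_organ(.data$organ)) |>
      group_by(.data$organ) |>
      summarise(total = sum(.data$count), .groups = "drop") |>
      tidyr::complete(organ = factor(organ_levels(), levels = organ_levels()),
                      fill = list(total = 0)) |>
      arrange(.data$organ)
    mean_per_specimen <- sum(totals$total) / dplyr::n_distinct(df$specimen_id)
  }
  grand <- sum(totals$total)
  totals$percent <- if (grand > 0) round(100 * totals$total / grand, 1) else
    NA_real_
  attr(totals, "grand_total") <- grand
  attr(totals, "mean_per_specimen") <- mean_per_specimen
  totals
}
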