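test_that("annotation CSV round-trips and validates its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  ann <- make_annotations(list(
    list(organ = "bud", x = 5, y = 6),
    list(organ = "flower", x = 20, y = 30),
    list(organ = "fruit", x = 40, y = 50)))
  readr::write_csv(ann, path)
  got <- read_annotations(path)
  expect_equal(nrow(got), 3)
  expect_equal(dplyr::n_distinct(got$specimen_id), 1)
  expect_s3_class(got$organ, "factor")
  expect_equal(levels(got$organ), organ_levels())

  # empty table with a valid header
  readr::write_csv(ann[0, ], path)
  expect_equal(nrow(read_annotations(path)), 0)

  # unknown organ label is rejected with the offending row index
  bad <- make_annotations(list(list(organ = "flower"),
                               list(organ = "seed")))
  readr::write_csv(bad, path)
  expect_error(read_annotations(path), "seed.*row\\(s\\) 2",
               class = "phenocount_schema_error")

  # missing column is a schema error
  readr::write_csv(ann[, -4], path)
  expect_error(read_annotations(path), "missing required column",
               class = "phenocount_schema_error")
})

test_that("manifest validation catches unknown specimens and out-of-bounds dots", {
  specimens <- tibble::tibble(
    specimen_id = "S1", image_path = "s1.png", width = 100, height = 200,
    species = "sp", genus = "g")
  ok <- make_annotations(list(list(x = 99, y = 199)))
  expect_silent(validate_annotations(ok, specimens))
  expect_error(
    validate_annotations(make_annotations(list(list(specimen_id = "S9"))),
                         specimens),
    "unknown specimen", class = "phenocount_reference_error")
  expect_error(
    validate_annotations(make_annotations(list(list(x = 100, y = 10))),
                         specimens),
    "outside image bounds", class = "phenocount_reference_error")
  expect_error(
    validate_annotations(make_annotations(list(list(x = -1)))),
    "negative", class = "phenocount_schema_error")
})

test_that("select_single_annotator applies the priority order and reports drops", {
  ann <- make_annotations(list(
    list(specimen_id = "S1", annotator_id = "E2", organ = "bud"),
    list(specimen_id = "S1", annotator_id = "E1", organ = "flower"),
    list(specimen_id = "S1", annotator_id = "E1", organ = "flower"),
    list(specimen_id = "S2", annotator_id = "E2", organ = "fruit"),
    list(specimen_id = "S3", annotator_id = "C1", annotator_role = "crowd")))

  got <- select_single_annotator(ann, c("E1", "E2"), quiet = TRUE)
  s1 <- got[got$specimen_id == "S1", ]
  expect_true(all(s1$annotator_id == "E1"))  # E1 outranks E2
  expect_equal(nrow(s1), 2)
  expect_equal(got$annotator_id[got$specimen_id == "S2"], "E2")  # fallback
  expect_false("S3" %in% got$specimen_id)
  expect_equal(attr(got, "dropped_specimens"), "S3")
  expect_message(select_single_annotator(ann, c("E1", "E2")), "dropped 1")

  # idempotent
  again <- select_single_annotator(got, c("E1", "E2"), quiet = TRUE)
  expect_equal(again, got, ignore_attr = TRUE)
  expect_error(select_single_annotator(ann, character()), "non-empty")
})

test_that("specimen split conserves specimens, is deterministic, and sizes by round()", {
  specimens <- tibble::tibble(specimen_id = sprintf("S%02d", 1:10))
  for (seed in c(1, 2, 99)) {
    got <- split_specimens(specimens, 0.2, seed)
    expect_setequal(got$specimen_id, specimens$specimen_id)
    expect_equal(sum(got$split == "test"), 2)
    expect_equal(sum(got$split == "train"), 8)
    expect_equal(intersect(got$specimen_id[got$split == "test"],
                           got$specimen_id[got$split == "train"]),
                 character(0))
  }
  expect_identical(split_specimens(specimens, 0.3, 5),
                   split_specimens(specimens, 0.3, 5))
  # round() sizing, not floor/ceiling
  expect_equal(sum(split_specimens(specimens, 0.25, 1)$split == "test"), 2)
  expect_equal(
    sum(split_specimens(tibble::tibble(specimen_id = as.character(1:7)),
                        0.25, 1)$split == "test"), 2)
  expect_error(split_specimens(specimens, 1.2, 1), "in \\(0, 1\\)")
  expect_error(split_specimens(specimens[1, ], 0.5, 1), "at least 2")
})

test_that("count_truth counts markers per organ and rejects mixed annotators", {
  ann <- make_annotations(list(
    list(organ = "flower"), list(organ = "flower"), list(organ = "fruit")))
  got <- count_truth(ann)
  expect_equal(got$count, c(0L, 2L, 1L))
  expect_equal(as.character(got$organ), organ_levels())

  # permutation invariance of row order
  shuffled <- ann[c(3, 1, 2), ]
  expect_equal(count_truth(shuffled), got)

  # sterile specimen appears with an all-zero vector via the manifest
  specimens <- tibble::tibble(specimen_id = c("S1", "S2"))
  got2 <- count_truth(ann, specimens)
  expect_equal(got2$count[got2$specimen_id == "S2"], c(0L, 0L, 0L))

  mixed <- make_annotations(list(list(annotator_id = "E1"),
                                 list(annotator_id = "E2")))
  expect_error(count_truth(mixed), "multiple annotators",
               class = "phenocount_state_error")
})

test_that("composition percentages follow the totals and sum to 100", {
  got <- composition_summary(c(0, 10, 0))
  expect_equal(got$percent, c(0, 100, 0))

  zero <- composition_summary(c(0, 0, 0))
  expect_true(all(is.na(zero$percent)))

  # percentages sum to 100 +/- rounding for random totals
  withr::with_seed(11, {
    for (i in 1:25) {
      totals <- rpois(3, lambda = c(5, 60, 15)) + c(0, 1, 0)
      if (sum(totals) == 0) next
      expect_lte(abs(sum(composition_summary(totals)$percent) - 100),
                 0.1 + 1e-9)
    }
  })

  # tibble input also reports the mean structures per specimen
  counts <- make_counts(c("S1", "S2"), bud = c(1, 0), flower = c(2, 0),
                        fruit = c(1, 0))
  got2 <- composition_summary(counts)
  expect_equal(attr(got2, "grand_total"), 4)
  expect_equal(attr(got2, "mean_per_specimen"), 2)
})
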