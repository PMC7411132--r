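#' Configure an evaluation scenario
#'
#' Three scenarios cover the standard questions about detector training
#' strategy: `per_species` (one model per species, train = test = one
#' species), `global` (a single model for all species), and `transfer`
#' (train on some species, test on a species never seen in training —
#' train and test sets must be disjoint).
#'
#' @param scenario `"per_species"`, `"global"`, or `"transfer"`.
#' @param train_species Character vector of training species.
#' @param test_species Character vector of test species (defaults to
#'   `train_species` except for transfer).
#' @param seed Integer seed used by the run.
#' @param tau Detection confidence threshold (default 0.5).
#' @param backend_id Identifier of the detector backend.
#' @return A `scenario_config` list with a deterministic `config_id`.
#' @export
scenario_config <- function(scenario = c("global", "per_species", "transfer"),
                            train_species, test_species = NULL,
                            seed = 1L, tau = 0.5,
                            backend_id = "baseline-color-threshold") {
  scenario <- match.arg(scenario)
  if (is.null(test_species)) test_species <- train_species
  if (scenario == "per_species" &&
      (length(train_species) != 1 || !setequal(train_species, test_species))) {
    abort("per_species scenario requires train = test = one species",
          class = "phenocount_config_error")
  }
  if (scenario == "transfer" &&
      length(intersect(train_species, test_species)) > 0) {
    abort("transfer scenario requires disjoint train and test species",
          class = "phenocount_config_error")
  }
  cfg <- list(scenario = scenario,
              train_species = sort(train_species),
              test_species = sort(test_species),
              seed = as.integer(seed), tau = tau, backend_id = backend_id)
  cfg$config_id <- paste0(
    scenario, "/train=", paste(cfg$train_species, collapse = "+"),
    "/test=", paste(cfg$test_species, collapse = "+"),
    "/seed=", cfg$seed, "/tau=", tau, "/backend=", backend_id)
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$config_id, "\n")
  invisible(x)
}

#' Run an evaluation scenario end to end
#'
#' Fits the detector backend on the training species only (for the baseline
#' backend, "training" means fitting its organ color palette on the train
#' split), predicts counts on the test species, and evaluates them with the
#' full metrics suite. Transfer scenarios never leak test-species specimens
#' into training (asserted on specimen ids).
#'
#' @param config A [scenario_config()].
#' @param annotations Single-annotator annotation tibble.
#' @param specimens Specimen manifest covering all species in the config.
#' @param image_dir Directory for the manifest's `image_path` entries.
#' @param out_dir Optional directory; when given, the report is written as
#'   JSON plus tidy CSVs.
#' @return A `scenario_report` list: `config`, `mae`, `r_squared`,
#'   `letter_values` (per organ, of the signed counting error),
#'   `presence_dominance`, `errors`, `n_train`, `n_test`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
run_scenario <- function(config, annotations, specimens, image_dir = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  spx <- as_tibble(specimens)
  missing_sp <- setdiff(union(config$train_species, config$test_species),
                        spx$species)
  if (length(missing_sp) > 0) {
    abort(sprintf("run_scenario: species not in data: %s",
                  paste(missing_sp, collapse = ", ")),
          class = "phenocount_config_error")
  }
  train_spx <- filter(spx, .data$species %in% config$train_species)
  test_spx <- filter(spx, .data$species %in% config$test_species)
  if (config$scenario == "transfer") {
    stopifnot(length(intersect(train_spx$specimen_id,
                               test_spx$specimen_id)) == 0)
  }
  ann <- as_tibble(annotations)
  train_ann <- semi_join(ann, train_spx, by = "specimen_id")
  palette <- fit_palette(train_ann, train_spx, image_dir)
  backend <- baseline_detector(palette)
  dets <- detect_dataset(backend, test_spx, image_dir) |>
    filter_detections(config$tau)
  predicted <- count_detections(dets, test_spx)
  truth <- count_truth(semi_join(ann, test_spx, by = "specimen_id"),
                       test_spx)
  errors <- counting_error(truth, predicted)
  lv <- errors |>
    group_by(.data$organ) |>
    dplyr::group_map(~ mutate(letter_values(.x$error),
                              organ = .y$organ)) |>
    bind_rows()
  report <- list(config = config,
                 mae = mae(errors),
                 r_squared = r_squared(errors),
                 letter_values = lv,
                 presence_dominance = presence_dominance(truth, predicted),
                 errors = errors,
                 n_train = nrow(train_spx), n_test = nrow(test_spx))
  class(report) <- "scenario_report"
  if (!is.null(out_dir)) write_scenario_report(report, out_dir)
  report
}

#' Write a scenario report to disk
#'
#' @param report A `scenario_report`.
#' @param out_dir Output directory (created); writes `report.json` and tidy
#'   CSVs for each metric table.
#' @return Invisibly, the directory.
#' @export
write_scenario_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = unclass(report$config),
         mae = report$mae, r_squared = report$r_squared,
         presence_dominance = report$presence_dominance,
         n_train = report$n_train, n_test = report$n_test),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(report$mae, file.path(out_dir, "mae.csv"))
  readr::write_csv(report$r_squared, file.path(out_dir, "r_squared.csv"))
  readr::write_csv(report$letter_values,
                   file.path(out_dir, "letter_values.csv"))
  readr::write_csv(report$presence_dominance,
                   file.path(out_dir, "presence_dominance.csv"))
  readr::write_csv(report$errors, file.path(out_dir, "counting_errors.csv"))
  invisible(out_dir)
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report>", x$config$config_id, "\n")
  cat(sprintf("  specimens: %d train / %d test\n", x$n_train, x$n_test))
  cat(sprintf("  MAE (all): %.3f | R^2 (all): %.3f\n",
              x$mae$mae[4], x$r_squared$r_squared[4]))
  invisible(x)
}

#' Tidy a scenario report into per-organ metrics
#'
#' @param x A `scenario_report`.
#' @param ... Unused.
#' @return Tibble `organ`, `mae`, `r_squared`, `n`.
#' @method tidy scenario_report
#' @export
tidy.scenario_report <- function(x, ...) {
  inner_join(select(x$mae, "organ", "mae"),
             select(x$r_squared, "organ", "r_squared", "n"),
             by = "organ")
}

#' One-row summary of a scenario report
#'
#' @param x A `scenario_report`.
#' @param ... Unused.
#' @return One-row tibble: scenario, mae_all, r_squared_all, n_train,
#'   n_test.
#' @method glance scenario_report
#' @export
glance.scenario_report <- function(x, ...) {
  tibble(scenario = x$config$scenario,
         config_id = x$config$config_id,
         mae_all = x$mae$mae[4],
         r_squared_all = x$r_squared$r_squared[4],
         n_train = x$n_train, n_test = x$n_test)
}
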