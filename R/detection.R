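#' Construct the deterministic baseline detector
#'
#' The baseline backend segments organs by color: pixels within
#' `color_tol` (max absolute RGB channel difference) of an organ's palette
#' color are thresholded and grouped into connected components; components
#' below `min_area` pixels are discarded. Each surviving component becomes
#' one detection whose score is the fraction of its pixels within the
#' strict tolerance `color_tol / 2` of the palette color. Counting by
#' detection then trusts these instances as-is, so merged neighbors
#' under-count and split blobs over-count, exactly as a learned detector
#' would.
#'
#' @param palette Tibble with columns `organ`, `r`, `g`, `b` (one row per
#'   organ class, values in [0, 1]). See [fit_palette()].
#' @param color_tol Per-channel matching tolerance (default 0.12).
#' @param min_area Minimum component area in pixels (default 20).
#' @return A detector backend of class
#'   `c("baseline_detector", "pheno_detector")` with `name`, `version`,
#'   and a config id.
#' @export
baseline_detector <- function(palette, color_tol = 0.12, min_area = 20) {
  pal <- as_tibble(palette)
  assert_cols(pal, c("organ", "r", "g", "b"), "baseline_detector palette")
  if (nrow(pal) == 0) {
    abort("baseline_detector: empty palette", class = "phenocount_config_error")
  }
  pal$organ <- as_organ(pal$organ)
  backend <- list(
    name = "baseline-color-threshold",
    version = "1",
    palette = pal,
    color_tol = color_tol,
    min_area = min_area)
  backend$config_id <- paste0(
    "baseline/tol=", color_tol, "/min_area=", min_area, "/organs=",
    paste(pal$organ, collapse = "+"))
  class(backend) <- c("baseline_detector", "pheno_detector")
  backend
}

#' Fit a baseline palette from annotated training images
#'
#' "Training" the baseline backend means estimating each organ's color
#' class from the training split only: the median RGB color in a small
#' window around every training dot marker, taken per organ.
#'
#' @param annotations Annotation tibble (original-image coordinates).
#' @param specimens Specimen manifest for the training split.
#' @param image_dir Directory for the manifest's `image_path` entries
#'   (`NULL` to use them as-is).
#' @param window Half-width of the sampling window around each dot (px).
#' @return A palette tibble (`organ`, `r`, `g`, `b`).
#' @export
fit_palette <- function(annotations, specimens, image_dir = NULL, window = 2) {
  ann <- as_tibble(annotations)
  spx <- as_tibble(specimens)
  samples <- purrr::map_dfr(seq_len(nrow(spx)), function(i) {
    sp <- spx[i, ]
    dots <- filter(ann, .data$specimen_id == sp$specimen_id)
    if (nrow(dots) == 0) return(NULL)
    src <- if (is.null(image_dir)) sp$image_path else
      file.path(image_dir, sp$image_path)
    img <- read_image(src)
    h <- dim(img)[1]; w <- dim(img)[2]
    purrr::map_dfr(seq_len(nrow(dots)), function(j) {
      xs <- pmin(pmax(round(dots$x[j]) + (-window:window), 0), w - 1) + 1
      ys <- pmin(pmax(round(dots$y[j]) + (-window:window), 0), h - 1) + 1
      tibble(organ = dots$organ[j],
             r = median(img[ys, xs, 1]),
             g = median(img[ys, xs, 2]),
             b = median(img[ys, xs, 3]))
    })
  })
  if (nrow(samples) == 0) {
    abort("fit_palette: no annotated training dots",
          class = "phenocount_config_error")
  }
  samples |>
    mutate(organ = as_organ(.data$organ)) |>
    group_by(.data$organ) |>
    summarise(r = median(.data$r), g = median(.data$g), b = median(.data$b),
              .groups = "drop")
}

#' Run a detector backend on one image
#'
#' Generic entry point of the detector contract: every backend returns the
#' same detection schema, ordered deterministically, so downstream counting
#' is backend-agnostic.
#'
#' @param backend A detector backend (e.g. [baseline_detector()]).
#' @param image RGB array (resized working space).
#' @param specimen_id Id attached to the returned detections.
#' @return Detection tibble: `specimen_id`, `organ`, `score`, `x`, `y`
#'   (component centroid), `bbox_x`, `bbox_y`, `bbox_w`, `bbox_h`, `area`.
#' @export
detect <- function(backend, image, specimen_id = "specimen") {
  UseMethod("detect")
}

#' @export
detect.baseline_detector <- function(backend, image, specimen_id = "specimen") {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- purrr::map_dfr(seq_len(nrow(backend$palette)), function(k) {
    pal <- backend$palette[k, ]
    d <- pmax(abs(image[, , 1] - pal$r),
              pmax(abs(image[, , 2] - pal$g), abs(image[, , 3] - pal$b)))
    hit <- d <= backend$color_tol
    if (!any(hit)) return(NULL)
    # EBImage works x-by-y
    lab <- EBImage::bwlabel(EBImage::Image(t(hit)))
    labm <- t(EBImage::imageData(lab))
    ids <- seq_len(max(labm))
    purrr::map_dfr(ids, function(id) {
      px <- which(labm == id, arr.ind = TRUE)
      if (nrow(px) < backend$min_area) return(NULL)
      strict <- d[px] <= backend$color_tol / 2
      xs <- px[, 2] - 1; ys <- px[, 1] - 1
      tibble(specimen_id = specimen_id,
             organ = pal$organ,
             score = mean(strict),
             x = mean(xs), y = mean(ys),
             bbox_x = min(xs), bbox_y = min(ys),
             bbox_w = max(xs) - min(xs) + 1,
             bbox_h = max(ys) - min(ys) + 1,
             area = nrow(px))
    })
  })
  if (is.null(out) || nrow(out) == 0) return(empty_detections(specimen_id))
  arrange(out, .data$organ, .data$y, .data$x)
}

empty_detections <- function(specimen_id = character()) {
  tibble(specimen_id = character(),
         organ = factor(character(), levels = organ_levels()),
         score = numeric(), x = numeric(), y = numeric(),
         bbox_x = numeric(), bbox_y = numeric(),
         bbox_w = numeric(), bbox_h = numeric(), area = numeric())
}

#' Run a detector backend over a whole manifest
#'
#' @param backend A detector backend.
#' @param specimens Specimen manifest of the images to process.
#' @param image_dir Directory for the manifest's `image_path` entries.
#' @return Detection tibble over all specimens (possibly 0 rows).
#' @export
detect_dataset <- function(backend, specimens, image_dir = NULL) {
  spx <- as_tibble(specimens)
  out <- purrr::map_dfr(seq_len(nrow(spx)), function(i) {
    src <- if (is.null(image_dir)) spx$image_path[i] else
      file.path(image_dir, spx$image_path[i])
    detect(backend, read_image(src), spx$specimen_id[i])
  })
  if (nrow(out) == 0) empty_detections() else out
}

#' Filter detections by confidence score
#'
#' Keeps detections with `score >= tau`, preserving order. Monotone in
#' `tau`: raising the threshold never adds detections.
#'
#' @param detections Detection tibble.
#' @param tau Confidence threshold in [0, 1] (default 0.5).
#' @return Filtered detection tibble.
#' @export
filter_detections <- function(detections, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
    abort("tau must be a single number in [0, 1]")
  }
  filter(as_tibble(detections), .data$score >= tau)
}

#' Counts from detections: counting equals detection
#'
#' The predicted count of organ k on a specimen is simply the number of
#' detected instances of that organ — no spatial deduplication, so detector
#' over- and under-segmentation propagates into the counts by design.
#'
#' @param detections Detection tibble. Without `specimens`, all rows must
#'   share one `specimen_id` (mixed ids are an error).
#' @param specimens Optional manifest; when given, counting is grouped per
#'   specimen and specimens with no detections get all-zero counts.
#' @return Tidy count tibble (`specimen_id`, `organ`, `count`).
#' @export
count_detections <- function(detections, specimens = NULL) {
  df <- as_tibble(detections)
  if (is.null(specimens)) {
    ids <- unique(df$specimen_id)
    if (length(ids) > 1) {
      abort("count_detections: mixed specimen ids; pass `specimens` to count a dataset")
    }
    if (length(ids) == 0) ids <- "specimen"
    specimens <- tibble(specimen_id = ids)
  }
  count_structures(
    select(df, "specimen_id", "organ"), specimens)
}
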