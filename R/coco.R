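#' Read an image file as an RGB array
#'
#' @param path PNG image path.
#' @return Numeric array height x width x 3 with values in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  img[, , 1:3, drop = FALSE]
}

#' Write an RGB array as a PNG image
#' @param image Numeric array height x width x 3 in [0, 1].
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Resize an image according to a resize plan
#'
#' Bilinear resampling to the plan's target dimensions.
#'
#' @param image RGB array.
#' @param plan A [plan_resize()] plan for the image's dimensions.
#' @return Resized RGB array.
#' @export
resize_image <- function(image, plan) {
  stopifnot(inherits(plan, "resize_plan"))
  if (plan$target_width == plan$source_width &&
      plan$target_height == plan$source_height) {
    return(image)
  }
  # EBImage stores images x-by-y; our arrays are row (y) by column (x)
  eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = plan$target_width, h = plan$target_height)
  pmin(pmax(aperm(EBImage::imageData(out), c(2, 1, 3)), 0), 1)
}

coco_categories <- function() {
  tibble(id = 1:3, name = organ_levels(), supercategory = "reproductive_structure")
}

#' Export an annotated dataset as a COCO instance-segmentation dataset
#'
#' Writes resized images plus a COCO-dialect JSON in which every dot marker
#' becomes one instance annotation: a dodecagon polygon scaled by the
#' (genus, organ) calibrated radius, clipped to image bounds, with its
#' tight bounding box and rasterized pixel area (iscrowd = 0). Categories
#' are bud = 1, flower = 2, fruit = 3. The number of exported annotations
#' equals the number of input dots.
#'
#' @param annotations Single-annotator annotation tibble (original-image
#'   coordinates).
#' @param specimens Specimen manifest; `image_path` entries are resolved
#'   against `image_dir`.
#' @param radius_table Calibrated radius table (resized-space radii).
#' @param out_dir Output directory (created); resized images go to
#'   `out_dir/images/`, the JSON to `out_dir/annotations.json`.
#' @param image_dir Directory containing the source images (default: paths
#'   in the manifest are used as-is).
#' @param fallback_organ_mean Allow organ-level mean radius when a
#'   (genus, organ) entry is missing.
#' @return Invisibly, a list with `json_path`, `n_images`,
#'   `n_annotations`.
#' @export
export_coco <- function(annotations, specimens, radius_table, out_dir,
                        image_dir = NULL, fallback_organ_mean = FALSE) {
  ann <- as_tibble(annotations)
  spx <- as_tibble(specimens)
  # resolve radii up front so a missing entry fails before any I/O
  pairs <- distinct(ann, .data$genus, .data$organ)
  for (i in seq_len(nrow(pairs))) {
    radius_lookup(radius_table, pairs$genus[i], pairs$organ[i],
                  fallback_organ_mean)
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  images <- list(); annos <- list(); ann_id <- 0L
  for (i in seq_len(nrow(spx))) {
    sp <- spx[i, ]
    src <- if (is.null(image_dir)) sp$image_path else
      file.path(image_dir, sp$image_path)
    img <- read_image(src)
    plan <- plan_resize(sp$width, sp$height)
    out_name <- paste0(sp$specimen_id, ".png")
    write_image(resize_image(img, plan), file.path(out_dir, "images", out_name))
    images[[i]] <- list(id = i, file_name = out_name,
                        width = plan$target_width,
                        height = plan$target_height,
                        specimen_id = sp$specimen_id)
    dots <- filter(ann, .data$specimen_id == sp$specimen_id)
    if (nrow(dots) == 0) next
    dots <- transform_points(dots, plan)
    for (j in seq_len(nrow(dots))) {
      r <- radius_lookup(radius_table, dots$genus[j], dots$organ[j],
                         fallback_organ_mean)
      poly <- clip_polygon(build_dodecagon(dots$x[j], dots$y[j], r),
                           plan$target_width, plan$target_height)
      mask <- rasterize_polygon(poly, plan$target_width, plan$target_height,
                                clip = FALSE)
      ann_id <- ann_id + 1L
      bbox <- c(min(poly$x), min(poly$y),
                max(poly$x) - min(poly$x), max(poly$y) - min(poly$y))
      annos[[ann_id]] <- list(
        id = ann_id, image_id = i,
        category_id = match(as.character(dots$organ[j]), organ_levels()),
        segmentation = list(as.numeric(rbind(poly$x, poly$y))),
        bbox = as.numeric(bbox),
        area = sum(mask),
        iscrowd = 0L)
    }
  }
  json_path <- file.path(out_dir, "annotations.json")
  jsonlite::write_json(
    list(images = images, annotations = annos,
         categories = apply(coco_categories(), 1, as.list)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(json_path = json_path, n_images = nrow(spx),
                 n_annotations = ann_id))
}

#' Read back a COCO export as tidy tibbles
#'
#' @param json_path Path to a COCO annotations JSON.
#' @return List of tibbles: `images` (id, file_name, width, height,
#'   specimen_id) and `annotations` (id, image_id, organ, bbox columns,
#'   area, vertex count).
#' @export
read_coco <- function(json_path) {
  j <- jsonlite::read_json(json_path)
  images <- purrr::map_dfr(j$images, function(im) {
    tibble(id = im$id, file_name = im$file_name, width = im$width,
           height = im$height,
           specimen_id = im$specimen_id %||% NA_character_)
  })
  annotations <- purrr::map_dfr(j$annotations, function(a) {
    bb <- unlist(a$bbox)
    tibble(id = a$id, image_id = a$image_id,
           organ = organ_levels()[a$category_id],
           bbox_x = bb[1], bbox_y = bb[2], bbox_w = bb[3], bbox_h = bb[4],
           area = a$area,
           n_vertices = length(unlist(a$segmentation[[1]])) / 2)
  })
  if (nrow(annotations) > 0) {
    annotations$organ <- factor(annotations$organ, levels = organ_levels())
  }
  list(images = images, annotations = annotations)
}
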