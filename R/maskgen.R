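#' Calibrate an enclosing-circle radius for one (genus, organ) pair
#'
#' Dodecagon masks are scaled per genus and organ from the mean radius of
#' the circle enclosing a handful of manually segmented structures
#' (recommended n = 5 per pair). Radii are stored in *resized-image* pixels;
#' measurements taken on original images must be pre-multiplied by the
#' specimen's resize scale.
#'
#' @param samples Numeric vector of enclosing-circle radii (px, resized
#'   space), all positive.
#' @param genus,organ Labels for the calibrated entry.
#' @return One-row radius-table tibble: `genus`, `organ`, `radius_px`,
#'   `n_samples`. Warns when fewer than 5 samples are supplied.
#' @export
#' @examples
#' calibrate_radius(c(8, 10, 12), "Trillium", "flower")
calibrate_radius <- function(samples, genus, organ) {
  if (length(samples) == 0) abort("calibrate_radius: empty sample list")
  if (any(!is.finite(samples) | samples <= 0)) {
    abort("calibrate_radius: radii must be positive and finite")
  }
  if (length(samples) < 5) {
    warn(sprintf(
      "calibrate_radius(%s, %s): only %d sample(s); 5 per (genus, organ) are recommended",
      genus, organ, length(samples)))
  }
  tibble(genus = as.character(genus),
         organ = as_organ(organ),
         radius_px = mean(samples),
         n_samples = length(samples))
}

#' Calibrate a full radius table from measured samples
#'
#' @param samples A data frame with columns `genus`, `organ`, `radius`
#'   (one row per manually segmented structure).
#' @return Radius-table tibble with one row per (genus, organ) pair.
#' @export
calibrate_radii <- function(samples) {
  df <- as_tibble(samples)
  assert_cols(df, c("genus", "organ", "radius"), "calibrate_radii")
  df |>
    mutate(organ = as_organ(.data$organ)) |>
    group_by(.data$genus, .data$organ) |>
    summarise(radius_px = mean(.data$radius),
              n_samples = dplyr::n(), .groups = "drop") |>
    arrange(.data$genus, .data$organ)
}

#' Look up a mask radius, with optional organ-level fallback
#'
#' @param radius_table A radius table (see [calibrate_radii()]).
#' @param genus,organ The pair to resolve.
#' @param fallback_organ_mean If `TRUE`, a missing (genus, organ) entry
#'   falls back to the mean radius of that organ across genera; off by
#'   default.
#' @return Radius in resized-image pixels.
#' @export
radius_lookup <- function(radius_table, genus, organ,
                          fallback_organ_mean = FALSE) {
  organ <- as.character(organ)
  hit <- radius_table[radius_table$genus == genus &
                        as.character(radius_table$organ) == organ, ]
  if (nrow(hit) >= 1) return(hit$radius_px[[1]])
  if (fallback_organ_mean) {
    pool <- radius_table[as.character(radius_table$organ) == organ, ]
    if (nrow(pool) > 0) return(mean(pool$radius_px))
  }
  abort(sprintf("no radius entry for (genus = %s, organ = %s) and no fallback enabled",
                genus, organ),
        class = "phenocount_config_error")
}

#' Plan an aspect-preserving resize to the detector's working size
#'
#' Images are resized so the long edge fits `long_max` px and the short edge
#' fits `short_max` px, preserving aspect ratio and orientation:
#' scale = min(long_max/long, short_max/short). Smaller images are upscaled
#' by the same rule so that calibrated radii stay meaningful.
#'
#' @param width,height Source image dimensions in pixels (positive).
#' @param long_max,short_max Working-size constraints (default 1024 x 600).
#' @return A `resize_plan` list: `source_width`, `source_height`,
#'   `target_width`, `target_height`, `scale`.
#' @export
#' @examples
#' plan_resize(2048, 1200)  # scale 0.5 -> 1024 x 600
plan_resize <- function(width, height, long_max = 1024, short_max = 600) {
  if (width <= 0 || height <= 0) abort("plan_resize: non-positive dimensions")
  long <- max(width, height)
  short <- min(width, height)
  s <- min(long_max / long, short_max / short)
  plan <- list(source_width = width, source_height = height,
               target_width = max(1L, as.integer(round(s * width))),
               target_height = max(1L, as.integer(round(s * height))),
               scale = s)
  class(plan) <- "resize_plan"
  plan
}

#' @export
print.resize_plan <- function(x, ...) {
  cat(sprintf("<resize_plan> %d x %d -> %d x %d (scale %.4f)\n",
              x$source_width, x$source_height,
              x$target_width, x$target_height, x$scale))
  invisible(x)
}

#' Map source-image points into resized-image space
#'
#' @param points Data frame with `x`, `y` columns, 0-based pixel coordinates
#'   in the source image.
#' @param plan A [plan_resize()] plan.
#' @return The input with `x`, `y` replaced by scaled coordinates, clamped
#'   to the resized bounds `[0, target - 1]`.
#' @export
transform_points <- function(points, plan) {
  stopifnot(inherits(plan, "resize_plan"))
  df <- as_tibble(points)
  assert_cols(df, c("x", "y"), "transform_points")
  if (nrow(df) > 0 &&
      any(df$x < 0 | df$y < 0 |
          df$x >= plan$source_width | df$y >= plan$source_height)) {
    abort("transform_points: point(s) outside source image bounds")
  }
  mutate(df,
         x = pmin(pmax(.data$x * plan$scale, 0), plan$target_width - 1),
         y = pmin(pmax(.data$y * plan$scale, 0), plan$target_height - 1))
}

#' Construct a regular dodecagon mask polygon
#'
#' The surrogate segmentation mask around a dot marker: a regular 12-gon
#' inscribed in the circle of the calibrated radius. Vertex k sits at angle
#' 30k degrees from east, counter-clockwise, giving a consistent winding
#' order. Its exact area is 3 r^2 (closed form (n/2) r^2 sin(2*pi/n) at
#' n = 12).
#'
#' @param cx,cy Center (px).
#' @param radius Circumscribed-circle radius (px, > 0).
#' @return A 12-row tibble of vertices `x`, `y`.
#' @export
#' @examples
#' build_dodecagon(0, 0, 10)
build_dodecagon <- function(cx, cy, radius) {
  if (!is.finite(radius) || radius <= 0) {
    abort("build_dodecagon: radius must be positive")
  }
  ang <- 2 * pi * (0:11) / 12
  tibble(x = cx + radius * cos(ang), y = cy + radius * sin(ang))
}

#' Exact area of a dodecagon mask
#' @param radius Circumscribed-circle radius.
#' @return `3 * radius^2`.
#' @export
dodecagon_area <- function(radius) 3 * radius^2

# Shoelace area of a polygon given as a data frame of vertices.
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Clip a polygon to image bounds
#'
#' Sutherland-Hodgman clipping against the image rectangle
#' `[0, width] x [0, height]` (continuous coordinates); masks are clipped,
#' never wrapped.
#'
#' @param poly Data frame of vertices `x`, `y`.
#' @param width,height Image dimensions (px).
#' @return Clipped polygon tibble (possibly 0 rows if fully outside).
#' @export
clip_polygon <- function(poly, width, height) {
  edges <- list(
    function(p) p[1] >= 0,      # left
    function(p) p[1] <= width,  # right
    function(p) p[2] >= 0,      # top
    function(p) p[2] <= height) # bottom
  intersect_edge <- function(p1, p2, axis, value) {
    t <- (value - p1[axis]) / (p2[axis] - p1[axis])
    p1 + t * (p2 - p1)
  }
  params <- list(c(1, 0), c(1, width), c(2, 0), c(2, height))
  pts <- lapply(seq_len(nrow(poly)), function(i) c(poly$x[i], poly$y[i]))
  for (e in seq_along(edges)) {
    inside <- edges[[e]]
    axis <- params[[e]][1]; value <- params[[e]][2]
    out <- list()
    n <- length(pts)
    if (n == 0) break
    for (i in seq_len(n)) {
      cur <- pts[[i]]
      prev <- pts[[if (i == 1) n else i - 1]]
      if (inside(cur)) {
        if (!inside(prev)) {
          out[[length(out) + 1]] <- intersect_edge(prev, cur, axis, value)
        }
        out[[length(out) + 1]] <- cur
      } else if (inside(prev)) {
        out[[length(out) + 1]] <- intersect_edge(prev, cur, axis, value)
      }
    }
    pts <- out
  }
  if (length(pts) == 0) return(tibble(x = numeric(), y = numeric()))
  tibble(x = vapply(pts, `[`, numeric(1), 1),
         y = vapply(pts, `[`, numeric(1), 2))
}

#' Rasterize a polygon onto the image grid
#'
#' A pixel belongs to the mask when its center falls inside the (optionally
#' boundary-clipped) polygon; the image grid is half-open,
#' `[0, W) x [0, H)`, with pixel (i, j) centered at (i + 0.5, j + 0.5).
#'
#' @param poly Polygon tibble (`x`, `y` vertices).
#' @param width,height Image dimensions (px).
#' @param clip Clip the polygon to image bounds first (default `TRUE`).
#' @return Logical matrix `height` x `width` (rows = y). A polygon fully
#'   outside the image yields an empty mask with a warning.
#' @export
rasterize_polygon <- function(poly, width, height, clip = TRUE) {
  stopifnot(width > 0, height > 0)
  p <- if (clip) clip_polygon(poly, width, height) else as_tibble(poly)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  if (nrow(p) < 3) {
    warn("rasterize_polygon: polygon lies outside the image; empty mask")
    return(mask)
  }
  x0 <- max(0L, floor(min(p$x)))
  x1 <- min(width - 1L, ceiling(max(p$x)))
  y0 <- max(0L, floor(min(p$y)))
  y1 <- min(height - 1L, ceiling(max(p$y)))
  if (x1 < x0 || y1 < y0) {
    warn("rasterize_polygon: polygon lies outside the image; empty mask")
    return(mask)
  }
  xs <- seq(x0, x1) + 0.5
  ys <- seq(y0, y1) + 0.5
  grid <- expand.grid(x = xs, y = ys)
  inside <- pracma::inpolygon(grid$x, grid$y, p$x, p$y, boundary = TRUE)
  mask[cbind(rep(ys - 0.5, each = length(xs)) + 1L,
             rep(xs - 0.5, times = length(ys)) + 1L)] <- inside
  mask
}

#' Run-length encode a binary mask (column-major)
#'
#' Uncompressed COCO-style run-length encoding: the mask is flattened in
#' column-major order and stored as alternating run lengths starting with
#' the number of leading zeros. Encoding and decoding round-trip
#' losslessly.
#'
#' @param mask Logical matrix (rows = y).
#' @return List with `counts` (integer runs), `size` = c(height, width).
#' @export
encode_rle <- function(mask) {
  v <- as.integer(as.vector(mask))  # column-major, matches COCO order
  r <- rle(v)
  counts <- r$lengths
  if (length(r$values) > 0 && r$values[1] == 1L) counts <- c(0L, counts)
  list(counts = as.integer(counts), size = c(nrow(mask), ncol(mask)))
}

#' Decode a run-length encoded mask
#' @param rle A list as returned by [encode_rle()].
#' @return Logical matrix.
#' @export
decode_rle <- function(rle) {
  h <- rle$size[1]; w <- rle$size[2]
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(rle$counts)),
              times = rle$counts)
  matrix(vals, nrow = h, ncol = w)
}

#' Derive detector anchor sizes covering all dodecagon masks
#'
#' Region-proposal anchors must cover every mask entirely: the smallest
#' anchor must not exceed the smallest dodecagon's bounding-box side
#' (2 r cos 15 deg for a 12-gon with a flat-side orientation) and the
#' largest must reach the largest dodecagon's diameter (2 r). Sizes form a
#' geometric ladder of powers of two.
#'
#' @param radius_table Radius table (see [calibrate_radii()]).
#' @param aspect_ratios Anchor aspect ratios (default `c(0.5, 1, 2)`).
#' @return An `anchor_spec` list: strictly increasing `sizes` (px) and
#'   `aspect_ratios`.
#' @export
derive_anchor_spec <- function(radius_table, aspect_ratios = c(0.5, 1, 2)) {
  if (nrow(radius_table) == 0) abort("derive_anchor_spec: empty radius table")
  r_min <- min(radius_table$radius_px)
  r_max <- max(radius_table$radius_px)
  min_side <- 2 * r_min * cos(pi / 12)
  s0 <- 2^floor(log2(min_side))
  sizes <- s0
  while (tail(sizes, 1) < 2 * r_max) sizes <- c(sizes, 2 * tail(sizes, 1))
  spec <- list(sizes = sizes, aspect_ratios = aspect_ratios)
  class(spec) <- "anchor_spec"
  spec
}

#' @export
print.anchor_spec <- function(x, ...) {
  cat("<anchor_spec> sizes:", paste(x$sizes, collapse = ", "),
      "| aspect ratios:", paste(x$aspect_ratios, collapse = ", "), "\n")
  invisible(x)
}
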