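#' Default organ color palette for synthetic sheets
#'
#' Organ classes are rendered in visually distinct colors so that
#' detectability tracks organ size and distinctiveness: flowers as light
#' pink 5-lobed blobs, buds as small dark ellipses, fruits as mid-dark
#' disks. All pairwise max-channel distances (and distances to the sheet
#' background and clutter greens) exceed twice the baseline detector's
#' default color tolerance.
#'
#' @param variant `"default"` for the base palette, `"shifted"` for a
#'   second "species" whose organs take different colors — used to emulate
#'   morphological divergence in cross-species transfer experiments.
#' @return Palette tibble `organ`, `r`, `g`, `b`.
#' @export
default_palette <- function(variant = c("default", "shifted")) {
  variant <- match.arg(variant)
  if (variant == "default") {
    tibble(organ = as_organ(organ_levels()),
           r = c(0.30, 0.95, 0.70),
           g = c(0.22, 0.60, 0.25),
           b = c(0.45, 0.75, 0.15))
  } else {
    tibble(organ = as_organ(organ_levels()),
           r = c(0.75, 0.55, 0.20),
           g = c(0.65, 0.75, 0.45),
           b = c(0.20, 0.95, 0.60))
  }
}

synthetic_background <- function() c(0.91, 0.87, 0.78)
clutter_colors <- function() list(stem = c(0.33, 0.50, 0.28),
                                  leaf = c(0.42, 0.58, 0.33))

#' Parameters of the synthetic herbarium-sheet generator
#'
#' The generator emulates the statistical structure of a real phenology
#' dataset: strongly imbalanced organ frequencies (flowers >> fruits >>
#' buds), sparse sheets averaging fewer than 3 structures, and organ sizes
#' that differ by class. Per-organ counts follow a zero-inflated
#' (hurdle) Poisson: present with probability `presence[k]`, and
#' `1 + Poisson(lambda[k])` structures when present. The defaults give
#' expected marginal organ proportions of 6.2 / 77.4 / 16.4 percent
#' (bud/flower/fruit) and about 2.57 structures per sheet.
#'
#' @param width,height Sheet dimensions in px (default 600 x 1024, the
#'   detector's working size).
#' @param species,genus Taxon labels attached to generated specimens.
#' @param presence Named per-organ presence probabilities.
#' @param lambda Named per-organ Poisson means given presence.
#' @param radius_mean,radius_sd Named per-organ enclosing-circle radius
#'   distributions (px); radii are truncated below at
#'   `max(5, mean - 3 sd)`.
#' @param palette Organ palette tibble (see [default_palette()]).
#' @param clutter Expected number of green stem/leaf clutter elements.
#' @param overlap Allow organ instances to overlap (default `FALSE`:
#'   placement keeps instances separated so detection-by-color recovers
#'   every instance).
#' @param noise_sd Gaussian pixel noise standard deviation (default 0,
#'   noiseless).
#' @return A `sheet_params` list.
#' @export
sheet_params <- function(width = 600, height = 1024,
                         species = "Fictularia prima",
                         genus = "Fictularia",
                         presence = c(bud = 0.0975, flower = 0.8292,
                                      fruit = 0.20),
                         lambda = c(bud = 0.642, flower = 1.401,
                                    fruit = 1.112),
                         radius_mean = c(bud = 9, flower = 22, fruit = 14),
                         radius_sd = c(bud = 1, flower = 3, fruit = 2),
                         palette = default_palette(),
                         clutter = 6,
                         overlap = FALSE,
                         noise_sd = 0) {
  stopifnot(width > 0, height > 0,
            all(presence >= 0 & presence <= 1),
            all(lambda >= 0), all(radius_mean > 0))
  p <- list(width = width, height = height, species = species,
            genus = genus,
            presence = presence[organ_levels()],
            lambda = lambda[organ_levels()],
            radius_mean = radius_mean[organ_levels()],
            radius_sd = radius_sd[organ_levels()],
            palette = palette, clutter = clutter, overlap = overlap,
            noise_sd = noise_sd)
  class(p) <- "sheet_params"
  p
}

#' Draw per-specimen structure counts from the generator's model
#'
#' @param params A [sheet_params()] object.
#' @param n Number of specimens.
#' @param seed Integer seed.
#' @return Tidy count tibble (`specimen_id`, `organ`, `count`).
#' @export
sample_structure_counts <- function(params, n, seed) {
  stopifnot(inherits(params, "sheet_params"), n >= 1)
  withr::with_seed(seed, {
    purrr::map_dfr(organ_levels(), function(k) {
      present <- rbinom(n, 1, params$presence[[k]])
      tibble(specimen_id = sprintf("SYN%04d", seq_len(n)),
             organ = factor(k, levels = organ_levels()),
             count = as.integer(present * (1 + rpois(n, params$lambda[[k]]))))
    }) |>
      arrange(.data$specimen_id, .data$organ)
  })
}

# Membership predicate of one rendered organ instance over coordinate
# matrices X, Y (pixel centers). Shapes are symmetric so the mask centroid
# coincides with the center.
organ_membership <- function(organ, cx, cy, r, theta, X, Y) {
  dx <- X - cx; dy <- Y - cy
  switch(organ,
    fruit = dx^2 + dy^2 <= r^2,
    bud = {
      a <- r; b <- 0.6 * r
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      (u / a)^2 + (v / b)^2 <= 1
    },
    flower = {
      core <- dx^2 + dy^2 <= (0.45 * r)^2
      for (ang in theta + 2 * pi * (0:4) / 5) {
        lx <- cx + 0.52 * r * cos(ang)
        ly <- cy + 0.52 * r * sin(ang)
        core <- core | ((X - lx)^2 + (Y - ly)^2 <= (0.48 * r)^2)
      }
      core
    })
}

paint <- function(image, mask_window, rows, cols, color) {
  for (ch in 1:3) {
    layer <- image[rows, cols, ch]
    layer[mask_window] <- color[ch]
    image[rows, cols, ch] <- layer
  }
  image
}

draw_clutter <- function(image, params) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cols <- clutter_colors()
  n_elem <- rpois(1, params$clutter)
  X <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  Y <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
  for (e in seq_len(n_elem)) {
    if (runif(1) < 0.5) {
      # stem: a thick line segment growing roughly upward
      x0 <- runif(1, 0.1 * w, 0.9 * w); y0 <- runif(1, 0.5 * h, h)
      ang <- runif(1, -pi / 3, pi / 3) - pi / 2
      len <- runif(1, 0.2 * h, 0.6 * h)
      x1 <- x0 + len * cos(ang); y1 <- y0 + len * sin(ang)
      dx <- x1 - x0; dy <- y1 - y0
      t <- pmin(pmax(((X - x0) * dx + (Y - y0) * dy) / (dx^2 + dy^2), 0), 1)
      d2 <- (X - (x0 + t * dx))^2 + (Y - (y0 + t * dy))^2
      mask <- d2 <= runif(1, 1.5, 3)^2
      for (ch in 1:3) {
        layer <- image[, , ch]; layer[mask] <- cols$stem[ch]
        image[, , ch] <- layer
      }
    } else {
      # leaf: a tilted ellipse
      cx <- runif(1, 0, w); cy <- runif(1, 0, h)
      a <- runif(1, 15, 45); b <- 0.4 * a; th <- runif(1, 0, pi)
      u <- (X - cx) * cos(th) + (Y - cy) * sin(th)
      v <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
      mask <- (u / a)^2 + (v / b)^2 <= 1
      for (ch in 1:3) {
        layer <- image[, , ch]; layer[mask] <- cols$leaf[ch]
        image[, , ch] <- layer
      }
    }
  }
  image
}

#' Generate one synthetic herbarium sheet with full ground truth
#'
#' Renders a beige sheet with green stem/leaf clutter and the drawn number
#' of organ instances (lobed, elliptical, or disk blobs in organ-specific
#' colors). Placement keeps instances inside the sheet and, unless
#' `params$overlap` is set, separated from each other; a sheet whose
#' requested organs cannot be placed within the retry budget is an error.
#' Deterministic given the seed.
#'
#' @param params A [sheet_params()] object.
#' @param seed Integer seed.
#' @param specimen_id Id attached to the ground truth.
#' @return List with `image` (RGB array), `truth` (tibble `organ`, `x`,
#'   `y` — the truth-mask centroid, `radius`, and list-column `rle` with
#'   the full instance mask), and `counts` (tidy count tibble).
#' @export
generate_specimen <- function(params, seed, specimen_id = "SYN0001") {
  stopifnot(inherits(params, "sheet_params"))
  withr::with_seed(seed, {
    w <- params$width; h <- params$height
    counts <- purrr::map_int(organ_levels(), function(k) {
      as.integer(rbinom(1, 1, params$presence[[k]]) *
                   (1 + rpois(1, params$lambda[[k]])))
    })
    names(counts) <- organ_levels()
    image <- array(rep(synthetic_background(), each = h * w), dim = c(h, w, 3))
    image <- draw_clutter(image, params)

    placed <- tibble(organ = character(), x = numeric(), y = numeric(),
                     radius = numeric(), theta = numeric())
    for (k in organ_levels()) {
      n_k <- counts[[k]]
      if (n_k == 0) next
      for (j in seq_len(n_k)) {
        r <- max(max(5, params$radius_mean[[k]] - 3 * params$radius_sd[[k]]),
                 rnorm(1, params$radius_mean[[k]], params$radius_sd[[k]]))
        ok <- FALSE
        for (try in seq_len(300)) {
          cx <- runif(1, r + 2, w - r - 3)
          cy <- runif(1, r + 2, h - r - 3)
          if (params$overlap || nrow(placed) == 0 ||
              all((placed$x - cx)^2 + (placed$y - cy)^2 >
                    (placed$radius + r + 6)^2)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(
            "generate_specimen: could not place %s #%d without overlap (retry budget exhausted)",
            k, j), class = "phenocount_placement_error")
        }
        placed <- bind_rows(placed,
                            tibble(organ = k, x = cx, y = cy, radius = r,
                                   theta = runif(1, 0, pi)))
      }
    }

    truth <- purrr::map_dfr(seq_len(nrow(placed)), function(i) {
      p <- placed[i, ]
      x0 <- max(0, floor(p$x - p$radius - 1))
      x1 <- min(w - 1, ceiling(p$x + p$radius + 1))
      y0 <- max(0, floor(p$y - p$radius - 1))
      y1 <- min(h - 1, ceiling(p$y + p$radius + 1))
      Xw <- matrix(rep(x0:x1 + 0.5, each = y1 - y0 + 1), nrow = y1 - y0 + 1)
      Yw <- matrix(rep(y0:y1 + 0.5, times = x1 - x0 + 1), nrow = y1 - y0 + 1)
      mw <- organ_membership(p$organ, p$x, p$y, p$radius, p$theta, Xw, Yw)
      pal <- params$palette[as.character(params$palette$organ) == p$organ, ]
      image <<- paint(image, mw, (y0:y1) + 1, (x0:x1) + 1,
                      c(pal$r, pal$g, pal$b))
      full <- matrix(FALSE, nrow = h, ncol = w)
      full[(y0:y1) + 1, (x0:x1) + 1] <- mw
      px <- which(full, arr.ind = TRUE)
      tibble(organ = factor(p$organ, levels = organ_levels()),
             x = mean(px[, 2] - 1), y = mean(px[, 1] - 1),
             radius = p$radius,
             rle = list(encode_rle(full)))
    })
    if (params$noise_sd > 0) {
      image <- pmin(pmax(image + rnorm(length(image), 0, params$noise_sd),
                         0), 1)
    }
    if (nrow(truth) == 0) {
      truth <- tibble(organ = factor(character(), levels = organ_levels()),
                      x = numeric(), y = numeric(), radius = numeric(),
                      rle = list())
    }
    counts_tbl <- tibble(
      specimen_id = specimen_id,
      organ = factor(organ_levels(), levels = organ_levels()),
      count = as.integer(counts))
    list(image = image, truth = truth, counts = counts_tbl)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes everything the annotation pipeline consumes: `images/*.png`, a
#' specimen manifest (`manifest.csv`), a dot-annotation table
#' (`annotations.csv`, one expert row per ground-truth instance with the
#' dot at the truth-mask centroid), and a full ground-truth JSON
#' (`truth.json` with per-instance organ, center, radius, and RLE mask).
#'
#' @param n Number of specimens (>= 1).
#' @param params A [sheet_params()] object, or a list of them (one per
#'   synthetic "species"; specimens are assigned to species uniformly at
#'   random).
#' @param out_dir Output directory (created).
#' @param seed Integer seed; per-specimen seeds are derived from it.
#' @return Invisibly, a list with `specimens`, `annotations`, `truth_counts`
#'   tibbles and the paths written.
#' @export
generate_dataset <- function(n, params, out_dir, seed = 1) {
  stopifnot(n >= 1)
  if (inherits(params, "sheet_params")) params <- list(params)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  draws <- withr::with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1, n),
    species_idx = sample.int(length(params), n, replace = TRUE)))
  specimens <- list(); annotations <- list(); truth_counts <- list()
  truth_json <- list()
  for (i in seq_len(n)) {
    p <- params[[draws$species_idx[i]]]
    id <- sprintf("SYN%04d", i)
    spec <- generate_specimen(p, draws$seeds[i], id)
    img_rel <- file.path("images", paste0(id, ".png"))
    write_image(spec$image, file.path(out_dir, img_rel))
    specimens[[i]] <- tibble(
      specimen_id = id, image_path = img_rel,
      width = p$width, height = p$height,
      species = p$species, genus = p$genus)
    if (nrow(spec$truth) > 0) {
      annotations[[i]] <- tibble(
        specimen_id = id, annotator_id = "E1", annotator_role = "expert",
        organ = as.character(spec$truth$organ),
        x = spec$truth$x, y = spec$truth$y,
        species = p$species, genus = p$genus)
    }
    truth_counts[[i]] <- spec$counts
    truth_json[[i]] <- list(
      specimen_id = id,
      instances = purrr::map(seq_len(nrow(spec$truth)), function(j) {
        list(organ = as.character(spec$truth$organ[j]),
             x = spec$truth$x[j], y = spec$truth$y[j],
             radius = spec$truth$radius[j],
             rle_counts = spec$truth$rle[[j]]$counts,
             rle_size = spec$truth$rle[[j]]$size)
      }))
  }
  specimens <- bind_rows(specimens)
  annotations <- bind_rows(annotations)
  if (nrow(annotations) == 0) {
    annotations <- tibble(specimen_id = character(),
                          annotator_id = character(),
                          annotator_role = character(), organ = character(),
                          x = numeric(), y = numeric(),
                          species = character(), genus = character())
  }
  truth_counts <- bind_rows(truth_counts)
  readr::write_csv(specimens, file.path(out_dir, "manifest.csv"))
  readr::write_csv(annotations, file.path(out_dir, "annotations.csv"))
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(specimens = specimens, annotations = annotations,
                 truth_counts = truth_counts, dir = out_dir))
}

#' Read a generated ground-truth JSON
#'
#' @param path Path to a `truth.json` written by [generate_dataset()].
#' @return List with `instances` (tibble `specimen_id`, `organ`, `x`, `y`,
#'   `radius`, list-column `rle`) and `counts` (tidy count tibble over all
#'   specimens in the file).
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path)
  instances <- purrr::map_dfr(j, function(sp) {
    purrr::map_dfr(sp$instances, function(inst) {
      tibble(specimen_id = sp$specimen_id,
             organ = inst$organ, x = inst$x, y = inst$y,
             radius = inst$radius,
             rle = list(list(counts = as.integer(unlist(inst$rle_counts)),
                             size = as.integer(unlist(inst$rle_size)))))
    })
  })
  ids <- purrr::map_chr(j, "specimen_id")
  if (nrow(instances) > 0) {
    instances$organ <- as_organ(instances$organ)
    counts <- count_structures(
      select(instances, "specimen_id", "organ"),
      tibble(specimen_id = ids))
  } else {
    counts <- count_structures(
      tibble(specimen_id = character(), organ = character()),
      tibble(specimen_id = ids))
  }
  list(instances = instances, counts = counts)
}

#' Calibration radii implied by the generator's ground truth
#'
#' Mimics the manual calibration protocol on synthetic data: sample a few
#' ground-truth enclosing-circle radii per (genus, organ) and average them.
#'
#' @param truth_annotations Annotation tibble joined with truth radii
#'   (columns `genus`, `organ`, `radius`).
#' @param n_per_pair Samples per (genus, organ) pair (default 5).
#' @param seed Integer seed for the sample.
#' @return Radius table tibble.
#' @export
calibrate_from_truth <- function(truth_annotations, n_per_pair = 5, seed = 1) {
  df <- as_tibble(truth_annotations)
  assert_cols(df, c("genus", "organ", "radius"), "calibrate_from_truth")
  withr::with_seed(seed, {
    df |>
      group_by(.data$genus, .data$organ) |>
      dplyr::slice_sample(n = n_per_pair) |>
      ungroup() |>
      calibrate_radii()
  })
}
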