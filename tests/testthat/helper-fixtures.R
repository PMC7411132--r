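# Shared in-code fixtures: small annotation tables and rendered sheets.

make_annotations <- function(rows) {
  defaults <- tibble::tibble(
    specimen_id = "S1", annotator_id = "E1", annotator_role = "expert",
    organ = "flower", x = 10, y = 10,
    species = "Fictularia prima", genus = "Fictularia")
  out <- lapply(rows, function(r) {
    d <- defaults
    for (nm in names(r)) d[[nm]] <- r[[nm]]
    d
  })
  dplyr::bind_rows(out)
}

make_counts <- function(specimen_id, bud = 0, flower = 0, fruit = 0) {
  n <- length(specimen_id)
  bud <- rep(bud, length.out = n)
  flower <- rep(flower, length.out = n)
  fruit <- rep(fruit, length.out = n)
  tibble::tibble(
    specimen_id = rep(specimen_id, each = 3),
    organ = factor(rep(organ_levels(), n), levels = organ_levels()),
    count = as.vector(rbind(bud, flower, fruit)))
}

# n crowd-annotated flower markers on one specimen by one annotator.
crowd_rows <- function(specimen, annotator, flowers) {
  make_annotations(lapply(seq_len(flowers), function(i)
    list(specimen_id = specimen, annotator_id = annotator,
         annotator_role = "crowd", organ = "flower")))
}

# Blank synthetic sheet in the default background color.
blank_sheet <- function(width = 120, height = 160) {
  bg <- c(0.91, 0.87, 0.78)
  array(rep(bg, each = height * width), dim = c(height, width, 3))
}

# Paint a filled disk in organ color onto a sheet.
paint_disk <- function(image, cx, cy, r, color) {
  h <- dim(image)[1]; w <- dim(image)[2]
  X <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  Y <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
  mask <- (X - cx)^2 + (Y - cy)^2 <= r^2
  for (ch in 1:3) {
    layer <- image[, , ch]
    layer[mask] <- color[ch]
    image[, , ch] <- layer
  }
  image
}

organ_color <- function(organ, palette = default_palette()) {
  row <- palette[as.character(palette$organ) == organ, ]
  c(row$r, row$g, row$b)
}

# A small generated dataset on disk, shared across tests in a file.
small_dataset <- function(n = 6, seed = 7, params = sheet_params()) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  generate_dataset(n, params, dir, seed = seed)
  spx <- read_specimens(file.path(dir, "manifest.csv"))
  ann <- read_annotations(file.path(dir, "annotations.csv"), spx)
  list(dir = dir, specimens = spx, annotations = ann,
       truth = read_truth(file.path(dir, "truth.json")))
}
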