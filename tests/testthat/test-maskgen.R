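test_that("radius calibration averages samples and tracks provenance", {
  entry <- calibrate_radius(c(10, 10, 10, 10, 10), "Fictularia", "flower")
  expect_equal(entry$radius_px, 10)
  expect_equal(entry$n_samples, 5)
  expect_equal(suppressWarnings(
    calibrate_radius(c(8, 10, 12), "G", "bud")$radius_px), 10)
  expect_warning(calibrate_radius(5, "G", "fruit"), "5 per")
  expect_error(calibrate_radius(numeric(), "G", "bud"), "empty")
  expect_error(calibrate_radius(c(3, -1), "G", "bud"), "positive")

  rt <- calibrate_radii(tibble::tibble(
    genus = "G", organ = rep(c("bud", "flower"), each = 5),
    radius = c(rep(4, 5), 6:10)))
  expect_equal(nrow(rt), 2)
  expect_equal(rt$radius_px, c(4, 8))
  expect_equal(radius_lookup(rt, "G", "flower"), 8)
  expect_error(radius_lookup(rt, "G", "fruit"), "fruit",
               class = "phenocount_config_error")
  expect_equal(radius_lookup(rt, "H", "bud", fallback_organ_mean = TRUE), 4)
})

test_that("resize plans fit within 1024 x 600 preserving aspect ratio", {
  p <- plan_resize(2048, 1200)
  expect_equal(p$scale, 0.5)
  expect_equal(c(p$target_width, p$target_height), c(1024L, 600L))

  # long-edge constraint binds
  p2 <- plan_resize(4096, 1200)
  expect_equal(p2$scale, 0.25)
  expect_equal(c(p2$target_width, p2$target_height), c(1024L, 300L))

  # short-edge constraint binds on a square
  p3 <- plan_resize(1000, 1000)
  expect_equal(p3$scale, 0.6)
  expect_equal(c(p3$target_width, p3$target_height), c(600L, 600L))

  # portrait orientation preserved; small images are upscaled
  p4 <- plan_resize(300, 512)
  expect_equal(p4$scale, 2)
  expect_equal(c(p4$target_width, p4$target_height), c(600L, 1024L))
  expect_error(plan_resize(0, 10), "non-positive")
})

test_that("point transforms scale, fix the origin, and clamp corners", {
  plan <- plan_resize(2048, 1200)
  got <- transform_points(tibble::tibble(x = c(100, 0), y = c(200, 0)), plan)
  expect_equal(got$x, c(50, 0))
  expect_equal(got$y, c(100, 0))

  corner <- transform_points(
    tibble::tibble(x = 2047, y = 1199), plan)
  expect_lte(corner$x, plan$target_width - 1)
  expect_lte(corner$y, plan$target_height - 1)
  expect_error(transform_points(tibble::tibble(x = 2048, y = 0), plan),
               "outside source")
})

test_that("dodecagons are regular 12-gons with area 3 r^2", {
  for (r in c(1, 10, 32.5)) {
    poly <- build_dodecagon(0, 0, r)
    expect_equal(nrow(poly), 12)
    expect_equal(poly$x[1], r)
    expect_equal(poly$y[1], 0)
    expect_equal(sqrt(poly$x^2 + poly$y^2), rep(r, 12))
    # shoelace area equals the closed form (n/2) r^2 sin(2 pi / n) = 3 r^2
    area <- abs(sum(poly$x * dplyr::lead(poly$y, default = poly$y[1]) -
                      dplyr::lead(poly$x, default = poly$x[1]) * poly$y)) / 2
    expect_equal(area, dodecagon_area(r))
  }
  expect_equal(dodecagon_area(10), 300)
  expect_error(build_dodecagon(0, 0, 0), "positive")
})

test_that("rasterized dodecagon area matches 3 r^2 within 5% for r >= 8", {
  for (r in c(8, 10, 16, 25)) {
    mask <- rasterize_polygon(build_dodecagon(50, 50, r), 100, 100)
    expect_lte(abs(sum(mask) - 3 * r^2) / (3 * r^2), 0.05)
  }
  # independent pixel-center point-in-polygon oracle at r = 10
  poly <- build_dodecagon(50, 50, 10)
  mask <- rasterize_polygon(poly, 100, 100)
  centers <- expand.grid(x = (35:65) + 0.5, y = (35:65) + 0.5)
  sides <- cbind(poly, xn = c(poly$x[-1], poly$x[1]),
                 yn = c(poly$y[-1], poly$y[1]))
  inside <- vapply(seq_len(nrow(centers)), function(i) {
    # a convex polygon contains a point iff it is on one side of every edge
    cx <- centers$x[i]; cy <- centers$y[i]
    all((sides$xn - sides$x) * (cy - sides$y) -
          (sides$yn - sides$y) * (cx - sides$x) >= -1e-9)
  }, logical(1))
  expect_equal(sum(mask), sum(inside))
})

test_that("masks are clipped at image borders, never wrapped", {
  # dodecagon centered on the image corner keeps about a quarter of its area
  r <- 16
  mask <- rasterize_polygon(build_dodecagon(0, 0, r), 100, 100)
  expect_lte(abs(sum(mask) - 3 * r^2 / 4) / (3 * r^2 / 4), 0.10)
  expect_true(all(which(mask, arr.ind = TRUE) <= r + 1))

  expect_warning(
    empty <- rasterize_polygon(build_dodecagon(500, 500, 10), 100, 100),
    "outside")
  expect_equal(sum(empty), 0)

  clipped <- clip_polygon(build_dodecagon(0, 50, 10), 100, 100)
  expect_true(all(clipped$x >= 0))
})

test_that("run-length encoding round-trips masks losslessly", {
  withr::with_seed(3, {
    for (i in 1:10) {
      mask <- matrix(runif(30 * 17) < 0.3, nrow = 17)
      rle <- encode_rle(mask)
      expect_identical(decode_rle(rle), mask)
      expect_equal(sum(rle$counts), length(mask))
    }
  })
  all_on <- matrix(TRUE, 4, 4)
  expect_equal(encode_rle(all_on)$counts[1], 0L)  # leading zero-run kept
  expect_identical(decode_rle(encode_rle(all_on)), all_on)
})

test_that("anchor ladders cover the smallest and largest dodecagons", {
  rt1 <- tibble::tibble(genus = "G", organ = "flower", radius_px = 32,
                        n_samples = 5)
  spec1 <- derive_anchor_spec(rt1)
  expect_lte(min(spec1$sizes), 2 * 32 * cos(pi / 12))  # <= 61.8
  expect_gte(max(spec1$sizes), 64)

  rt2 <- tibble::tibble(genus = "G", organ = c("bud", "flower"),
                        radius_px = c(8, 64), n_samples = 5)
  spec2 <- derive_anchor_spec(rt2)
  expect_lte(min(spec2$sizes), 2 * 8 * cos(pi / 12))  # <= 15.45
  expect_gte(max(spec2$sizes), 128)
  expect_true(all(diff(spec2$sizes) > 0))
  expect_equal(spec2$aspect_ratios, c(0.5, 1, 2))
})
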