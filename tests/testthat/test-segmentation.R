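# Segmentation, morphology metrics, filtering and feature extraction.

test_that("gradient map is zero for constant stacks and peaks on edges", {
  st <- image_stack(A = matrix(7, 16, 16), B = matrix(3, 16, 16))
  expect_true(all(gradient_map(st, sigma = 0) == 0))

  step <- matrix(0, 20, 20); step[, 11:20] <- 100
  g <- gradient_map(image_stack(A = step), sigma = 0)
  # maxima exactly along the step columns, same in every row
  expect_true(all(apply(g, 1, which.max) %in% 10:11))
  expect_equal(g[1, ], g[10, ])
})

test_that("gradient map equals finite differences of the channel mean", {
  set.seed(8)
  a <- matrix(runif(64, 0, 100), 8, 8)
  b <- matrix(runif(64, 0, 100), 8, 8)
  g <- gradient_map(image_stack(A = a, B = b), sigma = 0)
  expect_equal(g, fd_gradient((a + b) / 2), tolerance = 1e-12)
})

test_that("segmentation recovers a grid of square cells", {
  img <- grid_membrane(k = 3, cell = 30, lw = 2)
  labs <- segment_fibres(img)
  expect_equal(max(labs), 9)
  # no fibre pixel on the true membrane
  expect_true(all(img[labs > 0] == 0))
  # without smoothing the binary fixture is segmented exactly: each
  # region is a full square interior
  exact <- segment_fibres(img, sigma = 0)
  expect_equal(max(exact), 9)
  for (k in 1:9) {
    idx <- which(exact == k, arr.ind = TRUE)
    expect_equal(nrow(idx), 30 * 30)
    expect_equal(diff(range(idx[, 1])), 29)
    expect_equal(diff(range(idx[, 2])), 29)
  }
})

test_that("segmentation degenerate inputs behave as documented", {
  expect_equal(max(segment_fibres(matrix(1000, 30, 30))), 0)
  expect_equal(max(segment_fibres(matrix(0, 30, 30))), 1)
  expect_error(segment_fibres(matrix(-1, 5, 5)), "non-negative")
})

test_that("disc morphology approaches the ideal circle", {
  m <- region_morphology(digital_disc(40))
  expect_equal(m$area, sum(digital_disc(40)))
  expect_equal(m$circularity, 1, tolerance = 0.05)
  expect_equal(m$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(m$convexity, 1, tolerance = 0.03)
  # convergence: larger disc is closer to circularity 1
  m2 <- region_morphology(digital_disc(15))
  expect_lte(abs(m$circularity - 1), abs(m2$circularity - 1) + 1e-6)
})

test_that("rectangle aspect ratio matches the second-moment oracle", {
  m <- region_morphology(digital_rect(10, 40))
  # exact discrete moments: var of 1..n is (n^2 - 1) / 12, plus 1/12 pixel
  # extent, so the ellipse axis ratio is sqrt(40^2 / 10^2) = 4 exactly
  expect_equal(m$aspect_ratio, 4, tolerance = 1e-9)
  expect_equal(m$convexity, 1, tolerance = 1e-9)
})

test_that("cross convexity equals area over convex-hull area", {
  a <- 12
  m <- region_morphology(digital_cross(a))
  # hull of the plus sign: 3a x 3a box minus four corner triangles of
  # area a^2/2 => 7a^2 (shoelace on the 12 corner points gives the same);
  # region area 5a^2, so convexity = 5/7
  expect_equal(m$area, 5 * a^2)
  expect_equal(m$convexity, 5 / 7, tolerance = 1e-9)
  expect_lt(m$convexity, 0.75)  # a cross is filtered out by default bounds
})

test_that("region_morphology rejects an empty mask", {
  expect_error(region_morphology(matrix(FALSE, 4, 4)), "empty")
})

test_that("filter_regions removes out-of-bound regions with reasons", {
  labs <- matrix(0L, 120, 240)
  labs[2:21, 2:21] <- 1L                        # area 400 < areamin
  d <- digital_disc(26, pad = 0)                # area ~2124, compact
  labs[40:(39 + nrow(d)), 40:(39 + ncol(d))][d] <- 2L
  cr <- digital_cross(12, pad = 0)              # convexity 5/7 < 0.75
  labs[40:(39 + nrow(cr)), 160:(159 + ncol(cr))][cr] <- 3L
  out <- filter_regions(labs, morphology_filter())
  removed <- attr(out, "removed")
  expect_equal(removed$region, c(1L, 3L))
  expect_match(removed$reason[1], "area")
  expect_match(removed$reason[2], "convexity")
  # survivor recompacted to label 1
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
  expect_equal(sum(out == 1L), sum(d))
})

test_that("filter_regions is idempotent and never grows the region count", {
  mos <- small_mosaic(seed = 2)
  labs <- segment_fibres(mos$stack$Dystrophin)
  f1 <- filter_regions(labs)
  f2 <- filter_regions(f1)
  expect_lte(max(f1), max(labs))
  expect_equal(unclass(f2)[, ], unclass(f1)[, ])
  expect_equal(nrow(attr(f2, "removed")), 0)
})

test_that("extract_features reports exact means and centroids", {
  labs <- matrix(0L, 10, 10)
  labs[2:4, 2:4] <- 1L
  labs[6:9, 6:8] <- 2L
  a <- matrix(0, 10, 10); a[labs == 1L] <- 7; a[labs == 2L] <- 20
  b <- matrix(5, 10, 10)
  ft <- extract_features(labs, image_stack(A = a, B = b))
  expect_equal(ft$A, c(7, 20))
  expect_equal(ft$B, c(5, 5))
  expect_equal(ft$x, c(3, 7))
  expect_equal(ft$y, c(3, 7.5))
  expect_error(extract_features(labs, image_stack(A = matrix(0, 4, 4))),
               "dimensions")
})

test_that("extract_features is invariant to label renumbering", {
  mos <- small_mosaic(seed = 5)
  labs <- mos$labels
  K <- max(labs)
  perm <- withr::with_seed(99, sample(K))
  relab <- labs
  relab[labs > 0] <- perm[labs[labs > 0]]
  a <- extract_features(labs, mos$stack)
  b <- extract_features(relab, mos$stack)
  b_reordered <- b[perm, ]  # new label perm[i] holds old region i
  expect_equal(b_reordered$VDAC1, a$VDAC1, ignore_attr = TRUE)
  expect_equal(b_reordered$area, a$area, ignore_attr = TRUE)
})

test_that("noiseless mosaic means are recovered exactly through truth labels", {
  mos <- small_mosaic(seed = 6, deficient_fraction = 0.3,
                      deficiency_factor = 0.2)
  ft <- extract_features(mos$labels, mos$stack)
  for (ch in c("VDAC1", "NDUFB8", "MTCO1", "SDHA")) {
    expect_equal(ft[[ch]], mos$truth[[ch]], tolerance = 1e-12)
  }
})

test_that("most ground-truth fibres are recovered one-to-one", {
  recovered <- total <- 0
  for (seed in 1:2) {
    mos <- generate_mosaic(mosaic_spec(field_size = 600, n_fibres = 50,
                                       rng_seed = seed))
    feats <- extract_features(filter_regions(segment_fibres(mos$stack$Dystrophin)),
                              mos$stack)
    ok <- match_truth(feats, mos$truth)
    recovered <- recovered + sum(ok); total <- total + length(ok)
  }
  expect_gte(recovered / total, 0.95)
})

test_that("image stacks round-trip through 16-bit TIFF files", {
  mos <- small_mosaic(seed = 4, field = 250, n = 12)
  dir <- withr::local_tempdir()
  paths <- write_image_stack(mos$stack, dir, "s1")
  back <- read_image_stack(paths)
  expect_equal(back[], mos$stack[], tolerance = 1e-12)
  # name parsing from file names
  unnamed <- read_image_stack(unname(paths))
  expect_setequal(names(unnamed), names(mos$stack))
})
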