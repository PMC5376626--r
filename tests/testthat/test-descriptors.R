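# Descriptor extraction: binarization/clean-up, skeleton and geometry
# metrics on known shapes, and composition on rendered systems.

test_that("clean renders pass through preprocessing unchanged", {
  img <- render(straight_system(40, 0.8), dpi = 150)
  mask <- preprocess(img)
  expect_identical(dim(mask), dim(img$pixels))
  expect_identical(as.vector(mask), as.vector(img$pixels < 128))
  expect_false(attr(mask, "empty"))
})

test_that("despeckle removes salt but keeps the root", {
  img <- render(straight_system(40, 0.8), dpi = 150)
  clean_area <- sum(preprocess(img))
  noisy <- apply_salt_pepper(img, "medium", 3)
  mask <- preprocess(noisy)
  expect_lt(abs(sum(mask) - clean_area) / clean_area, 0.05)
})

test_that("pure-noise images come back flagged empty", {
  noisy <- apply_salt_pepper(blank_image(80, 80), "medium", 9)
  mask <- preprocess(noisy)
  expect_true(attr(mask, "empty"))
  rec <- extract_descriptors(noisy)
  expect_true(all(is.na(rec)))
})

test_that("skeleton length and tips are exact on a thin line", {
  px <- matrix(255L, 40, 140)
  px[20, 11:128] <- 0L  # horizontal line, 118 px
  sc <- 300 / 25.4
  m <- preprocess(image_from_matrix(px, sc), despeckle_px = 4)
  sk <- skeleton_metrics(m, sc)
  expect_equal(sk$tip_count, 2)
  expect_gt(sk$length, 9.9)
  expect_lt(sk$length, 10.1)
})

test_that("a Y-shaped skeleton has three tips", {
  px <- matrix(255L, 60, 60)
  px[10:30, 30] <- 0L                      # stem
  for (k in 0:14) {
    px[30 + k, 30 - k] <- 0L               # left branch
    px[30 + k, 30 + k] <- 0L               # right branch
  }
  m <- preprocess(image_from_matrix(px))
  sk <- skeleton_metrics(m, 300 / 25.4)
  expect_equal(sk$tip_count, 3)
})

test_that("mean diameter from area/skeleton-length on a rectangle", {
  px <- matrix(255L, 30, 220)
  px[12:17, 11:210] <- 0L  # 200 x 6 px bar
  sc <- 300 / 25.4
  m <- preprocess(image_from_matrix(px, sc))
  sk <- skeleton_metrics(m, sc)
  expect_lt(abs(sk$diam_mean - 6 / sc) / (6 / sc), 0.15)
})

test_that("geometry metrics are exact on a filled rectangle", {
  fh <- 20; fw <- 12
  sc <- 150 / 25.4
  img <- rect_image(60, 40, 10, 10, fh, fw, sc)
  m <- preprocess(img)
  ge <- geometry_metrics(m, sc)
  expect_equal(ge$width, fw / sc)
  expect_equal(ge$depth, fh / sc)
  expect_equal(ge$width_depth_ratio, fw / fh)
  expect_equal(ge$com_x, 0.5)
  expect_equal(ge$com_y, 0.5)
  expect_equal(ge$area, fw * fh / sc^2)
  # a rectangle is its own convex hull
  expect_equal(ge$convexhull, ge$area)
  expect_equal(ge$exploration, 1)
})

test_that("non-convex shapes have exploration > 1", {
  px <- matrix(255L, 60, 60)
  px[10:50, 10:15] <- 0L
  px[45:50, 10:50] <- 0L  # L shape
  m <- preprocess(image_from_matrix(px))
  ge <- geometry_metrics(m, 150 / 25.4)
  expect_gt(ge$exploration, 1)
})

test_that("two corner dots: centered mass, hull matches brute force", {
  px <- matrix(255L, 50, 50)
  px[10, 10] <- 0L
  px[40, 40] <- 0L
  sc <- 150 / 25.4
  m <- preprocess(image_from_matrix(px, sc), despeckle_px = 1)
  ge <- geometry_metrics(m, sc)
  expect_equal(ge$com_x, 0.5)
  expect_equal(ge$com_y, 0.5)
  # brute-force oracle: hull over the corner points of every foreground
  # pixel, shoelace area
  idx <- which(unclass(m), arr.ind = TRUE)
  xs <- c(idx[, 2], idx[, 2], idx[, 2] - 1, idx[, 2] - 1)
  ys <- c(idx[, 1], idx[, 1] - 1, idx[, 1], idx[, 1] - 1)
  h <- grDevices::chull(xs, ys)
  x <- xs[h]; y <- ys[h]
  oracle <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2 / sc^2
  expect_equal(ge$convexhull, oracle)
})

test_that("skeleton length bounds the tip-to-base distance of one root", {
  s <- simulate(plain_axis_params(duration = 12, noise = 15, seed = 3))
  img <- render(s, dpi = 150)
  sk <- skeleton_metrics(preprocess(img), img$scale_px_per_mm)
  nd <- s$roots[[1]]$nodes
  chord <- sqrt((nd[nrow(nd), "x"] - nd[1, "x"])^2 +
                (nd[nrow(nd), "y"] - nd[1, "y"])^2)
  expect_gte(sk$length, chord)
})

test_that("descriptor records compose the three metric groups", {
  img <- rect_image()
  rec <- extract_descriptors(img)
  m <- preprocess(img)
  ge <- geometry_metrics(m, img$scale_px_per_mm)
  for (v in c("area", "width", "depth", "convexhull", "exploration"))
    expect_equal(rec[[v]], ge[[v]])
  expect_identical(rec, extract_descriptors(img))
})

test_that("depth from clean renders is within 2% of ground truth", {
  lib <- generate_library(15, 0.5, 52)
  gt <- ground_truth_table(lib)
  ds <- descriptor_table(lib, dpi = 150)
  err <- abs(ds$depth - gt$depth) / gt$depth
  expect_lt(max(err), 0.05)
  expect_lt(mean(err), 0.02)
})

test_that("tip counts track lateral counts on clean renders", {
  lib <- generate_library(25, 0.5, 61)
  gt <- ground_truth_table(lib)
  ds <- descriptor_table(lib, dpi = 150)
  keep <- gt$n_2plus_orders > 0
  expect_gt(cor(gt$n_2plus_orders[keep], ds$tip_count[keep]), 0)
})

test_that("length/tip errors do not improve as noise increases", {
  lib <- generate_library(12, 0.5, 71)
  gt <- ground_truth_table(lib)
  errs <- vapply(c("null", "medium", "high"), function(lv) {
    ds <- descriptor_table(lib, dpi = 150, noise_levels = lv)
    mean(abs(ds$length - gt$tot_root_length), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(errs) >= -1e-9))
})
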