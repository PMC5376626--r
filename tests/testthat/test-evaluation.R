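# Evaluation layer: MRE, r-squared matrices, overlap binning, PCA, MANOVA.

test_that("mean relative error matches hand arithmetic", {
  expect_equal(as.numeric(mean_relative_error(c(5, 5), c(5, 5))), 0)
  expect_equal(as.numeric(mean_relative_error(c(10, 20), c(9, 22))), 0.1,
               tolerance = 1e-12)
  expect_equal(as.numeric(mean_relative_error(c(3, 7), 2 * c(3, 7))), 1,
               tolerance = 1e-12)
  r <- mean_relative_error(c(0, 10), c(1, 11))
  expect_equal(as.numeric(r), 0.1)
  expect_identical(attr(r, "n_excluded"), 1L)
  expect_warning(out <- mean_relative_error(c(0, 0), c(1, 1)), "undefined")
  expect_true(is.na(out))
  expect_error(mean_relative_error(1:3, 1:2), "same length")
})

test_that("rmse matches hand arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(rmse(1:5, 1:5), 0)
})

test_that("MRE and r-squared are invariant to row order", {
  set.seed(1)
  truth <- runif(50, 1, 10); est <- truth + rnorm(50)
  o <- sample(50)
  expect_equal(as.numeric(mean_relative_error(truth, est)),
               as.numeric(mean_relative_error(truth[o], est[o])))
  expect_equal(cor(truth, est)^2, cor(truth[o], est[o])^2)
})

# small synthetic paired dataset builder
fake_paired <- function(n = 60, seed = 5) {
  withr::with_seed(seed, {
    gt <- data.frame(id = sprintf("s%03d", 1:n))
    for (v in rootbench_traits()) gt[[v]] <- runif(n, 1, 100)
    gt$plant_type <- rep(c("fibrous", "tap"), length.out = n)
    ds <- data.frame(id = gt$id, noise_level = "null")
    for (v in rootbench_descriptors()) ds[[v]] <- runif(n, 1, 100)
    ds$length <- gt$tot_root_length          # a perfectly informative column
    ov <- data.frame(id = gt$id, overlap_index = seq(0, 1, length.out = n))
    paired_dataset(gt, ds, ov)
  })
}

test_that("r2 matrix: perfect pairs give 1, noise gives ~0, types split", {
  d <- fake_paired()
  m <- r2_matrix(d, "null")
  expect_named(m, c("fibrous", "tap"))
  expect_equal(m$fibrous["length", "tot_root_length"], 1, tolerance = 1e-9)
  expect_equal(m$tap["length", "tot_root_length"], 1, tolerance = 1e-9)
  # independent-noise cells stay near zero on a larger null simulation
  set.seed(2)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(cor(x, y)^2, 0.01)
  # oracle cross-check of random cells against the textbook formula
  g <- d[d$plant_type == "fibrous", ]
  for (k in 1:5) {
    set.seed(k)
    dsc <- sample(rootbench_descriptors(), 1)
    trt <- sample(rootbench_traits(), 1)
    x <- g[[paste0("img_", dsc)]]; y <- g[[paste0("gt_", trt)]]
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    oracle <- sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(m$fibrous[dsc, trt], oracle, tolerance = 1e-9)
  }
})

test_that("single-bin overlap MRE reproduces the global MRE", {
  d <- fake_paired()
  tbl <- mre_by_overlap_bin(d, "tot_root_length", "length", n_bins = 1)
  expect_equal(tbl$mre,
               as.numeric(mean_relative_error(d$gt_tot_root_length,
                                              d$img_length)))
})

test_that("constructed monotone error yields increasing bin MREs", {
  d <- fake_paired()
  d$img_length <- d$gt_tot_root_length * (1 + d$overlap_index)
  tbl <- mre_by_overlap_bin(d, "tot_root_length", "length", n_bins = 5)
  expect_true(all(diff(tbl$mre) > 0))
  expect_false(any(tbl$flagged[tbl$n >= 5]))
})

test_that("sparse bins are flagged, not fabricated", {
  d <- fake_paired(n = 20)
  d$overlap_index <- c(rep(0.01, 19), 0.99)
  tbl <- mre_by_overlap_bin(d, "tot_root_length", "length", n_bins = 5)
  expect_true(all(tbl$n[2:4] == 0))
  expect_true(all(is.na(tbl$mre[2:4])))
  expect_true(all(tbl$flagged[2:5]))
})

test_that("PCA fractions sum to one and duplication boosts PC1", {
  d <- fake_paired()
  gt <- d[, paste0("gt_", rootbench_traits())]
  names(gt) <- rootbench_traits()
  p <- pca_ground_truth(gt)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  gt2 <- gt
  for (v in c("width", "depth", "n_1_orders", "n_2plus_orders"))
    gt2[[v]] <- gt2$tot_root_length * (1 + 1e-8 * seq_len(nrow(gt2)))
  p2 <- pca_ground_truth(gt2)
  expect_gt(p2$variance_fractions[1], p$variance_fractions[1])
})

test_that("MANOVA separates the simulator's fibrous and tap systems", {
  lib <- generate_library(80, 0.5, 99)
  gt <- ground_truth_table(lib)
  # length additivity makes the trait set exactly collinear; the aliased
  # column is dropped with a warning
  expect_warning(p <- manova_type_effect(gt, gt$plant_type), "aliased")
  expect_lt(p, 0.001)
})

test_that("MANOVA p-values are calibrated under the null", {
  # two groups drawn from one distribution: rejection rate ~ alpha
  n_rep <- 60
  rejects <- 0
  for (k in seq_len(n_rep)) {
    withr::with_seed(1000 + k, {
      x <- as.data.frame(matrix(rnorm(160 * 13), 160, 13))
      names(x) <- rootbench_traits()
      p <- manova_type_effect(x, rep(c("a", "b"), each = 80))
      if (p < 0.05) rejects <- rejects + 1
    })
  }
  expect_gte(rejects / n_rep, 0.0)
  expect_lte(rejects / n_rep, 0.15)
})

test_that("degenerate MANOVA input is handled explicitly", {
  x <- as.data.frame(matrix(rnorm(40 * 13), 40, 13))
  names(x) <- rootbench_traits()
  types <- rep(c("a", "b"), each = 20)
  # duplicated trait: aliased column dropped, analysis still valid
  xd <- x; xd$width <- xd$depth
  expect_warning(p <- manova_type_effect(xd, types), "aliased")
  expect_true(p >= 0 && p <= 1)
  # identical groups: zero between-group separation, p = 1
  xx <- rbind(x, x)
  p1 <- manova_type_effect(xx, rep(c("a", "b"), each = 40))
  expect_equal(p1, 1, tolerance = 1e-9)
  expect_error(manova_type_effect(x, rep("a", 40)), "two groups")
})
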