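# Random-forest calibration: splitting, imputation, grid fitting,
# selection and prediction.

fake_learning <- function(n = 200, seed = 3, with_na = FALSE) {
  withr::with_seed(seed, {
    f <- data.frame(a = runif(n), b = runif(n), c = runif(n))
    f$plant_type <- factor(rep(c("fibrous", "tap"), length.out = n),
                           levels = c("fibrous", "tap"))
    r <- data.frame(y1 = 3 * f$a + rnorm(n, 0, 0.05),
                    y2 = rep(7, n))
    if (with_na) r$y1[sample(n, round(0.1 * n))] <- NA
    learning_dataset(f, r)
  })
}

test_that("split is an exhaustive, disjoint, stratified partition", {
  d <- fake_learning(1000)
  sp <- split_train_test(d, split_spec(3 / 4, 11))
  expect_length(sp$train_idx, 750)
  expect_length(sp$test_idx, 250)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:1000)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  # stratified: both types half-half in train
  expect_identical(as.integer(table(sp$train$features$plant_type)),
                   c(375L, 375L))
  sp2 <- split_train_test(d, split_spec(3 / 4, 11))
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_train_test(fake_learning(5)), "at least 8")
})

test_that("imputation is the identity on complete data", {
  d <- fake_learning(50)
  expect_identical(impute_missing(d, rng_seed = 1)$responses, d$responses)
})

test_that("a missing cell in a constant column is imputed to the constant", {
  d <- fake_learning(50)
  d$responses$y2[10] <- NA
  out <- impute_missing(d, rng_seed = 1)
  expect_equal(out$responses$y2[10], 7)
  expect_identical(out$responses$y1, d$responses$y1)
})

test_that("forest refinement beats median-only imputation", {
  withr::with_seed(21, {
    n <- 300
    f <- data.frame(a = runif(n), b = runif(n))
    y_true <- 10 * f$a + 5 * f$b
    r <- data.frame(y = y_true)
    miss <- sample(n, 30)
    r$y[miss] <- NA
    d <- learning_dataset(f, r)
    out <- impute_missing(d, rng_seed = 4)
    rf_err <- rmse(y_true[miss], out$responses$y[miss])
    med_err <- rmse(y_true[miss], rep(median(r$y, na.rm = TRUE), 30))
    expect_lt(rf_err, med_err)
  })
})

test_that("fully-missing columns are rejected by name", {
  d <- fake_learning(50)
  d$responses$y1 <- NA_real_
  expect_error(impute_missing(d), "y1")
})

test_that("m = 1 candidates are single forests on the full training set", {
  d <- fake_learning(120)
  cand <- fit_grid(d, trees_grid = 30, splits_grid = 1, rng_seed = 5)
  c1 <- cand$by_response$y1[[1]]
  expect_length(c1$forests, 1)
  expect_equal(c1$forests[[1]]$ntree, 30)
  # the candidate's averaged prediction is exactly the single forest's
  newx <- d$features[1:10, ]
  expect_equal(rootbench:::.predict_candidate(c1, newx),
               unname(predict(c1$forests[[1]], newx)))
})

test_that("constant responses are predicted perfectly by every candidate", {
  d <- fake_learning(100)
  cand <- fit_grid(d, trees_grid = c(10, 30), splits_grid = c(1, 2),
                   rng_seed = 2, responses = "y2")
  for (cc in cand$by_response$y2)
    expect_equal(rootbench:::.predict_candidate(cc, d$features),
                 rep(7, 100), tolerance = 1e-9)
})

test_that("subset ensembles approach the single-forest error", {
  withr::with_seed(31, {
    n <- 500
    f <- data.frame(x = runif(n, 0, 10))
    r <- data.frame(y = 2 * f$x + rnorm(n, 0, 0.1))
    d <- learning_dataset(f, r)
    sp <- split_train_test(d, split_spec(3 / 4, 1))
    cand <- fit_grid(sp$train, trees_grid = 100, splits_grid = c(1, 2),
                     rng_seed = 6)
    errs <- vapply(cand$by_response$y, function(cc)
      rmse(sp$test$responses$y,
           rootbench:::.predict_candidate(cc, sp$test$features)), 0)
    expect_lt(abs(errs[2] - errs[1]) / errs[1], 0.15)
  })
})

test_that("selection returns the exhaustive RMSE minimizer", {
  d <- fake_learning(200)
  sp <- split_train_test(d, split_spec(3 / 4, 7))
  cand <- fit_grid(sp$train, trees_grid = c(10, 50), splits_grid = c(1, 2),
                   rng_seed = 8)
  model <- select_model(cand, sp$test)
  g <- model$rmse_grid$y1
  # exhaustive check against every candidate's recomputed error
  errs <- vapply(cand$by_response$y1, function(cc)
    rmse(sp$test$responses$y1,
         rootbench:::.predict_candidate(cc, sp$test$features)), 0)
  expect_equal(g$rmse, errs)
  expect_equal(model$models$y1$rmse, min(errs))
  sel <- which(g$trees == model$models$y1$trees & g$m == model$models$y1$m)
  expect_equal(errs[sel], min(errs))
})

test_that("selection rejects empty inputs and missing columns", {
  d <- fake_learning(100)
  sp <- split_train_test(d, split_spec(3 / 4, 7))
  cand <- fit_grid(sp$train, trees_grid = 10, splits_grid = 1, rng_seed = 1)
  bad <- sp$test
  bad$features$a <- NULL
  expect_error(select_model(cand, bad), "a")
  expect_error(fit_grid(sp$train, trees_grid = numeric(), splits_grid = 1),
               "non-empty")
  expect_error(fit_grid(sp$train, trees_grid = 10, splits_grid = 50),
               "nrow/10")
})

test_that("predictions are deterministic and schema-checked", {
  d <- fake_learning(150)
  sp <- split_train_test(d, split_spec(3 / 4, 2))
  model <- select_model(
    fit_grid(sp$train, trees_grid = 20, splits_grid = 1, rng_seed = 3),
    sp$test)
  p1 <- predict_traits(model, sp$test$features)
  p2 <- predict_traits(model, sp$test$features)
  expect_identical(p1, p2)
  expect_named(p1, c("y1", "y2"))
  expect_equal(p1$y2, rep(7, nrow(p1)), tolerance = 1e-9)
  expect_error(predict_traits(model, sp$test$features["a"]), "lack")
})

test_that("end-to-end calibration recovers a noisy linear response", {
  withr::with_seed(9, {
    n <- 240
    f <- data.frame(u = runif(n, 1, 5), v = runif(n, 0, 1))
    r <- data.frame(y = 4 * f$u + 2 * f$v + rnorm(n, 0, 0.2))
    cal <- calibrate_traits(f, r, rng_seed = 12, trees_grid = c(20, 60),
                            splits_grid = c(1, 2))
    pred <- predict_traits(cal$model, cal$split$test$features)
    expect_gt(cor(cal$split$test$responses$y, pred$y)^2, 0.9)
  })
})
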