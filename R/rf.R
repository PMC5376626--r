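# Random-forest trait calibration: median + forest imputation, a
# (trees x splits) candidate grid of subset-trained forests averaged at
# prediction time, and held-out RMSE model selection, one model per trait.
#
# The underlying forests come from the randomForest package. Note on the
# split criterion: for regression responses the forests split on variance
# reduction, the regression analogue of the Gini impurity used for
# classification in the same package.

#' Bundle features and responses into a learning dataset
#'
#' @param features data.frame of predictor columns (the image descriptors,
#'   optionally plus a `plant_type` factor).
#' @param responses data.frame of numeric response columns (the
#'   ground-truth traits), same row count.
#' @return object of class `learning_dataset`.
#' @export
learning_dataset <- function(features, responses) {
  if (nrow(features) != nrow(responses))
    stop("features and responses must have the same number of rows")
  if (!ncol(features) || !ncol(responses))
    stop("features and responses must each have at least one column")
  if (anyDuplicated(names(features)) || anyDuplicated(names(responses)))
    stop("column names must be unique within features and responses")
  if (is.character(features$plant_type))
    features$plant_type <- factor(features$plant_type,
                                  levels = c("fibrous", "tap"))
  structure(list(features = features, responses = responses),
            class = "learning_dataset")
}

#' @export
print.learning_dataset <- function(x, ...) {
  cat("learning_dataset:", nrow(x$features), "rows,",
      ncol(x$features), "features,", ncol(x$responses), "responses\n")
  invisible(x)
}

.ld_subset <- function(data, idx)
  learning_dataset(data$features[idx, , drop = FALSE],
                   data$responses[idx, , drop = FALSE])

#' Train/test split specification
#'
#' @param train_fraction fraction of rows used for training (default 3/4;
#'   the remaining quarter is the test set).
#' @param rng_seed integer seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 3 / 4, rng_seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  structure(list(train_fraction = train_fraction,
                 test_fraction = 1 - train_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "split_spec")
}

#' Split a learning dataset into train and test subsets
#'
#' Disjoint, exhaustive and seeded; when the features contain a
#' `plant_type` column with both types present, the split is stratified by
#' type.
#'
#' @param data a `learning_dataset` with at least 8 rows.
#' @param spec a `split_spec`.
#' @return list with elements `train` and `test` (both `learning_dataset`)
#'   and the row indices `train_idx`, `test_idx`.
#' @export
split_train_test <- function(data, spec = split_spec()) {
  n <- nrow(data$features)
  if (n < 8) stop("need at least 8 rows to split")
  strat <- data$features$plant_type
  withr::with_seed(spec$rng_seed, {
    if (!is.null(strat) && length(unique(strat)) > 1) {
      train_idx <- unlist(lapply(split(seq_len(n), strat), function(g)
        sample(g, round(length(g) * spec$train_fraction))),
        use.names = FALSE)
    } else {
      train_idx <- sample(seq_len(n), round(n * spec$train_fraction))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = .ld_subset(data, train_idx),
       test = .ld_subset(data, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Impute missing values (median, then a small forest)
#'
#' Each missing cell is first replaced by its column median; a 10-tree
#' regression forest fitted on the completed data (features and responses
#' together) then re-predicts the originally-missing cells from all other
#' columns. Observed values are never altered. Both feature and response
#' columns are treated.
#'
#' @param data a `learning_dataset`.
#' @param rng_seed optional seed for the forest refinement.
#' @param ntree trees in the refinement forest (default 10).
#' @return an imputed `learning_dataset`.
#' @export
impute_missing <- function(data, rng_seed = NULL, ntree = 10) {
  nf <- ncol(data$features)
  comb <- cbind(data$features, data$responses)
  orig_names <- names(comb)
  names(comb) <- c(paste0("f_", names(data$features)),
                   paste0("r_", names(data$responses)))
  num_cols <- names(comb)[vapply(comb, is.numeric, TRUE)]
  na_map <- lapply(comb[num_cols], is.na)
  run <- function() {
    filled <- comb
    for (j in num_cols) {
      if (!any(na_map[[j]])) next
      if (all(na_map[[j]]))
        stop("column '", sub("^[fr]_", "", j),
             "' is fully missing and cannot be imputed")
      v <- filled[[j]]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      filled[[j]] <- v
    }
    for (j in num_cols) {
      miss <- na_map[[j]]
      if (!any(miss)) next
      others <- filled[, setdiff(names(filled), j), drop = FALSE]
      fit <- suppressWarnings(randomForest::randomForest(
        x = others[!miss, , drop = FALSE], y = filled[[j]][!miss],
        ntree = ntree))
      filled[[j]][miss] <- stats::predict(fit, others[miss, , drop = FALSE])
    }
    names(filled) <- orig_names
    learning_dataset(filled[, seq_len(nf), drop = FALSE],
                     filled[, -seq_len(nf), drop = FALSE])
  }
  if (is.null(rng_seed)) run() else
    withr::with_seed(as.integer(rng_seed), run())
}

#' Fit the (trees x splits) candidate grid
#'
#' For every response variable and every pair `(t, m)` of the grids, the
#' training rows are partitioned into `m` disjoint subsets and a `t`-tree
#' regression forest is fitted on each; the candidate predicts by
#' averaging the `m` forests.
#'
#' @param train an imputed `learning_dataset` (no missing feature values).
#' @param trees_grid numbers of trees per forest (default 10/50/100/300).
#' @param splits_grid numbers of disjoint training subsets (default
#'   1/2/4); every value must be at most `nrow/10` so each subset keeps a
#'   reasonable size.
#' @param rng_seed integer seed (partitioning and forest growth).
#' @param responses optional subset of response names to model.
#' @return object of class `rf_candidates`.
#' @export
fit_grid <- function(train, trees_grid = c(10, 50, 100, 300),
                     splits_grid = c(1, 2, 4), rng_seed = 1,
                     responses = names(train$responses)) {
  if (!length(trees_grid) || !length(splits_grid))
    stop("grids must be non-empty")
  n <- nrow(train$features)
  if (max(splits_grid) > n / 10)
    stop("splits_grid values must not exceed nrow/10 = ", floor(n / 10))
  trees_grid <- sort(unique(as.integer(trees_grid)))
  splits_grid <- sort(unique(as.integer(splits_grid)))
  feats <- train$features
  out <- list()
  withr::with_seed(as.integer(rng_seed), {
    for (resp in responses) {
      y_all <- train$responses[[resp]]
      keep <- !is.na(y_all)
      cands <- list()
      for (t in trees_grid) for (m in splits_grid) {
        part <- sample(rep(seq_len(m), length.out = sum(keep)))
        rows <- which(keep)
        forests <- lapply(seq_len(m), function(k) {
          rk <- rows[part == k]
          suppressWarnings(
            randomForest::randomForest(x = feats[rk, , drop = FALSE],
                                       y = y_all[rk], ntree = t))
        })
        cands[[length(cands) + 1L]] <-
          list(trees = t, m = m, forests = forests)
      }
      out[[resp]] <- cands
    }
  })
  structure(list(by_response = out, feature_names = names(feats),
                 trees_grid = trees_grid, splits_grid = splits_grid),
            class = "rf_candidates")
}

# averaged prediction of one candidate
.predict_candidate <- function(cand, newdata) {
  preds <- vapply(cand$forests, function(f)
    as.numeric(stats::predict(f, newdata)), numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Select the best candidate per response by held-out RMSE
#'
#' Computes the held-out RMSE of every `(t, m)` candidate on the test set
#' and keeps the minimizer; ties break towards fewer trees, then fewer
#' splits.
#'
#' @param candidates an `rf_candidates` object from [fit_grid()].
#' @param test a `learning_dataset`, disjoint from the training rows.
#' @return object of class `ensemble_model`: per response the selected
#'   forests, the `(trees, m)` pair and the held-out RMSE; the full RMSE
#'   grid is kept in `rmse_grid` for inspection.
#' @export
select_model <- function(candidates, test) {
  if (!length(candidates$by_response)) stop("empty candidate set")
  if (!nrow(test$features)) stop("test set is empty")
  missing_cols <- setdiff(candidates$feature_names, names(test$features))
  if (length(missing_cols))
    stop("test features lack columns: ", paste(missing_cols, collapse = ", "))
  models <- list()
  grids <- list()
  for (resp in names(candidates$by_response)) {
    cands <- candidates$by_response[[resp]]
    truth <- test$responses[[resp]]
    errs <- vapply(cands, function(cand)
      rmse(truth, .predict_candidate(cand, test$features)), 0)
    # candidates are laid out t-major, m-minor and both grids ascending,
    # so the first minimum realizes the smaller-t-then-smaller-m tie-break
    best <- which.min(errs)
    grids[[resp]] <- data.frame(
      trees = vapply(cands, function(cc) cc$trees, 0L),
      m = vapply(cands, function(cc) cc$m, 0L),
      rmse = errs)
    models[[resp]] <- list(forests = cands[[best]]$forests,
                           trees = cands[[best]]$trees,
                           m = cands[[best]]$m,
                           rmse = errs[best])
  }
  structure(list(models = models, feature_names = candidates$feature_names,
                 rmse_grid = grids),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Ensemble calibration model,", length(x$models), "response(s):\n")
  for (resp in names(x$models)) {
    m <- x$models[[resp]]
    cat(sprintf("  %-26s trees = %3d, m = %d, held-out RMSE = %.4g\n",
                resp, m$trees, m$m, m$rmse))
  }
  invisible(x)
}

#' Predict traits from image descriptors
#'
#' Averages, per response, the predictions of the selected subset forests.
#'
#' @param model an `ensemble_model`.
#' @param descriptors data.frame with the training feature columns.
#' @return data.frame, one column per response.
#' @export
predict_traits <- function(model, descriptors) {
  missing_cols <- setdiff(model$feature_names, names(descriptors))
  if (length(missing_cols))
    stop("descriptors lack feature columns: ",
         paste(missing_cols, collapse = ", "))
  descriptors <- descriptors[, model$feature_names, drop = FALSE]
  if (is.character(descriptors$plant_type))
    descriptors$plant_type <- factor(descriptors$plant_type,
                                     levels = c("fibrous", "tap"))
  out <- lapply(model$models, function(m)
    .predict_candidate(m, descriptors))
  as.data.frame(out, optional = TRUE)
}

#' End-to-end calibration convenience wrapper
#'
#' Splits, imputes the training set, fits the candidate grid and selects
#' per-response models by held-out RMSE.
#'
#' @param features,responses see [learning_dataset()].
#' @param rng_seed integer seed driving the split, imputation and forests.
#' @param trees_grid,splits_grid see [fit_grid()].
#' @param train_fraction see [split_spec()].
#' @param response_subset optional subset of response names.
#' @return list with `model` (an `ensemble_model`), `split` (the
#'   train/test split) and `train_imputed`.
#' @export
calibrate_traits <- function(features, responses, rng_seed = 1,
                             trees_grid = c(10, 50, 100, 300),
                             splits_grid = c(1, 2, 4),
                             train_fraction = 3 / 4,
                             response_subset = names(responses)) {
  data <- learning_dataset(features, responses)
  sp <- split_train_test(data, split_spec(train_fraction, rng_seed))
  train <- impute_missing(sp$train, rng_seed = rng_seed + 1L)
  # test features: fill rare missing cells with the training median (no
  # information may flow from test responses)
  for (j in names(sp$test$features)) {
    v <- sp$test$features[[j]]
    if (is.numeric(v) && anyNA(v)) {
      v[is.na(v)] <- stats::median(train$features[[j]])
      sp$test$features[[j]] <- v
    }
  }
  cands <- fit_grid(train, trees_grid, splits_grid,
                    rng_seed = rng_seed + 2L, responses = response_subset)
  model <- select_model(cands, sp$test)
  list(model = model, split = sp, train_imputed = train)
}
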