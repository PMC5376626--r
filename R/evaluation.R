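# Descriptor accuracy against ground truth: MRE, r-squared matrices,
# overlap-index binning, PCA and MANOVA of the trait table.

#' Mean Relative Error
#'
#' `MRE = (1/n) * sum(|truth_i - estimate_i| / truth_i)` over the pairs
#' with non-zero, non-missing truth (zero-truth pairs cannot be scored by
#' a relative error and are excluded; their count is reported in the
#' `n_excluded` attribute).
#'
#' @param truth,estimate numeric vectors of equal length.
#' @return numeric scalar with attributes `n_used` and `n_excluded`;
#'   `NA` (with a warning) when no pair can be retained.
#' @export
mean_relative_error <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    stop("truth and estimate must have the same length")
  keep <- !is.na(truth) & !is.na(estimate) & truth != 0
  n_exc <- length(truth) - sum(keep)
  if (!any(keep)) {
    warning("no pairs with non-zero, non-missing truth; MRE undefined")
    return(structure(NA_real_, n_used = 0L, n_excluded = n_exc))
  }
  structure(mean(abs(truth[keep] - estimate[keep]) / truth[keep]),
            n_used = sum(keep), n_excluded = n_exc)
}

#' Root-mean-square error
#'
#' `RMSE = sqrt(mean((truth - estimate)^2))` over non-missing pairs.
#'
#' @param truth,estimate numeric vectors of equal length.
#' @return numeric scalar.
#' @export
rmse <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    stop("truth and estimate must have the same length")
  keep <- !is.na(truth) & !is.na(estimate)
  sqrt(mean((truth[keep] - estimate[keep])^2))
}

#' Join ground truth, descriptors and overlap index into one table
#'
#' The join is one-to-one on (`id`, `noise_level`); duplicated keys are
#' rejected. Trait columns are prefixed `gt_` and descriptor columns
#' `img_` so that the shared names (width, depth) stay distinguishable.
#'
#' @param truth output of [ground_truth_table()].
#' @param descriptors output of [descriptor_table()].
#' @param overlap optional data.frame with columns `id`, `overlap_index`.
#' @return data.frame of class `paired_dataset`.
#' @export
paired_dataset <- function(truth, descriptors, overlap = NULL) {
  if (anyDuplicated(truth$id)) stop("duplicated system ids in truth")
  if (anyDuplicated(descriptors[c("id", "noise_level")]))
    stop("duplicated (id, noise_level) rows in descriptors")
  tr <- truth
  names(tr)[names(tr) %in% rootbench_traits()] <-
    paste0("gt_", names(tr)[names(tr) %in% rootbench_traits()])
  ds <- descriptors
  names(ds)[names(ds) %in% rootbench_descriptors()] <-
    paste0("img_", names(ds)[names(ds) %in% rootbench_descriptors()])
  out <- merge(ds, tr, by = "id", sort = FALSE)
  if (!is.null(overlap)) out <- merge(out, overlap, by = "id", sort = FALSE)
  class(out) <- c("paired_dataset", "data.frame")
  out
}

#' r-squared matrix between descriptors and traits
#'
#' For each (descriptor, trait) pair and each plant type separately, the
#' squared Pearson correlation of a univariate linear regression, with
#' listwise deletion per cell. Cells with fewer than 3 complete pairs or a
#' constant variable are `NA`.
#'
#' @param data a `paired_dataset`.
#' @param noise noise level to keep (`"null"`, `"medium"`, `"high"`).
#' @return named list (one matrix per plant type), each a
#'   descriptor x trait matrix of r-squared values.
#' @export
r2_matrix <- function(data, noise = "null") {
  d <- data[data$noise_level == noise, , drop = FALSE]
  if (!nrow(d)) stop("no rows at noise level ", noise)
  descs <- paste0("img_", rootbench_descriptors())
  traits <- paste0("gt_", rootbench_traits())
  out <- lapply(split(d, d$plant_type), function(g) {
    m <- matrix(NA_real_, length(descs), length(traits),
                dimnames = list(rootbench_descriptors(), rootbench_traits()))
    for (i in seq_along(descs)) for (j in seq_along(traits)) {
      x <- g[[descs[i]]]; y <- g[[traits[j]]]
      keep <- !is.na(x) & !is.na(y)
      if (sum(keep) < 3) next
      if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) next
      m[i, j] <- stats::cor(x[keep], y[keep])^2
    }
    m
  })
  out
}

#' MRE as a function of the overlap index
#'
#' The overlap index is split into `n_bins` equal-width bins over its
#' observed range and the MRE of `descriptor` against `trait` is computed
#' within each bin. Bins with fewer than 5 rows are flagged (their MRE is
#' reported as computed, or `NA` when empty, never fabricated).
#'
#' @param data a `paired_dataset` that includes an `overlap_index` column.
#' @param trait ground-truth trait name (one of [rootbench_traits()]).
#' @param descriptor descriptor name (one of [rootbench_descriptors()]).
#' @param n_bins number of equal-width bins (>= 1).
#' @param noise noise level to keep.
#' @return data.frame with columns `bin`, `lo`, `hi`, `n`, `mre`,
#'   `flagged`.
#' @export
mre_by_overlap_bin <- function(data, trait, descriptor, n_bins = 5,
                               noise = "null") {
  if (n_bins < 1) stop("n_bins must be >= 1")
  d <- data[data$noise_level == noise, , drop = FALSE]
  if (!nrow(d)) stop("empty dataset")
  if (is.null(d$overlap_index)) stop("data has no overlap_index column")
  ov <- d$overlap_index
  lo <- min(ov); hi <- max(ov)
  breaks <- if (hi > lo) seq(lo, hi, length.out = n_bins + 1) else
    c(lo, lo + seq_len(n_bins))
  bin <- findInterval(ov, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  truth <- d[[paste0("gt_", trait)]]
  est <- d[[paste0("img_", descriptor)]]
  res <- lapply(seq_len(n_bins), function(b) {
    k <- bin == b
    mre <- if (any(k))
      suppressWarnings(as.numeric(mean_relative_error(truth[k], est[k])))
    else NA_real_
    data.frame(bin = b, lo = breaks[b], hi = breaks[b + 1],
               n = sum(k), mre = mre, flagged = sum(k) < 5)
  })
  do.call(rbind, res)
}

# median-impute the trait columns of a table (for the multivariate
# analyses only; the learning pipeline has its own imputation)
.impute_median <- function(x) {
  for (j in seq_len(ncol(x))) {
    v <- x[[j]]
    if (anyNA(v)) {
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      x[[j]] <- v
    }
  }
  x
}

#' PCA of the ground-truth trait table
#'
#' Traits are median-imputed, standardized to unit variance (they span
#' several orders of magnitude, mm to counts) and decomposed with
#' `prcomp`. Zero-variance columns are dropped with a warning.
#'
#' @param truths data.frame containing the 13 trait columns (extra columns
#'   are ignored).
#' @return list with `variance_fractions` (descending, summing to 1),
#'   `loadings` and `scores`.
#' @export
pca_ground_truth <- function(truths) {
  x <- truths[, intersect(rootbench_traits(), names(truths)), drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 systems")
  x <- .impute_median(x)
  sds <- vapply(x, stats::sd, 0)
  if (any(sds == 0)) {
    warning("dropping zero-variance trait columns: ",
            paste(names(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  fr <- p$sdev^2 / sum(p$sdev^2)
  list(variance_fractions = fr, loadings = p$rotation, scores = p$x)
}

#' MANOVA of the plant-type effect on the trait table
#'
#' One-way MANOVA (Pillai's trace) of plant type on the standardized,
#' median-imputed traits; returns the approximate-F probability. Both
#' groups must be present, each larger than the number of traits, and the
#' within-group covariance must be non-degenerate.
#'
#' @param truths data.frame containing the 13 trait columns.
#' @param types factor/character of group labels, one per row.
#' @return p-value of the Pillai trace approximate-F test.
#' @export
manova_type_effect <- function(truths, types) {
  types <- factor(types)
  if (nlevels(types) < 2) stop("need at least two groups")
  x <- truths[, intersect(rootbench_traits(), names(truths)), drop = FALSE]
  x <- .impute_median(x)
  sds <- vapply(x, stats::sd, 0)
  x <- x[, sds > 0, drop = FALSE]
  if (min(table(types)) <= ncol(x))
    stop("each group must have more rows than traits")
  xm <- scale(as.matrix(x))
  # drop traits that are collinear within groups (e.g. total and mean
  # first-order length coincide for every single-axis system)
  resid <- xm - apply(xm, 2, function(v) stats::ave(v, types))
  q <- qr(resid)
  if (q$rank < ncol(xm)) {
    keep <- sort(q$pivot[seq_len(q$rank)])
    warning("dropping trait columns aliased within groups: ",
            paste(colnames(xm)[-keep], collapse = ", "))
    xm <- xm[, keep, drop = FALSE]
  }
  fit <- stats::manova(xm ~ types)
  p <- tryCatch(summary(fit, test = "Pillai")$stats[1, "Pr(>F)"],
                error = function(e)
                  stop("degenerate covariance; MANOVA undefined: ",
                       conditionMessage(e)))
  unname(p)
}
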