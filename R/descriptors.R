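# Image descriptor extraction: binarization/clean-up, skeleton metrics and
# whole-shape geometry, mirroring the classical global root image
# descriptor set (projected area, skeleton length, tip count, mean
# diameter, width/depth, center of mass, convex hull, exploration ratio).

#' Names of the image descriptors
#'
#' @return character vector of the 11 descriptor column names.
#' @export
rootbench_descriptors <- function() {
  c("area", "length", "tip_count", "diam_mean", "width", "depth",
    "width_depth_ratio", "com_x", "com_y", "convexhull", "exploration")
}

# sum of the 8 shifted copies of a logical matrix (neighbour counts)
.neighbour_counts <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  cnt <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    cnt <- cnt + p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  cnt
}

#' Binarize and clean a root image
#'
#' Global threshold (dark foreground), removal of connected components
#' smaller than the despeckle area (salt), then a one-sided 3x3 majority
#' pass that flips background pixels surrounded by foreground (pepper
#' holes); foreground pixels are never eroded, so a clean render passes
#' through unchanged.
#'
#' @param image a `raster_image`.
#' @param threshold intensity below which a pixel is foreground.
#' @param despeckle_px minimum connected-component area kept, px.
#' @return logical matrix (TRUE = root); attribute `empty` is TRUE when no
#'   foreground survives the clean-up.
#' @export
preprocess <- function(image, threshold = rootbench_config()$threshold,
                       despeckle_px = rootbench_config()$despeckle_px) {
  mask <- image$pixels < threshold
  if (any(mask) && despeckle_px > 1)
    mask <- cpp_despeckle(mask, as.integer(despeckle_px))
  if (any(mask)) {
    # fill pepper: background pixel with >= 5 foreground neighbours
    cnt <- .neighbour_counts(mask)
    mask[!mask & cnt >= 5] <- TRUE
  }
  attr(mask, "empty") <- !any(mask)
  mask
}

#' Skeleton-based morphological descriptors
#'
#' The mask is thinned to a one-pixel skeleton (Zhang-Suen). Length is the
#' weighted count of skeleton adjacencies (1 for 4-neighbours, sqrt(2) for
#' diagonal links, diagonals skipped when a 4-connected path covers them),
#' converted to mm. Tips are skeleton pixels with exactly one skeleton
#' neighbour. The mean diameter is the classical area / skeleton-length
#' estimator. (A distance-map based diameter estimator is a possible
#' alternative; see `rootbench_config()$diam_from_distance_map`.)
#'
#' @param mask logical matrix from [preprocess()].
#' @param scale pixels per mm.
#' @return list with `length` (mm), `tip_count`, `diam_mean` (mm).
#' @export
skeleton_metrics <- function(mask, scale) {
  if (isTRUE(attr(mask, "empty")) || !any(mask))
    return(list(length = NA_real_, tip_count = NA_real_,
                diam_mean = NA_real_))
  skel <- cpp_thin(mask)
  H <- nrow(skel); W <- ncol(skel)
  n_h <- sum(skel[, -W] & skel[, -1])
  n_v <- sum(skel[-H, ] & skel[-1, ])
  # diagonal adjacencies, skipped when either 4-connected via is skeleton
  d1 <- skel[-H, -W] & skel[-1, -1] & !(skel[-1, -W] | skel[-H, -1])
  d2 <- skel[-1, -W] & skel[-H, -1] & !(skel[-H, -W] | skel[-1, -1])
  len_px <- n_h + n_v + sqrt(2) * (sum(d1) + sum(d2))
  cnt <- .neighbour_counts(skel)
  tips <- sum(skel & cnt == 1)
  diam <- if (len_px > 0) (sum(mask) / len_px) / scale else NA_real_
  list(length = len_px / scale, tip_count = as.numeric(tips),
       diam_mean = diam)
}

# convex hull area (mm^2) of the foreground, over pixel squares: the hull
# corner candidates are the row/column extreme pixels, each contributing
# its four pixel corners, so a filled rectangle is exactly its own hull.
.hull_area_px2 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  r <- idx[, 1]; c <- idx[, 2]
  cand <- unique(rbind(
    do.call(rbind, lapply(split(seq_along(r), r), function(k) {
      rr <- r[k][1]; rbind(c(rr, min(c[k])), c(rr, max(c[k])))
    })),
    do.call(rbind, lapply(split(seq_along(c), c), function(k) {
      cc <- c[k][1]; rbind(c(min(r[k]), cc), c(max(r[k]), cc))
    }))))
  # pixel (r, c) spans [c-1, c] x [r-1, r] in pixel units
  px <- c(cand[, 2], cand[, 2], cand[, 2] - 1, cand[, 2] - 1)
  py <- c(cand[, 1], cand[, 1] - 1, cand[, 1], cand[, 1] - 1)
  h <- grDevices::chull(px, py)
  if (length(h) < 3) return(0)
  x <- px[h]; y <- py[h]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Whole-shape geometrical descriptors
#'
#' Area is the foreground pixel count; width/depth are the bounding-box
#' extents; the center of mass is the foreground centroid expressed in
#' relative bounding-box coordinates (0.5, 0.5 for a symmetric shape); the
#' convex hull is the area of the smallest convex shape containing the
#' foreground; exploration is the hull-to-projected-area ratio (set
#' `exploration_inverse` in the config for the reciprocal, "solidity"
#' direction used by part of the literature).
#'
#' @param mask logical matrix from [preprocess()].
#' @param scale pixels per mm.
#' @param exploration_inverse report area/hull instead of hull/area.
#' @return list with `area` (mm^2), `width`, `depth` (mm),
#'   `width_depth_ratio`, `com_x`, `com_y`, `convexhull` (mm^2),
#'   `exploration`.
#' @export
geometry_metrics <- function(mask, scale,
                             exploration_inverse =
                               rootbench_config()$exploration_inverse) {
  empty <- list(area = NA_real_, width = NA_real_, depth = NA_real_,
                width_depth_ratio = NA_real_, com_x = NA_real_,
                com_y = NA_real_, convexhull = NA_real_,
                exploration = NA_real_)
  if (isTRUE(attr(mask, "empty")) || !any(mask)) return(empty)
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  area_px <- nrow(idx)
  wpx <- max(c) - min(c) + 1L
  dpx <- max(r) - min(r) + 1L
  com_x <- if (wpx > 1) (mean(c) - min(c) + 0.5) / wpx else 0.5
  com_y <- if (dpx > 1) (mean(r) - min(r) + 0.5) / dpx else 0.5
  hull_px2 <- .hull_area_px2(mask)
  area <- area_px / scale^2
  hull <- hull_px2 / scale^2
  expl <- if (area > 0) hull / area else NA_real_
  if (exploration_inverse && is.finite(expl) && expl > 0) expl <- 1 / expl
  list(area = area, width = wpx / scale, depth = dpx / scale,
       width_depth_ratio = wpx / dpx, com_x = com_x, com_y = com_y,
       convexhull = hull, exploration = expl)
}

#' Extract the full descriptor record of one image
#'
#' Composition of [preprocess()], [skeleton_metrics()] and
#' [geometry_metrics()]. An image whose mask is empty after clean-up
#' yields a record of missing values.
#'
#' @param image a `raster_image` (its `scale_px_per_mm` provides the
#'   mm/pixel conversion).
#' @param config configuration list, see [rootbench_config()].
#' @return one-row `data.frame` with the 11 descriptor columns
#'   (see [rootbench_descriptors()]).
#' @export
extract_descriptors <- function(image, config = rootbench_config()) {
  mask <- preprocess(image, config$threshold, config$despeckle_px)
  sc <- image$scale_px_per_mm
  sk <- skeleton_metrics(mask, sc)
  ge <- geometry_metrics(mask, sc, config$exploration_inverse)
  data.frame(area = ge$area, length = sk$length, tip_count = sk$tip_count,
             diam_mean = sk$diam_mean, width = ge$width, depth = ge$depth,
             width_depth_ratio = ge$width_depth_ratio,
             com_x = ge$com_x, com_y = ge$com_y,
             convexhull = ge$convexhull, exploration = ge$exploration)
}

#' Descriptor table for a library
#'
#' Renders every system (once) and measures it at each requested noise
#' level; noisy variants of the same render share the clean image, with
#' the noise seed derived from the system seed.
#'
#' @param library a `root_library`.
#' @param dpi rendering resolution.
#' @param noise_levels subset of `c("null", "medium", "high")`.
#' @param config configuration list.
#' @param progress print a dot every 100 systems.
#' @return data.frame with columns `id`, `noise_level` and the 11
#'   descriptors.
#' @export
descriptor_table <- function(library, dpi = rootbench_config()$dpi,
                             noise_levels = "null",
                             config = rootbench_config(),
                             progress = FALSE) {
  rows <- vector("list", length(library) * length(noise_levels))
  k <- 0L
  for (i in seq_along(library)) {
    e <- library[[i]]
    img <- render(e$system, dpi = dpi, margin_mm = config$margin_mm)
    for (lv in noise_levels) {
      noisy <- apply_salt_pepper(img, lv, rng_seed = e$seed,
                                 fractions = config$noise_fractions)
      k <- k + 1L
      rows[[k]] <- cbind(data.frame(id = e$id, noise_level = lv,
                                    stringsAsFactors = FALSE),
                         extract_descriptors(noisy, config))
    }
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, rows)
}
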