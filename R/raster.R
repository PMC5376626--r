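# Rendering root systems to images and degrading them with noise.

#' Construct a raster image object
#'
#' @param pixels integer matrix of intensities in `[0, 255]` (rows = y,
#'   columns = x; 0 is black foreground, 255 white background).
#' @param scale_px_per_mm resolution in pixels per mm.
#' @param noise_level one of `"null"`, `"medium"`, `"high"`.
#' @param origin_offset_px length-2 numeric, position of the seed point in
#'   pixel coordinates (x, y).
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, scale_px_per_mm, noise_level = "null",
                         origin_offset_px = c(0, 0)) {
  if (!is.matrix(pixels) || !length(pixels)) stop("pixels must be a non-empty matrix")
  if (scale_px_per_mm <= 0) stop("scale_px_per_mm must be > 0")
  structure(list(pixels = pixels, scale_px_per_mm = scale_px_per_mm,
                 noise_level = noise_level,
                 origin_offset_px = origin_offset_px),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("raster_image %d x %d px, %.3f px/mm, noise = %s, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_px_per_mm,
              x$noise_level, sum(x$pixels < 128)))
  invisible(x)
}

# all edges of a system as a table in mm, with per-edge mean diameter
.system_edges <- function(system) {
  segs <- lapply(seq_along(system$roots), function(i) {
    nd <- system$roots[[i]]$nodes
    if (nrow(nd) < 2) return(NULL)
    m <- nrow(nd)
    cbind(x0 = nd[-m, "x"], y0 = nd[-m, "y"],
          x1 = nd[-1, "x"], y1 = nd[-1, "y"],
          diam = (nd[-m, "diam"] + nd[-1, "diam"]) / 2,
          root = i, edge = seq_len(m - 1) - 1L)
  })
  do.call(rbind, segs)
}

#' Render a root system to a binary image
#'
#' Draws every root as a stroked polyline on a white background: the local
#' stroke width equals the local root diameter converted to pixels (round
#' caps, minimum stroke half-width 0.5 px so thin roots stay visible). The
#' canvas is the system bounding box plus a fixed margin; no anti-aliasing
#' is applied so the output is binary.
#'
#' @param system a `root_system`.
#' @param dpi resolution, dots per inch (300 DPI is 11.811 px/mm).
#' @param margin_mm white margin around the bounding box.
#' @return A `raster_image` with `noise_level = "null"`.
#' @export
render <- function(system, dpi = rootbench_config()$dpi,
                   margin_mm = rootbench_config()$margin_mm) {
  if (dpi <= 0) stop("dpi must be > 0")
  scale <- dpi / 25.4
  edges <- .system_edges(system)
  if (is.null(edges)) {
    warning("degenerate system (no grown root): blank canvas")
    px <- matrix(255L, nrow = max(2, ceiling(2 * margin_mm * scale)),
                 ncol = max(2, ceiling(2 * margin_mm * scale)))
    return(raster_image(px, scale, "null",
                        origin_offset_px = c(margin_mm, margin_mm) * scale))
  }
  xs <- c(edges[, "x0"], edges[, "x1"])
  ys <- c(edges[, "y0"], edges[, "y1"])
  pad <- margin_mm + max(edges[, "diam"]) / 2
  xmin <- min(xs) - pad; xmax <- max(xs) + pad
  ymin <- min(ys) - pad; ymax <- max(ys) + pad
  W <- max(2L, as.integer(ceiling((xmax - xmin) * scale)))
  H <- max(2L, as.integer(ceiling((ymax - ymin) * scale)))
  hw <- pmax(0.5, edges[, "diam"] / 2 * scale)
  mask <- cpp_draw_segments(H, W,
                            (edges[, "x0"] - xmin) * scale,
                            (edges[, "y0"] - ymin) * scale,
                            (edges[, "x1"] - xmin) * scale,
                            (edges[, "y1"] - ymin) * scale,
                            hw)
  px <- matrix(255L, H, W)
  px[mask] <- 0L
  raster_image(px, scale, "null",
               origin_offset_px = c((0 - xmin) * scale, (0 - ymin) * scale))
}

#' Degrade an image with salt-and-pepper noise
#'
#' A fraction of the pixels, chosen uniformly at random, is set to black or
#' white with equal probability. Level `"null"` returns the input
#' unchanged; the fractions for `"medium"` and `"high"` are configuration
#' constants (defaults 5\% and 15\%).
#'
#' @param image a `raster_image`.
#' @param level `"null"`, `"medium"` or `"high"`.
#' @param rng_seed integer seed; the operation is deterministic given the
#'   seed and does not disturb the caller's RNG.
#' @param fractions named fractions for the non-null levels.
#' @return A `raster_image` with the same geometry and updated
#'   `noise_level` tag.
#' @export
apply_salt_pepper <- function(image, level, rng_seed = 1,
                              fractions = rootbench_config()$noise_fractions) {
  if (!level %in% c("null", names(fractions)))
    stop("unknown noise level: ", level)
  if (level == "null") return(image)
  p <- fractions[[level]]
  px <- image$pixels
  n <- length(px)
  withr::with_seed(as.integer(rng_seed), {
    idx <- sample.int(n, round(p * n))
    px[idx] <- sample(c(0L, 255L), length(idx), replace = TRUE)
  })
  out <- image
  out$pixels <- px
  out$noise_level <- level
  out
}

#' Vector overlap index of a root system
#'
#' The fraction of polyline segments whose stroked area (capsule of width
#' equal to the local diameter) intersects the stroke of another,
#' non-adjacent segment: two segments overlap when the minimal distance
#' between them is smaller than the sum of their radii. Adjacent edges of
#' the same root and a lateral's first edge against the parent edges
#' flanking its insertion point are excluded, so an unbranched straight
#' root scores 0.
#'
#' @param system a `root_system` with at least one grown root.
#' @return proportion in `[0, 1]`.
#' @export
overlap_index <- function(system) {
  edges <- .system_edges(system)
  if (is.null(edges)) stop("system has no segments")
  nroots <- length(system$roots)
  parent_of <- vapply(system$roots, function(r)
    if (is.na(r$parent)) -1L else r$parent - 1L, 1L)
  ins_edge <- integer(nroots)
  for (i in seq_len(nroots)) {
    r <- system$roots[[i]]
    if (is.na(r$parent)) { ins_edge[i] <- -1L; next }
    pn <- system$roots[[r$parent]]$nodes
    at <- .polyline_at(pn[, "x"], pn[, "y"], r$insertion_position_mm)
    ins_edge[i] <- at$edge - 1L
  }
  hit <- cpp_segment_overlap(edges[, "x0"], edges[, "y0"],
                             edges[, "x1"], edges[, "y1"],
                             edges[, "diam"] / 2,
                             as.integer(edges[, "root"]) - 1L,
                             as.integer(edges[, "edge"]),
                             parent_of, ins_edge)
  mean(hit)
}

#' Write a raster image (and its scale sidecar) to disk
#'
#' Images are written as PNG by default (lossless, so descriptor runs are
#' deterministic); JPEG would match a camera workflow more closely but is
#' not bit-stable. A JSON sidecar stores the px/mm scale.
#'
#' @param image a `raster_image`.
#' @param path output path (`.png`).
#' @param sidecar write `<path>.json` holding scale and noise level.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, sidecar = TRUE) {
  png::writePNG(image$pixels / 255, path)
  if (sidecar) {
    jsonlite::write_json(
      list(scale_px_per_mm = image$scale_px_per_mm,
           noise_level = image$noise_level,
           origin_offset_px = image$origin_offset_px),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a raster image written by [write_image()]
#'
#' @param path path to the PNG file; the `<path>.json` sidecar provides the
#'   scale and noise level.
#' @return A `raster_image`.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar with image scale: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  raster_image(px, meta$scale_px_per_mm, meta$noise_level,
               meta$origin_offset_px)
}
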