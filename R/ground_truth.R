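# Ground-truth trait extraction from the vector representation.

#' Names of the ground-truth traits
#'
#' The 13 morphological and geometrical traits measured exactly on the
#' simulated root system: cumulative and mean lengths by root order, root
#' counts, lateral density, mean diameters, mean lateral insertion angle,
#' and the width/depth of the node cloud.
#'
#' @return character vector of 13 column names.
#' @export
rootbench_traits <- function() {
  c("tot_root_length", "tot_1_order_length", "tot_2plus_order_length",
    "mean_1_order_length", "mean_2plus_order_length",
    "n_1_orders", "n_2plus_orders", "mean_2plus_order_density",
    "mean_1_order_diam", "mean_2plus_order_diam", "mean_2plus_order_angle",
    "width", "depth")
}

# length-weighted mean node diameter of one root
.root_diam <- function(nodes) {
  if (nrow(nodes) < 2) return(mean(nodes[, "diam"]))
  seg <- sqrt(diff(nodes[, "x"])^2 + diff(nodes[, "y"])^2)
  dmid <- (nodes[-1, "diam"] + nodes[-nrow(nodes), "diam"]) / 2
  if (sum(seg) == 0) return(mean(nodes[, "diam"]))
  sum(dmid * seg) / sum(seg)
}

#' Compute the ground-truth traits of a root system
#'
#' Lengths are polyline arc lengths; per-root diameters are length-weighted
#' means of the node diameters; the lateral density is, for each
#' first-order root, its lateral count divided by its own length, averaged
#' over the axes; the insertion angle is the unsigned angle between a
#' lateral's initial direction and the parent's local tangent at the
#' insertion abscissa; width is the x-extent and depth the maximal y of
#' the node cloud (the seed sits at y = 0, y grows downward). Means over
#' empty sets (e.g. lateral traits of an unbranched system) are reported
#' as `NA`.
#'
#' @param system a `root_system`.
#' @return A one-row `data.frame` with the 13 trait columns (see
#'   [rootbench_traits()]) plus `plant_type`.
#' @export
compute_ground_truth <- function(system) {
  roots <- system$roots
  if (!length(roots)) stop("root system has no roots")
  ords <- vapply(roots, function(r) r$order, 1L)
  lens <- vapply(roots, function(r) .root_length(r$nodes), 0)
  diams <- vapply(roots, function(r) .root_diam(r$nodes), 0)
  ax <- which(ords == 1L)
  lat <- which(ords >= 2L)

  # per-axis lateral density: count of laterals on that axis / axis length
  dens <- NA_real_
  if (length(ax)) {
    parent_ids <- vapply(roots, function(r)
      if (is.na(r$parent)) NA_integer_ else r$parent, 1L)
    per_axis <- vapply(ax, function(i) {
      cnt <- sum(parent_ids == i, na.rm = TRUE)
      if (lens[i] > 0) cnt / lens[i] else NA_real_
    }, 0)
    dens <- if (all(is.na(per_axis))) NA_real_ else mean(per_axis, na.rm = TRUE)
  }

  # unsigned insertion angles of laterals against the parent tangent
  angles <- vapply(lat, function(i) {
    r <- roots[[i]]
    if (nrow(r$nodes) < 2) return(NA_real_)
    par <- roots[[r$parent]]
    at <- .polyline_at(par$nodes[, "x"], par$nodes[, "y"],
                       r$insertion_position_mm)
    v1 <- c(sin(at$angle), cos(at$angle))
    dx <- r$nodes[2, "x"] - r$nodes[1, "x"]
    dy <- r$nodes[2, "y"] - r$nodes[1, "y"]
    nv <- sqrt(dx^2 + dy^2)
    if (nv == 0) return(NA_real_)
    acos(min(max((v1[1] * dx + v1[2] * dy) / nv, -1), 1)) * 180 / pi
  }, 0)

  xs <- unlist(lapply(roots, function(r) r$nodes[, "x"]))
  ys <- unlist(lapply(roots, function(r) r$nodes[, "y"]))

  mean_or_na <- function(v) if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  out <- data.frame(
    tot_root_length = sum(lens),
    tot_1_order_length = sum(lens[ax]),
    tot_2plus_order_length = sum(lens[lat]),
    mean_1_order_length = mean_or_na(lens[ax]),
    mean_2plus_order_length = if (length(lat)) mean(lens[lat]) else NA_real_,
    n_1_orders = length(ax),
    n_2plus_orders = length(lat),
    mean_2plus_order_density = dens,
    mean_1_order_diam = mean_or_na(diams[ax]),
    mean_2plus_order_diam = if (length(lat)) mean(diams[lat]) else NA_real_,
    mean_2plus_order_angle = if (length(lat) && any(!is.na(angles)))
      mean(angles, na.rm = TRUE) else NA_real_,
    width = max(xs) - min(xs),
    depth = max(ys),
    plant_type = system$plant_type,
    stringsAsFactors = FALSE)
  out
}

#' Ground-truth table for a library
#'
#' One row per system, in library order, with an `id` column first.
#'
#' @param library a `root_library` from [generate_library()].
#' @return data.frame with columns `id`, the 13 traits and `plant_type`.
#' @export
ground_truth_table <- function(library) {
  rows <- lapply(library, function(e)
    cbind(data.frame(id = e$id, stringsAsFactors = FALSE),
          compute_ground_truth(e$system)))
  do.call(rbind, rows)
}
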