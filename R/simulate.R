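# Root growth engine.
#
# Growth rules (apical elongation proportional to apical diameter,
# acropetal lateral emission at fixed spacing, daughter diameter as a
# perturbed fraction of the mother apical diameter, arrest below a minimal
# diameter, heading blended each step with the downward vertical plus
# Gaussian noise, pipe-model-like radial growth) follow the classical
# minimal-parameter architectural root models. Headings are angles from
# the +y (downward) axis; the seed sits at the origin and all coordinates
# are in millimetres.

# position, tangent angle and edge index at curvilinear abscissa s on a
# polyline (base -> tip)
.polyline_at <- function(x, y, s) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- min(max(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(seg))
  f <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
  list(x = x[i] + f * (x[i + 1] - x[i]),
       y = y[i] + f * (y[i + 1] - y[i]),
       angle = atan2(x[i + 1] - x[i], y[i + 1] - y[i]),
       edge = i)
}

#' Simulate the growth of one root system
#'
#' Deterministically (given `p$rng_seed`) grows a 2D root system: each
#' living tip elongates by `elong_coeff * apical_diameter` per day along a
#' heading blended with the downward vertical (gravitropism) and perturbed
#' by Gaussian noise; laterals are emitted acropetally every
#' `interbranch_mm` along every root, with apical diameter
#' `diam_ratio * mother_apical` perturbed by a relative s.d. `diam_cv`;
#' tips whose diameter falls below `d_min_mm` never elongate (daughters
#' below the threshold are not emitted). For tap systems every node
#' thickens each step by `sec_growth_coeff` times the number of root
#' apices downstream of it (pipe-model-like radial growth).
#'
#' @param p a `simulation_params` object (see [simulation_params()]).
#' @return An object of class `root_system`: a list with elements `roots`
#'   (each root a list with an `nodes` matrix of x/y/diam rows base to tip,
#'   `order`, `parent` index and `insertion_position_mm`), `plant_type` and
#'   `params`.
#' @export
simulate <- function(p) {
  validate_params(p)
  if (p$duration_days < 0) stop("duration_days must be >= 0")
  withr::with_seed(p$rng_seed, .simulate_impl(p))
}

.simulate_impl <- function(p) {
  dt <- p$time_step_days
  n_steps <- if (p$duration_days <= 0) 0L else
    as.integer(floor(p$duration_days / dt + 1e-9))

  rx <- list(); ry <- list(); rd <- list()
  ord <- integer(); parent <- integer(); inspos <- numeric()
  heading <- numeric(); apical <- numeric()
  rlen <- numeric(); next_ba <- numeric()
  n <- 0L

  add_root <- function(x, y, d, order, par, pos, hd) {
    n <<- n + 1L
    rx[[n]] <<- x; ry[[n]] <<- y; rd[[n]] <<- d
    ord[n] <<- order; parent[n] <<- par; inspos[n] <<- pos
    heading[n] <<- hd; apical[n] <<- d[1]
    rlen[n] <<- 0; next_ba[n] <<- p$interbranch_mm
  }

  # first-order axes fan out around the vertical
  axis_angles <- if (p$n_axes == 1) 0 else
    stats::runif(p$n_axes, -60, 60) * pi / 180
  for (k in seq_len(p$n_axes))
    add_root(0, 0, p$d_axis_mm, 1L, NA_integer_, NA_real_, axis_angles[k])

  for (step in seq_len(n_steps)) {
    n_now <- n
    for (i in seq_len(n_now)) {
      if (apical[i] < p$d_min_mm) next
      el <- p$elong_coeff * apical[i] * dt
      if (el <= 0) next
      th <- heading[i]
      v <- c((1 - p$tropism_strength) * sin(th),
             (1 - p$tropism_strength) * cos(th) + p$tropism_strength)
      th <- atan2(v[1], v[2]) +
        stats::rnorm(1, 0, p$direction_noise_sd_deg * pi / 180)
      # tips never elongate upward: clamp to 85 deg off the vertical
      th <- min(max(th, -85 * pi / 180), 85 * pi / 180)
      heading[i] <- th
      k <- length(rx[[i]])
      rx[[i]] <- c(rx[[i]], rx[[i]][k] + el * sin(th))
      ry[[i]] <- c(ry[[i]], ry[[i]][k] + el * cos(th))
      rd[[i]] <- c(rd[[i]], apical[i])
      rlen[i] <- rlen[i] + el
      # acropetal lateral emission at fixed spacing
      while (is.finite(next_ba[i]) && rlen[i] >= next_ba[i] - 1e-9) {
        ba <- next_ba[i]
        next_ba[i] <- next_ba[i] + p$interbranch_mm
        dchild <- p$diam_ratio * apical[i] *
          (1 + stats::rnorm(1, 0, p$diam_cv))
        ang <- stats::rnorm(1, p$insertion_angle_mean_deg,
                            p$insertion_angle_sd_deg)
        ang <- min(max(ang, 5), 95) * pi / 180 * sample(c(-1, 1), 1)
        if (dchild >= p$d_min_mm) {
          at <- .polyline_at(rx[[i]], ry[[i]], ba)
          # plagiotropic emergence: laterals set off sideways or downward,
          # never above the horizontal (gravitropic systems)
          hd0 <- at$angle + ang
          hd0 <- min(max(hd0, -80 * pi / 180), 80 * pi / 180)
          add_root(at$x, at$y, dchild, ord[i] + 1L, i, ba, hd0)
        }
      }
    }
    if (p$sec_growth_coeff > 0 && n > 0) {
      # pipe-model-like radial growth: each node thickens in proportion to
      # the number of apices downstream of it
      ap <- rep(1, n)
      for (i in rev(seq_len(n)))
        if (!is.na(parent[i])) ap[parent[i]] <- ap[parent[i]] + ap[i]
      kids <- split(seq_len(n), factor(parent, levels = seq_len(n)))
      for (i in seq_len(n)) {
        ch <- kids[[i]]
        if (length(rx[[i]]) < 2 && !length(ch)) {
          rd[[i]] <- rd[[i]] + p$sec_growth_coeff * dt
          next
        }
        node_ab <- c(0, cumsum(sqrt(diff(rx[[i]])^2 + diff(ry[[i]])^2)))
        down <- rep(1, length(node_ab))
        if (length(ch)) {
          o <- order(inspos[ch])
          pos_s <- inspos[ch][o]
          ap_s <- ap[ch][o]
          pre <- cumsum(ap_s)
          idx <- findInterval(node_ab, pos_s)
          tot <- pre[length(pre)]
          down <- down + tot - ifelse(idx > 0, pre[pmax(idx, 1)], 0)
        }
        rd[[i]] <- rd[[i]] + p$sec_growth_coeff * dt * down
      }
      apical[seq_len(n)] <- vapply(seq_len(n),
                                   function(i) rd[[i]][length(rd[[i]])], 0)
    }
  }

  # laterals that never elongated are unemerged primordia: drop them.
  keep <- vapply(seq_len(n), function(i)
    ord[i] == 1L || length(rx[[i]]) >= 2, TRUE)
  idx_map <- cumsum(keep)
  roots <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_len(n)) {
    if (!keep[i]) next
    j <- j + 1L
    roots[[j]] <- list(
      nodes = cbind(x = rx[[i]], y = ry[[i]], diam = rd[[i]]),
      order = ord[i],
      parent = if (is.na(parent[i])) NA_integer_ else idx_map[parent[i]],
      insertion_position_mm = inspos[i])
  }
  structure(list(roots = roots, plant_type = p$plant_type, params = p),
            class = "root_system")
}

#' @export
print.root_system <- function(x, ...) {
  ords <- vapply(x$roots, function(r) r$order, 1L)
  cat("Simulated", x$plant_type, "root system:",
      sum(ords == 1), "axes,", sum(ords >= 2), "laterals,",
      sprintf("total length %.1f mm\n", total_length(x)))
  invisible(x)
}

#' Total root length of a system
#'
#' Sum of polyline arc lengths over all roots, in mm.
#' @param system a `root_system`.
#' @return numeric scalar, mm.
#' @export
total_length <- function(system) {
  sum(vapply(system$roots, function(r) .root_length(r$nodes), 0))
}

.root_length <- function(nodes) {
  if (nrow(nodes) < 2) return(0)
  sum(sqrt(diff(nodes[, "x"])^2 + diff(nodes[, "y"])^2))
}

#' Validate the structural invariants of a root system
#'
#' Checks that the parent graph is a forest, that the number of first-order
#' roots matches the parameters, and that every lateral's insertion point
#' lies on its parent polyline (within 1e-6 mm).
#'
#' @param system a `root_system`.
#' @return `system`, invisibly; errors on violation.
#' @export
validate_root_system <- function(system) {
  roots <- system$roots
  if (!length(roots)) stop("root system has no roots")
  ords <- vapply(roots, function(r) r$order, 1L)
  if (!is.null(system$params) &&
      sum(ords == 1) != system$params$n_axes)
    stop("number of first-order roots does not match n_axes")
  for (i in seq_along(roots)) {
    r <- roots[[i]]
    if ((r$order == 1) != is.na(r$parent))
      stop("root ", i, ": order/parent inconsistency")
    if (!is.na(r$parent)) {
      par <- roots[[r$parent]]
      if (par$order != r$order - 1L)
        stop("root ", i, ": parent order must be one less")
      at <- .polyline_at(par$nodes[, "x"], par$nodes[, "y"],
                         r$insertion_position_mm)
      d <- sqrt((at$x - r$nodes[1, "x"])^2 + (at$y - r$nodes[1, "y"])^2)
      if (d > 1e-6)
        stop("root ", i, ": insertion point off parent polyline (", d, " mm)")
    }
  }
  # forest check: walking up parents must terminate
  for (i in seq_along(roots)) {
    j <- i; hops <- 0L
    while (!is.na(roots[[j]]$parent)) {
      j <- roots[[j]]$parent
      hops <- hops + 1L
      if (hops > length(roots)) stop("cycle in parent graph")
    }
  }
  invisible(system)
}

#' Generate a reproducible library of root systems
#'
#' Builds `round(n * fibrous_fraction)` fibrous and the remaining tap
#' systems, each from its own parameter draw. Per-system seeds are derived
#' deterministically from `base_seed`, so the same call always reproduces
#' the same library, system by system.
#'
#' @param n number of systems (0 gives an empty library).
#' @param fibrous_fraction proportion of fibrous systems, in `[0, 1]`.
#' @param base_seed integer seed.
#' @param intervals sampling intervals (see [sampling_intervals()]).
#' @param progress print a dot every 100 systems.
#' @return An object of class `root_library`: a list of entries, each with
#'   `id`, `plant_type`, `seed`, `params` and `system`.
#' @export
generate_library <- function(n, fibrous_fraction = 0.5, base_seed = 1,
                             intervals = sampling_intervals(),
                             progress = FALSE) {
  if (length(n) != 1 || is.na(n) || n < 0) stop("n must be >= 0")
  n <- as.integer(n)
  if (fibrous_fraction < 0 || fibrous_fraction > 1)
    stop("fibrous_fraction must lie in [0, 1]")
  n_fib <- as.integer(round(n * fibrous_fraction))
  types <- c(rep("fibrous", n_fib), rep("tap", n - n_fib))
  seeds <- (as.numeric(base_seed) + 1000003 * seq_len(n)) %% 2147483647
  seeds <- as.integer(ifelse(seeds == 0, 1, seeds))
  lib <- vector("list", n)
  for (i in seq_len(n)) {
    prm <- sample_parameters(types[i], seeds[i], intervals)
    lib[[i]] <- list(id = sprintf("sys_%05d", i), plant_type = types[i],
                     seed = seeds[i], params = prm, system = simulate(prm))
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(lib, class = "root_library")
}

#' @export
print.root_library <- function(x, ...) {
  types <- vapply(x, function(e) e$plant_type, "")
  cat("Root system library:", length(x), "systems (",
      sum(types == "fibrous"), "fibrous,", sum(types == "tap"), "tap )\n")
  invisible(x)
}
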