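# Hand-built root systems used as oracles throughout the suite.

make_root <- function(x, y, diam, order = 1L, parent = NA_integer_,
                      insertion = NA_real_) {
  list(nodes = cbind(x = x, y = y, diam = rep_len(diam, length(x))),
       order = as.integer(order), parent = parent,
       insertion_position_mm = insertion)
}

make_system <- function(roots, plant_type = "fibrous", params = NULL) {
  structure(list(roots = roots, plant_type = plant_type, params = params),
            class = "root_system")
}

# single straight vertical root from the seed, length L, constant diameter
straight_system <- function(length_mm = 100, diam = 0.5, n_nodes = 11) {
  y <- seq(0, length_mm, length.out = n_nodes)
  make_system(list(make_root(rep(0, n_nodes), y, diam)))
}

# 100 mm vertical axis with five 10 mm horizontal laterals, all diameter d
axis_with_laterals <- function(d = 0.5, lat_positions = seq(10, 90, by = 20),
                               lat_len = 10) {
  axis <- make_root(c(0, 0), c(0, 100), d)
  lats <- lapply(seq_along(lat_positions), function(k) {
    p <- lat_positions[k]
    side <- if (k %% 2 == 0) 1 else -1
    make_root(c(0, side * lat_len), c(p, p), d, order = 2L,
              parent = 1L, insertion = p)
  })
  make_system(c(list(axis), lats))
}

# parameters for a deterministic unbranched single axis
plain_axis_params <- function(duration = 10, elong = 10, d = 0.3, seed = 1,
                              interbranch = Inf, tropism = 0, noise = 0) {
  simulation_params(
    plant_type = "fibrous", n_axes = 1, duration_days = duration,
    time_step_days = 1, elong_coeff = elong, d_axis_mm = d,
    d_min_mm = 0.05, diam_ratio = 0.5, diam_cv = 0,
    interbranch_mm = interbranch, insertion_angle_mean_deg = 60,
    insertion_angle_sd_deg = 0, tropism_strength = tropism,
    direction_noise_sd_deg = noise, sec_growth_coeff = 0, rng_seed = seed)
}

# a small raster image from a pixel matrix (255 = background)
image_from_matrix <- function(px, scale = 150 / 25.4) {
  raster_image(px, scale_px_per_mm = scale)
}

# blank white canvas
blank_image <- function(h = 60, w = 60, scale = 150 / 25.4) {
  image_from_matrix(matrix(255L, h, w), scale)
}

# rectangle of foreground (black) pixels
rect_image <- function(h = 60, w = 40, top = 10, left = 10, fh = 20, fw = 12,
                       scale = 150 / 25.4) {
  px <- matrix(255L, h, w)
  px[top:(top + fh - 1), left:(left + fw - 1)] <- 0L
  image_from_matrix(px, scale)
}
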