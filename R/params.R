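#' Construct a set of root growth parameters
#'
#' Low-level constructor with full invariant checking. Most users will call
#' [sample_parameters()] instead; this constructor is the entry point for
#' hand-built parameter sets in tests and calibration studies.
#'
#' @param plant_type `"fibrous"` (several first-order axes, no radial
#'   growth) or `"tap"` (a single axis with radial growth).
#' @param n_axes number of first-order roots (1-20 for fibrous, 1 for tap).
#' @param duration_days simulated time, days.
#' @param time_step_days integration step, days (default 1).
#' @param elong_coeff elongation rate per unit apical diameter,
#'   mm day^-1 mm^-1.
#' @param d_axis_mm initial apical diameter of the axes, mm.
#' @param d_min_mm apical diameter below which a tip stops elongating, mm.
#' @param diam_ratio daughter/mother apical diameter ratio, in (0, 1).
#' @param diam_cv relative standard deviation of the daughter diameter.
#' @param interbranch_mm distance between successive lateral insertion
#'   points along a parent, mm. `Inf` disables branching.
#' @param insertion_angle_mean_deg,insertion_angle_sd_deg normal
#'   distribution of the unsigned lateral insertion angle, degrees.
#' @param tropism_strength per-step weight pulling the heading towards the
#'   downward vertical, in `[0, 1]`.
#' @param direction_noise_sd_deg s.d. of the per-step random heading
#'   deviation, degrees.
#' @param sec_growth_coeff radial growth rate, mm day^-1 per downstream
#'   apex; must be 0 for fibrous and > 0 for tap systems.
#' @param rng_seed integer seed making the simulation reproducible.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(plant_type, n_axes, duration_days,
                              time_step_days = 1, elong_coeff, d_axis_mm,
                              d_min_mm, diam_ratio, diam_cv, interbranch_mm,
                              insertion_angle_mean_deg, insertion_angle_sd_deg,
                              tropism_strength, direction_noise_sd_deg,
                              sec_growth_coeff, rng_seed) {
  p <- list(plant_type = plant_type, n_axes = as.integer(n_axes),
            duration_days = duration_days, time_step_days = time_step_days,
            elong_coeff = elong_coeff, d_axis_mm = d_axis_mm,
            d_min_mm = d_min_mm, diam_ratio = diam_ratio, diam_cv = diam_cv,
            interbranch_mm = interbranch_mm,
            insertion_angle_mean_deg = insertion_angle_mean_deg,
            insertion_angle_sd_deg = insertion_angle_sd_deg,
            tropism_strength = tropism_strength,
            direction_noise_sd_deg = direction_noise_sd_deg,
            sec_growth_coeff = sec_growth_coeff,
            rng_seed = as.integer(rng_seed))
  class(p) <- "simulation_params"
  validate_params(p)
  p
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Root growth parameters (", x$plant_type, ")\n", sep = "")
  flds <- setdiff(names(x), "plant_type")
  for (f in flds) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Validate growth parameters
#'
#' Checks the type invariants: fibrous systems have no radial growth and
#' 1-20 axes; tap systems have a single axis and positive radial growth;
#' rates, diameters and distances are non-negative and the daughter
#' diameter ratio lies in (0, 1).
#'
#' @param p a `simulation_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  if (!p$plant_type %in% c("fibrous", "tap"))
    stop("unknown plant_type: ", p$plant_type,
         " (must be \"fibrous\" or \"tap\")")
  if (p$plant_type == "fibrous") {
    if (p$sec_growth_coeff != 0)
      stop("fibrous systems must have sec_growth_coeff = 0")
    if (p$n_axes < 1 || p$n_axes > 20)
      stop("fibrous n_axes must be in [1, 20]")
  } else {
    if (p$n_axes != 1) stop("tap systems must have n_axes = 1")
    if (p$sec_growth_coeff <= 0)
      stop("tap systems must have sec_growth_coeff > 0")
  }
  nonneg <- c("duration_days", "elong_coeff", "d_axis_mm", "d_min_mm",
              "diam_cv", "insertion_angle_sd_deg", "tropism_strength",
              "direction_noise_sd_deg", "interbranch_mm")
  for (f in nonneg)
    if (is.na(p[[f]]) || p[[f]] < 0) stop(f, " must be >= 0")
  if (p$time_step_days <= 0) stop("time_step_days must be > 0")
  if (p$interbranch_mm <= 0) stop("interbranch_mm must be > 0 (Inf disables branching)")
  if (p$diam_ratio <= 0 || p$diam_ratio >= 1)
    stop("diam_ratio must lie in (0, 1)")
  invisible(p)
}

#' Draw a random set of growth parameters
#'
#' Samples every growth-model parameter uniformly from the per-type
#' intervals of the sampling configuration file, emulating a library built
#' from "a random set of parameters" per run. The draw is fully determined
#' by `rng_seed` and does not disturb the caller's RNG state.
#'
#' @param plant_type `"fibrous"` or `"tap"`.
#' @param rng_seed integer seed.
#' @param intervals sampling intervals, as returned by
#'   [sampling_intervals()].
#' @return A `simulation_params` object.
#' @examples
#' p <- sample_parameters("fibrous", rng_seed = 1)
#' p$sec_growth_coeff  # 0: no radial growth in fibrous systems
#' @export
sample_parameters <- function(plant_type, rng_seed,
                              intervals = sampling_intervals()) {
  if (length(plant_type) != 1 || !plant_type %in% c("fibrous", "tap"))
    stop("unknown plant_type: ", paste(plant_type, collapse = ","),
         " (must be \"fibrous\" or \"tap\")")
  iv <- intervals[[plant_type]]
  withr::with_seed(as.integer(rng_seed), {
    u <- function(nm) stats::runif(1, iv[[nm]][1], iv[[nm]][2])
    n_axes <- if (plant_type == "tap") 1L else
      sample(seq.int(iv$n_axes[1], iv$n_axes[2]), 1)
    sec <- if (plant_type == "fibrous") 0 else u("sec_growth_coeff")
    simulation_params(
      plant_type = plant_type, n_axes = n_axes,
      duration_days = u("duration_days"), time_step_days = 1,
      elong_coeff = u("elong_coeff"), d_axis_mm = u("d_axis_mm"),
      d_min_mm = u("d_min_mm"), diam_ratio = u("diam_ratio"),
      diam_cv = u("diam_cv"), interbranch_mm = u("interbranch_mm"),
      insertion_angle_mean_deg = u("insertion_angle_mean_deg"),
      insertion_angle_sd_deg = u("insertion_angle_sd_deg"),
      tropism_strength = u("tropism_strength"),
      direction_noise_sd_deg = u("direction_noise_sd_deg"),
      sec_growth_coeff = sec, rng_seed = as.integer(rng_seed))
  })
}
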