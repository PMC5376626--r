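# End-to-end orchestration: generate -> rasterize -> analyze -> report ->
# calibrate, with explicit seeding and a manifest of hashes so a re-run
# with the same configuration reproduces every CSV byte for byte.

#' Build a pipeline run configuration
#'
#' @param out_dir output directory (required; created if absent).
#' @param n library size.
#' @param fibrous_fraction proportion of fibrous systems.
#' @param dpi rendering resolution.
#' @param noise_levels noise levels to render and analyze.
#' @param seed master seed; all stage seeds derive from it.
#' @param trees_grid,splits_grid forest grids for the calibration stage.
#' @param train enable the calibration stage (slowest part).
#' @param sampling_file path to the sampling-intervals JSON.
#' @param config descriptor/render configuration, see [rootbench_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, n = 100, fibrous_fraction = 0.5,
                       dpi = 300, noise_levels = c("null", "medium", "high"),
                       seed = 1, trees_grid = c(10, 50, 100, 300),
                       splits_grid = c(1, 2, 4), train = FALSE,
                       sampling_file = rootbench_config()$sampling_file,
                       config = rootbench_config()) {
  if (missing(out_dir) || is.null(out_dir) || !nzchar(out_dir))
    stop("out_dir is required")
  if (!file.exists(sampling_file))
    stop("sampling file does not exist: ", sampling_file)
  stopifnot(n >= 0, dpi > 0)
  structure(list(out_dir = out_dir, n = as.integer(n),
                 fibrous_fraction = fibrous_fraction, dpi = dpi,
                 noise_levels = noise_levels, seed = as.integer(seed),
                 trees_grid = trees_grid, splits_grid = splits_grid,
                 train = train, sampling_file = sampling_file,
                 config = config),
            class = "run_config")
}

#' Run the full benchmarking pipeline
#'
#' Generates the library, writes one RSML file per system plus
#' `ground_truth.csv` and `library_index.csv` (ids, seeds, overlap index),
#' renders the images (one PNG per system and noise level, with scale
#' sidecars), extracts `descriptors.csv`, writes the evaluation report
#' (r-squared matrices per type and noise, MRE-by-overlap tables, a JSON
#' summary with PCA fractions and the MANOVA p-value) and optionally
#' trains one calibration model per noise level. A `manifest.json`
#' records the configuration, seeds and md5 hashes of every CSV.
#'
#' @param cfg a `run_config`.
#' @param progress print progress dots.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  for (d in c("", "rsml", "images", "report", "models"))
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)

  # stage 1: generate
  lib <- generate_library(cfg$n, cfg$fibrous_fraction, cfg$seed,
                          intervals = sampling_intervals(cfg$sampling_file),
                          progress = progress)
  truth <- ground_truth_table(lib)
  utils::write.csv(truth, file.path(out, "ground_truth.csv"),
                   row.names = FALSE)
  idx <- data.frame(
    id = vapply(lib, function(e) e$id, ""),
    plant_type = vapply(lib, function(e) e$plant_type, ""),
    seed = vapply(lib, function(e) e$seed, 1L),
    overlap_index = vapply(lib, function(e) overlap_index(e$system), 0))
  utils::write.csv(idx, file.path(out, "library_index.csv"),
                   row.names = FALSE)
  for (e in lib)
    write_rsml(e$system, file.path(out, "rsml", paste0(e$id, ".rsml")))

  # stage 2 + 3: rasterize and analyze
  rows <- list()
  for (e in lib) {
    img <- render(e$system, dpi = cfg$dpi,
                  margin_mm = cfg$config$margin_mm)
    for (lv in cfg$noise_levels) {
      noisy <- apply_salt_pepper(img, lv, rng_seed = e$seed,
                                 fractions = cfg$config$noise_fractions)
      write_image(noisy,
                  file.path(out, "images", paste0(e$id, "_", lv, ".png")))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(id = e$id, noise_level = lv,
                         stringsAsFactors = FALSE),
              extract_descriptors(noisy, cfg$config))
    }
  }
  descs <- do.call(rbind, rows)
  utils::write.csv(descs, file.path(out, "descriptors.csv"),
                   row.names = FALSE)

  # stage 4: report
  paired <- paired_dataset(truth, descs,
                           overlap = idx[, c("id", "overlap_index")])
  for (lv in cfg$noise_levels) {
    r2 <- r2_matrix(paired, noise = lv)
    for (tp in names(r2))
      utils::write.csv(r2[[tp]],
        file.path(out, "report", sprintf("r2_%s_%s.csv", tp, lv)))
    mre_tbl <- mre_by_overlap_bin(paired, "tot_root_length", "length",
                                  n_bins = 5, noise = lv)
    utils::write.csv(mre_tbl,
      file.path(out, "report", sprintf("mre_overlap_length_%s.csv", lv)),
      row.names = FALSE)
  }
  pca <- pca_ground_truth(truth)
  summary <- list(
    n = cfg$n,
    pca_variance_fractions = pca$variance_fractions,
    manova_p = tryCatch(
      suppressWarnings(manova_type_effect(truth, truth$plant_type)),
      error = function(e) NA_real_))
  jsonlite::write_json(summary, file.path(out, "report", "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 5: calibrate (per noise level)
  if (cfg$train) {
    for (lv in cfg$noise_levels) {
      d <- descs[descs$noise_level == lv, ]
      feats <- d[, rootbench_descriptors()]
      feats$plant_type <- truth$plant_type[match(d$id, truth$id)]
      resp <- truth[match(d$id, truth$id), rootbench_traits()]
      cal <- calibrate_traits(feats, resp, rng_seed = cfg$seed,
                              trees_grid = cfg$trees_grid,
                              splits_grid = cfg$splits_grid)
      saveRDS(cal$model,
              file.path(out, "models", sprintf("model_%s.rds", lv)))
    }
  }

  csvs <- list.files(out, pattern = "\\.csv$", recursive = TRUE,
                     full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rootbench")),
    seed = cfg$seed, n = cfg$n, dpi = cfg$dpi,
    noise_levels = cfg$noise_levels,
    hashes = as.list(tools::md5sum(sort(csvs))))
  names(manifest$hashes) <- basename(names(manifest$hashes))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Command-line interface
#'
#' Thin subcommand wrapper over the package functions, installed as
#' `inst/cli/rootbench`. Subcommands: `run` (full pipeline), `generate`,
#' `predict`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly.
#' @export
rootbench_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rootbench <command> [options]",
    "commands:",
    "  run      --out DIR [--n N] [--fibrous-fraction F] [--dpi D]",
    "           [--seed S] [--train]",
    "  generate --out DIR [--n N] [--fibrous-fraction F] [--seed S]",
    "  predict  --model FILE --descriptors CSV --out CSV", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (!length(i)) return(default)
    rest[i[1] + 1]
  }
  has <- function(flag) flag %in% rest
  if (cmd %in% c("run", "generate")) {
    out <- opt("--out")
    if (is.null(out)) stop("--out is required")
    cfg <- run_config(
      out_dir = out,
      n = as.integer(opt("--n", "100")),
      fibrous_fraction = as.numeric(opt("--fibrous-fraction", "0.5")),
      dpi = as.numeric(opt("--dpi", "300")),
      seed = as.integer(opt("--seed", "1")),
      train = has("--train"))
    if (cmd == "generate") {
      lib <- generate_library(cfg$n, cfg$fibrous_fraction, cfg$seed)
      dir.create(file.path(out, "rsml"), showWarnings = FALSE,
                 recursive = TRUE)
      utils::write.csv(ground_truth_table(lib),
                       file.path(out, "ground_truth.csv"),
                       row.names = FALSE)
      for (e in lib)
        write_rsml(e$system, file.path(out, "rsml",
                                       paste0(e$id, ".rsml")))
    } else {
      run_pipeline(cfg, progress = interactive())
    }
  } else if (cmd == "predict") {
    model <- readRDS(opt("--model"))
    descs <- utils::read.csv(opt("--descriptors"),
                             stringsAsFactors = FALSE)
    preds <- predict_traits(model, descs)
    utils::write.csv(preds, opt("--out"), row.names = FALSE)
  } else {
    cat(usage, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
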