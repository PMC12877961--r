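# End-to-end orchestration: denoise -> extract -> repair -> skeletonize ->
# morphometry, with a plain-text (YAML) config that round-trips and is
# embedded in every output bundle.

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the reconstruction pipeline. Two
#' presets mirror the two supported acquisition regimes: `"fmost"`
#' (anisotropic 1 x 1 x 2.5 um spacing, denoising threshold 220) and
#' `"microct"` (0.65 um isotropic, threshold 40). Everything is
#' overridable.
#'
#' @param preset `"fmost"` or `"microct"`.
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @param polarity `"bright"` or `"dark"` foreground.
#' @param threshold denoising intensity threshold.
#' @param min_volume component volume filter in um^3 (default 1000).
#' @param connectivity labeling adjacency (default 26).
#' @param snap_radius soma-seed snap radius in um (default 5).
#' @param lambda,gamma tracing-cost parameters (see [trace_cost_params()]).
#' @param sholl_step Sholl sphere spacing in um (default 10).
#' @param prune_um skeleton spur-pruning threshold in um (default 3).
#' @param resample_um SWC node arc spacing in um (default 2).
#' @param seed RNG seed recorded with the run.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(preset = c("fmost", "microct"),
                            spacing = NULL, polarity = "bright",
                            threshold = NULL, min_volume = 1000,
                            connectivity = 26L, snap_radius = 5,
                            lambda = 10, gamma = 2, sholl_step = 10,
                            prune_um = 3, resample_um = 2, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(spacing))
    spacing <- if (preset == "fmost") c(2.5, 1, 1) else c(0.65, 0.65, 0.65)
  if (is.null(threshold)) threshold <- if (preset == "fmost") 220 else 40
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            threshold >= 0, threshold <= 255,
            min_volume >= 0, connectivity %in% c(6L, 18L, 26L),
            snap_radius >= 0, lambda > 0, gamma >= 1,
            sholl_step > 0, prune_um >= 0, resample_um > 0)
  structure(list(preset = preset, spacing = spacing, polarity = polarity,
                 threshold = threshold, min_volume = min_volume,
                 connectivity = as.integer(connectivity),
                 snap_radius = snap_radius, lambda = lambda, gamma = gamma,
                 sholl_step = sholl_step, prune_um = prune_um,
                 resample_um = resample_um, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write pipeline configuration
#'
#' Plain YAML; `read_config(write_config(cfg, f))` reproduces the
#' configuration exactly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  v <- yaml::read_yaml(path)
  do.call(pipeline_config, v)
}

#' Run the full reconstruction pipeline
#'
#' Executes denoise -> extract -> repair -> skeletonize -> morphometry on a
#' volume plus markers, writing the full output bundle to `out_dir`:
#' raw-stage and revised SWC trees, the denoised / extracted / repaired
#' masks, threshold-stage CSVs, morphometry and Sholl CSVs, a
#' human-readable comparison log, the repair report, the exact
#' configuration used, and a structured run log with per-stage voxel and
#' component counts. Any stage failure is an error naming the stage.
#'
#' @param volume_path TIFF stack or slice directory (see [read_volume()]).
#' @param markers_path marker CSV with exactly one `soma_seed` (see
#'   [read_markers()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the key in-memory results: `raw_tree`,
#'   `revised_tree`, `comparison`, `repair`, `paths` of written files.
#' @export
run_pipeline <- function(volume_path, markers_path, config = pipeline_config(),
                         out_dir = "neurostitch_out") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  set.seed(config$seed)

  vol <- stage("read", {
    v <- read_volume(volume_path, config$spacing, config$polarity)
    if (v$bit_depth == 16L) v <- convert_to_8bit(v) else v
  })
  note("read: volume %s, %d x %d x %d voxels, %d-bit", volume_path,
       dim(vol$grid)[1], dim(vol$grid)[2], dim(vol$grid)[3], vol$bit_depth)
  markers <- stage("markers", read_markers(markers_path, require_soma = TRUE))
  note("markers: %d rows (%d terminals)", nrow(markers),
       sum(markers$kind == "branch_terminal"))

  denoised <- stage("denoise", threshold_volume(vol, config$threshold))
  note("denoise: threshold %g -> %d foreground voxels", config$threshold,
       sum(denoised$grid))
  lab <- stage("extract", label_components(denoised, config$connectivity))
  note("extract: %d components before volume filter", nrow(lab$components))
  filtered <- stage("extract", filter_small_components(lab, config$min_volume))
  lab2 <- stage("extract", label_components(filtered, config$connectivity))
  note("extract: %d components of >= %g um^3", nrow(lab2$components),
       config$min_volume)
  soma <- soma_position(markers)
  neuron <- stage("extract",
                  select_neuron(lab2, soma, snap_radius = config$snap_radius))
  neuron <- stage("edit", apply_edits(neuron, markers))
  note("extract: neuron component %d voxels after edits", sum(neuron$grid))

  params <- trace_cost_params(lambda = config$lambda, gamma = config$gamma)
  raw_tree <- stage("skeletonize", skeletonize_to_swc(
    neuron, vol, soma, params, prune_um = config$prune_um,
    resample_um = config$resample_um,
    intensity_threshold = config$threshold))
  note("raw reconstruction: %d branches, %.1f um",
       length(branch_segments(raw_tree)), total_length(raw_tree))

  rep <- stage("repair", repair_neuron(
    neuron, vol, markers, params,
    intensity_threshold = config$threshold, foreground = denoised,
    connectivity = config$connectivity))
  note("repair: %d/%d terminals repaired, %d already connected",
       sum(rep$report$status == "repaired"), nrow(rep$report),
       sum(rep$report$status == "already_connected"))
  revised_tree <- stage("skeletonize", skeletonize_to_swc(
    rep$mask, vol, soma, params, prune_um = config$prune_um,
    resample_um = config$resample_um,
    intensity_threshold = config$threshold))
  note("revised reconstruction: %d branches, %.1f um",
       length(branch_segments(revised_tree)), total_length(revised_tree))

  cmp <- stage("morphometry", {
    dmax <- max(10, sqrt(max((revised_tree$x - soma[1])^2 +
                             (revised_tree$y - soma[2])^2 +
                             (revised_tree$z - soma[3])^2)))
    radii <- seq(config$sholl_step,
                 max(config$sholl_step,
                     ceiling(dmax / config$sholl_step) * config$sholl_step),
                 by = config$sholl_step)
    compare_morphometry(raw_tree, revised_tree, sholl_radii = radii)
  })

  paths <- list(
    raw_swc = file.path(out_dir, "raw.swc"),
    revised_swc = file.path(out_dir, "revised.swc"),
    denoised_mask = file.path(out_dir, "denoised_mask.tif"),
    neuron_mask = file.path(out_dir, "neuron_mask.tif"),
    repaired_mask = file.path(out_dir, "repaired_mask.tif"),
    repair_report = file.path(out_dir, "repair_report.csv"),
    morphometry = file.path(out_dir, "morphometry.csv"),
    sholl = file.path(out_dir, "sholl.csv"),
    comparison = file.path(out_dir, "comparison.txt"),
    config = file.path(out_dir, "config.yaml"),
    log = file.path(out_dir, "run_log.txt"))
  write_swc(raw_tree, paths$raw_swc)
  write_swc(revised_tree, paths$revised_swc)
  write_mask(denoised, paths$denoised_mask)
  write_mask(neuron, paths$neuron_mask)
  write_mask(rep$mask, paths$repaired_mask)
  write.csv(rep$report, paths$repair_report, row.names = FALSE)
  write.csv(cmp$changes, paths$morphometry, row.names = FALSE)
  sh <- data.frame(radius = cmp$raw$sholl$radius,
                   raw_crossings = cmp$raw$sholl$crossings,
                   revised_crossings = cmp$revised$sholl$crossings)
  write.csv(sh, paths$sholl, row.names = FALSE)
  writeLines(utils::capture.output(print(cmp)), paths$comparison)
  write_config(config, paths$config)
  writeLines(log_lines, paths$log)

  invisible(list(raw_tree = raw_tree, revised_tree = revised_tree,
                 comparison = cmp, repair = rep, neuron_mask = neuron,
                 repaired_mask = rep$mask, paths = paths))
}

#' Write a threshold report as CSV
#'
#' @param report an [evaluate_thresholds()] result.
#' @param path output CSV path.
#' @export
write_threshold_report <- function(report, path) {
  stopifnot(inherits(report, "threshold_report"))
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
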