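# Config-driven pipeline: simulate phantoms/cohorts, fit volumes, apply
# the oxygen model, segment zones, build atlases and run cohort
# statistics, reading and writing NIfTI volumes and CSV tables, with a
# JSON run manifest. The exported `run_*` functions are also the backend
# of the command line interface (inst/cli/cthmap).

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config file: acquisition, AIF, phantom,
#' fit, oxygen, zones and cohort sections. Every section is validated
#' against its module's constructor before any stage runs.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    acquisition = list(tr = 1.5, te = 0.040, n_dynamics = 80,
                       kappa = 1, baseline_frames = 8),
    aif = list(amplitude = 30, arrival_time = 12, shape = 3, scale = 1.5,
               recirculation_fraction = 0, recirculation_delay = 20),
    phantom = list(type = "wm", group = "hemizygote", snr = 20,
                   block = c(4, 3, 2)),
    fit = list(n_multistart = 3, delay_grid = 0,
               upsample = 4),
    oxygen = list(mode = "full_bkcr", rate_k = 4.5e-3, p50 = 26,
                  hill_h = 2.8, tissue_pt = 25, arterial_saturation = 0.95),
    zones = list(ring_width = 2, margin = 6),
    cohort = list(n_subjects_per_group = 10,
                  groups = c("control", "hemizygote"),
                  visits_per_subject = 1, age_range = c(4, 16))
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file, overlays it on [default_config()] (file keys win)
#' and validates each section by building the corresponding parameter
#' objects.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list with parsed parameter objects in
#'   attribute-free form.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  do.call(acquisition_params, cfg$acquisition)
  do.call(aif_model, cfg$aif)
  do.call(oxygen_params, cfg$oxygen)
  fit_args <- cfg$fit
  do.call(fit_options, fit_args)
  if (cfg$zones$ring_width < 0 || cfg$zones$margin < 0)
    stopf("zone ring_width and margin must be non-negative")
  invisible(TRUE)
}

config_objects <- function(cfg) {
  list(acq = do.call(acquisition_params, cfg$acquisition),
       aif = do.call(aif_model, cfg$aif),
       oxy = do.call(oxygen_params, cfg$oxygen),
       fit = do.call(fit_options, cfg$fit))
}

#' Write a 3D or 4D volume as NIfTI
#'
#' @param vol numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix.
#' @export
write_volume <- function(vol, path, affine = diag(4)) {
  img <- RNifti::asNifti(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume not found: %s", path)
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  if (length(d) == 2L) d <- c(d, 1L)   # NIfTI drops trailing singleton dims
  array(as.numeric(arr), dim = d)
}

write_maps_nifti <- function(maps, dir, prefix) {
  paths <- character(0)
  for (nm in MAP_NAMES) {
    if (is.null(maps[[nm]])) next
    p <- file.path(dir, sprintf("%s_%s.nii", prefix, nm))
    write_volume(maps[[nm]], p, maps$affine)
    paths <- c(paths, p)
  }
  paths
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, cfg, seed, stages) {
  manifest <- list(config_hash = config_hash(cfg), seed = seed,
                   tool = sprintf("cthmap %s",
                                  as.character(utils::packageVersion("cthmap"))),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = stages)
  path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  missing <- unlist(lapply(stages, function(s) s$outputs))
  missing <- missing[!file.exists(missing)]
  if (length(missing) > 0)
    stopf("manifest lists missing outputs: %s", paste(missing, collapse = ", "))
  invisible(path)
}

ensure_outdir <- function(out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory %s", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe); file.remove(probe); TRUE },
                 warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok) stopf("output directory %s is not writable", out_dir)
  invisible(out_dir)
}

#' Simulate phantom or cohort inputs to disk
#'
#' Writes the 4D signal series, region/brain masks, ground-truth maps,
#' the AIF curve (CSV) and a JSON manifest. Identical `(config, seed)`
#' produce identical NIfTI payloads.
#'
#' @param cfg configuration list from [read_config()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides `cfg$seed` when non-NULL.
#' @param verbose print stage messages.
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(cfg = default_config(), out_dir, seed = NULL,
                         verbose = TRUE) {
  ensure_outdir(out_dir)
  seed <- as.integer(seed %||% cfg$seed)
  ob <- config_objects(cfg)
  ph_cfg <- cfg$phantom
  stages <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  if (identical(ph_cfg$type, "cohort")) {
    cspec <- cohort_spec(n_subjects_per_group = cfg$cohort$n_subjects_per_group,
                         groups = cfg$cohort$groups,
                         visits_per_subject = cfg$cohort$visits_per_subject,
                         age_range = cfg$cohort$age_range,
                         phantom = ph_cfg$subtype %||% "wm",
                         block = ph_cfg$block %||% c(4, 3, 2),
                         snr = ph_cfg$snr)
    coh <- make_cohort(cspec, ob$acq, ob$aif, seed = seed)
    outs <- character(0)
    for (s in coh$subjects) {
      for (v in seq_along(s$visits)) {
        ph <- s$visits[[v]]
        p <- file.path(out_dir, sprintf("%s_v%d_series.nii", s$id, v))
        write_volume(ph$signal, p)
        outs <- c(outs, p)
      }
    }
    rec_path <- file.path(out_dir, "truth_records.csv")
    utils::write.csv(coh$truth_records, rec_path, row.names = FALSE)
    outs <- c(outs, rec_path)
    say("simulated cohort: %d subjects, %d files", length(coh$subjects),
        length(outs))
    stages[[1]] <- list(stage = "simulate", outputs = outs, status = "ok")
    return(invisible(write_manifest(out_dir, cfg, seed, stages)))
  }

  params <- if (identical(ph_cfg$type, "regional"))
    default_region_params(ph_cfg$group %||% "hemizygote")
  else default_wm_params(ph_cfg$group %||% "hemizygote")
  n_regions <- length(params)
  labels <- block_labels(n_regions, block = ph_cfg$block %||% c(4, 3, 2),
                         ncol = min(4, n_regions))
  spec <- phantom_spec(labels, params,
                       noise_sigma = ph_cfg$noise_sigma %||% 0,
                       snr = ph_cfg$snr, seed = seed)
  ph <- make_region_phantom(spec, ob$acq, ob$aif, oxygen = ob$oxy)
  series_path <- file.path(out_dir, "series.nii")
  write_volume(ph$signal, series_path)
  labels_path <- file.path(out_dir, "labels.nii")
  write_volume(ph$labels, labels_path)
  mask_path <- file.path(out_dir, "brain_mask.nii")
  write_volume(1 * (ph$labels > 0), mask_path)
  truth_paths <- write_maps_nifti(ph$truth, out_dir, "truth")
  aif_path <- file.path(out_dir, "aif.csv")
  utils::write.csv(data.frame(time = ph$time, concentration = ph$aif),
                   aif_path, row.names = FALSE)
  say("simulated phantom %s: %d in-mask voxels",
      paste(dim(ph$labels), collapse = "x"), sum(ph$labels > 0))
  stages[[1]] <- list(stage = "simulate", status = "ok",
                      outputs = c(series_path, labels_path, mask_path,
                                  truth_paths, aif_path))
  invisible(write_manifest(out_dir, cfg, seed, stages))
}

#' Fit perfusion maps for a series on disk
#'
#' Reads a 4D series and mask, converts signal to concentration, obtains
#' the AIF (from CSV or by automatic selection), fits the vascular model
#' voxel-wise, applies the oxygen model, and writes one NIfTI per map
#' plus CSV fit diagnostics.
#'
#' @param series_path 4D NIfTI path.
#' @param mask_path 3D mask NIfTI path.
#' @param cfg configuration list.
#' @param out_dir output directory.
#' @param aif_path optional CSV (`time, concentration`) with the AIF;
#'   when absent the AIF is selected automatically within the mask.
#' @param verbose print stage messages.
#' @return Invisibly a list with the maps and the number of
#'   non-converged voxels; an error is raised if more than half the
#'   in-mask voxels fail to converge.
#' @export
run_fit <- function(series_path, mask_path, cfg = default_config(), out_dir,
                    aif_path = NULL, verbose = TRUE) {
  ensure_outdir(out_dir)
  ob <- config_objects(cfg)
  signal <- read_volume(series_path)
  if (length(dim(signal)) != 4L) stopf("series must be 4D: %s", series_path)
  mask <- as_mask(read_volume(mask_path))
  time_grid <- frame_times(ob$acq)
  conc <- signal_to_concentration(signal, ob$acq)
  aif <- if (!is.null(aif_path)) {
    tab <- utils::read.csv(aif_path)
    stats::approx(tab$time, tab$concentration, xout = time_grid, rule = 2)$y
  } else {
    select_aif(conc, mask)
  }
  fitres <- fit_volume(conc, aif, mask, time_grid, ob$fit)
  maps <- oxygen_maps(fitres$maps, ob$oxy)
  paths <- write_maps_nifti(maps, out_dir, "fitted")
  diag_path <- file.path(out_dir, "fit_diagnostics.csv")
  utils::write.csv(fitres$diagnostics, diag_path, row.names = FALSE)
  n_in <- sum(mask)
  if (verbose)
    message(sprintf("fitted %d voxels, %d not converged", n_in, fitres$n_failed))
  if (n_in > 0 && fitres$n_failed > 0.5 * n_in)
    stopf("more than half of in-mask voxels failed to converge (%d of %d)",
          fitres$n_failed, n_in)
  invisible(list(maps = maps, n_failed = fitres$n_failed,
                 outputs = c(paths, diag_path)))
}

#' Segment lesion zones and write zone statistics
#'
#' @param t2_path,enh_path,wm_path NIfTI mask paths (enhancement may be
#'   NULL).
#' @param map_paths named character vector of parameter-map NIfTI paths
#'   for which per-zone statistics are reported.
#' @param cfg configuration list.
#' @param out_dir output directory.
#' @return Invisibly the zone label path and the statistics table.
#' @export
run_zones <- function(t2_path, enh_path = NULL, wm_path, map_paths = character(0),
                      cfg = default_config(), out_dir) {
  ensure_outdir(out_dir)
  t2 <- read_volume(t2_path)
  wm <- read_volume(wm_path)
  enh <- if (!is.null(enh_path)) read_volume(enh_path)
  zones <- segment_lesion_zones(t2, enh, wm,
                                ring_width = cfg$zones$ring_width,
                                margin = cfg$zones$margin)
  lab_path <- file.path(out_dir, "zone_labels.nii")
  write_volume(zone_labels(zones), lab_path)
  rows <- list()
  for (mi in seq_along(map_paths)) {
    map <- read_volume(map_paths[[mi]])
    mname <- names(map_paths)[mi] %||% basename(map_paths[[mi]])
    for (z in names(zones)) {
      if (!any(zones[[z]])) next
      st <- roi_mean(map, zones[[z]], label = z)
      rows[[length(rows) + 1L]] <- data.frame(map = mname, zone = z,
                                              n_voxels = st$n_voxels,
                                              mean = st$mean, sd = st$sd)
    }
  }
  stats_tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  stats_path <- file.path(out_dir, "zone_stats.csv")
  utils::write.csv(stats_tab, stats_path, row.names = FALSE)
  invisible(list(labels = lab_path, stats = stats_tab, outputs = c(lab_path, stats_path)))
}

#' Group and longitudinal statistics for a record table
#'
#' Emits group-contrast and cohort-summary CSVs for a tidy record table
#' (as produced by [make_cohort()] or [run_simulate()] in cohort mode).
#'
#' @param records_path CSV path of the record table.
#' @param cfg configuration list.
#' @param out_dir output directory.
#' @param map map name to contrast (default `"cth"`).
#' @param region region to contrast (default `"WM"`).
#' @return Invisibly the comparison result and summary table.
#' @export
run_cohort_stats <- function(records_path, cfg = default_config(), out_dir,
                             map = "cth", region = "WM") {
  ensure_outdir(out_dir)
  records <- utils::read.csv(records_path)
  need <- c("subject_id", "group", "visit", "region", "map", "value")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stopf("record table lacks columns: %s", paste(miss, collapse = ", "))
  summary_tab <- summarize_cohort(records)
  utils::write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  sel <- records[records$map == map & records$region == region, , drop = FALSE]
  groups <- unique(sel$group)
  cmp <- NULL
  if (length(groups) == 2 && all(table(sel$group) >= 2)) {
    cmp <- compare_groups(sel, arms = groups)
    utils::write.csv(as.data.frame(cmp),
                     file.path(out_dir, "group_contrast.csv"),
                     row.names = FALSE)
  }
  invisible(list(comparison = cmp, summary = summary_tab))
}
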