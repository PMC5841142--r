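# Turn-key synthetic recovery studies: generate a phantom or cohort under
# the committed group conditions, run the full signal -> concentration ->
# voxel-fit -> oxygen pipeline, and report the group-level map statistics
# that the published group values anchor. These are the workhorses of the
# reproducibility script and of the acceptance-style tests.

# The phantom-study fit configuration: the generator introduces no
# voxel-level arrival dispersion, so the delay search is pinned at zero
# (see the methods vignette for the delay-degeneracy rationale).
study_fit_options <- function() {
  fit_options(n_multistart = 3, delay_grid = 0)
}

#' Fit a phantom end-to-end
#'
#' Converts a phantom's signal series to concentration, fits the vascular
#' model over the given mask and optionally applies the oxygen model.
#'
#' @param phantom a `dsc_phantom` (or a list with `signal`, `aif`, `time`,
#'   `acq`).
#' @param mask 3D mask of voxels to fit (default: all labelled voxels).
#' @param opts a [fit_options()]; defaults to the phantom-study
#'   configuration (3 restarts, delay fixed at 0).
#' @param oxygen an [oxygen_params()] or `NULL` to skip OEC/CMRO2max.
#' @return A [perfusion_maps()] object.
#' @export
fit_phantom <- function(phantom, mask = NULL, opts = NULL, oxygen = oxygen_params()) {
  if (is.null(mask)) mask <- phantom$labels > 0
  if (is.null(opts)) opts <- study_fit_options()
  conc <- signal_to_concentration(phantom$signal, phantom$acq)
  res <- fit_volume(conc, phantom$aif, mask, phantom$time, opts)
  maps <- res$maps
  if (!is.null(oxygen)) maps <- oxygen_maps(maps, oxygen)
  maps
}

#' Whole-white-matter cohort recovery study
#'
#' Simulates `n_subjects` single-compartment white-matter phantoms under
#' the committed group conditions (plus a thalamus block), fits every
#' subject, and returns per-subject WM-masked map means and their cohort
#' means — the synthetic analogue of the whole-WM group comparison.
#'
#' @param group `"control"` or `"hemizygote"`.
#' @param n_subjects number of subjects.
#' @param seed cohort seed.
#' @param snr contrast-to-noise ratio of the simulated series.
#' @param block voxel block per region (WM voxel count is `prod(block)`).
#' @param opts fit options (default phantom-study configuration).
#' @param oxygen oxygen model for CMRO2max.
#' @return List with `per_subject` (data frame: subject, cth, cbf, mtt,
#'   k_app, oec, cmro2max over the WM mask) and `cohort_mean` (named
#'   vector of the column means).
#' @export
wm_cohort_study <- function(group = c("hemizygote", "control"),
                            n_subjects = 10, seed = 1, snr = 20,
                            block = c(4, 3, 2), opts = NULL,
                            oxygen = oxygen_params()) {
  group <- match.arg(group)
  params <- default_wm_params(group, oxygen)
  labels <- block_labels(2, block = block, ncol = 2)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sub_seed <- (seed * 1000L + s) %% .Machine$integer.max
    spec <- phantom_spec(labels, params, snr = snr, seed = sub_seed)
    ph <- make_region_phantom(spec, with_oxygen = FALSE)
    wm <- ph$labels == 1L
    maps <- fit_phantom(ph, mask = wm, opts = opts, oxygen = oxygen)
    rows[[s]] <- data.frame(
      subject = s,
      cth = roi_mean(maps$cth, wm)$mean,
      cbf = roi_mean(maps$cbf, wm)$mean,
      mtt = roi_mean(maps$mtt, wm)$mean,
      k_app = roi_mean(maps$k_app, wm)$mean,
      oec = roi_mean(maps$oec, wm)$mean,
      cmro2max = roi_mean(maps$cmro2max, wm)$mean,
      cth_truth = roi_mean(ph$truth$cth, wm)$mean)
  }
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       cohort_mean = colMeans(per_subject[, -1, drop = FALSE]))
}

#' Nine-region survey recovery study
#'
#' Simulates `n_subjects` nine-region white-matter phantoms (plus
#' thalamus) under the committed regional conditions, fits all regions of
#' each subject, and reports the cohort mean of the fixed-size centroid
#' ROI means per region — mirroring a group statistic over bilateral
#' standardised ROIs rather than a single-phantom readout.
#'
#' @param group `"control"` or `"hemizygote"`.
#' @param seed study seed (per-subject seeds are derived from it).
#' @param snr contrast-to-noise ratio.
#' @param block voxel block per region.
#' @param roi_voxels ROI size per region (capped at the region size).
#' @param n_subjects number of subject phantoms averaged.
#' @param regions optional character vector of region names to fit and
#'   report (default: all ten); restricting the fit to the regions under
#'   study keeps large cohorts cheap.
#' @param opts fit options.
#' @return Data frame with one row per region: region, n_voxels (per
#'   subject), cohort-mean fitted CTH, cohort-mean ground-truth CTH, and
#'   thalamus-normalised rCTH.
#' @export
regional_study <- function(group = "hemizygote", seed = 1, snr = 20,
                           block = c(4, 3, 2), roi_voxels = 24,
                           n_subjects = 1, regions = NULL, opts = NULL) {
  params <- default_region_params(group)
  labels <- block_labels(10, block = block, ncol = 4)
  name_of <- attr(params, "region_names")
  fit_labels <- if (is.null(regions)) 1:10 else {
    hit <- as.integer(names(name_of)[match(unique(c(regions, "THA")), name_of)])
    if (anyNA(hit)) stopf("unknown region name(s)")
    sort(hit)
  }
  per_subject <- list()
  for (s in seq_len(n_subjects)) {
    sub_seed <- (seed * 1000L + s) %% .Machine$integer.max
    spec <- phantom_spec(labels, params, snr = snr, seed = sub_seed)
    ph <- make_region_phantom(spec, with_oxygen = FALSE)
    rois <- region_rois(ph$labels, n_voxels = roi_voxels)
    fit_mask <- Reduce(`|`, lapply(fit_labels, function(lb) rois[[as.character(lb)]]))
    maps <- fit_phantom(ph, mask = fit_mask, opts = opts, oxygen = NULL)
    tha_mean <- roi_mean(maps$cth, rois[["10"]])$mean
    per_subject[[s]] <- do.call(rbind, lapply(fit_labels, function(lb) {
      roi <- rois[[as.character(lb)]]
      st <- roi_mean(maps$cth, roi, label = ph$region_names[[as.character(lb)]])
      data.frame(subject = s, region = st$region, n_voxels = st$n_voxels,
                 cth = st$mean,
                 cth_truth = roi_mean(ph$truth$cth, roi)$mean,
                 rcth = st$mean / tha_mean)
    }))
  }
  all <- do.call(rbind, per_subject)
  out <- do.call(rbind, lapply(split(all, all$region), function(rs) {
    data.frame(region = rs$region[1], n_voxels = rs$n_voxels[1],
               cth = mean(rs$cth), cth_truth = mean(rs$cth_truth),
               rcth = mean(rs$rcth))
  }))
  out <- out[order(match(out$region, c(REGION_ORDER, "THA"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lesion-zone recovery study
#'
#' Simulates the concentric lesion phantom, segments Zones A-E from the
#' phantom's T2/enhancement/WM masks (not from the generator's private
#' zone masks), fits the requested zones, and reports per-zone fitted and
#' ground-truth CTH means.
#'
#' @param seed phantom seed.
#' @param snr contrast-to-noise ratio.
#' @param geometry a [lesion_geometry()].
#' @param zones_to_fit character subset of `zone_a` ... `zone_e`.
#' @param opts fit options.
#' @return Data frame with one row per fitted zone.
#' @export
lesion_zone_study <- function(seed = 1, snr = 20,
                              geometry = lesion_geometry(),
                              zones_to_fit = c("zone_d", "zone_e"),
                              opts = NULL) {
  ph <- make_lesion_phantom(geometry = geometry, seed = seed, snr = snr)
  zones <- segment_lesion_zones(ph$masks$t2_baseline, ph$masks$enh_baseline,
                                ph$masks$wm,
                                ring_width = geometry$ring_width,
                                margin = geometry$margin)
  rows <- list()
  for (zn in zones_to_fit) {
    mask <- zones[[zn]]
    if (!any(mask)) next
    maps <- fit_phantom(list(signal = ph$baseline$signal, aif = ph$aif,
                             time = ph$time, acq = ph$acq),
                        mask = mask, opts = opts, oxygen = NULL)
    rows[[zn]] <- data.frame(
      zone = zn, n_voxels = sum(mask),
      cth = roi_mean(maps$cth, mask)$mean,
      cth_truth = roi_mean(ph$baseline$truth$cth, mask)$mean)
  }
  do.call(rbind, rows)
}
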