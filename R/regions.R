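# Lesion probability atlases, concentric zone segmentation, progression
# partitions and ROI statistics.

#' Lesion zone container
#'
#' The five concentric compartments of an inflammatory white-matter
#' lesion: A (central T2-hyperintense, non-enhancing core), B (enhancing
#' rim), C (T2-hyperintense non-enhancing leading edge), D (adjacent
#' normal-appearing white matter ring) and E (distant NAWM beyond a
#' safety margin). Zones must be pairwise disjoint.
#'
#' @param zone_a,zone_b,zone_c,zone_d,zone_e binary 3D masks on a common
#'   grid.
#' @return An object of class `lesion_zones`.
#' @export
lesion_zones <- function(zone_a, zone_b, zone_c, zone_d, zone_e) {
  zs <- list(zone_a = as_mask(zone_a), zone_b = as_mask(zone_b),
             zone_c = as_mask(zone_c), zone_d = as_mask(zone_d),
             zone_e = as_mask(zone_e))
  for (nm in names(zs)[-1]) check_same_dim(zs$zone_a, zs[[nm]], "zone masks")
  total <- Reduce(`+`, zs)
  if (any(total > 1))
    stopf("lesion zones overlap at %d voxels", sum(total > 1))
  structure(zs, class = "lesion_zones")
}

#' @export
print.lesion_zones <- function(x, ...) {
  cat("Lesion zones (voxels):",
      paste(sprintf("%s=%d", toupper(substr(names(x), 6, 6)),
                    vapply(x, sum, 1)), collapse = " "), "\n")
  invisible(x)
}

#' Convert lesion zones to a label volume
#'
#' @param zones a [lesion_zones()] object.
#' @return 3D integer array with A=1 ... E=5, 0 elsewhere.
#' @export
zone_labels <- function(zones) {
  stopifnot(inherits(zones, "lesion_zones"))
  lab <- array(0L, dim(zones$zone_a))
  for (i in seq_along(zones)) lab[zones[[i]]] <- i
  lab
}

#' Build a lesion probability atlas from binary masks
#'
#' Voxelwise sum of the subject lesion masks divided by the number of
#' subjects.
#'
#' @param masks non-empty list of binary 3D volumes on a common grid.
#' @return An object of class `probability_atlas` with fields
#'   `probability` (3D array of fractions) and `n_subjects`.
#' @export
build_probability_atlas <- function(masks) {
  if (!is.list(masks) || length(masks) == 0)
    stopf("masks must be a non-empty list")
  m1 <- as_mask(masks[[1]])
  acc <- array(0, dim(m1))
  for (m in masks) {
    mm <- as_mask(m)
    check_same_dim(m1, mm, "lesion masks")
    acc <- acc + mm
  }
  structure(list(probability = acc / length(masks),
                 n_subjects = length(masks)),
            class = "probability_atlas")
}

#' @export
print.probability_atlas <- function(x, ...) {
  cat(sprintf("Lesion probability atlas: %d subjects, max probability %.3g\n",
              x$n_subjects, max(x$probability)))
  invisible(x)
}

#' Mean lesion probability over a region of interest
#'
#' @param atlas a [build_probability_atlas()] result.
#' @param roi non-empty binary mask on the atlas grid.
#' @return Mean atlas probability over the ROI, a fraction.
#' @export
region_probability <- function(atlas, roi) {
  stopifnot(inherits(atlas, "probability_atlas"))
  m <- as_mask(roi)
  check_same_dim(atlas$probability, m, "atlas and roi")
  if (!any(m)) stopf("roi is empty")
  mean(atlas$probability[m])
}

#' Segment a lesion into the five concentric zones
#'
#' Mask algebra plus morphological dilation: B is the enhancement inside
#' the lesion; A is the non-enhancing lesion component enclosed by B,
#' identified by 26-connected flood fill from the voxel nearest the
#' lesion centroid; C is the remaining lesion; D is the `ring_width`
#' dilation ring around the lesion restricted to white matter; E is white
#' matter beyond a `margin` dilation of the lesion. Enhancement outside
#' the lesion is clipped with a warning; with no enhancement, A and B are
#' empty and C is the whole lesion.
#'
#' @param t2_lesion binary T2-hyperintense lesion mask.
#' @param enhancement binary contrast-enhancement mask (may be NULL/empty).
#' @param wm binary white-matter mask.
#' @param ring_width Zone D ring width, voxels.
#' @param margin Zone E exclusion margin, voxels.
#' @param exclusion optional mask removed from every zone (e.g.
#'   infratentorial or corticospinal tract tissue).
#' @return A [lesion_zones()] object.
#' @export
segment_lesion_zones <- function(t2_lesion, enhancement = NULL, wm,
                                 ring_width = 2, margin = 6,
                                 exclusion = NULL) {
  lesion <- as_mask(t2_lesion)
  wm <- as_mask(wm)
  check_same_dim(lesion, wm, "lesion and wm masks")
  enh <- if (is.null(enhancement)) array(FALSE, dim(lesion)) else as_mask(enhancement)
  check_same_dim(lesion, enh, "lesion and enhancement masks")
  if (!any(lesion)) {
    warnf("empty lesion mask: all zones empty")
    z0 <- array(FALSE, dim(lesion))
    return(lesion_zones(z0, z0, z0, z0, z0))
  }
  outside <- sum(enh & !lesion)
  if (outside > 0) {
    warnf("%d enhancement voxels outside the lesion were clipped", outside)
  }
  b <- enh & lesion
  if (any(b)) {
    interior <- lesion & !b
    start <- nearest_in_mask(interior, mask_centroid(lesion))
    a <- flood_fill(interior, start)
  } else {
    a <- array(FALSE, dim(lesion))
  }
  cmask <- lesion & !a & !b
  d <- dilate_mask(lesion, ring_width) & !lesion & wm
  e <- wm & !dilate_mask(lesion, margin)
  if (!is.null(exclusion)) {
    ex <- !as_mask(exclusion)
    a <- a & ex; b <- b & ex; cmask <- cmask & ex; d <- d & ex; e <- e & ex
  }
  lesion_zones(a, b, cmask, d, e)
}

#' Partition a baseline zone by follow-up status
#'
#' Exact set operations: `converting` is the part of the baseline zone
#' covered by the follow-up mask, `nonconverting` the rest; together they
#' partition the input zone.
#'
#' @param zone_baseline binary baseline zone mask.
#' @param followup_mask binary abnormality mask at follow-up.
#' @return List with masks `converting` and `nonconverting`.
#' @export
partition_progression <- function(zone_baseline, followup_mask) {
  z <- as_mask(zone_baseline)
  f <- as_mask(followup_mask)
  check_same_dim(z, f, "zone and follow-up masks")
  list(converting = z & f, nonconverting = z & !f)
}

#' ROI summary of a parameter map
#'
#' Mean and sample SD of a map over the non-missing voxels of an ROI.
#'
#' @param map 3D volume (missing voxels `NA`).
#' @param roi binary mask.
#' @param label optional region label carried into the result.
#' @return An object of class `roi_stat` (fields `region`, `n_voxels`,
#'   `mean`, `sd`).
#' @export
roi_mean <- function(map, roi, label = NULL) {
  m <- as_mask(roi)
  check_same_dim(map, m, "map and roi")
  vals <- map[m]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stopf("ROI contains no non-missing voxels")
  structure(list(region = label %||% NA_character_,
                 n_voxels = length(vals), mean = mean(vals),
                 sd = if (length(vals) > 1) stats::sd(vals) else NA_real_),
            class = "roi_stat")
}

#' @export
print.roi_stat <- function(x, ...) {
  cat(sprintf("ROI %s: n=%d, mean %.4g, sd %.4g\n",
              x$region, x$n_voxels, x$mean, x$sd))
  invisible(x)
}

#' @export
as.data.frame.roi_stat <- function(x, ...) {
  data.frame(region = x$region, n_voxels = x$n_voxels, mean = x$mean, sd = x$sd)
}

#' Reference-normalised ROI value
#'
#' Ratio of the ROI mean to a reference-region mean of the same map, e.g.
#' thalamus-normalised relative CTH (rCTH).
#'
#' @param map 3D volume.
#' @param roi binary mask of the region of interest.
#' @param reference_roi binary mask of the normalisation region.
#' @return Dimensionless ratio.
#' @export
relative_value <- function(map, roi, reference_roi) {
  ref <- roi_mean(map, reference_roi)
  if (!is.finite(ref$mean) || ref$mean <= 0)
    stopf("reference region mean is not positive (%.4g): cannot normalise", ref$mean)
  roi_mean(map, roi)$mean / ref$mean
}

#' Fixed-size ROIs centred on region centroids
#'
#' For each label, selects the `n_voxels` region voxels nearest the region
#' centroid (Euclidean distance in index space, ties broken by index
#' order), emulating standardised small ROIs placed per anatomical region.
#'
#' @param labels 3D integer label array.
#' @param n_voxels ROI size; regions smaller than this return the whole
#'   region.
#' @return Named list of binary masks, one per positive label.
#' @export
region_rois <- function(labels, n_voxels = 24) {
  labs <- sort(unique(as.vector(labels)))
  labs <- labs[labs > 0]
  out <- list()
  for (lb in labs) {
    m <- labels == lb
    idx <- which(m, arr.ind = TRUE)
    ctr <- colMeans(idx)
    d2 <- colSums((t(idx) - ctr)^2)
    take <- order(d2)[seq_len(min(n_voxels, nrow(idx)))]
    roi <- array(FALSE, dim(labels))
    roi[idx[take, , drop = FALSE]] <- TRUE
    out[[as.character(lb)]] <- roi
  }
  out
}
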