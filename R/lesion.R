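# Concentric lesion-zone phantom: a T2-hyperintense lesion with an
# enhancing rim embedded in white matter, with designated sectors of the
# perilesional ring (Zone D) converting to T2 hyperintensity and of the
# lesion leading edge (Zone C) converting to contrast enhancement on
# follow-up. Zone ground truths default to the published group values
# (Zone D 3.01 s vs distant NAWM 2.20 s; converting 4.09 s vs
# non-converting 2.62 s; leakage -0.04e-3 vs 0.02e-3 /min in the Zone C
# sectors), with the converting fraction of Zone D chosen so the sector
# mixture reproduces the Zone D mean.

#' Lesion phantom geometry
#'
#' Nested concentric in-plane squares spanning the full slab thickness:
#' core (Zone A) inside an enhancing rim (Zone B) inside the lesion edge
#' (Zone C); Zone D is the `ring_width`-voxel dilation ring around the
#' lesion and Zone E the white matter beyond a `margin`-voxel safety
#' dilation. Converting sectors are contiguous blocks on the +x side.
#'
#' @param dims volume dimensions (x, y, z).
#' @param core_half,enh_width,lesion_half in-plane Chebyshev radii: Zone A
#'   is `<= core_half`, Zone B `<= core_half + enh_width`, the lesion
#'   `<= lesion_half`.
#' @param ring_width Zone D ring width in voxels.
#' @param margin dilation distance separating Zone E from the lesion.
#' @param converting_fraction fraction of Zone D converting to T2
#'   hyperintensity on follow-up (default chosen so the sector mixture
#'   mean matches the committed Zone D value).
#' @param enh_converting_fraction fraction of Zone C converting to
#'   enhancement on follow-up.
#' @return An object of class `lesion_geometry`.
#' @export
lesion_geometry <- function(dims = c(26, 26, 3), core_half = 2, enh_width = 1,
                            lesion_half = 5, ring_width = 2, margin = 6,
                            converting_fraction = (3.01 - 2.62) / (4.09 - 2.62),
                            enh_converting_fraction = 0.4) {
  if (lesion_half <= core_half + enh_width)
    stopf("lesion_half must exceed core_half + enh_width")
  if (converting_fraction < 0 || converting_fraction > 1 ||
      enh_converting_fraction < 0 || enh_converting_fraction > 1)
    stopf("converting fractions must lie in [0, 1]")
  structure(list(dims = dims, core_half = core_half, enh_width = enh_width,
                 lesion_half = lesion_half, ring_width = ring_width,
                 margin = margin, converting_fraction = converting_fraction,
                 enh_converting_fraction = enh_converting_fraction),
            class = "lesion_geometry")
}

#' Default lesion zone generative parameters
#'
#' Per-zone [region_params()] for the lesion phantom; Zone C and Zone D
#' are split into their follow-up-converting and non-converting sectors.
#'
#' @return Named list with entries `A`, `B`, `C_non`, `C_enh`, `D_conv`,
#'   `D_non`, `E`.
#' @export
default_zone_params <- function() {
  rth <- 3.20 / 4.5   # hemizygote-like relative heterogeneity for lesion WM
  zp <- function(cth, cth_sd, k_app, k_app_sd, cbf = 45) {
    region_params(cbf = cbf, mtt = cth / rth, cth = cth,
                  k_app = k_app, cbf_sd = 0.08 * cbf,
                  mtt_sd = 0.08 * cth / rth, cth_sd = cth_sd,
                  k_app_sd = k_app_sd)
  }
  list(A      = zp(4.30, 0.50, 0.02e-3, 0.01e-3, cbf = 30),
       B      = zp(4.10, 0.50, 0.15e-3, 0.05e-3, cbf = 40),
       C_non  = zp(3.70, 0.50, 0.02e-3, 0.02e-3),
       C_enh  = zp(3.70, 0.50, -0.04e-3, 0.03e-3),
       D_conv = zp(4.09, 0.87, 0.04e-3, 0.01e-3, cbf = 50),
       D_non  = zp(2.62, 0.57, 0.02e-3, 0.01e-3, cbf = 50),
       E      = zp(2.20, 0.26, 0.01e-3, 0.01e-3, cbf = 55))
}

# in-plane Chebyshev-radius mask around the volume centre
centred_square <- function(dims, half) {
  cx <- ceiling(dims[1] / 2); cy <- ceiling(dims[2] / 2)
  m <- array(FALSE, dims)
  xs <- pmax(1, cx - half):pmin(dims[1], cx + half)
  ys <- pmax(1, cy - half):pmin(dims[2], cy + half)
  m[xs, ys, ] <- TRUE
  m
}

# contiguous +x sector holding `fraction` of the mask voxels
plus_x_sector <- function(mask, fraction) {
  out <- array(FALSE, dim(mask))
  n_take <- round(fraction * sum(mask))
  if (n_take == 0) return(out)
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2], idx[, 3], decreasing = TRUE)
  out[idx[ord[seq_len(n_take)], , drop = FALSE]] <- TRUE
  out
}

#' Generate a two-timepoint concentric lesion-zone phantom
#'
#' Builds nested lesion zone masks, draws ground truth per zone sector,
#' and simulates baseline and follow-up DSC series. On follow-up the
#' converting sector of Zone D becomes T2-hyperintense (taking Zone C
#' parameters) and the converting sector of Zone C becomes enhancing
#' (taking Zone B parameters); with both converting fractions zero the
#' follow-up masks and ground truth equal baseline.
#'
#' @param zone_params list as produced by [default_zone_params()].
#' @param geometry a [lesion_geometry()].
#' @param acq an [acquisition_params()].
#' @param aif an [aif_model()].
#' @param seed RNG seed.
#' @param noise_sigma,snr noise specification as in [phantom_spec()].
#' @param upsample convolution upsampling factor.
#' @return An object of class `lesion_phantom`: `baseline` and `followup`
#'   (each with `signal` and `truth`), `masks` (t2/enhancement at both
#'   timepoints plus `wm`), `sectors`, ground-truth `zones`
#'   (a `lesion_zones` object), `time`, `aif`, `acq`.
#' @export
make_lesion_phantom <- function(zone_params = default_zone_params(),
                                geometry = lesion_geometry(),
                                acq = acquisition_params(), aif = aif_model(),
                                seed = 1, noise_sigma = 0, snr = NULL,
                                upsample = 4) {
  stopifnot(inherits(geometry, "lesion_geometry"))
  need <- c("A", "B", "C_non", "C_enh", "D_conv", "D_non", "E")
  miss <- setdiff(need, names(zone_params))
  if (length(miss) > 0) stopf("zone_params missing: %s", paste(miss, collapse = ", "))
  g <- geometry
  dims <- g$dims
  wm <- array(TRUE, dims)

  a <- centred_square(dims, g$core_half)
  ab <- centred_square(dims, g$core_half + g$enh_width)
  lesion <- centred_square(dims, g$lesion_half)
  b <- ab & !a
  cmask <- lesion & !ab
  d <- dilate_mask(lesion, g$ring_width) & !lesion & wm
  e <- wm & !dilate_mask(lesion, g$margin)

  zones <- lesion_zones(a, b, cmask, d, e)   # validates disjointness

  d_conv <- plus_x_sector(d, g$converting_fraction)
  d_non <- d & !d_conv
  c_enh <- plus_x_sector(cmask, g$enh_converting_fraction)
  c_non <- cmask & !c_enh

  # generation sub-labels; NAWM between D and E shares Zone E parameters
  sub <- array(0L, dims)
  sub[e] <- 7L; sub[wm & !lesion & !d & !e] <- 7L
  sub[d_non] <- 6L; sub[d_conv] <- 5L
  sub[c_non] <- 3L; sub[c_enh] <- 4L
  sub[b] <- 2L; sub[a] <- 1L
  key <- c("A", "B", "C_non", "C_enh", "D_conv", "D_non", "E")

  base_params <- stats::setNames(zone_params[key], as.character(1:7))
  spec_base <- phantom_spec(sub, base_params, noise_sigma = noise_sigma,
                            snr = snr, seed = seed)
  baseline <- make_region_phantom(spec_base, acq, aif, upsample = upsample,
                                  with_oxygen = FALSE)

  # follow-up: converted sectors take the parameters of the zone they join
  fu_params <- base_params
  fu_params[["5"]] <- zone_params$C_non   # D converting -> lesion edge tissue
  fu_params[["4"]] <- zone_params$B       # C enhancing -> active rim tissue
  spec_fu <- phantom_spec(sub, fu_params, noise_sigma = noise_sigma,
                          snr = snr, seed = seed + 1L)
  followup <- make_region_phantom(spec_fu, acq, aif, upsample = upsample,
                                  with_oxygen = FALSE)

  masks <- list(t2_baseline = lesion, enh_baseline = b,
                t2_followup = lesion | d_conv, enh_followup = b | c_enh,
                wm = wm)
  structure(list(baseline = list(signal = baseline$signal, truth = baseline$truth),
                 followup = list(signal = followup$signal, truth = followup$truth),
                 masks = masks,
                 sectors = list(d_converting = d_conv, d_nonconverting = d_non,
                                c_enhancing = c_enh, c_nonenhancing = c_non),
                 zones = zones, geometry = g, acq = acq,
                 time = baseline$time, aif = baseline$aif,
                 noise_sigma = baseline$noise_sigma),
            class = "lesion_phantom")
}

#' @export
print.lesion_phantom <- function(x, ...) {
  zs <- vapply(x$zones[c("zone_a", "zone_b", "zone_c", "zone_d", "zone_e")],
               sum, 1)
  cat(sprintf("Lesion phantom %s; zone voxels A %d, B %d, C %d, D %d, E %d\n",
              paste(x$geometry$dims, collapse = "x"),
              zs[1], zs[2], zs[3], zs[4], zs[5]))
  cat(sprintf("  converting: %d of %d Zone D voxels, %d of %d Zone C voxels\n",
              sum(x$sectors$d_converting), zs[4],
              sum(x$sectors$c_enhancing), zs[3]))
  invisible(x)
}
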