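# Volume-level fitting: apply the voxel fit across a masked 4D series and
# collect aligned 3D parameter maps.

MAP_NAMES <- c("cbf", "mtt", "cth", "k_app", "oec", "cmro2max")

#' Aligned perfusion parameter maps
#'
#' A container of 3D volumes (cbf, mtt, cth, k_app and, once the oxygen
#' model has been applied, oec and cmro2max) sharing one shape and affine.
#' Undefined voxels carry `NA`.
#'
#' @param cbf,mtt,cth,k_app,oec,cmro2max 3D arrays (oec/cmro2max may be
#'   `NULL` until [oxygen_maps()] is applied).
#' @param affine 4x4 voxel-to-world matrix carried through to NIfTI output.
#' @return An object of class `perfusion_maps`.
#' @export
perfusion_maps <- function(cbf, mtt, cth, k_app, oec = NULL, cmro2max = NULL,
                           affine = diag(4)) {
  vols <- list(cbf = cbf, mtt = mtt, cth = cth, k_app = k_app,
               oec = oec, cmro2max = cmro2max)
  ref <- dim(cbf)
  if (length(ref) != 3L) stopf("maps must be 3D arrays")
  for (nm in names(vols)) {
    if (is.null(vols[[nm]])) next
    if (!identical(dim(vols[[nm]]), ref))
      stopf("map '%s' does not share the common shape", nm)
  }
  for (nm in c("mtt", "cth")) {
    v <- vols[[nm]]
    if (any(v < 0, na.rm = TRUE)) stopf("map '%s' must be non-negative where defined", nm)
  }
  structure(c(vols, list(affine = affine)), class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  d <- dim(x$cbf)
  cat(sprintf("Perfusion maps %dx%dx%d\n", d[1], d[2], d[3]))
  for (nm in MAP_NAMES) {
    v <- x[[nm]]
    if (is.null(v)) { cat(sprintf("  %-8s <not computed>\n", nm)); next }
    ok <- is.finite(v)
    cat(sprintf("  %-8s defined %d/%d, mean %.4g, sd %.4g\n",
                nm, sum(ok), length(v), mean(v[ok]), stats::sd(v[ok])))
  }
  invisible(x)
}

#' @export
summary.perfusion_maps <- function(object, ...) {
  rows <- lapply(MAP_NAMES, function(nm) {
    v <- object[[nm]]
    if (is.null(v)) return(NULL)
    ok <- is.finite(v)
    data.frame(map = nm, n_defined = sum(ok),
               mean = mean(v[ok]), sd = stats::sd(v[ok]),
               min = suppressWarnings(min(v[ok])),
               max = suppressWarnings(max(v[ok])))
  })
  do.call(rbind, rows)
}

#' @export
as.data.frame.perfusion_maps <- function(x, ...) {
  ok_any <- Reduce(`|`, lapply(MAP_NAMES, function(nm) {
    if (is.null(x[[nm]])) array(FALSE, dim(x$cbf)) else is.finite(x[[nm]])
  }))
  idx <- which(ok_any, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3])
  for (nm in MAP_NAMES) out[[nm]] <- if (is.null(x[[nm]])) NA_real_ else x[[nm]][idx]
  out
}

#' Fit the vascular model over a masked volume
#'
#' Applies [fit_voxel()] to every in-mask voxel of a 4D concentration
#' series. Out-of-mask voxels are `NA` in every output map; in-mask voxels
#' whose curves are entirely missing propagate as missing. Results do not
#' depend on the voxel visiting order.
#'
#' @param conc4d 4D concentration array (x, y, z, t).
#' @param aif arterial input concentration on the frame grid.
#' @param mask 3D logical/0-1 array selecting voxels to fit.
#' @param time_grid uniform frame time grid, seconds.
#' @param opts a [fit_options()] object.
#' @param affine affine carried into the output maps.
#' @return A list with `maps` (a [perfusion_maps()] with the kinetic
#'   subset filled), `diagnostics` (data frame: voxel index, parameters,
#'   rss, converged, n_restarts_used) and `n_failed`.
#' @export
fit_volume <- function(conc4d, aif, mask, time_grid, opts = fit_options(),
                       affine = diag(4)) {
  dims <- dim(conc4d)
  if (length(dims) != 4L) stopf("conc4d must be a 4D array")
  if (!identical(dim(mask), dims[1:3]))
    stopf("mask shape %s does not match volume %s",
          paste(dim(mask), collapse = "x"), paste(dims[1:3], collapse = "x"))
  m <- as_mask(mask)
  empty <- array(NA_real_, dims[1:3])
  maps <- list(cbf = empty, mtt = empty, cth = empty, k_app = empty,
               delay = empty, rss = empty)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warnf("empty mask: returning empty maps")
    pm <- perfusion_maps(empty, empty, empty, empty, affine = affine)
    return(list(maps = pm, diagnostics = data.frame(), n_failed = 0L))
  }
  nvox <- prod(dims[1:3])
  cm <- matrix(conc4d, nrow = nvox, ncol = dims[4])
  lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] + (idx[, 3] - 1L) * dims[1] * dims[2]
  diag_rows <- vector("list", nrow(idx))
  n_failed <- 0L
  for (v in seq_len(nrow(idx))) {
    fit <- fit_voxel(cm[lin[v], ], aif, time_grid, opts)
    cf <- fit$coefficients
    maps$cbf[lin[v]] <- cf[["cbf"]]
    maps$k_app[lin[v]] <- cf[["k_app"]]
    maps$delay[lin[v]] <- cf[["delay"]]
    maps$rss[lin[v]] <- fit$rss
    if (!fit$missing) {
      s <- transit_stats(fit$transit)
      maps$mtt[lin[v]] <- s$mtt
      maps$cth[lin[v]] <- s$cth
    }
    if (!fit$converged) n_failed <- n_failed + 1L
    diag_rows[[v]] <- data.frame(i = idx[v, 1], j = idx[v, 2], k = idx[v, 3],
                                 cbf = cf[["cbf"]], alpha = cf[["alpha"]],
                                 beta = cf[["beta"]], k_app = cf[["k_app"]],
                                 delay = cf[["delay"]], rss = fit$rss,
                                 converged = fit$converged,
                                 n_restarts_used = fit$n_restarts_used)
  }
  pm <- perfusion_maps(maps$cbf, maps$mtt, maps$cth, maps$k_app, affine = affine)
  pm$delay <- maps$delay
  pm$rss <- maps$rss
  list(maps = pm, diagnostics = do.call(rbind, diag_rows), n_failed = n_failed)
}

#' Automatic arterial input function selection
#'
#' Scores every in-mask voxel on a composite of early bolus arrival, high
#' peak concentration and narrow first-passage width (rank sum of the
#' three), and returns the mean curve of the top-scoring candidates.
#' A user-supplied `aif_mask` bypasses selection and returns the mean
#' curve over that mask.
#'
#' @param conc4d 4D concentration array.
#' @param brain_mask 3D mask of voxels to consider.
#' @param n_candidates number of top-scoring voxels averaged.
#' @param min_peak_factor candidates must exceed this multiple of the
#'   median in-mask peak; if none do, selection fails with an error
#'   advising a manual AIF.
#' @param aif_mask optional mask that bypasses automatic selection.
#' @return The selected AIF curve, with attribute `"voxels"` holding the
#'   linear indices of the contributing voxels.
#' @export
select_aif <- function(conc4d, brain_mask, n_candidates = 5,
                       min_peak_factor = 2, aif_mask = NULL) {
  dims <- dim(conc4d)
  if (length(dims) != 4L) stopf("conc4d must be a 4D array")
  nvox <- prod(dims[1:3])
  cm <- matrix(conc4d, nrow = nvox, ncol = dims[4])
  if (!is.null(aif_mask)) {
    check_same_dim(aif_mask, array(0, dims[1:3]), "aif_mask and volume")
    sel <- which(as_mask(aif_mask))
    if (length(sel) == 0) stopf("aif_mask is empty")
    out <- colMeans(cm[sel, , drop = FALSE], na.rm = TRUE)
    attr(out, "voxels") <- sel
    return(out)
  }
  m <- as_mask(brain_mask)
  check_same_dim(m, array(0, dims[1:3]), "brain_mask and volume")
  sel <- which(m)
  if (length(sel) == 0) stopf("brain_mask is empty")
  sub <- cm[sel, , drop = FALSE]
  ok <- rowSums(!is.finite(sub)) == 0
  sel <- sel[ok]; sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) == 0) stopf("no finite curves inside the brain mask")
  if (nrow(sub) == 1) {
    out <- as.numeric(sub)
    attr(out, "voxels") <- sel
    return(out)
  }
  peak <- apply(sub, 1, max)
  ttp <- apply(sub, 1, which.max)
  fwhm <- apply(sub, 1, function(y) sum(y >= max(y) / 2))
  eligible <- peak > min_peak_factor * stats::median(peak)
  if (!any(eligible))
    stopf(paste("AIF selection failed: no voxel peak exceeds %.3g x the median;",
                "supply a manual AIF or AIF mask"), min_peak_factor)
  score <- rank(peak, ties.method = "first") +
    rank(-ttp, ties.method = "first") + rank(-fwhm, ties.method = "first")
  score[!eligible] <- -Inf
  take <- order(score, decreasing = TRUE)[seq_len(min(n_candidates, sum(eligible)))]
  out <- colMeans(sub[take, , drop = FALSE])
  attr(out, "voxels") <- sel[take]
  out
}
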