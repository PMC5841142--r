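#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a private RNG stream, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

is_binary_mask <- function(x) {
  is.array(x) && all(x %in% c(0, 1, TRUE, FALSE, NA))
}

as_mask <- function(x) {
  m <- array(as.logical(x), dim = dim(x))
  m[is.na(m)] <- FALSE
  m
}

check_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stopf("%s do not share dimensions: %s vs %s", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# Uniform-grid check; returns the common step.
grid_step <- function(time_grid) {
  if (length(time_grid) < 2 || is.unsorted(time_grid, strictly = TRUE))
    stopf("time grid must be strictly increasing")
  dt <- diff(time_grid)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1])
    stopf("time grid must be uniformly spaced")
  dt[1]
}

# Cumulative trapezoidal integral on a uniform grid, y(0) at first node.
cumtrapz_uniform <- function(y, dt) {
  dt * (cumsum(y) - 0.5 * y - 0.5 * y[1])
}

# Trapezoid-rule convolution integral (f * g)(t_k) on a shared uniform grid,
# via FFT; returns a vector of the same length.
conv_trapz <- function(f, g, dt) {
  n <- length(f)
  full <- stats::convolve(f, rev(g), type = "open")[seq_len(n)]
  (full - 0.5 * f[1] * g - 0.5 * f * g[1]) * dt
}

# Binary dilation by `k` voxels in the Chebyshev metric (26-connectivity
# per step). The 3x3x3 box maximum is separable, so one dilation step is a
# sequential +/-1 shift-OR along each axis.
dilate_mask <- function(mask, k) {
  m <- as_mask(mask)
  if (k <= 0) return(m)
  dims <- dim(m)
  shift1 <- function(x, d, by) {
    out <- array(FALSE, dims)
    n <- dims[d]
    if (n == 1L) return(out)
    to <- lapply(dims, seq_len)
    from <- to
    if (by == 1L) { to[[d]] <- 2:n; from[[d]] <- 1:(n - 1L) }
    else          { to[[d]] <- 1:(n - 1L); from[[d]] <- 2:n }
    src <- do.call(`[`, c(list(x), from, list(drop = FALSE)))
    do.call(`[<-`, c(list(out), to, list(value = src)))
  }
  for (i in seq_len(k)) {
    for (d in seq_along(dims)) {
      if (dims[d] == 1L) next
      m <- m | shift1(m, d, 1L) | shift1(m, d, -1L)
    }
  }
  m
}

# Connected component (26-neighbourhood) of `mask` containing `start`
# (an index triplet); breadth-first search on the voxel grid.
flood_fill <- function(mask, start) {
  m <- as_mask(mask)
  dims <- dim(m)
  out <- array(FALSE, dims)
  if (!m[start[1], start[2], start[3]]) return(out)
  lin <- function(ijk) ijk[1] + (ijk[2] - 1L) * dims[1] + (ijk[3] - 1L) * dims[1] * dims[2]
  nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  queue <- matrix(as.integer(start), ncol = 3)
  out[queue] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    cand <- sweep(nb, 2, as.integer(cur), `+`)
    keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
            cand[, 2] >= 1 & cand[, 2] <= dims[2] &
            cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    hit <- m[cand] & !out[cand]
    if (any(hit)) {
      new <- cand[hit, , drop = FALSE]
      out[new] <- TRUE
      queue <- rbind(queue, new)
    }
  }
  out
}

mask_centroid <- function(mask) {
  idx <- which(as_mask(mask), arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("cannot take centroid of an empty mask")
  colMeans(idx)
}

# Voxel in `mask` nearest (Euclidean, index space) to point `p`.
nearest_in_mask <- function(mask, p) {
  idx <- which(as_mask(mask), arr.ind = TRUE)
  d2 <- colSums((t(idx) - p)^2)
  as.integer(idx[which.min(d2), ])
}
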