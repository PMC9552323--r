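#' Voxel grids
#'
#' A `VoxelGrid` describes a regular 3-D voxel lattice in world millimetre
#' coordinates. Axis order is LR (x), AP (y, positive = posterior),
#' SI (z, positive = superior). `origin` is the world position of the centre
#' of voxel (1,1,1); voxel (i,j,k) is centred at
#' `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param shape integer length-3, number of voxels per axis.
#' @param spacing numeric length-3 (or scalar), voxel size in mm. Default 3 mm
#'   isotropic, the resolution of the dose grid.
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre. Default centres the grid on the world origin.
#' @param frame character label, `"reference"` or `"fraction-k"`.
#' @return An object of class `VoxelGrid`.
#' @export
voxel_grid <- function(shape, spacing = c(3, 3, 3), origin = NULL,
                       frame = "reference") {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be > 0 on all axes")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), frame = frame),
            class = "VoxelGrid")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  cat(sprintf("VoxelGrid %dx%dx%d @ (%g, %g, %g) mm [%s]\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$frame))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' Voxel volume in cm^3
#' @param grid a `VoxelGrid`.
#' @return scalar voxel volume (cm^3).
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of all voxel centres
#'
#' @param grid a `VoxelGrid`.
#' @return an `n x 3` matrix of world mm coordinates in column-major voxel
#'   order (matching R array linearisation).
#' @export
grid_coords <- function(grid) {
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
  n <- grid$shape
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

#' Trilinear interpolation of a 3-D array at world points
#'
#' Values outside the grid return `fill`. If `na_fallback` is `TRUE`, points
#' whose trilinear neighbourhood contains `NA`s (e.g. at a mask edge) fall
#' back to the nearest-voxel value.
#'
#' @param arr numeric 3-D array on `grid`.
#' @param grid a `VoxelGrid`.
#' @param pts `n x 3` matrix of world mm coordinates.
#' @param fill value for points outside the grid (default 0).
#' @param na_fallback nearest-neighbour fallback where trilinear hits `NA`.
#' @return numeric vector of length `n`.
#' @export
interp3 <- function(arr, grid, pts, fill = 0, na_fallback = FALSE) {
  d <- dim(arr)
  stopifnot(all(d == grid$shape))
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  ci <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
  inside <- ci[, 1] >= 1 & ci[, 1] <= d[1] &
            ci[, 2] >= 1 & ci[, 2] <= d[2] &
            ci[, 3] >= 1 & ci[, 3] <= d[3]
  out <- rep(as.numeric(fill), nrow(pts))
  if (!any(inside)) return(out)
  ci <- ci[inside, , drop = FALSE]
  i0 <- floor(ci)
  # clamp so that i0 and i0+1 are valid; points exactly on the far face land
  # in the last cell with fractional coordinate 1
  for (a in 1:3) i0[, a] <- pmin(pmax(i0[, a], 1), d[a] - 1)
  fr <- ci - i0
  s1 <- 1L; s2 <- d[1]; s3 <- d[1] * d[2]
  base <- (i0[, 1] - 1) * s1 + (i0[, 2] - 1) * s2 + (i0[, 3] - 1) * s3 + 1
  v <- numeric(nrow(ci)); wna <- numeric(nrow(ci))
  hasna <- rep(FALSE, nrow(ci))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    idx <- base + dx * s1 + dy * s2 + dz * s3
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    val <- arr[idx]
    nab <- is.na(val)
    if (any(nab)) { hasna <- hasna | (nab & w > 0); val[nab] <- 0 }
    v <- v + w * val
  }
  if (na_fallback && any(hasna)) {
    ni <- round(ci[hasna, , drop = FALSE])
    for (a in 1:3) ni[, a] <- pmin(pmax(ni[, a], 1), d[a])
    nn <- arr[(ni[, 1] - 1) * s1 + (ni[, 2] - 1) * s2 + (ni[, 3] - 1) * s3 + 1]
    v[hasna] <- nn
  } else if (any(hasna)) {
    v[hasna] <- NA_real_
  }
  out[inside] <- v
  out
}

# periodic coordinate vector for FFT kernels: distance to nearest image
fft_axis_dist <- function(n, sp) {
  m <- 0:(n - 1)
  pmin(m, n - m) * sp
}

#' Gaussian smoothing of a 3-D array (FFT, periodic boundaries)
#'
#' @param arr numeric 3-D array.
#' @param grid a `VoxelGrid`.
#' @param sigma_mm Gaussian kernel SD in mm (scalar or per-axis).
#' @return smoothed array, same dimensions.
#' @export
gauss_smooth3 <- function(arr, grid, sigma_mm) {
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3L)
  d <- dim(arr)
  ks <- lapply(1:3, function(a) {
    x <- fft_axis_dist(d[a], grid$spacing[a])
    k <- exp(-x^2 / (2 * sigma_mm[a]^2))
    k / sum(k)
  })
  kf <- lapply(ks, stats::fft)
  K <- outer(outer(kf[[1]], kf[[2]]), kf[[3]])
  dim(K) <- d
  res <- Re(stats::fft(stats::fft(arr) * K, inverse = TRUE)) / prod(d)
  array(res, d)
}

#' Morphological dilation of a mask by an ellipsoid in mm
#'
#' Voxel-centre semantics: a voxel belongs to the dilation iff its centre lies
#' within the (an)isotropic ellipsoid of semi-axes `radii_mm` around some mask
#' voxel centre. Implemented by FFT convolution with the ellipsoid indicator.
#'
#' @param mask logical 3-D array.
#' @param grid a `VoxelGrid`.
#' @param radii_mm scalar or length-3 (LR, AP, SI) radii in mm.
#' @return logical array of the dilated mask.
#' @export
dilate_mask <- function(mask, grid, radii_mm) {
  if (length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  stopifnot(all(radii_mm >= 0))
  if (all(radii_mm < min(grid$spacing) / 2)) {
    if (any(radii_mm > 0))
      warning("dilation radius below half a voxel; rounded to 0 mm")
    return(mask)
  }
  d <- dim(mask)
  ax <- lapply(1:3, function(a) fft_axis_dist(d[a], grid$spacing[a]))
  r1 <- (ax[[1]] / max(radii_mm[1], 1e-9))^2
  r2 <- (ax[[2]] / max(radii_mm[2], 1e-9))^2
  r3 <- (ax[[3]] / max(radii_mm[3], 1e-9))^2
  B <- outer(outer(r1, r2, "+"), r3, "+") <= 1 + 1e-12
  conv <- Re(stats::fft(stats::fft(array(as.numeric(mask), d)) *
                          stats::fft(array(as.numeric(B), d)), inverse = TRUE)) / prod(d)
  array(conv > 0.5, d)
}

#' Mask centroid in world coordinates
#' @param mask logical 3-D array.
#' @param grid a `VoxelGrid`.
#' @return length-3 world mm coordinate of the mask centroid.
#' @export
mask_centroid <- function(mask, grid) {
  if (!any(mask)) stop("empty mask has no centroid")
  X <- grid_coords(grid)
  colMeans(X[as.vector(mask), , drop = FALSE])
}

# derive a reproducible 31-bit sub-seed from a master seed and string labels
derive_seed <- function(master, ...) {
  lab <- paste(c(...), collapse = "/")
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# evaluate an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
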