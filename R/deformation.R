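# Interfraction anatomy variation. The ground-truth transform T maps a
# reference-frame point to its fraction-frame position and is composed of
#   T = Rigid o Smooth o RectumScale
# where RectumScale radially inflates/deflates the rectum tube (volume ratio
# rho, with a smooth falloff into surrounding tissue), Smooth adds a
# Gaussian-filtered random vector field, and Rigid is a translation plus a
# rotation about the LR axis through the prostate centre. Fraction masks are
# exact voxelizations of the deformed analytic shapes via the inverse map.
# Both directions are stored as displacement vector fields (DVFs):
#   dvf_to_ref  (fraction grid): y + u(y) = T^{-1}(y), pulls reference data
#                                into the fraction frame (ADC transfer)
#   dvf_to_frac (reference grid): x + v(x) = T(x), pulls fraction data back
#                                to the reference frame (dose mapping)

make_transform <- function(case, spec, seed) {
  grid <- case$grid
  with_seed(seed, {
    shift <- stats::rnorm(3, 0, spec$shift_sd_mm)
    theta <- stats::rnorm(1, 0, spec$rot_sd_deg) * pi / 180
    rho <- exp(stats::rnorm(1, 0, spec$rectum_logsd))
    rho <- min(max(rho, spec$rectum_ratio_bounds[1]), spec$rectum_ratio_bounds[2])
    sfield <- NULL
    if (spec$def_amp_mm > 0) {
      sfield <- array(0, c(grid$shape, 3))
      for (a in 1:3) {
        f <- gauss_smooth3(array(stats::rnorm(n_voxels(grid)), grid$shape),
                           grid, spec$corr_len_mm / 2)
        sfield[, , , a] <- f / stats::sd(f) * spec$def_amp_mm
      }
    }
    list(shift = shift, theta = theta, rho = rho, sfield = sfield,
         center = mask_centroid(case$structures$prostate, grid),
         rect = case$shapes$rectum, grid = grid)
  })
}

transform_override <- function(tr, spec) {
  for (nm in c("shift", "theta", "rho", "focal"))
    if (!is.null(spec[[nm]])) tr[[nm]] <- spec[[nm]]
  tr
}

# --- rectum radial scaling --------------------------------------------------

rect_zscale <- function(z, rect, taper = 12) {
  # 1 inside the tube's z-range, cosine taper to 0 over `taper` mm beyond it
  below <- pmax(rect$z_range[1] - z, 0)
  above <- pmax(z - rect$z_range[2], 0)
  d <- pmin((below + above) / taper, 1)
  0.5 * (1 + cos(pi * d))
}

rect_forward <- function(pts, rect, rho, falloff_w = 12) {
  if (abs(rho - 1) < 1e-12) return(pts)
  s0 <- sqrt(rho)
  a <- rect_zscale(pts[, 3], rect)
  s <- 1 + (s0 - 1) * a
  dx <- pts[, 1] - rect$center_xy[1]
  dy <- pts[, 2] - rect$center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  r0 <- rect$radius
  rp <- ifelse(r <= r0, r * s, r + (s - 1) * r0 * exp(-((r - r0) / falloff_w)^2))
  f <- ifelse(r > 1e-9, rp / r, s)
  cbind(rect$center_xy[1] + dx * f, rect$center_xy[2] + dy * f, pts[, 3])
}

rect_inverse <- function(pts, rect, rho, falloff_w = 12) {
  if (abs(rho - 1) < 1e-12) return(pts)
  s0 <- sqrt(rho)
  a <- rect_zscale(pts[, 3], rect)
  s <- 1 + (s0 - 1) * a
  dx <- pts[, 1] - rect$center_xy[1]
  dy <- pts[, 2] - rect$center_xy[2]
  rp <- sqrt(dx^2 + dy^2)
  r0 <- rect$radius
  r <- rp / s                                  # exact if the point maps from inside
  for (it in 1:12) {
    rin <- rp / s
    rout <- rp - (s - 1) * r0 * exp(-((r - r0) / falloff_w)^2)
    r <- ifelse(rin <= r0, rin, rout)
  }
  f <- ifelse(rp > 1e-9, r / rp, 1 / s)
  cbind(rect$center_xy[1] + dx * f, rect$center_xy[2] + dy * f, pts[, 3])
}

# --- rigid component --------------------------------------------------------

rot_lr <- function(theta) {
  # rotation about the LR (x) axis
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
}

rigid_forward <- function(pts, tr) {
  q <- sweep(pts, 2, tr$center, "-") %*% t(rot_lr(tr$theta))
  sweep(q, 2, tr$center + tr$shift, "+")
}

rigid_inverse <- function(pts, tr) {
  q <- sweep(pts, 2, tr$center + tr$shift, "-") %*% rot_lr(tr$theta)
  sweep(q, 2, tr$center, "+")
}

# --- smooth field -----------------------------------------------------------

sfield_at <- function(tr, pts) {
  s <- if (is.null(tr$sfield)) matrix(0, nrow(pts), 3)
       else cbind(interp3(tr$sfield[, , , 1], tr$grid, pts),
                  interp3(tr$sfield[, , , 2], tr$grid, pts),
                  interp3(tr$sfield[, , , 3], tr$grid, pts))
  if (!is.null(tr$focal)) {
    # localized Gaussian push: a directed deformation of a sub-region
    # (e.g. displacing a lesion-bearing part of the gland)
    fc <- tr$focal
    r2 <- rowSums(sweep(pts, 2, fc$center, "-")^2) / fc$radius_mm^2
    amp <- fc$amp_mm * exp(-r2 / 2)
    dir <- fc$dir / sqrt(sum(fc$dir^2))
    s <- s + outer(amp, dir)
  }
  s
}

smooth_forward <- function(pts, tr) pts + sfield_at(tr, pts)

smooth_inverse <- function(pts, tr, iter = 8) {
  x <- pts
  for (i in seq_len(iter)) x <- pts - sfield_at(tr, x)
  x
}

transform_forward <- function(pts, tr)
  rigid_forward(smooth_forward(rect_forward(pts, tr$rect, tr$rho), tr), tr)

transform_inverse <- function(pts, tr)
  rect_inverse(smooth_inverse(rigid_inverse(pts, tr), tr), tr$rect, tr$rho)

# minimum Jacobian determinant of x -> x + v(x) by central differences
min_jacobian <- function(dvf, grid) {
  d <- dim(dvf)[1:3]
  J <- array(0, c(d - 2L, 3, 3))
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); kk <- 2:(d[3] - 1)
  for (c in 1:3) {
    v <- dvf[, , , c]
    J[, , , c, 1] <- (v[ii + 1, jj, kk] - v[ii - 1, jj, kk]) / (2 * grid$spacing[1])
    J[, , , c, 2] <- (v[ii, jj + 1, kk] - v[ii, jj - 1, kk]) / (2 * grid$spacing[2])
    J[, , , c, 3] <- (v[ii, jj, kk + 1] - v[ii, jj, kk - 1]) / (2 * grid$spacing[3])
  }
  a <- 1 + J[, , , 1, 1]; b <- J[, , , 1, 2]; cc <- J[, , , 1, 3]
  dd <- J[, , , 2, 1]; e <- 1 + J[, , , 2, 2]; f <- J[, , , 2, 3]
  g <- J[, , , 3, 1]; h <- J[, , , 3, 2]; i9 <- 1 + J[, , , 3, 3]
  det <- a * (e * i9 - f * h) - b * (dd * i9 - f * g) + cc * (dd * h - e * g)
  min(det)
}

#' Generate one fraction's anatomy-of-the-day
#'
#' Samples an interfraction transform (rigid shift and rotation, smooth random
#' deformation, rectum volume change), voxelizes the deformed organ shapes on
#' the fraction grid, transfers the reference ADC map into the fraction frame
#' (the pre-treatment ADC is assumed to determine radiosensitivity invariantly
#' over the course) and stores the ground-truth displacement vector fields in
#' both directions.
#'
#' @param case a [generate_case()] result.
#' @param k fraction index in 1..7.
#' @param spec deformation settings, see `study_config()$deformation`. May
#'   additionally carry fixed `shift` (mm), `theta` (rad) or `rho` (rectum
#'   volume ratio) entries that override the sampled values (used for
#'   engineered-fraction experiments).
#' @param seed integer seed (defaults to a sub-seed of the case seed).
#' @return an object of class `FractionAnatomy`: `k`, `grid` (frame label
#'   `fraction-k`), `structures`, `adc`, `dvf_to_ref`, `dvf_to_frac`,
#'   `rigid` (shift + rotation), `rho`.
#' @export
generate_fraction <- function(case, k, spec = case$config$deformation,
                              seed = derive_seed(case$seed, "fraction", k)) {
  stopifnot(k >= 1, k <= case$config$fractions)
  if (spec$def_amp_mm > 0 && spec$corr_len_mm <= max(case$grid$spacing))
    stop("deformation correlation length must exceed the voxel spacing")
  grid <- case$grid
  pts <- grid_coords(grid)
  for (attempt in 0:spec$max_regen) {
    tr <- make_transform(case, spec, derive_seed(seed, "try", attempt))
    tr <- transform_override(tr, spec)
    fwd <- transform_forward(pts, tr)
    dvf_to_frac <- array(fwd - pts, c(grid$shape, 3))
    if (min_jacobian(dvf_to_frac, grid) > 0) break
    if (spec$on_fold == "error" || attempt == spec$max_regen)
      stop("deformation field folds (non-positive Jacobian)")
  }
  inv <- transform_inverse(pts, tr)
  dvf_to_ref <- array(inv - pts, c(grid$shape, 3))
  fgrid <- voxel_grid(grid$shape, grid$spacing, grid$origin,
                      frame = sprintf("fraction-%d", k))
  st <- lapply(case$shapes, function(sh) array(shape_indicator(sh, inv), grid$shape))
  st$sv <- st$sv & !st$prostate
  st$rectum <- st$rectum & !st$prostate & !st$sv
  st$bladder <- st$bladder & !st$prostate & !st$sv
  bounds <- spec$rectum_ratio_bounds
  vr <- sum(st$rectum) / sum(case$structures$rectum)
  if (vr < bounds[1] - 0.05 || vr > bounds[2] + 0.05)
    stop(sprintf("fraction rectum volume ratio %.2f outside configured bounds", vr))
  adc <- transfer_adc(case$adc, dvf_to_ref, grid, st$prostate)
  structure(list(k = k, grid = fgrid, structures = st, adc = adc,
                 dvf_to_ref = dvf_to_ref, dvf_to_frac = dvf_to_frac,
                 rigid = list(shift = tr$shift, theta = tr$theta),
                 rho = tr$rho, seed = seed),
            class = "FractionAnatomy")
}

#' Generate all fractions of a treatment course
#'
#' @param case a `Case`.
#' @param spec deformation settings.
#' @param n number of fractions.
#' @return list of `FractionAnatomy`, attached to the case as `$fractions`.
#' @export
generate_fractions <- function(case, spec = case$config$deformation,
                               n = case$config$fractions) {
  case$fractions <- lapply(seq_len(n), function(k) generate_fraction(case, k, spec))
  case
}

#' Transfer the reference ADC map into a fraction frame
#'
#' Pull-back interpolation of the reference ADC along the fraction-to-reference
#' DVF: the value at fraction voxel `y` is the reference ADC at `y + u(y)`.
#' Interpolation is trilinear with nearest-neighbour fallback at the prostate
#' mask edge; the result is masked to the fraction prostate.
#'
#' @param adc reference ADC array (NA outside the reference prostate).
#' @param dvf_to_ref displacement field on the fraction grid (4-D array,
#'   last dimension LR/AP/SI components in mm).
#' @param grid the shared `VoxelGrid`.
#' @param fraction_prostate logical mask of the fraction-frame prostate.
#' @return ADC array in the fraction frame, NA outside `fraction_prostate`.
#' @export
transfer_adc <- function(adc, dvf_to_ref, grid, fraction_prostate) {
  if (!all(dim(dvf_to_ref)[1:3] == grid$shape) || dim(dvf_to_ref)[4] != 3)
    stop("DVF dimensions do not match the grid")
  idx <- which(fraction_prostate)
  pts <- grid_coords(grid)[idx, , drop = FALSE]
  u <- cbind(dvf_to_ref[, , , 1][idx], dvf_to_ref[, , , 2][idx], dvf_to_ref[, , , 3][idx])
  # prefer the generator's unmasked field: the tissue continues past the
  # delineated boundary, so rim voxels interpolate real values instead of
  # falling back to nearest-neighbour
  src <- attr(adc, "field")
  if (is.null(src)) src <- adc
  vals <- interp3(src, grid, pts + u, fill = NA_real_, na_fallback = TRUE)
  if (anyNA(vals)) vals[is.na(vals)] <- mean(vals, na.rm = TRUE)
  out <- array(NA_real_, grid$shape)
  out[idx] <- vals
  out
}

#' Warp a fraction-frame mask to the reference frame along the ground-truth DVF
#'
#' Used for generator self-consistency checks: the warped fraction prostate
#' must reproduce the reference prostate (Dice >= 0.95).
#'
#' @param mask logical array in the fraction frame.
#' @param dvf_to_frac displacement field on the reference grid.
#' @param grid the shared `VoxelGrid`.
#' @return logical array in the reference frame.
#' @export
warp_mask <- function(mask, dvf_to_frac, grid) {
  pts <- grid_coords(grid)
  v <- cbind(as.vector(dvf_to_frac[, , , 1]),
             as.vector(dvf_to_frac[, , , 2]),
             as.vector(dvf_to_frac[, , , 3]))
  vals <- interp3(array(as.numeric(mask), grid$shape), grid, pts + v, fill = 0)
  array(vals > 0.5, grid$shape)
}
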