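# Simplified deterministic dose engine. Dose is linear in the weights of a
# fixed beamlet basis: n_beams equispaced coplanar gantry directions, each
# carrying a lattice of Gaussian pencil beamlets (lateral penumbra sigma,
# default 4 mm, so the 90-10% falloff spans about 1 cm) with a mild
# exponential depth attenuation referenced to the grid entry plane. Because
# the attenuation is anatomy-independent, one influence matrix serves every
# fraction and arm of a case.

#' Closed-form dose kernel of a single beamlet
#'
#' `K(x) = exp(-mu * (s - s_min)) * exp(-r^2 / (2 sigma^2))` where `s` is the
#' depth coordinate along the beam axis and `r` the lateral distance from the
#' beamlet axis.
#'
#' @param pts `n x 3` world points (mm).
#' @param u,v,w beam unit vectors (depth, in-plane lateral, SI).
#' @param a,b beamlet lateral offsets (mm) along `v` and `w`.
#' @param s_min depth reference (mm).
#' @param sigma_mm lateral penumbra SD (mm).
#' @param mu_per_mm attenuation coefficient (1/mm).
#' @return kernel values (dimensionless; dose = weight * kernel).
#' @export
beamlet_kernel <- function(pts, u, v, w, a, b, s_min, sigma_mm, mu_per_mm) {
  s <- pts %*% u
  r2 <- (pts %*% v - a)^2 + (pts %*% w - b)^2
  as.vector(exp(-mu_per_mm * (s - s_min)) * exp(-r2 / (2 * sigma_mm^2)))
}

#' Build the beamlet dose engine for a grid and target aperture
#'
#' Assembles the sparse dose-influence matrix of all beamlets whose central
#' axes pass near the aperture structure (target plus robustness and
#' penumbra padding).
#'
#' @param grid a `VoxelGrid`.
#' @param aperture_mask logical array; beamlets are retained if their axis
#'   passes within `aperture_pad_mm` of this structure's projection.
#' @param engine_cfg engine settings, see `study_config()$engine`.
#' @return object of class `DoseEngine`: sparse influence matrix `A`
#'   (voxels x beamlets), beamlet metadata, grid.
#' @export
build_engine <- function(grid, aperture_mask, engine_cfg = study_config()$engine) {
  nb <- engine_cfg$n_beams
  del <- engine_cfg$beamlet_mm
  sig <- engine_cfg$sigma_mm
  mu <- engine_cfg$mu_per_mm
  rc <- engine_cfg$cutoff_sigma * sig
  pad <- engine_cfg$aperture_pad_mm
  X <- grid_coords(grid)
  nvox <- nrow(X)
  ap_idx <- which(as.vector(aperture_mask))
  if (!length(ap_idx)) stop("empty beamlet basis: aperture mask is empty")
  win <- ceiling(rc / del)
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  cols <- list(); ncol_tot <- 0L
  for (j in seq_len(nb)) {
    phi <- 2 * pi * (j - 1) / nb
    u <- c(cos(phi), sin(phi), 0)
    v <- c(-sin(phi), cos(phi), 0)
    p <- as.vector(X %*% v)
    q <- X[, 3]
    s <- as.vector(X %*% u)
    s_min <- min(s)
    att <- exp(-mu * (s - s_min))
    # beamlet lattice covering the aperture projection plus padding
    pa <- p[ap_idx]; qa <- q[ap_idx]
    a0 <- floor((min(pa) - pad) / del) * del
    b0 <- floor((min(qa) - pad) / del) * del
    na <- ceiling((max(pa) + pad - a0) / del) + 1L
    nbl <- ceiling((max(qa) + pad - b0) / del) + 1L
    # occupancy of the projected aperture on the lattice, dilated by pad
    occ <- matrix(FALSE, na, nbl)
    ia_ap <- pmin(pmax(round((pa - a0) / del) + 1L, 1L), na)
    ib_ap <- pmin(pmax(round((qa - b0) / del) + 1L, 1L), nbl)
    occ[cbind(ia_ap, ib_ap)] <- TRUE
    pw <- ceiling(pad / del)
    keep <- occ
    for (da in -pw:pw) for (db in -pw:pw) {
      if (da^2 + db^2 > pw^2 + 1e-9) next
      sa <- max(1, 1 - da):min(na, na - da)
      sb <- max(1, 1 - db):min(nbl, nbl - db)
      keep[sa + da, sb + db] <- keep[sa + da, sb + db] | occ[sa, sb]
    }
    colmap <- matrix(0L, na, nbl)
    kk <- which(keep)
    colmap[kk] <- seq_along(kk) + ncol_tot
    cols[[j]] <- data.frame(beam = j,
                            a = a0 + ((kk - 1L) %% na) * del,
                            b = b0 + ((kk - 1L) %/% na) * del)
    ra <- round((p - a0) / del)
    rb <- round((q - b0) / del)
    for (oa in -win:win) for (ob in -win:win) {
      ia <- ra + oa; ib <- rb + ob
      ok <- ia >= 0L & ia < na & ib >= 0L & ib < nbl
      if (!any(ok)) next
      cm <- rep(0L, nvox)
      cm[ok] <- colmap[cbind(ia[ok] + 1L, ib[ok] + 1L)]
      ok <- cm > 0L
      if (!any(ok)) next
      aa <- a0 + ia * del; bb <- b0 + ib * del
      r2 <- (p - aa)^2 + (q - bb)^2
      ok <- ok & r2 <= rc^2
      if (!any(ok)) next
      trip_i[[length(trip_i) + 1L]] <- which(ok)
      trip_j[[length(trip_j) + 1L]] <- cm[ok]
      trip_x[[length(trip_x) + 1L]] <- att[ok] * exp(-r2[ok] / (2 * sig^2))
    }
    ncol_tot <- ncol_tot + length(kk)
  }
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(nvox, ncol_tot))
  structure(list(A = A, grid = grid, beamlets = do.call(rbind, cols),
                 cfg = engine_cfg),
            class = "DoseEngine")
}

#' @export
print.DoseEngine <- function(x, ...) {
  cat(sprintf("DoseEngine: %d beams, %d beamlets, %d voxels, %.1fM nonzeros\n",
              length(unique(x$beamlets$beam)), ncol(x$A), nrow(x$A),
              Matrix::nnzero(x$A) / 1e6))
  invisible(x)
}

#' Compute the dose of a plan
#'
#' @param engine a `DoseEngine`.
#' @param weights non-negative beamlet weights (length `ncol(A)`).
#' @return physical dose array (Gy) on the engine grid.
#' @export
compute_dose <- function(engine, weights) {
  if (length(weights) != ncol(engine$A)) stop("weight length mismatch")
  if (any(weights < 0)) stop("beamlet weights must be non-negative")
  array(as.vector(engine$A %*% weights), engine$grid$shape)
}

#' Rigidly translate a dose distribution
#'
#' Evaluates `dose(x - delta)`: the dose pattern is moved by `delta` (mm),
#' emulating a couch/field translation. Values sampled from outside the grid
#' are zero.
#'
#' @param dose dose array.
#' @param grid its `VoxelGrid`.
#' @param delta length-3 translation (mm).
#' @return translated dose array.
#' @export
shift_dose <- function(dose, grid, delta) {
  if (all(abs(delta) < 1e-12)) return(dose)
  if (any(abs(delta) > (grid$shape * grid$spacing) / 3))
    stop("translation moves the beam off the dose grid")
  pts <- sweep(grid_coords(grid), 2, delta, "-")
  array(interp3(dose, grid, pts, fill = 0), grid$shape)
}

#' Recalculate a plan's dose on a fraction anatomy after rigid CTV alignment
#'
#' Simulates delivery of a conventional reference plan with the field setup
#' translated to track the fraction CTV centroid (gold-marker registration)
#' plus a sampled residual execution error. Rotations and deformations of the
#' anatomy are not compensated; this is the mechanism behind conventional
#' target misses.
#'
#' @param plan_dose total reference-plan dose array (Gy).
#' @param grid the shared `VoxelGrid`.
#' @param ctv_translation length-3 mm translation from reference CTV centroid
#'   to the fraction CTV centroid.
#' @param residual length-3 mm residual execution error (default 0).
#' @param n_fractions divide the translated dose by this to obtain the
#'   per-fraction dose (default 7).
#' @return per-fraction dose array in the fraction frame.
#' @export
recalc_with_shift <- function(plan_dose, grid, ctv_translation,
                              residual = c(0, 0, 0), n_fractions = 7L) {
  shift_dose(plan_dose, grid, ctv_translation + residual) / n_fractions
}
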