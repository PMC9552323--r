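# Plan optimization. Both arms optimize non-negative beamlet weights with
# L-BFGS-B and analytic gradients. Dose-volume quantities are handled via
# smooth sigmoid surrogates during iteration and verified exactly (voxel
# counting) afterwards; hard constraints are enforced by penalty escalation
# until the exact evaluation passes.

#' Robustness scenario set
#'
#' The nominal scenario plus axis-aligned patient setup displacements of
#' +/- the robustness distance along each of the three axes (7 scenarios).
#'
#' @param robust_distance_mm robustness distance (mm), >= 0.
#' @return list of length-3 displacement vectors (mm); the nominal zero
#'   scenario is always first.
#' @export
scenario_set <- function(robust_distance_mm) {
  stopifnot(robust_distance_mm >= 0)
  sc <- list(c(0, 0, 0))
  if (robust_distance_mm > 0) {
    for (ax in 1:3) for (sgn in c(-1, 1)) {
      d <- c(0, 0, 0); d[ax] <- sgn * robust_distance_mm
      sc[[length(sc) + 1L]] <- d
    }
  }
  sc
}

# linear-index offsets of integer-voxel scenario shifts; scenario dose at a
# voxel is the nominal dose at (voxel index + offset)
scenario_offsets <- function(scenarios, grid) {
  s3 <- grid$shape
  vapply(scenarios, function(d) {
    iv <- round(d / grid$spacing)
    as.integer(iv[1] + iv[2] * s3[1] + iv[3] * s3[1] * s3[2])
  }, integer(1))
}

relu <- function(x) pmax(x, 0)


# exact volume-at-dose (%)
vad_exact <- function(d, level) 100 * mean(d > level)

#' Planning problem description
#'
#' Collects everything one optimization needs: target and OAR voxel indices,
#' the prescription (fixed homogeneous dose or TCP maximization), rectum
#' criteria, soft near-maximum objectives and the robustness distance.
#'
#' @param case a `Case` (or equivalent list with `grid` + `structures`).
#' @param structures named list of masks to plan on (defaults to the case's
#'   reference structures; pass a fraction's structures for daily replanning).
#' @param arm one of `"Homo-conv"`, `"Homo-adap"`, `"DPBN-conv"`, `"DPBN-adap"`.
#' @param d_p prescription dose (Gy) for homogeneous arms.
#' @param config the study configuration.
#' @return list of class `PlanningProblem`.
#' @export
planning_problem <- function(case, arm, d_p = NULL,
                             structures = case$structures,
                             config = case$config) {
  workflow <- if (grepl("adap$", arm)) "adaptive" else "conventional"
  dpbn <- grepl("^DPBN", arm)
  if (!dpbn && is.null(d_p)) stop("homogeneous arms need a prescription dose d_p")
  if (dpbn && !is.null(d_p)) stop("exactly one of d_p / TCP goal may be set")
  grid <- case$grid
  mres <- margin_from_budget(build_budget(workflow, config$fractions),
                             config$margins$rounding)
  margin <- mres$reported_mm
  sv_margin <- if (workflow == "adaptive") config$margins$sv_adaptive
               else config$margins$sv_conventional
  ptv <- expand_ctv(structures$prostate, grid, margin)
  sv_ptv <- expand_ctv(structures$sv, grid, sv_margin) & !ptv
  targets <- ptv | sv_ptv
  # shells around the targets for the dose falloff objective: the allowed
  # dose cap decays with distance from the target surface
  shell_caps <- numeric(prod(grid$shape))
  prev <- targets
  ref_dose <- if (dpbn) config$prescription$d_high else d_p
  for (ring in 1:5) {
    cur <- dilate_mask(prev, grid, 3)
    shell_caps[cur & !prev] <- ref_dose * exp(-ring * 3 / 6)
    prev <- cur
  }
  outside <- !targets
  far <- outside & !prev
  shell_caps[as.vector(far)] <- ref_dose * exp(-18 / 6)
  structure(list(
    arm = arm, workflow = workflow, dpbn = dpbn, d_p = d_p,
    grid = grid, structures = structures,
    ptv = ptv, sv_ptv = sv_ptv,
    margin_mm = margin, sv_margin_mm = sv_margin,
    robust_mm = if (dpbn) margin else 0,
    rectum_criteria = config$rectum_criteria,
    oar_d2_soft = config$oar_d2_soft,
    sv_dose = config$prescription$sv_dose,
    falloff_caps = shell_caps, falloff_idx = which(as.vector(outside)),
    config = config), class = "PlanningProblem")
}

# shared exact post-check of the rectum criteria (percent points over limit)
rectum_violation <- function(dose, rectum_mask, criteria) {
  dr <- dose[rectum_mask]
  c(V33 = vad_exact(dr, 33) - criteria$V33,
    V38 = vad_exact(dr, 38) - criteria$V38,
    V41 = vad_exact(dr, 41) - criteria$V41)
}

uniform_init <- function(engine, target_idx, level) {
  w <- rep(1, ncol(engine$A))
  d <- as.vector(engine$A %*% w)
  w * level / mean(d[target_idx])
}

#' Optimize a homogeneous plan
#'
#' Target coverage is enforced as hard criteria (`D98 >= 0.95 D_p`,
#' `D2 <= 1.05 D_p` on the PTV, near-min coverage of the SV PTV) with rectum
#' volume-at-dose and near-maximum criteria as penalised objectives. The
#' optimizer reruns with boosted target weights until the exact coverage
#' check passes.
#'
#' @param problem a `PlanningProblem` with `d_p` set.
#' @param engine a `DoseEngine` on the same grid.
#' @param maxit L-BFGS-B iteration cap per round.
#' @param init optional warm-start weights.
#' @return object of class `Plan`: weights, nominal dose array, metadata.
#' @export
optimize_homogeneous <- function(problem, engine, maxit = 150L, init = NULL) {
  stopifnot(!problem$dpbn)
  dp <- problem$d_p
  tidx <- which(as.vector(problem$ptv))
  sidx <- which(as.vector(problem$sv_ptv))
  ridx <- which(as.vector(problem$structures$rectum))
  bidx <- which(as.vector(problem$structures$bladder))
  fidx <- problem$falloff_idx
  caps <- problem$falloff_caps[fidx]
  crit <- problem$rectum_criteria
  d2s <- problem$oar_d2_soft
  svd <- problem$sv_dose
  A <- engine$A
  nvox <- nrow(A)
  wt <- 1; wr <- 0.02; wf <- 0.05; w2 <- 0.004; wsv <- 0.6
  fgrad <- function(w) {
    d <- as.vector(A %*% w)
    g <- numeric(nvox)
    dt <- d[tidx]
    # uniformity + one-sided guards just inside the 0.95/1.05 band
    obj <- wt * (mean((dt - dp)^2) / dp^2 +
                 4 * mean(relu(0.97 * dp - dt)^2) / dp^2 +
                 4 * mean(relu(dt - 1.03 * dp)^2) / dp^2)
    g[tidx] <- g[tidx] + wt * (2 * (dt - dp) - 8 * relu(0.97 * dp - dt) +
                               8 * relu(dt - 1.03 * dp)) / (length(tidx) * dp^2)
    ds <- d[sidx]
    obj <- obj + wsv * mean(relu(svd - ds)^2) / svd^2
    g[sidx] <- g[sidx] - wsv * 2 * relu(svd - ds) / (length(sidx) * svd^2)
    dr <- d[ridx]
    for (lv in list(c(33, crit$V33), c(38, crit$V38), c(41, crit$V41))) {
      sg <- stats::plogis((dr - lv[1]) / 0.6)
      v <- 100 * mean(sg)
      ex <- relu(v - lv[2])
      obj <- obj + wr * ex^2
      if (ex > 0)
        g[ridx] <- g[ridx] + wr * 2 * ex * 100 * sg * (1 - sg) / (0.6 * length(ridx))
    }
    doar <- d[c(ridx, bidx)]
    obj <- obj + w2 * mean(relu(doar - d2s)^2) / d2s^2
    g[c(ridx, bidx)] <- g[c(ridx, bidx)] +
      w2 * 2 * relu(doar - d2s) / (length(doar) * d2s^2)
    df <- d[fidx]
    obj <- obj + wf * mean(relu(df - caps)^2) / dp^2
    g[fidx] <- g[fidx] + wf * 2 * relu(df - caps) / (length(fidx) * dp^2)
    list(value = obj, grad = as.vector(Matrix::crossprod(A, g)))
  }
  w <- if (is.null(init)) uniform_init(engine, tidx, dp) else init
  for (round in 1:4) {
    opt <- stats::optim(w, fn = function(w) fgrad(w)$value,
                        gr = function(w) fgrad(w)$grad,
                        method = "L-BFGS-B", lower = 0,
                        control = list(maxit = maxit, factr = 1e9))
    w <- opt$par
    d <- as.vector(A %*% w)
    dvh <- dvh_metrics(d, problem$ptv, d_levels = c(2, 98))
    ok <- dvh$D98 >= 0.95 * dp && dvh$D2 <= 1.05 * dp
    if (ok) break
    wt <- wt * 5
  }
  if (!ok) stop(sprintf(
    "homogeneous plan infeasible at D_p = %.2f Gy (D98 %.2f, D2 %.2f)",
    dp, dvh$D98, dvh$D2))
  structure(list(arm = problem$arm, weights = w,
                 dose = array(d, problem$grid$shape),
                 d_p = dp, margin_mm = problem$margin_mm,
                 robust_mm = 0, grid = problem$grid),
            class = "Plan")
}

#' Optimize a dose-painting-by-numbers plan
#'
#' Maximizes the worst-scenario TCP over the robustness scenario set
#' ('treat-to-tolerance': no upper bound on prostate voxel dose) subject to
#' hard rectum volume-at-dose constraints evaluated on the nominal scenario,
#' an SV near-minimum prescription, and soft near-maximum/falloff objectives.
#' Only the TCP objective is robust; rectum constraints are nominal.
#'
#' @param problem a `PlanningProblem` for a DPBN arm.
#' @param posterior Gleason posterior matrix for the planning prostate voxels
#'   (rows in `which(prostate_mask)` order).
#' @param engine a `DoseEngine`.
#' @param cal a `DoseResponseCalibration`.
#' @param maxit iteration cap per penalty round.
#' @param init optional warm-start weights.
#' @return object of class `Plan` (with `tcp_nominal` and the exact rectum
#'   volume-at-dose values attached).
#' @export
optimize_dpbn <- function(problem, posterior, engine, cal = default_calibration(),
                          maxit = 150L, init = NULL) {
  stopifnot(problem$dpbn)
  grid <- problem$grid
  N <- problem$config$fractions
  ab <- cal$alpha_beta
  pidx <- which(as.vector(problem$structures$prostate))
  vidx <- which(as.vector(problem$structures$sv))
  tidx <- c(pidx, vidx)
  P <- rbind(posterior, gs6_posterior(length(vidx), cal))
  vv <- voxel_volume_cc(grid) / cal$v_ref
  ridx <- which(as.vector(problem$structures$rectum))
  bidx <- which(as.vector(problem$structures$bladder))
  sidx <- which(as.vector(problem$sv_ptv | problem$structures$sv))
  fidx <- problem$falloff_idx
  caps <- problem$falloff_caps[fidx]
  crit <- problem$rectum_criteria
  limits <- c(crit$V33, crit$V38, crit$V41)
  levels <- c(33, 38, 41)
  d2s <- problem$oar_d2_soft
  svd <- problem$sv_dose
  offs <- scenario_offsets(scenario_set(problem$robust_mm), grid)
  A <- engine$A
  nvox <- nrow(A)
  k_g <- 4 * cal$categories$gamma50
  d50 <- cal$categories$d50
  tau <- 0.2
  wr <- 5; wf <- 0.4; w2 <- 0.02; wsv <- 0.4
  buf <- 0.3                      # internal surrogate headroom (pp)
  fgrad <- function(w) {
    d <- as.vector(A %*% w)
    g <- numeric(nvox)
    # robust TCP term: soft minimum of log TCP over scenarios
    ell <- numeric(length(offs))
    dlogs <- vector("list", length(offs))
    for (s in seq_along(offs)) {
      ds <- d[tidx + offs[s]]
      E <- ds * (ds / N + ab) / (2 + ab)
      dEdd <- (2 * ds / N + ab) / (2 + ab)
      m <- numeric(length(ds)); mp <- numeric(length(ds))
      for (gcat in seq_along(d50)) {
        S <- stats::plogis(k_g[gcat] * (E / d50[gcat] - 1))
        m <- m + P[, gcat] * S
        mp <- mp + P[, gcat] * k_g[gcat] / d50[gcat] * S * (1 - S)
      }
      m <- pmax(m, 1e-12)
      ell[s] <- vv * sum(log(m))
      dlogs[[s]] <- vv * mp / m * dEdd
    }
    eshift <- exp(-(ell - min(ell)) / tau)
    om <- eshift / sum(eshift)
    # smooth minimum of log TCP over scenarios (negated: we minimize)
    obj <- -(min(ell) - tau * log(sum(eshift)))
    for (s in seq_along(offs))
      g[tidx + offs[s]] <- g[tidx + offs[s]] - om[s] * dlogs[[s]]
    dr <- d[ridx]
    for (ci in 1:3) {
      sg <- stats::plogis((dr - levels[ci]) / 0.6)
      v <- 100 * mean(sg)
      ex <- relu(v - (limits[ci] - buf))
      obj <- obj + wr * ex^2
      if (ex > 0)
        g[ridx] <- g[ridx] + wr * 2 * ex * 100 * sg * (1 - sg) / (0.6 * length(ridx))
    }
    ds2 <- d[sidx]
    obj <- obj + wsv * mean(relu(svd - ds2)^2) / svd^2
    g[sidx] <- g[sidx] - wsv * 2 * relu(svd - ds2) / (length(sidx) * svd^2)
    doar <- d[c(ridx, bidx)]
    obj <- obj + w2 * mean(relu(doar - d2s)^2) / d2s^2
    g[c(ridx, bidx)] <- g[c(ridx, bidx)] +
      w2 * 2 * relu(doar - d2s) / (length(doar) * d2s^2)
    df <- d[fidx]
    obj <- obj + wf * mean(relu(df - caps)^2) / 50^2
    g[fidx] <- g[fidx] + wf * 2 * relu(df - caps) / (length(fidx) * 50^2)
    list(value = obj, grad = as.vector(Matrix::crossprod(A, g)))
  }
  w <- if (is.null(init)) uniform_init(engine, pidx, 50) else init
  viol <- NULL
  for (round in 1:6) {
    opt <- stats::optim(w, fn = function(w) fgrad(w)$value,
                        gr = function(w) fgrad(w)$grad,
                        method = "L-BFGS-B", lower = 0,
                        control = list(maxit = maxit, factr = 1e9))
    w <- opt$par
    d <- as.vector(A %*% w)
    viol <- rectum_violation(array(d, grid$shape), problem$structures$rectum, crit)
    if (all(viol <= 0)) break
    wr <- wr * 6
    maxit <- 80L
  }
  if (any(viol > 0)) stop(sprintf(
    "DPBN rectum constraints unsatisfiable; binding constraint %s exceeds limit by %.2f pp",
    names(viol)[which.max(viol)], max(viol)))
  dose <- array(d, grid$shape)
  eqd2 <- eqd2_convert(dose, N, ab)
  tcp <- compute_tcp(eqd2, posterior, problem$structures$prostate,
                     problem$structures$sv, grid, cal)
  structure(list(arm = problem$arm, weights = w, dose = dose,
                 d_p = NULL, margin_mm = problem$margin_mm,
                 robust_mm = problem$robust_mm, tcp_nominal = tcp,
                 rectum_vad = c(V33 = vad_exact(d[ridx], 33),
                                V38 = vad_exact(d[ridx], 38),
                                V41 = vad_exact(d[ridx], 41)),
                 grid = problem$grid),
            class = "Plan")
}

#' @export
print.Plan <- function(x, ...) {
  if (is.null(x$d_p))
    cat(sprintf("Plan [%s]: DPBN, robust %g mm, nominal TCP %.3f, rectum V33/V38/V41 = %.1f/%.1f/%.1f%%\n",
                x$arm, x$robust_mm, x$tcp_nominal,
                x$rectum_vad[1], x$rectum_vad[2], x$rectum_vad[3]))
  else
    cat(sprintf("Plan [%s]: homogeneous D_p = %.2f Gy, margin %g mm\n",
                x$arm, x$d_p, x$margin_mm))
  invisible(x)
}

#' The homogeneous prescription dose ladder
#'
#' @param config a `study_config`.
#' @return vector of prescription doses (Gy), 43.89 to 60.89 in 1-Gy steps
#'   by default.
#' @export
dose_ladder <- function(config = study_config()) {
  p <- config$prescription
  seq(p$d_low, p$d_high, by = p$d_step)
}
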