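#' Dose-response calibration
#'
#' The tumor control model is a voxel-product TCP: each voxel carries a
#' posterior over Gleason score categories inferred from its ADC value, each
#' category has a control-probability curve as a function of EQD2 calibrated
#' at a reference volume `v_ref`, and the voxel control probability is the
#' posterior mixture of category curves raised to `v_voxel / v_ref`. The TCP
#' of a target is the product of its voxel control probabilities.
#'
#' Category curves are logistic in EQD2,
#' `S_g(E) = 1 / (1 + exp(4 * gamma50 * (1 - E / D50)))`,
#' with `D50` increasing with Gleason category (higher grade, more resistant).
#' The ADC-to-Gleason mapping is an ordinal logistic ('low precision')
#' mapping: `P(GS >= g | ADC) = plogis((c_g - ADC) / width)` with decreasing
#' cutpoints `c_g`, so low ADC implies high probability of high Gleason score.
#'
#' The shipped default calibration is anchored so that a pure-GS6 volume at
#' the EQD2 of 43.89 Gy in 7 fractions (91.6 Gy_1.93) has a control
#' probability above 99% at seminal-vesicle volumes, and so that prescription
#' doses in the 44-61 Gy range put GS6-dominated targets in the high-90s TCP
#' regime with a flattening dose-response at the upper end.
#'
#' @param path optional YAML calibration file (see
#'   `system.file("extdata", "calibration_default.yaml", package = "dpaintsim")`
#'   for the schema). Default returns the shipped calibration.
#' @return object of class `DoseResponseCalibration`.
#' @export
default_calibration <- function(path = NULL) {
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cal <- structure(list(
      alpha_beta = y$alpha_beta, v_ref = y$v_ref,
      categories = data.frame(
        name = vapply(y$categories, `[[`, "", "name"),
        d50 = vapply(y$categories, `[[`, 0, "d50"),
        gamma50 = vapply(y$categories, `[[`, 0, "gamma50")),
      adc_mapping = list(cutpoints = as.numeric(y$adc_mapping$cutpoints),
                         width = y$adc_mapping$width)
    ), class = "DoseResponseCalibration")
  } else {
    cal <- structure(list(
      alpha_beta = 1.93,
      v_ref = 1.0,                       # cm^3 at which category curves apply
      categories = data.frame(
        name = c("GS6", "GS7", "GS8", "GS9"),
        d50 = c(48, 60, 70, 80),        # EQD2 Gy for 50% control of v_ref
        gamma50 = c(2.5, 2.5, 2.5, 2.5)),
      adc_mapping = list(cutpoints = c(900, 750, 600),  # 1e-6 mm^2/s
                         width = 80)
    ), class = "DoseResponseCalibration")
  }
  validate_calibration(cal)
  cal
}

validate_calibration <- function(cal) {
  stopifnot(cal$alpha_beta > 0, cal$v_ref > 0,
            nrow(cal$categories) >= 2,
            length(cal$adc_mapping$cutpoints) == nrow(cal$categories) - 1)
  if (is.unsorted(cal$categories$d50))
    stop("category D50 must be non-decreasing with Gleason category")
  if (is.unsorted(rev(cal$adc_mapping$cutpoints)))
    stop("ADC cutpoints must decrease with Gleason category")
  # ordering invariant: lower-risk curve >= higher-risk curve at every dose
  E <- seq(0, 200, by = 2)
  S <- control_curves(E, cal)
  if (any(diff(t(S)) > 1e-12))
    stop("control curves are not ordered by risk category")
  invisible(cal)
}

#' Write a calibration to YAML
#' @param cal a `DoseResponseCalibration`.
#' @param path output file.
#' @export
write_calibration <- function(cal, path) {
  y <- list(alpha_beta = cal$alpha_beta, v_ref = cal$v_ref,
            categories = lapply(seq_len(nrow(cal$categories)), function(i)
              as.list(cal$categories[i, ])),
            adc_mapping = cal$adc_mapping)
  yaml::write_yaml(y, path)
  invisible(path)
}

# category control curves at EQD2 values; returns length(E) x n_categories
control_curves <- function(eqd2, cal) {
  k <- 4 * cal$categories$gamma50
  d50 <- cal$categories$d50
  S <- matrix(0, length(eqd2), length(d50))
  for (g in seq_along(d50)) S[, g] <- stats::plogis(k[g] * (eqd2 / d50[g] - 1))
  S
}

# derivative of the control curves w.r.t. EQD2
control_curves_deriv <- function(eqd2, cal) {
  k <- 4 * cal$categories$gamma50
  d50 <- cal$categories$d50
  S <- control_curves(eqd2, cal)
  for (g in seq_along(d50)) S[, g] <- k[g] / d50[g] * S[, g] * (1 - S[, g])
  S
}

#' EQD2 conversion under the linear-quadratic model
#'
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)` with fraction dose
#' `d = D / N`. Applied voxel-wise when `D` is a map.
#'
#' @param D total physical dose (Gy), scalar or array.
#' @param N number of fractions (>= 1).
#' @param alpha_beta alpha/beta ratio in Gy (default 1.93).
#' @return EQD2 in Gy, same shape as `D`.
#' @export
eqd2_convert <- function(D, N, alpha_beta = 1.93) {
  if (length(N) != 1 || N < 1) stop("N must be a single integer >= 1")
  if (alpha_beta <= 0) stop("alpha/beta must be > 0")
  if (any(D < 0)) stop("dose must be non-negative")
  D * (D / N + alpha_beta) / (2 + alpha_beta)
}

#' Map ADC values to a Gleason-score posterior
#'
#' Ordinal-logistic 'low precision' mapping: low ADC voxels carry high
#' probability of high Gleason categories; the expected Gleason score is
#' non-increasing in ADC.
#'
#' @param adc positive ADC values (1e-6 mm^2/s), vector.
#' @param cal a `DoseResponseCalibration`.
#' @return `length(adc) x n_categories` matrix of class `GleasonPosterior`;
#'   rows sum to 1.
#' @export
adc_to_gleason <- function(adc, cal = default_calibration()) {
  adc <- as.numeric(adc)
  if (anyNA(adc) || any(adc <= 0)) stop("ADC values must be positive and non-missing")
  cp <- cal$adc_mapping$cutpoints
  w <- cal$adc_mapping$width
  nc <- nrow(cal$categories)
  Pge <- matrix(0, length(adc), nc)
  Pge[, 1] <- 1
  for (g in 2:nc) Pge[, g] <- stats::plogis((cp[g - 1] - adc) / w)
  P <- Pge - cbind(Pge[, -1, drop = FALSE], 0)
  colnames(P) <- cal$categories$name
  structure(P, class = c("GleasonPosterior", "matrix"))
}

# degenerate posterior on the lowest-risk category (used for SV voxels,
# which have no ADC information)
gs6_posterior <- function(n, cal) {
  P <- matrix(0, n, nrow(cal$categories))
  P[, 1] <- 1
  colnames(P) <- cal$categories$name
  P
}

#' Voxel control probability
#'
#' `p = [sum_g P(g | ADC) * S_g(EQD2)] ^ (v_voxel / v_ref)`: the voxel is
#' treated as a single lesion of uncertain grade (mixture first, volume
#' exponent second).
#'
#' @param eqd2 EQD2 values (Gy), vector.
#' @param posterior matrix of category probabilities (rows match `eqd2`).
#' @param voxel_volume voxel volume in cm^3 (scalar or vector).
#' @param cal a `DoseResponseCalibration`.
#' @return control probabilities in `[0, 1]`.
#' @export
voxel_control_prob <- function(eqd2, posterior, voxel_volume,
                               cal = default_calibration()) {
  if (any(eqd2 < 0)) stop("EQD2 must be non-negative")
  posterior <- matrix(posterior, ncol = nrow(cal$categories))
  if (abs(sum(posterior[1, ]) - 1) > 1e-6) stop("posterior rows must sum to 1")
  S <- control_curves(as.numeric(eqd2), cal)
  m <- rowSums(posterior * S)
  pmin(pmax(m, 0), 1)^(voxel_volume / cal$v_ref)
}

#' Tumor control probability of a target from an EQD2 map
#'
#' Product over prostate and SV voxels of the voxel control probabilities.
#' Prostate voxels use the ADC-derived Gleason posterior; SV voxels have no
#' ADC and are assigned a degenerate GS6 (lowest risk) posterior.
#'
#' @param eqd2_map EQD2 array (Gy) on `grid`.
#' @param posterior `GleasonPosterior` matrix for the prostate voxels, in
#'   `which(prostate_mask)` order.
#' @param prostate_mask,sv_mask logical arrays on `grid`.
#' @param grid a `VoxelGrid`.
#' @param cal a `DoseResponseCalibration`.
#' @return TCP in `[0, 1]`.
#' @export
compute_tcp <- function(eqd2_map, posterior, prostate_mask, sv_mask, grid,
                        cal = default_calibration()) {
  npro <- sum(prostate_mask)
  if (npro + sum(sv_mask) == 0) stop("empty target")
  if (!is.null(posterior) && nrow(posterior) != npro)
    stop("posterior rows must match prostate voxel count")
  vv <- voxel_volume_cc(grid)
  lt <- 0
  if (npro > 0) {
    p <- voxel_control_prob(eqd2_map[prostate_mask], posterior, vv, cal)
    lt <- lt + sum(log(pmax(p, 1e-300)))
  }
  nsv <- sum(sv_mask)
  if (nsv > 0) {
    p <- voxel_control_prob(eqd2_map[sv_mask], gs6_posterior(nsv, cal), vv, cal)
    lt <- lt + sum(log(pmax(p, 1e-300)))
  }
  exp(lt)
}

#' Fraction-specific TCP
#'
#' TCP of a single fraction as if it were delivered for the entire treatment:
#' the per-fraction physical dose is scaled by `N`, converted to EQD2 with
#' `N` fractions, and evaluated with [compute_tcp()] on the fraction's own
#' anatomy.
#'
#' @param fraction_dose per-fraction physical dose array (Gy).
#' @param N number of fractions in the full course.
#' @param posterior Gleason posterior of the (fraction-frame) prostate voxels.
#' @param prostate_mask,sv_mask fraction-frame target masks.
#' @param grid the `VoxelGrid`.
#' @param cal a `DoseResponseCalibration`.
#' @return TCP in `[0, 1]`.
#' @export
fraction_tcp <- function(fraction_dose, N, posterior, prostate_mask, sv_mask,
                         grid, cal = default_calibration()) {
  eqd2 <- eqd2_convert(fraction_dose * N, N, cal$alpha_beta)
  compute_tcp(eqd2, posterior, prostate_mask, sv_mask, grid, cal)
}
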