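#' Uncertainty budgets for the two treatment workflows
#'
#' Named 1-mm-scale SD components split into systematic (Sigma, preparation
#' errors) and random (sigma, daily execution variations) groups. Both
#' workflows carry intrafraction motion, interobserver delineation and
#' machine-precision components (1 mm SD each). The conventional workflow
#' additionally carries the residual interfraction prostate deformation and
#' the combined image-registration/table-translation uncertainty (1 mm SD
#' each); in the adaptive workflow those are removed by daily redelineation.
#'
#' The systematic/random split (not uniquely determined by the component
#' list) defaults to: adaptive - all three components random, since daily
#' redelineation turns the delineation error into a per-fraction error;
#' conventional - delineation, deformation residual and registration/table
#' systematic, intrafraction and machine random. This is the split that
#' reproduces the 3 mm / 6 mm margins under ceiling rounding.
#'
#' @param workflow `"conventional"` or `"adaptive"`.
#' @param N number of fractions (default 7).
#' @return object of class `UncertaintyBudget`: a data.frame of components
#'   (`name`, `sd_mm`, `class`) with attributes `workflow` and `N`.
#' @export
build_budget <- function(workflow = c("conventional", "adaptive"), N = 7L) {
  workflow <- match.arg(workflow)
  comp <- data.frame(
    name = c("intrafraction", "delineation", "machine"),
    sd_mm = 1,
    class = if (workflow == "adaptive") "random"
            else c("random", "systematic", "random"),
    stringsAsFactors = FALSE)
  if (workflow == "conventional") {
    comp <- rbind(comp, data.frame(
      name = c("deformation_residual", "registration_table"),
      sd_mm = 1, class = "systematic", stringsAsFactors = FALSE))
  }
  structure(comp, workflow = workflow, N = as.integer(N),
            class = c("UncertaintyBudget", "data.frame"))
}

# quadrature sums of the systematic / random groups
budget_sigmas <- function(budget) {
  Sig <- sqrt(sum(budget$sd_mm[budget$class == "systematic"]^2))
  sig <- sqrt(sum(budget$sd_mm[budget$class == "random"]^2))
  c(Sigma = Sig, sigma = sig)
}

#' Effective uncertainty components for a finite number of fractions
#'
#' `Sigma_eff^2 = Sigma^2 + sigma^2 / N` and
#' `sigma_eff^2 = sigma^2 * (1 - 1/N)`: with few fractions, part of the
#' random execution variation does not average out and acts systematically.
#'
#' @param Sigma systematic SD (mm).
#' @param sigma random SD (mm).
#' @param N number of fractions (>= 1).
#' @return named vector `c(Sigma_eff, sigma_eff)` in mm.
#' @export
effective_components <- function(Sigma, sigma, N) {
  if (length(N) != 1 || N < 1) stop("N must be a single integer >= 1")
  stopifnot(Sigma >= 0, sigma >= 0)
  Sigma <- unname(Sigma); sigma <- unname(sigma)
  c(Sigma_eff = sqrt(Sigma^2 + sigma^2 / N),
    sigma_eff = sqrt(sigma^2 * (1 - 1 / N)))
}

#' van Herk margin
#'
#' `M = 2.5 * Sigma_eff + 0.7 * sigma_eff` (mm).
#'
#' @param Sigma_eff,sigma_eff effective SDs in mm.
#' @return margin in mm (not rounded).
#' @export
margin_mm <- function(Sigma_eff, sigma_eff) {
  stopifnot(Sigma_eff >= 0, sigma_eff >= 0)
  2.5 * Sigma_eff + 0.7 * sigma_eff
}

#' Margin from an uncertainty budget
#'
#' Combines the budget's quadrature sums, the effective components for its
#' fraction number, and the van Herk recipe; reports the margin under the
#' configured rounding policy (default: ceiling to integer mm, clinically
#' conservative).
#'
#' @param budget an `UncertaintyBudget`.
#' @param rounding `"ceiling"`, `"round"` or `"none"`.
#' @return object of class `MarginResult`: list with `Sigma_eff`,
#'   `sigma_eff`, `raw_mm`, `reported_mm`.
#' @export
margin_from_budget <- function(budget, rounding = "ceiling") {
  s <- budget_sigmas(budget)
  eff <- effective_components(s["Sigma"], s["sigma"], attr(budget, "N"))
  raw <- margin_mm(eff["Sigma_eff"], eff["sigma_eff"])
  rep <- switch(rounding,
                ceiling = ceiling(raw), round = round(raw), none = raw,
                stop("unknown rounding policy: ", rounding))
  structure(list(Sigma_eff = unname(eff["Sigma_eff"]),
                 sigma_eff = unname(eff["sigma_eff"]),
                 raw_mm = unname(raw), reported_mm = unname(rep),
                 workflow = attr(budget, "workflow")),
            class = "MarginResult")
}

#' @export
print.MarginResult <- function(x, ...) {
  cat(sprintf("%s margin: Sigma_eff %.3f mm, sigma_eff %.3f mm, raw %.3f mm -> %g mm\n",
              x$workflow, x$Sigma_eff, x$sigma_eff, x$raw_mm, x$reported_mm))
  invisible(x)
}

#' Expand a CTV mask to a PTV
#'
#' Morphological dilation with an (an)isotropic ellipsoidal structuring
#' element in physical millimetres (voxel-centre inclusion semantics).
#'
#' @param mask logical CTV array.
#' @param grid a `VoxelGrid`.
#' @param margin scalar isotropic margin, or length-3 `(LR, AP, SI)` mm.
#' @return logical PTV array (always a superset of the CTV).
#' @export
expand_ctv <- function(mask, grid, margin) {
  dilate_mask(mask, grid, margin)
}
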