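#' Study arm specification
#'
#' @param arm one of `"Homo-conv"`, `"Homo-adap"`, `"DPBN-conv"`,
#'   `"DPBN-adap"`.
#' @param d_p prescription dose (Gy) for the homogeneous arms.
#' @return list of class `ArmSpec` with the workflow label and prescription.
#' @export
arm_spec <- function(arm = c("Homo-conv", "Homo-adap", "DPBN-conv", "DPBN-adap"),
                     d_p = NULL) {
  arm <- match.arg(arm)
  dpbn <- grepl("^DPBN", arm)
  if (!dpbn && is.null(d_p)) stop("homogeneous arms need d_p")
  structure(list(arm = arm, dpbn = dpbn,
                 workflow = if (grepl("adap$", arm)) "adaptive" else "conventional",
                 d_p = d_p), class = "ArmSpec")
}

#' Sample rigid execution errors for a treatment course
#'
#' Systematic (preparation) components are drawn once per course; random
#' (execution) components are drawn independently per fraction. Each
#' component contributes an independent Gaussian per axis with its budget SD.
#'
#' @param budget an `UncertaintyBudget`.
#' @param seed integer seed.
#' @param n_fractions number of fractions (default the budget's `N`).
#' @return `n_fractions x 3` matrix of displacements (mm); the per-course
#'   systematic part is attached as attribute `"systematic"`.
#' @export
sample_execution_error <- function(budget, seed, n_fractions = attr(budget, "N")) {
  sds <- budget_sigmas(budget)
  with_seed(seed, {
    sys <- stats::rnorm(3, 0, sds["Sigma"])
    rnd <- matrix(stats::rnorm(3 * n_fractions, 0, sds["sigma"]),
                  n_fractions, 3, byrow = TRUE)
    out <- sweep(rnd, 2, sys, "+")
    attr(out, "systematic") <- sys
    out
  })
}

# residual delivery budget: the explicitly simulated anatomy already carries
# the interfraction deformation, so its residual component is excluded from
# the sampled delivery errors (it would otherwise be counted twice)
delivery_budget <- function(workflow, N) {
  b <- build_budget(workflow, N)
  structure(b[b$name != "deformation_residual", ],
            workflow = workflow, N = attr(b, "N"),
            class = class(b))
}

#' Simulate a full treatment course for one arm
#'
#' Conventional arms optimize one reference plan on the reference anatomy
#' and deliver it on each fraction via rigid CTV-centroid translation
#' (gold-marker alignment) plus a sampled residual error; anatomy rotations
#' and deformations are not compensated. Adaptive arms re-optimize on each
#' fraction's anatomy-of-the-day (with the ADC map transferred to that
#' fraction) and deliver with the smaller adaptive residual errors. If a
#' daily optimization fails, the previous day's plan is delivered and the
#' failure is recorded in `$fallbacks`.
#'
#' @param case a `Case` with generated fractions (see [generate_fractions()]).
#' @param arm an `ArmSpec` or arm name.
#' @param engine optional pre-built `DoseEngine` (built from the case if
#'   missing).
#' @param cal a `DoseResponseCalibration`.
#' @param seed integer seed for the sampled execution errors.
#' @param d_p prescription dose if `arm` is a homogeneous arm name.
#' @return object of class `CourseResult`: per-fraction delivered doses
#'   (fraction frame, per-fraction scale), plans, residual errors, fraction
#'   anatomies.
#' @export
simulate_course <- function(case, arm, engine = NULL,
                            cal = default_calibration(),
                            seed = derive_seed(case$seed, "course", if (is.character(arm)) arm else arm$arm),
                            d_p = NULL) {
  if (is.character(arm)) arm <- arm_spec(arm, d_p)
  cfg <- case$config
  N <- cfg$fractions
  if (length(case$fractions) != N) stop("case must carry ", N, " generated fractions")
  if (is.null(engine)) engine <- case_engine(case)
  residuals <- if (isTRUE(cfg$sample_residuals))
    sample_execution_error(delivery_budget(arm$workflow, N), derive_seed(seed, "resid"))
  else matrix(0, N, 3)
  ref_ctv <- mask_centroid(case$structures$prostate, case$grid)
  plans <- list(); doses <- list(); fallbacks <- integer()
  if (arm$workflow == "conventional") {
    plan <- plan_for(case, arm, case$structures, engine, cal, d_p = arm$d_p)
    for (k in seq_len(N)) {
      fr <- case$fractions[[k]]
      tr <- mask_centroid(fr$structures$prostate, case$grid) - ref_ctv
      doses[[k]] <- recalc_with_shift(plan$dose, case$grid, tr,
                                      residuals[k, ], N)
    }
    plans <- list(plan)
  } else {
    prev <- NULL
    for (k in seq_len(N)) {
      fr <- case$fractions[[k]]
      pk <- tryCatch(
        plan_for(case, arm, fr$structures, engine, cal, d_p = arm$d_p,
                 adc = fr$adc, init = if (!is.null(prev)) prev$weights),
        error = function(e) NULL)
      if (is.null(pk)) {
        if (is.null(prev)) stop("adaptive planning failed on fraction 1")
        fallbacks <- c(fallbacks, k)
        pk <- prev
      }
      plans[[k]] <- pk
      doses[[k]] <- shift_dose(pk$dose, case$grid, residuals[k, ]) / N
      prev <- pk
    }
  }
  structure(list(case_id = case$id, arm = arm$arm, workflow = arm$workflow,
                 grid = case$grid, plans = plans, plan = plans[[1]],
                 fraction_doses = doses, residuals = residuals,
                 fractions = case$fractions,
                 case_structures = case$structures,
                 fallbacks = fallbacks, config = cfg),
            class = "CourseResult")
}

# build a plan for the requested arm on the given (reference or daily)
# structures; DPBN plans use the ADC of the same frame
plan_for <- function(case, arm, structures, engine, cal, d_p = NULL, adc = NULL,
                     init = NULL) {
  problem <- planning_problem(case, arm$arm, d_p = if (arm$dpbn) NULL else d_p,
                              structures = structures)
  if (arm$dpbn) {
    if (is.null(adc)) adc <- case$adc
    post <- adc_to_gleason(adc[structures$prostate], cal)
    optimize_dpbn(problem, post, engine, cal,
                  maxit = if (is.null(init)) 150L else 60L, init = init)
  } else {
    optimize_homogeneous(problem, engine,
                         maxit = if (is.null(init)) 150L else 60L, init = init)
  }
}

#' Build the dose engine for a case
#'
#' The beamlet aperture covers the reference prostate and SV expanded by the
#' configured padding, which also accommodates the daily anatomies.
#'
#' @param case a `Case`.
#' @return a `DoseEngine`.
#' @export
case_engine <- function(case) {
  ap <- case$structures$prostate | case$structures$sv
  build_engine(case$grid, ap, case$config$engine)
}

#' @export
print.CourseResult <- function(x, ...) {
  cat(sprintf("CourseResult %s / %s: %d fractions%s\n", x$case_id, x$arm,
              length(x$fraction_doses),
              if (length(x$fallbacks)) paste0(", fallbacks at ",
                                              paste(x$fallbacks, collapse = ","))
              else ""))
  invisible(x)
}

#' Engineered target-miss experiment
#'
#' Constructs a single fraction whose prostate rotation plus a focal
#' deformation move the first (high-Gleason) ADC lesion beyond the
#' conventional 6 mm margin, delivers the conventional DPBN reference plan
#' via rigid CTV-centroid recalculation, re-plans adaptively on the same
#' anatomy, and compares the fraction-specific TCPs (fraction doses scaled
#' to a full course). This isolates the target-miss mechanism of the
#' conventional workflow; no residual errors are sampled.
#'
#' @param case a `Case`.
#' @param rotation_deg prostate rotation about the LR axis (degrees).
#' @param push_mm amplitude of the focal deformation at the lesion (mm).
#' @param push_radius_mm Gaussian radius of the focal deformation (mm).
#' @param cal a `DoseResponseCalibration`.
#' @return list with `tcp_conventional`, `tcp_adaptive`, `diff_pp` (their
#'   difference in percentage points) and the engineered `fraction`.
#' @export
target_miss_experiment <- function(case, rotation_deg = 30, push_mm = 15,
                                   push_radius_mm = 20,
                                   cal = default_calibration()) {
  les <- attr(case$adc, "lesions")
  if (!length(les)) stop("case has no ADC lesion to displace")
  spec <- case$config$deformation
  spec$theta <- rotation_deg * pi / 180
  spec$shift <- c(0, 0, 0)
  spec$rho <- 1
  spec$focal <- list(center = les[[1]]$center, dir = c(0, -0.6, -0.8),
                     amp_mm = push_mm, radius_mm = push_radius_mm)
  fr <- generate_fraction(case, 5, spec)
  N <- case$config$fractions
  # aperture must cover both the planning and the engineered anatomy
  ap <- case$structures$prostate | case$structures$sv |
    fr$structures$prostate | fr$structures$sv
  engine <- build_engine(case$grid, ap, case$config$engine)
  post_ref <- adc_to_gleason(case$adc[case$structures$prostate], cal)
  plan_c <- optimize_dpbn(planning_problem(case, "DPBN-conv"), post_ref,
                          engine, cal)
  trn <- mask_centroid(fr$structures$prostate, case$grid) -
    mask_centroid(case$structures$prostate, case$grid)
  d_conv <- recalc_with_shift(plan_c$dose, case$grid, trn, n_fractions = N)
  post_fr <- adc_to_gleason(fr$adc[fr$structures$prostate], cal)
  tcp_conv <- fraction_tcp(d_conv, N, post_fr, fr$structures$prostate,
                           fr$structures$sv, case$grid, cal)
  plan_a <- optimize_dpbn(planning_problem(case, "DPBN-adap",
                                           structures = fr$structures),
                          post_fr, engine, cal)
  tcp_adap <- fraction_tcp(plan_a$dose / N, N, post_fr,
                           fr$structures$prostate, fr$structures$sv,
                           case$grid, cal)
  list(tcp_conventional = tcp_conv, tcp_adaptive = tcp_adap,
       diff_pp = 100 * (tcp_adap - tcp_conv), fraction = fr)
}
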