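#' Default study configuration
#'
#' Returns the full configuration of the simulation study: phantom geometry
#' ranges, ADC field and lesion statistics, the interfraction deformation
#' model, uncertainty budgets, prescriptions and organ-at-risk criteria.
#' All values can be overridden via `modifyList()`-style nested lists, or
#' round-tripped through YAML with [read_study_config()] /
#' [write_study_config()].
#'
#' @param ... named nested lists merged over the defaults.
#' @return a nested list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    grid = list(shape = c(44L, 44L, 36L), spacing = c(3, 3, 3)),
    geometry = list(
      prostate_volume_cc = c(30, 60),
      prostate_base_semi = c(21, 18, 19),   # LR/AP/SI template semi-axes, mm
      rectum_radius_mm   = c(11, 14),
      rectum_gap_mm      = 4,
      rectum_z_range_mm  = c(-48, 42),
      sv_semi            = c(9, 11, 12),
      sv_x_offset_mm     = 14,
      sv_y_offset_mm     = 12,
      sv_z_offset_mm     = 8,
      bladder_center_mm  = c(0, -20, 30),
      bladder_semi_mm    = c(32, 27, 24)
    ),
    adc = list(
      mean = 1100, sd = 140,                # 1e-6 mm^2/s, background field
      corr_len_mm = 12,
      floor = 100,
      lesions = list(count_range = c(1L, 3L),
                     radius_mm = c(4, 9),
                     depth = 0.4,            # fractional ADC suppression at core
                     center_frac = 0.55)     # radial placement within prostate
    ),
    deformation = list(
      shift_sd_mm = c(1.5, 2.5, 2.5),
      rot_sd_deg = 1.5,
      def_amp_mm = 2,
      corr_len_mm = 25,
      rectum_logsd = 0.2,
      rectum_ratio_bounds = c(0.5, 2.2),
      on_fold = "regenerate",                # or "error"
      max_regen = 3L
    ),
    fractions = 7L,
    alpha_beta = 1.93,
    prescription = list(
      d_low = 43.89, d_high = 60.89, d_step = 1,
      sv_dose = 43.89
    ),
    rectum_criteria = list(V33 = 30, V38 = 15, V41 = 10),  # % limits
    oar_d2_soft = 42.7,
    margins = list(
      sv_adaptive = c(5, 7, 7), sv_conventional = c(6, 9, 9),  # LR/AP/SI mm
      rounding = "ceiling"
    ),
    engine = list(
      n_beams = 7L, beamlet_mm = 6, sigma_mm = 4, mu_per_mm = 0.004,
      cutoff_sigma = 2.5, aperture_pad_mm = 15
    ),
    sample_residuals = TRUE
  )
  ov <- list(...)
  if (length(ov)) cfg <- utils::modifyList(cfg, ov)
  class(cfg) <- c("study_config", "list")
  cfg
}

#' Read / write a study configuration as YAML
#' @param path file path.
#' @return `read_study_config()` returns a `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(study_config, cfg)
}

#' @rdname read_study_config
#' @param cfg a `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
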