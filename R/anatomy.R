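#' Synthetic reference anatomy and ADC maps
#'
#' A `Case` is the unit of study: one reference pelvic anatomy (labelled
#' masks on a voxel grid) combined with one realistic prostate ADC map.
#' Masks are voxel-centre inclusions of simple parametric organ shapes:
#' an ellipsoidal prostate CTV, paired seminal-vesicle (SV) lobes
#' superior-posterior, a tubular rectum posterior to the prostate, and an
#' ellipsoidal bladder superior-anterior. OAR masks are cropped against the
#' target structures so that no voxel is both target and OAR.
#'
#' @param config a [study_config()].
#' @param seed integer master seed; the same `(config, seed)` pair yields a
#'   bit-identical case.
#' @param id case identifier string.
#' @return an object of class `Case` with elements `grid`, `structures`
#'   (named list of logical arrays: prostate, sv, rectum, bladder), `adc`
#'   (array, NA outside the prostate), `shapes` (analytic shape parameters)
#'   and `id`.
#' @export
generate_case <- function(config = study_config(), seed = 1L, id = NULL) {
  grid <- voxel_grid(config$grid$shape, config$grid$spacing)
  shapes <- sample_shapes(config$geometry, derive_seed(seed, "shapes"))
  pts <- grid_coords(grid)
  prostate <- voxelize_shape(shapes$prostate, grid, pts)
  sv <- voxelize_shape(shapes$sv, grid, pts)
  rectum <- voxelize_shape(shapes$rectum, grid, pts)
  bladder <- voxelize_shape(shapes$bladder, grid, pts)
  # targets take precedence; OARs must not intersect the CTVs
  sv <- sv & !prostate
  rectum <- rectum & !prostate & !sv
  bladder <- bladder & !prostate & !sv
  st <- list(prostate = prostate, sv = sv, rectum = rectum, bladder = bladder)
  for (nm in names(st)) if (!any(st[[nm]]))
    stop("infeasible geometry: required structure '", nm, "' is empty")
  if (any(prostate & rectum)) stop("infeasible geometry: prostate intersects rectum")
  adc <- generate_adc_map(grid, prostate, config$adc, derive_seed(seed, "adc"))
  if (is.null(id)) id <- sprintf("case-%d", seed)
  structure(list(id = id, grid = grid, structures = st, adc = adc,
                 shapes = shapes, config = config, seed = seed),
            class = "Case")
}

#' @export
print.Case <- function(x, ...) {
  vol <- vapply(x$structures, function(m) sum(m) * voxel_volume_cc(x$grid), 0)
  cat(sprintf("Case %s: prostate %.1f cm^3, SV %.1f, rectum %.1f, bladder %.1f; ADC mean %.0f\n",
              x$id, vol["prostate"], vol["sv"], vol["rectum"], vol["bladder"],
              mean(x$adc, na.rm = TRUE)))
  invisible(x)
}

#' Generate a prostate ADC map with focal low-ADC lesions
#'
#' Produces a spatially smooth background field (Gaussian random field with
#' configured mean/SD/correlation length) multiplied by one or more focal
#' suppression profiles that emulate cellular, likely high-Gleason lesions.
#' Values are strictly positive; the map is `NA` outside the prostate mask.
#'
#' @param grid a `VoxelGrid`.
#' @param prostate_mask logical array on `grid`.
#' @param adc_spec ADC settings, see `study_config()$adc`. `lesions$count_range`
#'   may be a fixed count or a range sampled per case.
#' @param seed integer seed.
#' @return numeric array (units 1e-6 mm^2/s), `NA` outside the prostate; the
#'   lesion centres and radii used are attached as attribute `"lesions"`.
#' @export
generate_adc_map <- function(grid, prostate_mask, adc_spec, seed = 1L) {
  les <- adc_spec$lesions
  # half-extent of the prostate bounding box: a lesion must fit inside
  idx <- which(prostate_mask, arr.ind = TRUE)
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * grid$spacing / 2
  if (max(les$radius_mm) > max(ext))
    stop("lesion radius ", max(les$radius_mm), " mm exceeds prostate extent")
  with_seed(seed, {
    noise <- array(stats::rnorm(n_voxels(grid)), grid$shape)
    sm <- gauss_smooth3(noise, grid, adc_spec$corr_len_mm / 2)
    # scale so the within-prostate SD matches the configured value
    sm <- sm / stats::sd(sm[prostate_mask])
    adc <- adc_spec$mean + adc_spec$sd * sm
    cr <- les$count_range
    n_les <- if (length(cr) > 1L) sample(cr[1]:cr[2], 1L) else as.integer(cr)
    lesions <- list()
    if (n_les > 0) {
      ctr <- mask_centroid(prostate_mask, grid)
      for (l in seq_len(n_les)) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        pos <- ctr + dir * les$center_frac * ext
        rl <- stats::runif(1, les$radius_mm[1], les$radius_mm[2])
        X <- grid_coords(grid)
        r2 <- rowSums(sweep(X, 2, pos, "-")^2) / rl^2
        prof <- pmax(0, 1 - r2)^2            # compact, smooth suppression
        adc <- adc * (1 - les$depth * array(prof, grid$shape))
        lesions[[l]] <- list(center = pos, radius_mm = rl)
      }
    }
    adc <- array(pmax(adc, adc_spec$floor), grid$shape)
    field <- adc                       # unmasked continuation for interpolation
    adc[!prostate_mask] <- NA_real_
    attr(adc, "lesions") <- lesions
    attr(adc, "field") <- field
    adc
  })
}
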