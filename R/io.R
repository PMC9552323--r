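#' Write a volume to NIfTI
#'
#' Masks are written as uint8 labels, ADC and dose as float32. The grid
#' spacing is stored in the NIfTI pixdim.
#'
#' @param vol numeric or logical 3-D array.
#' @param grid its `VoxelGrid`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, grid, path) {
  dt <- if (is.logical(vol)) "uint8" else "float"
  img <- RNifti::asNifti(array(if (is.logical(vol)) as.integer(vol)
                               else as.numeric(vol), grid$shape),
                         datatype = dt)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param frame frame label for the returned grid.
#' @return list with `vol` (array) and `grid` (a `VoxelGrid` centred on the
#'   world origin).
#' @export
read_volume <- function(path, frame = "reference") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim(img))
  list(vol = arr, grid = voxel_grid(dim(arr), sp, frame = frame))
}

#' Export a case (masks, ADC, manifest) to a directory
#'
#' @param case a `Case`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(case$structures)) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(case$structures[[nm]], case$grid, f)
    files[[nm]] <- basename(f)
  }
  adc <- case$adc; adc[is.na(adc)] <- 0
  write_volume(adc, case$grid, file.path(dir, "adc.nii.gz"))
  files$adc <- "adc.nii.gz"
  manifest <- list(id = case$id, seed = case$seed,
                   grid = list(shape = case$grid$shape,
                               spacing = case$grid$spacing,
                               origin = case$grid$origin),
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Export course endpoints and margins to a run manifest
#'
#' Echoes the uncertainty budgets, derived margins and endpoint table into a
#' JSON manifest plus a CSV of endpoints, for provenance.
#'
#' @param endpoints data.frame of accumulated endpoints
#'   (see [course_endpoints()]).
#' @param dir output directory.
#' @param config the `study_config` used.
#' @return the directory, invisibly.
#' @export
write_run_manifest <- function(endpoints, dir, config = study_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(endpoints, file.path(dir, "endpoints.csv"), row.names = FALSE)
  budgets <- lapply(c("conventional", "adaptive"), function(wf) {
    b <- build_budget(wf, config$fractions)
    m <- margin_from_budget(b, config$margins$rounding)
    list(workflow = wf,
         components = lapply(seq_len(nrow(b)), function(i) as.list(b[i, ])),
         Sigma_eff = m$Sigma_eff, sigma_eff = m$sigma_eff,
         raw_margin_mm = m$raw_mm, reported_margin_mm = m$reported_mm)
  })
  jsonlite::write_json(list(budgets = budgets,
                            endpoints_csv = "endpoints.csv"),
                       file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
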