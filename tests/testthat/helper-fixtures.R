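# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fix_case <- function() {
  if (is.null(.fixtures$case)) .fixtures$case <- generate_case(seed = 11)
  .fixtures$case
}

fix_engine <- function() {
  if (is.null(.fixtures$engine)) .fixtures$engine <- case_engine(fix_case())
  .fixtures$engine
}

fix_cal <- function() default_calibration()

# small centred grid for oracle-scale tests
small_grid <- function(shape = c(12, 12, 10), spacing = 3) {
  voxel_grid(shape, spacing)
}

# ball mask around the grid centre
ball_mask <- function(grid, radius_mm, center = c(0, 0, 0)) {
  X <- grid_coords(grid)
  array(rowSums(sweep(X, 2, center, "-")^2) <= radius_mm^2, grid$shape)
}

fix_case_fr <- function() {
  if (is.null(.fixtures$case_fr)) .fixtures$case_fr <- generate_fractions(fix_case())
  .fixtures$case_fr
}
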