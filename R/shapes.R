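# Analytic organ shapes. Each shape is a parameter list with a type tag; the
# indicator is evaluated at arbitrary world points, which keeps fraction masks
# crisp under deformation (the deformed indicator is sampled directly instead
# of interpolating a binary mask).

shape_ellipsoid <- function(center, semi) {
  list(type = "ellipsoid", center = as.numeric(center), semi = as.numeric(semi))
}

shape_union <- function(...) list(type = "union", parts = list(...))

# vertical tube (rectum): circular cross-section in the LR/AP plane
shape_tube <- function(center_xy, radius, z_range) {
  list(type = "tube", center_xy = as.numeric(center_xy),
       radius = radius, z_range = as.numeric(z_range))
}

shape_indicator <- function(shape, pts) {
  switch(shape$type,
    ellipsoid = {
      q <- sweep(pts, 2, shape$center, "-")
      (q[, 1] / shape$semi[1])^2 + (q[, 2] / shape$semi[2])^2 +
        (q[, 3] / shape$semi[3])^2 <= 1
    },
    tube = {
      r2 <- (pts[, 1] - shape$center_xy[1])^2 + (pts[, 2] - shape$center_xy[2])^2
      r2 <= shape$radius^2 & pts[, 3] >= shape$z_range[1] & pts[, 3] <= shape$z_range[2]
    },
    union = {
      res <- rep(FALSE, nrow(pts))
      for (p in shape$parts) res <- res | shape_indicator(p, pts)
      res
    },
    stop("unknown shape type: ", shape$type)
  )
}

voxelize_shape <- function(shape, grid, pts = grid_coords(grid)) {
  array(shape_indicator(shape, pts), grid$shape)
}

# sample per-case organ shape parameters from the configured ranges
sample_shapes <- function(geom, seed) {
  with_seed(seed, {
    vol <- stats::runif(1, geom$prostate_volume_cc[1], geom$prostate_volume_cc[2])
    base <- geom$prostate_base_semi                      # mm, shape template
    s <- (vol * 1000 / (4 / 3 * pi * prod(base)))^(1 / 3)
    jit <- exp(stats::runif(3, -0.05, 0.05))
    jit <- jit / prod(jit)^(1 / 3)                        # volume-preserving jitter
    semi <- base * s * jit
    rect_r <- stats::runif(1, geom$rectum_radius_mm[1], geom$rectum_radius_mm[2])
    rect_y <- semi[2] + geom$rectum_gap_mm + rect_r
    sv_semi <- geom$sv_semi
    sv_cz <- semi[3] + geom$sv_z_offset_mm
    list(
      prostate = shape_ellipsoid(c(0, 0, 0), semi),
      sv = shape_union(
        shape_ellipsoid(c(-geom$sv_x_offset_mm, geom$sv_y_offset_mm, sv_cz), sv_semi),
        shape_ellipsoid(c(geom$sv_x_offset_mm, geom$sv_y_offset_mm, sv_cz), sv_semi)),
      rectum = shape_tube(c(0, rect_y), rect_r, geom$rectum_z_range_mm),
      bladder = shape_ellipsoid(geom$bladder_center_mm, geom$bladder_semi_mm)
    )
  })
}
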