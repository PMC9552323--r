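test_that("dose mapping is exact for identity and integer-translation DVFs", {
  g <- small_grid()
  set.seed(21)
  dose <- array(runif(prod(g$shape), 0, 60), g$shape)
  dvf0 <- array(0, c(g$shape, 3))
  out <- map_dose(dose, dvf0, g)
  expect_equal(as.vector(out), as.vector(dose), tolerance = 1e-12)
  expect_equal(attr(out, "n_outside"), 0)
  # one-voxel translation: shifted copy, values exact
  dvf <- dvf0; dvf[, , , 3] <- g$spacing[3]
  out <- map_dose(dose, dvf, g)
  n3 <- g$shape[3]
  expect_equal(out[, , 1:(n3 - 1)], dose[, , 2:n3], tolerance = 1e-12)
  expect_equal(attr(out, "n_outside"), prod(g$shape[1:2]))
  expect_error(map_dose(dose, array(0, c(2, 2, 2, 3)), g), "mismatch")
})

test_that("EQD2 accumulation of equal fractions equals the closed form", {
  g <- small_grid(c(6, 6, 5))
  set.seed(22)
  total <- array(runif(prod(g$shape), 30, 62), g$shape)
  per <- lapply(1:7, function(k) total / 7)
  acc <- accumulate(per, "eqd2", 1.93)
  expect_equal(as.vector(acc), as.vector(eqd2_convert(total, 7, 1.93)),
               tolerance = 1e-9)
  # physical accumulation conserves dose exactly
  expect_equal(accumulate(per, "physical"), total, tolerance = 1e-12)
  one_zero <- per; one_zero[[4]] <- total * 0
  expect_equal(accumulate(one_zero, "physical"), total * 6 / 7, tolerance = 1e-12)
  expect_error(accumulate(per[1:5], "physical", N = 7), "expected 7")
})

test_that("unequal-fraction EQD2 accumulation matches the per-voxel hand formula", {
  ab <- 1.93
  d <- c(5, 6.5, 7, 4.2, 8, 6, 7.3)    # per-fraction doses of one voxel
  doses <- lapply(d, function(x) array(x, c(1, 1, 1)))
  acc <- accumulate(doses, "eqd2", ab)
  hand <- sum(d * (d + ab) / (2 + ab))
  expect_equal(acc[1, 1, 1], hand, tolerance = 1e-12)
})

test_that("DVH metrics match counting oracles", {
  g <- small_grid(c(10, 10, 2))
  mask <- array(TRUE, g$shape)
  dose <- array(50, g$shape)
  m <- dvh_metrics(dose, mask)
  expect_equal(m$V41, 100); expect_equal(m$V33, 100)
  expect_equal(m$D2, 50); expect_equal(m$D98, 50); expect_equal(m$Dmean, 50)
  m <- dvh_metrics(array(30, g$shape), mask)
  expect_equal(m$V33, 0)
  # half 20 Gy, half 44 Gy
  dose <- array(20, g$shape); dose[, , 2] <- 44
  m <- dvh_metrics(dose, mask, prescription = 43.89)
  expect_equal(m$V33, 50)
  expect_equal(m$Dmean, 32)
  expect_equal(m$V95, 50)
  expect_error(dvh_metrics(dose, array(FALSE, g$shape)), "empty mask")
})

test_that("Dice matches direct counts", {
  g <- small_grid(c(6, 6, 4))
  a <- array(FALSE, g$shape); b <- array(FALSE, g$shape)
  a[1:2, 1, 1] <- TRUE
  b[2:3, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)       # |A|=|B|=2, overlap 1
  b2 <- array(FALSE, g$shape); b2[5, 5, 3] <- TRUE
  expect_equal(dice(a, b2), 0)
  expect_warning(expect_equal(dice(b2 & FALSE, b2 & FALSE), 1), "empty")
})

test_that("Hausdorff distance matches a brute-force all-pairs oracle", {
  g <- small_grid(c(8, 8, 6))
  a <- array(FALSE, g$shape); a[4, 4, 3] <- TRUE
  b <- array(FALSE, g$shape); b[5, 4, 3] <- TRUE
  expect_equal(hausdorff(a, a, g), 0)
  expect_equal(hausdorff(a, b, g), 3)   # single voxels one 3-mm step apart
  # random small masks vs. exhaustive surface-pair oracle
  brute <- function(a, b) {
    X <- grid_coords(g)
    pa <- X[as.vector(dpaintsim:::surface_voxels(a)), , drop = FALSE]
    pb <- X[as.vector(dpaintsim:::surface_voxels(b)), , drop = FALSE]
    dmat <- as.matrix(stats::dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                                  nrow(pa) + seq_len(nrow(pb))]
    max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
  }
  set.seed(23)
  for (i in 1:5) {
    a <- ball_mask(g, runif(1, 3, 8), center = runif(3, -3, 3))
    b <- ball_mask(g, runif(1, 3, 8), center = runif(3, -3, 3))
    if (!any(a) || !any(b)) next
    expect_equal(hausdorff(a, b, g), brute(a, b), tolerance = 1e-9)
  }
  # shell case: A strictly inside B
  a <- ball_mask(g, 3); b <- ball_mask(g, 9)
  expect_equal(hausdorff(a, b, g), brute(a, b), tolerance = 1e-9)
  expect_error(hausdorff(a, a & FALSE, g), "non-empty")
})

test_that("volume-at-dose is invariant under identity mapping but not under volume change", {
  case <- fix_case()
  g <- case$grid
  rect <- case$structures$rectum
  # synthetic dose gradient falling off behind the prostate
  X <- grid_coords(g)
  dose <- array(60 * exp(-pmax(X[, 2] - 20, 0) / 25), g$shape)
  v_before <- 100 * mean(dose[rect] > 41)
  dvf0 <- array(0, c(g$shape, 3))
  expect_equal(100 * mean(map_dose(dose, dvf0, g)[rect] > 41), v_before,
               tolerance = 1e-9)
  # volume-changing fraction: pre- and post-mapping VaD diverge, and the
  # divergence grows with the volume-change magnitude
  sp <- case$config$deformation
  sp$shift_sd_mm <- c(0, 0, 0); sp$rot_sd_deg <- 0; sp$def_amp_mm <- 0
  dev <- vapply(c(1.3, 1.9), function(rho) {
    sp$rho <- rho
    fr <- generate_fraction(case, 1, sp)
    pre <- 100 * mean(dose[fr$structures$rectum] > 41)
    post <- 100 * mean(map_dose(dose, fr$dvf_to_frac, g)[rect] > 41)
    abs(post - pre)
  }, 0)
  expect_gt(dev[2], 0.5)
  expect_gte(dev[2], dev[1])
})

test_that("similarity report certifies ground-truth registration quality", {
  case <- fix_case_fr()
  rep <- similarity_report(case, structures = "prostate")
  expect_equal(nrow(rep), case$config$fractions)
  expect_true(all(rep$dice >= 0.95))
  expect_true(all(rep$hausdorff_mm < 10))
})
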