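test_that("EQD2 conversion reproduces the clinical anchors", {
  # 43.89 Gy in 7 fractions at alpha/beta 1.93 is the 91.6 Gy EQD2 level
  expect_equal(eqd2_convert(43.89, 7, 1.93), 91.6, tolerance = 0.05 / 91.6)
  # identity at 2 Gy per fraction
  expect_equal(eqd2_convert(2 * 12, 12, 1.93), 24, tolerance = 1e-12)
  # independent BED oracle: BED = D (1 + d / ab), EQD2 = BED / (1 + 2 / ab)
  bed_oracle <- function(D, N, ab) D * (1 + (D / N) / ab) / (1 + 2 / ab)
  expect_equal(eqd2_convert(60.89, 7, 1.93), bed_oracle(60.89, 7, 1.93),
               tolerance = 1e-12)
  expect_equal(bed_oracle(60.89, 7, 1.93), 164.7, tolerance = 0.1 / 164.7)
  expect_error(eqd2_convert(10, 0), "N must be")
  expect_error(eqd2_convert(-1, 7), "non-negative")
})

test_that("the ADC-to-Gleason posterior is a valid, monotone mapping", {
  cal <- fix_cal()
  adc <- seq(300, 3000, by = 50)
  P <- adc_to_gleason(adc, cal)
  expect_equal(rowSums(P), rep(1, length(adc)), tolerance = 1e-9)
  expect_true(all(P >= 0))
  # expected Gleason score non-increasing in ADC
  egs <- as.vector(P %*% seq_len(ncol(P)))
  expect_true(all(diff(egs) <= 1e-12))
  # very high ADC concentrates on the lowest category
  hi <- adc_to_gleason(3 * 1046, cal)
  expect_gt(hi[1, 1], 0.99)
  # low ADC carries high probability of high Gleason scores
  lo <- adc_to_gleason(400, cal)
  expect_gt(sum(lo[1, 3:4]), 0.5)
  expect_error(adc_to_gleason(c(800, -1), cal), "positive")
})

test_that("voxel control probability behaves per the mixture-exponent model", {
  cal <- fix_cal()
  sv_vol <- 10                                 # cm^3, whole-vesicle scale
  g6 <- c(1, 0, 0, 0)
  # zero dose fails
  expect_lt(voxel_control_prob(0, g6, cal$v_ref, cal), 0.01)
  # GS6 at the 91.6 Gy EQD2 anchor controls a whole SV volume
  expect_gte(voxel_control_prob(91.6, g6, sv_vol, cal), 0.99)
  # mixture lies between the pure-category values
  g9 <- c(0, 0, 0, 1)
  mix <- c(0.5, 0, 0, 0.5)
  p6 <- voxel_control_prob(70, g6, 1, cal)
  p9 <- voxel_control_prob(70, g9, 1, cal)
  pm <- voxel_control_prob(70, mix, 1, cal)
  expect_gt(pm, min(p6, p9)); expect_lt(pm, max(p6, p9))
  # monotone non-decreasing in dose
  p <- voxel_control_prob(seq(0, 150, 5), matrix(rep(mix, 31), 31, byrow = TRUE),
                          1, cal)
  expect_true(all(diff(p) >= -1e-12))
})

test_that("TCP follows the voxel product law and volume-exponent invariance", {
  cal <- fix_cal()
  g <- voxel_grid(c(4, 4, 4), spacing = 10)     # 1 cm^3 voxels = v_ref
  eq <- array(0, g$shape)
  pro <- array(FALSE, g$shape); sv <- array(FALSE, g$shape)
  # single-voxel target equals the voxel control probability
  pro[2, 2, 2] <- TRUE
  eq[2, 2, 2] <- 80
  post <- adc_to_gleason(1046, cal)
  expect_equal(compute_tcp(eq, post, pro, sv, g, cal),
               voxel_control_prob(80, post, 1, cal), tolerance = 1e-12)
  # product law: two voxels with p = 0.99 each give 0.9801
  cal2 <- cal
  d99 <- cal$categories$d50[1] * (1 - log(1 / 0.99 - 1) / (4 * cal$categories$gamma50[1]))
  pro[3, 2, 2] <- TRUE; eq[3, 2, 2] <- d99; eq[2, 2, 2] <- d99
  p1 <- voxel_control_prob(d99, c(1, 0, 0, 0), 1, cal)
  expect_equal(p1, 0.99, tolerance = 1e-9)
  g6post <- matrix(rep(c(1, 0, 0, 0), 2), 2, byrow = TRUE)
  expect_equal(compute_tcp(eq, g6post, pro, sv, g, cal), 0.9801, tolerance = 1e-9)
  expect_error(compute_tcp(eq, NULL, array(FALSE, g$shape), sv, g, cal), "empty target")
})

test_that("uniform-dose TCP at fixed total volume is voxel-size invariant", {
  cal <- fix_cal()
  # total volume v_ref at uniform dose: TCP equals the single-voxel value
  # regardless of voxelization (exponents sum to v_ref)
  tcp_for <- function(nvox) {
    g <- voxel_grid(c(nvox, 1, 1), spacing = c(10 / nvox, 10, 10))
    eq <- array(91.6, g$shape)
    pro <- array(TRUE, g$shape)
    post <- matrix(rep(c(1, 0, 0, 0), nvox), nvox, byrow = TRUE)
    compute_tcp(eq, post, pro, array(FALSE, g$shape), g, cal)
  }
  expect_equal(tcp_for(1), tcp_for(5), tolerance = 1e-9)
  expect_equal(tcp_for(5), tcp_for(20), tolerance = 1e-9)
})

test_that("fraction TCP is consistent with the plan TCP for unperturbed delivery", {
  cal <- fix_cal()
  g <- voxel_grid(c(6, 6, 6), spacing = 5)
  pro <- ball_mask(g, 10); sv <- array(FALSE, g$shape)
  dose <- array(50, g$shape)
  post <- adc_to_gleason(rep(1046, sum(pro)), cal)
  plan_tcp <- compute_tcp(eqd2_convert(dose, 7, cal$alpha_beta), post, pro, sv, g, cal)
  expect_equal(fraction_tcp(dose / 7, 7, post, pro, sv, g, cal), plan_tcp,
               tolerance = 1e-9)
  expect_lt(fraction_tcp(dose * 0, 7, post, pro, sv, g, cal), 0.01)
})

test_that("the dose-response flattens at high dose", {
  cal <- fix_cal()
  case <- fix_case()
  pro <- case$structures$prostate; sv <- case$structures$sv
  post <- adc_to_gleason(case$adc[pro], cal)
  tcp_at <- function(D) {
    eq <- array(eqd2_convert(D, 7, cal$alpha_beta), case$grid$shape)
    compute_tcp(eq, post, pro, sv, case$grid, cal)
  }
  grad44 <- tcp_at(45) - tcp_at(44)
  grad56 <- tcp_at(57) - tcp_at(56)
  expect_gt(grad44, 0); expect_gte(grad44, grad56)
  # monotone in uniform dose
  tcps <- vapply(seq(40, 62, 2), tcp_at, 0)
  expect_true(all(diff(tcps) >= -1e-12))
})

test_that("calibration files round-trip through YAML", {
  cal <- fix_cal()
  f <- tempfile(fileext = ".yaml")
  write_calibration(cal, f)
  cal2 <- default_calibration(f)
  expect_equal(cal2$alpha_beta, cal$alpha_beta)
  expect_equal(cal2$categories$d50, cal$categories$d50)
  expect_equal(cal2$adc_mapping$cutpoints, cal$adc_mapping$cutpoints)
})
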