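zero_spec <- function(case) {
  sp <- case$config$deformation
  sp$shift_sd_mm <- c(0, 0, 0); sp$rot_sd_deg <- 0
  sp$def_amp_mm <- 0; sp$rectum_logsd <- 0
  sp
}

test_that("zero-amplitude deformation yields identical anatomy and identity DVF", {
  case <- fix_case()
  fr <- generate_fraction(case, 1, zero_spec(case))
  expect_identical(fr$structures$prostate, case$structures$prostate)
  expect_identical(fr$structures$rectum, case$structures$rectum)
  expect_lt(max(abs(fr$dvf_to_frac)), 1e-9)
  expect_lt(max(abs(fr$dvf_to_ref)), 1e-9)
  expect_equal(as.vector(fr$adc[fr$structures$prostate]),
               as.vector(case$adc[case$structures$prostate]), tolerance = 1e-9)
})

test_that("a pure rigid shift displaces the prostate centroid accordingly", {
  case <- fix_case()
  sp <- zero_spec(case)
  sp$shift <- c(3, 0, 0)
  fr <- generate_fraction(case, 2, sp)
  d <- mask_centroid(fr$structures$prostate, case$grid) -
    mask_centroid(case$structures$prostate, case$grid)
  # centroid arithmetic oracle, voxelization-limited accuracy
  expect_equal(unname(d), c(3, 0, 0), tolerance = 0.35)
})

test_that("the rectum volume-change factor is realised within 5%", {
  case <- fix_case()
  sp <- zero_spec(case)
  sp$rho <- 2.0
  fr <- generate_fraction(case, 3, sp)
  ratio <- sum(fr$structures$rectum) / sum(case$structures$rectum)
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("ground-truth DVFs are self-consistent (warped masks reproduce reference)", {
  case <- fix_case()
  for (k in 1:3) {
    fr <- generate_fraction(case, k)
    w <- warp_mask(fr$structures$prostate, fr$dvf_to_frac, case$grid)
    expect_gte(dice(w, case$structures$prostate), 0.95)
  }
})

test_that("fractions are deterministic in the seed and independent across k", {
  case <- fix_case()
  a <- generate_fraction(case, 1)
  b <- generate_fraction(case, 1)
  expect_identical(a$structures, b$structures)
  expect_equal(a$rigid$shift, b$rigid$shift)
  c2 <- generate_fraction(case, 2)
  expect_false(isTRUE(all.equal(a$rigid$shift, c2$rigid$shift)))
})

test_that("ADC transfer preserves the distribution under default deformations", {
  case <- fix_case()
  ref <- case$adc[case$structures$prostate]
  for (k in 1:3) {
    fr <- generate_fraction(case, k)
    frv <- fr$adc[fr$structures$prostate]
    expect_lt(abs(mean(frv) - mean(ref)) / mean(ref), 0.05)
    expect_lt(abs(stats::sd(frv) - stats::sd(ref)) / stats::sd(ref), 0.10)
  }
})

test_that("ADC transfer along an integer-voxel translation shifts values exactly", {
  case <- fix_case()
  g <- case$grid
  sh <- c(g$spacing[1], 0, 0)          # one voxel along LR
  dvf <- array(0, c(g$shape, 3))
  dvf[, , , 1] <- sh[1]                # fraction voxel y maps to y + 3mm in reference
  d <- g$shape
  fmask <- array(FALSE, d)
  fmask[1:(d[1] - 1), , ] <- case$structures$prostate[2:d[1], , ]
  out <- transfer_adc(case$adc, dvf, g, fmask)
  expect_equal(out[1:(d[1] - 1), , ][fmask[1:(d[1] - 1), , ]],
               case$adc[2:d[1], , ][fmask[1:(d[1] - 1), , ]], tolerance = 1e-9)
})

test_that("folding deformations are rejected when regeneration is disabled", {
  case <- fix_case()
  sp <- zero_spec(case)
  sp$on_fold <- "error"; sp$max_regen <- 0L
  # a focal push far stronger than its radius folds the field
  sp$focal <- list(center = c(0, 0, 0), dir = c(1, 0, 0),
                   amp_mm = 60, radius_mm = 10)
  expect_error(generate_fraction(case, 4, sp), "fold")
})
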