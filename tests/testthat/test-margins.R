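test_that("effective components match a Monte-Carlo variance oracle", {
  # Sigma_eff^2 is the variance of the course-mean displacement; sigma_eff^2
  # the expected within-course variance (denominator N)
  mc_oracle <- function(Sigma, sigma, N, M = 40000) {
    set.seed(97)
    sys <- rnorm(M, 0, Sigma)
    rnd <- matrix(rnorm(M * N, 0, sigma), M, N)
    course_mean <- sys + rowMeans(rnd)
    within_var <- rowMeans((rnd - rowMeans(rnd))^2)
    c(sqrt(stats::var(course_mean)), sqrt(mean(within_var)))
  }
  eff <- effective_components(0, sqrt(3), 7)
  expect_equal(unname(eff), c(0.655, 1.604), tolerance = 0.01)
  mc <- mc_oracle(0, sqrt(3), 7)
  expect_equal(unname(eff), mc, tolerance = 0.03)
  set.seed(31)
  for (i in 1:10) {
    Sg <- runif(1, 0, 3); sg <- runif(1, 0, 3); N <- sample(2:15, 1)
    eff <- effective_components(Sg, sg, N)
    mc <- mc_oracle(Sg, sg, N)
    expect_equal(unname(eff), mc, tolerance = 0.05)
  }
  expect_equal(unname(effective_components(0, 0, 7)), c(0, 0))
  # large-N limit recovers the raw components
  eff <- effective_components(1.2, 0.8, 1e6)
  expect_equal(unname(eff), c(1.2, 0.8), tolerance = 1e-3)
})

test_that("the margin recipe and budgets reproduce the 3 mm / 6 mm margins", {
  expect_equal(margin_mm(0, 0), 0)
  expect_equal(margin_mm(1, 1), 3.2)
  ad <- build_budget("adaptive")
  co <- build_budget("conventional")
  expect_setequal(ad$name, c("intrafraction", "delineation", "machine"))
  expect_true(all(c("deformation_residual", "registration_table") %in% co$name))
  expect_true(all(ad$name %in% co$name))  # conventional is a superset
  expect_true(all(ad$sd_mm == 1) && all(co$sd_mm == 1))
  # quadrature sums
  sa <- dpaintsim:::budget_sigmas(ad)
  sc <- dpaintsim:::budget_sigmas(co)
  expect_equal(unname(sa["sigma"]), sqrt(3), tolerance = 1e-12)
  expect_equal(unname(sa["Sigma"]), 0)
  expect_equal(unname(sqrt(sum(sc^2))), sqrt(5), tolerance = 1e-12)
  ma <- margin_from_budget(ad)
  mc <- margin_from_budget(co)
  expect_equal(ma$raw_mm, 2.759, tolerance = 1e-3)
  expect_equal(mc$raw_mm, 5.448, tolerance = 1e-3)
  expect_equal(ma$reported_mm, 3)
  expect_equal(mc$reported_mm, 6)
  expect_gte(ma$reported_mm, ma$raw_mm)
  expect_error(build_budget("robotic"), "arg")
})

test_that("the margin is monotone in components and decreasing in N", {
  base <- margin_mm(effective_components(1, 1, 7)[1], effective_components(1, 1, 7)[2])
  up <- margin_mm(effective_components(1.5, 1, 7)[1], effective_components(1.5, 1, 7)[2])
  expect_gt(up, base)
  m5 <- effective_components(1, 1.5, 5)
  m9 <- effective_components(1, 1.5, 9)
  expect_gt(margin_mm(m5[1], m5[2]), margin_mm(m9[1], m9[2]))
})

test_that("CTV expansion matches brute-force distance semantics", {
  g <- small_grid(c(13, 13, 11))
  ctv <- array(FALSE, g$shape); ctv[7, 7, 6] <- TRUE
  ptv <- expand_ctv(ctv, g, 6)
  X <- grid_coords(g)
  ctr <- X[which(as.vector(ctv)), ]
  want <- array(rowSums(sweep(X, 2, ctr, "-")^2) <= 36 + 1e-9, g$shape)
  expect_identical(ptv, want)
  expect_true(all(ptv[ctv]))
  # zero margin is the identity
  expect_identical(expand_ctv(ctv, g, 0), ctv)
  # anisotropic margin: AP extension equals the AP margin within one voxel
  ptv2 <- expand_ctv(ctv, g, c(5, 7, 7))
  idx <- which(ptv2, arr.ind = TRUE)
  ext <- (apply(idx, 2, max) - apply(idx, 2, min)) / 2 * g$spacing
  expect_lte(abs(ext[2] - 7), g$spacing[2])
  expect_lte(abs(ext[1] - 5), g$spacing[1])
  expect_warning(expand_ctv(ctv, g, 0.5), "half a voxel")
})
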