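test_that("scenario sets enumerate the nominal and axis displacements", {
  expect_equal(scenario_set(0), list(c(0, 0, 0)))
  sc <- scenario_set(3)
  expect_length(sc, 7)
  expect_equal(sc[[1]], c(0, 0, 0))
  norms <- vapply(sc, function(d) sqrt(sum(d^2)), 0)
  expect_equal(max(norms), 3)
  sc6 <- scenario_set(6)
  M <- do.call(rbind, sc6)
  for (ax in 1:3) {
    expect_true(any(M[, ax] == 6) && any(M[, ax] == -6))
  }
  expect_error(scenario_set(-1))
})

test_that("the homogeneous dose ladder spans 43.89 to 60.89 Gy in 18 steps", {
  lad <- dose_ladder()
  expect_length(lad, 18)
  expect_equal(lad[1], 43.89)
  expect_equal(lad[18], 60.89)
  expect_equal(unique(diff(lad)), 1)
})

test_that("homogeneous plans meet the coverage band on the default phantom", {
  case <- fix_case()
  eng <- fix_engine()
  prob <- planning_problem(case, "Homo-conv", d_p = 43.89)
  expect_equal(prob$margin_mm, 6)
  plan <- optimize_homogeneous(prob, eng)
  dvh <- dvh_metrics(plan$dose, prob$ptv, d_levels = c(2, 98))
  expect_gte(dvh$D98, 0.95 * 43.89)
  expect_lte(dvh$D2, 1.05 * 43.89)
  # SV PTV near-minimum coverage
  svd <- dvh_metrics(plan$dose, prob$sv_ptv, d_levels = 98)
  expect_gte(svd$D98, 0.9 * 43.89)
  .fixtures$homo_plan <- plan
})

test_that("a two-voxel dose-budget oracle assigns more dose to the higher Gleason voxel", {
  # exhaustive search over two-level allocations of a fixed EQD2 budget:
  # the TCP-optimal split always favours the high-Gleason voxel
  cal <- fix_cal()
  g9 <- c(0, 0, 0.2, 0.8); g6 <- c(0.9, 0.1, 0, 0)
  budget <- 240
  split <- seq(0.3, 0.7, by = 0.005)
  tcp2 <- vapply(split, function(f) {
    voxel_control_prob(budget * f, g9, 1, cal) *
      voxel_control_prob(budget * (1 - f), g6, 1, cal)
  }, 0)
  best <- split[which.max(tcp2)]
  expect_gt(best, 0.5)
})

test_that("DPBN plans respect rectum constraints and boost the low-ADC lesion", {
  case <- fix_case()
  eng <- fix_engine()
  cal <- fix_cal()
  prob <- planning_problem(case, "DPBN-adap")
  post <- adc_to_gleason(case$adc[case$structures$prostate], cal)
  plan <- optimize_dpbn(prob, post, eng, cal)
  expect_true(all(plan$rectum_vad <= c(30, 15, 10)))
  expect_gt(plan$tcp_nominal, 0.95)
  # dose ordering follows predicted radioresistance: voxels with high
  # expected Gleason score receive more dose than low ones
  pro <- case$structures$prostate
  egs <- as.vector(post %*% seq_len(ncol(post)))
  dpro <- plan$dose[pro]
  hi <- egs >= stats::quantile(egs, 0.9)
  lo <- egs <= stats::quantile(egs, 0.5)
  expect_gt(mean(dpro[hi]), mean(dpro[lo]) + 1)
  # no upper limit on voxel dose: painting exceeds the homogeneous ceiling
  expect_gt(max(dpro), 1.05 * 43.89)
  .fixtures$dpbn_plan <- plan
})

test_that("robust DPBN protects the worst scenario at least as well as non-robust", {
  case <- fix_case()
  eng <- fix_engine()
  cal <- fix_cal()
  post <- adc_to_gleason(case$adc[case$structures$prostate], cal)
  prob <- planning_problem(case, "DPBN-adap")
  plan_rob <- if (!is.null(.fixtures$dpbn_plan)) .fixtures$dpbn_plan
              else optimize_dpbn(prob, post, eng, cal)
  prob0 <- prob; prob0$robust_mm <- 0
  plan0 <- optimize_dpbn(prob0, post, eng, cal)
  worst_tcp <- function(plan) {
    offs <- dpaintsim:::scenario_offsets(scenario_set(prob$robust_mm), case$grid)
    d <- as.vector(plan$dose)
    tidx <- which(as.vector(case$structures$prostate))
    vidx <- which(as.vector(case$structures$sv))
    P <- rbind(post, dpaintsim:::gs6_posterior(length(vidx), cal))
    min(vapply(offs, function(o) {
      eq <- eqd2_convert(d[c(tidx, vidx) + o], 7, cal$alpha_beta)
      sum(log(pmax(voxel_control_prob(eq, P, voxel_volume_cc(case$grid), cal),
                   1e-300)))
    }, 0))
  }
  expect_gte(worst_tcp(plan_rob), worst_tcp(plan0) - 0.02)
})
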