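test_that("closed-form limits: nonbinders and absent receptor reduce to bulk flow", {
  ## single nonbinder
  st <- solveSteadyState(cargoSystem(
    data.frame(name = "x", synthesis = 2, kd = Inf), kBulk = 0.25, vr = 5))
  expect_equal(st$conc, 2 / 0.25, tolerance = 1e-9)
  expect_equal(st$flux_receptor, 0)
  ## binder but vr = 0
  st2 <- solveSteadyState(cargoSystem(
    data.frame(name = "y", synthesis = 3, kd = 0.1), kBulk = 0.5, vr = 0))
  expect_equal(st2$conc, 3 / 0.5, tolerance = 1e-9)
  ## multi-cargo bulk-only
  st3 <- solveSteadyState(cargoSystem(
    data.frame(name = letters[1:4], synthesis = c(1, 2, 3, 4),
               kd = c(0.1, 1, 10, Inf)), kBulk = 0.2, vr = 0))
  expect_equal(st3$conc, c(1, 2, 3, 4) / 0.2, tolerance = 1e-9)
})

test_that("steady state matches independent long-time ODE integration", {
  skip_if_not_installed("deSolve")
  cases <- list(
    list(s = c(1, 1), kd = c(0.05, 1), kb = 0.1, vr = 2),
    list(s = c(0.5, 2), kd = c(0.01, 0.5), kb = 0.05, vr = 1),
    list(s = c(1, 1), kd = c(0.2, Inf), kb = 0.1, vr = 50),
    list(s = c(3, 0.2), kd = c(0.5, 0.05), kb = 1, vr = 0.3))
  for (cs in cases) {
    st <- solveSteadyState(cargoSystem(
      data.frame(name = c("a", "b"), synthesis = cs$s, kd = cs$kd),
      kBulk = cs$kb, vr = cs$vr))
    oracle <- odeSteadyState(cs$s, cs$kd, cs$kb, cs$vr)
    expect_equal(st$conc, oracle, tolerance = 1e-6)
  }
})

test_that("flux conservation holds at steady state for every cargo", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(1:5, 1)
    sys <- cargoSystem(
      data.frame(name = paste0("c", 1:n),
                 synthesis = runif(n, 0.1, 5),
                 kd = ifelse(runif(n) < 0.2, Inf, 10^runif(n, -2, 1))),
      kBulk = 10^runif(1, -2, 0), vr = 10^runif(1, -2, 1.5))
    st <- solveSteadyState(sys)
    expect_true(all(abs(sys@cargo$synthesis -
                          (st$flux_bulk + st$flux_receptor)) < 1e-8))
    expect_true(all(st$conc >= 0))
    expect_true(S4Vectors::metadata(st)$start_agreement < 1e-6)
  }
})

test_that("the smaller-Kd cargo always sits at a strictly lower steady state", {
  set.seed(23)
  for (i in 1:10) {
    kds <- sort(10^runif(2, -2, 1))
    s <- runif(1, 0.5, 3)
    st <- solveSteadyState(cargoSystem(
      data.frame(name = c("strong", "modest"), synthesis = c(s, s),
                 kd = kds), kBulk = 0.1,
      vr = runif(1, 0.1, 2) * s))       # receptor-limited regimes
    expect_lt(st$conc[1], st$conc[2])
  }
})

test_that("steady states are invariant to joint rescaling of all rates", {
  cargo <- data.frame(name = c("a", "b"), synthesis = c(1, 2),
                      kd = c(0.1, 3))
  st1 <- solveSteadyState(cargoSystem(cargo, kBulk = 0.2, vr = 1))
  f <- 37
  cargo2 <- cargo; cargo2$synthesis <- cargo$synthesis * f
  st2 <- solveSteadyState(cargoSystem(cargo2, kBulk = 0.2 * f, vr = 1 * f))
  expect_equal(st1$conc, st2$conc, tolerance = 1e-8)
})

test_that("coexpression in receptor excess leaves the strong cargo unchanged", {
  sc <- genScenarios()[["receptor-excess-coexpression"]]
  r <- coexpressionExperiment(sc$strong, sc$other, sc$kBulk, sc$vr)
  expect_lt(r$rel_change, 0.01)
  ## symmetric cargo get identical steady states
  a <- data.frame(name = "a", synthesis = 1, kd = 0.3)
  b <- data.frame(name = "b", synthesis = 1, kd = 0.3)
  st <- coexpressionExperiment(a, b, 0.1, 1)$state_coexpressed
  expect_equal(st$conc[1], st$conc[2], tolerance = 1e-9)
  ## receptor-limited regime: both concentrations rise vs excess
  skip_if_not_installed("deSolve")
  st_lim <- solveSteadyState(cargoSystem(
    rbind(sc$strong, sc$other), sc$kBulk, vr = 0.5))
  oracle <- odeSteadyState(c(1, 1), c(sc$strong$kd, sc$other$kd),
                           sc$kBulk, 0.5)
  expect_equal(st_lim$conc, oracle, tolerance = 1e-6)
  st_exc <- coexpressionExperiment(sc$strong, sc$other, sc$kBulk,
                                   sc$vr)$state_coexpressed
  expect_true(all(st_lim$conc >= st_exc$conc - 1e-9))
})

test_that("receptor depletion raises both levels; the ratio relaxes toward the bulk limit", {
  sc <- genScenarios()[["knockdown-grid"]]
  grid <- knockdownExperiment(sc$strong, sc$modest, sc$kBulk, sc$vr,
                              sc$factors)
  ## identity case: factor 1 reproduces the baseline system
  base <- solveSteadyState(cargoSystem(rbind(sc$strong, sc$modest),
                                       sc$kBulk, sc$vr))
  expect_equal(grid$conc_strong[1], base$conc[1], tolerance = 1e-9)
  ## both absolute levels non-decreasing as capacity falls
  expect_true(all(diff(grid$conc_strong) >= -1e-9))
  expect_true(all(diff(grid$conc_modest) >= -1e-9))
  ## complete-depletion limit: equal synthesis means ratio -> 1
  tiny <- knockdownExperiment(sc$strong, sc$modest, sc$kBulk, sc$vr,
                              factors = 1e-9)
  expect_equal(tiny$ratio, 1, tolerance = 1e-4)
  ## the concentration ratio relaxes monotonically toward that limit
  expect_true(all(diff(grid$ratio) <= 1e-9))
  expect_true(all(grid$ratio >= 1 - 1e-9))
  ## while the strong cargo keeps the larger receptor-flux share throughout
  for (f in sc$factors) {
    st <- solveSteadyState(cargoSystem(rbind(sc$strong, sc$modest),
                                       sc$kBulk, sc$vr * f))
    expect_gte(st$flux_receptor[1], st$flux_receptor[2])
  }
  expect_error(knockdownExperiment(sc$modest, sc$strong, sc$kBulk, sc$vr),
               "strong")
})

test_that("aggregation flags respect thresholds, inclusivity and the receptor-null scenario", {
  sc <- genScenarios()[["surf4-null"]]
  with_rec <- aggregationFlags(solveSteadyState(sc$system))
  without <- aggregationFlags(solveSteadyState(sc$system_null))
  expect_false(with_rec$aggregated)
  expect_true(without$aggregated)
  ## infinite threshold never flags
  st <- solveSteadyState(cargoSystem(
    data.frame(name = "x", synthesis = 5, kd = Inf, c_agg = Inf),
    kBulk = 0.01, vr = 0))
  expect_false(aggregationFlags(st)$aggregated)
  ## boundary: concentration exactly at threshold is flagged (inclusive)
  st2 <- solveSteadyState(cargoSystem(
    data.frame(name = "x", synthesis = 1, kd = Inf, c_agg = 10),
    kBulk = 0.1, vr = 0))
  expect_equal(st2$conc, 10, tolerance = 1e-9)
  expect_true(aggregationFlags(st2)$aggregated)
  expect_equal(aggregationFlags(st2)$margin, 0, tolerance = 1e-9)
})

test_that("invalid system specifications are rejected", {
  expect_error(cargoSystem(data.frame(name = "x", synthesis = -1, kd = 1),
                           kBulk = 0.1, vr = 1), "synthesis")
  expect_error(cargoSystem(data.frame(name = "x", synthesis = 1, kd = 0),
                           kBulk = 0.1, vr = 1), "kd")
  expect_error(cargoSystem(data.frame(name = "x", synthesis = 1, kd = 1),
                           kBulk = 0, vr = 1), "kBulk")
  expect_error(cargoSystem(data.frame(name = "x", synthesis = 1, kd = 1),
                           kBulk = 0.1, vr = -1), "vr")
})
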