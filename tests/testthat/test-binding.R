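test_that("noiseless titration data recover the generating parameters exactly", {
  d <- genBindingData(bmax = 100, kdTrue = 200, b0 = 0, noiseSd = 0, seed = 1)
  fit <- fitSaturation(d)
  expect_true(fit@converged)
  expect_true(fit@saturable)
  expect_equal(kd(fit), 200, tolerance = 1e-6)
  expect_equal(bmax(fit), 100, tolerance = 1e-6)
})

test_that("at c = Kd exactly half of Bmax above background is bound", {
  d <- genBindingData(bmax = 80, kdTrue = 250, b0 = 12, noiseSd = 0.05,
                      seed = 4)
  fit <- fitSaturation(d)
  e <- fit@estimates
  expect_equal(predictBinding(fit, e[["Kd"]]),
               e[["b0"]] + e[["Bmax"]] / 2, tolerance = 1e-12)
})

test_that("least-squares fit agrees with a dense grid-search oracle", {
  d <- genBindingData(bmax = 100, kdTrue = 250, b0 = 5, noiseSd = 0.05,
                      replicates = 3, seed = 9)
  fit <- fitSaturation(d)
  oracle <- gridSearchBindingFit(d$concentration, d$signal)
  kd_step <- 1  # refined oracle grid resolution in nM
  expect_lt(abs(kd(fit) - oracle$kd), 2 * kd_step)
  expect_lt(abs(bmax(fit) - oracle$bmax) / oracle$bmax, 0.02)
})

test_that("a background-only ligand is classified as non-saturable, not an error", {
  flat <- genBindingData(bmax = 0, kdTrue = 200, b0 = 10, noiseSd = 0.05,
                         seed = 2)
  fit <- fitSaturation(flat)
  expect_false(fit@saturable)
  expect_match(fit@message, "no saturable binding")
})

test_that("fit is invariant to concentration unit rescaling", {
  d <- genBindingData(bmax = 100, kdTrue = 250, b0 = 5, noiseSd = 0.05,
                      seed = 13)
  fit_nM <- fitSaturation(d)
  d_uM <- d; d_uM$concentration <- d$concentration / 1000
  fit_uM <- fitSaturation(d_uM)
  expect_equal(kd(fit_uM) * 1000, kd(fit_nM), tolerance = 1e-4)
  expect_equal(bmax(fit_uM), bmax(fit_nM), tolerance = 1e-6)
})

test_that("input contracts are enforced", {
  expect_error(fitSaturation(data.frame(concentration = c(0, 100, 200),
                                        signal = 1:3)),
               "4 distinct")
  expect_error(fitSaturation(data.frame(concentration = c(-1, 0, 1, 2),
                                        signal = 1:4)),
               ">= 0")
})

test_that("median Kd recovery error stays below 15% at the six-point design with 5% noise", {
  errs <- vapply(1:200, function(i) {
    d <- genBindingData(bmax = 100, kdTrue = 250, b0 = 5, noiseSd = 0.05,
                        seed = 10000 + i)
    abs(kd(fitSaturation(d)) - 250) / 250
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("plateau estimation: onset, flat and right-censored cases", {
  dose <- c(0, 10, 20, 30, 40)
  resp <- c(2, 35, 80, 100, 100.5)    # plateau onset at 30
  est <- doseResponsePlateau(dose, resp)
  expect_true(abs(est$plateau_dose - 30) <= 10)  # within one dose step
  expect_false(est$censored)
  flat <- doseResponsePlateau(dose, rep(5, 5))
  expect_identical(flat$plateau_dose, 0)
  expect_false(flat$censored)
  rising <- doseResponsePlateau(dose, c(0, 10, 30, 60, 100))
  expect_true(rising$censored)
  expect_warning(doseResponsePlateau(dose, c(0, 50, 10, 60, 100)),
                 "monotonicity")
})

test_that("motif binding comparison recovers the constructed rank order", {
  set.seed(21)
  means <- c(APV = 100, FSM = 60, ISV = 55, ITV = 50, EET = 12, EEE = 10)
  d <- do.call(rbind, lapply(names(means), function(m)
    data.frame(motif = m, signal = rnorm(8, means[m], 4))))
  res <- compareMotifBinding(d)
  expect_identical(res$summary$motif[1], "APV")
  expect_true(all(res$summary$motif[5:6] %in% c("EET", "EEE")))
  ## strong vs references significant after Holm correction
  tt <- res$tests
  expect_true(all(tt$significant[tt$motif %in% c("FSM", "ISV", "ITV") &
                                   tt$reference == "APV"]))
  expect_true(all(tt$significant[tt$motif %in% c("FSM", "ISV", "ITV") &
                                   tt$reference == "EET"]))
})

test_that("identical distributions rarely reach significance (type-I control)", {
  set.seed(33)
  hits <- vapply(1:60, function(i) {
    d <- data.frame(motif = rep(c("APV", "EET", "ITV"), each = 7),
                    signal = rnorm(21, 50, 5))
    res <- compareMotifBinding(d)
    any(res$tests$significant)
  }, logical(1))
  ## familywise alpha = 0.05 under Holm; allow Monte-Carlo slack
  expect_lt(mean(hits), 0.2)
})

test_that("single-replicate motifs get means only, no tests", {
  d <- data.frame(motif = c("APV", "APV", "EET"), signal = c(10, 12, 3))
  res <- compareMotifBinding(d)
  expect_true(is.na(res$summary$sem[res$summary$motif == "EET"]))
  expect_true(is.null(res$tests) || !"EET" %in% res$tests$motif)
})
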