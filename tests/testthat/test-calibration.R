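test_that("dimer derivatives follow mass action and conserve totals", {
  d1 <- dimerDerivatives(c(D = 1, A = 1, DA = 0), a = 0.1, d = 0.1)
  expect_equal(d1[["DA"]], 0.1)
  expect_equal(d1[["D"]], -0.1)

  # equilibrium state: a A D = d DA
  d2 <- dimerDerivatives(c(D = 0.5, A = 0.5, DA = 0.25), a = 0.1, d = 0.1)
  expect_equal(unname(d2), c(0, 0, 0))

  # a = 0: complex only decays
  d3 <- dimerDerivatives(c(D = 0.3, A = 0.7, DA = 0.4), a = 0, d = 0.2)
  expect_lte(d3[["DA"]], 0)

  # conservation: dD + dDA = 0 and dA + dDA = 0 for random states
  set.seed(1)
  for (i in 1:20) {
    st <- c(D = runif(1), A = runif(1), DA = runif(1))
    dd <- dimerDerivatives(st, a = runif(1, 0, 0.5), d = runif(1, 0, 0.5))
    expect_equal(dd[["D"]] + dd[["DA"]], 0)
    expect_equal(dd[["A"]] + dd[["DA"]], 0)
  }
})

test_that("steady-state bound fraction matches the quadratic closed form", {
  # a = d, equal unit start: (3 - sqrt(5))/2
  expect_equal(steadyStateBoundFraction(0.1, 0.1), (3 - sqrt(5)) / 2,
               tolerance = 1e-9)
  # irreversible limit binds all donor; no association binds none
  expect_equal(steadyStateBoundFraction(0.1, 0), 1, tolerance = 1e-4)
  expect_identical(steadyStateBoundFraction(0, 0.2), 0)

  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, 0.01, 0.5); d <- runif(1, 0.01, 0.5)
    expect_equal(steadyStateBoundFraction(a, d), quadraticBoundFraction(a, d),
                 tolerance = 1e-7)
  }
})

test_that("bound fraction is monotone in the rates", {
  as <- c(0.05, 0.1, 0.2, 0.4)
  bf_a <- vapply(as, steadyStateBoundFraction, numeric(1), d = 0.1)
  expect_true(all(diff(bf_a) > 0))
  ds <- c(0.05, 0.1, 0.2, 0.4)
  bf_d <- vapply(ds, function(d) steadyStateBoundFraction(0.1, d), numeric(1))
  expect_true(all(diff(bf_d) < 0))
})

test_that("scanRates accepts pairs on the affinity ratio line", {
  sr <- scanRates(0.28, gridStep = coarseGrid$gridStep, tol = coarseGrid$tol)
  p <- acceptedPairs(sr)
  expect_gt(nrow(p), 0)
  expect_true(all(abs(p$boundFraction - 0.28) <= coarseGrid$tol))
  # accepted pairs lie near d = a (1-b)^2 / b
  ratio <- 0.72^2 / 0.28
  expect_true(all(abs(p$d / p$a - ratio) < 0.05 * ratio))

  # higher affinity -> larger a/d ratio
  srHi <- scanRates(0.36, gridStep = coarseGrid$gridStep, tol = coarseGrid$tol)
  expect_gt(mean(acceptedPairs(srHi)$a / acceptedPairs(srHi)$d),
            mean(p$a / p$d))

  # b = 0 accepts exactly the a = 0 column
  sr0 <- scanRates(0, gridStep = 0.1)
  expect_true(all(acceptedPairs(sr0)$a == 0))
  expect_true(all(acceptedPairs(sr0)$boundFraction == 0))

  # an unattainably tight tolerance on a coarse grid is a distinct error
  expect_error(scanRates(0.281117, gridStep = 0.1, tol = 1e-9),
               "no grid pair")
})

test_that("closed-form pre-filter matches brute-force integration", {
  srFast <- scanRates(0.3, gridMax = 0.1, gridStep = 5e-3, tol = 2e-3)
  srSlow <- scanRates(0.3, gridMax = 0.1, gridStep = 5e-3, tol = 2e-3,
                      exhaustive = TRUE)
  expect_equal(acceptedPairs(srFast)[, c("a", "d")],
               acceptedPairs(srSlow)[, c("a", "d")])
})

test_that("selectRate policies behave and are reproducible", {
  sr <- scanRates(0.28, gridStep = coarseGrid$gridStep, tol = coarseGrid$tol)
  p <- acceptedPairs(sr)
  expect_equal(selectRate(sr, "fastest")[["a"]], max(p$a))
  expect_equal(selectRate(sr, "slowest")[["a"]], min(p$a[p$a > 0]))
  expect_identical(selectRate(sr, "random", seed = 11),
                   selectRate(sr, "random", seed = 11))
})

test_that("affinity tables round-trip through CSV", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(data.frame(label = names(wtAffinities()),
                              binding = unname(wtAffinities()),
                              source_note = "measured"),
                   path, row.names = FALSE)
  expect_identical(readAffinities(path), wtAffinities())
})

test_that("calibrateAll produces a complete, reproducible rate set", {
  rs <- coarseCalibrate(seed = 3)
  rv <- rateValues(rs)
  expect_length(rv, 10)
  expect_true(all(rv >= 0))
  # each selected pair reproduces its target affinity
  for (lab in names(rs@provenance)) {
    pr <- rs@provenance[[lab]]
    expect_lt(abs(steadyStateBoundFraction(pr$a, pr$d) - pr$target),
              coarseGrid$tol * 1.01)
  }
  expect_identical(rateValues(coarseCalibrate(seed = 3)), rv)
  expect_error(calibrateAll(c(BRAVOWOX5 = 0.2)), "missing affinity")

  # trimer-path rates are unchanged between WT and PrD-deletion calibration
  rsD <- coarseCalibrate(deltaPrdAffinities(), seed = 3)
  tr <- c("a_WOX5PLT3BRAVO1", "d_WOX5PLT3BRAVO1",
          "a_WOX5PLT3BRAVO2", "d_WOX5PLT3BRAVO2",
          "a_BRAVOWOX5", "d_BRAVOWOX5")
  expect_identical(rateValues(rsD)[tr], rv[tr])
  expect_false(identical(rateValues(rsD)[["d_WOX5PLT3"]], rv[["d_WOX5PLT3"]]))
})
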