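test_that("amplitude-weighted lifetime sums components correctly", {
  one <- new("FlimFit", amplitudes = 1, lifetimes = 3.0, background = 0,
             logLik = 0, converged = TRUE)
  expect_equal(amplitudeWeightedLifetime(one), 3.0)
  two <- new("FlimFit", amplitudes = c(0.5, 0.5), lifetimes = c(1, 3),
             background = 0, logLik = 0, converged = TRUE)
  expect_equal(amplitudeWeightedLifetime(two), 2.0)
  mix <- new("FlimFit", amplitudes = c(0.28, 0.72), lifetimes = c(1.2, 3.0),
             background = 0, logLik = 0, converged = TRUE)
  expect_equal(amplitudeWeightedLifetime(mix), 2.496)
})

test_that("donor-only fitting recovers the simulated lifetime", {
  d <- simulateDecay(DecayParams(alphaF = 0, tauD = 3.0, nPhotons = 1e6,
                                 seed = 31))
  fit <- fitDonorOnly(d)
  expect_true(fit@converged)
  expect_gt(amplitudeWeightedLifetime(fit), 2.97)
  expect_lt(amplitudeWeightedLifetime(fit), 3.03)

  d2 <- simulateDecay(DecayParams(alphaF = 0, tauD = 2.5, nPhotons = 3e5,
                                  seed = 32))
  expect_equal(amplitudeWeightedLifetime(fitDonorOnly(d2)), 2.5,
               tolerance = 0.02)

  # degenerate input
  expect_error(new("DecayHistogram", time = 1:10, counts = rep(0, 10),
                   window = 31.25) |> validObject(),
               "photons")
})

test_that("FRET fitting recovers amplitude and lifetime with tauD fixed", {
  d <- simulateDecay(DecayParams(alphaF = 0.3, tauF = 1.2, tauD = 3.0,
                                 nPhotons = 1e6, seed = 33))
  fit <- fitFret(d, tauD = 3.0)
  expect_gt(fit@amplitudes[1], 0.27)
  expect_lt(fit@amplitudes[1], 0.33)
  expect_equal(fit@lifetimes[1], 1.2, tolerance = 0.05)
  expect_false(fit@boundary)

  # no FRET: fitted amplitude stays below the 10 percent binding cutoff
  d0 <- simulateDecay(DecayParams(alphaF = 0, nPhotons = 1e5, seed = 34))
  f0 <- fitFret(d0, tauD = 3.0)
  expect_lt(100 * f0@amplitudes[1], 10)

  # efficiency beyond the 80 percent cap pushes tauF onto its bound
  dHi <- simulateDecay(DecayParams(alphaF = 0.5, tauF = 0.3, tauD = 3.0,
                                   nPhotons = 3e5, seed = 35))
  fHi <- fitFret(dHi, tauD = 3.0)
  expect_true(fHi@boundary)
  expect_equal(fHi@lifetimes[1], 0.2 * 3.0, tolerance = 0.01)
})

test_that("doubling the photon count narrows the amplitude error", {
  errAt <- function(n, seeds) {
    median(vapply(seeds, function(s) {
      d <- simulateDecay(DecayParams(alphaF = 0.3, tauF = 1.2, nPhotons = n,
                                     seed = s))
      abs(fitFret(d, tauD = 3.0)@amplitudes[1] - 0.3)
    }, numeric(1)))
  }
  expect_lt(errAt(8e4, 41:48), errAt(5e3, 41:48) + 0.002)
})

test_that("binding and efficiency derive from the fit as published", {
  f <- new("FlimFit", amplitudes = c(0.28, 0.72), lifetimes = c(1.2, 3.0),
           background = 0, logLik = 0, converged = TRUE)
  br <- bindingAndEfficiency(f, tauD = 3.0)
  expect_equal(br@binding, 28)
  expect_equal(br@fretEfficiency, 60)
  expect_equal(br@tauAv, 2.496)

  # boundary case: full binding at the lowest admissible efficiency
  fb <- new("FlimFit", amplitudes = c(1, 0), lifetimes = c(2.7, 3.0),
            background = 0, logLik = 0, converged = TRUE)
  brb <- bindingAndEfficiency(fb, tauD = 3.0)
  expect_equal(brb@binding, 100)
  expect_equal(brb@fretEfficiency, 10)

  mono <- new("FlimFit", amplitudes = 1, lifetimes = 3, background = 0,
              logLik = 0, converged = TRUE)
  expect_error(bindingAndEfficiency(mono, 3.0), "two-component")
})
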