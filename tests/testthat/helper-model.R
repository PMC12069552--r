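# shared fixtures: coarse calibration settings keep unit tests fast; the
# acceptance tests use the full reference grid

coarseGrid <- list(gridStep = 2e-3, tol = 1e-4)

coarseCalibrate <- function(affinities = wtAffinities(), seed = 1L,
                            policy = "random") {
  calibrateAll(affinities, gridStep = coarseGrid$gridStep,
               tol = coarseGrid$tol, policy = policy, seed = seed)
}

# independent closed-form oracle: smaller root of a x^2 - (2a + d) x + a = 0
quadraticBoundFraction <- function(a, d) {
  if (a == 0) return(0)
  roots <- polyroot(c(a, -(2 * a + d), a))
  min(Re(roots))
}

# integrate the seven-species system with an independent deSolve call,
# returning the trajectory (for conservation checks)
scnTrajectory <- function(totals, rates, times = c(0, 10^(0:4))) {
  y0 <- c(WOX5 = totals[[1]], BRAVO = totals[[2]], PLT3 = totals[[3]],
          WOX5PLT3 = 0, BRAVOPLT3 = 0, BRAVOWOX5 = 0, WOX5PLT3BRAVO = 0)
  deSolve::lsoda(y0, times, function(t, y, p) list(scnDerivatives(y, rates)),
                 NULL, rtol = 1e-10, atol = 1e-12)
}

speciesTotals <- function(state) {
  c(WOX5 = sum(state[c("WOX5", "WOX5PLT3", "BRAVOWOX5", "WOX5PLT3BRAVO")]),
    BRAVO = sum(state[c("BRAVO", "BRAVOPLT3", "BRAVOWOX5", "WOX5PLT3BRAVO")]),
    PLT3 = sum(state[c("PLT3", "WOX5PLT3", "BRAVOPLT3", "WOX5PLT3BRAVO")]))
}
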