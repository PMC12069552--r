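test_that("seven-species derivatives vanish where they must", {
  rs <- RateSet(a = 0, d = 0)
  st <- c(WOX5 = 0.5, BRAVO = 0.3, PLT3 = 0.7, WOX5PLT3 = 0.1,
          BRAVOPLT3 = 0.2, BRAVOWOX5 = 0.05, WOX5PLT3BRAVO = 0.02)
  expect_equal(unname(scnDerivatives(st, rs)), rep(0, 7))

  # no dimers yet: the trimer cannot form, whatever the rates
  rs2 <- RateSet(a = 0.3, d = 0)
  free <- c(WOX5 = 1, BRAVO = 1, PLT3 = 1, WOX5PLT3 = 0, BRAVOPLT3 = 0,
            BRAVOWOX5 = 0, WOX5PLT3BRAVO = 0)
  expect_equal(scnDerivatives(free, rs2)[["WOX5PLT3BRAVO"]], 0)
})

test_that("derivative groups cancel algebraically at random states", {
  set.seed(42)
  for (i in 1:25) {
    st <- setNames(runif(7, 0, 1),
                   c("WOX5", "BRAVO", "PLT3", "WOX5PLT3", "BRAVOPLT3",
                     "BRAVOWOX5", "WOX5PLT3BRAVO"))
    rs <- RateSet(a = runif(5, 0, 0.5), d = runif(5, 0, 0.5))
    dv <- scnDerivatives(st, rs)
    wox5 <- dv[["WOX5"]] + dv[["WOX5PLT3"]] + dv[["BRAVOWOX5"]] +
      dv[["WOX5PLT3BRAVO"]]
    bravo <- dv[["BRAVO"]] + dv[["BRAVOPLT3"]] + dv[["BRAVOWOX5"]] +
      dv[["WOX5PLT3BRAVO"]]
    plt3 <- dv[["PLT3"]] + dv[["WOX5PLT3"]] + dv[["BRAVOPLT3"]] +
      dv[["WOX5PLT3BRAVO"]]
    expect_equal(wox5, 0, tolerance = 1e-14)
    expect_equal(bravo, 0, tolerance = 1e-14)
    expect_equal(plt3, 0, tolerance = 1e-14)
  }
})

test_that("protein totals are conserved along trajectories", {
  set.seed(5)
  for (i in 1:5) {
    rs <- RateSet(a = runif(5, 0.02, 0.5), d = runif(5, 0.02, 0.5))
    tot <- runif(3, 0.1, 1)
    tr <- scnTrajectory(tot, rs, times = c(0, 1, 10, 100, 1000))
    t0 <- speciesTotals(tr[1, -1])
    for (r in 2:nrow(tr)) {
      tt <- speciesTotals(tr[r, -1])
      expect_true(all(abs(tt - t0) / t0 <= 1e-9))
    }
  }
})

test_that("simulateCell matches an algebraically solved fixed point", {
  skip_if_not_installed("pracma")
  rs <- RateSet(a = 0.1, d = 0.05)
  st <- simulateCell(c(WOX5 = 1, BRAVO = 1, PLT3 = 1), rs)

  # independent oracle: solve the steady-state system for the complexes
  # given the conservation laws, with a generic nonlinear root finder
  rv <- rateValues(rs)
  f <- function(x) {
    full <- c(WOX5 = 1 - x[1] - x[3] - x[4], BRAVO = 1 - x[2] - x[3] - x[4],
              PLT3 = 1 - x[1] - x[2] - x[4], WOX5PLT3 = x[1],
              BRAVOPLT3 = x[2], BRAVOWOX5 = x[3], WOX5PLT3BRAVO = x[4])
    scnDerivatives(full, rv)[c("WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5",
                               "WOX5PLT3BRAVO")]
  }
  sol <- pracma::fsolve(f, x0 = c(0.2, 0.2, 0.2, 0.1), tol = 1e-12)
  expect_equal(unname(st[c("WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5",
                           "WOX5PLT3BRAVO")]),
               unname(sol$x), tolerance = 1e-6)
})

test_that("degenerate cells and mass-action scaling behave", {
  rs <- RateSet(a = 0.2, d = 0.1)
  st <- simulateCell(c(WOX5 = 0, BRAVO = 0, PLT3 = 0.4), rs)
  expect_equal(st[["PLT3"]], 0.4)
  expect_equal(unname(st[c("WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5",
                           "WOX5PLT3BRAVO")]), rep(0, 4))

  # doubling the totals increases every bound fraction (mass action)
  s1 <- simulateCell(c(WOX5 = 0.4, BRAVO = 0.4, PLT3 = 0.4), rs)
  s2 <- simulateCell(c(WOX5 = 0.8, BRAVO = 0.8, PLT3 = 0.8), rs)
  bound1 <- 1 - s1[c("WOX5", "BRAVO", "PLT3")] / 0.4
  bound2 <- 1 - s2[c("WOX5", "BRAVO", "PLT3")] / 0.8
  expect_true(all(bound2 > bound1))
})

test_that("steady state is reached from random feasible partitions too", {
  rs <- RateSet(a = c(0.1, 0.3, 0.2, 0.15, 0.25), d = c(0.2, 0.1, 0.3, 0.2, 0.1))
  st <- simulateCell(c(WOX5 = 0.6, BRAVO = 0.8, PLT3 = 0.5), rs,
                     randomStarts = 3L, seed = 2)
  expect_lt(attr(st, "diagnostics")$multistartSpread, 1e-6)
})

test_that("simulateNiche builds a consistent SummarizedExperiment", {
  rs <- RateSet(a = 0.1, d = 0.05)
  ns <- simulateNiche(defaultWtAbundance(), rs, scenario = "demo")
  expect_s4_class(ns, "NicheSignature")
  m <- signatureMatrix(ns)
  expect_identical(colnames(m), c("SI", "QC", "CSC", "CC"))
  cd <- SummarizedExperiment::colData(ns)

  # totals reconstruct from the parts
  for (j in seq_len(ncol(m))) {
    tt <- speciesTotals(m[, j])
    expect_equal(unname(tt[["WOX5"]]), unname(cd$totalWOX5[j]), tolerance = 1e-6)
    expect_equal(unname(tt[["BRAVO"]]), unname(cd$totalBRAVO[j]), tolerance = 1e-6)
    expect_equal(unname(tt[["PLT3"]]), unname(cd$totalPLT3[j]), tolerance = 1e-6)
  }
  expect_identical(S4Vectors::metadata(ns)$scenario, "demo")
  expect_error(simulateNiche(defaultWtAbundance()@means[1:3, ], rs),
               "missing cell type")
})

test_that("heatmap and radar exports are shaped and normalised correctly", {
  ns <- simulateNiche(defaultWtAbundance(), RateSet(a = 0.1, d = 0.05))
  hm <- heatmapMatrix(ns)
  expect_equal(dim(hm), c(7L, 4L))
  expect_true(all(apply(hm, 1, max) == 1))
  rd <- radarData(ns)
  expect_equal(nrow(rd), 16L)
  expect_setequal(unique(rd$complex),
                  c("WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5", "WOX5PLT3BRAVO"))
})
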