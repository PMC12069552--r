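test_that("default abundance configuration matches the described pattern", {
  cfg <- defaultWtAbundance()
  m <- cfg@means
  # anchor: BRAVO in stele initials is the global maximum, exactly 1
  expect_identical(m["SI", "BRAVO"], 1)
  expect_equal(sum(m == 1), 1)
  # BRAVO strictly decreasing towards the columella
  expect_true(all(diff(m[, "BRAVO"]) < 0))
  # WOX5 peaks in the QC, is lower in SI/CSC, near absent in CC
  expect_identical(names(which.max(m[, "WOX5"])), "QC")
  expect_lt(m["CC", "WOX5"], 0.05)
  expect_lt(m["CC", "BRAVO"], 0.05)
  # PLT3 similar in SI/QC/CSC, lower in CC
  expect_lt(max(m[c("SI", "QC", "CSC"), "PLT3"]) /
              min(m[c("SI", "QC", "CSC"), "PLT3"]), 1.5)
  expect_lt(m["CC", "PLT3"], min(m[c("SI", "QC", "CSC"), "PLT3"]))
  expect_error(validObject(new("AbundanceConfig", means = m * 0.5, sd = 0.05,
                               nucleiRange = c(1L, 3L), nRoots = 28L,
                               seed = 1L)),
               "anchor")
})

test_that("abundance sampling is deterministic, truncated and well shaped", {
  cfg <- defaultWtAbundance(sd = 0, nRoots = 4L)
  tab <- sampleAbundances(cfg)
  # zero noise reproduces the configured means exactly
  for (i in seq_len(nrow(tab)))
    expect_identical(tab$intensity[i],
                     cfg@means[as.character(tab$cell_type[i]),
                               as.character(tab$protein[i])])

  cfg2 <- defaultWtAbundance(sd = 0.1, nRoots = 28L, seed = 9L)
  t1 <- sampleAbundances(cfg2)
  t2 <- sampleAbundances(cfg2)
  expect_identical(t1, t2)
  expect_true(all(t1$intensity >= 0))
  # 28 root-level means per (cell type, protein)
  perGroup <- with(unique(t1[, c("root_id", "cell_type", "protein")]),
                   table(cell_type, protein))
  expect_true(all(perGroup == 28))
  # nuclei counts stay within the configured range
  nn <- stats::aggregate(nucleus_id ~ root_id + cell_type + protein, t1, max)
  expect_true(all(nn$nucleus_id >= 1 & nn$nucleus_id <= 3))
  # root_mean is the mean over that root's nuclei
  one <- t1[t1$root_id == 1 & t1$cell_type == "QC" & t1$protein == "WOX5", ]
  expect_equal(unique(one$root_mean), mean(one$intensity))
})

test_that("binding samples follow the generating distribution", {
  bs <- sampleBinding(28.0, 11.7, 10000, seed = 2)
  expect_lt(abs(mean(bs@samples) - 28.0), 0.5)
  expect_identical(sampleBinding(5, 3, 50, seed = 4)@samples,
                   sampleBinding(5, 3, 50, seed = 4)@samples)
  # sd = 0 gives exact values; negative draws are kept
  expect_true(all(sampleBinding(8.8, 0, 20)@samples == 8.8))
  neg <- sampleBinding(0, 6, 500, seed = 1)
  expect_true(any(neg@samples < 0))
  expect_error(sampleBinding(10, 5, 0), "n must be")
})

test_that("decay simulation honours its parameters and conventions", {
  expect_error(DecayParams(tauD = 2, tauF = 2.5), "smaller than tauD")
  expect_error(DecayParams(nPhotons = 0), "positive")

  # pure donor decay: wrapped-exponential mean arrival time
  p <- DecayParams(alphaF = 0, sigmaIrf = 0, nPhotons = 1e6, seed = 21)
  d <- simulateDecay(p)
  q <- exp(-p@window / p@tauD)
  oracleMean <- p@tauD - p@window * q / (1 - q)
  empMean <- sum(d@time * d@counts) / sum(d@counts)
  expect_lt(abs(empMean - oracleMean), 0.01)

  # photon-count amplitude convention: alphaF is the expected share of
  # FRET-component photons
  p2 <- DecayParams(alphaF = 0.4, nPhotons = 2e5, seed = 8)
  d2 <- simulateDecay(p2)
  expect_lt(abs(d2@params$nFret / p2@nPhotons - 0.4), 0.01)

  # determinism
  expect_identical(simulateDecay(p2)@counts, simulateDecay(p2)@counts)

  # background adds roughly its expectation
  p3 <- DecayParams(alphaF = 0, background = 2, nPhotons = 1e4, seed = 3)
  d3 <- simulateDecay(p3)
  expect_lt(abs(sum(d3@counts) - (1e4 + 2 * 1024)) / (1e4 + 2 * 1024), 0.05)
})

test_that("decay histograms round-trip through CSV with sidecar", {
  d <- simulateDecay(DecayParams(alphaF = 0.2, nPhotons = 5e3, seed = 6))
  path <- tempfile(fileext = ".csv")
  writeDecay(d, path)
  d2 <- readDecay(path)
  expect_equal(d2@counts, d@counts)
  expect_equal(d2@window, d@window)
  expect_equal(d2@params$alphaF, 0.2)
  unlink(c(path, paste0(path, ".json")))
})
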