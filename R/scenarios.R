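## Named experiments: wild type, the PLT3 PrD-deletion perturbation, and
## the seven control simulations.

#' Wild-type binding affinity table
#'
#' The measured FRET-FLIM binding fractions used for calibration: BRAVO-WOX5
#' 22.4 percent, WOX5-PLT3 30.6, BRAVO-PLT3 28.0, trimer path 1 (BRAVO
#' binding the WOX5-PLT3 dimer) 36.3 and trimer path 2 (WOX5 binding the
#' BRAVO-PLT3 dimer) 29.8. The BRAVO-PLT3 value is from the first
#' measurement series; the independent repeat (22.8 percent) is available
#' via \code{bravoPlt3Repeat}.
#'
#' @param bravoPlt3Repeat Use the repeat measurement (0.228) for BRAVO-PLT3.
#' @return Named numeric of binding fractions.
#' @export
wtAffinities <- function(bravoPlt3Repeat = FALSE) {
  c(BRAVOWOX5 = 0.224,
    WOX5PLT3 = 0.306,
    BRAVOPLT3 = if (bravoPlt3Repeat) 0.228 else 0.280,
    WOX5PLT3BRAVO1 = 0.363,
    WOX5PLT3BRAVO2 = 0.298)
}

#' PrD-deletion affinity table
#'
#' Replaces the WOX5-PLT3 affinity by the value measured with the
#' PrD-deletion variant (18.5 percent) and BRAVO-PLT3 by 11.7 percent; the
#' trimer-path entries are kept at their wild-type values by default. The
#' re-measured trimer-path affinities for the variant (31.5 and 28.9
#' percent) can be substituted via \code{trimerAffinities}.
#'
#' @param wt Wild-type affinity table, default \code{wtAffinities()}.
#' @param trimerAffinities Optional numeric(2) replacing the two trimer-path
#'   entries, e.g. \code{c(0.315, 0.289)}.
#' @return Named numeric of binding fractions.
#' @export
deltaPrdAffinities <- function(wt = wtAffinities(), trimerAffinities = NULL) {
  out <- wt
  out["WOX5PLT3"] <- 0.185
  out["BRAVOPLT3"] <- 0.117
  if (!is.null(trimerAffinities)) {
    stopifnot(length(trimerAffinities) == 2L)
    out["WOX5PLT3BRAVO1"] <- trimerAffinities[1]
    out["WOX5PLT3BRAVO2"] <- trimerAffinities[2]
  }
  out
}

#' Names of the built-in scenarios
#' @return Character vector.
#' @export
scenarioNames <- function() c("wt", "dprd", paste0("c", 1:7))

#' Run a named scenario
#'
#' \code{"wt"} calibrates rates to the measured wild-type affinities and
#' simulates the niche at the measured abundances; \code{"dprd"} does the
#' same with the PrD-deletion affinity table (trimer-path rates identical to
#' the wild type under the same seed). Controls: \code{c1} equal association
#' and dissociation (a = d = 0.1) at measured abundances; \code{c2} a = 0.1,
#' d = 0.05 at measured abundances; \code{c3} a = 0.05, d = 0.1 at measured
#' abundances; \code{c4} calibrated rates at equal abundances; \code{c5}
#' equal rates and equal abundances; \code{c6} a = 0.1, d = 0.05 at equal
#' abundances; \code{c7} a = 0.05, d = 0.1 at equal abundances.
#'
#' @param name Scenario name, see \code{\link{scenarioNames}}.
#' @param abundance Abundance source for the measured scenarios, default
#'   \code{\link{defaultWtAbundance}()}.
#' @param equalLevel Common abundance of the equal-abundance controls,
#'   default 0.5.
#' @param rates Optional pre-calibrated \linkS4class{RateSet} (used for
#'   \code{wt}, \code{dprd} and \code{c4}; ignored by the fixed-rate
#'   controls). Calibration is otherwise run internally.
#' @param gridMax,gridStep,tol,policy,seed Calibration and selection
#'   settings, see \code{\link{calibrateAll}}.
#' @param trimerAffinities Passed to \code{\link{deltaPrdAffinities}} for
#'   the \code{dprd} scenario.
#' @param ... Passed to \code{\link{simulateNiche}}.
#' @return A \linkS4class{NicheSignature}.
#' @export
runScenario <- function(name, abundance = defaultWtAbundance(),
                        equalLevel = 0.5, rates = NULL, gridMax = 0.5,
                        gridStep = 2e-4, tol = 1e-5, policy = "random",
                        seed = 1L, trimerAffinities = NULL, ...) {
  name <- match.arg(name, scenarioNames())
  calib <- function(aff) calibrateAll(aff, gridMax = gridMax,
                                      gridStep = gridStep, tol = tol,
                                      policy = policy, seed = seed)
  ab <- abundanceMatrix(abundance)
  eq <- equalAbundanceMatrix(equalLevel)
  spec <- switch(name,
    wt   = list(ab = ab, rs = if (is.null(rates)) calib(wtAffinities()) else rates),
    dprd = list(ab = ab, rs = if (is.null(rates))
      calib(deltaPrdAffinities(trimerAffinities = trimerAffinities)) else rates),
    c1 = list(ab = ab, rs = RateSet(a = 0.1, d = 0.1)),
    c2 = list(ab = ab, rs = RateSet(a = 0.1, d = 0.05)),
    c3 = list(ab = ab, rs = RateSet(a = 0.05, d = 0.1)),
    c4 = list(ab = eq, rs = if (is.null(rates)) calib(wtAffinities()) else rates),
    c5 = list(ab = eq, rs = RateSet(a = 0.1, d = 0.1)),
    c6 = list(ab = eq, rs = RateSet(a = 0.1, d = 0.05)),
    c7 = list(ab = eq, rs = RateSet(a = 0.05, d = 0.1)))
  simulateNiche(spec$ab, spec$rs, scenario = name, ...)
}

#' Compare two niche signatures
#'
#' Entry-wise absolute and relative differences, the qualitative pattern
#' flags of both signatures, and an L1 distance between the max-normalised
#' signature matrices (scale-free, zero iff identical).
#'
#' @param A,B \linkS4class{NicheSignature} objects with matching species and
#'   cell types.
#' @return A \linkS4class{SignatureComparison}.
#' @export
compareSignatures <- function(A, B) {
  mA <- signatureMatrix(A); mB <- signatureMatrix(B)
  if (!identical(dimnames(mA), dimnames(mB)))
    stop("signatures have mismatched species/cell types")
  abs_ <- mB - mA
  rel <- abs_ / ifelse(mA == 0, NA_real_, mA)
  dist <- sum(abs(mA / max(mA) - mB / max(mB)))
  new("SignatureComparison", absDiff = abs_, relDiff = rel,
      flagsA = signatureFlags(A), flagsB = signatureFlags(B),
      distance = dist)
}
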