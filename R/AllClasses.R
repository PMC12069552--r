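## Central S4 containers.

COMPLEX_LABELS <- c("BRAVOWOX5", "WOX5PLT3", "BRAVOPLT3",
                    "WOX5PLT3BRAVO1", "WOX5PLT3BRAVO2")

CELL_TYPES <- c("SI", "QC", "CSC", "CC")
PROTEINS   <- c("BRAVO", "PLT3", "WOX5")

SPECIES <- c("WOX5", "BRAVO", "PLT3",
             "WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5", "WOX5PLT3BRAVO")

rateNames <- function() {
  as.vector(rbind(paste0("a_", COMPLEX_LABELS), paste0("d_", COMPLEX_LABELS)))
}

#' Association/dissociation rate constants for the niche model
#'
#' Holds the ten mass-action rate constants of the seven-species complex
#' formation system: one association (\code{a_}) and one dissociation
#' (\code{d_}) rate for each of the three heterodimers and the two
#' trimer-formation paths (binding of BRAVO to the WOX5-PLT3 dimer, and of
#' WOX5 to the BRAVO-PLT3 dimer). Rates are in arbitrary units.
#'
#' @slot rates Named numeric vector of length 10; names are
#'   \code{a_<complex>} and \code{d_<complex>} for the complex labels
#'   \code{BRAVOWOX5}, \code{WOX5PLT3}, \code{BRAVOPLT3},
#'   \code{WOX5PLT3BRAVO1}, \code{WOX5PLT3BRAVO2}.
#' @slot provenance List with per-complex calibration details (target binding
#'   fraction, selection policy, number of accepted grid pairs); may be empty
#'   for manually constructed rate sets.
#'
#' @export
setClass("RateSet",
  representation(rates = "numeric", provenance = "list"),
  prototype(provenance = list()))

setValidity("RateSet", function(object) {
  r <- object@rates
  if (length(r) != 10L || !identical(names(r), rateNames()))
    return("rates must be a named numeric(10) with names a_/d_ per complex")
  if (anyNA(r) || any(r < 0))
    return("all rates must be non-negative and non-missing")
  TRUE
})

#' Result of a grid scan for one binding affinity
#'
#' All (association, dissociation) grid pairs whose dimer steady state
#' reproduces a target binding fraction within tolerance.
#'
#' @slot label Complex label the scan was run for.
#' @slot target Target binding fraction in [0, 1].
#' @slot pairs data.frame with columns \code{a}, \code{d} and
#'   \code{boundFraction} (the ODE-verified steady-state bound fraction).
#' @slot tol Acceptance tolerance on the bound fraction.
#' @slot gridMax,gridStep Scan grid specification (endpoints inclusive).
#'
#' @export
setClass("ScanResult",
  representation(label = "character", target = "numeric", pairs = "data.frame",
                 tol = "numeric", gridMax = "numeric", gridStep = "numeric"))

setValidity("ScanResult", function(object) {
  if (length(object@target) != 1L || object@target < 0 || object@target > 1)
    return("target binding fraction must be a single value in [0, 1]")
  if (!all(c("a", "d", "boundFraction") %in% names(object@pairs)))
    return("pairs must have columns a, d, boundFraction")
  TRUE
})

#' Configuration of the synthetic abundance generator
#'
#' Mean relative fluorescence intensity per (cell type, protein), plus the
#' per-nucleus measurement noise and the sampling design (number of roots,
#' nuclei measured per cell type and root). Means are normalised so that the
#' overall maximum -- BRAVO in the stele initials -- equals 1.
#'
#' @slot means 4 x 3 numeric matrix (rows SI, QC, CSC, CC; columns BRAVO,
#'   PLT3, WOX5) of mean relative intensities in [0, 1]; exactly one entry
#'   is 1 (the normalisation anchor).
#' @slot sd Per-nucleus Gaussian noise standard deviation (>= 0).
#' @slot nucleiRange Integer range (min, max) of nuclei measured per cell
#'   type and root.
#' @slot nRoots Number of roots (biological replicates).
#' @slot seed Integer seed for reproducible sampling.
#'
#' @export
setClass("AbundanceConfig",
  representation(means = "matrix", sd = "numeric", nucleiRange = "integer",
                 nRoots = "integer", seed = "integer"))

setValidity("AbundanceConfig", function(object) {
  m <- object@means
  if (!identical(rownames(m), CELL_TYPES) || !identical(colnames(m), PROTEINS))
    return("means must be a 4x3 matrix with rows SI,QC,CSC,CC and columns BRAVO,PLT3,WOX5")
  if (anyNA(m) || any(m < 0) || any(m > 1))
    return("all means must lie in [0, 1]")
  if (sum(m == 1) != 1L)
    return("exactly one (cell type, protein) mean must equal 1 (normalisation anchor)")
  if (object@sd < 0) return("sd must be >= 0")
  if (length(object@nucleiRange) != 2L || any(object@nucleiRange < 1L) ||
      object@nucleiRange[1] > object@nucleiRange[2])
    return("nucleiRange must be an increasing positive integer pair")
  if (object@nRoots < 1L) return("nRoots must be positive")
  TRUE
})

#' A set of synthetic per-nucleus binding observations
#'
#' Binding percentages drawn around a generating mean; values may be
#' negative, as observed for donor-only and negative controls.
#'
#' @slot label Sample label.
#' @slot samples Numeric vector of binding values (percent).
#' @slot mean,sd Generating mean and standard deviation (percent).
#'
#' @export
setClass("BindingSampleSet",
  representation(label = "character", samples = "numeric",
                 mean = "numeric", sd = "numeric"))

setValidity("BindingSampleSet", function(object) {
  if (length(object@samples) < 1L) return("at least one sample required")
  if (object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' Parameters of a simulated TCSPC fluorescence decay
#'
#' @slot tauD Donor-only fluorescence lifetime (ns).
#' @slot tauF Lifetime of the FRET-shortened component (ns); 0 < tauF < tauD.
#' @slot alphaF Amplitude fraction of the FRET component in [0, 1]. The
#'   amplitude convention is photon-count based: \code{alphaF} is the
#'   probability that a detected signal photon stems from the FRET
#'   component, read as the fraction of donor molecules undergoing FRET
#'   under equal molecular brightness.
#' @slot sigmaIrf Gaussian instrument-response width (ns).
#' @slot background Expected background counts per bin.
#' @slot window Repetition window (ns); 31.25 ns corresponds to the 32 MHz
#'   pulse rate used for the FRET-FLIM acquisitions.
#' @slot nPhotons Number of signal photons to draw.
#' @slot nBins Number of histogram bins across the window.
#' @slot seed Integer seed.
#'
#' @export
setClass("DecayParams",
  representation(tauD = "numeric", tauF = "numeric", alphaF = "numeric",
                 sigmaIrf = "numeric", background = "numeric",
                 window = "numeric", nPhotons = "integer", nBins = "integer",
                 seed = "integer"))

setValidity("DecayParams", function(object) {
  if (object@tauF <= 0 || object@tauD <= 0) return("lifetimes must be positive")
  if (object@tauF >= object@tauD) return("tauF must be smaller than tauD")
  if (object@alphaF < 0 || object@alphaF > 1) return("alphaF must lie in [0, 1]")
  if (object@sigmaIrf < 0) return("sigmaIrf must be >= 0")
  if (object@background < 0) return("background must be >= 0")
  if (object@window <= 0) return("window must be positive")
  if (object@nPhotons < 1L) return("nPhotons must be positive")
  if (object@nBins < 8L) return("nBins must be at least 8")
  TRUE
})

#' Binned photon-arrival histogram
#'
#' @slot time Bin centres (ns), strictly increasing.
#' @slot counts Non-negative photon counts per bin.
#' @slot window Repetition window (ns).
#' @slot irfSigma Gaussian IRF width used for analytic reconvolution during
#'   fitting (ns); 0 means no IRF broadening.
#' @slot params List of generating parameters (empty for measured data).
#'
#' @export
setClass("DecayHistogram",
  representation(time = "numeric", counts = "numeric", window = "numeric",
                 irfSigma = "numeric", params = "list"),
  prototype(irfSigma = 0, params = list()))

setValidity("DecayHistogram", function(object) {
  if (length(object@time) != length(object@counts))
    return("time and counts must have equal length")
  if (any(diff(object@time) <= 0)) return("bin centres must be strictly increasing")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (sum(object@counts) <= 0) return("histogram must contain photons")
  TRUE
})

#' Maximum-likelihood multi-exponential decay fit
#'
#' @slot amplitudes Normalised component amplitudes (sum to 1).
#' @slot lifetimes Component lifetimes (ns), same length as amplitudes.
#' @slot background Fitted total background counts.
#' @slot logLik Poisson log-likelihood at the optimum.
#' @slot converged Logical; optimiser convergence.
#' @slot boundary Logical; TRUE when a constrained lifetime sits on its bound.
#'
#' @export
setClass("FlimFit",
  representation(amplitudes = "numeric", lifetimes = "numeric",
                 background = "numeric", logLik = "numeric",
                 converged = "logical", boundary = "logical"),
  prototype(boundary = FALSE))

setValidity("FlimFit", function(object) {
  k <- length(object@amplitudes)
  if (k < 1L || k > 2L) return("1 or 2 components supported")
  if (length(object@lifetimes) != k) return("amplitudes and lifetimes must match")
  if (any(object@amplitudes < 0)) return("amplitudes must be non-negative")
  if (abs(sum(object@amplitudes) - 1) > 1e-8)
    return("amplitudes must be normalised to sum to 1")
  if (any(object@lifetimes <= 0)) return("lifetimes must be positive")
  TRUE
})

#' Binding and FRET efficiency derived from a decay fit
#'
#' @slot binding FRET-component amplitude x 100 (percent); the measure of
#'   protein affinity.
#' @slot fretEfficiency 100 x (1 - tauF/tauD) (percent); the measure of
#'   proximity, constrained to [10, 80] during fitting.
#' @slot tauAv Amplitude-weighted lifetime (ns).
#' @slot tauD Donor-only lifetime used (ns).
#'
#' @export
setClass("BindingResult",
  representation(binding = "numeric", fretEfficiency = "numeric",
                 tauAv = "numeric", tauD = "numeric"))

#' Steady-state complex signature of the stem cell niche
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"steadyState"}
#' holding the steady-state level of each species (rows: free WOX5, BRAVO,
#' PLT3 and the complexes WOX5PLT3, BRAVOPLT3, BRAVOWOX5, WOX5PLT3BRAVO) per
#' simulated cell type (columns SI, QC, CSC, CC). Column data store the input
#' protein totals and convergence diagnostics; metadata store the
#' \linkS4class{RateSet} and scenario name.
#'
#' @export
setClass("NicheSignature", contains = "SummarizedExperiment")

setValidity("NicheSignature", function(object) {
  if (!"steadyState" %in% SummarizedExperiment::assayNames(object))
    return("assay 'steadyState' missing")
  if (!identical(rownames(object), SPECIES))
    return("rows must be the seven model species")
  TRUE
})

#' Comparison of two niche signatures
#'
#' @slot absDiff,relDiff Per-entry absolute and relative differences (B - A).
#' @slot flagsA,flagsB Qualitative pattern flags of each signature.
#' @slot distance L1 distance between the max-normalised signatures.
#'
#' @export
setClass("SignatureComparison",
  representation(absDiff = "matrix", relDiff = "matrix",
                 flagsA = "logical", flagsB = "logical", distance = "numeric"))
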