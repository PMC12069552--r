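#' @import methods
NULL

#' Extract rate constants
#'
#' @param object A \linkS4class{RateSet}.
#' @return Named numeric vector of the ten rate constants.
#' @export
setGeneric("rateValues", function(object) standardGeneric("rateValues"))

#' Accepted grid pairs of a scan
#'
#' @param object A \linkS4class{ScanResult}.
#' @return data.frame of accepted (a, d) pairs with verified bound fractions.
#' @export
setGeneric("acceptedPairs", function(object) standardGeneric("acceptedPairs"))

#' Steady-state signature matrix
#'
#' @param object A \linkS4class{NicheSignature}.
#' @return Numeric species x cell-type matrix of steady-state levels.
#' @export
setGeneric("signatureMatrix", function(object) standardGeneric("signatureMatrix"))

#' Amplitude-weighted lifetime
#'
#' Sums each decay component's lifetime weighted by its normalised
#' amplitude, the standard summary of multi-exponential FLIM fits.
#'
#' @param object A \linkS4class{FlimFit}.
#' @return Lifetime in ns.
#' @export
setGeneric("amplitudeWeightedLifetime",
           function(object) standardGeneric("amplitudeWeightedLifetime"))

#' @rdname rateValues
setMethod("rateValues", "RateSet", function(object) object@rates)

#' @rdname acceptedPairs
setMethod("acceptedPairs", "ScanResult", function(object) object@pairs)

#' @rdname signatureMatrix
setMethod("signatureMatrix", "NicheSignature", function(object)
  SummarizedExperiment::assay(object, "steadyState"))

setMethod("show", "RateSet", function(object) {
  cat("RateSet (arbitrary units)\n")
  m <- matrix(object@rates, nrow = 2,
              dimnames = list(c("association", "dissociation"), COMPLEX_LABELS))
  print(round(m, 4))
  if (length(object@provenance))
    cat("calibrated complexes:", paste(names(object@provenance), collapse = ", "), "\n")
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult '%s': target bound fraction %.4f, %d accepted pair(s)\n",
              object@label, object@target, nrow(object@pairs)))
  cat(sprintf("grid [0, %g] step %g, tolerance %g\n",
              object@gridMax, object@gridStep, object@tol))
})

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d bins over %.2f ns, %d photons\n",
              length(object@time), object@window, round(sum(object@counts))))
})

setMethod("show", "FlimFit", function(object) {
  cat(sprintf("FlimFit (%d component%s)%s\n", length(object@amplitudes),
              if (length(object@amplitudes) > 1) "s" else "",
              if (object@boundary) " [boundary]" else ""))
  print(data.frame(amplitude = round(object@amplitudes, 4),
                   lifetime_ns = round(object@lifetimes, 4)))
  cat(sprintf("tau_av = %.4f ns, logLik = %.1f, converged = %s\n",
              amplitudeWeightedLifetime(object), object@logLik, object@converged))
})

setMethod("show", "BindingResult", function(object) {
  cat(sprintf("binding = %.1f%%, FRET efficiency = %.1f%%, tau_av = %.3f ns (tau_D = %.3f ns)\n",
              object@binding, object@fretEfficiency, object@tauAv, object@tauD))
})

setMethod("show", "SignatureComparison", function(object) {
  cat("SignatureComparison\n")
  cat(sprintf("L1 distance (max-normalised): %.4f\n", object@distance))
  both <- rbind(A = object@flagsA, B = object@flagsB)
  print(both)
})

setMethod("show", "AbundanceConfig", function(object) {
  cat(sprintf("AbundanceConfig: %d roots, %d-%d nuclei per cell type, sd = %g\n",
              object@nRoots, object@nucleiRange[1], object@nucleiRange[2], object@sd))
  print(round(object@means, 3))
})
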