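## Dimer kinetics and rate calibration against FRET-FLIM binding fractions.

#' Construct a RateSet
#'
#' @param rates Named numeric(10) of association/dissociation constants, or
#'   missing to build from \code{a} and \code{d}.
#' @param a,d Optional numeric(5) of association and dissociation rates in
#'   complex-label order (BRAVOWOX5, WOX5PLT3, BRAVOPLT3, WOX5PLT3BRAVO1,
#'   WOX5PLT3BRAVO2); recycled if length 1.
#' @param provenance Optional calibration provenance list.
#' @return A \linkS4class{RateSet}.
#' @examples
#' RateSet(a = 0.1, d = 0.05)
#' @export
RateSet <- function(rates = NULL, a = NULL, d = NULL, provenance = list()) {
  if (is.null(rates)) {
    stopifnot(!is.null(a), !is.null(d))
    a <- rep_len(a, 5L)
    d <- rep_len(d, 5L)
    rates <- as.vector(rbind(a, d))
    names(rates) <- rateNames()
  }
  new("RateSet", rates = rates[rateNames()], provenance = provenance)
}

#' Time derivatives of the donor/acceptor dimer system
#'
#' Mass-action kinetics of a single complex: the complex DA forms at rate
#' \code{a * A * D} and dissociates at rate \code{d * DA}; free donor and
#' acceptor change by the opposite amount, so D + DA and A + DA are conserved.
#'
#' @param state Named numeric: \code{D}, \code{A}, \code{DA} (arbitrary
#'   units, non-negative).
#' @param a,d Association and dissociation rate constants.
#' @return Named numeric of derivatives (dD, dA, dDA).
#' @examples
#' dimerDerivatives(c(D = 1, A = 1, DA = 0), a = 0.1, d = 0.1)
#' @export
dimerDerivatives <- function(state, a, d) {
  flux <- a * state[["A"]] * state[["D"]] - d * state[["DA"]]
  c(D = -flux, A = -flux, DA = flux)
}

## closed-form steady state: smaller root of a*(D0-x)(A0-x) = d*x,
## vectorised over a and d. Used as the scan pre-filter; the accepted set is
## always re-verified by integration.
closedFormBoundFraction <- function(a, d, D0 = 1, A0 = 1) {
  n <- max(length(a), length(d))
  a <- rep_len(a, n); d <- rep_len(d, n)
  s <- a * (D0 + A0) + d
  disc <- s^2 - 4 * a^2 * D0 * A0
  x <- (s - sqrt(pmax(disc, 0))) / (2 * a)
  x[a == 0] <- 0
  x / D0
}

#' Steady-state bound donor fraction of the dimer system
#'
#' Integrates the dimer equations from the given initial condition until the
#' largest derivative falls below \code{steadyTol}, and returns the fraction
#' of the donor pool bound in the complex, \code{DA_ss / (D0 + DA0)}. With
#' equal unit initial concentrations this is the quantity matched to the
#' FRET-FLIM binding fraction during calibration.
#'
#' @param a,d Rate constants (a + d must be positive).
#' @param initial Initial state, default \code{c(D = 1, A = 1, DA = 0)} --
#'   equal donor and acceptor levels, mimicking the transient co-expression
#'   experiments.
#' @param steadyTol Steady-state criterion on \code{max |dX/dt|}.
#' @param tMax Hard time cap; failure to converge is an error.
#' @param rtol,atol Integrator tolerances.
#' @return Bound donor fraction in [0, 1].
#' @examples
#' steadyStateBoundFraction(0.1, 0.1)   # (3 - sqrt(5))/2
#' @export
steadyStateBoundFraction <- function(a, d, initial = c(D = 1, A = 1, DA = 0),
                                     steadyTol = 1e-12, tMax = 1e6,
                                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(a >= 0, d >= 0, a + d > 0, all(initial >= 0))
  donor0 <- initial[["D"]] + initial[["DA"]]
  if (donor0 == 0) return(0)
  if (a == 0 && initial[["DA"]] == 0) return(0)
  if (d == 0 && a > 0) {
    ## irreversible limit: binding proceeds until the scarcer partner is
    ## exhausted; the approach is algebraic (~1/t), so the residual
    ## criterion is ill-suited and the limit is evaluated analytically
    acceptor0 <- initial[["A"]] + initial[["DA"]]
    return(min(donor0, acceptor0) / donor0)
  }
  rhs <- function(t, y, p) list(dimerDerivatives(y, a, d))
  rootf <- function(t, y, p) max(abs(dimerDerivatives(y, a, d))) - steadyTol
  out <- deSolve::lsodar(initial, times = c(0, tMax), func = rhs, parms = NULL,
                         rtol = rtol, atol = atol, rootfunc = rootf)
  if (is.null(attr(out, "troot")) && max(abs(dimerDerivatives(out[nrow(out), -1], a, d))) > steadyTol)
    stop("dimer system did not reach steady state within the time cap")
  unname(out[nrow(out), "DA"] / donor0)
}

#' Scan the (a, d) grid for rates reproducing a binding fraction
#'
#' Evaluates every pair on the inclusive grid \code{seq(0, gridMax,
#' gridStep)} x \code{seq(0, gridMax, gridStep)} (the degenerate pair a = d =
#' 0 excluded) and accepts pairs whose dimer steady-state bound fraction,
#' from equal unit initial concentrations, lies within \code{tol} of
#' \code{target}. Candidates are located with the closed-form steady state
#' (the smaller root of \code{a (1-x)^2 = d x}) and every candidate is then
#' verified by integrating the differential equations, so the accepted set is
#' identical to brute-force integration of the full grid;
#' \code{exhaustive = TRUE} forces brute-force integration (practical only
#' for reduced grids).
#'
#' @param target Target binding fraction in [0, 1].
#' @param label Optional complex label carried into the result.
#' @param gridMax,gridStep Grid specification; defaults 0.5 and 2e-4.
#' @param tol Acceptance tolerance, default 1e-5.
#' @param exhaustive Integrate every grid pair instead of pre-filtering.
#' @param verify Integrate candidate pairs to confirm (default TRUE).
#' @return A \linkS4class{ScanResult}. An empty accepted set raises an error
#'   identifying the condition.
#' @examples
#' sr <- scanRates(0.28, gridStep = 5e-3, tol = 1e-3)
#' head(acceptedPairs(sr))
#' @export
scanRates <- function(target, label = "complex", gridMax = 0.5,
                      gridStep = 2e-4, tol = 1e-5, exhaustive = FALSE,
                      verify = TRUE) {
  stopifnot(target >= 0, target <= 1, gridMax > 0, gridStep > 0, tol > 0)
  grid <- seq(0, gridMax, by = gridStep)
  cand <- NULL
  if (target == 0) {
    ## only a = 0 yields zero complex; any dissociation rate qualifies
    cand <- data.frame(a = 0, d = grid[grid > 0])
  } else if (exhaustive) {
    hits <- list()
    for (a in grid) for (d in grid) {
      if (a == 0 && d == 0) next
      if (abs(steadyStateBoundFraction(a, d) - target) <= tol)
        hits[[length(hits) + 1L]] <- c(a, d)
    }
    cand <- if (length(hits))
      as.data.frame(do.call(rbind, hits)) else data.frame(a = numeric(), d = numeric())
    names(cand) <- c("a", "d")
  } else {
    hits <- vector("list", length(grid))
    for (i in seq_along(grid)[-1]) {
      x <- closedFormBoundFraction(grid[i], grid)
      j <- which(abs(x - target) <= tol)
      if (length(j)) hits[[i]] <- cbind(a = grid[i], d = grid[j])
    }
    cand <- as.data.frame(do.call(rbind, hits))
    if (!nrow(cand)) cand <- data.frame(a = numeric(), d = numeric())
  }
  if (!nrow(cand))
    stop(sprintf("no grid pair reproduces binding fraction %g within %g (grid step %g): refine the grid or relax tol",
                 target, tol, gridStep))
  if (verify && target > 0 && !exhaustive) {
    bf <- vapply(seq_len(nrow(cand)), function(i)
      steadyStateBoundFraction(cand$a[i], cand$d[i]), numeric(1))
    keep <- abs(bf - target) <= tol
    cand <- cand[keep, , drop = FALSE]
    cand$boundFraction <- bf[keep]
  } else if (target == 0) {
    cand$boundFraction <- 0
  } else {
    cand$boundFraction <- vapply(seq_len(nrow(cand)), function(i)
      steadyStateBoundFraction(cand$a[i], cand$d[i]), numeric(1))
  }
  if (!nrow(cand))
    stop("all closed-form candidates failed integration verification")
  rownames(cand) <- NULL
  new("ScanResult", label = label, target = target, pairs = cand,
      tol = tol, gridMax = gridMax, gridStep = gridStep)
}

#' Select one rate pair from a scan result
#'
#' The accepted pairs of a scan differ only in the speed at which the complex
#' forms; the steady-state level is the same. The niche simulations use one
#' pair selected at random (the reference behaviour); \code{"fastest"} and
#' \code{"slowest"} pick the extreme association rates for robustness checks.
#'
#' @param scan A \linkS4class{ScanResult} with a non-empty accepted set.
#' @param policy One of \code{"random"}, \code{"fastest"}, \code{"slowest"}.
#' @param seed Integer seed (used by the random policy).
#' @return Named numeric \code{c(a = , d = )}.
#' @export
selectRate <- function(scan, policy = c("random", "fastest", "slowest"),
                       seed = 1L) {
  policy <- match.arg(policy)
  p <- scan@pairs
  if (!nrow(p)) stop("empty accepted set")
  i <- switch(policy,
    random  = { set.seed(as.integer(seed)); sample.int(nrow(p), 1L) },
    fastest = which.max(p$a),
    slowest = { j <- which(p$a > 0); j[which.min(p$a[j])] })
  if (!length(i)) stop("no pair satisfies the policy (all a = 0?)")
  c(a = p$a[i], d = p$d[i])
}

#' Read a binding affinity table from CSV
#'
#' Expects columns \code{label} and \code{binding} (fraction in [0, 1]);
#' extra columns such as a source note are ignored.
#'
#' @param path CSV path.
#' @return Named numeric of binding fractions.
#' @export
readAffinities <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("label", "binding") %in% names(d)))
  setNames(d$binding, d$label)
}

#' Calibrate the full rate set from a binding affinity table
#'
#' Runs \code{\link{scanRates}} for each complex and selects one accepted
#' pair per complex. The trimer paths are calibrated as two-body problems:
#' the split-fluorophore-reconstituted dimer is treated as a unit donor
#' species binding the third protein. Selection is seeded per complex
#' (\code{seed + position in the label order}) so that complexes sharing a
#' label and target across two calibrations -- e.g. the trimer paths of the
#' wild type and the PLT3 PrD-deletion variant -- receive identical rates.
#'
#' @param affinities Named numeric of binding fractions in [0, 1] with names
#'   among the five complex labels, or a data.frame with columns
#'   \code{label} and \code{binding}.
#' @param gridMax,gridStep,tol Scan settings, see \code{\link{scanRates}}.
#' @param policy,seed Selection settings, see \code{\link{selectRate}}.
#' @return A \linkS4class{RateSet} with calibration provenance.
#' @examples
#' \donttest{
#' rs <- calibrateAll(wtAffinities(), gridStep = 2e-3, tol = 1e-4)
#' rateValues(rs)
#' }
#' @export
calibrateAll <- function(affinities, gridMax = 0.5, gridStep = 2e-4,
                         tol = 1e-5, policy = "random", seed = 1L) {
  if (is.data.frame(affinities)) {
    b <- affinities$binding
    names(b) <- affinities$label
    affinities <- b
  }
  missing <- setdiff(COMPLEX_LABELS, names(affinities))
  if (length(missing))
    stop("missing affinity for complex(es): ", paste(missing, collapse = ", "))
  rates <- numeric(0)
  prov <- list()
  for (i in seq_along(COMPLEX_LABELS)) {
    lab <- COMPLEX_LABELS[i]
    sr <- scanRates(affinities[[lab]], label = lab, gridMax = gridMax,
                    gridStep = gridStep, tol = tol)
    pair <- selectRate(sr, policy = policy, seed = as.integer(seed) + i)
    rates[paste0("a_", lab)] <- pair[["a"]]
    rates[paste0("d_", lab)] <- pair[["d"]]
    prov[[lab]] <- list(target = affinities[[lab]], a = pair[["a"]],
                        d = pair[["d"]], nAccepted = nrow(sr@pairs),
                        policy = policy)
  }
  RateSet(rates = rates, provenance = prov)
}
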