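## Seven-species mass-action model of WOX5/PLT3/BRAVO complex formation.

#' Time derivatives of the seven-species complex system
#'
#' Mass-action kinetics for free WOX5, BRAVO and PLT3 and the complexes
#' WOX5-PLT3, BRAVO-PLT3, BRAVO-WOX5 and the trimer WOX5-PLT3-BRAVO. The
#' trimer forms along two paths -- BRAVO binding the WOX5-PLT3 dimer, or
#' WOX5 binding the BRAVO-PLT3 dimer -- and dissociates along both; free
#' PLT3 exchanges with the trimer only through the dimers. Each protein's
#' total (free + complexes containing it) is conserved.
#'
#' @param state Named numeric of the seven species (order \code{WOX5, BRAVO,
#'   PLT3, WOX5PLT3, BRAVOPLT3, BRAVOWOX5, WOX5PLT3BRAVO}).
#' @param rates A \linkS4class{RateSet} or its named numeric(10).
#' @return Named numeric of time derivatives.
#' @export
scnDerivatives <- function(state, rates) {
  if (is(rates, "RateSet")) rates <- rates@rates
  W  <- state[["WOX5"]];     B  <- state[["BRAVO"]];     P <- state[["PLT3"]]
  WP <- state[["WOX5PLT3"]]; BP <- state[["BRAVOPLT3"]]
  BW <- state[["BRAVOWOX5"]]; TR <- state[["WOX5PLT3BRAVO"]]
  aBW <- rates[["a_BRAVOWOX5"]];      dBW <- rates[["d_BRAVOWOX5"]]
  aWP <- rates[["a_WOX5PLT3"]];       dWP <- rates[["d_WOX5PLT3"]]
  aBP <- rates[["a_BRAVOPLT3"]];      dBP <- rates[["d_BRAVOPLT3"]]
  aT1 <- rates[["a_WOX5PLT3BRAVO1"]]; dT1 <- rates[["d_WOX5PLT3BRAVO1"]]
  aT2 <- rates[["a_WOX5PLT3BRAVO2"]]; dT2 <- rates[["d_WOX5PLT3BRAVO2"]]
  c(WOX5 = dBW * BW + dWP * WP + dT2 * TR -
      W * (aBW * B + aWP * P + aT2 * BP),
    BRAVO = dBW * BW + dBP * BP + dT1 * TR -
      B * (aBW * W + aBP * P + aT1 * WP),
    PLT3 = dBP * BP + dWP * WP - P * (aBP * B + aWP * W),
    WOX5PLT3 = aWP * W * P - dWP * WP - aT1 * WP * B + dT1 * TR,
    BRAVOPLT3 = aBP * B * P - dBP * BP - aT2 * BP * W + dT2 * TR,
    BRAVOWOX5 = aBW * B * W - dBW * BW,
    WOX5PLT3BRAVO = aT1 * WP * B + aT2 * BP * W - (dT1 + dT2) * TR)
}

## conservation totals of a seven-species state (or matrix with species rows)
proteinTotals <- function(state) {
  g <- function(x, sp) sum(x[sp])
  tot <- function(x) c(
    WOX5  = g(x, c("WOX5", "WOX5PLT3", "BRAVOWOX5", "WOX5PLT3BRAVO")),
    BRAVO = g(x, c("BRAVO", "BRAVOPLT3", "BRAVOWOX5", "WOX5PLT3BRAVO")),
    PLT3  = g(x, c("PLT3", "WOX5PLT3", "BRAVOPLT3", "WOX5PLT3BRAVO")))
  if (is.matrix(state)) apply(state, 2, tot) else tot(state)
}

#' Simulate one cell to steady state
#'
#' Integrates the seven-species system from an all-free initial condition
#' (measured protein totals, no complexes) until the largest derivative
#' falls below \code{steadyTol}. Protein totals are conserved along the
#' trajectory; the steady state describes how each cell's protein content is
#' partitioned into complexes.
#'
#' @param totals Named numeric \code{c(WOX5 = , BRAVO = , PLT3 = )} of
#'   relative protein levels (arbitrary units, >= 0).
#' @param rates A \linkS4class{RateSet}.
#' @param steadyTol Steady-state criterion on \code{max |dX/dt|}.
#' @param tMax Time cap; an error is raised if steady state is not reached.
#' @param rtol,atol Integrator tolerances.
#' @param randomStarts Additional integrations from random feasible
#'   partitions of the totals, as a multistability guard; the maximum
#'   pairwise deviation is reported in the diagnostics.
#' @param seed Seed for the random starts.
#' @return Named numeric of the seven steady-state levels, with attribute
#'   \code{"diagnostics"} (convergence time, residual, multistart spread).
#' @export
simulateCell <- function(totals, rates, steadyTol = 1e-12, tMax = 1e6,
                         rtol = 1e-10, atol = 1e-12, randomStarts = 0L,
                         seed = 1L) {
  stopifnot(all(totals >= 0))
  if (is(rates, "RateSet")) rv <- rates@rates else rv <- rates
  integrate1 <- function(y0) {
    rhs <- function(t, y, p) list(scnDerivatives(y, rv))
    rootf <- function(t, y, p) max(abs(scnDerivatives(y, rv))) - steadyTol
    out <- deSolve::lsodar(y0, times = c(0, tMax), func = rhs, parms = NULL,
                           rtol = rtol, atol = atol, rootfunc = rootf)
    y <- out[nrow(out), -1]
    res <- max(abs(scnDerivatives(y, rv)))
    if (is.null(attr(out, "troot")) && res > steadyTol)
      stop("cell did not reach steady state within the time cap")
    if (any(y < -1e-12))
      warning("integrator produced negative concentrations beyond tolerance")
    y <- pmax(y, 0)
    list(state = y, time = out[nrow(out), 1], residual = res)
  }
  y0 <- c(WOX5 = totals[["WOX5"]], BRAVO = totals[["BRAVO"]],
          PLT3 = totals[["PLT3"]], WOX5PLT3 = 0, BRAVOPLT3 = 0,
          BRAVOWOX5 = 0, WOX5PLT3BRAVO = 0)
  main <- integrate1(y0)
  spread <- 0
  if (randomStarts > 0L) {
    set.seed(as.integer(seed))
    for (k in seq_len(randomStarts)) {
      ## random feasible partition: put a random share of the limiting
      ## amounts into each complex, remainder free
      fW <- runif(3); fB <- runif(3); fP <- runif(3)
      wp <- min(totals[["WOX5"]], totals[["PLT3"]]) * fW[1] * 0.3
      bp <- min(totals[["BRAVO"]], totals[["PLT3"]] - wp) * fB[1] * 0.3
      bw <- min(totals[["BRAVO"]] - bp, totals[["WOX5"]] - wp) * fB[2] * 0.3
      bw <- max(bw, 0)
      alt <- c(WOX5 = totals[["WOX5"]] - wp - bw,
               BRAVO = totals[["BRAVO"]] - bp - bw,
               PLT3 = totals[["PLT3"]] - wp - bp,
               WOX5PLT3 = wp, BRAVOPLT3 = bp, BRAVOWOX5 = bw,
               WOX5PLT3BRAVO = 0)
      res <- integrate1(alt)
      spread <- max(spread, max(abs(res$state - main$state)))
    }
  }
  structure(main$state,
            diagnostics = list(time = main$time, residual = main$residual,
                               multistartSpread = spread))
}

#' Simulate the whole stem cell niche
#'
#' Runs \code{\link{simulateCell}} for each cell type of an abundance table
#' and assembles the steady-state complex signature.
#'
#' @param abundance An \linkS4class{AbundanceConfig} (its means are used), or
#'   a cell-type x protein matrix, or a tidy data.frame with columns
#'   \code{cell_type}, \code{protein}, \code{total}. All four cell types
#'   (SI, QC, CSC, CC) must be present.
#' @param rates A \linkS4class{RateSet}.
#' @param scenario Scenario name stored in the metadata.
#' @param ... Passed to \code{\link{simulateCell}}.
#' @return A \linkS4class{NicheSignature}.
#' @examples
#' \donttest{
#' rs <- RateSet(a = 0.1, d = 0.05)
#' ns <- simulateNiche(defaultWtAbundance(), rs)
#' signatureMatrix(ns)
#' }
#' @export
simulateNiche <- function(abundance, rates, scenario = "custom", ...) {
  ab <- abundanceMatrix(abundance)
  missing <- setdiff(CELL_TYPES, rownames(ab))
  if (length(missing))
    stop("missing cell type(s): ", paste(missing, collapse = ", "))
  states <- matrix(NA_real_, nrow = length(SPECIES), ncol = length(CELL_TYPES),
                   dimnames = list(SPECIES, CELL_TYPES))
  diag_time <- diag_res <- numeric(length(CELL_TYPES))
  for (j in seq_along(CELL_TYPES)) {
    ct <- CELL_TYPES[j]
    st <- simulateCell(c(WOX5 = ab[ct, "WOX5"], BRAVO = ab[ct, "BRAVO"],
                         PLT3 = ab[ct, "PLT3"]), rates, ...)
    states[, j] <- st[SPECIES]
    dg <- attr(st, "diagnostics")
    diag_time[j] <- dg$time; diag_res[j] <- dg$residual
  }
  cd <- S4Vectors::DataFrame(
    cellType = CELL_TYPES,
    totalWOX5 = ab[CELL_TYPES, "WOX5"], totalBRAVO = ab[CELL_TYPES, "BRAVO"],
    totalPLT3 = ab[CELL_TYPES, "PLT3"],
    convergenceTime = diag_time, residual = diag_res)
  rd <- S4Vectors::DataFrame(
    species = SPECIES,
    role = c("free", "free", "free", "dimer", "dimer", "dimer", "trimer"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(steadyState = states), rowData = rd, colData = cd,
    metadata = list(rates = if (is(rates, "RateSet")) rates else RateSet(rates = rates),
                    scenario = scenario))
  new("NicheSignature", se)
}

asSignatureMatrix <- function(x) {
  if (is(x, "NicheSignature")) signatureMatrix(x) else as.matrix(x)
}

## coerce the accepted abundance inputs to a cell-type x protein matrix
abundanceMatrix <- function(abundance) {
  if (is(abundance, "AbundanceConfig")) return(abundance@means)
  if (is.matrix(abundance)) return(abundance)
  if (is.data.frame(abundance)) {
    m <- matrix(NA_real_, length(CELL_TYPES), length(PROTEINS),
                dimnames = list(CELL_TYPES, PROTEINS))
    for (i in seq_len(nrow(abundance)))
      m[abundance$cell_type[i], abundance$protein[i]] <- abundance$total[i]
    if (anyNA(m)) stop("incomplete abundance table")
    return(m)
  }
  stop("unsupported abundance input")
}

#' Qualitative pattern flags of a niche signature
#'
#' The boolean features summarising the predicted wild-type pattern: the
#' trimer peaks in the stele initials and quiescent centre; the WOX5-PLT3
#' dimer peaks in the columella stem cells; free BRAVO peaks in the stele
#' initials and free WOX5 in the quiescent centre; free PLT3 is the dominant
#' free protein in columella stem cells and columella cells; and all
#' complexes in the columella cells stay below 5 percent of their niche-wide
#' maxima.
#'
#' @param signature A \linkS4class{NicheSignature} or species x cell-type
#'   matrix.
#' @return Named logical vector of seven flags.
#' @export
signatureFlags <- function(signature) {
  m <- asSignatureMatrix(signature)
  complexes <- c("WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5", "WOX5PLT3BRAVO")
  cmax <- apply(m[complexes, ], 1, max)
  c(trimerMaxSIQC =
      min(m["WOX5PLT3BRAVO", c("SI", "QC")]) >= max(m["WOX5PLT3BRAVO", c("CSC", "CC")]),
    wox5plt3MaxCSC = names(which.max(m["WOX5PLT3", ])) == "CSC",
    freeBravoMaxSI = names(which.max(m["BRAVO", ])) == "SI",
    freeWox5MaxQC = names(which.max(m["WOX5", ])) == "QC",
    freePlt3DominantCSC = m["PLT3", "CSC"] >= max(m[c("WOX5", "BRAVO"), "CSC"]),
    freePlt3DominantCC = m["PLT3", "CC"] >= max(m[c("WOX5", "BRAVO"), "CC"]),
    ccComplexesNegligible = all(m[complexes, "CC"] < 0.05 * cmax))
}

#' Heatmap matrix of a niche signature
#'
#' Rows are the four complexes and three free proteins, columns the cell
#' types; by default each row is normalised to its maximum across cell
#' types, mirroring the published heatmap display.
#'
#' @param signature A \linkS4class{NicheSignature}.
#' @param normalize \code{"row-max"} (default), \code{"global-max"} or
#'   \code{"none"}.
#' @return Numeric matrix.
#' @export
heatmapMatrix <- function(signature, normalize = c("row-max", "global-max", "none")) {
  normalize <- match.arg(normalize)
  m <- asSignatureMatrix(signature)
  m <- m[c("WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5", "WOX5PLT3BRAVO",
           "WOX5", "BRAVO", "PLT3"), , drop = FALSE]
  switch(normalize,
    "row-max" = {
      mx <- apply(m, 1, max)
      mx[mx == 0] <- 1
      m / mx
    },
    "global-max" = m / max(m),
    "none" = m)
}

#' Radar-chart data of the complex levels
#'
#' @param signature A \linkS4class{NicheSignature}.
#' @return data.frame with one row per (cell type, complex axis).
#' @export
radarData <- function(signature) {
  m <- asSignatureMatrix(signature)
  complexes <- c("WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5", "WOX5PLT3BRAVO")
  data.frame(cell_type = rep(colnames(m), each = length(complexes)),
             complex = rep(complexes, times = ncol(m)),
             level = as.vector(m[complexes, ]))
}
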