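## Poisson maximum-likelihood lifetime fitting of TCSPC decay histograms,
## and the binding / FRET-efficiency quantities derived from the fits.

erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

## Gaussian(0, sigma) (x) Exp(tau) density at u (analytic reconvolution);
## sigma = 0 reduces to the plain exponential.
expGaussDensity <- function(u, tau, sigma) {
  if (sigma <= 0) {
    out <- numeric(length(u))
    ok <- u >= 0
    out[ok] <- exp(-u[ok] / tau) / tau
    return(out)
  }
  (1 / (2 * tau)) * exp(sigma^2 / (2 * tau^2) - u / tau) *
    erfc((sigma / tau - u / sigma) / sqrt(2))
}

## density wrapped into the repetition window [0, T): photons from earlier
## pulses fold back (m >= 1), IRF jitter folds t near T to small u (m = -1)
wrappedDensity <- function(t, tau, sigma, window) {
  g <- 0
  for (m in -1:2) g <- g + expGaussDensity(t + m * window, tau, sigma)
  g
}

## negative Poisson log-likelihood of a 1- or 2-component model;
## mixture densities are precomputed by the callers
poissonNLL <- function(mu, y) {
  mu <- pmax(mu, 1e-12)
  sum(mu - y * log(mu))
}

#' @rdname amplitudeWeightedLifetime
setMethod("amplitudeWeightedLifetime", "FlimFit", function(object) {
  if (!length(object@amplitudes)) stop("empty component list")
  sum(object@amplitudes * object@lifetimes)
})

#' Fit a donor-only decay
#'
#' Maximum-likelihood mono- or biexponential fit with a Poisson likelihood
#' per bin, the standard model for photon counting. The instrument response
#' is handled by analytic Gaussian-exponential reconvolution using the
#' histogram's IRF width; with no width recorded, fitting starts 0.5 ns
#' after the histogram peak (tail fit). The mono/bi choice is made by BIC.
#' The donor lifetime is reported as the amplitude-weighted lifetime.
#'
#' @param decay A \linkS4class{DecayHistogram}.
#' @param model \code{"auto"} (BIC selection), \code{"mono"} or \code{"bi"}.
#' @return A \linkS4class{FlimFit}; non-convergence is flagged, not raised.
#' @export
fitDonorOnly <- function(decay, model = c("auto", "mono", "bi")) {
  model <- match.arg(model)
  d <- fitData(decay)
  mono <- fitMono(d)
  if (model == "mono") return(mono)
  bi <- fitBi(d)
  if (model == "bi") return(bi)
  nb <- length(d$y)
  bicMono <- 2 * (-mono@logLik) + 3 * log(nb)
  bicBi <- 2 * (-bi@logLik) + 5 * log(nb)
  if (bicBi < bicMono) bi else mono
}

## shared per-histogram fitting data; applies the tail-fit fallback when no
## IRF width is available
fitData <- function(decay) {
  stopifnot(is(decay, "DecayHistogram"))
  t <- decay@time; y <- decay@counts
  sigma <- decay@irfSigma
  if (sigma <= 0) {
    start <- t[which.max(y)] + 0.5
    keep <- t >= start
    if (sum(keep) < 16L) keep <- rep(TRUE, length(t))
    t <- t[keep]; y <- y[keep]
  }
  list(t = t, y = y, dt = diff(decay@time[1:2]), window = decay@window,
      sigma = max(sigma, 0), nb = length(y))
}

fitMono <- function(d) {
  tau0 <- min(max(sum(d$t * d$y) / sum(d$y), 0.3), 10)
  S0 <- sum(d$y)
  p0 <- c(log(tau0), log(S0), log(max(S0 * 1e-4, 1e-3)))
  nll <- function(p) {
    g <- wrappedDensity(d$t, exp(p[1]), d$sigma, d$window)
    poissonNLL(exp(p[2]) * g * d$dt + exp(p[3]) / d$nb, d$y)
  }
  fit <- stats::optim(p0, nll, method = "L-BFGS-B",
                      lower = c(log(0.05), log(S0 * 0.2), log(1e-6)),
                      upper = c(log(20), log(S0 * 5), log(S0)),
                      control = list(maxit = 500))
  new("FlimFit", amplitudes = 1, lifetimes = exp(fit$par[1]),
      background = exp(fit$par[3]), logLik = -fit$value,
      converged = fit$convergence == 0)
}

fitBi <- function(d) {
  tau0 <- min(max(sum(d$t * d$y) / sum(d$y), 0.3), 10)
  S0 <- sum(d$y)
  p0 <- c(stats::qlogis(0.3), log(tau0 * 0.5), log(tau0 * 1.3),
          log(S0), log(max(S0 * 1e-4, 1e-3)))
  nll <- function(p) {
    al <- stats::plogis(p[1])
    g <- al * wrappedDensity(d$t, exp(p[2]), d$sigma, d$window) +
      (1 - al) * wrappedDensity(d$t, exp(p[3]), d$sigma, d$window)
    poissonNLL(exp(p[4]) * g * d$dt + exp(p[5]) / d$nb, d$y)
  }
  fit <- stats::optim(p0, nll, method = "L-BFGS-B",
                      lower = c(-8, log(0.05), log(0.05), log(S0 * 0.2), log(1e-6)),
                      upper = c(8, log(20), log(20), log(S0 * 5), log(S0)),
                      control = list(maxit = 1000))
  al <- stats::plogis(fit$par[1])
  taus <- exp(fit$par[2:3])
  amps <- c(al, 1 - al)
  o <- order(taus)
  new("FlimFit", amplitudes = amps[o], lifetimes = taus[o],
      background = exp(fit$par[5]), logLik = -fit$value,
      converged = fit$convergence == 0)
}

#' Fit the FRET fraction of a decay with a fixed donor lifetime
#'
#' Two-component Poisson maximum-likelihood fit in which one lifetime is
#' fixed to the donor-only lifetime and the FRET-component lifetime is
#' constrained so that the implied FRET efficiency lies within
#' \code{effRange} (default 10 to 80 percent, the interval the fitting
#' process confines efficiencies to). The FRET-component amplitude measures
#' the fraction of donor molecules undergoing FRET ("binding").
#'
#' @param decay A \linkS4class{DecayHistogram}.
#' @param tauD Donor-only lifetime (ns), > 0.
#' @param effRange FRET-efficiency constraint interval (fractions).
#' @return A \linkS4class{FlimFit} with the FRET component first
#'   (\code{amplitudes[1]} = alpha_F, \code{lifetimes[1]} = tau_F);
#'   solutions on the lifetime constraint boundary are flagged.
#' @export
fitFret <- function(decay, tauD, effRange = c(0.10, 0.80)) {
  stopifnot(tauD > 0, length(effRange) == 2L, effRange[1] < effRange[2])
  d <- fitData(decay)
  lo <- (1 - effRange[2]) * tauD
  hi <- (1 - effRange[1]) * tauD
  gD <- wrappedDensity(d$t, tauD, d$sigma, d$window)
  S0 <- sum(d$y)
  p0 <- c(stats::qlogis(0.2), 0, log(S0), log(max(S0 * 1e-4, 1e-3)))
  nll <- function(p) {
    al <- stats::plogis(p[1])
    tauF <- lo + (hi - lo) * stats::plogis(p[2])
    g <- al * wrappedDensity(d$t, tauF, d$sigma, d$window) + (1 - al) * gD
    poissonNLL(exp(p[3]) * g * d$dt + exp(p[4]) / d$nb, d$y)
  }
  fit <- stats::optim(p0, nll, method = "L-BFGS-B",
                      lower = c(-10, -10, log(S0 * 0.2), log(1e-6)),
                      upper = c(10, 10, log(S0 * 5), log(S0)),
                      control = list(maxit = 1000))
  al <- stats::plogis(fit$par[1])
  tauF <- lo + (hi - lo) * stats::plogis(fit$par[2])
  onBoundary <- (tauF - lo) < 0.005 * (hi - lo) || (hi - tauF) < 0.005 * (hi - lo)
  new("FlimFit", amplitudes = c(al, 1 - al), lifetimes = c(tauF, tauD),
      background = exp(fit$par[4]), logLik = -fit$value,
      converged = fit$convergence == 0, boundary = onBoundary)
}

#' Binding and FRET efficiency from a two-component fit
#'
#' Binding is the FRET-component amplitude times 100 (the share of donor
#' molecules in complex); the FRET efficiency is \code{100 * (1 -
#' tauF/tauD)} (proximity/orientation). The amplitude-weighted lifetime is
#' reported alongside.
#'
#' @param fit A two-component \linkS4class{FlimFit} (FRET component = the
#'   component whose lifetime is not the donor lifetime).
#' @param tauD Donor-only lifetime (ns).
#' @return A \linkS4class{BindingResult}.
#' @examples
#' f <- new("FlimFit", amplitudes = c(0.28, 0.72), lifetimes = c(1.2, 3.0),
#'          background = 0, logLik = 0, converged = TRUE)
#' bindingAndEfficiency(f, tauD = 3.0)
#' @export
bindingAndEfficiency <- function(fit, tauD) {
  if (length(fit@amplitudes) != 2L)
    stop("a two-component fit is required")
  iF <- which(abs(fit@lifetimes - tauD) > 1e-9)
  iF <- if (length(iF)) iF[which.min(fit@lifetimes[iF])] else which.min(fit@lifetimes)
  new("BindingResult",
      binding = 100 * fit@amplitudes[iF],
      fretEfficiency = 100 * (1 - fit@lifetimes[iF] / tauD),
      tauAv = amplitudeWeightedLifetime(fit),
      tauD = tauD)
}
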