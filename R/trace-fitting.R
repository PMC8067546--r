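## Per-injection reduction of stepwise sensorgrams: each concentration
## step is fitted with a single rising exponential
##   sigma(t) = sigma_prev + (Sigma - sigma_prev) * (1 - exp(-Gamma (t - t0)))
## giving the extrapolated asymptote Sigma(c), the growth rate Gamma(c)
## and the initial slope sigma'(c) = Gamma * (Sigma - sigma_prev).

## Profiled least squares: for fixed Gamma the amplitude is linear, so a
## 1-D search over log(Gamma) followed by a Gauss-Newton polish is robust
## on both noiseless and noisy segments (plain nls chokes on exact data).
fitExpSegment <- function(tRel, y, sigmaPrev) {
  z <- y - sigmaPrev
  sseFor <- function(logGamma) {
    f <- 1 - exp(-exp(logGamma) * tRel)
    amp <- sum(f * z) / sum(f * f)
    sum((z - amp * f)^2)
  }
  ## initial Gamma from the time to half the total rise
  rise <- mean(z[tRel >= stats::quantile(tRel, 0.9)])
  iHalf <- which(z >= rise / 2)
  tHalf <- if (length(iHalf)) max(tRel[iHalf[1]], tRel[2]) else max(tRel) / 2
  g0 <- log(2) / tHalf
  opt <- stats::optimize(sseFor, interval = log(g0) + c(-log(100), log(100)),
                         tol = 1e-9)
  gamma <- exp(opt$minimum)
  f <- 1 - exp(-gamma * tRel)
  amp <- sum(f * z) / sum(f * f)
  ## Gauss-Newton polish on (amp, gamma)
  for (iter in 1:60) {
    e <- exp(-gamma * tRel)
    f <- 1 - e
    r <- z - amp * f
    J <- cbind(f, amp * tRel * e)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    ampNew <- amp + step[1]
    gammaNew <- gamma + step[2]
    if (!is.finite(ampNew) || !is.finite(gammaNew) || gammaNew <= 0) break
    relStep <- max(abs(step[1]) / max(abs(amp), 1e-12),
                   abs(step[2]) / gamma)
    amp <- ampNew; gamma <- gammaNew
    if (relStep < 1e-13) break
  }
  if (!is.finite(gamma) || gamma <= 0)
    nwStop("per-step exponential fit did not converge (non-finite rate)",
           "nwFitError")
  e <- exp(-gamma * tRel)
  f <- 1 - e
  r <- z - amp * f
  sse <- sum(r^2)
  J <- cbind(f, amp * tRel * e)
  n <- length(z)
  covM <- tryCatch(sse / max(n - 2L, 1L) * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 2, 2))
  list(amp = amp, gamma = gamma, sse = sse,
       seAmp = sqrt(abs(covM[1, 1])), seGamma = sqrt(abs(covM[2, 2])))
}

#' Fit one injection step with a single rising exponential
#'
#' Least-squares fit of \eqn{\sigma(t) = \sigma_{prev} + (\Sigma -
#' \sigma_{prev})(1 - e^{-\Gamma (t - t_0)})} over one constant-concentration
#' segment, with time measured from the injection.  The asymptote is
#' stored as the absolute level \eqn{\Sigma(c)} (previous plateau plus
#' fitted increment) so it can feed the Langmuir isotherm directly.  The
#' initial slope is computed analytically from the fit,
#' \eqn{\sigma'(c) = \Gamma (\Sigma - \sigma_{prev})}, which is far less
#' noise-sensitive than finite differences on the first points.
#'
#' A step whose total rise is below three times the noise estimate is
#' marked unusable (\code{usable = FALSE}, \code{Sigma = sigmaPrev},
#' \code{Gamma = NA}) rather than fitted.
#'
#' @param times sample times of the segment, s
#' @param sigma surface-density samples of the segment
#' @param t0 injection time, s
#' @param sigmaPrev plateau level before this step
#' @param c step concentration, nM (carried through to the result)
#' @param discard seconds to drop after the injection (mixing transient)
#' @return list with \code{c}, \code{Sigma}, \code{Gamma}, \code{slope0},
#'   \code{sigmaPrev}, \code{seSigma}, \code{seGamma}, \code{residualRms},
#'   \code{usable}, \code{nPoints}
#' @export
fitStep <- function(times, sigma, t0, sigmaPrev, c = NA_real_, discard = 10) {
  keep <- times >= t0 + discard
  if (sum(keep) < 10L)
    nwStop("fewer than 10 samples after the discard window", "nwDataError")
  tRel <- times[keep] - t0
  y <- sigma[keep]
  noiseEst <- stats::sd(diff(y)) / sqrt(2)
  rise <- mean(y[tRel >= stats::quantile(tRel, 0.9)]) - sigmaPrev
  if (!is.finite(rise) || rise <= 0 || rise < 3 * noiseEst) {
    return(list(c = c, Sigma = sigmaPrev, Gamma = NA_real_,
                slope0 = NA_real_, sigmaPrev = sigmaPrev,
                seSigma = NA_real_, seGamma = NA_real_,
                residualRms = stats::sd(y - sigmaPrev), usable = FALSE,
                nPoints = length(y)))
  }
  fit <- fitExpSegment(tRel, y, sigmaPrev)
  list(c = c, Sigma = sigmaPrev + fit$amp, Gamma = fit$gamma,
       slope0 = fit$gamma * fit$amp, sigmaPrev = sigmaPrev,
       seSigma = fit$seAmp, seGamma = fit$seGamma,
       residualRms = sqrt(fit$sse / length(y)), usable = TRUE,
       nPoints = length(y))
}

#' Fit every injection step of a stepwise titration trace
#'
#' Slices the trace at the injection times and chains
#' \code{\link{fitStep}} over the steps: each step starts from the
#' previous step's fitted curve evaluated at the next injection time (the
#' model plateau, not the noisy last sample).
#'
#' @param trace a \code{\link{BindingTrace}}
#' @param discard seconds to drop after each injection
#' @return an \code{S4Vectors::DataFrame} with one row per step and
#'   columns \code{step}, \code{c}, \code{Sigma}, \code{Gamma},
#'   \code{slope0}, \code{sigmaPrev}, \code{seSigma}, \code{seGamma},
#'   \code{residualRms}, \code{usable}; trace identity in
#'   \code{metadata()}
#' @export
fitAllSteps <- function(trace, discard = 10) {
  stopifnot(is(trace, "BindingTrace"))
  sch <- trace@schedule
  st <- sch@stepTimes
  cc <- sch@concentrations
  n <- length(st)
  rows <- vector("list", n)
  sigmaPrev <- 0
  prevFit <- NULL
  for (k in seq_len(n)) {
    tEnd <- if (k < n) st[k + 1] else Inf
    inSeg <- trace@times >= st[k] & trace@times < tEnd
    if (!is.null(prevFit)) {
      sigmaPrev <- if (isTRUE(prevFit$usable))
        prevFit$sigmaPrev + (prevFit$Sigma - prevFit$sigmaPrev) *
          (1 - exp(-prevFit$Gamma * (st[k] - st[k - 1])))
      else prevFit$Sigma
    }
    rows[[k]] <- fitStep(trace@times[inSeg], trace@sigma[inSeg],
                         t0 = st[k], sigmaPrev = sigmaPrev, c = cc[k],
                         discard = discard)
    prevFit <- rows[[k]]
  }
  out <- S4Vectors::DataFrame(
    step = seq_len(n),
    do.call(rbind, lapply(rows, data.frame)))
  S4Vectors::metadata(out) <- list(probeClass = trace@probeClass,
                                   spotId = trace@spotId,
                                   temperature = sch@temperature,
                                   ionicStrength = sch@ionicStrength)
  out
}

#' Single-exponential rate vs concentration line fit
#'
#' For a single-well probe the growth rate is linear in concentration,
#' \eqn{\Gamma(c) = k_{on} c + k_{off}}; the slope and intercept of the
#' (weighted) regression of the per-step rates on concentration estimate
#' the two kinetic constants.  For nested-well traces the fitted
#' intercept falls below the true \code{koff1} because the effective
#' escape from the nested system is slower.
#'
#' @param steps result of \code{\link{fitAllSteps}}
#' @param weighted use 1/se^2 weights when all rate standard errors are
#'   finite and positive (default TRUE)
#' @return list with \code{kon} (1/(s nM)), \code{koff} (1/s), named
#'   \code{se}, and \code{flags}
#' @export
gammaLineFit <- function(steps, weighted = TRUE) {
  d <- as.data.frame(steps[steps$usable, , drop = FALSE])
  if (length(unique(d$c)) < 2L)
    nwStop("at least two distinct concentrations with usable fits are required",
           "nwDataError")
  w <- NULL
  if (weighted && all(is.finite(d$seGamma)) && all(d$seGamma > 0) &&
      max(d$seGamma) / min(d$seGamma) < 1e6)
    w <- 1 / d$seGamma^2
  fit <- stats::lm(Gamma ~ c, data = d, weights = w)
  cf <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  flags <- character()
  if (cf[2] <= 0) flags <- c(flags, "no-binding-signal")
  list(kon = unname(cf[2]), koff = unname(cf[1]),
       se = c(kon = unname(se[2]), koff = unname(se[1])), flags = flags)
}
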