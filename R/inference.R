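## Condition-level estimation: paired Langmuir isotherm with a shared
## saturation density, kon from initial slopes, K2 extraction, the joint
## nested-well kinetic fit, and van't Hoff thermodynamics.

#' Paired Langmuir fit of specific and nonspecific asymptotes
#'
#' Simultaneous least squares of the per-step asymptotes of a probe pair
#' against \eqn{\Sigma(c) = \Sigma_\infty c/(c + K_d)} with one shared
#' saturation density and one dissociation constant per probe class.
#' Sharing \eqn{\Sigma_\infty} encodes the assumption that the maximum
#' protein load per probe depends on probe length, not on the presence
#' of the specific tract.
#'
#' @param stepsSpecific,stepsNonspecific results of
#'   \code{\link{fitAllSteps}} for the two probes of a pair
#' @return an \code{\link{IsothermFit}}.  \code{Kd specific >= Kd
#'   nonspecific} triggers a warning flag (expected-ordering violation),
#'   not an error; poorly identified designs (all-linear or
#'   all-saturated) attach an identifiability flag.
#' @export
langmuirPairFit <- function(stepsSpecific, stepsNonspecific) {
  dSp <- as.data.frame(stepsSpecific[stepsSpecific$usable, , drop = FALSE])
  dNs <- as.data.frame(stepsNonspecific[stepsNonspecific$usable, , drop = FALSE])
  if (length(unique(dSp$c)) < 3L || length(unique(dNs$c)) < 3L)
    nwStop("at least 3 usable concentrations per probe class are required",
           "nwDataError")
  cSp <- dSp$c; ySp <- dSp$Sigma
  cNs <- dNs$c; yNs <- dNs$Sigma
  y <- c(ySp, yNs)

  profiled <- function(kdSp, kdNs) {
    f <- c(cSp / (cSp + kdSp), cNs / (cNs + kdNs))
    sInf <- sum(y * f) / sum(f * f)
    list(sInf = sInf, sse = sum((y - sInf * f)^2))
  }
  obj <- function(p) profiled(exp(p[1]), exp(p[2]))$sse
  ## half-saturation initial guesses
  initKd <- function(cc, yy) {
    i <- which.min(abs(yy - max(yy) / 2))
    max(cc[i], min(cc))
  }
  p0 <- log(c(initKd(cSp, ySp), initKd(cNs, yNs)))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (!is.finite(opt$value))
    nwStop("paired Langmuir fit did not converge", "nwFitError")
  kdSp <- exp(opt$par[1]); kdNs <- exp(opt$par[2])
  pr <- profiled(kdSp, kdNs)
  sInf <- pr$sInf

  ## 3-parameter Jacobian (Sigma_inf, kdSp, kdNs) for standard errors
  fSp <- cSp / (cSp + kdSp); fNs <- cNs / (cNs + kdNs)
  J <- rbind(
    cbind(fSp, -sInf * cSp / (cSp + kdSp)^2, 0),
    cbind(fNs, 0, -sInf * cNs / (cNs + kdNs)^2))
  n <- length(y)
  s2 <- pr$sse / max(n - 3L, 1L)
  covM <- tryCatch(s2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 3, 3))
  dimnames(covM) <- rep(list(c("sigmaInf", "kdSpecific", "kdNonspecific")), 2)

  flags <- character()
  if (kdSp >= kdNs * (1 - 1e-8)) {
    flags <- c(flags, "kd-ordering-violated")
    nwWarn("fitted Kd(specific) >= Kd(nonspecific): no apparent selectivity",
           "nwOrderingWarning")
  }
  maxC <- max(c(cSp, cNs)); minC <- min(c(cSp, cNs))
  if (kdSp > 2 * maxC || kdNs > 2 * maxC)
    flags <- c(flags, "identifiability-all-linear")
  if (kdSp < minC / 2 && kdNs < minC / 2)
    flags <- c(flags, "identifiability-all-saturated")

  new("IsothermFit", sigmaInf = sInf, kdSpecific = kdSp, kdNonspecific = kdNs,
      se = c(sigmaInf = sqrt(abs(covM[1, 1])),
             kdSpecific = sqrt(abs(covM[2, 2])),
             kdNonspecific = sqrt(abs(covM[3, 3]))),
      cov = covM,
      temperature = S4Vectors::metadata(stepsSpecific)$temperature %||% 303.15,
      ionicStrength = S4Vectors::metadata(stepsSpecific)$ionicStrength %||% 150,
      flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Association rate from the initial slopes of the titration steps
#'
#' For binding from an empty surface the initial slope obeys
#' \eqn{\sigma'(c) = \Sigma_\infty k_{on} c}, so \code{kon} is the slope
#' of the origin-forced regression of \eqn{\sigma'(c)/\Sigma_\infty} on
#' the concentration regressor, pooling specific and nonspecific points
#' (a single common \code{kon}).  In a stepwise titration the exact
#' per-step slope is \eqn{k_{on} \Sigma_\infty K_d \Delta c /
#' (c_{prev} + K_d)}: the plain regressors \code{"c"} (as in the
#' original analysis) and \code{"delta_c"} are therefore biased once
#' \eqn{c_{prev}} is comparable to \eqn{K_d}; regressor \code{"exact"}
#' uses the fitted per-class \eqn{K_d} to remove that bias.
#'
#' Per-class dissociation rates are computed as \eqn{k_{off} = K_d k_{on}}.
#'
#' @param stepsSpecific,stepsNonspecific results of \code{\link{fitAllSteps}}
#' @param isotherm the \code{\link{IsothermFit}} of the same pair
#'   (provides \eqn{\Sigma_\infty} and the \eqn{K_d} values)
#' @param regressor "c" (default, as printed), "delta_c", or "exact"
#' @return a \code{\link{RateEstimate}}
#' @export
konFromSlopes <- function(stepsSpecific, stepsNonspecific, isotherm,
                          regressor = c("c", "delta_c", "exact")) {
  regressor <- match.arg(regressor)
  stopifnot(is(isotherm, "IsothermFit"))
  sInf <- isotherm@sigmaInf

  build <- function(steps, kd) {
    d <- as.data.frame(steps)
    cPrev <- c(0, d$c[-length(d$c)])
    d$cPrev <- cPrev
    d <- d[d$usable & is.finite(d$slope0), , drop = FALSE]
    x <- switch(regressor,
                c = d$c,
                delta_c = d$c - d$cPrev,
                exact = kd * (d$c - d$cPrev) / (d$cPrev + kd))
    data.frame(x = x, y = d$slope0 / sInf)
  }
  dd <- rbind(build(stepsSpecific, isotherm@kdSpecific),
              build(stepsNonspecific, isotherm@kdNonspecific))
  if (nrow(dd) < 1L || all(dd$x == 0))
    nwStop("no usable initial-slope data", "nwDataError")
  fit <- stats::lm(y ~ x + 0, data = dd)
  kon <- unname(stats::coef(fit)[1])
  ## noiseless fixtures make summary.lm grumble about perfect fits
  seKon <- sqrt(suppressWarnings(stats::vcov(fit))[1, 1])
  flags <- character()
  if (kon < 0)
    nwStop("fitted kon is negative: no binding signal in the initial slopes",
           "nwNoBindingSignalError")
  if (kon == 0) flags <- c(flags, "no-binding-signal")
  new("RateEstimate", kon = kon,
      koffSpecific = isotherm@kdSpecific * kon,
      koffNonspecific = isotherm@kdNonspecific * kon,
      se = c(kon = seKon,
             koffSpecific = isotherm@kdSpecific * seKon,
             koffNonspecific = isotherm@kdNonspecific * seKon),
      regressor = regressor, flags = flags)
}

#' Extract the specific-binding coefficient K2 from a paired isotherm fit
#'
#' \eqn{K_2 = K_d^{sp} / (K_d^{ns} - K_d^{sp})}, with first-order
#' (delta-method) uncertainty propagated from the covariance of the two
#' dissociation constants.  The uncertainty diverges as the two Kd
#' values approach each other, which is why a residual-bootstrap
#' alternative (\code{\link{bootstrapK2}}) is also provided.
#'
#' @param isotherm an \code{\link{IsothermFit}}
#' @return list with \code{K2} and \code{se}
#' @examples
#' # K2 for Kd_sp = 27.59 nM against K1 = 200 nM is ~0.16
#' @export
extractK2 <- function(isotherm) {
  stopifnot(is(isotherm, "IsothermFit"))
  kdSp <- isotherm@kdSpecific
  kdNs <- isotherm@kdNonspecific
  if (kdSp >= kdNs)
    nwStop("Kd(specific) >= Kd(nonspecific): K2 is not defined (specific probe cannot bind more weakly than the nonspecific reference)",
           "nwNonphysicalSelectivityError")
  gap <- kdNs - kdSp
  K2 <- kdSp / gap
  grad <- c(kdNs / gap^2, -kdSp / gap^2)   # d/dKdSp, d/dKdNs
  covKd <- isotherm@cov[2:3, 2:3]
  se <- if (all(is.finite(covKd))) sqrt(abs(drop(grad %*% covKd %*% grad)))
        else NA_real_
  list(K2 = K2, se = se)
}

#' Residual-bootstrap uncertainty for K2
#'
#' Resamples the residuals of the paired Langmuir fit over the usable
#' steps, refits, and re-extracts K2 \code{nBoot} times.
#'
#' @param stepsSpecific,stepsNonspecific results of \code{\link{fitAllSteps}}
#' @param nBoot number of resamples (default 500)
#' @param seed integer seed
#' @return list with \code{K2} (point estimate), \code{se} (bootstrap
#'   sd), and \code{quantiles} (2.5/50/97.5 percent)
#' @export
bootstrapK2 <- function(stepsSpecific, stepsNonspecific, nBoot = 500, seed = 1) {
  iso <- langmuirPairFit(stepsSpecific, stepsNonspecific)
  point <- extractK2(iso)$K2
  dSp <- as.data.frame(stepsSpecific)
  dNs <- as.data.frame(stepsNonspecific)
  fitSp <- iso@sigmaInf * dSp$c / (dSp$c + iso@kdSpecific)
  fitNs <- iso@sigmaInf * dNs$c / (dNs$c + iso@kdNonspecific)
  resSp <- dSp$Sigma - fitSp
  resNs <- dNs$Sigma - fitNs
  pooled <- c(resSp[dSp$usable], resNs[dNs$usable])
  draws <- withLocalSeed(deriveSeed(seed, "bootK2"), {
    vapply(seq_len(nBoot), function(b) {
      sSp <- stepsSpecific
      sNs <- stepsNonspecific
      sSp$Sigma <- fitSp + sample(pooled, nrow(dSp), replace = TRUE)
      sNs$Sigma <- fitNs + sample(pooled, nrow(dNs), replace = TRUE)
      k <- tryCatch(extractK2(suppressWarnings(langmuirPairFit(sSp, sNs)))$K2,
                    error = function(e) NA_real_)
      k
    }, numeric(1))
  })
  list(K2 = point, se = stats::sd(draws, na.rm = TRUE),
       quantiles = stats::quantile(draws, c(0.025, 0.5, 0.975), na.rm = TRUE))
}

## pooled model evaluation for the joint fit
jointModel <- function(kon1, K1v, kon2, K2v, traceSp, traceNs) {
  ratesSp <- RateSet(kon1 = kon1, koff1 = K1v * kon1,
                     kon2 = kon2, koff2 = K2v * kon2)
  ratesNs <- RateSet(kon1 = kon1, koff1 = K1v * kon1)
  thSp <- nwSolve(ratesSp, traceSp@schedule, traceSp@times)
  thNs <- nwSolve(ratesNs, traceNs@schedule, traceNs@times)
  c(thSp[, 1] + thSp[, 2], thNs[, 1] + thNs[, 2])
}

#' Joint nested-well kinetic fit of a specific/nonspecific trace pair
#'
#' Simultaneous least squares of both full sensorgrams against the
#' piecewise nested-well solution.  The nonspecific trace constrains
#' \code{kon1}, \code{koff1} and the shared saturation density; the
#' specific trace additionally constrains the inner-well rates
#' \code{kon2}, \code{koff2}.  Parameters are optimised as
#' \code{(log kon1, log K1, log kon2, log K2)} to enforce positivity,
#' with the saturation density profiled out linearly; initial values
#' come from the stepwise/Langmuir analysis (with a small multi-start
#' grid over \code{kon2}, which the equilibrium data do not pin down).
#'
#' The fit reports whether it sits in the fast-inner-exchange regime
#' (slow relaxation time within 5 percent of its limiting value at the
#' top concentration); there, \code{kon2} is only bounded from below and
#' a \code{kon2-lower-bound} flag is attached.
#'
#' @param traceSpecific,traceNonspecific paired \code{\link{BindingTrace}}
#'   objects recorded under the same condition
#' @param init optional named list (kon1, K1, kon2, K2) of starting values
#' @return an \code{\link{NWFit}}
#' @export
nwJointFit <- function(traceSpecific, traceNonspecific, init = NULL) {
  stopifnot(is(traceSpecific, "BindingTrace"),
            is(traceNonspecific, "BindingTrace"))
  ySp <- traceSpecific@sigma
  yNs <- traceNonspecific@sigma
  y <- c(ySp, yNs)

  if (is.null(init)) {
    stepsNs <- fitAllSteps(traceNonspecific)
    stepsSp <- fitAllSteps(traceSpecific)
    gl <- tryCatch(gammaLineFit(stepsNs), error = function(e) NULL)
    kon1_0 <- if (!is.null(gl) && gl$kon > 0) gl$kon else 1e-5
    koff1_0 <- if (!is.null(gl) && gl$koff > 0) gl$koff else 1e-3
    K1_0 <- koff1_0 / kon1_0
    iso <- tryCatch(suppressWarnings(langmuirPairFit(stepsSp, stepsNs)),
                    error = function(e) NULL)
    K2_0 <- if (!is.null(iso) && iso@kdSpecific < iso@kdNonspecific)
      iso@kdSpecific / (iso@kdNonspecific - iso@kdSpecific) else 0.2
    if (!is.null(iso)) K1_0 <- iso@kdNonspecific
    init <- list(kon1 = kon1_0, K1 = K1_0, kon2 = NA, K2 = K2_0)
  }

  sseFor <- function(p) {
    m <- tryCatch(jointModel(exp(p[1]), exp(p[2]), exp(p[3]), exp(p[4]),
                             traceSpecific, traceNonspecific),
                  error = function(e) NULL)
    if (is.null(m) || any(!is.finite(m))) return(1e30)
    sInf <- sum(y * m) / sum(m * m)
    sum((y - sInf * m)^2)
  }

  kon2Grid <- if (is.finite(init$kon2 %||% NA)) init$kon2
              else 10^seq(-4, -1, by = 1)
  starts <- lapply(kon2Grid, function(k2on)
    log(c(init$kon1, init$K1, k2on, init$K2)))
  sseStart <- vapply(starts, sseFor, numeric(1))
  p0 <- starts[[which.min(sseStart)]]

  opt <- stats::optim(p0, sseFor, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-13))
  opt <- stats::optim(opt$par, sseFor, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-13))
  if (!is.finite(opt$value) || opt$value >= 1e30)
    nwStop("joint nested-well fit did not converge", "nwFitError")
  p <- opt$par
  kon1 <- exp(p[1]); K1v <- exp(p[2]); kon2v <- exp(p[3]); K2v <- exp(p[4])
  m <- jointModel(kon1, K1v, kon2v, K2v, traceSpecific, traceNonspecific)
  sInf <- sum(y * m) / sum(m * m)
  sse <- sum((y - sInf * m)^2)

  flags <- character()
  if (K2v > 100) flags <- c(flags, "single-well-collapse")

  ## profile flatness in kon2 at fixed K2 (fast-exchange degeneracy)
  sse10 <- sseFor(p + c(0, 0, log(10), 0))
  if (is.finite(sse10) && (sse10 - sse) <= 1e-4 * max(sse, 1e-12))
    flags <- c(flags, "kon2-lower-bound")

  ## uncertainties: numerical Jacobian in the natural parameters
  theta <- c(kon1 = kon1, koff1 = K1v * kon1, kon2 = kon2v,
             koff2 = K2v * kon2v, sigmaInf = sInf)
  modelAt <- function(th) {
    th["sigmaInf"] * jointModel(th[["kon1"]], th[["koff1"]] / th[["kon1"]],
                                th[["kon2"]], th[["koff2"]] / th[["kon2"]],
                                traceSpecific, traceNonspecific)
  }
  J <- matrix(NA_real_, length(y), 5)
  base <- modelAt(theta)
  for (j in 1:5) {
    h <- theta[j] * 1e-6
    thp <- theta; thp[j] <- thp[j] + h
    J[, j] <- (modelAt(thp) - base) / h
  }
  s2 <- sse / max(length(y) - 5L, 1L)
  covM <- tryCatch(s2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 5, 5))
  se <- sqrt(abs(diag(covM)))
  names(se) <- names(theta)

  rates <- RateSet(kon1 = kon1, koff1 = K1v * kon1,
                   kon2 = kon2v, koff2 = K2v * kon2v)
  cTop <- max(traceSpecific@schedule@concentrations)
  tauL <- relaxationSpectrum(cTop, rates)$tauL
  tauLInf <- tauLLimit(cTop, kon1, K1v * kon1, K2v)
  new("NWFit", rates = rates, sigmaInf = sInf, se = se, sse = sse,
      tauL = tauL, tauLInf = tauLInf,
      fastExchange = abs(tauL - tauLInf) / tauLInf <= 0.05, flags = flags)
}

#' Van't Hoff decomposition of a K2(T) series
#'
#' Weighted linear regression of \eqn{\ln K_2} on \eqn{1/T} under the
#' dissociation-like convention \eqn{K_2 = \exp(\Delta H/RT - \Delta
#' S/R)}: the slope is \eqn{\Delta H/R} and the intercept
#' \eqn{-\Delta S/R}.  Weights are \eqn{1/se(\ln K_2)^2} when per-point
#' standard errors are supplied.
#'
#' @param series data.frame with columns \code{T} (K), \code{K2}, and
#'   optionally \code{se} (standard error of K2)
#' @return a \code{\link{ThermoFit}} with \eqn{\Delta H} in kcal/mol and
#'   \eqn{\Delta S} in cal/(mol K)
#' @examples
#' s <- generateK2TemperatureSeries(-12.8, -38.7)
#' vantHoffFit(s)   # recovers dH = -12.8, dS = -38.7 exactly
#' @export
vantHoffFit <- function(series) {
  if (!is.data.frame(series) || !all(c("T", "K2") %in% names(series)))
    nwStop("series must be a data.frame with columns T and K2", "nwDataError")
  if (nrow(series) < 3L)
    nwStop("at least 3 temperatures are required", "nwDataError")
  if (any(!is.finite(series$K2)) || any(series$K2 <= 0))
    nwStop("K2 values must be positive and finite", "nwDataError")
  if (any(series$T <= 0))
    nwStop("temperatures must be positive (K)", "nwDataError")
  x <- 1 / series$T
  yy <- log(series$K2)
  w <- NULL
  if ("se" %in% names(series) && all(is.finite(series$se)) &&
      all(series$se > 0))
    w <- (series$K2 / series$se)^2
  fit <- stats::lm(yy ~ x, weights = w)
  cf <- stats::coef(fit)
  V <- suppressWarnings(stats::vcov(fit))
  dH <- unname(cf[2]) * .RGasKcal
  dS <- -unname(cf[1]) * .RGasCal
  covHS <- matrix(c(.RGasKcal^2 * V[2, 2], -.RGasKcal * .RGasCal * V[1, 2],
                    -.RGasKcal * .RGasCal * V[1, 2], .RGasCal^2 * V[1, 1]),
                  2, 2, dimnames = rep(list(c("dH", "dS")), 2))
  new("ThermoFit", dH = dH, dS = dS,
      se = c(dH = sqrt(covHS[1, 1]), dS = sqrt(covHS[2, 2])),
      cov = covHS, nTemps = nrow(series))
}

#' Free-energy gap between specific and nonspecific binding
#'
#' \eqn{\Delta G = RT \ln K_2}, negative when the specific (docked)
#' state is favoured, because \eqn{K_2} is the dissociation-like ratio
#' of nonspecifically to specifically bound protein.  Note this inverts
#' the common association-constant convention.
#'
#' @param K2 specific-binding coefficient, > 0
#' @param T temperature, K (default 303.15, i.e. 30 C)
#' @return kcal/mol
#' @examples
#' deltaG(0.16)   # about -1.1 kcal/mol
#' @export
deltaG <- function(K2, T = 303.15) {
  assertPositiveScalar(K2, "K2")
  assertPositiveScalar(T, "T")
  .RGasKcal * T * log(K2)
}

#' Fraction of bound protein in the specifically docked state
#'
#' At equilibrium a fraction \eqn{1/(1+K_2)} of the protein bound to a
#' consensus-carrying probe is actually docked on the cognate site; for
#' \eqn{K_2 = 0.16}, 8.6 out of 10 bound dimers are docked.
#'
#' @param K2 specific-binding coefficient, >= 0
#' @return dimensionless fraction in [0, 1]
#' @examples
#' 10 * fractionSpecific(0.16)   # ~8.6
#' @export
fractionSpecific <- function(K2) {
  assertNonNegativeScalar(K2, "K2")
  1 / (1 + K2)
}

#' Free-energy difference between two measured dissociation constants
#'
#' \eqn{\Delta\Delta G = RT \ln(K_d^{ns} / K_d^{sp})}, the apparent
#' free-energy advantage of the specific probe over the nonspecific one.
#'
#' @param KdSpecific,KdNonspecific dissociation constants, nM
#' @param T temperature, K
#' @return kcal/mol (positive when the specific probe binds more strongly)
#' @examples
#' deltaDeltaG(30, 200)   # ~1.14 kcal/mol
#' @export
deltaDeltaG <- function(KdSpecific, KdNonspecific, T = 303.15) {
  assertPositiveScalar(KdSpecific, "KdSpecific")
  assertPositiveScalar(KdNonspecific, "KdNonspecific")
  assertPositiveScalar(T, "T")
  .RGasKcal * T * log(KdNonspecific / KdSpecific)
}
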