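#' @import methods
NULL

#' RateSet: kinetic rate constants of the nested-well model
#'
#' Holds the four rate constants of the sequential two-state (nested-well)
#' binding scheme: a bimolecular outer step (solution protein binding any
#' DNA, rates \code{kon1} in 1/(s nM) and \code{koff1} in 1/s) followed by
#' a unimolecular inner step (nonspecifically bound protein docking onto
#' the consensus site, rates \code{kon2} and \code{koff2}, both 1/s).
#' \code{kon2 = 0} denotes a single-well (purely nonspecific) probe.
#'
#' Derived constants: \code{K1 = koff1/kon1} (nM) is the dissociation
#' constant of the outer, nonspecific well; \code{K2 = koff2/kon2}
#' (dimensionless) is the ratio of nonspecifically to specifically bound
#' protein at equilibrium, defined only when \code{kon2 > 0}.  Small
#' \code{K2} means strong selectivity.
#'
#' @slot kon1 bimolecular association rate, 1/(s nM)
#' @slot koff1 nonspecific dissociation rate, 1/s
#' @slot kon2 nonspecific-to-specific docking rate, 1/s (0 = single well)
#' @slot koff2 specific-to-nonspecific escape rate, 1/s
#'
#' @examples
#' r <- RateSet(kon1 = 1.6e-5, koff1 = 3.2e-3, kon2 = 5e-3, koff2 = 8e-4)
#' K1(r); K2(r); effectiveKd(r)
#' @export
setClass("RateSet",
  representation(kon1 = "numeric", koff1 = "numeric",
                 kon2 = "numeric", koff2 = "numeric"))

setValidity("RateSet", function(object) {
  msgs <- character()
  for (s in c("kon1", "koff1", "kon2", "koff2")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msgs <- c(msgs, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msgs)) return(msgs)
  if (object@kon1 <= 0) msgs <- c(msgs, "kon1 must be > 0")
  if (object@koff1 <= 0) msgs <- c(msgs, "koff1 must be > 0")
  if (object@kon2 < 0) msgs <- c(msgs, "kon2 must be >= 0")
  if (object@koff2 < 0) msgs <- c(msgs, "koff2 must be >= 0")
  if (object@kon2 > 0 && object@koff2 <= 0)
    msgs <- c(msgs, "koff2 must be > 0 when kon2 > 0")
  if (object@kon2 == 0 && object@koff2 != 0)
    msgs <- c(msgs, "koff2 must be 0 when kon2 = 0 (single-well probe)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname RateSet-class
#' @param kon1,koff1,kon2,koff2 rate constants (see slots)
#' @return \code{RateSet()} returns a validated \code{RateSet} object.
#' @export
RateSet <- function(kon1, koff1, kon2 = 0, koff2 = 0) {
  new("RateSet", kon1 = as.numeric(kon1), koff1 = as.numeric(koff1),
      kon2 = as.numeric(kon2), koff2 = as.numeric(koff2))
}

#' StepSchedule: stepwise titration injection schedule
#'
#' Describes a stepwise titration: at each injection time the analyte
#' concentration in the flow cell is raised to a new (non-decreasing)
#' value and held constant until the next injection (excess-analyte
#' assumption: no depletion within a step).
#'
#' @slot stepTimes injection times, s, strictly increasing, first at 0
#' @slot concentrations concentration after each injection, nM, non-decreasing
#' @slot endTime end of the recorded trace, s (> last injection time)
#' @slot temperature sample temperature, K
#' @slot ionicStrength ionic strength, mM NaCl
#' @export
setClass("StepSchedule",
  representation(stepTimes = "numeric", concentrations = "numeric",
                 endTime = "numeric", temperature = "numeric",
                 ionicStrength = "numeric"))

setValidity("StepSchedule", function(object) {
  msgs <- character()
  st <- object@stepTimes; cc <- object@concentrations
  if (length(st) != length(cc))
    msgs <- c(msgs, "stepTimes and concentrations must have equal length")
  if (length(st) < 1L) msgs <- c(msgs, "at least one injection is required")
  if (length(st) >= 1L && st[1] != 0)
    msgs <- c(msgs, "first injection must be at t = 0")
  if (length(st) > 1L && any(diff(st) <= 0))
    msgs <- c(msgs, "stepTimes must be strictly increasing")
  if (any(!is.finite(cc)) || any(cc < 0))
    msgs <- c(msgs, "concentrations must be finite and non-negative")
  if (length(cc) > 1L && any(diff(cc) < 0))
    msgs <- c(msgs, "concentrations must be non-decreasing (stepwise titration)")
  if (length(object@endTime) != 1L || !is.finite(object@endTime) ||
      (length(st) >= 1L && object@endTime <= st[length(st)]))
    msgs <- c(msgs, "endTime must exceed the last injection time")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msgs <- c(msgs, "temperature (K) must be a positive scalar")
  if (length(object@ionicStrength) != 1L || object@ionicStrength < 0)
    msgs <- c(msgs, "ionicStrength (mM) must be a non-negative scalar")
  if (length(msgs)) msgs else TRUE
})

#' @rdname StepSchedule-class
#' @param stepTimes,concentrations,endTime,temperature,ionicStrength see slots
#' @return \code{StepSchedule()} returns a validated \code{StepSchedule}.
#' @export
StepSchedule <- function(stepTimes, concentrations, endTime,
                         temperature = 303.15, ionicStrength = 150) {
  if (missing(endTime))
    endTime <- stepTimes[length(stepTimes)] +
      if (length(stepTimes) > 1L) mean(diff(stepTimes)) else 3000
  new("StepSchedule", stepTimes = as.numeric(stepTimes),
      concentrations = as.numeric(concentrations),
      endTime = as.numeric(endTime), temperature = as.numeric(temperature),
      ionicStrength = as.numeric(ionicStrength))
}

#' BindingTrace: one spot's sensorgram plus its injection schedule
#'
#' A sampled surface mass density time series \eqn{\sigma(t)} for one
#' probe spot, together with the injection schedule it was recorded
#' under and the probe class ("specific" carries the consensus sequence,
#' "nonspecific" does not).
#'
#' @slot times sample times, s, strictly increasing
#' @slot sigma surface density samples, instrument units
#' @slot schedule a \code{\link{StepSchedule}}
#' @slot probeClass "specific" or "nonspecific"
#' @slot spotId spot label
#' @export
setClass("BindingTrace",
  representation(times = "numeric", sigma = "numeric",
                 schedule = "StepSchedule", probeClass = "character",
                 spotId = "character"))

setValidity("BindingTrace", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@sigma))
    msgs <- c(msgs, "times and sigma must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(!is.finite(object@sigma)))
    msgs <- c(msgs, "sigma must be finite")
  if (length(object@probeClass) != 1L ||
      !object@probeClass %in% c("specific", "nonspecific"))
    msgs <- c(msgs, "probeClass must be 'specific' or 'nonspecific'")
  if (length(object@spotId) != 1L || !nzchar(object@spotId))
    msgs <- c(msgs, "spotId must be a non-empty string")
  if (length(msgs)) msgs else TRUE
})

#' @rdname BindingTrace-class
#' @param times,sigma,schedule,probeClass,spotId see slots
#' @return \code{BindingTrace()} returns a validated \code{BindingTrace}.
#' @export
BindingTrace <- function(times, sigma, schedule, probeClass, spotId) {
  new("BindingTrace", times = as.numeric(times), sigma = as.numeric(sigma),
      schedule = schedule, probeClass = as.character(probeClass),
      spotId = as.character(spotId))
}

#' IsothermFit: paired Langmuir fit with a shared saturation density
#'
#' Result of the simultaneous Langmuir fit of the per-step asymptotes
#' \eqn{\Sigma(c)} of a specific/nonspecific probe pair, with one shared
#' saturation density \eqn{\Sigma_\infty} and one dissociation constant
#' per probe class.
#'
#' @slot sigmaInf shared saturation density, instrument units
#' @slot kdSpecific effective dissociation constant of the specific probe, nM
#' @slot kdNonspecific dissociation constant of the nonspecific probe, nM
#' @slot se named standard errors (sigmaInf, kdSpecific, kdNonspecific)
#' @slot cov 3x3 covariance matrix of the parameters
#' @slot temperature condition temperature, K
#' @slot ionicStrength condition ionic strength, mM
#' @slot flags character vector of fit diagnostics
#' @export
setClass("IsothermFit",
  representation(sigmaInf = "numeric", kdSpecific = "numeric",
                 kdNonspecific = "numeric", se = "numeric", cov = "matrix",
                 temperature = "numeric", ionicStrength = "numeric",
                 flags = "character"))

setValidity("IsothermFit", function(object) {
  msgs <- character()
  if (object@sigmaInf <= 0) msgs <- c(msgs, "sigmaInf must be > 0")
  if (object@kdSpecific <= 0 || object@kdNonspecific <= 0)
    msgs <- c(msgs, "Kd values must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' RateEstimate: kinetic rates from the initial-slope analysis
#'
#' A common association rate \code{kon} (pooled over both probe classes)
#' with the per-class dissociation rates computed as \code{koff = Kd * kon}.
#'
#' @slot kon association rate, 1/(s nM)
#' @slot koffSpecific dissociation rate of the specific probe, 1/s
#' @slot koffNonspecific dissociation rate of the nonspecific probe, 1/s
#' @slot se named standard errors
#' @slot regressor which concentration regressor was used (c, delta_c, exact)
#' @slot flags character vector of diagnostics
#' @export
setClass("RateEstimate",
  representation(kon = "numeric", koffSpecific = "numeric",
                 koffNonspecific = "numeric", se = "numeric",
                 regressor = "character", flags = "character"))

#' NWFit: joint kinetic fit of a specific/nonspecific trace pair
#'
#' @slot rates fitted \code{\link{RateSet}}
#' @slot sigmaInf fitted shared saturation density
#' @slot se named standard errors on (kon1, koff1, kon2, koff2, sigmaInf)
#' @slot sse residual sum of squares
#' @slot tauL slow relaxation time at the top concentration, s
#' @slot tauLInf fast-inner-exchange limit of tauL at that concentration, s
#' @slot fastExchange TRUE when tauL is within 5 percent of tauLInf
#' @slot flags character vector of diagnostics
#' @export
setClass("NWFit",
  representation(rates = "RateSet", sigmaInf = "numeric", se = "numeric",
                 sse = "numeric", tauL = "numeric", tauLInf = "numeric",
                 fastExchange = "logical", flags = "character"))

#' ThermoFit: van't Hoff decomposition of K2(T)
#'
#' Linear regression of ln K2 on 1/T following the convention
#' \eqn{K_2 = \exp(\Delta H/RT - \Delta S/R)}: because K2 is a
#' dissociation-like ratio (nonspecific over specific), the slope is
#' \eqn{+\Delta H/R} and the intercept \eqn{-\Delta S/R}, the reverse of
#' the usual association convention.
#'
#' @slot dH binding enthalpy change, kcal/mol
#' @slot dS binding entropy change, cal/(mol K)
#' @slot se named standard errors (dH, dS)
#' @slot cov 2x2 covariance of (dH, dS), units (kcal/mol)^2 etc.
#' @slot nTemps number of temperatures used
#' @export
setClass("ThermoFit",
  representation(dH = "numeric", dS = "numeric", se = "numeric",
                 cov = "matrix", nTemps = "numeric"))

## show methods ------------------------------------------------------------

setMethod("show", "RateSet", function(object) {
  cat("RateSet (nested-well kinetic constants)\n")
  cat(sprintf("  kon1  = %.4g 1/(s nM)   koff1 = %.4g 1/s\n",
              object@kon1, object@koff1))
  if (object@kon2 > 0) {
    cat(sprintf("  kon2  = %.4g 1/s        koff2 = %.4g 1/s\n",
                object@kon2, object@koff2))
    cat(sprintf("  K1 = %.4g nM   K2 = %.4g   effective Kd = %.4g nM\n",
                K1(object), K2(object), effectiveKd(object)))
  } else {
    cat("  kon2  = 0 (single-well / nonspecific probe)\n")
    cat(sprintf("  K1 = %.4g nM\n", K1(object)))
  }
})

setMethod("show", "StepSchedule", function(object) {
  cat(sprintf(
    "StepSchedule: %d injections, c = %.3g..%.3g nM, end %.0f s, T = %.2f K, Is = %.0f mM\n",
    length(object@stepTimes), object@concentrations[1],
    object@concentrations[length(object@concentrations)],
    object@endTime, object@temperature, object@ionicStrength))
})

setMethod("show", "BindingTrace", function(object) {
  cat(sprintf("BindingTrace '%s' (%s probe): %d samples over %.0f s\n",
              object@spotId, object@probeClass, length(object@times),
              if (length(object@times)) diff(range(object@times)) else 0))
  show(object@schedule)
})

setMethod("show", "IsothermFit", function(object) {
  cat("IsothermFit (paired Langmuir, shared saturation density)\n")
  cat(sprintf("  Sigma_inf = %.4g +/- %.2g\n",
              object@sigmaInf, object@se["sigmaInf"]))
  cat(sprintf("  Kd specific    = %.4g +/- %.2g nM\n",
              object@kdSpecific, object@se["kdSpecific"]))
  cat(sprintf("  Kd nonspecific = %.4g +/- %.2g nM\n",
              object@kdNonspecific, object@se["kdNonspecific"]))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "RateEstimate", function(object) {
  cat("RateEstimate (initial-slope analysis)\n")
  cat(sprintf("  kon = %.4g +/- %.2g 1/(s nM)  [regressor: %s]\n",
              object@kon, object@se["kon"], object@regressor))
  cat(sprintf("  koff specific = %.4g 1/s, koff nonspecific = %.4g 1/s\n",
              object@koffSpecific, object@koffNonspecific))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "NWFit", function(object) {
  cat("NWFit (joint nested-well kinetic fit)\n")
  show(object@rates)
  cat(sprintf("  Sigma_inf = %.4g, SSE = %.4g\n", object@sigmaInf, object@sse))
  cat(sprintf("  tauL = %.4g s vs tauL_inf = %.4g s (fast exchange: %s)\n",
              object@tauL, object@tauLInf, object@fastExchange))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ThermoFit", function(object) {
  cat("ThermoFit (van't Hoff decomposition of K2(T))\n")
  cat(sprintf("  dH = %.4g +/- %.2g kcal/mol\n", object@dH, object@se["dH"]))
  cat(sprintf("  dS = %.4g +/- %.2g cal/(mol K)\n", object@dS, object@se["dS"]))
  cat(sprintf("  dG(303.15 K) = %.4g kcal/mol over %d temperatures\n",
              deltaGAt(object, 303.15), as.integer(object@nTemps)))
})
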