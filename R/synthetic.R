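## Synthetic sensorgram generator.  Emulates the stepwise-titration
## experiments: paired specific/nonspecific probes sharing a saturation
## density, exponential-like relaxation per concentration step, additive
## Gaussian measurement noise, and K2(T) condition series.

#' Default stepwise titration schedule
#'
#' A doubling concentration ladder starting at 0.08 nM and capped with a
#' final step at 50 nM (the experimental titration range), one injection
#' every \code{stepDuration} seconds, at 30 C (303.15 K) and 150 mM NaCl.
#'
#' @param stepDuration seconds between injections (default 3000 s, long
#'   enough that the slowest default synthetic mode is near-saturated)
#' @param temperature K
#' @param ionicStrength mM NaCl
#' @return a \code{\link{StepSchedule}} with 11 steps, 0.08 to 50 nM
#' @examples
#' makeDefaultSchedule()
#' @export
makeDefaultSchedule <- function(stepDuration = 3000, temperature = 303.15,
                                ionicStrength = 150) {
  assertPositiveScalar(stepDuration, "stepDuration")
  conc <- 0.08 * 2^(0:30)
  conc <- c(conc[conc < 50], 50)
  StepSchedule(stepTimes = (seq_along(conc) - 1) * stepDuration,
               concentrations = conc,
               endTime = length(conc) * stepDuration,
               temperature = temperature, ionicStrength = ionicStrength)
}

#' Generate one synthetic sensorgram
#'
#' Samples the piecewise analytic nested-well solution on a regular time
#' grid, scales it by the saturation density and adds i.i.d. zero-mean
#' Gaussian noise.  The output is a pure function of the parameters and
#' the seed; the per-trace RNG stream is derived from
#' \code{(seed, spotId)} so fixture sets are order-independent.
#'
#' @param rates a \code{\link{RateSet}}
#' @param schedule a \code{\link{StepSchedule}}
#' @param sigmaInf saturation surface density, instrument units
#' @param noiseSd noise standard deviation, instrument units
#' @param sampleDt sampling interval, s
#' @param seed integer base seed
#' @param spotId spot label (also seeds the per-trace stream)
#' @param probeClass "specific" or "nonspecific"; default inferred from
#'   \code{kon2(rates) > 0}
#' @return a \code{\link{BindingTrace}}
#' @export
generateTrace <- function(rates, schedule, sigmaInf = 1000, noiseSd = 0,
                          sampleDt = 10, seed = 1, spotId = "spot1",
                          probeClass = NULL) {
  stopifnot(is(rates, "RateSet"), is(schedule, "StepSchedule"))
  assertPositiveScalar(sigmaInf, "sigmaInf")
  assertNonNegativeScalar(noiseSd, "noiseSd")
  assertPositiveScalar(sampleDt, "sampleDt")
  if (is.null(probeClass))
    probeClass <- if (rates@kon2 > 0) "specific" else "nonspecific"
  times <- seq(0, schedule@endTime, by = sampleDt)
  theta <- nwSolve(rates, schedule, times)
  sigma <- sigmaInf * (theta[, 1] + theta[, 2])
  if (noiseSd > 0) {
    noise <- withLocalSeed(deriveSeed(seed, spotId),
                           stats::rnorm(length(times), 0, noiseSd))
    sigma <- sigma + noise
  }
  BindingTrace(times = times, sigma = sigma, schedule = schedule,
               probeClass = probeClass, spotId = spotId)
}

#' Generate a paired specific/nonspecific probe fixture
#'
#' Both traces share the association rate \code{kon1}, the nonspecific
#' dissociation rate \code{koff1 = K1 * kon1} and the saturation density
#' \code{sigmaInf} (the maximum load of a probe does not depend on the
#' presence of the specific tract).  The specific trace adds the inner
#' well with \code{koff2 = K2 * kon2}; the nonspecific trace has
#' \code{kon2 = 0}.
#'
#' @param K1 nonspecific dissociation constant, nM
#' @param K2 specific-binding coefficient, dimensionless
#' @param kon1 association rate, 1/(s nM)
#' @param kon2 docking rate of the specific probe, 1/s
#' @param sigmaInf shared saturation density
#' @param schedule a \code{\link{StepSchedule}}
#' @param noiseSd noise standard deviation
#' @param sampleDt sampling interval, s
#' @param seed integer base seed
#' @param idPrefix prefix for the two spot labels
#' @return list with elements \code{specific} and \code{nonspecific},
#'   both \code{\link{BindingTrace}} objects
#' @examples
#' pair <- generateProbePair(K1 = 200, K2 = 0.16, schedule = makeDefaultSchedule())
#' @export
generateProbePair <- function(K1 = 200, K2 = 0.16, kon1 = 1.6e-5,
                              kon2 = 5e-3, sigmaInf = 1000,
                              schedule = makeDefaultSchedule(),
                              noiseSd = 0, sampleDt = 10, seed = 1,
                              idPrefix = "pair") {
  assertPositiveScalar(K1, "K1")
  assertPositiveScalar(K2, "K2")
  assertPositiveScalar(kon1, "kon1")
  assertPositiveScalar(kon2, "kon2")
  ratesSp <- RateSet(kon1 = kon1, koff1 = K1 * kon1,
                     kon2 = kon2, koff2 = K2 * kon2)
  ratesNs <- RateSet(kon1 = kon1, koff1 = K1 * kon1)
  list(
    specific = generateTrace(ratesSp, schedule, sigmaInf, noiseSd, sampleDt,
                             seed, spotId = paste0(idPrefix, "_sp"),
                             probeClass = "specific"),
    nonspecific = generateTrace(ratesNs, schedule, sigmaInf, noiseSd, sampleDt,
                                seed, spotId = paste0(idPrefix, "_ns"),
                                probeClass = "nonspecific"))
}

#' Generate a K2(T) temperature series
#'
#' Evaluates the van't Hoff form \eqn{K_2(T) = \exp(\Delta H/RT -
#' \Delta S/R)} (dissociation-like sign convention) on a temperature
#' grid, optionally multiplied by lognormal noise
#' \eqn{\exp(N(0, relNoise))}.
#'
#' @param dH enthalpy change, kcal/mol
#' @param dS entropy change, cal/(mol K)
#' @param temperatures K; default 6 points spanning 288.15-310.15 K
#' @param relNoise lognormal sd on the natural-log scale (0 = noiseless)
#' @param seed integer seed
#' @return data.frame with columns \code{T} (K) and \code{K2}
#' @examples
#' generateK2TemperatureSeries(-12.8, -38.7)   # K2(303.15 K) ~ 0.17
#' @export
generateK2TemperatureSeries <- function(dH, dS,
                                        temperatures = seq(288.15, 310.15,
                                                           length.out = 6),
                                        relNoise = 0, seed = 1) {
  if (any(temperatures <= 0))
    nwStop("temperatures must be positive (K)", "nwInvalidParameterError")
  assertNonNegativeScalar(relNoise, "relNoise")
  K2 <- exp(dH / (.RGasKcal * temperatures) - dS / .RGasCal)
  if (relNoise > 0) {
    fac <- withLocalSeed(deriveSeed(seed, "k2series"),
                         exp(stats::rnorm(length(temperatures), 0, relNoise)))
    K2 <- K2 * fac
  }
  data.frame(T = temperatures, K2 = K2)
}

#' Generate a multi-condition fixture set
#'
#' One specific/nonspecific trace pair per row of the condition table,
#' emulating e.g. an ionic-strength series where each condition has its
#' own \code{K1} and \code{K2} but shares the kinetic settings.
#'
#' @param conditions data.frame with columns \code{K1} (nM), \code{K2},
#'   and optionally \code{label}, \code{temperature} (K),
#'   \code{ionicStrength} (mM)
#' @param kon1,kon2,sigmaInf,schedule,noiseSd,sampleDt,seed shared
#'   settings, as in \code{\link{generateProbePair}}
#' @return named list of probe pairs (one per condition)
#' @export
generateConditionTable <- function(conditions, kon1 = 1.6e-5, kon2 = 5e-3,
                                   sigmaInf = 1000,
                                   schedule = makeDefaultSchedule(),
                                   noiseSd = 0, sampleDt = 10, seed = 1) {
  if (!is.data.frame(conditions) || !all(c("K1", "K2") %in% names(conditions)))
    nwStop("conditions must be a data.frame with columns K1 and K2",
           "nwConfigurationError")
  if (nrow(conditions) < 1L)
    nwStop("conditions table is empty", "nwConfigurationError")
  labels <- if ("label" %in% names(conditions)) as.character(conditions$label)
            else sprintf("cond%02d", seq_len(nrow(conditions)))
  if (anyDuplicated(labels))
    nwStop("condition labels must be unique", "nwConfigurationError")
  out <- vector("list", nrow(conditions))
  names(out) <- labels
  for (i in seq_len(nrow(conditions))) {
    sch <- schedule
    if ("temperature" %in% names(conditions))
      sch@temperature <- conditions$temperature[i]
    if ("ionicStrength" %in% names(conditions))
      sch@ionicStrength <- conditions$ionicStrength[i]
    validObject(sch)
    out[[i]] <- generateProbePair(K1 = conditions$K1[i], K2 = conditions$K2[i],
                                  kon1 = kon1, kon2 = kon2,
                                  sigmaInf = sigmaInf, schedule = sch,
                                  noiseSd = noiseSd, sampleDt = sampleDt,
                                  seed = seed, idPrefix = labels[i])
  }
  out
}
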