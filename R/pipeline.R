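## Condition-level pipeline: stepwise reduction -> paired isotherm ->
## initial-slope kinetics -> K2 -> joint kinetic fit -> summary.

#' Full analysis of one specific/nonspecific probe pair
#'
#' Runs the complete per-condition analysis chain on a paired pair of
#' stepwise-titration sensorgrams: per-step exponential fits, the paired
#' Langmuir isotherm with shared saturation density, the pooled
#' initial-slope estimate of \code{kon} (with \code{koff = Kd kon} per
#' class), extraction of the specific-binding coefficient \code{K2}, the
#' free-energy gap \code{dG = RT ln K2} and the apparent difference
#' \code{ddG = RT ln(Kd_ns/Kd_sp)}, and (optionally) the joint
#' nested-well kinetic fit of both raw traces.
#'
#' @param traceSpecific,traceNonspecific paired \code{\link{BindingTrace}}s
#' @param discard seconds discarded after each injection
#' @param konRegressor regressor for \code{\link{konFromSlopes}}; the
#'   pipeline default "exact" removes the stepwise-titration bias using
#'   the fitted Kd values
#' @param jointFit also run \code{\link{nwJointFit}} (default TRUE)
#' @param bootstrap add a residual-bootstrap K2 uncertainty
#' @param nBoot bootstrap resamples
#' @param seed integer seed (bootstrap only; the rest is deterministic)
#' @return list with components \code{stepsSpecific},
#'   \code{stepsNonspecific}, \code{isotherm}, \code{rates}, \code{K2},
#'   \code{nwFit} (or NULL) and \code{summary} (a flat named list
#'   suitable for \code{\link{writeSummary}})
#' @export
analyzeProbePair <- function(traceSpecific, traceNonspecific, discard = 10,
                             konRegressor = "exact", jointFit = TRUE,
                             bootstrap = FALSE, nBoot = 500, seed = 1) {
  stopifnot(is(traceSpecific, "BindingTrace"),
            is(traceNonspecific, "BindingTrace"))
  if (traceSpecific@probeClass != "specific" ||
      traceNonspecific@probeClass != "nonspecific")
    nwStop("analyzeProbePair expects (specific, nonspecific) traces in that order",
           "nwConsistencyError")
  stepsSp <- fitAllSteps(traceSpecific, discard = discard)
  stepsNs <- fitAllSteps(traceNonspecific, discard = discard)
  iso <- langmuirPairFit(stepsSp, stepsNs)
  rates <- konFromSlopes(stepsSp, stepsNs, iso, regressor = konRegressor)
  k2 <- extractK2(iso)
  if (bootstrap) {
    bs <- bootstrapK2(stepsSp, stepsNs, nBoot = nBoot, seed = seed)
    k2$seBootstrap <- bs$se
    k2$quantiles <- bs$quantiles
  }
  nw <- if (jointFit) nwJointFit(traceSpecific, traceNonspecific) else NULL
  Tcond <- iso@temperature
  summary <- list(
    temperature_K = Tcond,
    ionic_strength_mM = iso@ionicStrength,
    sigma_inf = iso@sigmaInf, sigma_inf_se = unname(iso@se["sigmaInf"]),
    Kd_sp = iso@kdSpecific, Kd_sp_se = unname(iso@se["kdSpecific"]),
    Kd_ns = iso@kdNonspecific, Kd_ns_se = unname(iso@se["kdNonspecific"]),
    kon = rates@kon, kon_se = unname(rates@se["kon"]),
    koff_sp = rates@koffSpecific, koff_ns = rates@koffNonspecific,
    K2 = k2$K2, K2_se = k2$se,
    dG_kcal = deltaG(k2$K2, Tcond),
    ddG_kcal = deltaDeltaG(iso@kdSpecific, iso@kdNonspecific, Tcond),
    flags = c(iso@flags, rates@flags, if (!is.null(nw)) nw@flags))
  if (!is.null(nw)) {
    summary <- c(summary, list(
      joint_kon1 = nw@rates@kon1, joint_koff1 = nw@rates@koff1,
      joint_kon2 = nw@rates@kon2, joint_koff2 = nw@rates@koff2,
      joint_K1 = K1(nw@rates), joint_K2 = K2(nw@rates),
      joint_Kd_eff = effectiveKd(nw@rates),
      joint_sigma_inf = nw@sigmaInf,
      tauL_s = nw@tauL, tauL_inf_s = nw@tauLInf,
      fast_exchange = nw@fastExchange))
  }
  list(stepsSpecific = stepsSp, stepsNonspecific = stepsNs, isotherm = iso,
       rates = rates, K2 = k2, nwFit = nw, summary = summary)
}

#' Analyse a set of conditions (e.g. an ionic-strength series)
#'
#' Applies \code{\link{analyzeProbePair}} to each condition's trace pair
#' independently (no pooling model across conditions) and binds the
#' condition summaries into one table.
#'
#' @param pairs named list of lists with elements \code{specific} and
#'   \code{nonspecific} (as produced by \code{\link{generateConditionTable}})
#' @param ... passed to \code{\link{analyzeProbePair}}
#' @return data.frame with one row per condition (numeric summary fields)
#' @export
analyzeConditionSet <- function(pairs, ...) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  rows <- lapply(names(pairs), function(nm) {
    res <- analyzeProbePair(pairs[[nm]]$specific, pairs[[nm]]$nonspecific, ...)
    s <- res$summary
    s$flags <- NULL
    s$fast_exchange <- NULL
    cbind(data.frame(condition = nm), as.data.frame(s))
  })
  common <- Reduce(intersect, lapply(rows, names))
  do.call(rbind, lapply(rows, function(r) r[, common, drop = FALSE]))
}

#' K2(T) series from a set of per-temperature condition summaries
#'
#' Convenience bridge from \code{\link{analyzeConditionSet}} output to
#' \code{\link{vantHoffFit}} input.
#'
#' @param conditionTable data.frame from \code{\link{analyzeConditionSet}}
#' @return data.frame with columns \code{T}, \code{K2}, \code{se}
#' @export
k2SeriesFromConditions <- function(conditionTable) {
  data.frame(T = conditionTable$temperature_K, K2 = conditionTable$K2,
             se = conditionTable$K2_se)
}
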