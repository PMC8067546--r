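# Condition-level inference: paired isotherm, initial-slope kinetics,
# K2 extraction, joint kinetic fit, van't Hoff thermodynamics.

makeStepsTable <- function(cc, Sigma, cls = "specific") {
  out <- S4Vectors::DataFrame(
    step = seq_along(cc), c = cc, Sigma = Sigma, Gamma = 1e-3,
    slope0 = NA_real_, sigmaPrev = 0, seSigma = 1e-6, seGamma = 1e-6,
    residualRms = 0, usable = TRUE, nPoints = 100)
  S4Vectors::metadata(out) <- list(probeClass = cls, spotId = cls,
                                   temperature = 303.15, ionicStrength = 150)
  out
}

test_that("paired Langmuir fit recovers exact asymptotes to < 0.1%", {
  cc <- makeDefaultSchedule()@concentrations
  sSp <- makeStepsTable(cc, 1000 * cc / (cc + 27.59))
  sNs <- makeStepsTable(cc, 1000 * cc / (cc + 200), "nonspecific")
  iso <- suppressWarnings(langmuirPairFit(sSp, sNs))
  expect_equal(sigmaInf(iso), 1000, tolerance = 1e-3)
  expect_equal(kdSpecific(iso), 27.59, tolerance = 1e-3)
  expect_equal(kdNonspecific(iso), 200, tolerance = 1e-3)
  # identical inputs give identical Kd estimates
  isoEq <- suppressWarnings(langmuirPairFit(sSp, sSp))
  expect_equal(kdSpecific(isoEq), kdNonspecific(isoEq), tolerance = 1e-6)
  expect_true("kd-ordering-violated" %in% fitFlags(isoEq))
})

test_that("noisy isotherm recovers Kd within 3 reported standard errors", {
  pair <- generateProbePair(K1 = 200, K2 = 0.16, sigmaInf = 1000,
                            schedule = makeDefaultSchedule(stepDuration = 9000),
                            noiseSd = 10, sampleDt = 15, seed = 42)
  iso <- langmuirPairFit(fitAllSteps(pair$specific),
                         fitAllSteps(pair$nonspecific))
  kdEff <- effectiveKd(200, 0.16)
  expect_lt(abs(kdSpecific(iso) - kdEff), 3 * stdErrors(iso)["kdSpecific"])
  expect_lt(abs(kdNonspecific(iso) - 200),
            3 * stdErrors(iso)["kdNonspecific"])
})

test_that("kon from first-step initial slope is exact for binding from zero", {
  # several single-step traces at different c, binding from the empty
  # surface: sigma'(c) = Sigma_inf kon c holds exactly
  sw <- singleWellRates()
  cc <- c(5, 10, 20)
  rows <- lapply(cc, function(c0) {
    tr <- generateTrace(sw, oneStepSchedule(c0, 6000), 1000, 0, 5)
    fitStep(traceTimes(tr), traceSigma(tr), 0, 0, c = c0)
  })
  tab <- S4Vectors::DataFrame(step = seq_along(cc),
                              do.call(rbind, lapply(rows, data.frame)))
  S4Vectors::metadata(tab) <- list(probeClass = "nonspecific", spotId = "x",
                                   temperature = 303.15, ionicStrength = 150)
  iso <- new("IsothermFit", sigmaInf = 1000, kdSpecific = 27.59,
             kdNonspecific = 200, se = c(sigmaInf = 1, kdSpecific = 1,
                                         kdNonspecific = 1),
             cov = diag(3), temperature = 303.15, ionicStrength = 150,
             flags = character())
  est <- konFromSlopes(tab, tab, iso, regressor = "c")
  expect_equal(konRate(est), 1.6e-5, tolerance = 1e-7)
  expect_equal(koffNonspecific(est), 200 * konRate(est), tolerance = 1e-12)

  # zero signal: kon = 0, flagged
  tab0 <- tab
  tab0$slope0 <- rep(0, nrow(tab0))
  est0 <- konFromSlopes(tab0, tab0, iso, regressor = "c")
  expect_equal(konRate(est0), 0)
  expect_true("no-binding-signal" %in% fitFlags(est0))
})

test_that("stepwise-titration kon regressors behave as the closed form predicts", {
  # full ladder: delta_c regressor is closer to truth than c; both
  # within a factor 2; the Kd-corrected regressor removes the bias for
  # single-well traces
  sw <- singleWellRates()
  sch <- makeDefaultSchedule(stepDuration = 12000)
  tr <- generateTrace(sw, sch, sigmaInf = 1000, noiseSd = 0, sampleDt = 20)
  steps <- fitAllSteps(tr)
  iso <- new("IsothermFit", sigmaInf = 1000, kdSpecific = 200,
             kdNonspecific = 200, se = c(sigmaInf = 1, kdSpecific = 1,
                                         kdNonspecific = 1),
             cov = diag(3), temperature = 303.15, ionicStrength = 150,
             flags = character())
  konC <- konRate(konFromSlopes(steps, steps, iso, regressor = "c"))
  konDc <- konRate(konFromSlopes(steps, steps, iso, regressor = "delta_c"))
  konEx <- konRate(konFromSlopes(steps, steps, iso, regressor = "exact"))
  truth <- 1.6e-5
  expect_lt(abs(konDc - truth), abs(konC - truth))
  expect_equal(konEx, truth, tolerance = 1e-4)
  # the plain regressors underestimate kon by exactly the factor the
  # closed-form per-step slope kon*Kd*dc/(c_prev + Kd) predicts
  cc <- steps$c
  dc <- cc - c(0, cc[-length(cc)])
  w <- 200 * dc / (c(0, cc[-length(cc)]) + 200)
  expect_equal(konC, truth * sum(cc * w) / sum(cc^2), tolerance = 1e-3)
  expect_equal(konDc, truth * sum(dc * w) / sum(dc^2), tolerance = 1e-3)
  expect_lt(konC, konDc)
})

test_that("K2 extraction and its error propagation follow the nested-well algebra", {
  iso <- new("IsothermFit", sigmaInf = 1000, kdSpecific = 27.59,
             kdNonspecific = 200,
             se = c(sigmaInf = 5, kdSpecific = 1.2, kdNonspecific = 8),
             cov = diag(c(25, 1.44, 64)), temperature = 303.15,
             ionicStrength = 150, flags = character())
  k2 <- extractK2(iso)
  expect_equal(k2$K2, 27.59 / (200 - 27.59), tolerance = 1e-12)
  expect_equal(k2$K2, 0.16, tolerance = 1e-2)
  gap <- 200 - 27.59
  seExp <- sqrt((200 / gap^2 * 1.2)^2 + (27.59 / gap^2 * 8)^2)
  expect_equal(k2$se, seExp, tolerance = 1e-10)
  # equal halves give K2 = 1
  iso2 <- iso; iso2@kdSpecific <- 100
  expect_equal(extractK2(iso2)$K2, 1.0)
  iso3 <- iso; iso3@kdSpecific <- 250
  expect_error(extractK2(iso3), class = "nwNonphysicalSelectivityError")
})

test_that("noiseless end-to-end pipeline recovers K2 = 0.16 within 1e-3", {
  sch <- makeDefaultSchedule(stepDuration = 15000)
  pair <- generateProbePair(K1 = 200, K2 = 0.16, schedule = sch,
                            noiseSd = 0, sampleDt = 25)
  res <- analyzeProbePair(pair$specific, pair$nonspecific, jointFit = TRUE)
  expect_equal(res$K2$K2, 0.16, tolerance = 1e-3 / 0.16)
  # consistency chain: the equilibrium (Langmuir) route and the kinetic
  # (joint-fit) route agree on K2 for the same fixture
  expect_equal(res$K2$K2, K2(res$nwFit), tolerance = 0.01)
})

test_that("joint nested-well fit recovers all four rates to < 1% on noiseless data", {
  sch <- makeDefaultSchedule()
  pair <- generateProbePair(K1 = 200, K2 = 0.16, kon1 = 1.6e-5, kon2 = 5e-3,
                            sigmaInf = 1000, schedule = sch, noiseSd = 0,
                            sampleDt = 25)
  fit <- nwJointFit(pair$specific, pair$nonspecific)
  r <- fittedRates(fit)
  expect_equal(kon1(r), 1.6e-5, tolerance = 0.01)
  expect_equal(koff1(r), 3.2e-3, tolerance = 0.01)
  expect_equal(kon2(r), 5e-3, tolerance = 0.01)
  expect_equal(koff2(r), 8e-4, tolerance = 0.01)
  expect_equal(sigmaInf(fit), 1000, tolerance = 0.01)
  expect_equal(K2(fit), 0.16, tolerance = 0.01)
})

test_that("joint fit flags the single-well collapse and the fast-exchange regime", {
  sch <- makeDefaultSchedule(stepDuration = 1500)
  # 'specific' trace actually generated with no inner well
  ns <- generateTrace(singleWellRates(), sch, 1000, 0, 25,
                      spotId = "ns", probeClass = "nonspecific")
  spFake <- generateTrace(singleWellRates(), sch, 1000, 0, 25,
                          spotId = "sp", probeClass = "specific")
  fit <- nwJointFit(spFake, ns)
  expect_true(any(c("single-well-collapse", "kon2-lower-bound") %in%
                  fitFlags(fit)))
  expect_gt(K2(fit), 10)

  # fast-exchange fixture: inner rates 100x faster at the same K2
  pairFast <- generateProbePair(K1 = 200, K2 = 0.16, kon2 = 0.5,
                                schedule = makeDefaultSchedule(stepDuration = 1500),
                                noiseSd = 0, sampleDt = 25)
  fitFast <- nwJointFit(pairFast$specific, pairFast$nonspecific)
  expect_true(fitFast@fastExchange)
  expect_equal(fitFast@tauL, fitFast@tauLInf, tolerance = 0.05)
})

test_that("van't Hoff regression is the exact inverse of the generator", {
  s <- generateK2TemperatureSeries(-12.8, -38.7)
  tf <- vantHoffFit(s)
  expect_equal(deltaH(tf), -12.8, tolerance = 1e-10)
  expect_equal(deltaS(tf), -38.7, tolerance = 1e-10)
  # temperature-independent K2 means zero enthalpy
  tf0 <- vantHoffFit(data.frame(T = c(290, 300, 310), K2 = rep(0.2, 3)))
  expect_equal(deltaH(tf0), 0, tolerance = 1e-12)
  # dG self-consistency: R T ln K2_model(T) = dH - T dS identically
  Tg <- seq(280, 320, by = 5)
  expect_equal(1.987e-3 * Tg * log(k2Model(tf, Tg)),
               deltaH(tf) - Tg * deltaS(tf) / 1000, tolerance = 1e-12)
  expect_error(vantHoffFit(data.frame(T = c(290, 300, 310), K2 = c(1, -1, 1))),
               class = "nwDataError")
  expect_error(vantHoffFit(s[1:2, ]), class = "nwDataError")
})

test_that("van't Hoff recovery under 5% lognormal noise is unbiased within 1 kcal/mol", {
  dHs <- vapply(1:200, function(seed) {
    s <- generateK2TemperatureSeries(-12.8, -38.7, relNoise = 0.05,
                                     seed = seed)
    deltaH(vantHoffFit(s))
  }, numeric(1))
  expect_lt(abs(mean(dHs) + 12.8), 1)
  expect_gt(sd(dHs), 0)
})

test_that("thermodynamic arithmetic matches the printed conventions", {
  expect_equal(deltaG(0.16, 303.15), -1.1, tolerance = 0.05 / 1.1)
  expect_equal(signif(deltaG(0.16, 303.15), 2), -1.1)
  expect_equal(deltaG(1, 310), 0)
  expect_equal(deltaG(0.169, 303.15), -1.07, tolerance = 1e-2)
  expect_equal(10 * fractionSpecific(0.16), 8.6, tolerance = 1e-2)
  expect_equal(fractionSpecific(0), 1)
  expect_equal(fractionSpecific(1), 0.5)
  expect_equal(deltaDeltaG(30, 200, 303.15), 1.14, tolerance = 1e-2)
  expect_equal(deltaDeltaG(25, 160, 303.15), 1.12, tolerance = 1e-2)
  expect_equal(deltaDeltaG(50, 50), 0)
  expect_error(deltaG(-0.1), class = "nwInvalidParameterError")
  expect_error(fractionSpecific(-1), class = "nwInvalidParameterError")
  expect_error(deltaDeltaG(0, 10), class = "nwInvalidParameterError")
})

test_that("recovered effective Kd increases monotonically with the generating K2", {
  sch <- makeDefaultSchedule(stepDuration = 12000)
  kds <- vapply(c(0.1, 0.3, 1, 3), function(k2) {
    pair <- generateProbePair(K1 = 200, K2 = k2, schedule = sch,
                              noiseSd = 0, sampleDt = 50)
    iso <- suppressWarnings(
      langmuirPairFit(fitAllSteps(pair$specific),
                      fitAllSteps(pair$nonspecific)))
    kdSpecific(iso)
  }, numeric(1))
  expect_true(all(diff(kds) > 0))
})

test_that("bootstrap K2 uncertainty is finite and seed-stable", {
  pair <- generateProbePair(K1 = 200, K2 = 0.16,
                            schedule = makeDefaultSchedule(stepDuration = 9000),
                            noiseSd = 10, sampleDt = 30, seed = 7)
  sSp <- fitAllSteps(pair$specific)
  sNs <- fitAllSteps(pair$nonspecific)
  b1 <- bootstrapK2(sSp, sNs, nBoot = 50, seed = 3)
  b2 <- bootstrapK2(sSp, sNs, nBoot = 50, seed = 3)
  expect_identical(b1$se, b2$se)
  expect_true(is.finite(b1$se) && b1$se > 0)
  expect_true(b1$quantiles[1] < b1$quantiles[3])
})
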