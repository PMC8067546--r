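# Synthetic sensorgram generator: schedule defaults, determinism,
# oracle equivalence of noiseless traces, paired-probe structure, and
# the K2(T) condition series.

test_that("default schedule is the doubling ladder 0.08..50 nM at 30 C", {
  sch <- makeDefaultSchedule()
  cc <- concentrations(sch)
  expect_length(cc, 11)
  expect_equal(cc[1], 0.08)
  expect_equal(cc[length(cc)], 50)
  expect_equal(cc[1:10], 0.08 * 2^(0:9))
  expect_true(all(diff(cc) > 0))
  expect_equal(diff(stepTimes(sch)), rep(3000, 10))
  expect_equal(temperature(sch), 303.15)
  expect_equal(ionicStrength(sch), 150)
})

test_that("noiseless traces equal the oracle and noise is seed-deterministic", {
  r <- defaultRates()
  sch <- makeDefaultSchedule()
  tr <- generateTrace(r, sch, sigmaInf = 1000, noiseSd = 0, sampleDt = 50)
  th <- odeOracle(r, sch, traceTimes(tr))
  expect_lt(max(abs(traceSigma(tr) - 1000 * (th[, 1] + th[, 2]))), 1e-8)

  # single-well one-step trace is the textbook rising exponential
  sw <- singleWellRates()
  sch1 <- oneStepSchedule(10)
  tr1 <- generateTrace(sw, sch1, sigmaInf = 1000, noiseSd = 0, sampleDt = 10)
  gam <- 1.6e-5 * 10 + 3.2e-3
  expected <- 1000 * 10 / 210 * (1 - exp(-gam * traceTimes(tr1)))
  expect_equal(traceSigma(tr1), expected, tolerance = 1e-12)

  # same seed twice -> identical; different seed -> different
  a <- generateTrace(r, sch, noiseSd = 10, seed = 7)
  b <- generateTrace(r, sch, noiseSd = 10, seed = 7)
  c3 <- generateTrace(r, sch, noiseSd = 10, seed = 8)
  expect_identical(traceSigma(a), traceSigma(b))
  expect_false(identical(traceSigma(a), traceSigma(c3)))
  # generation does not disturb the global RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generateTrace(r, sch, noiseSd = 10, seed = 7))
  expect_identical(rnorm(3), before)
})

test_that("probe pairs share the saturation density and order as expected", {
  schL <- makeDefaultSchedule(stepDuration = 15000)
  pair <- generateProbePair(K1 = 200, K2 = 0.16, kon1 = 1.6e-5, kon2 = 5e-3,
                            sigmaInf = 1000, schedule = schL, noiseSd = 0,
                            sampleDt = 50)
  expect_equal(probeClass(pair$specific), "specific")
  expect_equal(probeClass(pair$nonspecific), "nonspecific")
  tSp <- traceSigma(pair$specific)
  tNs <- traceSigma(pair$nonspecific)
  # specific plateau larger at the end of every step
  st <- stepTimes(schL)
  ends <- c(st[-1], endTime(schL)) - 50
  idx <- findInterval(ends, traceTimes(pair$specific))
  expect_true(all(tSp[idx] > tNs[idx]))
  # plateau ratio at the end of a long step approaches the Langmuir ratio
  kdEff <- effectiveKd(200, 0.16)
  c5 <- concentrations(schL)[5]
  i5 <- idx[5]
  ratio <- (c5 / (c5 + kdEff)) / (c5 / (c5 + 200))
  expect_equal(tSp[i5] / tNs[i5], ratio, tolerance = 0.02)
  # slower approach on the specific probe: larger remaining deficit
  # mid-step (relative to its own plateau) on an early step
  tMid <- st[2] + 400
  iMid <- which.min(abs(traceTimes(pair$specific) - tMid))
  fracSp <- tSp[iMid] / tSp[idx[2]]
  fracNs <- tNs[iMid] / tNs[idx[2]]
  expect_lt(fracSp, fracNs)

  # K2 -> Inf: the two traces coincide (empty inner well)
  pairInf <- generateProbePair(K1 = 200, K2 = 1e8, kon1 = 1.6e-5, kon2 = 5e-3,
                               schedule = makeDefaultSchedule(), noiseSd = 0,
                               sampleDt = 100)
  expect_lt(max(abs(traceSigma(pairInf$specific) -
                    traceSigma(pairInf$nonspecific))), 1e-4 * 1000)
})

test_that("K2 temperature series follows the van't Hoff form", {
  s <- generateK2TemperatureSeries(-12.8, -38.7, temperatures = 303.15,
                                   relNoise = 0)
  expect_equal(s$K2, exp(-12.8 / (1.987e-3 * 303.15) + 38.7 / 1.987),
               tolerance = 1e-12)
  expect_equal(s$K2, 0.17, tolerance = 0.01)
  # zero enthalpy and entropy: K2 = 1 everywhere
  s0 <- generateK2TemperatureSeries(0, 0)
  expect_equal(s0$K2, rep(1, 6))
  # exothermic docking: K2 increases with temperature
  sm <- generateK2TemperatureSeries(-12.8, -38.7)
  expect_true(all(diff(sm$K2) > 0))
  # lognormal noise is seed-deterministic and positive
  sn1 <- generateK2TemperatureSeries(-12.8, -38.7, relNoise = 0.05, seed = 3)
  sn2 <- generateK2TemperatureSeries(-12.8, -38.7, relNoise = 0.05, seed = 3)
  expect_identical(sn1$K2, sn2$K2)
  expect_true(all(sn1$K2 > 0))
})

test_that("condition tables produce one reproducible pair per condition", {
  cond <- data.frame(K1 = c(200, 220), K2 = c(0.16, 0.4),
                     label = c("is150", "is250"),
                     ionicStrength = c(150, 250))
  sch <- makeDefaultSchedule(stepDuration = 1500)
  fx <- generateConditionTable(cond, schedule = sch, noiseSd = 5,
                               sampleDt = 50, seed = 2)
  expect_named(fx, c("is150", "is250"))
  expect_equal(ionicStrength(schedule(fx$is250$specific)), 250)
  # single condition reduces to generateProbePair with the same label seed
  fx1 <- generateConditionTable(cond[1, ], schedule = sch, noiseSd = 5,
                                sampleDt = 50, seed = 2)
  direct <- generateProbePair(K1 = 200, K2 = 0.16, schedule = sch,
                              noiseSd = 5, sampleDt = 50, seed = 2,
                              idPrefix = "is150")
  expect_identical(traceSigma(fx1$is150$specific), traceSigma(direct$specific))
  # reproducible across calls
  fxb <- generateConditionTable(cond, schedule = sch, noiseSd = 5,
                                sampleDt = 50, seed = 2)
  expect_identical(traceSigma(fx$is150$nonspecific),
                   traceSigma(fxb$is150$nonspecific))
  expect_error(generateConditionTable(data.frame(K1 = 1)),
               class = "nwConfigurationError")
})

test_that("noise perturbs the fitted step asymptote at the expected scale", {
  # sd s noise over n points moves Sigma by O(s/sqrt(n))
  sch1 <- oneStepSchedule(10, duration = 6000)
  sw <- singleWellRates()
  clean <- fitStep(traceTimes(tr <- generateTrace(sw, sch1, 1000, 0, 5)),
                   traceSigma(tr), 0, 0, c = 10)
  set.seed(17)
  devs <- replicate(20, {
    trN <- generateTrace(sw, sch1, 1000, 10, 5, seed = sample.int(1e6, 1))
    fitStep(traceTimes(trN), traceSigma(trN), 0, 0, c = 10)$Sigma - clean$Sigma
  })
  n <- length(traceTimes(tr))
  expect_lt(sd(devs), 10 * 10 / sqrt(n))   # well below 10 x the naive bound
  expect_lt(abs(mean(devs)), 3 * 10 / sqrt(n))
})
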