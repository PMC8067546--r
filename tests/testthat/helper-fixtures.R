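# Shared fixtures.  Rates follow the experimentally determined scale:
# kon ~ 1.6e-5 1/(s nM), nonspecific koff ~ 3.2e-3 1/s (K1 = 200 nM),
# K2 = 0.16 with docking rate kon2 = 5e-3 1/s.

defaultRates <- function() RateSet(kon1 = 1.6e-5, koff1 = 3.2e-3,
                                   kon2 = 5e-3, koff2 = 8e-4)

singleWellRates <- function() RateSet(kon1 = 1.6e-5, koff1 = 3.2e-3)

# log-uniform draw of physically plausible nested-well rates
randomRates <- function() {
  RateSet(kon1 = 10^runif(1, -5.5, -4.5),
          koff1 = 10^runif(1, -3.5, -2.5),
          kon2 = 10^runif(1, -3.5, -2.5),
          koff2 = 10^runif(1, -4.5, -3))
}

oneStepSchedule <- function(c, duration = 3000, ...) {
  StepSchedule(stepTimes = 0, concentrations = c, endTime = duration, ...)
}
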