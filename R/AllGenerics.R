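## Accessor generics.  Slot access from user code is discouraged; these
## are the supported surface.

#' @rdname RateSet-class
#' @param object,x a package object
#' @export
setGeneric("kon1", function(object) standardGeneric("kon1"))
#' @rdname RateSet-class
#' @export
setGeneric("koff1", function(object) standardGeneric("koff1"))
#' @rdname RateSet-class
#' @export
setGeneric("kon2", function(object) standardGeneric("kon2"))
#' @rdname RateSet-class
#' @export
setGeneric("koff2", function(object) standardGeneric("koff2"))

#' @rdname RateSet-class
#' @export
setGeneric("K1", function(object) standardGeneric("K1"))

#' @rdname RateSet-class
#' @export
setGeneric("K2", function(object) standardGeneric("K2"))

setMethod("kon1", "RateSet", function(object) object@kon1)
setMethod("koff1", "RateSet", function(object) object@koff1)
setMethod("kon2", "RateSet", function(object) object@kon2)
setMethod("koff2", "RateSet", function(object) object@koff2)

setMethod("K1", "RateSet", function(object) object@koff1 / object@kon1)

setMethod("K2", "RateSet", function(object) {
  if (object@kon2 <= 0)
    nwStop("K2 is undefined for a single-well RateSet (kon2 = 0)",
           "nwInvalidParameterError")
  object@koff2 / object@kon2
})

#' @rdname StepSchedule-class
#' @param object a package object
#' @export
setGeneric("stepTimes", function(object) standardGeneric("stepTimes"))
#' @rdname StepSchedule-class
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))
#' @rdname StepSchedule-class
#' @export
setGeneric("endTime", function(object) standardGeneric("endTime"))
#' @rdname StepSchedule-class
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))
#' @rdname StepSchedule-class
#' @export
setGeneric("ionicStrength", function(object) standardGeneric("ionicStrength"))

setMethod("stepTimes", "StepSchedule", function(object) object@stepTimes)
setMethod("concentrations", "StepSchedule", function(object) object@concentrations)
setMethod("endTime", "StepSchedule", function(object) object@endTime)
setMethod("temperature", "StepSchedule", function(object) object@temperature)
setMethod("ionicStrength", "StepSchedule", function(object) object@ionicStrength)

#' @rdname BindingTrace-class
#' @param object a package object
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname BindingTrace-class
#' @export
setGeneric("traceSigma", function(object) standardGeneric("traceSigma"))
#' @rdname BindingTrace-class
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))
#' @rdname BindingTrace-class
#' @export
setGeneric("probeClass", function(object) standardGeneric("probeClass"))
#' @rdname BindingTrace-class
#' @export
setGeneric("spotId", function(object) standardGeneric("spotId"))

setMethod("traceTimes", "BindingTrace", function(object) object@times)
setMethod("traceSigma", "BindingTrace", function(object) object@sigma)
setMethod("schedule", "BindingTrace", function(object) object@schedule)
setMethod("probeClass", "BindingTrace", function(object) object@probeClass)
setMethod("spotId", "BindingTrace", function(object) object@spotId)
setMethod("stepTimes", "BindingTrace", function(object) object@schedule@stepTimes)
setMethod("concentrations", "BindingTrace", function(object) object@schedule@concentrations)

#' @rdname IsothermFit-class
#' @param object a package object
#' @export
setGeneric("sigmaInf", function(object) standardGeneric("sigmaInf"))
#' @rdname IsothermFit-class
#' @export
setGeneric("kdSpecific", function(object) standardGeneric("kdSpecific"))
#' @rdname IsothermFit-class
#' @export
setGeneric("kdNonspecific", function(object) standardGeneric("kdNonspecific"))
#' @rdname IsothermFit-class
#' @export
setGeneric("stdErrors", function(object) standardGeneric("stdErrors"))
#' @rdname IsothermFit-class
#' @export
setGeneric("fitFlags", function(object) standardGeneric("fitFlags"))

setMethod("sigmaInf", "IsothermFit", function(object) object@sigmaInf)
setMethod("kdSpecific", "IsothermFit", function(object) object@kdSpecific)
setMethod("kdNonspecific", "IsothermFit", function(object) object@kdNonspecific)
setMethod("stdErrors", "IsothermFit", function(object) object@se)
setMethod("fitFlags", "IsothermFit", function(object) object@flags)

#' @rdname RateEstimate-class
#' @param object a package object
#' @export
setGeneric("konRate", function(object) standardGeneric("konRate"))
#' @rdname RateEstimate-class
#' @export
setGeneric("koffSpecific", function(object) standardGeneric("koffSpecific"))
#' @rdname RateEstimate-class
#' @export
setGeneric("koffNonspecific", function(object) standardGeneric("koffNonspecific"))

setMethod("konRate", "RateEstimate", function(object) object@kon)
setMethod("koffSpecific", "RateEstimate", function(object) object@koffSpecific)
setMethod("koffNonspecific", "RateEstimate", function(object) object@koffNonspecific)
setMethod("stdErrors", "RateEstimate", function(object) object@se)
setMethod("fitFlags", "RateEstimate", function(object) object@flags)

#' @rdname NWFit-class
#' @param object a package object
#' @export
setGeneric("fittedRates", function(object) standardGeneric("fittedRates"))

setMethod("fittedRates", "NWFit", function(object) object@rates)
setMethod("sigmaInf", "NWFit", function(object) object@sigmaInf)
setMethod("stdErrors", "NWFit", function(object) object@se)
setMethod("fitFlags", "NWFit", function(object) object@flags)
setMethod("K1", "NWFit", function(object) K1(object@rates))
setMethod("K2", "NWFit", function(object) K2(object@rates))

#' @rdname ThermoFit-class
#' @param object a package object
#' @export
setGeneric("deltaH", function(object) standardGeneric("deltaH"))
#' @rdname ThermoFit-class
#' @export
setGeneric("deltaS", function(object) standardGeneric("deltaS"))
#' @rdname ThermoFit-class
#' @param T temperature, K
#' @export
setGeneric("deltaGAt", function(object, T) standardGeneric("deltaGAt"))
#' @rdname ThermoFit-class
#' @export
setGeneric("k2Model", function(object, T) standardGeneric("k2Model"))

setMethod("deltaH", "ThermoFit", function(object) object@dH)
setMethod("deltaS", "ThermoFit", function(object) object@dS)
setMethod("stdErrors", "ThermoFit", function(object) object@se)

## dG(T) = dH - T*dS/1000 (dS is in cal/(mol K)); identical to
## R*T*ln K2_model(T) by construction.
setMethod("deltaGAt", "ThermoFit", function(object, T) {
  object@dH - T * object@dS / 1000
})

setMethod("k2Model", "ThermoFit", function(object, T) {
  exp(object@dH / (.RGasKcal * T) - object@dS / .RGasCal)
})

#' @rdname effectiveKd
#' @export
setGeneric("effectiveKd", function(object, ...) standardGeneric("effectiveKd"))
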