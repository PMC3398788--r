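#' @include AllClasses.R
NULL

#' Species names of a kinetic model
#' @param object a \linkS4class{KineticModel}.
#' @return character vector of species names in state order.
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' Parameter names of a kinetic model or parameter space
#' @param object a \linkS4class{KineticModel} or \linkS4class{ParameterSpace}.
#' @return character vector of parameter names.
#' @export
setGeneric("parameterNames", function(object) standardGeneric("parameterNames"))

#' Nominal parameter values
#' @param object a \linkS4class{KineticModel} or \linkS4class{ParameterSpace}.
#' @return named numeric vector of nominal values.
#' @export
setGeneric("nominalParameters",
           function(object) standardGeneric("nominalParameters"))

#' Conditions bundled with a model
#' @param object a \linkS4class{KineticModel}.
#' @return list of \linkS4class{Condition} objects.
#' @export
setGeneric("modelConditions",
           function(object) standardGeneric("modelConditions"))

#' Readouts bundled with a model
#' @param object a \linkS4class{KineticModel}.
#' @return list of \linkS4class{Readout} objects.
#' @export
setGeneric("modelReadouts", function(object) standardGeneric("modelReadouts"))

#' Names of perturbable parameters (hypercube axes)
#' @param object a \linkS4class{ParameterSpace}.
#' @return character vector in entry order.
#' @export
setGeneric("perturbableNames",
           function(object) standardGeneric("perturbableNames"))

#' Records of a metric table
#' @param object a \linkS4class{MetricTable}.
#' @return data.frame of per-(sample, condition, readout) records.
#' @export
setGeneric("metricRecords", function(object) standardGeneric("metricRecords"))

#' Tabular view of an analysis result
#' @param object a \linkS4class{PrccProfile}, \linkS4class{SensitivityProfile},
#'   \linkS4class{ProfileComparison}, \linkS4class{TargetCalls},
#'   \linkS4class{LsaSpectrum} or \linkS4class{ParameterSpace}.
#' @return data.frame.
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))
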