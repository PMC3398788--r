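#' @import methods
NULL

#' Integration settings for kinetic model simulation
#'
#' Holds the integration horizon, the dense output grid used for plotting,
#' and the solver tolerances. Units are minutes (time) and nM (amounts).
#'
#' @slot horizon numeric(1), integration horizon T in minutes.
#' @slot times numeric, strictly increasing output grid in [0, horizon].
#' @slot rtol numeric(1), relative solver tolerance.
#' @slot atol numeric(1), absolute solver tolerance in nM.
#' @exportClass SimulationSettings
setClass("SimulationSettings",
  representation(horizon = "numeric", times = "numeric",
                 rtol = "numeric", atol = "numeric"))

setValidity("SimulationSettings", function(object) {
  msg <- character()
  if (length(object@horizon) != 1L || !is.finite(object@horizon) ||
      object@horizon <= 0)
    msg <- c(msg, "'horizon' must be a single positive number (minutes)")
  if (length(object@times) < 2L || any(!is.finite(object@times)) ||
      any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (length(object@times) && (min(object@times) < 0 ||
      max(object@times) > object@horizon + 1e-9))
    msg <- c(msg, "'times' must lie in [0, horizon]")
  if (object@rtol <= 0 || object@atol <= 0)
    msg <- c(msg, "solver tolerances must be positive")
  if (length(msg)) msg else TRUE
})

#' A named simulation condition (parameter overrides)
#'
#' A condition fixes externally controlled parameters -- typically ligand and
#' inhibitor concentrations -- at the values used in the experiment being
#' imitated. Overridden parameters are excluded from hypercube sampling.
#'
#' @slot name character(1) label, e.g. "no_drug".
#' @slot overrides named numeric, parameter name -> fixed value (nM).
#' @exportClass Condition
setClass("Condition",
  representation(name = "character", overrides = "numeric"))

setValidity("Condition", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (length(object@overrides) &&
      (is.null(names(object@overrides)) || any(!nzchar(names(object@overrides)))))
    msg <- c(msg, "'overrides' must be a named numeric vector")
  if (any(!is.finite(object@overrides)))
    msg <- c(msg, "override values must be finite")
  if (length(msg)) msg else TRUE
})

#' A composite phospho-protein readout
#'
#' The readout y(t) is the sum of the contributing species, normalised by a
#' total-protein parameter, so y is the dimensionless fraction of the protein
#' pool in the measured (phosphorylated) forms.
#'
#' @slot name character(1) label, e.g. "pAkt".
#' @slot species character, non-empty set of contributing species names.
#' @slot normalizer character(1), name of the total-protein parameter (nM).
#' @exportClass Readout
setClass("Readout",
  representation(name = "character", species = "character",
                 normalizer = "character"))

setValidity("Readout", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  if (!length(object@species)) msg <- c(msg, "'species' must be non-empty")
  if (length(object@normalizer) != 1L)
    msg <- c(msg, "'normalizer' must be a single parameter name")
  if (length(msg)) msg else TRUE
})

#' A kinetic reaction-network model
#'
#' An autonomous ODE system in nM and minutes, defined by species, parameters,
#' and reactions with explicit rate-law expressions and stoichiometry.
#' Initial amounts may be given as numbers or as expressions over parameters
#' (e.g. a species initialised to a total-concentration parameter).
#'
#' @slot name character(1) model identifier.
#' @slot species data.frame with columns \code{name} (character) and
#'   \code{initial} (numeric, nM).
#' @slot initialExprs named list of unevaluated expressions giving initial
#'   amounts in terms of parameters; overrides \code{species$initial}.
#' @slot parameters named numeric of nominal parameter values.
#' @slot parameterUnits named character of unit strings (informational).
#' @slot reactions list; each element a list with \code{id} (character),
#'   \code{reactants}/\code{products} (named numeric stoichiometries) and
#'   \code{rate} (an R expression over species and parameter names).
#' @slot conserved named list of conserved pools; each element a list with
#'   \code{species} (character vector) and \code{total} (parameter name).
#' @slot conditions list of \linkS4class{Condition} bundled with the model.
#' @slot readouts list of \linkS4class{Readout} bundled with the model.
#' @exportClass KineticModel
setClass("KineticModel",
  representation(name = "character", species = "data.frame",
                 initialExprs = "list", parameters = "numeric",
                 parameterUnits = "character", reactions = "list",
                 conserved = "list", conditions = "list", readouts = "list"))

setValidity("KineticModel", function(object) {
  msg <- character()
  sp <- object@species
  if (!all(c("name", "initial") %in% names(sp)))
    msg <- c(msg, "species data.frame needs columns 'name' and 'initial'")
  else {
    if (anyDuplicated(sp$name)) msg <- c(msg, "duplicate species names")
    if (is.null(names(object@parameters)) && length(object@parameters))
      msg <- c(msg, "'parameters' must be named")
    if (anyDuplicated(names(object@parameters)))
      msg <- c(msg, "duplicate parameter names")
    both <- intersect(sp$name, names(object@parameters))
    if (length(both))
      msg <- c(msg, paste0("names used as both species and parameter: ",
                           paste(both, collapse = ", ")))
    known <- c(sp$name, names(object@parameters))
    for (rx in object@reactions) {
      if (!all(c("id", "reactants", "products", "rate") %in% names(rx))) {
        msg <- c(msg, "each reaction needs id, reactants, products, rate")
        break
      }
      bad <- setdiff(all.vars(rx$rate), known)
      if (length(bad))
        msg <- c(msg, paste0("reaction ", rx$id, " rate references unknown: ",
                             paste(bad, collapse = ", ")))
      badsp <- setdiff(c(names(rx$reactants), names(rx$products)), sp$name)
      if (length(badsp))
        msg <- c(msg, paste0("reaction ", rx$id, " uses unknown species: ",
                             paste(badsp, collapse = ", ")))
    }
    for (nm in names(object@conserved)) {
      pool <- object@conserved[[nm]]
      if (!all(pool$species %in% sp$name))
        msg <- c(msg, paste0("conserved pool ", nm, " lists unknown species"))
      if (!pool$total %in% names(object@parameters))
        msg <- c(msg, paste0("conserved pool ", nm, " total '", pool$total,
                             "' is not a parameter"))
    }
    badinit <- setdiff(names(object@initialExprs), sp$name)
    if (length(badinit))
      msg <- c(msg, paste0("initial expressions for unknown species: ",
                           paste(badinit, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Parameter-space definition for global sensitivity analysis
#'
#' An ordered table of model parameters with nominal value, sampling bounds,
#' within-range scale (log10 or linear) and a perturbable flag. Perturbable
#' entries define the axes of the GSA hypercube; the rest (fixed external
#' compounds such as ligand and inhibitor doses) keep their nominal or
#' condition-assigned values.
#'
#' @slot entries data.frame with columns name, nominal, lower, upper,
#'   scale ("log10" or "linear"), perturbable (logical).
#' @exportClass ParameterSpace
setClass("ParameterSpace", representation(entries = "data.frame"))

setValidity("ParameterSpace", function(object) {
  e <- object@entries
  need <- c("name", "nominal", "lower", "upper", "scale", "perturbable")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(e$name)) msg <- c(msg, "duplicate parameter names")
  if (!all(e$scale %in% c("log10", "linear")))
    msg <- c(msg, "scale must be 'log10' or 'linear'")
  p <- e[e$perturbable, , drop = FALSE]
  if (nrow(p)) {
    if (any(p$lower >= p$upper))
      msg <- c(msg, "perturbable entries need lower < upper")
    if (any(p$nominal < p$lower - 1e-12 | p$nominal > p$upper + 1e-12))
      msg <- c(msg, "perturbable nominal values must lie within bounds")
    if (any(p$scale == "log10" & p$lower <= 0))
      msg <- c(msg, "log10-scaled entries need positive lower bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Sobol sample of the parameter hypercube
#'
#' Pairs the raw unit-hypercube Sobol points with their scaled parameter
#' values. Columns correspond to the perturbable entries of the generating
#' \linkS4class{ParameterSpace}, rows to samples (ids 0-based to match the
#' position in the Sobol sequence after the skip).
#'
#' @slot unit numeric matrix N x k of points in [0, 1).
#' @slot scaled numeric matrix N x k of parameter values within bounds.
#' @slot space the generating \linkS4class{ParameterSpace}.
#' @slot skip integer(1), number of initial Sobol points dropped.
#' @exportClass SampleMatrix
setClass("SampleMatrix",
  representation(unit = "matrix", scaled = "matrix",
                 space = "ParameterSpace", skip = "integer"))

setValidity("SampleMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@unit), dim(object@scaled)))
    msg <- c(msg, "unit and scaled matrices must have identical shape")
  if (any(object@unit < 0 | object@unit >= 1))
    msg <- c(msg, "unit points must lie in [0, 1)")
  pn <- perturbableNames(object@space)
  if (!identical(colnames(object@scaled), pn))
    msg <- c(msg, "scaled columns must match perturbable parameters in order")
  if (length(msg)) msg else TRUE
})

#' Ensemble metric table
#'
#' One row per (sample, condition, readout) holding the area under the
#' normalised readout time course, S_y (minutes), its dimensionless
#' normalisation S_y,n = S_y / T, the solver status and the plausibility
#' accept flag. Metadata records the run configuration and failure /
#' rejection tallies.
#'
#' @slot records data.frame with columns sample_id, condition, readout,
#'   S_y, S_y_n, status, accept.
#' @slot metadata list with elements N, T, threshold, reference_condition,
#'   n_failed, n_rejected.
#' @exportClass MetricTable
setClass("MetricTable",
  representation(records = "data.frame", metadata = "list"))

setValidity("MetricTable", function(object) {
  r <- object@records
  need <- c("sample_id", "condition", "readout", "S_y", "S_y_n",
            "status", "accept")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(r[c("sample_id", "condition", "readout")]))
    msg <- c(msg, "duplicate (sample, condition, readout) keys")
  ok <- r$status == "ok"
  if (any(ok & (r$S_y_n < -1e-6 | r$S_y_n > 1 + 1e-6), na.rm = TRUE))
    msg <- c(msg, "successful records must have S_y_n in [0, 1] (tolerance 1e-6)")
  if (any(r$accept & !ok))
    msg <- c(msg, "accepted records must have solver status 'ok'")
  if (length(msg)) msg else TRUE
})

#' PRCC sensitivity profile for one condition and readout
#'
#' Per-parameter partial rank correlation coefficients of the normalised AUC
#' metric, with two-sided p-values from the t approximation. The regression
#' intermediates (coefficients and residual vectors of the two rank
#' regressions) are retained for audit.
#'
#' @slot table data.frame with columns parameter, prcc, p_value, significant,
#'   rank (importance rank by |PRCC|, 1 = most important).
#' @slot condition character(1).
#' @slot readout character(1).
#' @slot N integer(1), samples used.
#' @slot k integer(1), perturbable parameter count.
#' @slot alpha numeric(1), significance level used for the flag.
#' @slot audit list per parameter with elements a0, a, b0, b, resid_p, resid_s.
#' @exportClass PrccProfile
setClass("PrccProfile",
  representation(table = "data.frame", condition = "character",
                 readout = "character", N = "integer", k = "integer",
                 alpha = "numeric", audit = "list"))

setValidity("PrccProfile", function(object) {
  t <- object@table
  need <- c("parameter", "prcc", "p_value", "significant", "rank")
  if (!all(need %in% names(t)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (any(abs(t$prcc) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "PRCC values must lie in [-1, 1]")
  if (any(t$p_value < 0 | t$p_value > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Top-down coefficient of concordance between two rankings
#'
#' @slot coefficient numeric(1) in [-1, 1]; 1 for identical rankings.
#' @slot n integer(1), number of ranked items.
#' @slot rankA,rankB numeric, the two rankings compared (1 = top).
#' @exportClass TdccResult
setClass("TdccResult",
  representation(coefficient = "numeric", n = "integer",
                 rankA = "numeric", rankB = "numeric"))

#' Local sensitivity spectrum
#'
#' Normalised central-difference sensitivity coefficients of the AUC metric
#' with respect to each parameter at the nominal point.
#'
#' @slot table data.frame with columns parameter, coefficient, nominal.
#' @slot condition character(1).
#' @slot readout character(1).
#' @slot relStep numeric(1), relative perturbation dP/P.
#' @exportClass LsaSpectrum
setClass("LsaSpectrum",
  representation(table = "data.frame", condition = "character",
                 readout = "character", relStep = "numeric"))

#' Display-ordered sensitivity profile
#'
#' A \linkS4class{PrccProfile} re-ordered for interpretation: entries sorted
#' by signed PRCC descending (the "poles" of the spectrum), with importance
#' ranks by |PRCC|.
#'
#' @slot table data.frame with columns parameter, prcc, p_value, significant,
#'   rank.
#' @slot condition character(1).
#' @slot readout character(1).
#' @exportClass SensitivityProfile
setClass("SensitivityProfile",
  representation(table = "data.frame", condition = "character",
                 readout = "character"))

#' Paired no-drug / drug profile comparison
#'
#' @slot table data.frame with one row per parameter: prcc and p in each
#'   condition, delta_abs = |prcc_drug| - |prcc_no_drug|, rank shift
#'   (positive = more important under drug), and significance-crossing flags.
#' @slot conditionNoDrug,conditionDrug character(1) labels.
#' @slot readout character(1).
#' @exportClass ProfileComparison
setClass("ProfileComparison",
  representation(table = "data.frame", conditionNoDrug = "character",
                 conditionDrug = "character", readout = "character"))

#' Drug-target / biomarker classification calls
#'
#' @slot table data.frame with one row per parameter and logical columns for
#'   each category plus a collapsed 'categories' string.
#' @slot thresholds list with alpha, min_abs_prcc, delta_threshold.
#' @exportClass TargetCalls
setClass("TargetCalls",
  representation(table = "data.frame", thresholds = "list"))
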