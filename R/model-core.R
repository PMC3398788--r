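#' @include AllGenerics.R
NULL

#' Construct integration settings
#'
#' @param horizon integration horizon T in minutes. The default of 60 min is
#'   chosen to capture the transient phospho-protein response to ligand
#'   stimulation.
#' @param times output grid; defaults to 241 evenly spaced points on
#'   [0, horizon]. The grid is for time-course inspection and plotting only;
#'   AUC metrics are integrated jointly with the ODE system and do not depend
#'   on it.
#' @param rtol,atol relative / absolute solver tolerances. The defaults
#'   (1e-6, 1e-9 nM) are tight enough for the stiff ensembles produced by
#'   100-fold rate-constant sampling.
#' @return a \linkS4class{SimulationSettings} object.
#' @examples
#' SimulationSettings(horizon = 60)
#' @export
SimulationSettings <- function(horizon = 60,
                               times = seq(0, horizon, length.out = 241L),
                               rtol = 1e-6, atol = 1e-9) {
  new("SimulationSettings", horizon = as.numeric(horizon),
      times = as.numeric(times), rtol = rtol, atol = atol)
}

#' Construct a simulation condition
#'
#' @param name condition label.
#' @param overrides named numeric vector of parameter overrides
#'   (e.g. \code{c(HRG = 1, Per = 100)}).
#' @return a \linkS4class{Condition} object.
#' @examples
#' Condition("with_drug", c(HRG = 1, Per = 100))
#' @export
Condition <- function(name, overrides = numeric()) {
  new("Condition", name = name, overrides = overrides)
}

#' Construct a composite readout
#'
#' @param name readout label.
#' @param species character vector of contributing species.
#' @param normalizer name of the total-protein parameter dividing the sum.
#' @return a \linkS4class{Readout} object.
#' @examples
#' Readout("pAkt", species = "pAkt", normalizer = "Akt_tot")
#' @export
Readout <- function(name, species, normalizer) {
  new("Readout", name = name, species = species, normalizer = normalizer)
}

#' Construct a kinetic model
#'
#' @param name model identifier.
#' @param species data.frame with columns \code{name}, \code{initial} (nM).
#' @param parameters named numeric vector of nominal values.
#' @param reactions list of reactions; each a list with \code{id},
#'   \code{reactants}, \code{products} (named stoichiometries) and
#'   \code{rate} (an R expression, e.g. \code{quote(k1 * A)}).
#' @param initialExprs optional named list of expressions for initial amounts
#'   in terms of parameters (e.g. \code{list(Akt = quote(Akt_tot))}).
#' @param conserved optional named list of conserved pools, each a list with
#'   \code{species} and \code{total} (a parameter name).
#' @param parameterUnits optional named character of unit strings.
#' @param conditions,readouts optional lists of \linkS4class{Condition} /
#'   \linkS4class{Readout} objects bundled with the model.
#' @return a validated \linkS4class{KineticModel}.
#' @examples
#' m <- KineticModel("decay",
#'   species = data.frame(name = "A", initial = 1),
#'   parameters = c(k = 0.5),
#'   reactions = list(list(id = "r1", reactants = c(A = 1),
#'                         products = numeric(), rate = quote(k * A))))
#' speciesNames(m)
#' @export
KineticModel <- function(name, species, parameters, reactions,
                         initialExprs = list(), conserved = list(),
                         parameterUnits = character(), conditions = list(),
                         readouts = list()) {
  species$name <- as.character(species$name)
  new("KineticModel", name = name, species = species,
      initialExprs = initialExprs, parameters = parameters,
      parameterUnits = parameterUnits, reactions = reactions,
      conserved = conserved, conditions = conditions, readouts = readouts)
}

#' @describeIn KineticModel species names in state order
#' @param object a \linkS4class{KineticModel}.
#' @export
setMethod("speciesNames", "KineticModel",
          function(object) object@species$name)

#' @rdname parameterNames
#' @export
setMethod("parameterNames", "KineticModel",
          function(object) names(object@parameters))

#' @rdname nominalParameters
#' @export
setMethod("nominalParameters", "KineticModel",
          function(object) object@parameters)

#' @rdname modelConditions
#' @export
setMethod("modelConditions", "KineticModel", function(object) object@conditions)

#' @rdname modelReadouts
#' @export
setMethod("modelReadouts", "KineticModel", function(object) object@readouts)

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel '", object@name, "': ", nrow(object@species),
      " species, ", length(object@parameters), " parameters, ",
      length(object@reactions), " reactions\n", sep = "")
  if (length(object@conserved))
    cat("  conserved pools:", paste(names(object@conserved), collapse = ", "),
        "\n")
  if (length(object@conditions))
    cat("  conditions:",
        paste(vapply(object@conditions, function(x) x@name, ""),
              collapse = ", "), "\n")
  if (length(object@readouts))
    cat("  readouts:",
        paste(vapply(object@readouts, function(x) x@name, ""),
              collapse = ", "), "\n")
})

setMethod("show", "Condition", function(object) {
  cat("Condition '", object@name, "'", sep = "")
  if (length(object@overrides))
    cat(": ", paste(names(object@overrides), "=", object@overrides,
                    collapse = ", "), sep = "")
  cat("\n")
})

setMethod("show", "Readout", function(object) {
  cat("Readout '", object@name, "' = (",
      paste(object@species, collapse = " + "), ") / ", object@normalizer,
      "\n", sep = "")
})

# ---- right-hand-side compilation -------------------------------------------

#' Generate the ODE right-hand-side function of a model
#'
#' Emits (and byte-compiles) a deSolve-style derivative function as
#' straight-line code, with one optional auxiliary cumulative state per
#' readout so that AUC metrics are integrated jointly with the system.
#' Ensemble loops generate this once and pass it to
#' \code{\link{simulateModel}} via its \code{rhs} argument.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param readouts list of \linkS4class{Readout}s to augment with.
#' @return a function (t, state, parms) suitable for deSolve integrators.
#' @export
makeRhsFunction <- function(model, readouts = list()) {
  sp <- model@species$name
  nsp <- length(sp)
  rateExprs <- lapply(model@reactions, `[[`, "rate")
  used <- unique(unlist(lapply(rateExprs, all.vars)))
  usedPar <- intersect(names(model@parameters), used)
  normPars <- vapply(readouts, function(r) r@normalizer, "")
  usedPar <- union(usedPar, normPars)

  lines <- character()
  for (i in seq_along(sp))
    lines <- c(lines, sprintf("%s <- state[[%dL]]", sp[i], i))
  for (p in usedPar)
    lines <- c(lines, sprintf("%s <- parms[[\"%s\"]]", p, p))
  for (i in seq_along(rateExprs))
    lines <- c(lines, sprintf(".r%d <- %s", i,
                              paste(deparse(rateExprs[[i]]), collapse = " ")))
  # net derivative per species
  terms <- rep(list(character()), nsp)
  names(terms) <- sp
  for (i in seq_along(model@reactions)) {
    rx <- model@reactions[[i]]
    for (s in names(rx$reactants))
      terms[[s]] <- c(terms[[s]],
                      sprintf("- %g * .r%d", rx$reactants[[s]], i))
    for (s in names(rx$products))
      terms[[s]] <- c(terms[[s]],
                      sprintf("+ %g * .r%d", rx$products[[s]], i))
  }
  dnames <- paste0(".d_", sp)
  for (i in seq_along(sp)) {
    rhs <- if (length(terms[[i]])) paste(terms[[i]], collapse = " ") else "0"
    lines <- c(lines, sprintf("%s <- %s", dnames[i], rhs))
  }
  aucNames <- character()
  for (j in seq_along(readouts)) {
    r <- readouts[[j]]
    aucNames <- c(aucNames, sprintf(".d_auc%d", j))
    lines <- c(lines, sprintf(".d_auc%d <- (%s) / %s", j,
                              paste(r@species, collapse = " + "),
                              r@normalizer))
  }
  lines <- c(lines, sprintf("list(c(%s))",
                            paste(c(dnames, aucNames), collapse = ", ")))
  body <- paste(lines, collapse = "\n")
  f <- eval(parse(text = paste0("function(t, state, parms) {\n", body, "\n}")),
            envir = baseenv())
  compiler::cmpfun(f)
}

# Resolve the full parameter vector: nominal values overridden by an explicit
# assignment, then by condition overrides (which always win).
resolveParameters <- function(model, params = NULL, condition = NULL) {
  p <- model@parameters
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  if (!is.null(condition)) {
    bad <- setdiff(names(condition@overrides), names(p))
    if (length(bad))
      stop("condition overrides unknown parameter(s): ",
           paste(bad, collapse = ", "))
    p[names(condition@overrides)] <- condition@overrides
  }
  p
}

# Initial state with initial-assignment expressions evaluated over parameters.
resolveInitialState <- function(model, params) {
  y0 <- model@species$initial
  names(y0) <- model@species$name
  if (length(model@initialExprs)) {
    env <- as.list(params)
    for (s in names(model@initialExprs))
      y0[[s]] <- eval(model@initialExprs[[s]], env)
  }
  y0
}

#' Simulate a kinetic model
#'
#' Integrates the ODE system with a stiff solver (\code{deSolve::lsoda}) over
#' the output grid of \code{settings}. Solver failure never raises an error:
#' the returned trajectory carries a status attribute so that ensemble runs
#' over thousands of sampled parameter sets remain robust. A trajectory is
#' marked failed when the integrator does not complete, produces non-finite
#' values, or lets a species dip below \code{-100 * atol} (silent clamping
#' would bias AUC metrics, so negative excursions beyond solver noise are
#' treated as failures instead).
#'
#' @param model a \linkS4class{KineticModel}.
#' @param params optional named numeric of parameter values overriding the
#'   nominal ones (partial vectors allowed).
#' @param condition optional \linkS4class{Condition}; its overrides are
#'   applied last.
#' @param settings a \linkS4class{SimulationSettings}.
#' @param readouts optional list of \linkS4class{Readout}s; each adds an
#'   auxiliary cumulative state \code{auc_<name>} integrating the normalised
#'   readout jointly with the system.
#' @param rhs optional precompiled right-hand-side function from
#'   \code{makeRhsFunction(model, readouts)}; supplying it avoids
#'   regenerating the function on every call of an ensemble loop.
#' @return numeric matrix with a \code{time} column and one column per
#'   species (plus \code{auc_<name>} columns when readouts are given), with
#'   attributes \code{status} ("ok" or "failed:<reason>") and \code{params}
#'   (the resolved full parameter vector).
#' @examples
#' m <- makeAnalyticAucModel("exponential_relaxation")
#' tr <- simulateModel(m, settings = SimulationSettings(horizon = 1,
#'                                                      times = c(0, 1)))
#' tr[nrow(tr), "y"]   # ~ exp(-1)
#' @export
simulateModel <- function(model, params = NULL, condition = NULL,
                          settings = SimulationSettings(),
                          readouts = list(), rhs = NULL) {
  p <- resolveParameters(model, params, condition)
  statesp <- speciesNames(model)
  aucCols <- if (length(readouts))
    paste0("auc_", vapply(readouts, function(r) r@name, "")) else character()
  cols <- c("time", statesp, aucCols)
  failed <- function(reason) {
    out <- matrix(NA_real_, nrow = length(settings@times),
                  ncol = length(cols), dimnames = list(NULL, cols))
    out[, "time"] <- settings@times
    attr(out, "status") <- paste0("failed:", reason)
    attr(out, "params") <- p
    out
  }
  if (any(!is.finite(p))) return(failed("nonfinite_parameter"))
  for (r in readouts) {
    if (!all(r@species %in% statesp))
      stop("readout '", r@name, "' references unknown species: ",
           paste(setdiff(r@species, statesp), collapse = ", "))
    if (!r@normalizer %in% names(p))
      stop("readout normalizer '", r@normalizer, "' is not a parameter")
    if (!is.finite(p[[r@normalizer]]) || p[[r@normalizer]] <= 0)
      return(failed("bad_normalizer"))
  }
  y0 <- tryCatch(resolveInitialState(model, p), error = function(e) NULL)
  if (is.null(y0) || any(!is.finite(y0))) return(failed("bad_initial_state"))
  y0full <- c(y0, rep(0, length(readouts)))
  if (is.null(rhs)) rhs <- makeRhsFunction(model, readouts)
  d0 <- tryCatch(rhs(0, y0full, p), error = function(e) NULL)
  if (is.null(d0) || any(!is.finite(d0[[1L]]))) return(failed("nonfinite_rhs"))
  sol <- tryCatch(suppressWarnings(
    deSolve::lsoda(y = y0full, times = settings@times, func = rhs, parms = p,
                   rtol = settings@rtol, atol = settings@atol)),
    error = function(e) NULL)
  if (is.null(sol) || nrow(sol) < length(settings@times))
    return(failed("integration_incomplete"))
  m <- unclass(sol)
  attr(m, "istate") <- NULL
  attr(m, "rstate") <- NULL
  attr(m, "lengthvar") <- NULL
  attr(m, "type") <- NULL
  colnames(m) <- cols
  if (any(!is.finite(m))) {
    out <- failed("nonfinite_state")
    return(out)
  }
  if (min(m[, statesp]) < -100 * settings@atol)
    attr(m, "status") <- "failed:negative_state"
  else
    attr(m, "status") <- "ok"
  attr(m, "params") <- p
  m
}

#' Evaluate a composite readout on a trajectory
#'
#' Computes the normalised time course y(t) = sum(contributing species) /
#' normalizer, a dimensionless fraction of the total protein pool.
#'
#' @param trajectory matrix as returned by \code{\link{simulateModel}}.
#' @param readout a \linkS4class{Readout}.
#' @param params named numeric with the normalizer parameter; defaults to the
#'   \code{params} attribute of the trajectory.
#' @return data.frame with columns \code{time} (min) and \code{value}
#'   (dimensionless).
#' @examples
#' m <- makeReducedErbbModel()
#' tr <- simulateModel(m, condition = modelConditions(m)[["no_drug"]])
#' tc <- evaluateReadout(tr, modelReadouts(m)[["pAkt"]])
#' range(tc$value)
#' @export
evaluateReadout <- function(trajectory, readout,
                            params = attr(trajectory, "params")) {
  missing <- setdiff(readout@species, colnames(trajectory))
  if (length(missing))
    stop("trajectory lacks readout species: ", paste(missing, collapse = ", "))
  if (!readout@normalizer %in% names(params))
    stop("unknown normalizer parameter: ", readout@normalizer)
  norm <- params[[readout@normalizer]]
  if (!is.finite(norm) || norm <= 0)
    stop("normalizer '", readout@normalizer, "' must be positive")
  vals <- trajectory[, readout@species, drop = FALSE]
  data.frame(time = trajectory[, "time"],
             value = rowSums(vals) / norm)
}

#' Check declared conserved pools along a trajectory
#'
#' @param model a \linkS4class{KineticModel} with conserved pools declared.
#' @param trajectory matrix from \code{\link{simulateModel}}.
#' @param params resolved parameters (defaults to the trajectory attribute).
#' @return named numeric of maximum relative deviations of each pool sum from
#'   its declared total.
#' @export
conservationError <- function(model, trajectory,
                              params = attr(trajectory, "params")) {
  vapply(model@conserved, function(pool) {
    tot <- params[[pool$total]]
    sums <- rowSums(trajectory[, pool$species, drop = FALSE])
    max(abs(sums - tot)) / max(abs(tot), .Machine$double.eps)
  }, numeric(1))
}
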