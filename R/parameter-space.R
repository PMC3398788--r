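#' @include AllGenerics.R
NULL

#' Construct a parameter space from an entries table
#'
#' @param entries data.frame with columns name, nominal, lower, upper,
#'   scale ("log10"/"linear"), perturbable (logical).
#' @return a validated \linkS4class{ParameterSpace}.
#' @seealso \code{\link{buildParameterSpace}} for deriving a space from a
#'   model with the standard fold / concentration rules.
#' @export
ParameterSpace <- function(entries) {
  entries$name <- as.character(entries$name)
  entries$scale <- as.character(entries$scale)
  rownames(entries) <- NULL
  new("ParameterSpace", entries = entries)
}

#' @rdname perturbableNames
#' @export
setMethod("perturbableNames", "ParameterSpace", function(object)
  object@entries$name[object@entries$perturbable])

#' @rdname parameterNames
#' @export
setMethod("parameterNames", "ParameterSpace", function(object)
  object@entries$name)

#' @rdname nominalParameters
#' @export
setMethod("nominalParameters", "ParameterSpace", function(object) {
  out <- object@entries$nominal
  names(out) <- object@entries$name
  out
})

#' @rdname resultTable
#' @export
setMethod("resultTable", "ParameterSpace", function(object) object@entries)

setMethod("show", "ParameterSpace", function(object) {
  e <- object@entries
  cat("ParameterSpace: ", nrow(e), " parameters, ", sum(e$perturbable),
      " perturbable (", sum(e$scale == "log10" & e$perturbable),
      " log10-scaled)\n", sep = "")
})

#' Build the GSA hypercube for a model
#'
#' Applies the standard boundary rules: kinetic constants span one order of
#' magnitude above and below their nominal value (bounds
#' [nominal/fold, nominal*fold], default fold 10, giving an effective
#' 100-fold range), while total protein concentrations are varied within a
#' common absolute window (default 10--1000 nM, the range into which most
#' receptor-pathway protein abundance estimates fall). Parameters named in
#' \code{fixed_names} -- typically external compound doses such as ligand and
#' inhibitor concentrations, which the paired conditions control -- are
#' marked non-perturbable. Explicit per-parameter range overrides win over
#' both rules.
#'
#' Sampling within ranges is log-uniform for both rules (fold-symmetric
#' ranges are symmetric in log space; a linear-uniform rule would put 90% of
#' the mass in the upper decade).
#'
#' @param model a \linkS4class{KineticModel}.
#' @param kinetic_fold fold-range for kinetic constants (> 1, default 10).
#' @param conc_bounds length-2 numeric, absolute bounds in nM for
#'   concentration totals (default c(10, 1000)).
#' @param conc_names character vector naming the parameters treated as
#'   concentration totals; defaults to the totals of the model's conserved
#'   pools plus any parameter whose declared unit is "nM".
#' @param fixed_names parameters excluded from the hypercube.
#' @param range_overrides named list of length-2 numeric bounds that replace
#'   the rule-derived ones.
#' @return a \linkS4class{ParameterSpace} with one entry per model parameter
#'   in model order.
#' @examples
#' m <- makeReducedErbbModel()
#' sp <- buildParameterSpace(m, fixed_names = c("HRG", "Per"))
#' head(resultTable(sp))
#' @export
buildParameterSpace <- function(model, kinetic_fold = 10,
                                conc_bounds = c(10, 1000),
                                conc_names = NULL,
                                fixed_names = character(),
                                range_overrides = list()) {
  if (kinetic_fold <= 1) stop("'kinetic_fold' must be > 1")
  if (length(conc_bounds) != 2L || conc_bounds[1] <= 0 ||
      conc_bounds[1] >= conc_bounds[2])
    stop("'conc_bounds' must satisfy 0 < low < high")
  nominal <- model@parameters
  allNames <- names(nominal)
  bad <- setdiff(c(fixed_names, names(range_overrides)), allNames)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  if (is.null(conc_names)) {
    conc_names <- unique(c(
      vapply(model@conserved, `[[`, "", "total"),
      names(model@parameterUnits)[model@parameterUnits == "nM"]))
  }
  conc_names <- setdiff(conc_names, fixed_names)

  lower <- upper <- numeric(length(nominal))
  for (i in seq_along(nominal)) {
    nm <- allNames[i]
    if (nm %in% names(range_overrides)) {
      rng <- range_overrides[[nm]]
      lower[i] <- rng[1]; upper[i] <- rng[2]
    } else if (nm %in% conc_names) {
      lower[i] <- conc_bounds[1]; upper[i] <- conc_bounds[2]
    } else {
      if (nominal[i] <= 0 && !nm %in% fixed_names)
        stop("parameter '", nm, "' has nonpositive nominal value; ",
             "a fold-scaled range is undefined")
      lower[i] <- nominal[i] / kinetic_fold
      upper[i] <- nominal[i] * kinetic_fold
    }
  }
  perturbable <- !(allNames %in% fixed_names)
  # a nominal outside an overridden/absolute range cannot be perturbed
  # around; keep it inside by construction
  nomInside <- pmin(pmax(nominal, lower), upper)
  ParameterSpace(data.frame(
    name = allNames, nominal = unname(nomInside), lower = lower,
    upper = upper, scale = "log10", perturbable = perturbable,
    stringsAsFactors = FALSE))
}
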