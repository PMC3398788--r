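#' @include AllGenerics.R
NULL

#' Local sensitivity spectrum of the AUC metric
#'
#' Classical one-at-a-time local sensitivity analysis at the nominal point:
#' each parameter P_i is incremented and decremented by a fixed fraction of
#' its value (default 1%), and the normalised central-difference coefficient
#'
#'   C_i = [S(P_i + dP_i) - S(P_i - dP_i)] / S(P_i) * P_i / (2 dP_i)
#'
#' is reported, where S is the area under the readout time course and
#' dP_i = rel_step * P_i. C_i approximates the logarithmic gain
#' d log S / d log P_i, so coefficients are comparable across parameters of
#' different units and magnitudes. A spectrum is computed per condition, so
#' no-drug and drug spectra can be compared directly.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param readout a \linkS4class{Readout}.
#' @param params named numeric of nominal parameter values; defaults to the
#'   model's nominal vector.
#' @param condition optional \linkS4class{Condition}; overridden parameters
#'   are excluded from the spectrum.
#' @param parameters character vector of parameters to perturb; defaults to
#'   all parameters not overridden by the condition.
#' @param rel_step relative perturbation dP/P (default 0.01).
#' @param settings a \linkS4class{SimulationSettings}.
#' @return an \linkS4class{LsaSpectrum}; parameters absent from every rate
#'   law and initial assignment get a coefficient of exactly 0 without
#'   simulation.
#' @examples
#' m <- makeAnalyticAucModel("two_state")
#' resultTable(lsaSpectrum(m, modelReadouts(m)[[1]]))
#' @export
lsaSpectrum <- function(model, readout, params = NULL, condition = NULL,
                        parameters = NULL, rel_step = 0.01,
                        settings = SimulationSettings()) {
  p0 <- resolveParameters(model, params, condition)
  if (is.null(parameters)) {
    parameters <- names(p0)
    if (!is.null(condition))
      parameters <- setdiff(parameters, names(condition@overrides))
  }
  bad <- setdiff(parameters, names(p0))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  base <- aucMetric(model, readout, params = p0, settings = settings)
  if (base$status != "ok")
    stop("nominal simulation failed: ", base$status)
  if (!is.finite(base$S_y) || base$S_y == 0)
    stop("S(P) = 0 at the nominal point; the normalised coefficient is ",
         "undefined")
  # parameters that enter no rate law, initial assignment or the normalizer
  # cannot influence S; skip their four simulations
  usedVars <- unique(c(unlist(lapply(model@reactions,
                                     function(rx) all.vars(rx$rate))),
                       unlist(lapply(model@initialExprs, all.vars)),
                       readout@normalizer))
  coef <- numeric(length(parameters))
  names(coef) <- parameters
  for (nm in parameters) {
    if (!nm %in% usedVars || p0[[nm]] == 0) {
      coef[nm] <- 0
      next
    }
    dP <- rel_step * p0[[nm]]
    up <- p0; up[nm] <- p0[[nm]] + dP
    dn <- p0; dn[nm] <- p0[[nm]] - dP
    Su <- aucMetric(model, readout, params = up, settings = settings)
    Sd <- aucMetric(model, readout, params = dn, settings = settings)
    if (Su$status != "ok" || Sd$status != "ok") {
      coef[nm] <- NA_real_
      next
    }
    coef[nm] <- (Su$S_y - Sd$S_y) / base$S_y * p0[[nm]] / (2 * dP)
  }
  tab <- data.frame(parameter = parameters, coefficient = unname(coef),
                    nominal = unname(p0[parameters]),
                    stringsAsFactors = FALSE)
  new("LsaSpectrum", table = tab,
      condition = if (is.null(condition)) NA_character_ else condition@name,
      readout = readout@name, relStep = rel_step)
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "LsaSpectrum", function(object) object@table)

setMethod("show", "LsaSpectrum", function(object) {
  cat("LsaSpectrum (condition = ", object@condition, ", readout = ",
      object@readout, ", dP/P = ", object@relStep, ")\n", sep = "")
  tab <- object@table[order(-abs(object@table$coefficient)), ]
  print(utils::head(tab, 8), row.names = FALSE)
  if (nrow(tab) > 8) cat("  ... ", nrow(tab) - 8, " more\n", sep = "")
})
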