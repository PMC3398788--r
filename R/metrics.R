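#' @include AllGenerics.R
NULL

#' Area under a normalised readout time course
#'
#' Computes S_y = integral of y(t) over [0, T] by augmenting the ODE system
#' with an auxiliary cumulative state dS/dt = y(t) that is integrated jointly
#' with the model, so the accuracy of the integral tracks the solver
#' tolerances rather than the density of any output grid.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param readout a \linkS4class{Readout}.
#' @param params optional named parameter overrides.
#' @param condition optional \linkS4class{Condition}.
#' @param settings a \linkS4class{SimulationSettings}; the horizon T is the
#'   upper limit of integration.
#' @return list with elements \code{S_y} (minutes), \code{S_y_n}
#'   (dimensionless, S_y / T) and \code{status}.
#' @examples
#' m <- makeAnalyticAucModel("exponential_relaxation")
#' aucMetric(m, modelReadouts(m)[[1]],
#'           settings = SimulationSettings(horizon = 60))$S_y
#' # tau * (1 - exp(-60 / tau)) with the nominal tau = 10
#' @export
aucMetric <- function(model, readout, params = NULL, condition = NULL,
                      settings = SimulationSettings()) {
  # only the endpoints are needed; the auxiliary state carries the integral
  s2 <- new("SimulationSettings", horizon = settings@horizon,
            times = c(0, settings@horizon), rtol = settings@rtol,
            atol = settings@atol)
  tr <- simulateModel(model, params = params, condition = condition,
                      settings = s2, readouts = list(readout))
  status <- attr(tr, "status")
  S <- if (status == "ok") tr[nrow(tr), paste0("auc_", readout@name)]
       else NA_real_
  list(S_y = unname(S), S_y_n = unname(S) / settings@horizon, status = status)
}

#' Normalise an AUC metric by its theoretical maximum
#'
#' The theoretical maximum of S_y is T, attained when the whole protein pool
#' is phosphorylated in a sustained manner; S_y,n = S_y / T therefore lies in
#' [0, 1] and reads as the relative effectiveness of signal generation.
#'
#' @param S_y area under the normalised time course, minutes.
#' @param T_horizon integration horizon, minutes.
#' @return dimensionless S_y,n.
#' @export
normalizeMetric <- function(S_y, T_horizon) {
  if (any(T_horizon <= 0)) stop("'T_horizon' must be positive")
  S_y / T_horizon
}

#' Run the simulation ensemble over sampled parameter sets
#'
#' For every sampled parameter set and every condition, simulates the model
#' and records the AUC metric of each readout. Solver failures are flagged in
#' the record, never raised, so a single pathological parameter set cannot
#' abort an ensemble. The result is deterministic: identical inputs produce
#' an identical table.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param samples a \linkS4class{SampleMatrix}; its columns must not overlap
#'   any condition override.
#' @param conditions list of \linkS4class{Condition}s (typically a no-drug /
#'   drug pair).
#' @param readouts list of \linkS4class{Readout}s.
#' @param settings a \linkS4class{SimulationSettings}.
#' @param verbose log progress every 500 samples.
#' @return a \linkS4class{MetricTable} with accept flags initialised to the
#'   solver-success status (apply \code{\link{plausibilityFilter}} to impose
#'   the biological plausibility criterion).
#' @export
runEnsemble <- function(model, samples, conditions, readouts,
                        settings = SimulationSettings(), verbose = FALSE) {
  if (!length(conditions)) stop("'conditions' must be non-empty")
  if (!length(readouts)) stop("'readouts' must be non-empty")
  pn <- colnames(samples@scaled)
  bad <- setdiff(pn, names(model@parameters))
  if (length(bad))
    stop("sample columns are not model parameters: ",
         paste(bad, collapse = ", "))
  for (cond in conditions) {
    clash <- intersect(pn, names(cond@overrides))
    if (length(clash))
      stop("condition '", cond@name, "' overrides sampled parameter(s): ",
           paste(clash, collapse = ", "))
  }
  condNames <- vapply(conditions, function(x) x@name, "")
  roNames <- vapply(readouts, function(x) x@name, "")
  if (anyDuplicated(condNames)) stop("condition names must be unique")
  N <- nrow(samples@scaled)
  horizon <- settings@horizon
  s2 <- new("SimulationSettings", horizon = horizon, times = c(0, horizon),
            rtol = settings@rtol, atol = settings@atol)
  rhs <- makeRhsFunction(model, readouts)
  nrec <- N * length(conditions) * length(roNames)
  rec_sample <- integer(nrec); rec_cond <- character(nrec)
  rec_ro <- character(nrec); rec_S <- numeric(nrec)
  rec_status <- character(nrec)
  aucCols <- paste0("auc_", roNames)
  irec <- 0L
  for (i in seq_len(N)) {
    pi <- samples@scaled[i, ]
    for (ci in seq_along(conditions)) {
      tr <- simulateModel(model, params = pi, condition = conditions[[ci]],
                          settings = s2, readouts = readouts, rhs = rhs)
      status <- attr(tr, "status")
      Svals <- if (status == "ok") tr[nrow(tr), aucCols] else
        rep(NA_real_, length(aucCols))
      for (ri in seq_along(roNames)) {
        irec <- irec + 1L
        rec_sample[irec] <- i - 1L
        rec_cond[irec] <- condNames[ci]
        rec_ro[irec] <- roNames[ri]
        rec_S[irec] <- Svals[ri]
        rec_status[irec] <- status
      }
    }
    if (verbose && i %% 500L == 0L)
      message("ensemble: ", i, "/", N, " samples simulated")
  }
  records <- data.frame(sample_id = rec_sample, condition = rec_cond,
                        readout = rec_ro, S_y = rec_S,
                        S_y_n = rec_S / horizon, status = rec_status,
                        accept = rec_status == "ok",
                        stringsAsFactors = FALSE)
  nFailedSamples <- length(unique(records$sample_id[records$status != "ok"]))
  new("MetricTable", records = records,
      metadata = list(N = N, T = horizon, threshold = NA_real_,
                      reference_condition = NA_character_,
                      n_failed = nFailedSamples, n_rejected = NA_integer_))
}

#' @rdname metricRecords
#' @export
setMethod("metricRecords", "MetricTable", function(object) object@records)

setMethod("show", "MetricTable", function(object) {
  md <- object@metadata
  cat("MetricTable: ", nrow(object@records), " records (N = ", md$N,
      ", T = ", md$T, " min)\n", sep = "")
  cat("  solver failures: ", md$n_failed, " sample(s)\n", sep = "")
  if (!is.na(md$threshold))
    cat("  plausibility filter: S_y_n >= ", md$threshold, " on '",
        md$reference_condition, "'; rejected ", md$n_rejected,
        " sample(s)\n", sep = "")
})

#' Apply the biological plausibility filter
#'
#' A sampled parameter set is accepted when (i) its reference-condition
#' (no-drug) normalised metric reaches the threshold -- by default 0.01,
#' i.e. Akt phosphorylation exceeding 1% of the total Akt pool -- and (ii)
#' all of its condition runs succeeded. Acceptance is a per-sample property:
#' the drug-condition record of an accepted sample is always retained, and a
#' failed run in either condition drops the sample entirely (complete-case
#' rule).
#'
#' @param table a \linkS4class{MetricTable}.
#' @param threshold dimensionless acceptance threshold on S_y,n (default
#'   0.01).
#' @param reference_condition name of the condition the threshold is
#'   evaluated on (default the first condition present).
#' @param readout name of the readout the threshold is evaluated on (default
#'   the first readout present).
#' @return the table with updated accept flags and filter metadata.
#' @examples
#' # on a table with reference S_y_n of 0.005 / 0.02 / 0.5, the default
#' # threshold keeps the last two samples
#' @export
plausibilityFilter <- function(table, threshold = 0.01,
                               reference_condition = NULL, readout = NULL) {
  r <- table@records
  if (is.null(reference_condition)) reference_condition <- r$condition[1L]
  if (is.null(readout)) readout <- r$readout[1L]
  if (!reference_condition %in% r$condition)
    stop("unknown reference condition: ", reference_condition)
  ref <- r[r$condition == reference_condition & r$readout == readout, ]
  okBySample <- tapply(r$status == "ok", r$sample_id, all)
  passRef <- ref$S_y_n >= threshold & !is.na(ref$S_y_n)
  names(passRef) <- as.character(ref$sample_id)
  sampleKey <- as.character(r$sample_id)
  accept <- unname(passRef[sampleKey] & okBySample[sampleKey])
  accept[is.na(accept)] <- FALSE
  r$accept <- accept
  nRejected <- sum(!passRef & unname(okBySample[as.character(ref$sample_id)]),
                   na.rm = TRUE)
  md <- table@metadata
  md$threshold <- threshold
  md$reference_condition <- reference_condition
  md$n_rejected <- as.integer(nRejected)
  new("MetricTable", records = r, metadata = md)
}

#' Accepted sample ids of a metric table
#'
#' @param table a \linkS4class{MetricTable} (after
#'   \code{\link{plausibilityFilter}}).
#' @return integer vector of accepted sample ids (0-based).
#' @export
acceptedSamples <- function(table) {
  r <- table@records
  sort(unique(r$sample_id[r$accept]))
}

#' Write a metric table to TSV
#'
#' @param table a \linkS4class{MetricTable}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeMetricTable <- function(table, path) {
  utils::write.table(table@records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
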