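#' @include AllGenerics.R
NULL

#' Savage scores of a ranking
#'
#' The Savage score of rank r among n items is SS(r) = sum_{i=r}^{n} 1/i, so
#' rank 1 (most important) gets the largest score and differences between top
#' ranks are weighted more heavily than differences between bottom ranks.
#' Tied items share the mean of the Savage scores their positions span.
#'
#' @param ranks numeric vector of ranks (1 = top; average ties allowed).
#' @return numeric vector of Savage scores.
#' @examples
#' savageScores(1:3)   # 1/1 + 1/2 + 1/3, 1/2 + 1/3, 1/3
#' @export
savageScores <- function(ranks) {
  n <- length(ranks)
  if (any(!is.finite(ranks)) || any(ranks < 1 - 1e-9 | ranks > n + 1e-9))
    stop("'ranks' must be a valid ranking of its items")
  ss <- rev(cumsum(1 / rev(seq_len(n))))   # ss[r] for integer r
  out <- numeric(n)
  # a tie at average rank v with multiplicity m spans integer positions
  # v - (m-1)/2 .. v + (m-1)/2 and shares the mean of their scores
  for (v in unique(ranks)) {
    idx <- which(abs(ranks - v) < 1e-9)
    span <- seq.int(round(v - (length(idx) - 1) / 2),
                    length.out = length(idx))
    out[idx] <- mean(ss[span])
  }
  out
}

#' Top-down coefficient of concordance between two rankings
#'
#' Pearson correlation of the Savage-score vectors of two rankings of the
#' same items. The statistic is symmetric, equals 1 exactly when the
#' rankings are identical, and -- because Savage scores decay like 1/r --
#' is far more sensitive to disagreement among the top ranks than among the
#' bottom ones. It is used here to judge whether two consecutive sample
#' sizes produce concordant importance rankings, i.e. whether the sample is
#' large enough.
#'
#' @param rankA,rankB numeric rankings of the same items (1 = top).
#' @return a \linkS4class{TdccResult}.
#' @examples
#' tdcc(1:5, 1:5)@coefficient        # 1
#' tdcc(1:3, 3:1)@coefficient        # negative
#' @export
tdcc <- function(rankA, rankB) {
  if (length(rankA) != length(rankB))
    stop("rankings must have equal length")
  sa <- savageScores(rankA)
  sb <- savageScores(rankB)
  co <- stats::cor(sa, sb)
  new("TdccResult", coefficient = co, n = length(rankA),
      rankA = as.numeric(rankA), rankB = as.numeric(rankB))
}

setMethod("show", "TdccResult", function(object) {
  cat("TDCC = ", format(object@coefficient, digits = 6), " over ",
      object@n, " items\n", sep = "")
})

#' Sample-size adequacy scan via TDCC
#'
#' Runs the full pipeline (Sobol sampling, ensemble simulation, plausibility
#' filter, PRCC) at each sample size in \code{N_list}, ranks the parameters
#' by |PRCC| (importance), and reports the TDCC between each consecutive
#' pair of sample sizes. Because Sobol points are a deterministic sequence,
#' each larger run extends the smaller ones: the ensemble is simulated once
#' at max(N_list) and the smaller sample sizes reuse its prefixes.
#'
#' The scan saturating towards 1 indicates that adding samples no longer
#' changes which parameters are ranked most important, i.e. the sample size
#' is adequate.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param space a \linkS4class{ParameterSpace}.
#' @param conditions list of \linkS4class{Condition}s; the first is the
#'   reference (no-drug) condition for the filter.
#' @param readout a \linkS4class{Readout}.
#' @param N_list strictly increasing sample sizes. The default is the
#'   sequence used for full-scale signalling-network studies; desk-scale
#'   analyses of the bundled fixture use powers of two up to 4096.
#' @param settings a \linkS4class{SimulationSettings}.
#' @param threshold plausibility threshold (default 0.01).
#' @param condition name of the condition whose PRCC ranking is scanned
#'   (default the reference condition).
#' @param table optional precomputed \linkS4class{MetricTable} for
#'   max(N_list) samples (with matching \code{samples}); when supplied the
#'   ensemble step is skipped.
#' @param samples optional \linkS4class{SampleMatrix} matching \code{table}.
#' @param verbose log ensemble progress.
#' @return data.frame with columns N, N_prev, tdcc, n_accepted.
#' @export
sampleSizeScan <- function(model, space, conditions, readout,
                           N_list = c(5000, 10000, 30000, 40000, 50000,
                                      80000, 100000, 120000),
                           settings = SimulationSettings(),
                           threshold = 0.01, condition = NULL,
                           table = NULL, samples = NULL, verbose = FALSE) {
  if (any(diff(N_list) <= 0)) stop("'N_list' must be strictly increasing")
  Nmax <- max(N_list)
  if (is.null(samples)) samples <- sobolSample(space, Nmax)
  if (nrow(samples@scaled) < Nmax)
    stop("'samples' has fewer rows than max(N_list)")
  if (is.null(table)) {
    table <- runEnsemble(model, samples, conditions, list(readout),
                         settings = settings, verbose = verbose)
  }
  refName <- conditions[[1L]]@name
  if (is.null(condition)) condition <- refName
  rankings <- list()
  nAcc <- integer(length(N_list))
  for (i in seq_along(N_list)) {
    N <- N_list[i]
    sub <- new("MetricTable",
               records = table@records[table@records$sample_id < N, ],
               metadata = utils::modifyList(table@metadata, list(N = N)))
    sub <- plausibilityFilter(sub, threshold = threshold,
                              reference_condition = refName,
                              readout = readout@name)
    prof <- prccFromTable(sub, samples, condition, readout@name)
    rankings[[i]] <- prof@table$rank
    nAcc[i] <- length(acceptedSamples(sub))
  }
  out <- data.frame(N = N_list, N_prev = c(NA, N_list[-length(N_list)]),
                    tdcc = NA_real_, n_accepted = nAcc)
  for (i in seq_along(N_list)[-1L])
    out$tdcc[i] <- tdcc(rankings[[i - 1L]], rankings[[i]])@coefficient
  out
}
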