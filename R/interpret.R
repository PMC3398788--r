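#' @include AllGenerics.R
NULL

#' Build a display-ordered sensitivity profile
#'
#' Orders the parameters by signed PRCC descending, so the positive pole of
#' the spectrum (parameters whose higher values push the readout up --
#' candidate drug targets) sits at the top and the negative pole (parameters
#' acting as brakes on the signal) at the bottom. Importance ranks are by
#' |PRCC| descending. Ties preserve the input parameter order.
#'
#' @param profile a \linkS4class{PrccProfile}.
#' @return a \linkS4class{SensitivityProfile}.
#' @export
buildProfile <- function(profile) {
  tab <- profile@table
  ord <- order(-tab$prcc, seq_len(nrow(tab)))
  tab <- tab[ord, ]
  tab$rank <- rank(-abs(tab$prcc), ties.method = "average",
                   na.last = "keep")
  rownames(tab) <- NULL
  new("SensitivityProfile", table = tab, condition = profile@condition,
      readout = profile@readout)
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "SensitivityProfile", function(object) object@table)

setMethod("show", "SensitivityProfile", function(object) {
  cat("SensitivityProfile (condition = ", object@condition, ", readout = ",
      object@readout, "): ", nrow(object@table), " parameters\n", sep = "")
  print(utils::head(object@table, 8), row.names = FALSE)
})

#' Compare no-drug and drug sensitivity profiles
#'
#' Pairs the two profiles parameter-by-parameter and reports the change in
#' sensitivity magnitude (delta_abs = |PRCC_drug| - |PRCC_no_drug|), the
#' importance-rank shift (positive = more important under drug), and flags
#' for parameters crossing the significance threshold in either direction.
#' Parameters significant only under the drug have acquired sensitivity --
#' under an upstream-acting inhibitor these are typically receptor-level
#' parameters.
#'
#' @param no_drug,drug \linkS4class{SensitivityProfile}s over the same
#'   parameter universe and readout.
#' @return a \linkS4class{ProfileComparison}.
#' @export
compareProfiles <- function(no_drug, drug) {
  a <- no_drug@table; b <- drug@table
  if (!setequal(a$parameter, b$parameter))
    stop("profiles cover different parameter universes")
  if (!identical(no_drug@readout, drug@readout))
    stop("profiles are for different readouts")
  b <- b[match(a$parameter, b$parameter), ]
  tab <- data.frame(
    parameter = a$parameter,
    prcc_no_drug = a$prcc, p_no_drug = a$p_value,
    sig_no_drug = a$significant,
    prcc_drug = b$prcc, p_drug = b$p_value, sig_drug = b$significant,
    delta_abs = abs(b$prcc) - abs(a$prcc),
    rank_shift = a$rank - b$rank,
    gained_significance = !a$significant & b$significant,
    lost_significance = a$significant & !b$significant,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("ProfileComparison", table = tab, conditionNoDrug = no_drug@condition,
      conditionDrug = drug@condition, readout = no_drug@readout)
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "ProfileComparison", function(object) object@table)

setMethod("show", "ProfileComparison", function(object) {
  cat("ProfileComparison: '", object@conditionNoDrug, "' vs '",
      object@conditionDrug, "' (readout = ", object@readout, "), ",
      nrow(object@table), " parameters\n", sep = "")
  tab <- object@table[order(-abs(object@table$delta_abs)), ]
  print(utils::head(tab[c("parameter", "prcc_no_drug", "prcc_drug",
                          "delta_abs", "rank_shift")], 6), row.names = FALSE)
})

#' Classify parameters into target / biomarker categories
#'
#' Applies the interpretation rules for paired sensitivity profiles:
#' \itemize{
#'   \item \strong{drug_target}: significant positive PRCC in the no-drug
#'     profile -- lowering the parameter lowers the signal, so the protein is
#'     a candidate for direct inhibition;
#'   \item \strong{susceptibility_biomarker}: significant PRCC of either sign
#'     in the no-drug profile -- dysregulation in either direction marks
#'     elevated-signal risk (both poles of the spectrum);
#'   \item \strong{resistance_biomarker}: significant negative PRCC in the
#'     drug profile -- loss of the protein's activity raises the residual
#'     signal under treatment;
#'   \item \strong{combination_candidate}: significant positive PRCC in the
#'     drug profile -- the readout retains sensitivity to the parameter under
#'     treatment, so co-targeting it adds suppression;
#'   \item \strong{acquired_sensitivity}: |PRCC| increased by at least
#'     \code{delta_threshold} from no-drug to drug.
#' }
#' Significance requires both p < alpha and |PRCC| >= min_abs_prcc, making
#' every cutoff explicit configuration rather than visual judgement.
#'
#' @param comparison a \linkS4class{ProfileComparison}.
#' @param alpha significance level (default 0.05).
#' @param min_abs_prcc minimum coefficient magnitude (default 0.05).
#' @param delta_threshold minimum |PRCC| gain for the acquired-sensitivity
#'   flag (default 0.1).
#' @return a \linkS4class{TargetCalls}.
#' @export
classifyTargets <- function(comparison, alpha = 0.05, min_abs_prcc = 0.05,
                            delta_threshold = 0.1) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (min_abs_prcc <= 0 || min_abs_prcc >= 1)
    stop("'min_abs_prcc' must be in (0, 1)")
  tab <- comparison@table
  sigND <- !is.na(tab$p_no_drug) & tab$p_no_drug < alpha &
    abs(tab$prcc_no_drug) >= min_abs_prcc
  sigD <- !is.na(tab$p_drug) & tab$p_drug < alpha &
    abs(tab$prcc_drug) >= min_abs_prcc
  calls <- data.frame(
    parameter = tab$parameter,
    drug_target = sigND & tab$prcc_no_drug > 0,
    susceptibility_biomarker = sigND,
    resistance_biomarker = sigD & tab$prcc_drug < 0,
    combination_candidate = sigD & tab$prcc_drug > 0,
    acquired_sensitivity = !is.na(tab$delta_abs) &
      tab$delta_abs >= delta_threshold,
    stringsAsFactors = FALSE)
  cats <- c("drug_target", "susceptibility_biomarker",
            "resistance_biomarker", "combination_candidate",
            "acquired_sensitivity")
  calls$categories <- apply(calls[cats], 1, function(row)
    paste(cats[row], collapse = ","))
  new("TargetCalls", table = calls,
      thresholds = list(alpha = alpha, min_abs_prcc = min_abs_prcc,
                        delta_threshold = delta_threshold))
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "TargetCalls", function(object) object@table)

setMethod("show", "TargetCalls", function(object) {
  t <- object@table
  cat("TargetCalls (alpha = ", object@thresholds$alpha, ", |PRCC| >= ",
      object@thresholds$min_abs_prcc, ", delta >= ",
      object@thresholds$delta_threshold, ")\n", sep = "")
  for (ct in c("drug_target", "susceptibility_biomarker",
               "resistance_biomarker", "combination_candidate",
               "acquired_sensitivity"))
    cat("  ", ct, ": ", sum(t[[ct]]), "\n", sep = "")
})

#' Export sensitivity reports to TSV
#'
#' Writes (i) one profile TSV per condition, (ii) the paired comparison
#' table, (iii) the classification calls, and (iv) a heatmap-ready matrix of
#' the top_n parameters by maximum |PRCC| across conditions (rows ordered by
#' that maximum). Repeated invocation with the same inputs is byte-identical.
#'
#' @param profiles list of \linkS4class{SensitivityProfile}s.
#' @param comparison a \linkS4class{ProfileComparison}.
#' @param calls a \linkS4class{TargetCalls}.
#' @param dir output directory (created if missing).
#' @param top_n number of parameters in the heatmap matrix (default 40);
#'   capped at the parameter count.
#' @return invisibly, a character vector of the files written.
#' @export
exportReport <- function(profiles, comparison, calls, dir, top_n = 40L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                   format = "g"))
    df
  }
  writeTsv <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(fmt(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  files <- character()
  for (p in profiles)
    files <- c(files, writeTsv(p@table,
                               paste0("profile_", p@condition, ".tsv")))
  files <- c(files, writeTsv(comparison@table, "comparison.tsv"))
  files <- c(files, writeTsv(calls@table, "target_calls.tsv"))
  ctab <- comparison@table
  maxAbs <- pmax(abs(ctab$prcc_no_drug), abs(ctab$prcc_drug))
  ord <- order(-maxAbs, seq_len(nrow(ctab)))
  top <- utils::head(ord, min(top_n, nrow(ctab)))
  heat <- data.frame(parameter = ctab$parameter[top],
                     stringsAsFactors = FALSE)
  heat[[comparison@conditionNoDrug]] <- ctab$prcc_no_drug[top]
  heat[[comparison@conditionDrug]] <- ctab$prcc_drug[top]
  files <- c(files, writeTsv(heat, "heatmap_matrix.tsv"))
  invisible(files)
}
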