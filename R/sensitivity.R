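#' @include AllGenerics.R
NULL

#' Rank-transform a vector
#'
#' Ascending ranks with average ties, so that the rank sum is always
#' n(n+1)/2. Rank transformation makes the downstream correlation analysis
#' invariant to any strictly increasing transform of the inputs, reducing
#' the influence of nonlinearity on the sensitivity indices.
#'
#' @param values finite numeric vector.
#' @return numeric vector of ranks.
#' @examples
#' rankTransform(c(3, 1, 2))   # 3 1 2
#' rankTransform(c(1, 1, 2))   # 1.5 1.5 3
#' @export
rankTransform <- function(values) {
  if (any(!is.finite(values))) stop("'values' must be finite")
  rank(values, ties.method = "average")
}

# Residuals of y regressed (with intercept) on the columns of X, via QR.
# Returns the residual vector and the fitted coefficients for audit.
regressOut <- function(y, X) {
  D <- cbind(1, X)
  fit <- qr(D)
  if (fit$rank < ncol(D)) {
    keep <- fit$pivot[seq_len(fit$rank)]
    warning("rank-deficient regression design; dropping ",
            ncol(D) - fit$rank, " column(s)")
  }
  coefs <- qr.coef(fit, y)
  coefs[is.na(coefs)] <- 0
  list(residuals = y - D %*% coefs, coefficients = coefs)
}

#' Partial rank correlation coefficients
#'
#' For each parameter j, rank-transforms all parameter columns and the
#' metric, regresses the rank of parameter j on the ranks of all other
#' parameters and the rank of the metric on the same set, and returns the
#' Pearson correlation of the two residual vectors. The coefficient measures
#' the monotone association between parameter and output with the
#' (rank-linear) influence of every other parameter removed; its sign says
#' whether larger parameter values push the output up or down.
#'
#' @param X numeric matrix, one column per (perturbable) parameter; typically
#'   the accepted rows of a \linkS4class{SampleMatrix}'s scaled values.
#' @param y numeric vector of the metric (S_y,n), length nrow(X).
#' @param alpha significance level for the significance flag (default 0.05).
#' @param condition,readout labels stored in the result.
#' @param keepAudit retain regression coefficients and residual vectors.
#' @return a \linkS4class{PrccProfile}. Constant parameter columns get an NA
#'   coefficient with a warning.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(600), ncol = 3,
#'             dimnames = list(NULL, c("a", "b", "dummy")))
#' y <- X[, "a"] - 2 * X[, "b"]
#' resultTable(prccProfile(X, y))
#' @export
prccProfile <- function(X, y, alpha = 0.05, condition = NA_character_,
                        readout = NA_character_, keepAudit = FALSE) {
  X <- as.matrix(X)
  N <- nrow(X); k <- ncol(X)
  if (length(y) != N) stop("length(y) must equal nrow(X)")
  if (N < k + 3L) stop("need at least k + 3 samples for PRCC (N = ", N,
                       ", k = ", k, ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("p", seq_len(k))
  constant <- apply(X, 2, function(col) max(col) == min(col))
  if (any(constant))
    warning("constant parameter column(s): ",
            paste(colnames(X)[constant], collapse = ", "),
            "; their PRCC is undefined (NA)")
  R <- apply(X, 2, rankTransform)
  s_hat <- rankTransform(y)
  r <- rep(NA_real_, k)
  audit <- vector("list", k)
  names(audit) <- colnames(X)
  for (j in seq_len(k)) {
    if (constant[j]) next
    # constant columns carry no rank information and would only make the
    # regression designs deficient; they are excluded as predictors too
    others <- R[, setdiff(which(!constant), j), drop = FALSE]
    fp <- regressOut(R[, j], others)
    fs <- regressOut(s_hat, others)
    p_res <- fp$residuals
    s_res <- fs$residuals
    # Pearson correlation of the residuals, written out as the double-sum
    # quotient with the residual means removed
    p_bar <- mean(p_res); s_bar <- mean(s_res)
    num <- sum((p_res - p_bar) * (s_res - s_bar))
    den <- sqrt(sum((p_res - p_bar)^2) * sum((s_res - s_bar)^2))
    r[j] <- if (den > 0) num / den else NA_real_
    if (keepAudit)
      audit[[j]] <- list(a0 = fp$coefficients[1],
                         a = fp$coefficients[-1],
                         b0 = fs$coefficients[1],
                         b = fs$coefficients[-1],
                         resid_p = as.numeric(p_res),
                         resid_s = as.numeric(s_res))
  }
  p <- prccPvalue(r, N, k)
  tab <- data.frame(parameter = colnames(X), prcc = r, p_value = p,
                    significant = !is.na(p) & p < alpha,
                    rank = rank(-abs(r), ties.method = "average",
                                na.last = "keep"),
                    stringsAsFactors = FALSE)
  new("PrccProfile", table = tab, condition = condition, readout = readout,
      N = as.integer(N), k = as.integer(k), alpha = alpha,
      audit = if (keepAudit) audit else list())
}

#' Two-sided p-value of a PRCC coefficient
#'
#' t approximation for a partial correlation controlling k - 1 variables:
#' t = r * sqrt(df / (1 - r^2)) on df = N - 2 - (k - 1) degrees of freedom.
#'
#' @param r PRCC coefficient(s).
#' @param N number of samples.
#' @param k number of perturbable parameters (k - 1 of them controlled).
#' @return two-sided p-value(s) in [0, 1].
#' @export
prccPvalue <- function(r, N, k) {
  df <- N - 2L - (k - 1L)
  if (df <= 0L) stop("degrees of freedom <= 0 (N = ", N, ", k = ", k, ")")
  ifelse(is.na(r), NA_real_,
         ifelse(abs(r) >= 1, 0,
                2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)))
}

#' Significance of PRCC coefficients
#'
#' Two-sided p-values from the t approximation for a partial correlation
#' with k - 1 controlled variables: t = r * sqrt((N - 2 - (k - 1)) /
#' (1 - r^2)) on N - 2 - (k - 1) degrees of freedom.
#'
#' @param profile a \linkS4class{PrccProfile}.
#' @param alpha significance level for the flag (default 0.05).
#' @param adjust apply Benjamini-Hochberg correction across parameters
#'   before flagging (off by default).
#' @return the profile with recomputed p_value / significant columns.
#' @export
prccSignificance <- function(profile, alpha = profile@alpha,
                             adjust = FALSE) {
  tab <- profile@table
  tab$p_value <- prccPvalue(tab$prcc, profile@N, profile@k)
  pAdj <- if (adjust) stats::p.adjust(tab$p_value, method = "BH")
          else tab$p_value
  tab$significant <- !is.na(pAdj) & pAdj < alpha
  initialize(profile, table = tab, alpha = alpha)
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "PrccProfile", function(object) object@table)

setMethod("show", "PrccProfile", function(object) {
  cat("PrccProfile (condition = ", object@condition, ", readout = ",
      object@readout, "): N = ", object@N, ", k = ", object@k, "\n",
      sep = "")
  tab <- object@table[order(-abs(object@table$prcc)), ]
  print(utils::head(tab, 8), row.names = FALSE)
  if (nrow(tab) > 8) cat("  ... ", nrow(tab) - 8, " more\n", sep = "")
})

#' Quantitative monotonicity diagnostic
#'
#' The PRCC method presumes a monotone parameter-output relationship. This
#' check is a quantitative stand-in for visual scatterplot inspection: each
#' parameter's sampled values are cut into quantile bins, the mean rank of
#' the metric is computed per bin, and the parameter is flagged non-monotone
#' when the sequence of bin means shows both a significant rise and a
#' significant fall -- i.e. successive-bin differences of opposite signs
#' whose magnitude exceeds \code{z} standard errors.
#'
#' @param X numeric matrix of sampled parameter values.
#' @param y metric vector.
#' @param bins number of quantile bins (default 10); requires at least
#'   10 * bins samples.
#' @param z noise-band width in standard errors (default 3).
#' @return data.frame with columns parameter, monotone (logical), direction
#'   (+1 / -1 trend sign), max_up, max_down (largest standardised increments
#'   in each direction).
#' @export
monotonicityCheck <- function(X, y, bins = 10L, z = 3) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 10L * bins)
    stop("need at least ", 10L * bins, " samples for ", bins, " bins")
  if (is.null(colnames(X))) colnames(X) <- paste0("p", seq_len(ncol(X)))
  yr <- rankTransform(y)
  out <- lapply(seq_len(ncol(X)), function(j) {
    q <- stats::quantile(X[, j], probs = seq(0, 1, length.out = bins + 1L))
    grp <- cut(X[, j], breaks = unique(q), include.lowest = TRUE)
    m <- tapply(yr, grp, mean)
    se <- tapply(yr, grp, function(v) stats::sd(v) / sqrt(length(v)))
    d <- diff(m)
    sed <- sqrt(se[-length(se)]^2 + se[-1]^2)
    zscores <- d / sed
    up <- max(c(zscores, -Inf), na.rm = TRUE)
    down <- min(c(zscores, Inf), na.rm = TRUE)
    nonmono <- up > z && down < -z
    data.frame(parameter = colnames(X)[j], monotone = !nonmono,
               direction = sign(sum(d)), max_up = up, max_down = down,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' PRCC profile from a filtered metric table
#'
#' Convenience wrapper: extracts the accepted samples of one condition /
#' readout from a \linkS4class{MetricTable} and computes the PRCC profile
#' against the corresponding rows of the sample matrix.
#'
#' @param table a filtered \linkS4class{MetricTable}.
#' @param samples the \linkS4class{SampleMatrix} that generated the table.
#' @param condition condition name.
#' @param readout readout name (default the first present).
#' @param alpha significance level.
#' @param keepAudit see \code{\link{prccProfile}}.
#' @return a \linkS4class{PrccProfile}.
#' @export
prccFromTable <- function(table, samples, condition, readout = NULL,
                          alpha = 0.05, keepAudit = FALSE) {
  r <- table@records
  if (is.null(readout)) readout <- r$readout[1L]
  if (!condition %in% r$condition)
    stop("unknown condition: ", condition)
  sub <- r[r$condition == condition & r$readout == readout & r$accept, ]
  idx <- sub$sample_id + 1L
  prccProfile(samples@scaled[idx, , drop = FALSE], sub$S_y_n, alpha = alpha,
              condition = condition, readout = readout,
              keepAudit = keepAudit)
}
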