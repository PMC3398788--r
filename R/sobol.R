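#' @include AllClasses.R
NULL

# Package-local cache for the parsed direction-number table.
.sobolCache <- new.env(parent = emptyenv())

# Number of bits used for the integer Sobol states. 30 keeps every value
# within R's 32-bit signed integers (bitwXor operates on those).
.SOBOL_MAXBIT <- 30L

# Parse the bundled Joe-Kuo direction-number table: one row per dimension,
# columns dim, poly, m1..ms. Dimension 1 is the van der Corput sequence
# (all m_i = 1).
loadDirectionNumbers <- function() {
  if (!is.null(.sobolCache$directions)) return(.sobolCache$directions)
  path <- system.file("extdata", "joe-kuo-directions.tsv",
                      package = "SignalGSA", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  dirs <- lapply(rows, function(x) {
    v <- as.integer(x)
    list(poly = v[2L], m = v[-(1:2)])
  })
  .sobolCache$directions <- dirs
  dirs
}

# Direction integers v[1..maxbit] (scaled by 2^(maxbit - index)) for one
# dimension, from its primitive polynomial and initial m values.
directionIntegers <- function(dir, maxbit = .SOBOL_MAXBIT) {
  poly <- dir$poly
  if (poly <= 1L) {            # first dimension: m_i = 1 for all i
    return(bitwShiftL(1L, maxbit - seq_len(maxbit)))
  }
  s <- floor(log2(poly))
  a <- bitwAnd(bitwShiftR(poly, 1L), bitwShiftL(1L, s - 1L) - 1L)  # interior coefficients
  m <- dir$m[seq_len(s)]
  v <- integer(maxbit)
  for (i in seq_len(min(s, maxbit)))
    v[i] <- bitwShiftL(m[i], maxbit - i)
  if (maxbit > s) {
    for (i in (s + 1L):maxbit) {
      vi <- bitwXor(v[i - s], bitwShiftR(v[i - s], s))
      for (l in seq_len(s - 1L)) {
        if (bitwAnd(bitwShiftR(a, s - 1L - l), 1L) == 1L)
          vi <- bitwXor(vi, v[i - l])
      }
      v[i] <- vi
    }
  }
  v
}

#' Sobol low-discrepancy points in the unit hypercube
#'
#' Deterministic (unscrambled) Sobol sequence generated with the Gray-code
#' construction and Joe-Kuo direction numbers. Successive calls with the same
#' arguments return identical matrices, and all rows of a call are pairwise
#' distinct. By default the first point of the sequence (the all-zeros point)
#' is skipped so that no parameter sits exactly on its lower bound.
#'
#' Optional randomisation for uncertainty replicates is available as a random
#' digital (XOR) shift applied per dimension, which preserves the base-2 net
#' structure of the sequence; it is driven by \code{seed} and off by default
#' so that reproducibility requires no seed at all.
#'
#' @param k dimension (number of hypercube axes), at most the bundled
#'   direction-number table supports (128).
#' @param n number of points.
#' @param skip number of initial points of the sequence to drop (default 1,
#'   dropping the all-zeros point).
#' @param scramble logical; apply a random digital shift.
#' @param seed integer seed for the digital shift (required when
#'   \code{scramble = TRUE}).
#' @return numeric matrix n x k with values in [0, 1).
#' @examples
#' sobolUnitPoints(2, 4)          # first points after the zero point
#' sobolUnitPoints(1, 1)[1, 1]    # 0.5
#' @export
sobolUnitPoints <- function(k, n, skip = 1L, scramble = FALSE, seed = NULL) {
  k <- as.integer(k); n <- as.integer(n); skip <- as.integer(skip)
  if (k < 1L) stop("'k' must be >= 1")
  if (n < 1L) stop("'n' must be >= 1")
  if (skip < 0L) stop("'skip' must be >= 0")
  dirs <- loadDirectionNumbers()
  if (k > length(dirs))
    stop("dimension ", k, " exceeds the bundled direction-number table (",
         length(dirs), ")")
  maxbit <- .SOBOL_MAXBIT
  total <- n + skip
  if (total >= 2^maxbit) stop("too many points requested")
  V <- vapply(dirs[seq_len(k)], directionIntegers, integer(maxbit),
              maxbit = maxbit)                    # maxbit x k
  X <- matrix(0L, nrow = total, ncol = k)
  x <- integer(k)
  if (total > 1L) {
    for (i in seq_len(total - 1L)) {
      c <- 1L                                     # lowest zero bit of (i-1)
      val <- i - 1L
      while (bitwAnd(val, 1L) == 1L) {
        val <- bitwShiftR(val, 1L)
        c <- c + 1L
      }
      x <- bitwXor(x, V[c, ])
      X[i + 1L, ] <- x
    }
  }
  if (scramble) {
    if (is.null(seed)) stop("scrambling requires a 'seed'")
    shift <- withr_seed_sample(seed, k, maxbit)
    for (j in seq_len(k)) X[, j] <- bitwXor(X[, j], shift[j])
  }
  out <- X[(skip + 1L):total, , drop = FALSE] / 2^maxbit
  dimnames(out) <- NULL
  out
}

# Random 30-bit integers for the digital shift, drawn under a local RNG state
# so global reproducibility is unaffected.
withr_seed_sample <- function(seed, k, maxbit) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  as.integer(floor(runif(k) * 2^maxbit))
}

#' Scale unit-hypercube points to parameter values
#'
#' Maps each column of a unit-point matrix to the range of the corresponding
#' perturbable parameter: log10-scaled entries map u to
#' lower * (upper/lower)^u (uniform in log space, the natural choice for
#' fold-symmetric ranges), linear entries map u to lower + u * (upper -
#' lower). Non-perturbable parameters have no column; they are filled from
#' nominal and condition values at simulation time.
#'
#' @param unit numeric matrix of points in [0, 1), one column per
#'   perturbable parameter of \code{space}.
#' @param space a \linkS4class{ParameterSpace}.
#' @param skip the skip used when generating \code{unit} (stored for audit).
#' @return a \linkS4class{SampleMatrix}.
#' @examples
#' sp <- ParameterSpace(data.frame(
#'   name = "k1", nominal = 0.5, lower = 0.05, upper = 5,
#'   scale = "log10", perturbable = TRUE))
#' scalePoints(matrix(0.5, 1, 1), sp)   # geometric midpoint 0.5
#' @export
scalePoints <- function(unit, space, skip = 1L) {
  pn <- perturbableNames(space)
  if (ncol(unit) != length(pn))
    stop("unit matrix has ", ncol(unit), " columns but the space has ",
         length(pn), " perturbable parameters")
  e <- space@entries
  e <- e[e$perturbable, , drop = FALSE]
  scaled <- matrix(NA_real_, nrow = nrow(unit), ncol = ncol(unit),
                   dimnames = list(NULL, pn))
  for (j in seq_len(ncol(unit))) {
    u <- unit[, j]
    scaled[, j] <- if (e$scale[j] == "log10")
      e$lower[j] * (e$upper[j] / e$lower[j])^u
    else
      e$lower[j] + u * (e$upper[j] - e$lower[j])
  }
  new("SampleMatrix", unit = unit, scaled = scaled, space = space,
      skip = as.integer(skip))
}

#' Sample a parameter space with Sobol points
#'
#' Convenience wrapper combining \code{\link{sobolUnitPoints}} and
#' \code{\link{scalePoints}}.
#'
#' @param space a \linkS4class{ParameterSpace}.
#' @param n number of samples.
#' @param skip initial Sobol points to drop (default 1).
#' @param scramble,seed see \code{\link{sobolUnitPoints}}.
#' @return a \linkS4class{SampleMatrix}.
#' @export
sobolSample <- function(space, n, skip = 1L, scramble = FALSE, seed = NULL) {
  k <- length(perturbableNames(space))
  unit <- sobolUnitPoints(k, n, skip = skip, scramble = scramble, seed = seed)
  scalePoints(unit, space, skip = skip)
}

setMethod("show", "SampleMatrix", function(object) {
  cat("SampleMatrix: ", nrow(object@unit), " Sobol points x ",
      ncol(object@unit), " perturbable parameters (skip = ", object@skip,
      ")\n", sep = "")
})

#' Write a sample matrix to TSV
#'
#' Columns: sample_id (0-based position after the skip), then one column per
#' perturbable parameter with the scaled values.
#'
#' @param samples a \linkS4class{SampleMatrix}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSampleMatrix <- function(samples, path) {
  df <- data.frame(sample_id = seq_len(nrow(samples@scaled)) - 1L,
                   samples@scaled, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
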