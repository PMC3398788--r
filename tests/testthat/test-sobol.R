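test_that("the sequence matches reference direction-number values", {
  # frozen output of an independent Joe-Kuo direction-number generator
  expect_equal(sobolUnitPoints(1, 1)[1, 1], 0.5)
  expect_equal(sobolUnitPoints(1, 4, skip = 0)[, 1], c(0, 0.5, 0.75, 0.25))
  ref5 <- rbind(
    c(0.000, 0.000, 0.000, 0.000, 0.000),
    c(0.500, 0.500, 0.500, 0.500, 0.500),
    c(0.750, 0.250, 0.250, 0.250, 0.750),
    c(0.250, 0.750, 0.750, 0.750, 0.250),
    c(0.375, 0.375, 0.625, 0.875, 0.375),
    c(0.875, 0.875, 0.125, 0.375, 0.875),
    c(0.625, 0.125, 0.875, 0.625, 0.625),
    c(0.125, 0.625, 0.375, 0.125, 0.125))
  expect_equal(sobolUnitPoints(5, 8, skip = 0), ref5)
})

test_that("points are deterministic, distinct, and unique per coordinate", {
  expect_identical(sobolUnitPoints(7, 200), sobolUnitPoints(7, 200))
  P <- sobolUnitPoints(7, 512)
  expect_identical(anyDuplicated(P), 0L)
  # one-dimensional projections: N distinct values on every axis
  for (j in seq_len(ncol(P)))
    expect_length(unique(P[, j]), nrow(P))
})

test_that("a 1024-point block is a base-2 net on the half-cube", {
  P <- sobolUnitPoints(5, 1024, skip = 0)
  expect_identical(sum(apply(P < 0.5, 1, all)), 32L)
})

test_that("sub-box point fractions are proportional to volume", {
  set.seed(42)
  for (N in c(256L, 1024L, 4096L)) {
    P <- sobolUnitPoints(4, N)
    for (rep in 1:5) {
      lo <- runif(4, 0, 0.5)
      hi <- lo + runif(4, 0.2, 0.5)
      vol <- prod(hi - lo)
      inBox <- apply(t(P) > lo & t(P) < hi, 2, all)
      expect_lt(abs(mean(inBox) - vol), 3 * sqrt(vol * (1 - vol) / N))
    }
  }
})

test_that("dimension limit and argument errors are reported", {
  expect_error(sobolUnitPoints(129, 4), "exceeds")
  expect_error(sobolUnitPoints(0, 4), ">= 1")
  expect_error(sobolUnitPoints(2, 4, scramble = TRUE), "seed")
})

test_that("digital-shift scrambling is seed-deterministic and uniform", {
  A <- sobolUnitPoints(3, 256, scramble = TRUE, seed = 11L)
  B <- sobolUnitPoints(3, 256, scramble = TRUE, seed = 11L)
  C <- sobolUnitPoints(3, 256, scramble = TRUE, seed = 12L)
  expect_identical(A, B)
  expect_false(identical(A, C))
  expect_true(all(A >= 0 & A < 1))
})

test_that("scaling maps unit points to bounds on the declared scale", {
  sp <- ParameterSpace(data.frame(
    name = c("klog", "clin"), nominal = c(0.5, 55),
    lower = c(0.05, 10), upper = c(5, 100),
    scale = c("log10", "linear"), perturbable = TRUE))
  u <- matrix(c(0.5, 0, 0.999999, 0.5, 0, 0.999999), ncol = 2)
  sm <- scalePoints(u, sp)
  expect_equal(unname(sm@scaled[1, "klog"]), 0.5)        # geometric midpoint
  expect_equal(unname(sm@scaled[2, "klog"]), 0.05)       # lower bound exactly
  expect_lt(abs(sm@scaled[3, "klog"] - 5), 1e-4)         # approaches upper
  expect_equal(unname(sm@scaled[1, "clin"]), 55)
  expect_equal(unname(sm@scaled[2, "clin"]), 10)
  expect_error(scalePoints(matrix(0.5, 1, 3), sp), "perturbable")
})

test_that("sample matrices persist to TSV with ids and parameter columns", {
  sp <- ParameterSpace(data.frame(
    name = c("a", "b"), nominal = 1, lower = 0.1, upper = 10,
    scale = "log10", perturbable = TRUE))
  sm <- sobolSample(sp, 8)
  path <- tempfile(fileext = ".tsv")
  writeSampleMatrix(sm, path)
  back <- read.delim(path)
  expect_identical(names(back), c("sample_id", "a", "b"))
  expect_equal(back$a, unname(sm@scaled[, "a"]))
})
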