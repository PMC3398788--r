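test_that("rank transformation uses ascending average-tie ranks", {
  expect_equal(rankTransform(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rankTransform(c(1, 1, 2)), c(1.5, 1.5, 3))
  x <- runif(50) + 0.1
  expect_equal(rankTransform(log(x)), rankTransform(x))
  n <- 37
  expect_equal(sum(rankTransform(rnorm(n))), n * (n + 1) / 2)
  expect_error(rankTransform(c(1, NA)), "finite")
})

test_that("a perfectly monotone dependence gives PRCC 1", {
  set.seed(3)
  X <- matrix(runif(500 * 4), ncol = 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  y <- exp(3 * X[, 1])           # strictly increasing in p1 only
  tab <- resultTable(prccProfile(X, y))
  expect_equal(tab$prcc[1], 1, tolerance = 1e-9)
  expect_true(all(abs(tab$prcc[-1]) < 0.1))
})

test_that("residual regression agrees with the precision-matrix oracle", {
  set.seed(101)
  for (i in 1:5) {
    N <- 400; k <- 6
    X <- matrix(runif(N * k), ncol = k)
    y <- X %*% runif(k, -1, 1) + 0.3 * rnorm(N)
    got <- resultTable(prccProfile(X, as.numeric(y)))$prcc
    expect_lt(max(abs(got - prccPrecisionOracle(X, as.numeric(y)))), 1e-10)
  }
})

test_that("a strictly decreasing dependence yields a negative coefficient", {
  set.seed(5)
  X <- matrix(runif(300 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- -X[, "c"]^3 + 0.05 * rnorm(300)
  tab <- resultTable(prccProfile(X, y))
  expect_lt(tab$prcc[tab$parameter == "c"], 0)
})

test_that("PRCC is invariant to monotone transforms of a column", {
  set.seed(7)
  X <- matrix(runif(300 * 4) + 0.1, ncol = 4)
  y <- X[, 1] - X[, 2] + 0.2 * rnorm(300)
  base <- resultTable(prccProfile(X, y))$prcc
  X2 <- X; X2[, 1] <- log(X2[, 1]); X2[, 3] <- X2[, 3]^5
  trans <- resultTable(prccProfile(X2, y))$prcc
  expect_lt(max(abs(base - trans)), 1e-12)
})

test_that("all coefficients stay within [-1, 1]", {
  set.seed(11)
  for (i in 1:10) {
    X <- matrix(runif(60 * 5), ncol = 5)
    y <- rnorm(60)
    expect_true(all(abs(resultTable(prccProfile(X, y))$prcc) <= 1 + 1e-12))
  }
})

test_that("significance follows the partial-correlation t approximation", {
  expect_equal(prccPvalue(0, 1000, 5), 1)
  expect_lt(prccPvalue(0.999999, 1000, 5), 1e-100)
  # at very large N even |r| = 0.05 is overwhelmingly significant
  expect_lt(prccPvalue(0.05, 120000, 91), 0.05)
  expect_error(prccPvalue(0.5, 10, 20), "degrees of freedom")
  set.seed(2)
  X <- matrix(runif(200 * 3), ncol = 3)
  prof <- prccProfile(X, rnorm(200))
  reflag <- prccSignificance(prof, alpha = 1e-6)
  expect_true(all(!reflag@table$significant |
                    reflag@table$p_value < 1e-6))
})

test_that("an uninfluential dummy stays below the significance bound", {
  # scrambled-sampling replicates of a benchmark with one dummy coordinate
  hits <- 0L
  nrep <- 20L
  bench <- makeMonotoneBenchmark(4, c(1, -1, 1, 0))
  for (rep in seq_len(nrep)) {
    U <- sobolUnitPoints(4, 1024, scramble = TRUE, seed = 1000L + rep)
    y <- bench$fun(U)
    tab <- resultTable(prccProfile(U, y, alpha = 0.01))
    if (!tab$significant[4]) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.95)
})

test_that("constant columns are reported as undefined", {
  X <- cbind(a = runif(50), b = rep(1, 50), c = runif(50))
  expect_warning(prof <- prccProfile(X, rnorm(50)), "constant parameter")
  expect_true(is.na(resultTable(prof)$prcc[2]))
})

test_that("small samples are rejected", {
  X <- matrix(runif(5 * 3), ncol = 3)
  expect_error(prccProfile(X, rnorm(5)), "k \\+ 3")
})

test_that("the monotonicity diagnostic separates parabolas from cubics", {
  set.seed(13)
  X <- matrix(runif(2000 * 2), ncol = 2,
              dimnames = list(NULL, c("para", "cubic")))
  yPara <- -(X[, "para"] - 0.5)^2 + 0.01 * rnorm(2000)
  yCubic <- X[, "cubic"]^3 + 0.01 * rnorm(2000)
  expect_false(monotonicityCheck(X, yPara)$monotone[1])
  expect_true(monotonicityCheck(X, yCubic)$monotone[2])
  expect_error(monotonicityCheck(X[1:50, ], yPara[1:50]), "at least")
})

test_that("fixture pAkt AUC is monotone decreasing in total PTEN", {
  ens <- fixtureEnsemble(512L)
  r <- metricRecords(ens$table)
  sub <- r[r$condition == "no_drug" & r$accept, ]
  X <- ens$samples@scaled[sub$sample_id + 1L, , drop = FALSE]
  mono <- monotonicityCheck(X, sub$S_y_n, bins = 5)
  row <- mono[mono$parameter == "PTEN_tot", ]
  expect_true(row$monotone)
  expect_identical(row$direction, -1)
})
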