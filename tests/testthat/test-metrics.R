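test_that("jointly-integrated AUC matches closed forms", {
  m <- makeAnalyticAucModel("exponential_relaxation")
  ro <- modelReadouts(m)[[1]]
  s <- SimulationSettings(horizon = 60)
  for (tau in c(1, 10, 100)) {
    got <- aucMetric(m, ro, params = c(tau = tau), settings = s)
    expect_identical(got$status, "ok")
    expected <- analyticAuc("exponential_relaxation", c(tau = tau), 60)
    expect_lt(abs(got$S_y - expected) / expected, 1e-6)
  }
})

test_that("a constant saturated readout integrates to T and a silent one to 0", {
  m <- makeAnalyticAucModel("two_state")
  ro <- modelReadouts(m)[[1]]
  s <- SimulationSettings(horizon = 60)
  # k2 = 0 and fast activation: y -> 1 almost immediately, S ~ T
  full <- aucMetric(m, ro, params = c(k1 = 1e4, k2 = 0), settings = s)
  expect_equal(full$S_y, 60, tolerance = 1e-3)
  expect_equal(full$S_y_n, 1, tolerance = 1e-3)
  # k1 = 0: nothing activates, S = 0
  silent <- aucMetric(m, ro, params = c(k1 = 0), settings = s)
  expect_equal(silent$S_y, 0, tolerance = 1e-9)
})

test_that("AUC is additive over subintervals", {
  m <- makeAnalyticAucModel("exponential_relaxation")
  ro <- modelReadouts(m)[[1]]
  tight <- function(h) SimulationSettings(horizon = h, rtol = 1e-11,
                                          atol = 1e-13)
  S60 <- aucMetric(m, ro, settings = tight(60))$S_y
  S30 <- aucMetric(m, ro, settings = tight(30))$S_y
  # closed-form integral over [30, 60] at the nominal tau = 10
  tail <- 10 * (exp(-3) - exp(-6))
  expect_lt(abs((S60 - S30) - tail) / S60, 1e-8)
})

test_that("normalisation divides by the theoretical maximum", {
  expect_equal(normalizeMetric(60, 60), 1)
  expect_equal(normalizeMetric(0, 60), 0)
  expect_error(normalizeMetric(1, 0), "positive")
})

test_that("ensemble tables have one record per sample-condition pair", {
  m <- makeReducedErbbModel()
  sp <- reducedErbbSpace()
  sam <- sobolSample(sp, 2)
  mt <- runEnsemble(m, sam, modelConditions(m), modelReadouts(m))
  expect_identical(nrow(metricRecords(mt)), 4L)
  expect_identical(anyDuplicated(metricRecords(mt)[
    c("sample_id", "condition", "readout")]), 0L)
})

test_that("pathological samples are flagged failed, not raised", {
  m <- makeReducedErbbModel()
  sp <- reducedErbbSpace()
  sam <- sobolSample(sp, 2)
  sam@scaled[2, "kcat6"] <- NaN
  mt <- runEnsemble(m, sam, modelConditions(m), modelReadouts(m))
  r <- metricRecords(mt)
  expect_true(all(r$status[r$sample_id == 1] != "ok"))
  expect_true(all(r$status[r$sample_id == 0] == "ok"))
  expect_identical(mt@metadata$n_failed, 1L)
})

test_that("repeated ensemble runs are identical", {
  m <- makeReducedErbbModel()
  sam <- sobolSample(reducedErbbSpace(), 4)
  mt1 <- runEnsemble(m, sam, modelConditions(m), modelReadouts(m))
  mt2 <- runEnsemble(m, sam, modelConditions(m), modelReadouts(m))
  expect_identical(metricRecords(mt1), metricRecords(mt2))
})

test_that("ensembles reject configuration mismatches", {
  m <- makeReducedErbbModel()
  sam <- sobolSample(reducedErbbSpace(), 2)
  expect_error(
    runEnsemble(m, sam, list(Condition("bad", c(kcat6 = 1))),
                modelReadouts(m)),
    "overrides sampled parameter")
})

# a hand-built table for filter behaviour, mirroring a 3-sample ensemble
makeToyTable <- function(ref_syn = c(0.005, 0.02, 0.5),
                         drug_status = rep("ok", 3)) {
  rec <- rbind(
    data.frame(sample_id = 0:2, condition = "no_drug", readout = "y",
               S_y = ref_syn * 60, S_y_n = ref_syn, status = "ok",
               accept = TRUE),
    data.frame(sample_id = 0:2, condition = "with_drug", readout = "y",
               S_y = ifelse(drug_status == "ok", 0.1 * 60, NA),
               S_y_n = ifelse(drug_status == "ok", 0.1, NA),
               status = drug_status, accept = drug_status == "ok"))
  new("MetricTable", records = rec,
      metadata = list(N = 3L, T = 60, threshold = NA_real_,
                      reference_condition = NA_character_,
                      n_failed = sum(drug_status != "ok"),
                      n_rejected = NA_integer_))
}

test_that("the plausibility filter keeps samples above threshold", {
  mt <- plausibilityFilter(makeToyTable(), threshold = 0.01,
                           reference_condition = "no_drug")
  expect_identical(acceptedSamples(mt), c(1L, 2L))
  expect_identical(mt@metadata$n_rejected, 1L)
  # acceptance applies to both condition records of a sample
  r <- metricRecords(mt)
  expect_true(all(r$accept[r$sample_id %in% c(1, 2)]))
  expect_false(any(r$accept[r$sample_id == 0]))
})

test_that("filtering is monotone in the threshold and never adds records", {
  base <- makeToyTable()
  n0 <- nrow(metricRecords(base))
  acc <- lapply(c(0, 0.01, 0.1, 0.6), function(th) {
    mt <- plausibilityFilter(base, threshold = th,
                             reference_condition = "no_drug")
    expect_identical(nrow(metricRecords(mt)), n0)
    acceptedSamples(mt)
  })
  expect_identical(acc[[1]], 0:2)   # threshold 0 accepts all successful
  for (i in seq_along(acc)[-1])
    expect_true(all(acc[[i]] %in% acc[[i - 1]]))
})

test_that("a failed drug-condition run drops the sample (complete case)", {
  mt <- plausibilityFilter(
    makeToyTable(drug_status = c("failed:blowup", "ok", "ok")),
    threshold = 0.01, reference_condition = "no_drug")
  expect_identical(acceptedSamples(mt), c(1L, 2L))
  mt2 <- plausibilityFilter(
    makeToyTable(drug_status = c("ok", "failed:blowup", "ok")),
    threshold = 0.01, reference_condition = "no_drug")
  expect_identical(acceptedSamples(mt2), 2L)
})

test_that("unknown reference conditions are rejected", {
  expect_error(plausibilityFilter(makeToyTable(),
                                  reference_condition = "nope"),
               "unknown reference condition")
})
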