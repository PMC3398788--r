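# a PrccProfile built directly from coefficients, for rule-level tests
toyProfile <- function(prcc, p = NULL, condition = "c", alpha = 0.05,
                       names = paste0("param", seq_along(prcc))) {
  if (is.null(p)) p <- ifelse(abs(prcc) >= 0.3, 1e-6, 0.5)
  tab <- data.frame(parameter = names, prcc = prcc, p_value = p,
                    significant = p < alpha,
                    rank = rank(-abs(prcc), ties.method = "average"),
                    stringsAsFactors = FALSE)
  new("PrccProfile", table = tab, condition = condition, readout = "y",
      N = 1000L, k = length(prcc), alpha = alpha, audit = list())
}

test_that("profiles sort by signed PRCC with |PRCC| importance ranks", {
  prof <- buildProfile(toyProfile(c(0.9, -0.4, 0.1)))
  expect_identical(resultTable(prof)$parameter,
                   c("param1", "param3", "param2"))
  expect_equal(resultTable(prof)$rank, c(1, 3, 2))
})

test_that("ties preserve the input parameter order", {
  prof <- buildProfile(toyProfile(c(0, 0, 0)))
  expect_identical(resultTable(prof)$parameter,
                   c("param1", "param2", "param3"))
})

test_that("identical profiles compare with zero deltas and no flags", {
  a <- buildProfile(toyProfile(c(0.5, -0.2, 0.1), condition = "no_drug"))
  b <- buildProfile(toyProfile(c(0.5, -0.2, 0.1), condition = "drug"))
  cmp <- resultTable(compareProfiles(a, b))
  expect_true(all(cmp$delta_abs == 0))
  expect_true(all(cmp$rank_shift == 0))
  expect_false(any(cmp$gained_significance | cmp$lost_significance))
})

test_that("profiles over different universes are rejected", {
  a <- buildProfile(toyProfile(c(0.5, -0.2)))
  b <- buildProfile(toyProfile(c(0.5, -0.2, 0.1)))
  expect_error(compareProfiles(a, b), "universe")
})

test_that("classification applies the stated rules", {
  # A: strong positive in both conditions; B: negative only under drug;
  # C: insignificant everywhere
  nd <- buildProfile(toyProfile(c(A = 0.8, B = 0.01, C = 0.02),
                                names = c("A", "B", "C"),
                                condition = "no_drug"))
  wd <- buildProfile(toyProfile(c(A = 0.8, B = -0.6, C = 0.02),
                                names = c("A", "B", "C"),
                                condition = "with_drug"))
  calls <- resultTable(classifyTargets(compareProfiles(nd, wd),
                                       alpha = 0.05, min_abs_prcc = 0.05,
                                       delta_threshold = 0.1))
  rownames(calls) <- calls$parameter
  expect_identical(calls["A", "categories"],
                   "drug_target,susceptibility_biomarker,combination_candidate")
  expect_identical(calls["B", "categories"],
                   "resistance_biomarker,acquired_sensitivity")
  expect_identical(calls["C", "categories"], "")
})

test_that("classification is a pure function of the comparison table", {
  nd <- buildProfile(toyProfile(c(0.6, -0.5, 0.02), condition = "no_drug"))
  wd <- buildProfile(toyProfile(c(0.2, -0.7, 0.4), condition = "with_drug"))
  cmp <- compareProfiles(nd, wd)
  c1 <- classifyTargets(cmp, alpha = 0.01)
  # round-trip the comparison through serialisation
  tmp <- tempfile(fileext = ".tsv")
  write.table(resultTable(cmp), tmp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read.delim(tmp)
  cmp2 <- new("ProfileComparison", table = back,
              conditionNoDrug = "no_drug", conditionDrug = "with_drug",
              readout = "y")
  c2 <- classifyTargets(cmp2, alpha = 0.01)
  expect_equal(resultTable(c1), resultTable(c2))
})

test_that("reports are complete, capped and byte-identical on rerun", {
  k <- 50L
  set.seed(17)
  prcc1 <- runif(k, -1, 1); prcc2 <- runif(k, -1, 1)
  nd <- buildProfile(toyProfile(prcc1, condition = "no_drug",
                                names = paste0("P", 1:k)))
  wd <- buildProfile(toyProfile(prcc2, condition = "with_drug",
                                names = paste0("P", 1:k)))
  cmp <- compareProfiles(nd, wd)
  calls <- classifyTargets(cmp)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- exportReport(list(nd, wd), cmp, calls, d1)
  f2 <- exportReport(list(nd, wd), cmp, calls, d2)
  expect_setequal(basename(f1),
                  c("profile_no_drug.tsv", "profile_with_drug.tsv",
                    "comparison.tsv", "target_calls.tsv",
                    "heatmap_matrix.tsv"))
  heat <- read.delim(file.path(d1, "heatmap_matrix.tsv"))
  expect_identical(nrow(heat), 40L)             # default top_n
  for (f in basename(f1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # top_n beyond the parameter count returns everything, unpadded
  d3 <- tempfile()
  exportReport(list(nd, wd), cmp, calls, d3, top_n = 500)
  expect_identical(nrow(read.delim(file.path(d3, "heatmap_matrix.tsv"))),
                   k)
})
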