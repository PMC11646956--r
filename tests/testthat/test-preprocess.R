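## A tiny table with explicit QC columns for the filter boundary checks.
qcBoundaryTable <- function(qc_values, n_qc = length(qc_values)) {
  ## one feature, 4 samples + n_qc QCs
  m <- matrix(c(rep(1000, 4), qc_values), nrow = 1,
              dimnames = list("f1", NULL))
  colnames(m) <- sprintf("I%02d", seq_len(ncol(m)))
  makeTable(m, c(rep("sample", 4), rep("QC", n_qc)))
}

test_that("QC presence filter uses an inclusive 10% boundary", {
  cfg <- filterConfig()
  ## detected in 1 of 20 QCs (5%): removed
  one <- qcBoundaryTable(c(1000, rep(NA, 19)))
  expect_identical(qcPresenceFilter(one, cfg)$removed, "f1")
  ## detected in exactly 2 of 20 QCs (10%, "at least"): kept
  two <- qcBoundaryTable(c(1000, 1000, rep(NA, 18)))
  expect_identical(qcPresenceFilter(two, cfg)$removed, character())
  ## detected in all QCs: kept
  all_ <- qcBoundaryTable(rep(1000, 20))
  expect_identical(qcPresenceFilter(all_, cfg)$removed, character())
  ## no QC rows at all: error
  no_qc <- makeTable(matrix(1:4, 1, dimnames = list("f1", NULL)),
                     rep("sample", 4))
  expect_error(qcPresenceFilter(no_qc, cfg), "no QC injections")
})

test_that("QC RSD filter is strict at the 40% boundary", {
  cfg <- filterConfig()
  expect_identical(qcRsdFilter(qcBoundaryTable(c(100, 100, 100)), cfg)$removed,
                   character())                       # RSD 0%
  fifty <- qcBoundaryTable(c(50, 150))
  expect_equal(unname(qcRsd(fifty)), 100 * sd(c(50, 150)) / 100) # 70.71%
  expect_identical(qcRsdFilter(fifty, cfg)$removed, "f1")
  ## RSD exactly 40% (values 60/100/140: mean 100, sample SD exactly 40)
  exact <- qcBoundaryTable(c(60, 100, 140))
  expect_equal(unname(qcRsd(exact)), 40)
  expect_identical(qcRsdFilter(exact, cfg)$removed, "f1")  # strict "<"
  ## single QC value: insufficient support
  single <- qcBoundaryTable(c(1000, NA, NA))
  res <- qcRsdFilter(single, cfg)
  expect_identical(res$removed, "f1")
  expect_match(res$reasons[["f1"]], "insufficient QC support")
})

test_that("blank ratio filter boundary is inclusive and NA blanks keep", {
  cfg <- filterConfig()
  mk <- function(sample_mean, blank_vals) {
    m <- matrix(c(rep(sample_mean, 4), 1000, 1000, blank_vals), nrow = 1,
                dimnames = list("f1", NULL))
    colnames(m) <- sprintf("I%02d", seq_len(ncol(m)))
    makeTable(m, c(rep("sample", 4), "QC", "QC",
                   rep("blank", length(blank_vals))))
  }
  expect_identical(blankRatioFilter(mk(1000, c(400, 400)), cfg)$removed,
                   "f1")                               # ratio 2.5 < 3
  expect_identical(blankRatioFilter(mk(900, c(300, 300)), cfg)$removed,
                   character())                        # ratio 3.0, inclusive
  expect_identical(blankRatioFilter(mk(1000, c(NA, NA)), cfg)$removed,
                   character())                        # no blank signal
  no_blank <- qcBoundaryTable(c(1000, 1000))
  expect_warning(res <- blankRatioFilter(no_blank, cfg), "skipped")
  expect_identical(res$removed, character())
})

test_that("drift correction recovers a noiseless linear trend exactly", {
  tab <- linearDriftFixture()
  res <- driftCorrect(tab, span = 1)
  rsd_after <- qcRsd(res$table)
  expect_true(all(rsd_after < 1e-6))
  expect_length(res$model$flagged, 0L)
  ## sample count and feature count unchanged
  expect_equal(dim(res$table), dim(tab))
})

test_that("drift correction without drift is a per-batch rescaling", {
  fx <- smallSimFixture()
  ps <- synthPreset("small")
  run <- runSpec(n_features = 20L, n_batches = 2L, qc_interval = 5L,
                 drift_amplitude = 0, noise_cv = 0, missing_rate = 0)
  tab <- simulatePeakTable(fx$cohort[1:40, ], run, seed = 4L)$table
  out <- driftCorrect(tab)$table
  ratio <- intensities(out) / intensities(tab)
  for (b in unique(sampleData(tab)$batch)) {
    rb <- ratio[, sampleData(tab)$batch == b]
    expect_equal(max(abs(rb - rb[, 1L])), 0, tolerance = 1e-10)
  }
})

test_that("drift correction reduces QC RSD on the noisy preset", {
  fx <- smallSimFixture()
  before <- qcRsd(fx$sim$table)
  after <- qcRsd(driftCorrect(fx$sim$table)$table)
  expect_lt(median(after, na.rm = TRUE), median(before, na.rm = TRUE))
})

test_that("median-ratio fallback engages when a batch has few QCs", {
  m <- matrix(rep(c(100, 200, 300, 150, 250), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), sprintf("I%d", 1:5)))
  tab <- makeTable(m, c("QC", "sample", "sample", "QC", "sample"))
  expect_warning(res <- driftCorrect(tab), "median-ratio")
  expect_equal(dim(res$table), dim(tab))
  expect_equal(res$model$fallback_batches, 1L)
})

test_that("spline imputation interpolates and respects boundaries", {
  ## collinear points: natural spline reduces to the line
  m <- matrix(c(1, 2, NA, 4, 5), nrow = 1, dimnames = list("f1", NULL))
  colnames(m) <- sprintf("I%d", 1:5)
  tab <- makeTable(m, rep("sample", 5))
  out <- imputeMissing(tab)
  expect_equal(unname(intensities(out)["f1", 3L]), 3.0)

  ## no missing cells: identity
  full <- makeTable(matrix(1:10, 2, dimnames = list(NULL, NULL)),
                    rep("sample", 5))
  expect_equal(intensities(imputeMissing(full)), intensities(full))

  ## missing before the first observation: nearest observed value
  m2 <- matrix(c(NA, 2, 3, 4, 5), nrow = 1, dimnames = list("f1", NULL))
  colnames(m2) <- sprintf("I%d", 1:5)
  out2 <- imputeMissing(makeTable(m2, rep("sample", 5)))
  expect_equal(unname(intensities(out2)["f1", 1L]), 2)

  ## < 4 observed values: feature-median fallback
  m3 <- matrix(c(10, NA, 30, NA, NA), nrow = 1, dimnames = list("f1", NULL))
  colnames(m3) <- sprintf("I%d", 1:5)
  out3 <- imputeMissing(makeTable(m3, rep("sample", 5)))
  expect_equal(unname(intensities(out3)["f1", 2L]), 20)
})

test_that("log10 transform substitutes half-minimum for zeros", {
  m <- matrix(c(1, 1000, 0, 10), nrow = 1, dimnames = list("f1", NULL))
  colnames(m) <- sprintf("I%d", 1:4)
  tab <- makeTable(m, rep("sample", 4))
  out <- log10Transform(tab)
  v <- intensities(out)["f1", ]
  expect_equal(unname(v[1L]), 0)
  expect_equal(unname(v[2L]), 3)
  expect_equal(unname(v[3L]), log10(0.5))   # half of min positive (1)
  prov <- provenance(out)
  expect_equal(prov[[length(prov)]]$zero_substituted_features, 1L)
})

test_that("Pareto scaling has the defining centring/variance property", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), NULL))
  colnames(m) <- sprintf("I%d", 1:3)
  tab <- makeTable(m, rep("sample", 3))
  expect_warning(out <- paretoScale(tab), "zero-variance")
  expect_equal(unname(intensities(out)["f1", ]), c(-1, 0, 1))  # sd 1
  expect_equal(unname(intensities(out)["f2", ]), c(0, 0, 0))

  ## random table: every feature mean 0; variance equals pre-scaling SD
  set.seed(1)
  mr <- matrix(rexp(60, 0.1) + 1, nrow = 6)
  rownames(mr) <- sprintf("f%d", 1:6); colnames(mr) <- sprintf("I%d", 1:10)
  tabr <- makeTable(mr, rep("sample", 10))
  outr <- intensities(paretoScale(tabr))
  expect_lt(max(abs(rowMeans(outr))), 1e-10)
  expect_equal(unname(apply(outr, 1, var)), unname(apply(mr, 1, sd)),
               tolerance = 1e-12)
})

test_that("the full chain removes the engineered 2+2+2 features in order", {
  tab <- filterFixture()
  out <- runPreprocess(tab)
  expect_equal(nrow(out), 4L)
  expect_setequal(rownames(out), c("f07", "f08", "f09", "f10"))
  stages <- vapply(provenance(out), `[[`, "", "stage")
  expect_equal(
    stages[stages %in% c("qc_presence_filter", "qc_rsd_filter",
                         "blank_ratio_filter", "drift_correct",
                         "impute_missing", "log10_transform",
                         "pareto_scale")],
    c("qc_presence_filter", "qc_rsd_filter", "blank_ratio_filter",
      "drift_correct", "impute_missing", "log10_transform", "pareto_scale"))
  counts <- vapply(provenance(out), function(e) e$removed %||% NA_integer_,
                   NA_integer_)
  expect_equal(counts[!is.na(counts)], c(2L, 2L, 2L))
})

test_that("filters are idempotent on their own output", {
  tab <- filterFixture()
  cfg <- filterConfig()
  f1 <- qcPresenceFilter(tab, cfg)$table
  f2 <- qcRsdFilter(f1, cfg)$table
  f3 <- blankRatioFilter(f2, cfg)$table
  expect_identical(qcPresenceFilter(f3, cfg)$removed, character())
  expect_identical(qcRsdFilter(f3, cfg)$removed, character())
  expect_identical(blankRatioFilter(f3, cfg)$removed, character())
})

test_that("a table passing every filter keeps its feature count", {
  tab <- linearDriftFixture()
  ## warnings are expected here: no blanks (filter skipped) and, because the
  ## drift correction is exact on this fixture, zero-variance features at
  ## the Pareto stage
  out <- suppressWarnings(runPreprocess(tab, filterConfig()))
  expect_equal(nrow(out), nrow(tab))
})
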