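## Well-separated two-class toy problem.
separableXY <- function(n_per = 10L, p = 6L, gap = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, gap), n_per))
  colnames(X) <- sprintf("V%d", seq_len(p))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

test_that("PLS-DA separates a separable two-class problem", {
  d <- separableXY()
  fit <- fitPLS(d$X, d$y, 2L)
  expect_equal(ccr(d$y, predictClasses(fit, d$X)), 100)
  expect_s4_class(fit, "PLSModel")
  ## model invariants: unit-norm weights, orthogonal scores
  expect_equal(unname(colSums(fit@weights^2)), rep(1, fit@ncomp))
  tt <- crossprod(fit@scores)
  expect_lt(max(abs(tt[upper.tri(tt)])), 1e-8 * max(diag(tt)))
})

test_that("fitPLS validates its inputs", {
  d <- separableXY()
  expect_error(fitPLS(d$X, rep("a", nrow(d$X)), 2L), "at least 2 classes")
  expect_error(fitPLS(d$X, d$y, 50L), "exceeds")
})

test_that("NIPALS predictions match the SVD-based PLS oracle", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(12 * 6), 12, 6)
    y <- sample(rep(c("a", "b", "c"), 4))
    A <- sample(1:3, 1)
    fit <- fitPLS(X, y, A)
    expect_lt(max(abs(predictScores(fit, X) - svdPlsPredict(X, y, X, A))),
              1e-6)
  }
})

test_that("prediction ties resolve to the first class label", {
  d <- separableXY()
  fit <- fitPLS(d$X, d$y, 1L)
  ## at the training centroid the centred prediction is 0: exact tie
  centre <- matrix(fit@xmeans, 1)
  sc <- predictScores(fit, centre)
  expect_equal(unname(sc[1, 1]), unname(sc[1, 2]))
  expect_identical(predictClasses(fit, centre), "a")
})

test_that("classification metrics match hand-computed confusion tables", {
  ## all correct
  expect_equal(ccr(c("a", "b"), c("a", "b")), 100)
  mm <- macroMetrics(c("a", "b"), c("a", "b"))
  expect_equal(unname(mm), c(100, 100, 100))

  ## 3 balanced classes, exactly half of each correct
  truth <- rep(c("a", "b", "c"), each = 4)
  pred <- c("a", "a", "b", "b", "b", "b", "c", "c", "c", "c", "a", "a")
  expect_equal(ccr(truth, pred), 50)
  expect_equal(unname(classwiseRates(truth, pred)), c(50, 50, 50))

  ## binary 1-wrong-of-4 per the brute-force confusion table
  truth2 <- c("A", "A", "A", "A", "B", "B", "B", "B")
  pred2 <- c("A", "A", "A", "B", "B", "B", "B", "B")
  expect_equal(ccr(truth2, pred2), 87.5)
  tp_a <- 3; fn_a <- 1; tn_a <- 4; fp_a <- 0
  sens <- mean(c(100 * tp_a / (tp_a + fn_a), 100 * 4 / 4))
  spec <- mean(c(100 * tn_a / (tn_a + fp_a), 100 * 3 / 4))
  mm2 <- macroMetrics(truth2, pred2)
  expect_equal(unname(mm2["sensitivity"]), sens)
  expect_equal(unname(mm2["specificity"]), spec)
  expect_equal(unname(mm2["accuracy"]), 87.5)
})

test_that("SMOTE balances to the majority size inside the convex hull", {
  ## already balanced: identity
  d <- separableXY()
  out <- smoteOversample(d$X, d$y, seed = 1L)
  expect_identical(out$X, d$X)
  expect_identical(out$y, d$y)

  ## minority on a segment: synthetic points stay on it
  X <- rbind(matrix(rnorm(40), 20, 2),
             matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  y <- c(rep("maj", 20), "min", "min")
  res <- smoteOversample(X, y, k_neighbors = 1L, seed = 2L)
  expect_equal(as.vector(table(res$y)), c(20L, 20L))
  synth <- res$X[res$y == "min", ][-(1:2), ]
  expect_equal(synth[, 1], synth[, 2])                  # on the diagonal
  expect_true(all(synth >= 0 & synth <= 1))             # within the hull

  ## deterministic under seed
  res2 <- smoteOversample(X, y, k_neighbors = 1L, seed = 2L)
  expect_identical(res$X, res2$X)
})

test_that("SMOTE reproduces the 287/143/142 -> 287 x3 cohort balance", {
  set.seed(3)
  y <- rep(c("WE", "SA", "AC"), c(287, 143, 142))
  X <- matrix(rnorm(length(y) * 3), ncol = 3)
  res <- smoteOversample(X, y, seed = 4L)
  expect_equal(as.vector(table(res$y)[c("WE", "SA", "AC")]),
               c(287L, 287L, 287L))
})

test_that("bootstrap validation is exact on noiseless data and reproducible", {
  ## identical rows per class, zero noise: every OOB CCR is 100
  X <- rbind(matrix(rep(c(0, 0, 0), 10), 10, byrow = TRUE),
             matrix(rep(c(5, 5, 5), 10), 10, byrow = TRUE))
  y <- rep(c("a", "b"), each = 10)
  cfg <- bootstrapConfig(n_boot = 20L, n_perm = 0L, seed = 9L,
                         max_components = 2L, inner_cv_folds = 3L)
  ## rank-1 data: the second component is not extractable; that warning is
  ## expected here
  vs <- suppressWarnings(bootstrapValidate(X, y, cfg))
  expect_equal(vs@observed_ccr, rep(100, 20))
  expect_equal(vs@mean_ccr, 100)

  d <- separableXY(n_per = 15L, gap = 3)
  vs1 <- validatePLSDA(d$X, d$y, bootstrapConfig(n_boot = 10L, n_perm = 10L,
                                                 seed = 5L,
                                                 max_components = 3L,
                                                 inner_cv_folds = 3L))
  vs2 <- validatePLSDA(d$X, d$y, bootstrapConfig(n_boot = 10L, n_perm = 10L,
                                                 seed = 5L,
                                                 max_components = 3L,
                                                 inner_cv_folds = 3L))
  expect_identical(vs1@observed_ccr, vs2@observed_ccr)
  expect_identical(vs1@null_ccr, vs2@null_ccr)
  expect_identical(vs1@empirical_p, vs2@empirical_p)
})

test_that("permuted labels on effect-free data classify at chance", {
  set.seed(21)
  n <- 300L
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c("a", "b", "c"), each = 100L)
  fit <- withr::with_seed(3, fitPLS(X, sample(y), 2L))
  train_ccr <- ccr(sample(y), predictClasses(fit, X))
  ## training CCR approaches chance (1/3) as n grows: within 3 SE
  se <- 100 * sqrt(1 / 3 * 2 / 3 / n)
  expect_lt(abs(train_ccr - 100 / 3), 3 * se + 5)  # small optimism allowance
})

test_that("PCA scores and explained variance behave as eigenanalysis", {
  ## rank-1 matrix: PC1 explains everything
  x1 <- outer(1:8, c(1, 2, 3))
  p1 <- pcaScores(x1, 2L)
  expect_equal(p1$explained[1L], 1)

  ## orthogonal two-direction toy with known 4:1 variance split
  set.seed(5)
  n <- 2000L
  X <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 1))
  p2 <- pcaScores(X, 2L)
  ev <- eigen(cov(X))$values
  expect_equal(p2$explained, ev / sum(ev), tolerance = 1e-12)
  expect_equal(p2$explained[1L], 0.8, tolerance = 0.05)
})

test_that("QC injections cluster tighter than samples in PC space", {
  fx <- smallSimFixture()
  tab <- driftCorrect(fx$sim$table)$table
  tab <- imputeMissing(tab)
  keep <- sampleData(tab)$sample_type %in% c("sample", "QC")
  tab <- log10Transform(tab[, keep])
  X <- t(intensities(tab))
  pc <- pcaScores(X, 2L)
  is_qc <- sampleData(tab)$sample_type == "QC"
  d_qc <- mean(dist(pc$scores[is_qc, ]))
  d_sm <- mean(dist(pc$scores[!is_qc, ]))
  expect_lt(d_qc, d_sm)
})
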