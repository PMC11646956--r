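test_that("Mann-Whitney ranking matches exact enumeration", {
  X <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "f1"))
  r <- rankFeatures(X, c("g1", "g1", "g2", "g2"))
  expect_equal(r$statistic, 0)        # U = 0: complete separation
  expect_equal(r$p_value, 1 / 3)      # 2 * (1 / C(4,2))
  expect_equal(r$p_value, mwEnumOracle(c(1, 2), c(3, 4)))

  ## identical group distributions: no information, p = 1
  Xt <- matrix(c(1, 2, 1, 2), 4, 1, dimnames = list(NULL, "f1"))
  expect_equal(rankFeatures(Xt, c("g1", "g1", "g2", "g2"))$p_value, 1)
})

test_that("Kruskal-Wallis ranking reports the exact H statistic", {
  X <- matrix(1:6, 6, 1, dimnames = list(NULL, "f1"))
  labels <- rep(c("a", "b", "c"), each = 2)
  r <- rankFeatures(X, labels)
  h <- kwHOracle(1:6, labels)
  expect_equal(r$statistic, h)
  expect_equal(r$p_value, pchisq(h, df = 2, lower.tail = FALSE))
  ## this arrangement maximises H: enumeration confirms it is the extreme
  expect_equal(kwPermOracle(1:6, labels), 6 / 90)
  expect_error(rankFeatures(X, c("a", rep("b", 5))), "< 2 members")
})

test_that("significant set selection follows the alpha threshold", {
  rk <- data.frame(feature_id = sprintf("F%d", 1:5),
                   statistic = 1:5,
                   p_value = c(0.01, 0.05, 0.2, 1, 0.049))
  expect_setequal(significantSet(rk, 0.05), c("F1", "F2", "F5"))
  expect_identical(significantSet(rk, 1), rk$feature_id)    # alpha = 1: all
  rk$p_value <- rep(1, 5)
  expect_length(significantSet(rk, 0.05), 0L)               # all p = 1
  ## externally supplied VIP list overrides
  expect_identical(significantSet(rk, 0.05, vip_selected = c("F3", "F9")),
                   "F3")
})

test_that("feature-to-compound mapping deduplicates the compound set", {
  cmp <- bundledCompounds()
  ## glucose and mannose share a mass: one feature maps to both compounds
  feats <- data.frame(feature_id = c("q1", "q2"),
                      mz = rep(180.06339 + 1.007276, 2), rt = c(5, 6))
  res <- mzToCompounds(c("q1", "q2"), feats, cmp, tol_ppm = 5)
  expect_setequal(res$compound_set, c("HMDB0000122", "HMDB0000169"))
  expect_equal(nrow(res$candidates), 4L)  # 2 features x 2 compounds
})

test_that("pathway FET reproduces the hypergeometric tail", {
  ## pathway of 5 compounds, reference 20, 10 significant, all 5 hit
  universe <- sprintf("C%02d", 1:20)
  model <- new("PathwayModel",
               pathways = list(pw = list(name = "pw",
                                         compounds = universe[1:5])),
               universe = universe)
  sig <- universe[c(1:5, 6:10)]
  res <- pathwayFET(sig, model)
  expect_equal(res$hits_observed, 5L)
  expect_equal(res$hits_expected, 5 * 10 / 20)
  expect_equal(res$enrichment_ratio, 2)
  expect_equal(res$fet_p, 3003 / 184756)          # C(15,5)/C(20,10)
  expect_equal(res$fet_p, hyperTailOracle(20, 5, 10, 5))

  ## at-or-below-chance draw: no enrichment direction, p >= 0.5
  res2 <- pathwayFET(universe[c(1, 6:10)], model)  # 1 hit of 6 drawn
  expect_gte(res2$fet_p, 0.5)

  ## no significant compounds: p = 1 everywhere
  res3 <- pathwayFET(character(), model)
  expect_equal(res3$fet_p, 1)
  expect_equal(res3$hits_observed, 0L)
})

test_that("resampling adjustment is calibrated and deterministic", {
  lib <- simulateCompoundLibrary(30L, 3L, seed = 2L)
  feats <- data.frame(feature_id = sprintf("F%02d", 1:30),
                      mz = lib$compounds$monoisotopic_mass + 1.007276,
                      rt = 1:30)
  ## observed hits 0 -> empirical p = 1
  obs0 <- pathwayFET(character(), lib$model)
  adj0 <- resamplingAdjust(obs0, feats, sig_size = 5L, lib$model,
                           lib$compounds, n_resamples = 100L, seed = 3L)
  expect_equal(unname(adj0$resampling_p), rep(1, 3))

  ## planted enrichment: the significant set is exactly one pathway
  p1 <- pathwayCompounds(lib$model, "P01")
  sig_feats <- feats$feature_id[lib$compounds$compound_id %in% p1]
  obs <- pathwayFET(
    mzToCompounds(sig_feats, feats, lib$compounds)$compound_set, lib$model)
  adj <- resamplingAdjust(obs, feats, sig_size = length(sig_feats),
                          lib$model, lib$compounds, n_resamples = 200L,
                          seed = 4L)
  expect_equal(adj$resampling_p[adj$pathway_id == "P01"],
               1 / 201, ignore_attr = TRUE)
  adj2 <- resamplingAdjust(obs, feats, sig_size = length(sig_feats),
                           lib$model, lib$compounds, n_resamples = 200L,
                           seed = 4L)
  expect_identical(adj$resampling_p, adj2$resampling_p)
  expect_error(
    resamplingAdjust(obs, feats, sig_size = 50L, lib$model, lib$compounds,
                     n_resamples = 100L, seed = 1L), "exceeds")
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.3), 0.3)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(40)
  expect_equal(bhFdr(p), bhOracle(p))
  expect_error(bhFdr(c(0.5, 1.2)), "must lie in")
})

test_that("end-to-end enrichment flags a planted pathway", {
  lib <- simulateCompoundLibrary(40L, 4L, seed = 9L)
  set.seed(10)
  n <- 60L
  labels <- rep(c("g1", "g2"), each = n / 2)
  p <- 40L
  X <- matrix(rnorm(n * p), n, p)
  feats <- data.frame(feature_id = sprintf("F%02d", 1:p),
                      mz = lib$compounds$monoisotopic_mass + 1.007276,
                      rt = seq_len(p))
  colnames(X) <- feats$feature_id
  ## shift every feature of pathway P01 in group g2
  hit <- lib$compounds$compound_id %in% pathwayCompounds(lib$model, "P01")
  X[labels == "g2", hit] <- X[labels == "g2", hit] + 3
  res <- runEnrichment(X, labels, feats, lib$compounds, lib$model,
                       n_resamples = 200L, seed = 11L)
  expect_equal(res$pathway_id[1L], "P01")
  expect_lt(res$fdr_q[res$pathway_id == "P01"], 0.05)
  expect_equal(res$enrichment_ratio, res$hits_observed / res$hits_expected)
  ## ordering follows -log10 p
  expect_true(!is.unsorted(res$fet_p))
})
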