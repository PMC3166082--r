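test_that("Youden index is exact and antisymmetric under class swap", {
  expect_equal(youden(10, 0, 20, 0), 1)
  expect_equal(youden(5, 10, 10, 5), 0)
  expect_equal(youden(72, 0, 204, 0), 1)
  expect_error(youden(0, 5, 5, 0), "empty")
  # swapping classes together with predictions leaves J unchanged
  set.seed(4)
  for (i in 1:10) {
    cm <- sample(1:30, 4)
    expect_equal(youden(cm[1], cm[2], cm[3], cm[4]),
                 youden(cm[3], cm[4], cm[1], cm[2]))
  }
})

test_that("zero rule equals the majority-class frequency", {
  expect_equal(round(zeroRule(rep(c(0, 1), c(204, 72))), 4), 0.7391)
  expect_equal(zeroRule(rep(1, 10)), 1)
  expect_equal(zeroRule(rep(c(0, 1), 25)), 0.5)
  expect_error(zeroRule(integer()), "non-empty")
})

test_that("variance filter drops constant and near-constant columns", {
  X <- cbind(const = rep(1, 40), bin = rep(c(0, 1), c(4, 36)),
             cont = rnorm(40))
  kept <- varianceFilter(X)
  expect_false("const" %in% kept)
  expect_true(all(c("bin", "cont") %in% kept))
  expect_error(varianceFilter(cbind(a = rep(2, 5))), "every column")
})

test_that("feature weighting ranks label-aligned columns on top", {
  set.seed(7)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(label_copy = y + rnorm(n, 0, 0.01),
             label_dup = y + rnorm(n, 0, 0.01),
             noise = rnorm(n))
  for (m in c("correlation", "information_gain", "relief")) {
    w <- weightFeatures(X, y, m)
    expect_gt(min(w[c("label_copy", "label_dup")]), w[["noise"]])
  }
  # duplicated informative column receives (near-)equal weight
  for (m in c("correlation", "information_gain")) {
    w <- weightFeatures(X, y, m)
    expect_equal(w[["label_copy"]], w[["label_dup"]], tolerance = 0.05)
  }
  expect_error(weightFeatures(X, rep(1, n)), "two classes")
})

test_that("pure-noise weights sit near the permutation null", {
  set.seed(21)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(noise = rnorm(n))
  w_obs <- weightFeatures(x, y, "correlation")[["noise"]]
  null <- replicate(1000, abs(cor(x[, 1], sample(y))))
  expect_lt(w_obs, quantile(null, 0.999))
})

test_that("forest fits separable data and is deterministic under a seed", {
  set.seed(2)
  n <- 80
  X <- cbind(d1 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)), d2 = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  fit <- fitForest(X, y, forestSpec(seed = 9))
  expect_equal(predict(fit, X), y)  # training accuracy 1 on separated data
  fit2 <- fitForest(X, y, forestSpec(seed = 9))
  Xnew <- cbind(d1 = rnorm(50), d2 = rnorm(50))
  expect_identical(predict(fit, Xnew), predict(fit2, Xnew))
  expect_error(fitForest(X, rep(0, n)), "single-class")
})

test_that("mtry follows floor(log2(m)) + 1 with the loge alternative", {
  expect_equal(lysoSPAR:::mtryFor(forestSpec(), 4L), 3L)
  expect_equal(lysoSPAR:::mtryFor(forestSpec(), 100L), 7L)
  expect_equal(lysoSPAR:::mtryFor(forestSpec(mtry_rule = "loge"), 100L), 5L)
  expect_equal(lysoSPAR:::mtryFor(forestSpec(), 1L), 1L)
})

test_that("random labels give out-of-bag Youden near zero", {
  js <- vapply(1:12, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(200 * 4), 200, 4,
                  dimnames = list(NULL, paste0("d", 1:4)))
      y <- rbinom(200, 1, 0.5)
      r <- bootstrapValidate(X, y, forestSpec(seed = s), n_resamples = 30L,
                             seed = s)
      meanYouden(r)
    })
  }, 0)
  expect_lt(max(abs(js)), 0.15)
  expect_lt(abs(mean(js)), 0.06)
})

test_that("bootstrap validation is reproducible and near 1 on separable data", {
  set.seed(3)
  n <- 120
  X <- cbind(d1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)), d2 = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  r1 <- bootstrapValidate(X, y, forestSpec(seed = 1), n_resamples = 50L,
                          seed = 42L)
  expect_gt(meanYouden(r1), 0.95)
  expect_true(all(r1@accuracy >= 0 & r1@accuracy <= 1))
  expect_gte(sdYouden(r1), 0)
  r2 <- bootstrapValidate(X, y, forestSpec(seed = 1), n_resamples = 50L,
                          seed = 42L)
  expect_identical(resampleScores(r1), resampleScores(r2))
})

test_that("beam width covering the pool reproduces exhaustive size-1 search", {
  ml <- defaultMatrixAndLabels(2L)
  X <- ml$X[, c("logp_logweight", "pka_sum", "pka_acid", "si_vsa_pol",
                "mw", "noise01")]
  scores <- vapply(colnames(X), function(cc)
    meanYouden(bootstrapValidate(X[, cc, drop = FALSE], ml$y,
                                 n_resamples = 30L,
                                 seed = lysoSPAR:::fanSeed(5L, 7L))), 0)
  beam <- beamSearch(X, ml$y, beam_width = 10L, max_size = 1L,
                     score_resamples = 30L, seed = 5L)
  expect_identical(beam$size1$descriptors,
                   names(scores)[which.max(scores)])
})

test_that("adding a noise column to a winning pair does not help beyond 1 SD", {
  ml <- defaultMatrixAndLabels(2L)
  pair <- c("logp_logweight", "pka_sum")
  r2 <- bootstrapValidate(ml$X[, pair], ml$y, n_resamples = 100L, seed = 8L)
  r3 <- bootstrapValidate(ml$X[, c(pair, "noise03")], ml$y,
                          n_resamples = 100L, seed = 8L)
  expect_lt(meanYouden(r3) - meanYouden(r2), sdYouden(r2))
})

test_that("y-scrambling with a forced identity permutation equals plain validation", {
  ml <- defaultMatrixAndLabels(2L)
  combo <- c("logp_logweight", "pka_sum")
  ys <- yScramble(ml$X, ml$y, combo, n_permutations = 1L,
                  n_resamples = 30L, seed = 4L, identity_permutation = TRUE)
  ref <- bootstrapValidate(ml$X[, combo], ml$y, n_resamples = 30L,
                           seed = lysoSPAR:::fanSeed(4L, 2001L))
  expect_equal(ys$null_youden[1], meanYouden(ref))
})
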