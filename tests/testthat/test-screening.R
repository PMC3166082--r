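test_that("activity threshold is inclusive at 50.0 with reliability flags", {
  calls <- classifyActivity(c(44.1, 50.0, 50.1, 85))
  expect_equal(calls$class, c(1L, 1L, 0L, 0L))
  expect_false(calls$reliable[1])  # 44.1 is within 16 points of 50
  expect_false(calls$reliable[2])
  expect_true(calls$reliable[4])
  # idempotent: reclassifying the same residuals changes nothing
  expect_identical(classifyActivity(calls$residual_activity), calls)
  expect_error(classifyActivity(c(10, -2)), ">= 0")
})

test_that("bimodality analysis recovers a planted two-mode structure", {
  withr::with_seed(10, {
    x <- c(rnorm(72, 35, 8), rnorm(204, 85, 12))
    x <- pmin(pmax(x, 0), 120)
  })
  b <- bimodalityAnalysis(x)
  expect_lt(b$ks_p_overall, 0.001)
  expect_equal(b$means[1], 35, tolerance = 3)
  expect_equal(b$means[2], 85, tolerance = 3)
  expect_equal(sum(b$weights), 1, tolerance = 1e-6)
  # within-component normality is not rejected wholesale
  expect_true(any(b$ks_p_components > 0.01, na.rm = TRUE))
})

test_that("a unimodal sample keeps pooled KS p high in most seeds", {
  ok <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(300, 70, 10))
    b <- bimodalityAnalysis(x)
    # one normal: KS keeps the pooled normal, and the mixture degenerates
    # (a vanishing component or two near-coincident means)
    b$ks_p_overall > 0.05 &&
      (min(b$weights) < 0.1 || abs(diff(b$means)) < 2 * sd(x))
  }, TRUE)
  expect_gte(sum(ok), 16L)
})

test_that("bimodality cross-checks against an independent mixture fitter", {
  suppressMessages(library(mclust))
  x <- withr::with_seed(3, c(rnorm(80, 35, 8), rnorm(220, 85, 12)))
  b <- bimodalityAnalysis(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(b$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1)
})

test_that("degenerate bimodality inputs error out", {
  expect_error(bimodalityAnalysis(rep(50, 30)), "identical")
  expect_error(bimodalityAnalysis(rnorm(10)), "n >= 20")
})

test_that("virtual screening applies the exclusion cascade in order", {
  ml <- defaultMatrixAndLabels(1L)
  model <- fitForest(ml$X[, c("logp_logweight", "pka_sum", "pka_acid",
                              "si_vsa_pol")], ml$y, forestSpec(seed = 2))
  lib <- generateLibrary(generatorConfig(seed = 5L), "natural_like",
                         n = 200L, n_incalculable = 5L, n_quaternary = 2L,
                         n_duplicates = 4L)
  scr <- virtualScreen(lib$compounds, model, lib$structures)
  expect_equal(scr@n_excluded_incalculable, 5L)
  expect_equal(scr@n_excluded_quaternary, 2L)
  expect_equal(scr@n_excluded_duplicates, 4L)
  expect_equal(nScreened(scr), 200L - 5L - 2L - 4L)
  # counts reconcile by construction of the class validity too
  expect_equal(scr@n_input,
               nScreened(scr) + scr@n_excluded_incalculable +
                 scr@n_excluded_quaternary + scr@n_excluded_duplicates)
  expect_true(all(predictions(scr)$predicted_class %in% c(0L, 1L)))
  # quaternary compounds carry the right exclusion reason
  qids <- grep("QAT", scr@exclusions$id, value = TRUE)
  expect_equal(unique(scr@exclusions$reason[scr@exclusions$id %in% qids]),
               "quaternary_nitrogen")
  # the same structure under two ids: second occurrence excluded
  dups <- scr@exclusions$id[scr@exclusions$reason == "duplicate"]
  expect_equal(length(dups), 4L)
})

test_that("one-sided enrichment p matches brute-force enumeration exactly", {
  for (N in c(8, 15, 23, 30)) {
    for (K in c(2, floor(N / 3), floor(N / 2))) {
      for (m in c(2, floor(N / 4), floor(N / 2))) {
        for (k in 0:min(m, K)) {
          expect_equal(enrichmentP(k, m, K, N),
                       bruteForceEnrichP(k, m, K, N), tolerance = 1e-12)
        }
      }
    }
  }
  # and against the independent stats::fisher.test implementation
  p1 <- enrichmentP(8, 10, 20, 100)
  ft <- fisher.test(matrix(c(8, 2, 12, 78), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(p1, ft$p.value, tolerance = 1e-10)
})

test_that("group enrichment flags the loaded group and respects BH", {
  calls <- data.frame(id = sprintf("c%03d", 1:100),
                      predicted_class = rep(c(1L, 0L), c(10, 90)))
  groups <- data.frame(id = calls$id,
                       group = c(rep("G1", 10), rep(c("G2", "G3", "G4"), 30)))
  enr <- groupEnrichment(calls, groups)
  tab <- enr$table
  g1 <- tab[tab$group == "G1", ]
  expect_equal(g1$p, 1 / choose(100, 10), tolerance = 1e-9)
  expect_true(g1$enriched)
  expect_false(any(tab$enriched[tab$group != "G1"]))
  # single group holding all compounds has p = 1
  expect_equal(enrichmentP(10, 100, 10, 100), 1)
  # BH monotone in raw p order
  set.seed(9)
  for (i in 1:20) {
    p <- runif(15)
    adj <- p.adjust(p, "BH")
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("uniformly spread actives show no enrichment", {
  ok <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      calls <- data.frame(id = sprintf("c%03d", 1:200),
                          predicted_class = rbinom(200, 1, 0.1))
      groups <- data.frame(id = calls$id,
                           group = sample(paste0("G", 1:8), 200,
                                          replace = TRUE))
      enr <- groupEnrichment(calls, groups)
      all(enr$table$p_adjusted >= 0.05)
    })
  }, TRUE)
  expect_gte(sum(ok), 9L)
})

test_that("Rule-of-Five association reproduces the published contingency", {
  classes <- rep(c(1, 0), c(72, 204))
  violations <- c(rep(c(TRUE, FALSE), c(37, 35)),
                  rep(c(TRUE, FALSE), c(59, 145)))
  r <- rofAssociation(classes, violations)
  expect_equal(r$pct_violation_active, 51.4, tolerance = 0.05)
  expect_equal(r$pct_violation_inactive, 28.9, tolerance = 0.05)
  expect_lte(r$p, 0.005)
  # independent check of the chi-square p value
  ct <- chisq.test(matrix(c(35, 145, 37, 59), 2, byrow = TRUE),
                   correct = FALSE)
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)
  # identical rates give chi-square 0, p 1
  r0 <- rofAssociation(rep(c(1, 0), each = 40),
                       rep(c(TRUE, FALSE, TRUE, FALSE), each = 20))
  expect_equal(r0$chi_square, 0)
  expect_equal(r0$p, 1)
})

test_that("logBB association lists active poor-penetrants as violations", {
  cls <- c(1, 1, 0, 0, 1)
  bb <- c(0.4, 0.0, -0.8, 0.2, NA)
  r <- logbbAssociation(cls, bb, ids = letters[1:5])
  expect_equal(r$n_with_logbb, 4L)
  expect_identical(r$violations, character(0))
  r2 <- logbbAssociation(c(cls, 1), c(bb, -0.5), ids = letters[1:6])
  expect_identical(r2$violations, "f")
  expect_warning(r3 <- logbbAssociation(c(1, 0), c(NA, NA)), "logBB")
  expect_equal(r3$n_with_logbb, 0L)
})
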