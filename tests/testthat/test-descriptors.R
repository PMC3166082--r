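test_that("imputation fills pKa and k gaps with the documented constants", {
  d <- data.frame(id = c("a", "b", "c"), mw = 300,
                  pka_base1 = c(NA, 9.5, 9.5), pka_base2 = c(NA, NA, 8),
                  pka_acid = c(NA, 4, NA), k = c(NA, 3, NA))
  out <- imputeDescriptors(d)
  expect_equal(out$pka_base1, c(0, 9.5, 9.5))
  expect_equal(out$pka_base2, c(0, 0, 8))
  expect_equal(out$pka_acid, c(15, 4, 15))
  expect_equal(out$k, c(12, 3, 12))
  expect_match(out$imputed_fields[1], "pka_base1")
  expect_match(out$imputed_fields[1], "k")
  # fully specified row gains no flags
  full <- data.frame(id = "z", mw = 1, pka_base1 = 1, pka_base2 = 1,
                     pka_acid = 1, k = 1)
  expect_identical(imputeDescriptors(full)$imputed_fields, "")
})

test_that("ionization categories follow the relevance thresholds", {
  expect_identical(classifyIonization(9, NA, NA), "monobase")
  expect_identical(classifyIonization(9, 8, 4), "zwitter")
  expect_identical(classifyIonization(9, 8, NA), "bibase")
  expect_identical(classifyIonization(NA, NA, 4), "acid")
  # boundary: base below 3 and acid not below 10 are both irrelevant
  expect_identical(classifyIonization(2.9, NA, 12), "none")
  expect_identical(classifyIonization(3.0, NA, NA), "monobase")
  expect_identical(classifyIonization(NA, NA, 10), "none")
  expect_identical(classifyIonization(NA, NA, 9.99), "acid")
})

test_that("weight-corrected logP and size-intensive forms are exact", {
  expect_equal(logpLogWeight(5, 100), 4)
  expect_equal(logpLogWeight(0, 1), 0)
  expect_equal(logpLogWeight(5.45, 366.3), 5.45 - 0.5 * log10(366.3))
  expect_equal(logpLogWeight(5.45, 366.3), 4.1681, tolerance = 1e-4)
  expect_error(logpLogWeight(1, 0), "mw")
  expect_equal(sizeIntensive(50, 250), 0.2)
  expect_equal(sizeIntensive(0, 366.3), 0)
  expect_equal(sizeIntensive(83.5, 334), 0.25)
  expect_error(sizeIntensive(1, -1), "mw")
})

test_that("modified pKa sum uses the positive-second-base conditional", {
  expect_equal(pkaSumMod(9.5, 8), 17.5)
  expect_equal(pkaSumMod(9.5, 0), 9.5)
  expect_equal(pkaSumMod(9.5, -1.2), 9.5)
  # monotone non-decreasing in the positive part of the second argument
  b2 <- seq(-5, 10, by = 0.5)
  v <- pkaSumMod(rep(7, length(b2)), b2)
  expect_true(all(v >= 7))
  expect_true(all(diff(v) >= 0))
})

test_that("count descriptors match manual inspection", {
  mols <- testMols()
  cEth <- countDescriptors(mols$eth)
  expect_equal(cEth[["n_OpN"]], 1L)
  expect_equal(cEth[["n_hal"]], 0L)
  expect_equal(cEth[["n_XpC"]], 2L)
  expect_equal(cEth[["n_qN"]], 0L)
  cAc <- countDescriptors(mols$ac)
  expect_equal(cAc[["n_COOH"]], 1L)
  expect_equal(cAc[["n_OpN"]], 2L)
  expect_equal(countDescriptors(mols$tma)[["n_qN"]], 1L)
  expect_equal(countDescriptors(mols$amide)[["n_amines"]], 0L)
  expect_equal(countDescriptors(mols$amine2)[["n_amines"]], 1L)
  expect_equal(countDescriptors(mols$amidine)[["n_pdN"]], 1L)
  expect_equal(countDescriptors(mols$hal)[["n_hal"]], 2L)
})

test_that("count descriptors are invariant under atom reordering", {
  variants <- molFromSmiles(c(a = "NC(Cc1ccccc1)C(=O)O",
                              b = "OC(=O)C(N)Cc1ccccc1",
                              c = "c1ccccc1CC(N)C(O)=O"))
  counts <- lapply(variants, countDescriptors)
  expect_identical(counts$a, counts$b)
  expect_identical(counts$a, counts$c)
})

test_that("count invariants hold across generated structures", {
  s <- defaultSet(3L)
  counts <- t(vapply(s$structures[1:80], countDescriptors, integer(7)))
  expect_true(all(counts >= 0L))
  expect_true(all(counts[, "n_XpC"] >= counts[, "n_hal"]))
  expect_true(all(counts[, "n_OpN"] >= counts[, "n_COOH"]))
})

test_that("Rule-of-Five counts fire on strict inequalities only", {
  b <- lipinskiViolation(500, 5, 5, 10)
  expect_equal(b$count, 0L); expect_false(b$violated)
  v1 <- lipinskiViolation(366.3, 5.45, 1, 3)
  expect_equal(v1$count, 1L); expect_true(v1$violated)
  v2 <- lipinskiViolation(645.3, 8.89, 0, 4)
  expect_equal(v2$count, 2L)
  miss <- lipinskiViolation(NA, 2, 1, 1)
  expect_true(is.na(miss$count)); expect_true(is.na(miss$violated))
})

test_that("descriptor matrix wires derived forms together", {
  s <- defaultSet(1L)
  X <- buildDescriptorMatrix(s$compounds, s$structures)
  d <- compoundData(imputeDescriptors(s$compounds))
  expect_identical(rownames(X), d$id)
  expect_equal(X[, "logp_logweight"], setNames(logpLogWeight(d$logp, d$mw),
                                               d$id))
  # size-intensive column equals parent / mw within strict tolerance
  expect_equal(X[, "si_vsa_pol"] * d$mw, setNames(d$vsa_pol, d$id),
               tolerance = 1e-12)
  expect_true(all(c("n_qN", "n_amines") %in% colnames(X)))
  # logp_logweight strictly decreases in mw at fixed logp
  mws <- c(100, 200, 400, 800)
  expect_true(all(diff(logpLogWeight(rep(3, 4), mws)) < 0))
})

test_that("the structure-derived polar surface surrogate is flagged", {
  v <- approxVsaPol(testMols()$phe)
  expect_true(attr(v, "surrogate"))
  expect_gt(v, 0)
  expect_equal(as.numeric(approxVsaPol(testMols()$benzene)), 0)
})
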