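test_that("fingerprints are canonical, discriminating, and total", {
  mols <- testMols()
  fp1 <- triangleFingerprint(mols$benzene)
  expect_gt(length(fp1), 0)
  # atom-order invariance: same molecule entered differently
  alt <- molFromSmiles(c(x = "c1ccc(cc1)CC(C(=O)O)N"))$x
  expect_setequal(as.character(triangleFingerprint(mols$phe)),
                  as.character(triangleFingerprint(alt)))
  # different heteroaromatics differ
  expect_false(setequal(as.character(fp1),
                        as.character(triangleFingerprint(mols$pyridine))))
  # degenerate inputs fall back to smaller keys instead of failing
  fpm <- triangleFingerprint(mols$methane)
  expect_gt(length(fpm), 0)
  fpe <- triangleFingerprint(mols$eth)  # two typed atoms at most
  expect_gt(length(fpe), 0)
})

test_that("tanimoto has the set-arithmetic semantics", {
  a <- structure(c("k1", "k2", "k3", "k4"), scheme = "s")
  b <- structure(c("k3", "k4", "k5", "k6", "k7", "k8"), scheme = "s")
  expect_equal(tanimoto(a, b), 2 / 8)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, structure(c("z1", "z2"), scheme = "s")), 0)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_error(tanimoto(a, structure("k1", scheme = "t")), "scheme")
  expect_warning(t0 <- tanimoto(character(), character()), "empty")
  expect_equal(t0, 1)
})

test_that("tanimoto is 1 iff fingerprints are equal", {
  mols <- testMols()
  fps <- lapply(mols, triangleFingerprint)
  for (i in seq_along(fps))
    for (j in seq_along(fps)) {
      t <- suppressWarnings(tanimoto(fps[[i]], fps[[j]]))
      eq <- setequal(as.character(fps[[i]]), as.character(fps[[j]]))
      expect_identical(t == 1, eq)
    }
})

test_that("clustering at the cutoff honours complete-linkage semantics", {
  one <- structure(c("a", "b", "c"), scheme = "s")
  fps <- list(x1 = one, x2 = one, x3 = one)
  sol <- clusterAt(fps, 0.85)
  expect_equal(nClusters(sol), 1L)
  # mutually dissimilar: N clusters
  fps2 <- list(y1 = structure("p", scheme = "s"),
               y2 = structure("q", scheme = "s"),
               y3 = structure("r", scheme = "s"))
  expect_equal(nClusters(clusterAt(fps2, 0.85)), 3L)
  # two tight blobs: within > 0.9, between < 0.3
  blobA <- lapply(1:4, function(i)
    structure(c(paste0("a", 1:19), paste0("u", i)), scheme = "s"))
  blobB <- lapply(1:4, function(i)
    structure(c(paste0("b", 1:19), paste0("v", i)), scheme = "s"))
  fps3 <- c(blobA, blobB)
  names(fps3) <- paste0("m", 1:8)
  # verify the construction with brute-force pairwise similarities
  simWithin <- c(tanimoto(blobA[[1]], blobA[[2]]),
                 tanimoto(blobB[[1]], blobB[[3]]))
  simBetween <- tanimoto(blobA[[1]], blobB[[1]])
  expect_true(all(simWithin > 0.9) && simBetween < 0.3)
  sol3 <- clusterAt(fps3, 0.85)
  expect_equal(nClusters(sol3), 2L)
  asg <- sol3@assignment
  expect_equal(length(unique(asg[paste0("m", 1:4)])), 1L)
  expect_equal(length(unique(asg[paste0("m", 5:8)])), 1L)
  # all within-cluster pairwise similarities >= cutoff
  for (k in unique(asg)) {
    members <- names(asg)[asg == k]
    if (length(members) > 1)
      for (i in seq_along(members))
        for (j in seq_len(i - 1))
          expect_gte(tanimoto(fps3[[members[i]]], fps3[[members[j]]]), 0.85)
  }
})

test_that("cluster solutions are invariant under input permutation", {
  s <- defaultSet(2L)
  fps <- lapply(s$structures[1:25], triangleFingerprint)
  sol1 <- clusterAt(fps, 0.85)
  sol2 <- clusterAt(rev(fps), 0.85)
  expect_equal(nClusters(sol1), nClusters(sol2))
  ids <- names(sol1@assignment)
  # same partition up to label names
  expect_true(all(outer(sol1@assignment, sol1@assignment, "==") ==
                  outer(sol2@assignment[ids], sol2@assignment[ids], "==")))
})

test_that("div_rel spans (0, 1] and is monotone in the cutoff", {
  one <- structure(c("a", "b"), scheme = "s")
  fpsSame <- setNames(rep(list(one), 5), paste0("c", 1:5))
  expect_equal(divRel(clusterAt(fpsSame, 0.85)), 1 / 5)
  fpsDiff <- list(a = structure("p", scheme = "s"),
                  b = structure("q", scheme = "s"),
                  c = structure("r", scheme = "s"))
  expect_equal(divRel(clusterAt(fpsDiff, 0.85)), 1)
  expect_equal(divRel(48L, 72L), 48 / 72)
  # higher cutoff => at least as many clusters
  s <- defaultSet(2L)
  fps <- lapply(s$structures[1:30], triangleFingerprint)
  cuts <- c(0.3, 0.5, 0.7, 0.85, 0.95)
  dr <- vapply(cuts, function(ct) divRel(clusterAt(fps, ct)), 0)
  expect_true(all(diff(dr) >= 0))
  expect_true(all(dr > 0 & dr <= 1))
})
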