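# Shared fixtures, built once per test run.

.fixtureEnv <- new.env(parent = emptyenv())

# default synthetic experimental set (cached; several test files use it)
defaultSet <- function(seed = 1L) {
  key <- paste0("set", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- generateExperimentalSet(generatorConfig(seed = seed))
  .fixtureEnv[[key]]
}

defaultMatrixAndLabels <- function(seed = 1L) {
  key <- paste0("ml", seed)
  if (is.null(.fixtureEnv[[key]])) {
    s <- defaultSet(seed)
    d <- compoundData(s$compounds)
    X <- buildDescriptorMatrix(s$compounds,
      extra_columns = grep("^noise", names(d), value = TRUE))
    y <- classifyActivity(d$residual_activity, ids = d$id)$class
    .fixtureEnv[[key]] <- list(X = X, y = y, set = s)
  }
  .fixtureEnv[[key]]
}

# small molecule battery parsed once
testMols <- function() {
  if (is.null(.fixtureEnv$mols))
    .fixtureEnv$mols <- molFromSmiles(c(
      eth = "CCO", ac = "CC(=O)O", tma = "C[N+](C)(C)C",
      amide = "CC(=O)NC", benzene = "c1ccccc1", pyridine = "c1ccncc1",
      phe = "NC(Cc1ccccc1)C(=O)O", amidine = "CC(=N)N",
      methane = "C", hal = "ClCCBr", amine2 = "CCNCC"))
  .fixtureEnv$mols
}

# closed-form ion-trap steady-state ratio oracle (Henderson-Hasselbalch):
# in the neutral-only, zero-potential, no-sorption limit the neutral
# activity equalizes, so C_in/C_out = (total/neutral)_in / (total/neutral)_out
ionTrapOracle <- function(profile, ph_in, ph_out) {
  fin <- fractionSpeciation(profile, ph_in)[["neutral"]]
  fout <- fractionSpeciation(profile, ph_out)[["neutral"]]
  fout / fin
}

# neutral-only, zero-potential, no-sorption parameter preset
neutralOnlyParams <- function(...) {
  cellModelParams(ionic_perm_offset = -Inf, lipid_frac = 0,
                  potentials_mV = c(cytosol = 0, lysosome = 0,
                                    mitochondrion = 0), ...)
}

# brute-force one-sided Fisher p by explicit enumeration over tables at
# least as enriched (independent of phyper)
bruteForceEnrichP <- function(k, m, K, N) {
  js <- max(0, k):min(m, K)
  sum(vapply(js, function(j)
    choose(K, j) * choose(N - K, m - j), 0)) / choose(N, m)
}
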