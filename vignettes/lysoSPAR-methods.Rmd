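---
title: "Modelling functional ASM inhibition: methods and design notes"
author: "lysoSPAR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling functional ASM inhibition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysoSPAR)
```

## The scientific problem

Acid sphingomyelinase (ASM) is a lysosomal enzyme that hydrolyses
sphingomyelin to ceramide. Many cationic amphiphilic drugs — lipophilic
weak bases — accumulate in lysosomes by ion trapping: the neutral species
diffuses across membranes, is protonated in the acidic lumen, and the
charged species is retained. High lysosomal drug concentrations detach ASM
from the inner lysosomal membrane and lead to its degradation. Such drugs
inhibit ASM *functionally* (without binding the enzyme) and are called
FIASMAs (Functional Inhibitors of Acid SphingoMyelinAse). The assay
endpoint is residual ASM activity in percent of a solvent control after
drug exposure; a compound is rated active at residual activity
$\le 50.0\%$ (inclusive threshold, `classifyActivity()`).

lysoSPAR implements the full analysis chain around this endpoint:
physicochemical descriptors, a kinetic cell model of lysosomal
accumulation, a random-forest structure–property–activity (SPAR)
classifier with rigorous internal validation, a structural-diversity
statistic, and virtual-screening enrichment analysis — plus a synthetic
data generator so the entire chain can be exercised and tested without
external databases.

## Descriptors

Raw inputs (logP, the two most basic pKa values, the most acidic pKa,
molecular weight, polar van-der-Waals surface area `vsa_pol`, H-bond
counts) are accepted as table columns: in practice they come from
commercial calculators and are treated as data, not recomputed. The
package derives:

* `logp_logweight` $= \log P - \tfrac12\log_{10} MW$ — a size-corrected
  lipophilicity that tracks diffusion through lipid phases; base-10
  logarithm, consistent with the logP scale.
* `pka_sum` $=$ pKa$_1$ + pKa$_2$ if pKa$_2 > 0$, else pKa$_1$ — captures
  the extra trapping of a second basic nitrogen without letting the
  0-imputation distort monobases.
* `pka_acid` — the most acidic pKa; ensures acids are recognized as
  inactive (they are excluded from acidic compartments).
* `si_vsa_pol` $=$ `vsa_pol` $/ MW$ — the size-intensive polar surface
  area (size-intensive forms give more compact, more stable models).
* Count descriptors from the molecular graph: quaternary nitrogens
  (`n_qN`), carboxylic acids (`n_COOH`), N+O (`n_OpN`), halogens
  (`n_hal`), halogens+carbons (`n_XpC`), amines (`n_amines`; sp3,
  non-aromatic, non-amide — the graph cannot distinguish finer amine
  typings without a charge model), and amidine/guanidine N–C=N motifs
  (`n_pdN`).

Missing-value rules are fixed and auditable (`imputeDescriptors()`):
basic pKa gaps $\to 0$, acidic pKa gaps $\to 15$, $k$ gaps $\to 12$; each
imputed cell is flagged. Ionization categories use the relevance
thresholds basic pKa $\ge 3$ and acidic pKa $< 10$; compounds whose pKa
values fall outside this biologically relevant range are category `none`.
`approxVsaPol()` offers a structure-based stand-in for `vsa_pol` (fixed
area increments per polar atom and polar hydrogen, donors and acceptors
both counting as polar); it is flagged as a surrogate and never silently
substitutes for the input column.

Partial-charge descriptors (maximum/summed atomic charges and the like)
are not implemented: no charge assigner is part of the package's
dependency set, and none of them enters the final model; they are
recorded as unavailable rather than approximated.

## The lysosomal ion-trapping cell model

`simulateAccumulation()` integrates a Fick–Nernst–Planck compartment
model: external medium, cytosol, lysosome and mitochondrion, with drug
exchanging across the plasma, lysosomal and mitochondrial membranes. Four
speciation variants (monoacid, monobase, bibase, zwitter) give
Henderson–Hasselbalch microspecies fractions per compartment pH;
compounds with no pKa in the relevant region run as a monoacid with
pKa 15 (effectively neutral). Per microspecies:

* neutral flux $\propto P_n (a_\mathrm{out} - a_\mathrm{in})$ on
  activities $a = W f_s C$ ($W$ = free aqueous fraction, $f_s$ = species
  fraction, $C$ = total concentration);
* ionic flux in the Goldman form
  $P_i N (a_\mathrm{out} - a_\mathrm{in} e^N)/(e^N - 1)$,
  $N = zFV/RT$, so ions feel the membrane potential;
* lipid sorption via $W = 1/(1 + K L)$ with
  $\log_{10} K = \log P - 1$ and lipid volume fraction $L$ (5 % in
  cellular compartments, none outside).

Defaults (all named, all overridable in `cellModelParams()`): pH 7.4
external (7.5 "dmem" preset), 7.2 cytosol, 5.0 lysosome, 8.0
mitochondrion; potentials $-70$ mV plasma, $+10$ mV lysosome, $-160$ mV
mitochondrion; temperature 310 K; neutral permeability
$\log_{10} P_n\,[\mu\mathrm{m/min}] = \log P$, capped by an aqueous
boundary layer of $10^5\,\mu$m/min; ionic permeability $10^{-3.5} P_n$;
external concentration 10 µM. Published cell models of this kind often
bury such constants inside spreadsheet formulas; here every constant is
explicit and overridable. The preset was chosen so that a typical
trapped monobase (logP 3, pKa 9) reaches 95 % of its lysosomal steady
state in roughly ten minutes — inside the standard 30-minute screening
window — while very high logP (boundary-layer-limited permeation combined
with growing sorption), very high pKa (vanishing neutral fraction) and
bibasic speciation (divalent trapping) push the required incubation to
hours, the qualitative kinetics the screening design relies on.

The system is linear and time-invariant, so steady states are solved
exactly (`steadyStateConcentrations()`, also used for the `CLys`
descriptor); ODE trajectories (deSolve, `lsoda`, rtol $10^{-8}$) are
cross-checked against them and against the closed-form ion-trap ratio in
the neutral-only, zero-potential, no-sorption limit (relative tolerance
$10^{-4}$ in the tests). `requiredIncubation()` reports the first time
lysosomal concentration reaches a stated fraction of steady state; which
fraction counts as "sufficient" is a modelling choice, and 0.95 is this
package's documented default.
Mitochondrial accumulation is simulated but not used downstream.
Not modelled: transporter-mediated uptake, drug-induced pH perturbation,
cytotoxicity.

## Classifier and validation

The learner is a binary random forest (backed by \pkg{ranger}) with the
canonical settings `ntree = 51`, `nodesize = 1`, maximal depth 8 and
`mtry = floor(log2(m)) + 1` (the literature convention for "log(m)+1";
a natural-log variant is available). Feature preparation: a unit-range
variance filter (threshold $10^{-8}$), then a candidate pool formed as
the union of the top-30 columns under correlation, information-gain and
Relief weighting.

Validation is 200-fold bootstrap with out-of-bag scoring: each resample
fits on a with-replacement draw of the rows and evaluates the Youden
index ($J =$ sensitivity $+$ specificity $- 1$, robust to the 204:72
class imbalance) and accuracy on the out-of-bag rows; resamples with a
single-class out-of-bag set are redrawn and logged. Reported SDs are
across-resample SDs. Among the ways to score a bootstrap resample,
out-of-bag evaluation is the standard unbiased choice and is what the
package implements; the .632 estimator was considered and not taken (one
estimator, clearly documented, beats a flag nobody exercises).

`beamSearch()` selects descriptor combinations per size (1..5, beam
width 10). As its "modified" search step the package scores candidate
combinations with 30 bootstrap resamples and re-validates every size
winner with the full 200: the standard error of a 30-resample mean Youden
($\approx 0.087/\sqrt{30} \approx 0.016$) is an order of magnitude below
typical between-combination gaps, so the ranking is stable while the
search stays tractable on one CPU. Ties break toward fewer descriptors,
then lexicographic names, making results reproducible. All stochastic
steps take explicit seeds fanned out from a master seed by a
counter-based scheme.

`yScramble()` refits and re-validates the chosen combination on uniformly
permuted labels (default 1000 permutations; scaled-down runs are labelled
as such by the pipeline) and reports the null mean ± SD and the
z-distance of the unpermuted score.

## Structural diversity

`triangleFingerprint()` is an open reimplementation of a typed-triangle
2D pharmacophore fingerprint: atoms typed as donor / acceptor / cation /
anion / aromatic / hydrophobe, all typed-atom triples keyed by their
types and binned topological distances (bins 1, 2, 3, 4–5, 6–8, 9+),
keys canonicalized over the six vertex orders. Molecules with fewer than
three typed atoms fall back to pair/single keys so the fingerprint is
total. Tanimoto similarity on key sets feeds complete-linkage
hierarchical clustering cut at similarity 0.85 — complete linkage is
chosen because it guarantees the "clusters at 0.85 similarity" reading
(every within-cluster pair $\ge 0.85$). The relative structural
diversity is `div_rel` $=$ clusters / compounds $\in (0, 1]$.

Because the original fingerprint dialect is proprietary, absolute
`div_rel` values of external compound collections are approximated, not
reproduced; the package asserts the measure's properties ($1/N$ for
identical sets, 1 for mutually dissimilar sets, monotone in the cutoff)
rather than printed values.

## Screening and enrichment

`virtualScreen()` applies the exclusion cascade in a fixed order:
compounds with incalculable required descriptors, then quaternary
nitrogens (no passive membrane crossing), then structural duplicates
keyed by OpenBabel canonical SMILES of the structure as given (first
occurrence kept) — a documented choice, since duplicates across salts or
registration entries admit several reasonable keys. Group enrichment uses
the
one-sided Fisher exact test as the hypergeometric tail toward
overrepresentation, Benjamini–Hochberg corrected at 0.05 across groups;
the global test over the group-by-class table is a chi-square
(Monte-Carlo p when expected counts are small) and is labelled an
approximation, since the one-sided alternative of a global exact test on
a large table is not well defined. The Rule-of-Five association uses the
Pearson chi-square without continuity correction (matching the printed
significance of the 2×2 association more closely than the Yates-corrected
variant, which remains available). Bimodality of residual activities is
assessed with a pooled Kolmogorov–Smirnov test against a normal with
estimated moments (the Lilliefors-corrected p is reported alongside) and
a two-component Gaussian mixture fitted by EM, initialized by splitting
at the 50 % threshold, with per-component KS tests.

## The synthetic-data generator

`generateExperimentalSet()` emulates the assay campaign the pipeline
expects: 276 compounds, ionization mix 23 acids / 155 monobases /
22 zwitterions / 45 bibases / 31 without a relevant group,
category-conditional pKa, logP, MW and polar-surface draws, and — the key
design decision — an activity class generated *through the descriptor
mechanism*: the probability of functional inhibition is logistic in
`logp_logweight`, `pka_sum`, `pka_acid` and `si_vsa_pol` (coefficients
2.9, 1.0, 0.75, −65, intercept −18.2). The intercept was solved once on a
large sample so the expected active fraction equals 72/276; the slopes
were calibrated once so the true 4-descriptor model validates at a mean
bootstrap Youden of about 0.62–0.69 (accuracy ≈ 0.87) — the performance
regime such campaigns operate in — and then frozen. Because activity
flows through
the descriptors, beam search has a recoverable planted signal, which is
what the package's end-to-end tests lean on. Residual activities are
drawn from two truncated Gaussian modes (35 ± 8 for actives, 85 ± 12 for
inactives, truncated to [0, 120] — activities slightly above control
occur in real assays); the replicate SD of 16 percentage points drives
the near-threshold reliability flag. Eight uncorrelated noise descriptors
are appended.

Structures are template SMILES families (amine, diamine, acid, amino
acid, neutral ether, quaternary ammonium decorations on ring scaffolds)
indexed so that every compound is structurally distinct; they exist to
exercise parsers, count descriptors, the quaternary-nitrogen filter and
fingerprints, and are *not* chemically consistent with the drawn
descriptor values — a deliberate non-goal. Consequently, passing tests
demonstrate the statistical machinery, not chemical realism: the
generator does not emulate assay plate effects, correlated descriptor
errors, congeneric series, or the chemical space of real natural-product
collections.

`generateLibrary()` plants screening structure: drug-like libraries draw
~7 % of compounds from the active-mechanism region (rejection sampling at
true probability > 0.7; clearly-inactive region < 0.05) and concentrate
them in configured enriched groups; natural-product-like libraries use a
sparse active fraction plus exact counts of incalculable, quaternary and
duplicate entries (defaults 13/2/17 in 800) to exercise the exclusion
arithmetic end to end.

## Problem sizes and numerical choices

The package's own test and validation runs use the full 276-compound
default set with 200 bootstrap folds for every reported score, 30-fold
scoring inside the beam, Y-scrambling scaled to 100 permutations (the
1000-permutation default remains for full runs and the scaled-down label
is carried in reports), 20 generator seeds for the bimodality recovery
checks and 120 random configurations for the cell-model/closed-form
equivalence. EM stops at a relative log-likelihood change of $10^{-8}$
(component SDs floored at $10^{-3}$ for numerical safety); ODE tolerances
are rtol $10^{-8}$ / atol $10^{-10}$; steady states come from the exact
linear solve. Degenerate inputs (identical residual activities,
single-class labels, empty fingerprint sets, single-atom molecules,
variant/pKa mismatches) raise typed errors or documented fallbacks rather
than propagating NaNs.

## Known limitations

* Descriptor inputs from commercial calculators are data; the package
  cannot validate them, and the structure-based `vsa_pol` surrogate is an
  approximation.
* The cell model's constants are a documented preset, not a fit to
  measured uptake kinetics; only its closed-form limits are exact.
* The fingerprint dialect is package-specific; absolute diversity values
  are not comparable across dialects.
* The generator's structures and descriptor values are decoupled;
  anything that requires structure–property consistency (e.g. training
  count descriptors as informative features) is outside its scope.
* The classifier is a qualitative (binary) predictor for small drug-like
  molecules; it does not predict potency.
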