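#' GeneratorConfig: synthetic compound-set generator settings
#'
#' The generator emulates the statistical structure of a cell-based
#' residual-activity assay campaign: a mix of ionization categories,
#' physicochemical descriptors drawn from category-conditional
#' distributions, an activity mechanism in which the probability of
#' functional inhibition is a logistic function of the four mechanistic
#' descriptors (weight-corrected logP, summed basic pKa, most acidic pKa
#' and size-intensive polar surface area), and a bimodal residual-activity
#' readout with truncation at 120\% of control. Template-based SMILES
#' structures exercise the parsers, count descriptors, quaternary-nitrogen
#' filters and fingerprints; they are not realistic chemistry.
#'
#' @slot n_compounds number of compounds (default 276).
#' @slot category_mix named proportions over acid, monobase, zwitter,
#'   bibase, none (defaults 23/155/22/45/31 out of 276).
#' @slot mechanism named list: logistic coefficients \code{intercept},
#'   \code{llw}, \code{pka_sum}, \code{pka_acid}, \code{si_vsa}.
#' @slot active_mode,inactive_mode c(mean, sd) of the residual-activity
#'   modes (defaults 35 +/- 8 and 85 +/- 12, truncated to
#'   \code{activity_bounds}).
#' @slot activity_bounds truncation bounds (default c(0, 120)).
#' @slot replicate_sd replicate standard deviation of the assay
#'   (percentage points, default 16; drives the reliability flag).
#' @slot n_noise_descriptors uncorrelated noise columns appended
#'   (default 8).
#' @slot n_groups,enriched_groups,enrichment_prob library group structure:
#'   number of ATC-like groups, which carry the actives, and the
#'   probability that an active-region compound lands in an enriched
#'   group.
#' @slot seed master seed.
#' @export
setClass("GeneratorConfig", representation(n_compounds = "integer",
  category_mix = "numeric", mechanism = "list", active_mode = "numeric",
  inactive_mode = "numeric", activity_bounds = "numeric",
  replicate_sd = "numeric", n_noise_descriptors = "integer",
  n_groups = "integer", enriched_groups = "character",
  enrichment_prob = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  if (abs(sum(object@category_mix) - 1) > 1e-9)
    return("category_mix must sum to 1")
  if (any(c(object@active_mode[2], object@inactive_mode[2],
            object@replicate_sd) <= 0))
    return("SDs must be > 0")
  if (object@n_compounds < 10L) return("n_compounds must be >= 10")
  TRUE
})

#' Construct a generator configuration
#'
#' Defaults reproduce the assay-campaign structure the analysis assumes:
#' 276 compounds, the 23/155/22/45/31 ionization-category mix, a
#' mechanism-driven active fraction near 72/276, bimodal residual
#' activity with modes near 35\% and 85\%, and a 16-point replicate SD.
#'
#' @param n_compounds number of compounds.
#' @param category_mix named proportions (acid, monobase, zwitter, bibase,
#'   none).
#' @param mechanism logistic mechanism coefficients.
#' @param active_mode,inactive_mode residual-activity modes c(mean, sd).
#' @param activity_bounds truncation bounds.
#' @param replicate_sd assay replicate SD.
#' @param n_noise_descriptors noise columns.
#' @param n_groups,enriched_groups,enrichment_prob library group structure.
#' @param seed master seed.
#' @return A \linkS4class{GeneratorConfig}.
#' @examples
#' generatorConfig(seed = 7)
#' @export
generatorConfig <- function(n_compounds = 276L,
    category_mix = c(acid = 23, monobase = 155, zwitter = 22, bibase = 45,
                     none = 31) / 276,
    mechanism = list(intercept = -18.2, llw = 2.9, pka_sum = 1.0,
                     pka_acid = 0.75, si_vsa = -65),
    active_mode = c(35, 8), inactive_mode = c(85, 12),
    activity_bounds = c(0, 120), replicate_sd = 16,
    n_noise_descriptors = 8L, n_groups = 20L,
    enriched_groups = c("G03", "G08", "G15"), enrichment_prob = 0.8,
    seed = 1L) {
  new("GeneratorConfig", n_compounds = as.integer(n_compounds),
      category_mix = category_mix[c("acid", "monobase", "zwitter",
                                    "bibase", "none")],
      mechanism = mechanism, active_mode = active_mode,
      inactive_mode = inactive_mode, activity_bounds = activity_bounds,
      replicate_sd = replicate_sd,
      n_noise_descriptors = as.integer(n_noise_descriptors),
      n_groups = as.integer(n_groups), enriched_groups = enriched_groups,
      enrichment_prob = enrichment_prob, seed = as.integer(seed))
}

#' @export
setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig: n=%d, seed=%d\n", object@n_compounds,
              object@seed))
  cat("  category mix:", paste(sprintf("%s %.3f",
      names(object@category_mix), object@category_mix), collapse = ", "),
      "\n")
})

.truncNorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
    if (guard > 1000L) { x[bad] <- pmin(pmax(x[bad], lo), hi); break }
  }
  x
}

# template SMILES families; index decodes injectively into chain lengths,
# ring variant and methyl branch, so structures within a category are
# mutually distinct
.ringVariants <- c("c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1",
                   "c1ccc(Br)cc1", "c1ccncc1", "C1CCCCC1",
                   "c1ccc2ccccc2c1")

.makeSmiles <- function(category, index) {
  a <- index %% 12L
  rest <- index %/% 12L
  b <- rest %% 8L
  rest <- rest %/% 8L
  r <- rest %% length(.ringVariants)
  m <- (rest %/% length(.ringVariants)) %% 2L
  ring <- .ringVariants[r + 1L]
  chainA <- paste0(strrep("C", a), if (m == 1L) "C(C)" else "")
  chainB <- strrep("C", b)
  # families whose two chains would sit on one linear backbone encode the
  # second index as a branch (and skip the methyl toggle) so every index
  # yields a structurally distinct molecule
  lin <- strrep("C", a)
  branch <- if (b == 0L) "" else paste0("C(", strrep("C", b), ")")
  switch(category,
    monobase = paste0(chainA, "CN(C)", chainB, "C", ring),
    bibase = paste0("CN(C)", chainA, "CCN(C)", chainB, "C", ring),
    zwitter = paste0("NC", chainA, "C(C", chainB, ring, ")C(=O)O"),
    acid = paste0("OC(=O)", lin, branch, "C", ring),
    none = paste0("CCO", lin, branch, "C", ring),
    quaternary = paste0("C[N+](C)(C)", lin, branch, "C", ring),
    stop("unknown structure family: ", category))
}

# draw physicochemical inputs for n compounds of one ionization category
.drawCategory <- function(category, n) {
  mw <- pmin(pmax(rlnorm(n, log(340), 0.30), 90), 850)
  logp <- pmin(pmax(rnorm(n, 3.2, 1.6), -2), 9)
  vsa_pol <- pmax(0.18 * mw + rnorm(n, 0, 15), 5)
  pka_base1 <- rep(NA_real_, n); pka_base2 <- rep(NA_real_, n)
  pka_acid <- rep(NA_real_, n)
  if (category == "acid") {
    pka_acid <- .truncNorm(n, 4.5, 1.5, 0.5, 9.9)
  } else if (category == "monobase") {
    pka_base1 <- .truncNorm(n, 9.0, 1.5, 3, 12.5)
  } else if (category == "bibase") {
    pka_base1 <- .truncNorm(n, 9.5, 1.2, 3, 12.5)
    pka_base2 <- pmin(.truncNorm(n, 7.5, 1.5, 3, 12), pka_base1)
  } else if (category == "zwitter") {
    pka_base1 <- .truncNorm(n, 8.0, 1.5, 3, 12.5)
    pka_acid <- .truncNorm(n, 4.5, 1.5, 0.5, 9.9)
  } else { # none: no group at all or out-of-range pKa values
    outish <- runif(n) < 22 / 31
    weakBase <- outish & runif(n) < 0.5
    weakAcid <- outish & !weakBase
    pka_base1[weakBase] <- runif(sum(weakBase), 0.5, 2.9)
    pka_acid[weakAcid] <- runif(sum(weakAcid), 10.1, 13.5)
  }
  data.frame(mw = mw, logp = logp, vsa_pol = vsa_pol,
             pka_base1 = pka_base1, pka_base2 = pka_base2,
             pka_acid = pka_acid, stringsAsFactors = FALSE)
}

# logistic activity mechanism on the four post-imputation descriptors
.mechanismEta <- function(d, mech) {
  llw <- logpLogWeight(d$logp, d$mw)
  pks <- pkaSumMod(ifelse(is.na(d$pka_base1), 0, d$pka_base1),
                   ifelse(is.na(d$pka_base2), 0, d$pka_base2))
  pac <- ifelse(is.na(d$pka_acid), 15, d$pka_acid)
  si <- d$vsa_pol / d$mw
  mech$intercept + mech$llw * llw + mech$pka_sum * pks +
    mech$pka_acid * pac + mech$si_vsa * si
}

#' Generate a synthetic experimental compound set
#'
#' Draws a compound table with the statistical structure the analysis
#' pipeline assumes (see \linkS4class{GeneratorConfig}): ionization
#' categories from the configured mix, category-conditional pKa/logP/
#' MW/polar-surface values, an activity class driven by the logistic
#' mechanism on the four mechanistic descriptors, a bimodal
#' residual-activity readout, uncorrelated noise descriptors, and
#' template SMILES structures consistent with the category. All
#' randomness derives from the config seed (bit-reproducible).
#'
#' @param config A \linkS4class{GeneratorConfig}.
#' @param with_structures parse the template SMILES into molecular graphs
#'   (default TRUE; skipping saves time when only the table is needed --
#'   the table is identical either way).
#' @return list: \code{compounds} (\linkS4class{CompoundSet} including
#'   noise columns), \code{structures} (named list of
#'   \linkS4class{MolGraph}; NULL when skipped), \code{truth} (mechanism
#'   record: per-compound true probability, class, category, coefficients,
#'   mechanistic descriptor names).
#' @examples
#' \donttest{
#' set_ <- generateExperimentalSet(generatorConfig(n_compounds = 40L))
#' nCompounds(set_$compounds)
#' }
#' @export
generateExperimentalSet <- function(config = generatorConfig(),
                                    with_structures = TRUE) {
  stopifnot(is(config, "GeneratorConfig"))
  n <- config@n_compounds
  withSeed(fanSeed(config@seed, 1L), {
    categories <- sample(names(config@category_mix), n, replace = TRUE,
                         prob = config@category_mix)
    if (!all(names(config@category_mix) %in% unique(categories)) &&
        n >= 50L)
      categories[seq_along(config@category_mix)] <-
        names(config@category_mix)
    d <- do.call(rbind, lapply(seq_len(n), function(i)
      .drawCategory(categories[i], 1L)))
    d$category <- categories
    eta <- .mechanismEta(d, config@mechanism)
    p <- plogis(eta)
    cls <- rbinom(n, 1L, p)
    mode_ <- rbind(config@inactive_mode, config@active_mode)[cls + 1L, ,
                                                            drop = FALSE]
    d$residual_activity <- vapply(seq_len(n), function(i)
      .truncNorm(1L, mode_[i, 1], mode_[i, 2], config@activity_bounds[1],
                 config@activity_bounds[2]), 0)
    d$k <- ifelse(categories %in% c("monobase", "bibase", "zwitter") &
                    runif(n) > 0.1, sample(2:12, n, replace = TRUE),
                  NA_real_)
    d$hbd <- pmin(rpois(n, 1 + d$vsa_pol / 60), 8L)
    d$hba <- pmin(rpois(n, d$vsa_pol / 18), 14L)
    slow <- d$logp > 6 | pkaSumMod(ifelse(is.na(d$pka_base1), 0,
                                          d$pka_base1),
                                   ifelse(is.na(d$pka_base2), 0,
                                          d$pka_base2)) > 12
    d$incubation_min <- ifelse(slow, sample(c(60, 120, 180), n,
                                            replace = TRUE), 30)
    # logBB for a literature-like subset; actives drawn BBB-permeant
    hasBB <- runif(n) < 64 / 276
    d$logbb <- NA_real_
    d$logbb[hasBB & cls == 1L] <-
      .truncNorm(sum(hasBB & cls == 1L), 0.5, 0.4, 0, Inf)
    d$logbb[hasBB & cls == 0L] <- rnorm(sum(hasBB & cls == 0L), -0.2, 0.6)
    counters <- integer(length(config@category_mix))
    names(counters) <- names(config@category_mix)
    smiles <- character(n)
    for (i in seq_len(n)) {
      smiles[i] <- .makeSmiles(categories[i], counters[[categories[i]]])
      counters[[categories[i]]] <- counters[[categories[i]]] + 1L
    }
    noise <- NULL
    if (config@n_noise_descriptors > 0L) {
      noise <- matrix(rnorm(n * config@n_noise_descriptors), n,
                      config@n_noise_descriptors)
      colnames(noise) <- sprintf("noise%02d",
                                 seq_len(config@n_noise_descriptors))
    }
    tab <- data.frame(id = sprintf("SYN%04d", seq_len(n)),
                      name = sprintf("synthetic-%04d", seq_len(n)),
                      smiles = smiles, d, stringsAsFactors = FALSE)
    if (!is.null(noise)) tab <- cbind(tab, noise)
    compounds <- CompoundSet(tab, provenance = "synthetic experimental set")
    structures <- if (with_structures) molFromSmiles(smiles, tab$id)
    truth <- list(mechanism = config@mechanism,
                  mechanistic_descriptors = c("logp_logweight", "pka_sum",
                                              "pka_acid", "si_vsa_pol"),
                  probability = p, class = cls, category = categories,
                  seed = config@seed)
    list(compounds = compounds, structures = structures, truth = truth)
  })
}

# rejection-sample one compound from the active (or clearly inactive)
# mechanism region
.drawRegion <- function(active, mech, max_tries = 500L) {
  cats_active <- c("monobase", "bibase")
  cats_all <- c("acid", "monobase", "zwitter", "bibase", "none")
  for (t in seq_len(max_tries)) {
    cat_ <- if (active) sample(cats_active, 1L) else
      sample(cats_all, 1L, prob = c(0.25, 0.25, 0.15, 0.05, 0.30))
    d <- .drawCategory(cat_, 1L)
    p <- plogis(.mechanismEta(d, mech))
    if ((active && p > 0.7) || (!active && p < 0.05)) {
      d$category <- cat_
      return(d)
    }
  }
  d$category <- cat_
  d
}

#' Generate a synthetic screening library
#'
#' \code{drug_like}: about 7\% of compounds are drawn from the
#' active-mechanism region and concentrated in the configured enriched
#' groups, the rest from the clearly-inactive region (a planted enrichment
#' signal). \code{natural_like}: a sparse active fraction (< 1\%), more
#' acids and neutral scaffolds, plus configurable counts of compounds with
#' incalculable descriptors, quaternary nitrogens and exact structural
#' duplicates to exercise the exclusion filters.
#'
#' @param config A \linkS4class{GeneratorConfig} (seed and group structure
#'   are used).
#' @param kind "drug_like" or "natural_like".
#' @param n library size (default 2000 drug-like, 800 natural-like).
#' @param n_incalculable entries with missing required inputs
#'   (natural-like default 13).
#' @param n_quaternary quaternary-nitrogen entries (default 2).
#' @param n_duplicates exact duplicate entries (default 17).
#' @param active_fraction fraction drawn from the active-mechanism region
#'   (default 0.07 drug-like, 0.007 natural-like).
#' @return list: \code{compounds} (\linkS4class{CompoundSet} with
#'   \code{atc_codes} group labels), \code{structures},
#'   \code{truth} (region flags and planted group enrichment).
#' @export
generateLibrary <- function(config = generatorConfig(),
    kind = c("drug_like", "natural_like"), n = NULL,
    n_incalculable = NULL, n_quaternary = NULL, n_duplicates = NULL,
    active_fraction = NULL) {
  kind <- match.arg(kind)
  n <- n %||% if (kind == "drug_like") 2000L else 800L
  n_incalculable <- n_incalculable %||% if (kind == "drug_like") 0L else 13L
  n_quaternary <- n_quaternary %||% 2L
  n_duplicates <- n_duplicates %||% 17L
  active_fraction <- active_fraction %||%
    if (kind == "drug_like") 0.07 else 0.007
  n_base <- n - n_incalculable - n_quaternary - n_duplicates
  stopifnot(n_base > 10L)
  withSeed(fanSeed(config@seed, if (kind == "drug_like") 2L else 3L), {
    mech <- config@mechanism
    isActive <- runif(n_base) < active_fraction
    rows <- lapply(seq_len(n_base), function(i)
      .drawRegion(isActive[i], mech))
    d <- do.call(rbind, rows)
    counters <- c(acid = 0L, monobase = 0L, zwitter = 0L, bibase = 0L,
                  none = 0L, quaternary = 0L)
    smiles <- character(n_base)
    for (i in seq_len(n_base)) {
      smiles[i] <- .makeSmiles(d$category[i], counters[[d$category[i]]])
      counters[[d$category[i]]] <- counters[[d$category[i]]] + 1L
    }
    groups <- sprintf("G%02d", seq_len(config@n_groups))
    plain <- setdiff(groups, config@enriched_groups)
    grp <- character(n_base)
    for (i in seq_len(n_base)) {
      grp[i] <- if (isActive[i] && runif(1) < config@enrichment_prob)
        sample(config@enriched_groups, 1L) else sample(plain, 1L)
    }
    ids <- sprintf("%s%04d", if (kind == "drug_like") "LIB" else "NAT",
                   seq_len(n_base))
    tab <- data.frame(id = ids, name = ids, smiles = smiles, d,
                      atc_codes = grp, stringsAsFactors = FALSE)
    tab$category <- NULL
    extra <- list()
    # entries with incalculable descriptors (missing logp)
    if (n_incalculable > 0L) {
      inc <- do.call(rbind, lapply(seq_len(n_incalculable), function(i)
        .drawRegion(FALSE, mech)))
      inc$logp <- NA_real_
      idsI <- sprintf("%sINC%03d", substr(ids[1], 1, 3),
                      seq_len(n_incalculable))
      smI <- character(n_incalculable)
      for (i in seq_len(n_incalculable)) {
        smI[i] <- .makeSmiles(inc$category[i],
                              counters[[inc$category[i]]])
        counters[[inc$category[i]]] <- counters[[inc$category[i]]] + 1L
      }
      inc$category <- NULL
      extra$inc <- data.frame(id = idsI, name = idsI, smiles = smI, inc,
                              atc_codes = sample(plain, n_incalculable,
                                                 replace = TRUE),
                              stringsAsFactors = FALSE)
    }
    # quaternary-nitrogen entries (calculable, so they reach filter 2)
    if (n_quaternary > 0L) {
      qd <- do.call(rbind, lapply(seq_len(n_quaternary), function(i)
        .drawRegion(FALSE, mech)))
      qd$category <- NULL
      idsQ <- sprintf("%sQAT%03d", substr(ids[1], 1, 3),
                      seq_len(n_quaternary))
      smQ <- vapply(seq_len(n_quaternary) - 1L, function(i)
        .makeSmiles("quaternary", i), "")
      extra$quat <- data.frame(id = idsQ, name = idsQ, smiles = smQ, qd,
                               atc_codes = sample(plain, n_quaternary,
                                                  replace = TRUE),
                               stringsAsFactors = FALSE)
    }
    # exact duplicates of base entries (identical structure, new id)
    if (n_duplicates > 0L) {
      src <- sample(seq_len(n_base), n_duplicates)
      dupTab <- tab[src, , drop = FALSE]
      dupTab$id <- sprintf("%sDUP%03d", substr(ids[1], 1, 3),
                           seq_len(n_duplicates))
      dupTab$name <- dupTab$id
      extra$dup <- dupTab
    }
    full <- rbind(tab, do.call(rbind, unname(extra)))
    full <- full[withSeed(fanSeed(config@seed, 9L),
                          sample(nrow(full))), , drop = FALSE]
    compounds <- CompoundSet(full, provenance = paste0("synthetic ",
                                                       gsub("_", "-", kind),
                                                       " library"))
    structures <- molFromSmiles(full$smiles, full$id)
    truth <- list(active_region = setNames(isActive, ids),
                  enriched_groups = config@enriched_groups,
                  group = setNames(grp, ids), seed = config@seed)
    list(compounds = compounds, structures = structures, truth = truth)
  })
}
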