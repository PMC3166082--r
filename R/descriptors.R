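#' Impute missing descriptor inputs
#'
#' Applies the documented gap-filling rules of the modelling pipeline:
#' missing most-basic pKa values (\code{pka_base1}, \code{pka_base2}) are
#' substituted by 0, a missing most-acidic pKa (\code{pka_acid}) by 15, and
#' a missing heavy-atom count at the most basic nitrogen (\code{k}) by 12.
#' Every imputed entry is flagged so the step stays auditable.
#'
#' @param x A \linkS4class{CompoundSet} or a data.frame with the pKa/k
#'   columns.
#' @return Object of the same class with gaps filled; the attribute (for a
#'   data.frame) or column set \code{imputed_fields} records, per compound,
#'   a semicolon-separated list of imputed fields ("" when none).
#' @examples
#' d <- data.frame(id = "x", mw = 300, pka_base1 = NA, pka_acid = NA, k = NA)
#' imputeDescriptors(d)[, c("pka_base1", "pka_acid", "k", "imputed_fields")]
#' @export
imputeDescriptors <- function(x) {
  isCS <- is(x, "CompoundSet")
  d <- if (isCS) compoundData(x) else as.data.frame(x)
  rules <- c(pka_base1 = 0, pka_base2 = 0, pka_acid = 15, k = 12)
  flags <- rep("", nrow(d))
  for (f in names(rules)) {
    if (!f %in% names(d)) d[[f]] <- NA_real_
    gap <- is.na(d[[f]])
    if (any(gap)) {
      d[[f]][gap] <- rules[[f]]
      flags[gap] <- ifelse(nzchar(flags[gap]),
                           paste(flags[gap], f, sep = ";"), f)
    }
  }
  d$imputed_fields <- flags
  if (isCS) CompoundSet(d, provenance = provenance(x)) else d
}

#' Classify the ionization category of a compound
#'
#' Categories follow the chemistry-driven convention of the assay set: a
#' basic group is relevant iff its pKa >= 3, an acidic group iff its
#' pKa < 10. \code{acid}: relevant acid only; \code{monobase}: exactly one
#' relevant base, no relevant acid; \code{bibase}: two relevant bases, no
#' relevant acid; \code{zwitter}: at least one relevant base plus a relevant
#' acid; \code{none}: no relevant group (no ionizable group at all, or all
#' pKa values outside the biologically relevant range).
#'
#' Inputs must be pre-imputation so that true missingness is visible.
#'
#' @param pka_base1,pka_base2,pka_acid optional reals (NA when absent);
#'   vectors are recycled to common length.
#' @return character vector of categories.
#' @examples
#' classifyIonization(9, NA, NA)        # monobase
#' classifyIonization(9, 8, 4)          # zwitter
#' classifyIonization(2.9, NA, 12)      # none
#' @export
classifyIonization <- function(pka_base1, pka_base2 = NA_real_,
                               pka_acid = NA_real_) {
  n <- max(length(pka_base1), length(pka_base2), length(pka_acid))
  b1 <- rep_len(as.numeric(pka_base1), n)
  b2 <- rep_len(as.numeric(pka_base2), n)
  ac <- rep_len(as.numeric(pka_acid), n)
  nBase <- (!is.na(b1) & b1 >= 3) + (!is.na(b2) & b2 >= 3)
  hasAcid <- !is.na(ac) & ac < 10
  out <- rep("none", n)
  out[hasAcid & nBase == 0L] <- "acid"
  out[!hasAcid & nBase == 1L] <- "monobase"
  out[!hasAcid & nBase >= 2L] <- "bibase"
  out[hasAcid & nBase >= 1L] <- "zwitter"
  out
}

#' Weight-corrected logP
#'
#' \code{logp - 0.5 * log10(mw)}: a molecular-weight correction of logP that
#' tracks the diffusion of small molecules through lipid phases more closely
#' than logP itself (as used for blood-brain-barrier permeation modelling).
#' The logarithm base (10) matches the logP scale.
#'
#' @param logp octanol-water log partition coefficient.
#' @param mw molecular weight (g/mol), > 0.
#' @return numeric.
#' @examples
#' logpLogWeight(5, 100)  # 4
#' @export
logpLogWeight <- function(logp, mw) {
  if (any(!is.na(mw) & mw <= 0)) stop("mw must be > 0", call. = FALSE)
  logp - 0.5 * log10(mw)
}

#' Modified sum of the two most basic pKa values
#'
#' Returns \code{pka_base1 + pka_base2} when the second basic pKa is
#' positive, else \code{pka_base1}; captures the impact of a second basic
#' nitrogen without letting the 0-imputation (or negative estimates)
#' distort single-base compounds. Inputs are post-imputation.
#'
#' @param pka_base1 most basic pKa.
#' @param pka_base2 second-most basic pKa (0 when originally missing).
#' @return numeric.
#' @examples
#' pkaSumMod(9.5, 8)   # 17.5
#' pkaSumMod(9.5, 0)   # 9.5
#' @export
pkaSumMod <- function(pka_base1, pka_base2) {
  ifelse(!is.na(pka_base2) & pka_base2 > 0,
         pka_base1 + pka_base2, pka_base1)
}

#' Size-intensive form of a descriptor
#'
#' Divides a descriptor by molecular weight; size-intensive descriptors
#' give more compact and more stable models for sets of molecules spanning
#' a range of sizes.
#'
#' @param value descriptor value.
#' @param mw molecular weight (g/mol), > 0.
#' @return \code{value / mw}.
#' @examples
#' sizeIntensive(50, 250)  # 0.2
#' @export
sizeIntensive <- function(value, mw) {
  if (any(!is.na(mw) & mw <= 0)) stop("mw must be > 0", call. = FALSE)
  value / mw
}

# does atom i have a neighbour satisfying pred(j, order)?
.neighbours <- function(g, i) {
  b <- g@bonds
  c(b$to[b$from == i], b$from[b$to == i])
}

.bondOrder <- function(g, i, j) {
  b <- g@bonds
  hit <- (b$from == i & b$to == j) | (b$from == j & b$to == i)
  if (any(hit)) b$order[which(hit)[1L]] else 0L
}

#' Count-based molecular descriptors
#'
#' Computes the structural count descriptors from a sanitized molecular
#' graph:
#' \describe{
#'   \item{n_qN}{quaternary nitrogen atoms: N bearing formal charge +1 with
#'     four heavy-atom/explicit connections (no attached H).}
#'   \item{n_COOH}{carboxylic acid functions C(=O)OH.}
#'   \item{n_OpN}{sum of nitrogen and oxygen atoms.}
#'   \item{n_hal}{halogen atoms (F, Cl, Br, I).}
#'   \item{n_XpC}{sum of halogen and carbon atoms.}
#'   \item{n_amines}{amine nitrogens: sp3 (all single bonds), non-aromatic,
#'     not amide (no neighbouring carbonyl carbon), not quaternary.}
#'   \item{n_pdN}{protonizable delocalized nitrogens in an N-C=N motif
#'     (amidine/guanidine carbons with both a single- and a double-bonded
#'     nitrogen).}
#' }
#'
#' @param g A \linkS4class{MolGraph}.
#' @return named integer vector.
#' @examples
#' countDescriptors(molFromSmiles(c(q1 = "C[N+](C)(C)C"))[[1]])["n_qN"]
#' @export
countDescriptors <- function(g) {
  if (!is(g, "MolGraph")) stop("g must be a MolGraph", call. = FALSE)
  a <- g@atoms
  if (!nrow(a)) stop("empty molecular graph", call. = FALSE)
  el <- a$element
  halogens <- c("F", "Cl", "Br", "I")
  n_hal <- sum(el %in% halogens)
  n_OpN <- sum(el %in% c("N", "O"))
  n_XpC <- n_hal + sum(el == "C")
  isN <- which(el == "N")
  n_qN <- 0L; n_amines <- 0L; n_pdN <- 0L
  for (i in isN) {
    if (a$charge[i] == 1L && a$degree[i] == 4L && a$nH[i] == 0L)
      n_qN <- n_qN + 1L
  }
  # carbonyl carbons (C with a double-bonded O)
  isC <- which(el == "C")
  carbonylC <- vapply(isC, function(i) {
    nb <- .neighbours(g, i)
    any(el[nb] == "O" & vapply(nb, function(j)
      .bondOrder(g, i, j) == 2L, TRUE))
  }, TRUE)
  carbonylSet <- isC[carbonylC]
  n_COOH <- 0L
  for (i in carbonylSet) {
    nb <- .neighbours(g, i)
    hasOH <- any(vapply(nb, function(j) {
      el[j] == "O" && .bondOrder(g, i, j) == 1L &&
        (a$nH[j] >= 1L || a$charge[j] == -1L)
    }, TRUE))
    if (hasOH) n_COOH <- n_COOH + 1L
  }
  for (i in isN) {
    if (a$aromatic[i]) next
    nb <- .neighbours(g, i)
    orders <- vapply(nb, function(j) .bondOrder(g, i, j), 0L)
    if (length(orders) && any(orders > 1L)) next       # sp2/sp N
    if (a$charge[i] == 1L && a$nH[i] == 0L && a$degree[i] == 4L) next
    if (any(nb %in% carbonylSet)) next                  # amide
    n_amines <- n_amines + 1L
  }
  # N-C=N motif: count amidine/guanidine carbons
  for (i in isC) {
    nb <- .neighbours(g, i)
    nbN <- nb[el[nb] == "N"]
    if (length(nbN) < 2L) next
    ords <- vapply(nbN, function(j) .bondOrder(g, i, j), 0L)
    if (any(ords == 2L) && any(ords == 1L)) n_pdN <- n_pdN + 1L
  }
  c(n_qN = n_qN, n_COOH = n_COOH, n_OpN = n_OpN, n_hal = n_hal,
    n_XpC = n_XpC, n_amines = n_amines, n_pdN = n_pdN)
}

#' Approximate polar van-der-Waals surface area from a structure
#'
#' Surrogate for the polar surface descriptor when it is not supplied as an
#' input column: a fixed-increment sum over polar heavy atoms (N, O) and
#' their attached hydrogens, with both hydrogen-bond donors and acceptors
#' counting as polar. This is a documented approximation, not a replacement
#' for a calculator-derived value; results carry attribute
#' \code{surrogate = TRUE}.
#'
#' @param g A \linkS4class{MolGraph}.
#' @param heavy_increment surface increment per polar heavy atom (A^2).
#' @param h_increment increment per polar hydrogen (A^2).
#' @return approximate polar surface area in A^2.
#' @export
approxVsaPol <- function(g, heavy_increment = 9.2, h_increment = 4.6) {
  stopifnot(is(g, "MolGraph"))
  a <- g@atoms
  polar <- a$element %in% c("N", "O")
  out <- heavy_increment * sum(polar) + h_increment * sum(a$nH[polar])
  attr(out, "surrogate") <- TRUE
  out
}

#' Lipinski Rule-of-Five violation
#'
#' Counts contradictions to the four rules (strict inequalities:
#' mw > 500, logp > 5, hbd > 5, hba > 10); a compound violates the
#' Rule-of-Five when any rule fires. Compounds with a missing input are
#' flagged not evaluable (\code{NA} count) so they can be excluded from
#' downstream contingency tables.
#'
#' @param mw molecular weight (g/mol).
#' @param logp octanol-water log partition coefficient.
#' @param hbd H-bond donor count.
#' @param hba H-bond acceptor count.
#' @return data.frame with integer \code{count} (0..4, NA when not
#'   evaluable) and logical \code{violated}.
#' @examples
#' lipinskiViolation(500, 5, 5, 10)       # boundary: no violation
#' lipinskiViolation(366.3, 5.45, 1, 3)   # logp fires
#' @export
lipinskiViolation <- function(mw, logp, hbd, hba) {
  n <- max(length(mw), length(logp), length(hbd), length(hba))
  mw <- rep_len(as.numeric(mw), n); logp <- rep_len(as.numeric(logp), n)
  hbd <- rep_len(as.numeric(hbd), n); hba <- rep_len(as.numeric(hba), n)
  evaluable <- !(is.na(mw) | is.na(logp) | is.na(hbd) | is.na(hba))
  count <- ifelse(evaluable,
                  (mw > 500) + (logp > 5) + (hbd > 5) + (hba > 10),
                  NA_integer_)
  data.frame(count = as.integer(count), violated = count > 0L)
}

#' Build the descriptor matrix for modelling
#'
#' Assembles, per compound, the derived descriptors of the classification
#' pipeline from a (pre-imputation) compound table: the weight-corrected
#' logP \code{logp_logweight}, the modified basic pKa sum \code{pka_sum},
#' the most acidic pKa \code{pka_acid}, the size-intensive polar surface
#' area \code{si_vsa_pol} (= vsa_pol / mw), plus \code{mw}, \code{k} and,
#' when structures are given, the count descriptors. Imputation is applied
#' first (see \code{\link{imputeDescriptors}}).
#'
#' @param x A \linkS4class{CompoundSet}.
#' @param structures optional named list of \linkS4class{MolGraph} keyed by
#'   compound id (adds count descriptors; compounds without a structure get
#'   NA counts).
#' @param extra_columns additional numeric columns of \code{x} to carry
#'   through unchanged (e.g. generated noise descriptors).
#' @return numeric matrix, rows = compound ids, with attribute
#'   \code{imputed_fields}.
#' @export
buildDescriptorMatrix <- function(x, structures = NULL,
                                  extra_columns = NULL) {
  stopifnot(is(x, "CompoundSet"))
  d0 <- compoundData(x)
  d <- compoundData(imputeDescriptors(x))
  m <- cbind(
    logp_logweight = logpLogWeight(d$logp, d$mw),
    pka_sum = pkaSumMod(d$pka_base1, d$pka_base2),
    pka_acid = d$pka_acid,
    si_vsa_pol = sizeIntensive(d$vsa_pol, d$mw),
    mw = d$mw,
    k = d$k)
  if (!is.null(structures)) {
    cn <- c("n_qN", "n_COOH", "n_OpN", "n_hal", "n_XpC", "n_amines", "n_pdN")
    counts <- matrix(NA_real_, nrow(d), length(cn),
                     dimnames = list(NULL, cn))
    for (i in seq_len(nrow(d))) {
      g <- structures[[d$id[i]]]
      if (!is.null(g)) counts[i, ] <- countDescriptors(g)
    }
    m <- cbind(m, counts)
  }
  if (!is.null(extra_columns)) {
    keep <- intersect(extra_columns, names(d))
    if (length(keep))
      m <- cbind(m, as.matrix(d[, keep, drop = FALSE]))
  }
  rownames(m) <- d$id
  attr(m, "imputed_fields") <- d$imputed_fields
  m
}
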