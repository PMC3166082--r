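#' Classify functional inhibition from residual activity
#'
#' A residual ASM activity <= 50.0\% of solvent control is rated active
#' (class 1); the threshold is inclusive. Calls within one replicate
#' standard deviation of the threshold (default 16 percentage points, the
#' typical replicate SD of the assay) are flagged low-reliability.
#'
#' @param residual residual ASM activity in percent (>= 0).
#' @param sd replicate standard deviation in percentage points
#'   (default 16).
#' @param ids optional compound ids.
#' @param threshold activity threshold (default 50.0).
#' @return data.frame (id, residual_activity, class, reliable).
#' @examples
#' classifyActivity(c(44.1, 50.0, 50.1))
#' @export
classifyActivity <- function(residual, sd = 16, ids = NULL,
                             threshold = 50.0) {
  if (any(is.na(residual)))
    stop("residual activity must be present", call. = FALSE)
  if (any(residual < 0))
    stop("residual activity must be >= 0", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(residual))
  data.frame(id = ids, residual_activity = residual,
             class = as.integer(residual <= threshold),
             reliable = abs(residual - threshold) >= sd,
             stringsAsFactors = FALSE)
}

# two-component univariate Gaussian mixture by EM, initialized by
# splitting at the activity threshold (50)
.gaussianMixEM <- function(x, split = 50, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  lo <- x[x <= split]; hi <- x[x > split]
  if (length(lo) < 2L || length(hi) < 2L) {
    qs <- stats::quantile(x, c(0.25, 0.75))
    lo <- x[x <= stats::median(x)]; hi <- x[x > stats::median(x)]
    if (length(lo) < 2L || length(hi) < 2L)
      stop("degenerate input: cannot initialize mixture", call. = FALSE)
  }
  mu <- c(mean(lo), mean(hi))
  sig <- pmax(c(sd(lo), sd(hi)), 1e-3)
  lambda <- c(length(lo), length(hi)) / n
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- lambda[1] * dnorm(x, mu[1], sig[1])
    d2 <- lambda[2] * dnorm(x, mu[2], sig[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    lambda <- c(mean(r), 1 - mean(r))
    if (any(lambda < 1e-8)) break
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sig <- sqrt(pmax(c(sum(r * (x - mu[1])^2) / sum(r),
                       sum((1 - r) * (x - mu[2])^2) / sum(1 - r)), 1e-6))
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  list(means = mu[ord], sds = sig[ord], weights = lambda[ord],
       responsibility = if (ord[1] == 1) r else 1 - r,
       loglik = ll_old, converged = converged)
}

#' Bimodality analysis of residual activities
#'
#' Tests the pooled sample against a single normal distribution
#' (two-sided Kolmogorov-Smirnov with estimated mean/SD; the
#' Lilliefors-corrected p value is reported alongside), fits a
#' two-component Gaussian mixture by EM (initialized by splitting at the
#' activity threshold of 50), and KS-tests normality within each fitted
#' component.
#'
#' @param residuals residual activities in percent, n >= 20.
#' @param split initialization split point (default 50).
#' @return list: \code{ks_p_overall}, \code{lilliefors_p}, \code{means},
#'   \code{sds}, \code{weights}, \code{ks_p_components}, \code{converged},
#'   \code{assignment} (hard component labels 1 = lower mode).
#' @export
bimodalityAnalysis <- function(residuals, split = 50) {
  x <- as.numeric(residuals)
  if (length(x) < 20L) stop("need n >= 20", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate input: all values identical", call. = FALSE)
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  lil <- tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA)
  fit <- tryCatch(.gaussianMixEM(x, split = split), error = function(e) NULL)
  if (is.null(fit)) {
    return(list(ks_p_overall = ks$p.value, lilliefors_p = lil,
                means = mean(x), sds = sd(x), weights = 1,
                ks_p_components = NA_real_, converged = FALSE,
                assignment = rep(1L, length(x)),
                note = "EM failed; single-Gaussian fallback"))
  }
  assign_ <- ifelse(fit$responsibility >= 0.5, 1L, 2L)
  ksc <- vapply(1:2, function(k) {
    xs <- x[assign_ == k]
    if (length(xs) < 5L || sd(xs) == 0) return(NA_real_)
    suppressWarnings(ks.test(xs, "pnorm", mean(xs), sd(xs)))$p.value
  }, 0)
  list(ks_p_overall = ks$p.value, lilliefors_p = lil, means = fit$means,
       sds = fit$sds, weights = fit$weights, ks_p_components = ksc,
       converged = fit$converged, assignment = assign_)
}

#' Virtual screening of a compound library
#'
#' Applies the exclusion cascade and classifies the remaining compounds
#' with a fitted model. Exclusion order: (1) compounds whose required
#' descriptors are incalculable (missing non-imputable inputs), (2)
#' compounds with a quaternary nitrogen atom (no passive membrane
#' crossing), (3) structural duplicates (canonical-SMILES identity, first
#' occurrence kept).
#'
#' @param library A \linkS4class{CompoundSet}.
#' @param model an \code{asmForest} from \code{\link{fitForest}}.
#' @param structures optional named list of \linkS4class{MolGraph} keyed by
#'   compound id (enables the quaternary-N and duplicate filters; without
#'   structures those counts are 0).
#' @param descriptor_matrix optional precomputed descriptor matrix
#'   (rows = library ids); computed via
#'   \code{\link{buildDescriptorMatrix}} when absent.
#' @param library_tag free-text tag.
#' @return A \linkS4class{ScreenResult}.
#' @export
virtualScreen <- function(library, model, structures = NULL,
                          descriptor_matrix = NULL,
                          library_tag = provenance(library)) {
  stopifnot(is(library, "CompoundSet"), inherits(model, "asmForest"))
  if (is.null(descriptor_matrix))
    descriptor_matrix <- buildDescriptorMatrix(library, structures,
      extra_columns = setdiff(model$descriptors, c("logp_logweight",
        "pka_sum", "pka_acid", "si_vsa_pol", "mw", "k", "n_qN", "n_COOH",
        "n_OpN", "n_hal", "n_XpC", "n_amines", "n_pdN")))
  miss <- setdiff(model$descriptors, colnames(descriptor_matrix))
  if (length(miss))
    stop("descriptors not computable for this library: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- compoundIds(library)
  X <- descriptor_matrix[ids, model$descriptors, drop = FALSE]
  excl <- data.frame(id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  # 1. incalculable descriptors
  calc <- complete.cases(X)
  if (any(!calc))
    excl <- rbind(excl, data.frame(id = ids[!calc],
                                   reason = "incalculable"))
  keep <- ids[calc]
  # 2. quaternary nitrogen
  isQuat <- vapply(keep, function(id) {
    g <- structures[[id]]
    !is.null(g) && countDescriptors(g)[["n_qN"]] >= 1L
  }, TRUE)
  if (any(isQuat))
    excl <- rbind(excl, data.frame(id = keep[isQuat],
                                   reason = "quaternary_nitrogen"))
  keep <- keep[!isQuat]
  # 3. structural duplicates (first occurrence kept)
  canon <- vapply(keep, function(id) {
    g <- structures[[id]]
    if (is.null(g)) paste0("id:", id) else {
      cs <- canonicalSmiles(g)
      if (is.na(cs)) paste0("id:", id) else cs
    }
  }, "")
  dup <- duplicated(canon)
  if (any(dup))
    excl <- rbind(excl, data.frame(id = keep[dup], reason = "duplicate"))
  keep <- keep[!dup]
  if (!length(keep))
    stop("no compounds left after exclusion filters", call. = FALSE)
  pred <- predict(model, X[keep, , drop = FALSE])
  new("ScreenResult", library_tag = library_tag,
      n_input = length(ids),
      n_excluded_incalculable = sum(!calc),
      n_excluded_quaternary = sum(isQuat),
      n_excluded_duplicates = sum(dup),
      predictions = data.frame(id = keep, predicted_class = pred,
                               stringsAsFactors = FALSE),
      exclusions = excl, enrichment = data.frame(), global_test = list())
}

#' One-sided hypergeometric enrichment p value
#'
#' Probability of observing at least \code{k} actives in a group of size
#' \code{m}, drawing from \code{n_active} actives among \code{n_total}
#' compounds (Fisher's exact test, one-sided towards enrichment).
#'
#' @param k actives in the group.
#' @param m group size.
#' @param n_active total actives.
#' @param n_total total compounds.
#' @return p value.
#' @export
enrichmentP <- function(k, m, n_active, n_total) {
  phyper(k - 1, n_active, n_total - n_active, m, lower.tail = FALSE)
}

#' Group enrichment of predicted actives
#'
#' Per-group 2x2 tables (in-group vs rest, active vs inactive) tested with
#' the one-sided Fisher exact test (hypergeometric tail towards
#' enrichment) and Benjamini-Hochberg correction across groups at level
#' \code{alpha}. Compounds may carry several group memberships and are
#' counted once per group. A global group-by-class contingency test
#' (chi-square, Monte-Carlo p when any expected count is small) is
#' reported as an approximation of a global exact test.
#'
#' @param calls data.frame with columns \code{id} and
#'   \code{predicted_class} (0/1).
#' @param groups data.frame with columns \code{id} and \code{group}; or a
#'   named list id -> character vector of group ids.
#' @param alpha BH significance level (default 0.05).
#' @param mc_seed seed for the Monte-Carlo global test.
#' @return list with \code{table} (per-group rows: group, n_group,
#'   active_in, inactive_in, active_out, inactive_out, p, p_adjusted,
#'   enriched) and \code{global} (statistic, p, method).
#' @export
groupEnrichment <- function(calls, groups, alpha = 0.05, mc_seed = 1L) {
  stopifnot(all(c("id", "predicted_class") %in% names(calls)))
  if (is.list(groups) && !is.data.frame(groups)) {
    groups <- data.frame(
      id = rep(names(groups), lengths(groups)),
      group = unlist(groups, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  groups <- groups[groups$id %in% calls$id, , drop = FALSE]
  gids <- sort(unique(groups$group))
  if (length(gids) < 2L) stop("need >= 2 groups", call. = FALSE)
  cls <- setNames(calls$predicted_class, calls$id)
  n_total <- nrow(calls)
  n_active <- sum(calls$predicted_class == 1L)
  rows <- lapply(gids, function(gg) {
    members <- unique(groups$id[groups$group == gg])
    m <- length(members)
    if (m == 0L) return(NULL)
    k <- sum(cls[members] == 1L)
    data.frame(group = gg, n_group = m, active_in = k,
               inactive_in = m - k, active_out = n_active - k,
               inactive_out = (n_total - n_active) - (m - k),
               p = enrichmentP(k, m, n_active, n_total),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- p.adjust(tab$p, method = "BH")
  tab$enriched <- tab$p_adjusted < alpha
  # global contingency test over group x class (approximation)
  cont <- rbind(active = tab$active_in, inactive = tab$inactive_in)
  useMC <- any(suppressWarnings(chisq.test(cont))$expected < 5)
  gl <- withSeed(mc_seed, suppressWarnings(
    chisq.test(cont, simulate.p.value = useMC, B = 2000)))
  list(table = tab,
       global = list(statistic = unname(gl$statistic), p = gl$p.value,
                     method = if (useMC)
                       "chi-square, Monte-Carlo p (approximation)"
                     else "chi-square (approximation)"))
}

#' Association of Rule-of-Five violation with functional inhibition
#'
#' Pearson chi-square test (without continuity correction) of the 2x2
#' table class x Rule-of-Five violation, with per-class violation
#' percentages.
#'
#' @param classes experimental classes (0/1).
#' @param violations logical Rule-of-Five violation per compound
#'   (NA = not evaluable, excluded).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list: \code{counts} (2x2 matrix), \code{chi_square}, \code{p},
#'   \code{pct_violation_active}, \code{pct_violation_inactive}.
#' @export
rofAssociation <- function(classes, violations, correct = FALSE) {
  keep <- !is.na(violations) & !is.na(classes)
  classes <- classes[keep]; violations <- violations[keep]
  if (length(unique(classes)) < 2L)
    stop("both classes must be present", call. = FALSE)
  counts <- table(factor(violations, levels = c(FALSE, TRUE)),
                  factor(classes, levels = c(1, 0)))
  dimnames(counts) <- list(violation = c("none", "violated"),
                           class = c("active", "inactive"))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("a zero margin makes the test undefined", call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  list(counts = unclass(counts),
       chi_square = unname(ct$statistic), p = ct$p.value,
       pct_violation_active = 100 * counts["violated", "active"] /
         sum(counts[, "active"]),
       pct_violation_inactive = 100 * counts["violated", "inactive"] /
         sum(counts[, "inactive"]))
}

#' Association of blood-brain-barrier penetration with inhibition
#'
#' Cross-tabulates activity class against good BBB penetration
#' (logBB >= 0) for the compounds with a logBB value, and lists actives
#' with logBB < 0 as violations of the expected pattern (reported, not
#' fatal).
#'
#' @param classes classes (0/1).
#' @param logbb logBB values (NA allowed).
#' @param ids optional compound ids.
#' @return list: \code{table} (2x2), \code{n_with_logbb},
#'   \code{violations} (ids of actives with logBB < 0).
#' @export
logbbAssociation <- function(classes, logbb, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(classes))
  keep <- !is.na(logbb)
  if (!any(keep)) {
    warning("no logBB data available")
    return(list(table = NULL, n_with_logbb = 0L, violations = character()))
  }
  cls <- classes[keep]; bb <- logbb[keep]; idk <- ids[keep]
  tab <- table(class = factor(cls, levels = c(0, 1)),
               crosses_bbb = factor(bb >= 0, levels = c(FALSE, TRUE)))
  list(table = unclass(tab), n_with_logbb = sum(keep),
       violations = idk[cls == 1 & bb < 0])
}
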