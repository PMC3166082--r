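#' Youden index from a 2x2 confusion table
#'
#' \code{sensitivity + specificity - 1}; the primary performance measure
#' for the imbalanced two-class problem. Both classes must be represented
#' among the true labels.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (class 1 = positive).
#' @return Youden index in [-1, 1].
#' @examples
#' youden(10, 0, 20, 0)  # 1
#' youden(5, 10, 10, 5)  # 0
#' @export
youden <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0)
    stop("undefined metric: a class is empty", call. = FALSE)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Zero-rule baseline accuracy
#'
#' Accuracy of the classifier that always predicts the majority class.
#'
#' @param labels vector of class labels.
#' @return majority-class frequency.
#' @examples
#' zeroRule(rep(c(0, 1), c(204, 72)))  # 0.7391...
#' @export
zeroRule <- function(labels) {
  if (!length(labels)) stop("labels must be non-empty", call. = FALSE)
  max(table(labels)) / length(labels)
}

#' Remove features with very low variance
#'
#' Columns are scaled to unit range and removed when the scaled variance
#' falls below \code{threshold}; constant columns always fall.
#'
#' @param x numeric matrix (rows = compounds).
#' @param threshold variance threshold after unit-range scaling
#'   (default 1e-8).
#' @return character vector of retained column names.
#' @export
varianceFilter <- function(x, threshold = 1e-8) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  keep <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    rng <- diff(range(v))
    if (!is.finite(rng) || rng == 0) return(FALSE)
    var((v - min(v)) / rng) >= threshold
  }, TRUE)
  if (!any(keep))
    stop("variance filter removed every column", call. = FALSE)
  colnames(x)[keep]
}

# information gain of the best binary split of v against binary labels
.bestSplitIG <- function(v, y) {
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(y)
  H0 <- ent(table(y) / n)
  o <- order(v)
  vs <- v[o]; ys <- y[o]
  cut_idx <- which(diff(vs) > 0)
  if (!length(cut_idx)) return(0)
  best <- 0
  cum1 <- cumsum(ys == levels(factor(y))[2] | ys == 1)
  for (i in cut_idx) {
    nl <- i; nr <- n - i
    p1l <- cum1[i] / nl; p1r <- (cum1[n] - cum1[i]) / nr
    H <- (nl / n) * ent(c(p1l, 1 - p1l)) + (nr / n) * ent(c(p1r, 1 - p1r))
    gain <- H0 - H
    if (gain > best) best <- gain
  }
  best
}

# classic Relief weights: one nearest hit/miss per instance, features
# scaled to unit range; deterministic (all instances visited once)
.reliefWeights <- function(x, y) {
  n <- nrow(x); m <- ncol(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  xs <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  w <- numeric(m)
  d2 <- as.matrix(dist(xs))
  diag(d2) <- Inf
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_ <- which(y != y[i])
    if (!length(same) || !length(diff_)) next
    hit <- same[which.min(d2[i, same])]
    miss <- diff_[which.min(d2[i, diff_])]
    w <- w - abs(xs[i, ] - xs[hit, ]) / n + abs(xs[i, ] - xs[miss, ]) / n
  }
  setNames(w, colnames(x))
}

#' Label-relevance weighting of features
#'
#' Scores each descriptor column against the binary class labels by one of
#' three filter methods: absolute Pearson \code{correlation}, best-split
#' \code{information_gain} (bits), or classic \code{relief} (one nearest
#' hit/miss per instance). Higher weight = more label-relevant.
#'
#' @param x numeric matrix, named columns.
#' @param labels binary labels (0/1), both classes present with >= 2 rows
#'   each.
#' @param method weighting method.
#' @return named numeric vector of weights.
#' @export
weightFeatures <- function(x, labels,
                           method = c("correlation", "information_gain",
                                      "relief")) {
  method <- match.arg(method)
  y <- as.integer(as.character(factor(labels, levels = sort(unique(labels)),
                                      labels = seq_along(unique(labels)) - 1)))
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need >= 2 rows in each of two classes", call. = FALSE)
  switch(method,
    correlation = {
      w <- abs(apply(x, 2, function(v)
        if (sd(v) == 0) 0 else cor(v, y)))
      setNames(as.numeric(w), colnames(x))
    },
    information_gain = setNames(
      vapply(seq_len(ncol(x)), function(j) .bestSplitIG(x[, j], y), 0),
      colnames(x)),
    relief = .reliefWeights(x, y))
}

#' Candidate descriptor pool from a union of weighting methods
#'
#' Takes the top \code{q} columns under each weighting method and returns
#' their union, after the low-variance filter.
#'
#' @param x numeric matrix.
#' @param labels binary labels.
#' @param q top columns kept per method (default 30).
#' @param methods weighting methods to combine.
#' @param variance_threshold passed to \code{\link{varianceFilter}}.
#' @return character vector of candidate column names (matrix column
#'   order).
#' @export
selectCandidates <- function(x, labels, q = 30L,
                             methods = c("correlation", "information_gain",
                                         "relief"),
                             variance_threshold = 1e-8) {
  keep <- varianceFilter(x, variance_threshold)
  xf <- x[, keep, drop = FALSE]
  chosen <- character()
  for (m in methods) {
    w <- weightFeatures(xf, labels, m)
    chosen <- union(chosen, names(sort(w, decreasing = TRUE))[
      seq_len(min(q, length(w)))])
  }
  intersect(colnames(x), chosen)
}

#' Fit the binary random-forest classifier
#'
#' Ensemble of \code{ntree} depth-limited trees (Gini splits) trained on
#' bootstrap resamples of the rows, with
#' \code{mtry = floor(log2(m)) + 1} attributes sampled per split.
#' Deterministic given the spec seed. Backed by \pkg{ranger}.
#'
#' @param x numeric matrix of descriptors.
#' @param labels binary labels (0/1), both classes present.
#' @param spec A \linkS4class{ForestSpec}.
#' @return object of class \code{asmForest}.
#' @export
fitForest <- function(x, labels, spec = forestSpec()) {
  y <- factor(labels, levels = c(0, 1))
  if (length(unique(labels)) < 2L)
    stop("single-class input", call. = FALSE)
  if (any(is.na(x))) stop("descriptor matrix contains missing values",
                          call. = FALSE)
  fit <- ranger::ranger(x = x, y = y, num.trees = spec@ntree,
                        mtry = mtryFor(spec, ncol(x)),
                        min.node.size = spec@nodesize,
                        max.depth = spec@maxdepth, num.threads = 1L,
                        seed = spec@seed, verbose = FALSE)
  structure(list(fit = fit, descriptors = colnames(x), spec = spec),
            class = "asmForest")
}

#' @rdname fitForest
#' @param object An \code{asmForest}.
#' @param newdata numeric matrix with the model's descriptor columns.
#' @param ... unused.
#' @return \code{predict}: integer vector of predicted classes (0/1).
#' @export
predict.asmForest <- function(object, newdata, ...) {
  nd <- newdata[, object$descriptors, drop = FALSE]
  p <- predict(object$fit, nd, num.threads = 1L, verbose = FALSE)$predictions
  as.integer(as.character(p))
}

#' @export
print.asmForest <- function(x, ...) {
  cat(sprintf("asmForest: %d trees on %d descriptors (%s)\n",
              x$spec@ntree, length(x$descriptors),
              paste(x$descriptors, collapse = ", ")))
  invisible(x)
}

.confusion <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Bootstrap validation of the forest classifier
#'
#' For each of \code{n_resamples} bootstrap resamples, fits the forest on
#' the with-replacement sample and evaluates Youden index and accuracy on
#' the out-of-bag rows. Resamples whose out-of-bag set contains a single
#' class are redrawn (logged); more than 50\% redraws is an error.
#'
#' @param x numeric descriptor matrix.
#' @param labels binary labels (0/1).
#' @param spec A \linkS4class{ForestSpec}.
#' @param n_resamples number of bootstrap resamples (default 200).
#' @param seed master seed for the resampling plan.
#' @return A \linkS4class{ValidationReport}.
#' @export
bootstrapValidate <- function(x, labels, spec = forestSpec(),
                              n_resamples = 200L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("single-class input", call. = FALSE)
  n <- nrow(x)
  y <- as.integer(labels)
  yv <- numeric(n_resamples); av <- numeric(n_resamples)
  sv <- numeric(n_resamples); pv <- numeric(n_resamples)
  redrawn <- 0L
  for (b in seq_len(n_resamples)) {
    attempt <- 0L
    repeat {
      idx <- withSeed(fanSeed(seed, b * 131L + attempt),
                      sample.int(n, n, replace = TRUE))
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) >= 2L && length(unique(y[oob])) == 2L &&
          length(unique(y[idx])) == 2L) break
      attempt <- attempt + 1L; redrawn <- redrawn + 1L
      if (redrawn > n_resamples / 2)
        stop("more than 50% of bootstrap resamples redrawn", call. = FALSE)
    }
    bspec <- spec; bspec@seed <- fanSeed(seed, b)
    fit <- fitForest(x[idx, , drop = FALSE], y[idx], bspec)
    pred <- predict(fit, x[oob, , drop = FALSE])
    cm <- .confusion(y[oob], pred)
    yv[b] <- youden(cm["tp"], cm["fp"], cm["tn"], cm["fn"])
    av[b] <- (cm["tp"] + cm["tn"]) / length(oob)
    sv[b] <- cm["tp"] / (cm["tp"] + cm["fn"])
    pv[b] <- cm["tn"] / (cm["tn"] + cm["fp"])
  }
  if (redrawn > 0L)
    logMsg("bootstrap", redrawn, " resample(s) redrawn for single-class OOB")
  new("ValidationReport", youden = yv, accuracy = av, sensitivity = sv,
      specificity = pv, n_resamples = as.integer(n_resamples),
      seed = as.integer(seed), descriptors = colnames(x),
      n_redrawn = redrawn)
}

.comboKey <- function(cols) paste(sort(cols), collapse = "+")

#' Beam search over descriptor combinations
#'
#' Greedy beam search over combination sizes 1..\code{max_size}, scored by
#' the mean bootstrap-validated Youden index. To keep the search tractable
#' the in-loop scoring uses \code{score_resamples} bootstrap resamples
#' (enough to rank combinations: the standard error of a mean Youden at 30
#' resamples is well below typical between-combination gaps); the winner of
#' every size is then re-validated with the full \code{n_resamples}. Ties
#' are broken by fewer descriptors, then lexicographic name order.
#'
#' @param x numeric descriptor matrix.
#' @param labels binary labels (0/1).
#' @param candidates candidate column names (default: all columns).
#' @param beam_width beam width (default 10).
#' @param max_size largest combination size (default 5).
#' @param spec A \linkS4class{ForestSpec}.
#' @param n_resamples bootstrap folds for the reported winners
#'   (default 200).
#' @param score_resamples bootstrap folds used while searching
#'   (default 30).
#' @param seed master seed.
#' @return list with one element per size: \code{descriptors},
#'   \code{score} (search-time mean Youden) and \code{report}
#'   (full \linkS4class{ValidationReport}).
#' @export
beamSearch <- function(x, labels, candidates = colnames(x),
                       beam_width = 10L, max_size = 5L,
                       spec = forestSpec(), n_resamples = 200L,
                       score_resamples = 30L, seed = 1L) {
  stopifnot(length(candidates) >= 1L)
  candidates <- sort(intersect(colnames(x), candidates))
  scoreCache <- new.env(parent = emptyenv())
  scoreCombo <- function(cols) {
    key <- .comboKey(cols)
    if (!is.null(scoreCache[[key]])) return(scoreCache[[key]])
    rep_ <- bootstrapValidate(x[, cols, drop = FALSE], labels, spec,
                              n_resamples = score_resamples,
                              seed = fanSeed(seed, 7L))
    s <- meanYouden(rep_)
    scoreCache[[key]] <- s
    s
  }
  beam <- lapply(candidates, function(cc) cc)
  results <- vector("list", max_size)
  for (size in seq_len(max_size)) {
    combos <- unique(lapply(beam, sort))
    keys <- vapply(combos, .comboKey, "")
    combos <- combos[!duplicated(keys)]
    scores <- vapply(combos, scoreCombo, 0)
    ord <- order(-scores, lengths(combos),
                 vapply(combos, .comboKey, ""))
    combos <- combos[ord]; scores <- scores[ord]
    winner <- combos[[1L]]
    results[[size]] <- list(
      descriptors = winner, score = scores[[1L]],
      report = bootstrapValidate(x[, winner, drop = FALSE], labels, spec,
                                 n_resamples = n_resamples,
                                 seed = fanSeed(seed, 11L)))
    if (size == max_size) break
    top <- combos[seq_len(min(beam_width, length(combos)))]
    beam <- list()
    for (cmb in top)
      for (cc in setdiff(candidates, cmb))
        beam <- c(beam, list(c(cmb, cc)))
    if (!length(beam)) break
  }
  names(results) <- paste0("size", seq_len(max_size))
  results[!vapply(results, is.null, TRUE)]
}

#' Y-scrambling (response permutation) null distribution
#'
#' Refits and bootstrap-validates the model on uniformly permuted labels
#' \code{n_permutations} times to estimate the chance-correlation baseline
#' of the selected descriptor combination. Reports the null mean and SD of
#' the mean bootstrap Youden index and accuracy, and the z-distance of the
#' unpermuted score above the null.
#'
#' @param x numeric descriptor matrix.
#' @param labels binary labels (0/1).
#' @param combination descriptor column names of the fixed model.
#' @param spec A \linkS4class{ForestSpec}.
#' @param n_permutations number of label permutations (default 1000).
#' @param n_resamples bootstrap folds per permutation (default 200).
#' @param seed master seed.
#' @param identity_permutation if TRUE, do not permute (degenerate
#'   control; the "null" then equals the unpermuted validation).
#' @return list with \code{null_youden}, \code{null_accuracy} (per
#'   permutation mean scores), their means/SDs, the unpermuted
#'   \code{observed} report and \code{z_youden}.
#' @export
yScramble <- function(x, labels, combination, spec = forestSpec(),
                      n_permutations = 1000L, n_resamples = 200L,
                      seed = 1L, identity_permutation = FALSE) {
  xs <- x[, combination, drop = FALSE]
  observed <- bootstrapValidate(xs, labels, spec, n_resamples = n_resamples,
                                seed = fanSeed(seed, 1L))
  ny <- numeric(n_permutations); na_ <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    yp <- if (identity_permutation) labels else
      withSeed(fanSeed(seed, 1000L + p), sample(labels))
    rep_ <- bootstrapValidate(xs, yp, spec, n_resamples = n_resamples,
                              seed = fanSeed(seed, 2000L + p))
    ny[p] <- meanYouden(rep_); na_[p] <- meanAccuracy(rep_)
  }
  z <- if (n_permutations > 1L && sd(ny) > 0)
    (meanYouden(observed) - mean(ny)) / sd(ny) else NA_real_
  list(null_youden = ny, null_accuracy = na_,
       null_youden_mean = mean(ny), null_youden_sd = sd(ny),
       null_accuracy_mean = mean(na_), null_accuracy_sd = sd(na_),
       observed = observed, z_youden = z)
}
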