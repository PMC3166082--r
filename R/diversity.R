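#' Pharmacophore typing of atoms
#'
#' Assigns each heavy atom the 2D pharmacophore types used by the triangle
#' fingerprint: \code{donor} (N/O with attached H), \code{acceptor} (N/O
#' with formal charge <= 0, quaternary N excluded), \code{cation}
#' (formal charge > 0), \code{anion} (formal charge < 0), \code{aromatic},
#' and \code{hydrophobe} (uncharged carbon without N/O neighbour, or a
#' halogen). An atom may carry several types.
#'
#' @param g A \linkS4class{MolGraph}.
#' @return list of character vectors, one per atom (possibly empty).
#' @export
pharmacophoreTypes <- function(g) {
  stopifnot(is(g, "MolGraph"))
  a <- g@atoms
  n <- nrow(a)
  out <- vector("list", n)
  polarNb <- logical(n)
  for (b in seq_len(nrow(g@bonds))) {
    f <- g@bonds$from[b]; t <- g@bonds$to[b]
    if (a$element[t] %in% c("N", "O")) polarNb[f] <- TRUE
    if (a$element[f] %in% c("N", "O")) polarNb[t] <- TRUE
  }
  for (i in seq_len(n)) {
    tp <- character()
    el <- a$element[i]
    isQuat <- el == "N" && a$charge[i] == 1L && a$degree[i] == 4L &&
      a$nH[i] == 0L
    if (el %in% c("N", "O") && a$nH[i] >= 1L) tp <- c(tp, "donor")
    if (el %in% c("N", "O") && a$charge[i] <= 0L && !isQuat)
      tp <- c(tp, "acceptor")
    if (a$charge[i] > 0L) tp <- c(tp, "cation")
    if (a$charge[i] < 0L) tp <- c(tp, "anion")
    if (a$aromatic[i]) tp <- c(tp, "aromatic")
    if ((el == "C" && a$charge[i] == 0L && !polarNb[i]) ||
        el %in% c("F", "Cl", "Br", "I")) tp <- c(tp, "hydrophobe")
    out[[i]] <- tp
  }
  out
}

# topological distance bins {1, 2, 3, 4-5, 6-8, 9+}; disconnected pairs
# fall in their own bin
.distanceBin <- function(d) {
  ifelse(!is.finite(d), 7L,
    ifelse(d <= 3, as.integer(d),
      ifelse(d <= 5, 4L, ifelse(d <= 8, 5L, 6L))))
}

# canonical key of one typed triangle: minimum over vertex rotations and
# reflections of "t1,t2,t3|d12,d23,d31"
.triangleKey <- function(types, dbins) {
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))
  keys <- vapply(perms, function(p) {
    t_ <- types[p]
    d_ <- c(dbins[.pairIndex(p[1], p[2])], dbins[.pairIndex(p[2], p[3])],
            dbins[.pairIndex(p[3], p[1])])
    paste0(paste(t_, collapse = ","), "|", paste(d_, collapse = ","))
  }, "")
  min(keys)
}

# index of the unordered pair (i,j) of {1,2,3} into c(d12, d13, d23)
.pairIndex <- function(i, j) {
  s <- sort(c(i, j))
  if (s[1] == 1 && s[2] == 2) 1L else if (s[1] == 1 && s[2] == 3) 2L else 3L
}

#' Triangle pharmacophore fingerprint
#'
#' 2D fingerprint built from typed graph triangles: every triple of
#' pharmacophore-typed heavy atoms contributes a canonicalized key of its
#' three types and the binned topological distances between them (bins
#' 1, 2, 3, 4-5, 6-8, 9+). Atoms with several types use the
#' lexicographically first type (deterministic). Graphs with fewer than
#' three typed atoms fall back to pair and single keys so every non-empty
#' molecule has a non-empty fingerprint.
#'
#' @param g A \linkS4class{MolGraph} with >= 1 heavy atom.
#' @return object of class \code{TriangleFingerprint}: a character vector
#'   of unique feature keys with attributes \code{id} and \code{scheme}.
#' @export
triangleFingerprint <- function(g) {
  stopifnot(is(g, "MolGraph"))
  a <- g@atoms
  if (!nrow(a)) stop("empty molecular graph", call. = FALSE)
  types <- pharmacophoreTypes(g)
  primary <- vapply(types, function(tp)
    if (length(tp)) sort(tp)[1L] else NA_character_, "")
  typed <- which(!is.na(primary))
  keys <- character()
  if (length(typed) >= 3L) {
    ig <- igraph::graph_from_data_frame(
      g@bonds[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(a))))
    D <- igraph::distances(ig)
    idx <- as.character(typed)
    trip <- combn(seq_along(typed), 3L)
    for (cix in seq_len(ncol(trip))) {
      v <- typed[trip[, cix]]
      d12 <- .distanceBin(D[idx[trip[1, cix]], idx[trip[2, cix]]])
      d13 <- .distanceBin(D[idx[trip[1, cix]], idx[trip[3, cix]]])
      d23 <- .distanceBin(D[idx[trip[2, cix]], idx[trip[3, cix]]])
      keys <- c(keys, .triangleKey(primary[v], c(d12, d13, d23)))
    }
  } else if (length(typed) == 2L) {
    ig <- igraph::graph_from_data_frame(
      g@bonds[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(a))))
    D <- igraph::distances(ig)
    d <- .distanceBin(D[as.character(typed[1]), as.character(typed[2])])
    tp <- sort(primary[typed])
    keys <- paste0("pair:", tp[1], ",", tp[2], "|", d)
  } else if (length(typed) == 1L) {
    keys <- paste0("single:", primary[typed])
  }
  # element-count keys keep even fully untyped graphs distinguishable
  if (!length(keys))
    keys <- paste0("atom:", names(table(a$element)), ":",
                   table(a$element))
  structure(unique(keys), id = g@id, scheme = "tgt-v1",
            class = "TriangleFingerprint")
}

#' @export
print.TriangleFingerprint <- function(x, ...) {
  cat(sprintf("TriangleFingerprint '%s': %d features (scheme %s)\n",
              attr(x, "id"), length(x), attr(x, "scheme")))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' \code{|A intersect B| / |A union B|}. Two empty fingerprints are defined
#' as similarity 1 (with a warning). Fingerprints must come from the same
#' scheme.
#'
#' @param a,b \code{TriangleFingerprint} objects (or plain character
#'   feature sets).
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  sa <- attr(a, "scheme"); sb <- attr(b, "scheme")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    stop("fingerprint scheme mismatch: ", sa, " vs ", sb, call. = FALSE)
  A <- unique(as.character(a)); B <- unique(as.character(b))
  if (!length(A) && !length(B)) {
    warning("both fingerprints empty; similarity defined as 1")
    return(1)
  }
  length(intersect(A, B)) / length(union(A, B))
}

#' Hierarchical clustering of fingerprints at a similarity cutoff
#'
#' Complete-linkage agglomeration on the distance 1 - Tanimoto, cut at
#' distance \code{1 - cutoff}. Complete linkage guarantees that all
#' within-cluster pairwise similarities are >= the cutoff. Merge ties are
#' broken deterministically by clustering in sorted-id order.
#'
#' @param fps named list of fingerprints.
#' @param cutoff Tanimoto similarity cutoff (default 0.85).
#' @return A \linkS4class{ClusterSolution}.
#' @export
clusterAt <- function(fps, cutoff = 0.85) {
  stopifnot(length(fps) >= 1L)
  ids <- names(fps) %||% as.character(seq_along(fps))
  ord <- order(ids)
  fps <- fps[ord]; ids <- ids[ord]
  n <- length(fps)
  if (n == 1L)
    return(new("ClusterSolution",
               assignment = setNames(1L, ids), n_clusters = 1L,
               cutoff = cutoff))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n))
      D[i, j] <- D[j, i] <- 1 - tanimoto(fps[[i]], fps[[j]])
  hc <- hclust(as.dist(D), method = "complete")
  cl <- cutree(hc, h = (1 - cutoff) + 1e-12)
  # relabel clusters in order of first appearance for stability
  lab <- as.integer(factor(cl, levels = unique(cl)))
  new("ClusterSolution", assignment = setNames(lab, ids),
      n_clusters = max(lab), cutoff = cutoff)
}

#' Relative structural diversity (div_rel)
#'
#' Number of fingerprint clusters at the similarity cutoff divided by the
#' number of compounds: just above 0 when all compounds fall in one
#' cluster, 1 when every compound is its own cluster. Higher values mean
#' higher structural diversity.
#'
#' @param solution A \linkS4class{ClusterSolution} (or cluster count).
#' @param n_compounds total compounds in the set (defaults to the number
#'   clustered).
#' @return div_rel in (0, 1].
#' @examples
#' # N mutually dissimilar compounds give 1
#' @export
divRel <- function(solution, n_compounds = NULL) {
  k <- if (is(solution, "ClusterSolution")) solution@n_clusters
       else as.integer(solution)
  if (is.null(n_compounds))
    n_compounds <- if (is(solution, "ClusterSolution"))
      length(solution@assignment) else
      stop("n_compounds required when passing a cluster count",
           call. = FALSE)
  if (n_compounds < 1L) stop("n_compounds must be >= 1", call. = FALSE)
  k / n_compounds
}

#' Relative structural diversity of a set of structures
#'
#' Convenience wrapper: fingerprint every structure, cluster at the
#' cutoff, return div_rel.
#'
#' @param structures named list of \linkS4class{MolGraph}.
#' @param cutoff Tanimoto similarity cutoff (default 0.85).
#' @return list with \code{div_rel}, \code{n_clusters}, \code{n} and the
#'   \code{solution}.
#' @export
structuralDiversity <- function(structures, cutoff = 0.85) {
  fps <- lapply(structures, triangleFingerprint)
  sol <- clusterAt(fps, cutoff)
  list(div_rel = divRel(sol), n_clusters = nClusters(sol),
       n = length(structures), solution = sol)
}
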