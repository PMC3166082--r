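#' CompoundSet: a table of compounds with physicochemical annotation
#'
#' Central container for compound records. Each row holds one compound with
#' its identity (\code{id}, \code{name}, optional PubChem \code{cid}), an
#' optional SMILES structure string, the measured residual acid
#' sphingomyelinase (ASM) activity in percent of solvent control, the
#' incubation time in minutes, and the physicochemical inputs used by the
#' descriptor and cell-model machinery: octanol-water \code{logp}, the two
#' most basic pKa values (\code{pka_base1 >= pka_base2}), the most acidic
#' pKa (\code{pka_acid}), molecular weight \code{mw} (g/mol), polar
#' van-der-Waals surface area \code{vsa_pol} (A^2), H-bond donor/acceptor
#' counts, the number of heavy atoms at the most basic nitrogen (\code{k}),
#' and \code{logbb} (log brain/blood ratio). ATC-like group codes are kept
#' as a semicolon-separated string column \code{atc_codes}.
#'
#' Missing optional values are carried as \code{NA}, never as sentinel
#' numbers; the documented imputation step lives in
#' \code{\link{imputeDescriptors}}.
#'
#' @slot data data.frame with one row per compound; canonical columns are
#'   created on construction, unknown columns are preserved.
#' @slot provenance free-text source tag.
#' @export
setClass("CompoundSet",
  representation(data = "data.frame", provenance = "character"))

.canonicalColumns <- c("id", "name", "cid", "smiles", "residual_activity",
  "incubation_min", "logp", "pka_base1", "pka_base2", "pka_acid", "mw",
  "vsa_pol", "hbd", "hba", "k", "logbb", "atc_codes")

.numericColumns <- c("cid", "residual_activity", "incubation_min", "logp",
  "pka_base1", "pka_base2", "pka_acid", "mw", "vsa_pol", "hbd", "hba",
  "k", "logbb")

setValidity("CompoundSet", function(object) {
  d <- object@data
  msgs <- character()
  if (!all(c("id", "mw") %in% names(d)))
    msgs <- c(msgs, "columns 'id' and 'mw' are mandatory")
  if ("id" %in% names(d)) {
    dup <- unique(d$id[duplicated(d$id)])
    if (length(dup))
      msgs <- c(msgs, sprintf("duplicate compound ids: %s",
                              paste(dup, collapse = ", ")))
  }
  if ("mw" %in% names(d) && nrow(d) && any(!is.finite(d$mw) | d$mw <= 0))
    msgs <- c(msgs, "mw must be present and > 0 for every compound")
  if ("residual_activity" %in% names(d)) {
    ra <- d$residual_activity
    if (any(!is.na(ra) & ra < 0))
      msgs <- c(msgs, "residual_activity must be >= 0 when present")
  }
  if (all(c("pka_base1", "pka_base2") %in% names(d))) {
    both <- !is.na(d$pka_base1) & !is.na(d$pka_base2)
    if (any(both & d$pka_base2 > d$pka_base1))
      msgs <- c(msgs, "pka_base1 must be >= pka_base2 when both present")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a CompoundSet
#'
#' @param data data.frame with at least columns \code{id} and \code{mw}.
#' @param provenance free-text source tag.
#' @return A \linkS4class{CompoundSet}.
#' @examples
#' cs <- CompoundSet(data.frame(id = c("a", "b"), mw = c(180.2, 294.4),
#'                              logp = c(1.2, 4.4)))
#' nCompounds(cs)
#' @export
CompoundSet <- function(data, provenance = "user") {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"id" %in% names(data))
    stop("missing mandatory column: id", call. = FALSE)
  if (!"mw" %in% names(data))
    stop("missing mandatory column: mw", call. = FALSE)
  data$id <- as.character(data$id)
  for (cc in setdiff(.canonicalColumns, names(data))) {
    data[[cc]] <- if (cc %in% .numericColumns) NA_real_ else NA_character_
  }
  for (cc in intersect(.numericColumns, names(data)))
    data[[cc]] <- as.numeric(data[[cc]])
  # canonical columns first, extras after, original row order kept
  extra <- setdiff(names(data), .canonicalColumns)
  data <- data[, c(.canonicalColumns, extra), drop = FALSE]
  rownames(data) <- NULL
  new("CompoundSet", data = data, provenance = provenance)
}

#' @rdname CompoundSet-accessors
#' @export
setGeneric("compoundData", function(x) standardGeneric("compoundData"))

#' Accessors for CompoundSet
#'
#' \code{compoundData} returns the underlying data.frame,
#' \code{compoundIds} the compound identifiers, \code{nCompounds} the number
#' of compounds, \code{provenance} the source tag and \code{atcCodes} the
#' per-compound list of group codes.
#'
#' @param x A \linkS4class{CompoundSet}.
#' @return See individual descriptions.
#' @name CompoundSet-accessors
#' @aliases compoundData compoundIds nCompounds provenance atcCodes
#' @export
setMethod("compoundData", "CompoundSet", function(x) x@data)

#' @rdname CompoundSet-accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname CompoundSet-accessors
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@data$id)

#' @rdname CompoundSet-accessors
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))

#' @rdname CompoundSet-accessors
#' @export
setMethod("nCompounds", "CompoundSet", function(x) nrow(x@data))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname CompoundSet-accessors
#' @export
setMethod("provenance", "CompoundSet", function(x) x@provenance)

#' @rdname CompoundSet-accessors
#' @export
setGeneric("atcCodes", function(x) standardGeneric("atcCodes"))

#' @rdname CompoundSet-accessors
#' @export
setMethod("atcCodes", "CompoundSet", function(x) {
  raw <- x@data$atc_codes
  out <- lapply(raw, function(s) {
    if (is.na(s) || !nzchar(s)) character() else
      trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
  })
  names(out) <- x@data$id
  out
})

#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@data))

#' @export
setMethod("show", "CompoundSet", function(object) {
  cat(sprintf("CompoundSet with %d compounds (provenance: %s)\n",
              nrow(object@data), object@provenance))
  ra <- object@data$residual_activity
  if (any(!is.na(ra)))
    cat(sprintf("  residual ASM activity present for %d compounds\n",
                sum(!is.na(ra))))
  cat("  columns:", paste(head(names(object@data), 10L), collapse = ", "),
      if (ncol(object@data) > 10L) "..." else "", "\n")
})

#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  new("CompoundSet", data = x@data[i, , drop = FALSE],
      provenance = x@provenance)
})

#' ForestSpec: random-forest hyper-parameters
#'
#' Defaults follow the published model-construction settings: 51 trees,
#' terminal node size 1, maximal tree depth 8 and
#' \code{mtry = floor(log2(m)) + 1} attributes sampled per split (the
#' natural-log variant is available via \code{mtry_rule = "loge"}).
#'
#' @slot ntree number of trees.
#' @slot nodesize minimal terminal node size.
#' @slot maxdepth maximal tree depth.
#' @slot mtry_rule one of "log2", "loge".
#' @slot seed integer base seed for fitting.
#' @export
setClass("ForestSpec", representation(ntree = "integer", nodesize = "integer",
  maxdepth = "integer", mtry_rule = "character", seed = "integer"))

setValidity("ForestSpec", function(object) {
  if (object@ntree < 1L) return("ntree must be >= 1")
  if (object@nodesize < 1L) return("nodesize must be >= 1")
  if (object@maxdepth < 1L) return("maxdepth must be >= 1")
  if (!object@mtry_rule %in% c("log2", "loge"))
    return("mtry_rule must be 'log2' or 'loge'")
  TRUE
})

#' Construct a ForestSpec
#'
#' @param ntree number of trees (default 51).
#' @param nodesize minimal terminal node size (default 1).
#' @param maxdepth maximal tree depth (default 8).
#' @param mtry_rule how to derive the per-split attribute sample size from
#'   the number of columns m: \code{"log2"} gives \code{floor(log2(m)) + 1}
#'   (default), \code{"loge"} gives \code{floor(log(m)) + 1}.
#' @param seed integer seed.
#' @return A \linkS4class{ForestSpec}.
#' @examples
#' forestSpec()
#' @export
forestSpec <- function(ntree = 51L, nodesize = 1L, maxdepth = 8L,
                       mtry_rule = "log2", seed = 1L) {
  new("ForestSpec", ntree = as.integer(ntree), nodesize = as.integer(nodesize),
      maxdepth = as.integer(maxdepth), mtry_rule = mtry_rule,
      seed = as.integer(seed))
}

mtryFor <- function(spec, m) {
  v <- switch(spec@mtry_rule,
              log2 = floor(log2(m)) + 1,
              loge = floor(log(m)) + 1)
  as.integer(max(1L, min(m, v)))
}

#' @export
setMethod("show", "ForestSpec", function(object) {
  cat(sprintf(
    "ForestSpec: ntree=%d nodesize=%d maxdepth=%d mtry=floor(%s(m))+1 seed=%d\n",
    object@ntree, object@nodesize, object@maxdepth,
    if (object@mtry_rule == "log2") "log2" else "log", object@seed))
})

#' ValidationReport: bootstrap performance summary
#'
#' Holds per-resample Youden index and accuracy from out-of-bag bootstrap
#' validation, together with sensitivity/specificity summaries.
#'
#' @slot youden per-resample Youden indices.
#' @slot accuracy per-resample accuracies.
#' @slot sensitivity per-resample sensitivities.
#' @slot specificity per-resample specificities.
#' @slot n_resamples number of bootstrap resamples.
#' @slot seed integer seed used.
#' @slot descriptors descriptor set the model was fitted on.
#' @slot n_redrawn number of resamples redrawn for single-class
#'   out-of-bag sets.
#' @export
setClass("ValidationReport", representation(youden = "numeric",
  accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
  n_resamples = "integer", seed = "integer", descriptors = "character",
  n_redrawn = "integer"))

setValidity("ValidationReport", function(object) {
  if (any(object@youden < -1 - 1e-12 | object@youden > 1 + 1e-12))
    return("Youden indices must lie in [-1, 1]")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    return("accuracies must lie in [0, 1]")
  TRUE
})

#' Summary accessors for ValidationReport
#'
#' @param x A \linkS4class{ValidationReport}.
#' @return \code{meanYouden}/\code{sdYouden}/\code{meanAccuracy}/
#'   \code{sdAccuracy} return scalars; \code{resampleScores} the
#'   per-resample data.frame.
#' @name ValidationReport-accessors
#' @aliases meanYouden sdYouden meanAccuracy sdAccuracy resampleScores
#' @export
setGeneric("meanYouden", function(x) standardGeneric("meanYouden"))

#' @rdname ValidationReport-accessors
#' @export
setMethod("meanYouden", "ValidationReport", function(x) mean(x@youden))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("sdYouden", function(x) standardGeneric("sdYouden"))

#' @rdname ValidationReport-accessors
#' @export
setMethod("sdYouden", "ValidationReport", function(x) sd(x@youden))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname ValidationReport-accessors
#' @export
setMethod("meanAccuracy", "ValidationReport", function(x) mean(x@accuracy))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("sdAccuracy", function(x) standardGeneric("sdAccuracy"))

#' @rdname ValidationReport-accessors
#' @export
setMethod("sdAccuracy", "ValidationReport", function(x) sd(x@accuracy))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("resampleScores", function(x) standardGeneric("resampleScores"))

#' @rdname ValidationReport-accessors
#' @export
setMethod("resampleScores", "ValidationReport", function(x)
  data.frame(resample = seq_along(x@youden), youden = x@youden,
             accuracy = x@accuracy, sensitivity = x@sensitivity,
             specificity = x@specificity))

#' @export
setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport (%d-fold bootstrap, seed %d)\n",
              object@n_resamples, object@seed))
  cat(sprintf("  descriptors: %s\n",
              paste(object@descriptors, collapse = ", ")))
  cat(sprintf("  Youden   %0.3f +/- %0.3f\n", mean(object@youden),
              sd(object@youden)))
  cat(sprintf("  accuracy %0.3f +/- %0.3f\n", mean(object@accuracy),
              sd(object@accuracy)))
})

#' ClusterSolution: fingerprint clustering at a similarity cutoff
#'
#' @slot assignment integer cluster labels named by compound id.
#' @slot n_clusters number of clusters.
#' @slot cutoff Tanimoto similarity cutoff used.
#' @export
setClass("ClusterSolution", representation(assignment = "integer",
  n_clusters = "integer", cutoff = "numeric"))

setValidity("ClusterSolution", function(object) {
  if (length(object@assignment) &&
      !identical(sort(unique(as.integer(object@assignment))),
                 seq_len(object@n_clusters)))
    return("cluster labels must be 1..n_clusters, each used at least once")
  TRUE
})

#' @rdname divRel
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname divRel
#' @export
setMethod("nClusters", "ClusterSolution", function(x) x@n_clusters)

#' @export
setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf(
    "ClusterSolution: %d compounds in %d clusters at %.2f similarity\n",
    length(object@assignment), object@n_clusters, object@cutoff))
})

#' ScreenResult: virtual-screening outcome for one library
#'
#' Records the exclusion cascade (incalculable descriptors, quaternary
#' nitrogen, structural duplicates), the per-compound predictions, and the
#' per-group enrichment rows when group labels were supplied.
#'
#' @slot library_tag free-text library name.
#' @slot n_input number of input compounds.
#' @slot n_excluded_incalculable compounds lacking a required descriptor.
#' @slot n_excluded_quaternary compounds with a quaternary nitrogen atom.
#' @slot n_excluded_duplicates structural duplicates removed.
#' @slot predictions data.frame (id, predicted_class) for screened compounds.
#' @slot exclusions data.frame (id, reason) for excluded compounds.
#' @slot enrichment per-group enrichment data.frame (may have 0 rows).
#' @slot global_test list describing the global contingency test.
#' @export
setClass("ScreenResult", representation(library_tag = "character",
  n_input = "integer", n_excluded_incalculable = "integer",
  n_excluded_quaternary = "integer", n_excluded_duplicates = "integer",
  predictions = "data.frame", exclusions = "data.frame",
  enrichment = "data.frame", global_test = "list"))

setValidity("ScreenResult", function(object) {
  n_screened <- nrow(object@predictions)
  tot <- n_screened + object@n_excluded_incalculable +
    object@n_excluded_quaternary + object@n_excluded_duplicates
  if (tot != object@n_input)
    return("exclusion counts and screened compounds must sum to n_input")
  if (any(c(object@n_excluded_incalculable, object@n_excluded_quaternary,
            object@n_excluded_duplicates) < 0L))
    return("exclusion counts must be non-negative")
  TRUE
})

#' @rdname virtualScreen
#' @export
setGeneric("nScreened", function(x) standardGeneric("nScreened"))

#' @rdname virtualScreen
#' @export
setMethod("nScreened", "ScreenResult", function(x) nrow(x@predictions))

#' @rdname virtualScreen
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname virtualScreen
#' @export
setMethod("predictions", "ScreenResult", function(x) x@predictions)

#' @rdname groupEnrichment
#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))

#' @rdname groupEnrichment
#' @export
setMethod("enrichment", "ScreenResult", function(x) x@enrichment)

#' @export
setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult '%s'\n", object@library_tag))
  cat(sprintf("  input %d | incalculable %d | quaternary N %d | duplicates %d\n",
              object@n_input, object@n_excluded_incalculable,
              object@n_excluded_quaternary, object@n_excluded_duplicates))
  np <- nrow(object@predictions)
  na <- sum(object@predictions$predicted_class == 1L)
  cat(sprintf("  screened %d, predicted active %d (%.2f%%)\n",
              np, na, if (np) 100 * na / np else 0))
  if (nrow(object@enrichment))
    cat(sprintf("  %d groups tested, %d enriched (BH < 0.05)\n",
                nrow(object@enrichment),
                sum(object@enrichment$p_adjusted < 0.05)))
})
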