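#' MolGraph: a sanitized molecular graph
#'
#' Lightweight heavy-atom graph derived from a parsed structure: element
#' symbols, formal charges, perceived aromaticity, implicit hydrogen counts
#' and the bond list with (kekulized) bond orders. Built by
#' \code{\link{readStructures}} or \code{\link{molFromSmiles}}.
#'
#' @slot atoms data.frame with columns element, charge, aromatic, nH, degree.
#' @slot bonds data.frame with columns from, to, order.
#' @slot id compound identifier.
#' @slot smiles the input SMILES when known.
#' @export
setClass("MolGraph", representation(atoms = "data.frame",
  bonds = "data.frame", id = "character", smiles = "character"))

#' @export
setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph '%s': %d heavy atoms, %d bonds (%s)\n", object@id,
              nrow(object@atoms), nrow(object@bonds),
              paste0(unique(object@atoms$element), collapse = "")))
})

#' @rdname MolGraph-class
#' @param x A MolGraph.
#' @export
setGeneric("nHeavyAtoms", function(x) standardGeneric("nHeavyAtoms"))

#' @rdname MolGraph-class
#' @export
setMethod("nHeavyAtoms", "MolGraph", function(x) nrow(x@atoms))

# standard valences used to derive implicit hydrogen counts; the formal
# charge is added (N+ -> 4, O- -> 1)
.stdValence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                 I = 1, B = 3, Si = 4, Se = 2)

# Bond-less molecules (single heavy atom) confuse the SDF block reader;
# build the one-atom graph straight from the V2000 text instead.
.singleAtomGraph <- function(smi, id) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smi, "\n")),
    error = function(e) NULL)
  if (is.null(txt)) return(NULL)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 5L) return(NULL)
  natoms <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
  if (is.na(natoms) || natoms != 1L) return(NULL)
  element <- trimws(substr(lines[5L], 32L, 34L))
  charge <- 0L
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) charge <- as.integer(strsplit(trimws(
    sub("^M  CHG\\s+\\d+", "", chg[1L])), "\\s+")[[1L]][2L])
  val <- .stdValence[element]; if (is.na(val)) val <- 0
  atoms <- data.frame(element = element, charge = charge,
                      aromatic = FALSE,
                      nH = as.integer(max(0, val + charge)), degree = 0L,
                      stringsAsFactors = FALSE)
  new("MolGraph", atoms = atoms,
      bonds = data.frame(from = integer(), to = integer(),
                         order = integer()),
      id = as.character(id), smiles = as.character(smi))
}

# Convert one ChemmineR::SDF into a MolGraph: reads atoms, charges and
# bonds, perceives aromatic rings, and derives implicit hydrogen counts.
.sdfToMolGraph <- function(sdf, id, smiles = NA_character_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (!all(grepl("^[A-Za-z]+_[0-9]+$", rownames(ab))))
    stop("unreadable atom block", call. = FALSE)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  charge <- integer(n)
  binfo <- tryCatch(ChemmineR::bonds(sdf), error = function(e) NULL)
  if (!is.null(binfo) && nrow(binfo) == n) charge <- as.integer(binfo$charge)
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(from = integer(), to = integer(), order = integer())
  } else {
    data.frame(from = as.integer(bb[, 1L]), to = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  }
  aromatic <- logical(n)
  if (n >= 3L) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) NULL)
    if (!is.null(rg) && length(rg$AROMATIC)) {
      for (rn in names(rg$AROMATIC)[which(rg$AROMATIC)]) {
        idx <- as.integer(sub("^[A-Za-z]+_", "", rg$RINGS[[rn]]))
        aromatic[idx] <- TRUE
      }
    }
  }
  # drop explicit hydrogens (rare from SMILES input) but count them
  explicitH <- elements == "H"
  hFromExplicit <- integer(n)
  if (any(explicitH)) {
    for (b in seq_len(nrow(bonds))) {
      f <- bonds$from[b]; t <- bonds$to[b]
      if (explicitH[f] && !explicitH[t])
        hFromExplicit[t] <- hFromExplicit[t] + 1L
      if (explicitH[t] && !explicitH[f])
        hFromExplicit[f] <- hFromExplicit[f] + 1L
    }
    keep <- which(!explicitH)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    bonds <- bonds[!explicitH[bonds$from] & !explicitH[bonds$to], ,
                   drop = FALSE]
    bonds$from <- remap[bonds$from]; bonds$to <- remap[bonds$to]
    elements <- elements[keep]; charge <- charge[keep]
    aromatic <- aromatic[keep]; hFromExplicit <- hFromExplicit[keep]
    n <- length(keep)
  }
  orderSum <- numeric(n); degree <- integer(n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      f <- bonds$from[b]; t <- bonds$to[b]; o <- bonds$order[b]
      orderSum[f] <- orderSum[f] + o; orderSum[t] <- orderSum[t] + o
      degree[f] <- degree[f] + 1L; degree[t] <- degree[t] + 1L
    }
  }
  val <- .stdValence[elements]
  val[is.na(val)] <- 0
  nH <- pmax(0, round(val + charge - orderSum)) + hFromExplicit
  atoms <- data.frame(element = elements, charge = charge,
                      aromatic = aromatic, nH = as.integer(nH),
                      degree = degree, stringsAsFactors = FALSE)
  new("MolGraph", atoms = atoms, bonds = bonds, id = as.character(id),
      smiles = as.character(smiles))
}

#' Parse SMILES strings into molecular graphs
#'
#' Uses OpenBabel (via ChemmineOB/ChemmineR) to parse and sanitize each
#' SMILES: explicit charges are kept, aromaticity is perceived on the
#' kekulized graph, implicit hydrogens are derived from standard valences.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids identifiers (defaults to names or seq_along).
#' @return named list of \linkS4class{MolGraph}; unparseable entries are
#'   dropped and reported in \code{attr(, "failures")}.
#' @examples
#' g <- molFromSmiles(c(eth1 = "CCO"))
#' nHeavyAtoms(g$eth1)
#' @export
molFromSmiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles) %||% as.character(seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  out <- vector("list", length(smiles)); names(out) <- ids
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smiles[[i]])),
      error = function(e) NULL)
    if (!is.null(sdf) && length(sdf) == 1L) {
      g <- tryCatch({
        if (nrow(ChemmineR::atomblock(sdf[[1]])) < 1L) NULL
        else .sdfToMolGraph(sdf[[1]], ids[[i]], smiles[[i]])
      }, error = function(e) NULL)
      if (!is.null(g)) { out[[i]] <- g; ok[i] <- TRUE }
    }
    if (!ok[i]) {
      g <- .singleAtomGraph(smiles[[i]], ids[[i]])
      if (!is.null(g)) { out[[i]] <- g; ok[i] <- TRUE }
    }
  }
  failures <- ids[!ok]
  out <- out[ok]
  if (length(failures))
    logMsg("structures", sprintf("%d unparseable SMILES: %s",
           length(failures), paste(head(failures, 5L), collapse = ", ")))
  attr(out, "failures") <- failures
  out
}

#' Read molecular structures from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line, the identifier after
#' whitespace. SDF files are read as V2000 via ChemmineR. Unparseable
#' entries are reported (attribute \code{failures}) but not fatal; a file
#' with zero parseable structures is an error.
#'
#' @param path file path.
#' @param format "smiles" or "sdf".
#' @return named list of \linkS4class{MolGraph}, keyed by identifier.
#' @export
readStructures <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no structure records in ", path, call. = FALSE)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smi <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else as.character(i), "")
    out <- molFromSmiles(smi, ids)
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids)] <- as.character(which(!nzchar(ids)))
    out <- vector("list", length(sdfset)); names(out) <- ids
    ok <- logical(length(sdfset))
    for (i in seq_along(sdfset)) {
      out[[i]] <- tryCatch({
        if (nrow(ChemmineR::atomblock(sdfset[[i]])) < 1L) NULL
        else .sdfToMolGraph(sdfset[[i]], ids[i])
      }, error = function(e) NULL)
      ok[i] <- !is.null(out[[i]])
    }
    failures <- ids[!ok]
    out <- out[ok]
    attr(out, "failures") <- failures
  }
  if (!length(out))
    stop("no parseable structures in ", path, call. = FALSE)
  out
}

#' Read a compound table from CSV or TSV
#'
#' Expects a header row naming at least \code{id} and \code{mw}. Known
#' physicochemical columns are coerced to numeric; unknown columns are
#' preserved as auxiliary values. Empty cells map to missing optional
#' fields. Duplicate ids are a validation error.
#'
#' @param path file path.
#' @param format "csv" (comma, "." decimal) or "tsv".
#' @param provenance free-text source tag; defaults to the file name.
#' @return A \linkS4class{CompoundSet}, rows in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,mw,logp", "a,180.2,1.2", "b,294.4,4.4"), f)
#' readCompoundTable(f)
#' @export
readCompoundTable <- function(path, format = c("csv", "tsv"),
                              provenance = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                check.names = FALSE, na.strings = c("", "NA"))
  for (needed in c("id", "mw"))
    if (!needed %in% names(d))
      stop("missing mandatory column: ", needed, call. = FALSE)
  CompoundSet(d, provenance = provenance)
}

#' Write a compound table to CSV or TSV
#'
#' Numeric fields are written at full precision (17 significant digits) so
#' a write/read round trip reproduces all values exactly.
#'
#' @param x A \linkS4class{CompoundSet}.
#' @param path output file path.
#' @param format "csv" or "tsv".
#' @return \code{path}, invisibly.
#' @export
writeCompoundTable <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(x, "CompoundSet"))
  d <- x@data
  for (cc in names(d))
    if (is.numeric(d[[cc]]))
      d[[cc]] <- ifelse(is.na(d[[cc]]), NA,
                        formatC(d[[cc]], digits = 17, format = "g"))
  utils::write.table(d, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Canonical SMILES of a molecular graph
#'
#' Canonicalization via OpenBabel; used as the structural duplicate key in
#' \code{\link{virtualScreen}}.
#'
#' @param g A \linkS4class{MolGraph} with a stored SMILES, or a SMILES
#'   string.
#' @return canonical SMILES string, or \code{NA} if unavailable.
#' @export
canonicalSmiles <- function(g) {
  smi <- if (is(g, "MolGraph")) g@smiles else as.character(g)
  if (is.na(smi) || !nzchar(smi)) return(NA_character_)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = paste0(smi, "\n")),
    error = function(e) NA_character_)
  if (is.na(out)) return(NA_character_)
  strsplit(trimws(out), "[[:space:]]+")[[1L]][1L]
}
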