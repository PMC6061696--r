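## Ensemble construction and accessors.

#' Construct an Ensemble from an atom table and a coordinate array
#'
#' @param atoms `data.frame` with columns `resno`, `resname`, `atom`,
#'   `element`; atom names are normalized with [normalizeAtomName()] and
#'   residue names with the solvent/ion dialect table.
#' @param coords numeric array `natoms x 3 x nframes`, or a `natoms x 3`
#'   matrix for a single frame.
#' @param dt frame time step in ps (`NA` for model series).
#' @param provenance free-text label stored with the object.
#' @param aligned logical; `TRUE` only for ensembles already superposed on a
#'   common reference (set by [superposeAndRMSD()]).
#' @return an [Ensemble-class] object.
#' @export
ensemble <- function(atoms, coords, dt = NA_real_, provenance = "",
                     aligned = FALSE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$element))
    atoms$element <- guessElement(atoms$atom)
  atoms$atom <- normalizeAtomName(atoms$atom)
  atoms$resname <- normalizeResName(atoms$resname)
  atoms$resno <- as.integer(atoms$resno)
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  new("Ensemble", atoms = atoms, coords = coords, dt = as.numeric(dt),
      provenance = provenance, aligned = aligned)
}

## First character of the stripped atom name, with digits skipped (PDB
## hydrogen names like 1H5' start with a digit).
guessElement <- function(atom) {
  a <- gsub("[0-9']", "", normalizeAtomName(atom))
  two <- c("NA", "MG", "CL", "BR", "MN", "ZN", "FE")
  ifelse(a %in% two, a, substr(a, 1L, 1L))
}

#' @rdname ensemble-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname ensemble-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname ensemble-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname ensemble-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname ensemble-accessors
#' @export
setGeneric("frameDt", function(x) standardGeneric("frameDt"))
#' @rdname ensemble-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname ensemble-accessors
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' Ensemble accessors
#'
#' `nFrames()`/`nAtoms()` give dimensions; `atomTable()` the shared atom
#' table; `coords()` the `natoms x 3 x nframes` array; `frameDt()` the time
#' step in ps; `getFrame(x, i)` extracts frame `i` as a
#' [StructureFrame-class]; `isAligned()` reports whether the ensemble has
#' been superposed.
#'
#' @param x an [Ensemble-class].
#' @param i frame index.
#' @name ensemble-accessors
NULL

setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[3])
setMethod("nAtoms", "Ensemble", function(x) dim(x@coords)[1])
setMethod("atomTable", "Ensemble", function(x) x@atoms)
setMethod("coords", "Ensemble", function(x) x@coords)
setMethod("frameDt", "Ensemble", function(x) x@dt)
setMethod("isAligned", "Ensemble", function(x) x@aligned)

setMethod("getFrame", "Ensemble", function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > nFrames(x)) stop("frame index out of range")
  new("StructureFrame", atoms = x@atoms, xyz = x@coords[, , i, drop = TRUE],
      index = i, time = if (is.na(x@dt)) NA_real_ else (i - 1L) * x@dt)
})

## Coerce Ensemble / StructureFrame arguments uniformly: returns a list with
## the atom table and the coords array (a frame becomes a 1-frame array).
asCoordSet <- function(x) {
  if (is(x, "Ensemble"))
    list(atoms = x@atoms, coords = x@coords)
  else if (is(x, "StructureFrame"))
    list(atoms = x@atoms, coords = array(x@xyz, c(nrow(x@xyz), 3L, 1L)))
  else stop("expected an Ensemble or StructureFrame")
}

#' Subset an ensemble to a frame range
#'
#' @param x an [Ensemble-class].
#' @param frames integer vector of frame indices to keep (order preserved).
#' @return an [Ensemble-class] with the selected frames.
#' @export
subsetFrames <- function(x, frames) {
  stopifnot(is(x, "Ensemble"))
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > nFrames(x))) stop("frame index out of range")
  new("Ensemble", atoms = x@atoms,
      coords = x@coords[, , frames, drop = FALSE],
      dt = x@dt, provenance = x@provenance, aligned = x@aligned)
}
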