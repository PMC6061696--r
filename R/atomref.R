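## Atom addressing: author residue numbers + PDB atom names, with the
## prime/apostrophe/star dialects collapsed to one internal spelling.

#' Normalize a PDB atom name to the package's internal spelling
#'
#' Sugar atom names occur in several deposition dialects: `O2'` (apostrophe),
#' `O2′` (typographic prime) and `O2*` (star). All three are collapsed to
#' the apostrophe spelling. Old-style phosphate oxygen names `O1P`/`O2P`/`O3P`
#' are rewritten to the current `OP1`/`OP2`/`OP3`.
#'
#' @param x character vector of atom names.
#' @return character vector of normalized names.
#' @examples
#' normalizeAtomName(c("O2'", "O2′", "O2*", "O1P"))
#' @export
normalizeAtomName <- function(x) {
  x <- gsub("′", "'", x)
  x <- gsub("*", "'", x, fixed = TRUE)
  x <- trimws(x)
  swap <- c(O1P = "OP1", O2P = "OP2", O3P = "OP3")
  hit <- x %in% names(swap)
  x[hit] <- swap[x[hit]]
  x
}

## residue-name dialects for solvent and monovalent/divalent cations
.WATER_NAMES <- c("HOH", "WAT", "H2O", "TIP3", "SPC")
.ION_NAMES <- c(K = "K", `K+` = "K", NA. = "NA", `NA+` = "NA", MG = "MG",
                `MG2+` = "MG", SOD = "NA", POT = "K")

normalizeResName <- function(x) {
  x <- trimws(x)
  x[x %in% .WATER_NAMES] <- "HOH"
  key <- ifelse(x == "NA", "NA.", x)
  hit <- key %in% names(.ION_NAMES)
  x[hit] <- .ION_NAMES[key[hit]]
  x
}

isWaterName <- function(x) normalizeResName(x) == "HOH"
isIonName <- function(x, species = NULL) {
  x <- normalizeResName(x)
  if (is.null(species)) x %in% unique(unname(.ION_NAMES))
  else x == normalizeResName(species)
}

#' Create or parse an atom reference
#'
#' An `AtomRef` addresses exactly one atom in a frame by author residue number
#' and atom name, e.g. the imino nitrogen of uridine 14 is `atomRef("14:N3")`.
#' Residue numbering is the author numbering of the deposited entry (1-27 for
#' the neomycin-sensing riboswitch) and is never re-indexed.
#'
#' @param x either an `AtomRef` (returned as-is), or a string `"resno:atom"`
#'   such as `"14:N3"` or `"16:OP2"`.
#' @param resno,atom,resname alternative explicit construction.
#' @return an `AtomRef` object.
#' @examples
#' atomRef("14:N3")
#' atomRef(resno = 17, atom = "OP2")
#' @export
atomRef <- function(x = NULL, resno = NULL, atom = NULL, resname = NA_character_) {
  if (is(x, "AtomRef")) return(x)
  if (!is.null(x)) {
    if (!is.character(x) || length(x) != 1L)
      stop("atomRef() expects a single \"resno:atom\" string")
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[2]))
      stop("malformed atom reference: ", sQuote(x),
           " (expected \"resno:atom\", e.g. \"14:N3\")")
    resno <- suppressWarnings(as.integer(parts[1]))
    if (is.na(resno))
      stop("malformed atom reference: ", sQuote(x), " (non-integer residue)")
    atom <- parts[2]
  }
  new("AtomRef", resno = as.integer(resno),
      atom = normalizeAtomName(atom), resname = as.character(resname))
}

#' @describeIn AtomRef compact display, e.g. `14:N3`
#' @param object an `AtomRef`.
#' @export
setMethod("show", "AtomRef", function(object) {
  cat(formatAtomRef(object), "\n")
})

formatAtomRef <- function(ref) {
  lab <- if (!is.na(ref@resname)) paste0(ref@resname, ref@resno) else ref@resno
  paste0(lab, ":", ref@atom)
}

## Parse a semicolon-joined group such as "14:H5';14:H5''" into a list of refs
parseRefGroup <- function(x) {
  toks <- strsplit(x, ";", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty atom group")
  lapply(toks, atomRef)
}

#' Resolve an atom reference against an atom table
#'
#' @param atoms atom table (`data.frame` with columns `resno`, `resname`,
#'   `atom`) as stored in an [Ensemble-class].
#' @param ref an [AtomRef-class] or `"resno:atom"` string.
#' @return the single row index of the atom; an error naming the reference is
#'   raised when it resolves to zero or to several atoms.
#' @export
resolveAtom <- function(atoms, ref) {
  ref <- atomRef(ref)
  idx <- which(atoms$resno == ref@resno & atoms$atom == ref@atom)
  if (length(idx) == 0L)
    stop("atom reference ", sQuote(formatAtomRef(ref)), " matches no atom")
  if (length(idx) > 1L)
    stop("atom reference ", sQuote(formatAtomRef(ref)), " is ambiguous (",
         length(idx), " matches)")
  idx
}
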