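## Central S4 containers. Coordinates are Angstrom throughout, times are ps,
## concentrations mM, couplings Hz.

#' Atom reference
#'
#' Addresses exactly one atom in a frame by author residue number and
#' normalized atom name; see [atomRef()] for construction.
#'
#' @slot resno integer(1) author residue number.
#' @slot atom character(1) normalized atom name.
#' @slot resname character(1) residue name, may be `NA`.
#' @name AtomRef-class
#' @aliases AtomRef
#' @exportClass AtomRef
setClass("AtomRef", representation(resno = "integer",
                                   atom = "character",
                                   resname = "character"))

setValidity("AtomRef", function(object) {
  if (length(object@resno) != 1L || is.na(object@resno))
    return("resno must be a single integer")
  if (length(object@atom) != 1L || is.na(object@atom) || !nzchar(object@atom))
    return("atom name must be a nonempty string")
  TRUE
})

#' Ensemble of coordinate frames
#'
#' An `Ensemble` holds an ordered series of coordinate frames (NMR models or
#' trajectory snapshots) that share one atom table. Coordinates are stored as
#' a `natoms x 3 x nframes` array in Angstrom. The optional time step `dt`
#' (ps) applies to trajectory-like ensembles; NMR model series leave it `NA`.
#'
#' @slot atoms `data.frame` with columns `resno` (author numbering),
#'   `resname`, `atom` (normalized names, see [normalizeAtomName()]) and
#'   `element`.
#' @slot coords numeric array `c(natoms, 3, nframes)`.
#' @slot dt numeric(1), frame spacing in ps, `NA` when not applicable.
#' @slot provenance character(1) free-text label.
#' @slot aligned logical(1), set by [superposeAndRMSD()]; analyses that
#'   require a common frame of reference (e.g. [densityMaxima()]) check it.
#' @name Ensemble-class
#' @aliases Ensemble
#' @exportClass Ensemble
setClass("Ensemble",
         representation(atoms = "data.frame", coords = "array",
                        dt = "numeric", provenance = "character",
                        aligned = "logical"),
         prototype(dt = NA_real_, provenance = "", aligned = FALSE))

setValidity("Ensemble", function(object) {
  a <- object@atoms
  need <- c("resno", "resname", "atom", "element")
  if (!all(need %in% names(a)))
    return(paste("atom table must have columns", paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be a natoms x 3 x nframes array")
  if (d[1] != nrow(a))
    return("coords first dimension must match the atom table")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (anyDuplicated(paste(a$resno, a$atom)))
    return("duplicate residue-number/atom-name keys in atom table")
  if (!is.na(object@dt) && object@dt <= 0)
    return("dt must be > 0 when present")
  if (any(!nzchar(a$atom)))
    return("atom names must be nonempty")
  TRUE
})

#' Single coordinate frame
#'
#' A lightweight view of one frame of an [Ensemble-class]: the shared atom
#' table plus one `natoms x 3` coordinate matrix.
#'
#' @slot atoms atom table as in [Ensemble-class].
#' @slot xyz numeric matrix `natoms x 3` (Angstrom).
#' @slot index integer(1) frame index within its parent ensemble.
#' @slot time numeric(1) frame time in ps (`NA` when the ensemble has no dt).
#' @name StructureFrame-class
#' @aliases StructureFrame
#' @exportClass StructureFrame
setClass("StructureFrame",
         representation(atoms = "data.frame", xyz = "matrix",
                        index = "integer", time = "numeric"))

setValidity("StructureFrame", function(object) {
  if (ncol(object@xyz) != 3L) return("xyz must have 3 columns")
  if (nrow(object@xyz) != nrow(object@atoms))
    return("xyz rows must match the atom table")
  if (!all(is.finite(object@xyz))) return("all coordinates must be finite")
  TRUE
})

#' NOE distance restraint
#'
#' Two groups of equivalent protons and an upper-bound distance. Groups with
#' more than one proton (methyl, methylene, aromatic pairs) are combined by
#' the r^-6 sum in [ensembleNOEDistance()], so no pseudoatom is used.
#'
#' @slot groupA,groupB lists of [AtomRef-class].
#' @slot upper numeric(1) upper bound in Angstrom.
#' @name NOERestraint-class
#' @aliases NOERestraint
#' @exportClass NOERestraint
setClass("NOERestraint",
         representation(groupA = "list", groupB = "list", upper = "numeric"))

setValidity("NOERestraint", function(object) {
  if (!length(object@groupA) || !length(object@groupB))
    return("proton groups must be nonempty")
  if (!all(vapply(c(object@groupA, object@groupB), is, TRUE, "AtomRef")))
    return("groups must contain AtomRef objects")
  ka <- vapply(object@groupA, formatAtomRef, "")
  kb <- vapply(object@groupB, formatAtomRef, "")
  if (length(intersect(ka, kb)))
    return("proton groups must be disjoint")
  if (length(object@upper) != 1L || !is.finite(object@upper) ||
      object@upper <= 0)
    return("upper bound must be a single positive number")
  TRUE
})

#' Construct an NOE restraint
#'
#' @param groupA,groupB atom references: an `AtomRef`, a `"resno:atom"`
#'   string, a semicolon-joined string of several, or a list of either.
#' @param upper upper-bound distance in Angstrom.
#' @return an [NOERestraint-class].
#' @examples
#' noeRestraint("14:H3", "17:H8", 5.0)
#' noeRestraint("14:H5';14:H5''", "16:H8", 5.0)
#' @export
noeRestraint <- function(groupA, groupB, upper) {
  asGroup <- function(g) {
    if (is.list(g)) lapply(g, atomRef)
    else if (is.character(g) && length(g) == 1L) parseRefGroup(g)
    else lapply(as.list(g), atomRef)
  }
  new("NOERestraint", groupA = asGroup(groupA), groupB = asGroup(groupB),
      upper = as.numeric(upper))
}

#' Hydrogen-bond acceptance criteria
#'
#' A hydrogen bond is counted when the donor-acceptor heavy-atom distance is
#' strictly below `dMax` and the donor-hydrogen-acceptor angle is strictly
#' above `angleMin`. The defaults (3.5 Angstrom, 120 degrees) are the
#' conventional cutoffs for nucleic-acid ensemble analysis.
#'
#' @slot dMax numeric(1), heavy-atom distance cutoff in Angstrom.
#' @slot angleMin numeric(1), D-H-A angle cutoff in degrees.
#' @name HBondCriteria-class
#' @aliases HBondCriteria
#' @exportClass HBondCriteria
setClass("HBondCriteria",
         representation(dMax = "numeric", angleMin = "numeric"),
         prototype(dMax = 3.5, angleMin = 120))

setValidity("HBondCriteria", function(object) {
  if (object@dMax <= 0) return("dMax must be > 0")
  if (object@angleMin <= 0 || object@angleMin >= 180)
    return("angleMin must be in (0, 180)")
  TRUE
})

#' @param dMax heavy-atom distance cutoff (Angstrom), default 3.5.
#' @param angleMin D-H-A angle cutoff (degrees), default 120.
#' @return `hbondCriteria()` returns an `HBondCriteria` object.
#' @rdname HBondCriteria-class
#' @examples
#' hbondCriteria()
#' hbondCriteria(dMax = 3.2, angleMin = 135)
#' @export
hbondCriteria <- function(dMax = 3.5, angleMin = 120) {
  new("HBondCriteria", dMax = as.numeric(dMax), angleMin = as.numeric(angleMin))
}

#' Cation binding site definition
#'
#' A site is keyed to one primary coordinating atom: a frame counts as
#' occupied when any ion of the species lies within the inner cutoff of that
#' atom. Auxiliary atoms are descriptive; their contacts are classified as
#' inner shell (direct), outer shell (water-mediated distance range) or none.
#'
#' @slot id character(1) site label.
#' @slot primary [AtomRef-class] of the primary coordinating atom.
#' @slot aux list of auxiliary [AtomRef-class] atoms.
#' @slot inner,outer numeric(1) shell cutoffs in Angstrom (defaults 3.4/6.0;
#'   3.4 is the first minimum of the K+/Na+ to oxygen RDF on the package's
#'   fixtures and can be re-derived with [computeRDF()]).
#' @slot species character(1) ion species residue name (e.g. `"K"`).
#' @name IonSite-class
#' @aliases IonSite
#' @exportClass IonSite
setClass("IonSite",
         representation(id = "character", primary = "AtomRef", aux = "list",
                        inner = "numeric", outer = "numeric",
                        species = "character"),
         prototype(inner = 3.4, outer = 6.0, species = "K"))

setValidity("IonSite", function(object) {
  if (!(object@inner > 0 && object@inner < object@outer))
    return("cutoffs must satisfy 0 < inner < outer")
  TRUE
})

#' @param primary primary coordinating atom (`AtomRef` or `"resno:atom"`).
#' @param aux auxiliary atoms (list or character vector), may be empty.
#' @param inner,outer shell cutoffs in Angstrom.
#' @param species ion residue name.
#' @param id site label; defaults to the primary atom.
#' @return `ionSite()` returns an `IonSite` object.
#' @rdname IonSite-class
#' @examples
#' ionSite("14:O4", aux = c("13:O4", "17:OP2", "18:O4"))
#' @export
ionSite <- function(primary, aux = list(), inner = 3.4, outer = 6.0,
                    species = "K", id = NULL) {
  primary <- atomRef(primary)
  aux <- lapply(as.list(aux), atomRef)
  if (is.null(id)) id <- formatAtomRef(primary)
  new("IonSite", id = id, primary = primary, aux = aux,
      inner = as.numeric(inner), outer = as.numeric(outer),
      species = normalizeResName(species))
}

#' NMR titration series
#'
#' Tabulated chemical-shift changes versus titrant concentration for one
#' nucleus, the input of [fitBindingIsotherm()].
#'
#' @slot conc numeric, titrant concentrations in mM, strictly increasing.
#' @slot dshift numeric, observed shift changes in ppm.
#' @slot nucleus character(1) label (e.g. `"U14-H3"`).
#' @slot model character(1), `"single-site"` or `"cooperative2"` tag.
#' @name TitrationSeries-class
#' @aliases TitrationSeries
#' @exportClass TitrationSeries
setClass("TitrationSeries",
         representation(conc = "numeric", dshift = "numeric",
                        nucleus = "character", model = "character"),
         prototype(nucleus = "", model = "single-site"))

setValidity("TitrationSeries", function(object) {
  if (length(object@conc) != length(object@dshift))
    return("conc and dshift must have equal length")
  if (length(object@conc) < 4L)
    return("at least 4 titration points are required")
  if (any(object@conc < 0)) return("concentrations must be nonnegative")
  if (any(diff(object@conc) <= 0))
    return("concentrations must be strictly increasing")
  if (!object@model %in% c("single-site", "cooperative2"))
    return("model must be 'single-site' or 'cooperative2'")
  TRUE
})

#' @param conc concentrations (mM).
#' @param dshift shift changes (ppm).
#' @param nucleus nucleus label.
#' @param model `"single-site"` or `"cooperative2"`.
#' @return `titrationSeries()` returns a `TitrationSeries` object.
#' @rdname TitrationSeries-class
#' @examples
#' titrationSeries(c(0.5, 1, 3, 10, 30, 100), c(.03, .06, .1, .15, .18, .2))
#' @export
titrationSeries <- function(conc, dshift, nucleus = "", model = "single-site") {
  new("TitrationSeries", conc = as.numeric(conc), dshift = as.numeric(dshift),
      nucleus = nucleus, model = model)
}

#' Constant-time intensity-ratio series
#'
#' I_cross/I_ref ratios at a set of constant-time delays for one replicate of
#' a quantitative-J experiment, the input of [fitCTJCoupling()].
#'
#' @slot tau numeric, constant-time delays in seconds.
#' @slot ratio numeric, I_cross/I_ref; must lie in `[-1, 1]` (use
#'   `clip = TRUE` in [ctIntensitySeries()] to clip small overshoots).
#' @slot replicate character(1) replicate id.
#' @name CTIntensitySeries-class
#' @aliases CTIntensitySeries
#' @exportClass CTIntensitySeries
setClass("CTIntensitySeries",
         representation(tau = "numeric", ratio = "numeric",
                        replicate = "character"),
         prototype(replicate = "1"))

setValidity("CTIntensitySeries", function(object) {
  if (length(object@tau) != length(object@ratio))
    return("tau and ratio must have equal length")
  if (any(object@tau <= 0)) return("tau delays must be > 0")
  if (any(abs(object@ratio) > 1))
    return("ratios must lie in [-1, 1] (set clip = TRUE to clip)")
  TRUE
})

#' @param tau delays in seconds.
#' @param ratio I_cross/I_ref values.
#' @param replicate replicate id.
#' @param clip clip ratios marginally outside `[-1, 1]` (noise overshoot)
#'   back to the boundary instead of failing validation.
#' @return `ctIntensitySeries()` returns a `CTIntensitySeries` object.
#' @rdname CTIntensitySeries-class
#' @examples
#' ctIntensitySeries(tau = c(.05, .1, .15), ratio = c(.9, .65, .3))
#' @export
ctIntensitySeries <- function(tau, ratio, replicate = "1", clip = FALSE) {
  ratio <- as.numeric(ratio)
  if (clip) ratio <- pmin(1, pmax(-1, ratio))
  new("CTIntensitySeries", tau = as.numeric(tau), ratio = ratio,
      replicate = as.character(replicate))
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "Ensemble", function(object) {
  d <- dim(object@coords)
  cat("Ensemble:", d[3], "frame(s),", d[1], "atoms,",
      length(unique(object@atoms$resno)), "residues\n")
  if (!is.na(object@dt)) cat("  dt:", object@dt, "ps\n")
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
  if (object@aligned) cat("  (superposed on the ensemble average)\n")
})

setMethod("show", "StructureFrame", function(object) {
  cat("StructureFrame", object@index, "with", nrow(object@xyz), "atoms\n")
})

setMethod("show", "NOERestraint", function(object) {
  cat("NOERestraint:",
      paste(vapply(object@groupA, formatAtomRef, ""), collapse = ";"), "<->",
      paste(vapply(object@groupB, formatAtomRef, ""), collapse = ";"),
      " upper", object@upper, "A\n")
})

setMethod("show", "HBondCriteria", function(object) {
  cat("HBondCriteria: d <", object@dMax, "A, angle >", object@angleMin,
      "deg (strict)\n")
})

setMethod("show", "IonSite", function(object) {
  cat("IonSite", sQuote(object@id), "species", object@species,
      "| primary", formatAtomRef(object@primary),
      "| inner", object@inner, "A, outer", object@outer, "A\n")
})

setMethod("show", "TitrationSeries", function(object) {
  cat("TitrationSeries", sQuote(object@nucleus), "(", object@model, "):",
      length(object@conc), "points,",
      min(object@conc), "-", max(object@conc), "mM\n")
})

setMethod("show", "CTIntensitySeries", function(object) {
  cat("CTIntensitySeries replicate", object@replicate, ":",
      length(object@tau), "delays\n")
})
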