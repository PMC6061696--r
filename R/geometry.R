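## Elementary geometric operators, all vectorized across frames. Internal
## helpers take the (atoms, coords) pair produced by asCoordSet().

## frames x 3 coordinate trace of atom `i`
atomTrace <- function(coords, i) {
  m <- coords[i, , , drop = FALSE]
  matrix(aperm(m, c(3L, 2L, 1L)), ncol = 3L)
}

distSeries <- function(coords, i, j) {
  d <- atomTrace(coords, i) - atomTrace(coords, j)
  sqrt(rowSums(d * d))
}

## D-H-A angle at the hydrogen, in degrees
angleSeries <- function(coords, iD, iH, iA) {
  u <- atomTrace(coords, iD) - atomTrace(coords, iH)
  v <- atomTrace(coords, iA) - atomTrace(coords, iH)
  cosang <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Detect a hydrogen bond
#'
#' Evaluates the donor/hydrogen/acceptor triple in every frame against the
#' distance/angle criteria. Both thresholds are strict, exactly as
#' conventionally printed: the bond is counted when the donor-acceptor
#' heavy-atom distance is `< dMax` and the D-H-A angle is `> angleMin`.
#' Geometry is recorded for every frame whether or not the bond is satisfied.
#'
#' @param x an [Ensemble-class] or [StructureFrame-class].
#' @param donor,hydrogen,acceptor atom references (`AtomRef` or
#'   `"resno:atom"`).
#' @param criteria an [HBondCriteria-class]; default 3.5 Angstrom / 120 deg.
#' @return a `data.frame` with one row per frame and columns `frame`,
#'   `distance` (heavy-atom, Angstrom), `angle` (degrees) and `satisfied`.
#' @details A warning is issued when the hydrogen lies more than 1.2 Angstrom
#'   from the donor in the first frame (covalently implausible labelling).
#' @examples
#' e <- genConformerEnsemble(conformerSimSpec(nFrames = 1, seed = 1))
#' detectHBond(e, "13:N3", "13:H3", "18:O4")
#' @export
detectHBond <- function(x, donor, hydrogen, acceptor,
                        criteria = hbondCriteria()) {
  cs <- asCoordSet(x)
  iD <- resolveAtom(cs$atoms, donor)
  iH <- resolveAtom(cs$atoms, hydrogen)
  iA <- resolveAtom(cs$atoms, acceptor)
  dDH <- distSeries(cs$coords, iD, iH)
  if (dDH[1] > 1.2)
    warning("hydrogen ", sQuote(formatAtomRef(atomRef(hydrogen))),
            " is ", round(dDH[1], 2),
            " A from the donor; covalently implausible")
  d <- distSeries(cs$coords, iD, iA)
  ang <- angleSeries(cs$coords, iD, iH, iA)
  data.frame(frame = seq_along(d), distance = d, angle = ang,
             satisfied = d < criteria@dMax & ang > criteria@angleMin)
}

## Per-frame qualifying-water residue number (NA when none). Vectorized over
## frames; loops only over the (few) water residues, in increasing residue
## number so the first hit is the documented smallest-number tie-break.
waterBridgeSeries <- function(cs, iD, iH, iA, criteria) {
  atoms <- cs$atoms
  wat <- which(isWaterName(atoms$resname))
  nf <- dim(cs$coords)[3]
  out <- rep(NA_integer_, nf)
  if (!length(wat)) return(out)
  open <- rep(TRUE, nf)
  for (w in sort(unique(atoms$resno[wat]))) {
    rows <- wat[atoms$resno[wat] == w]
    iO <- rows[atoms$element[rows] == "O"]
    iHs <- rows[atoms$element[rows] == "H"]
    if (length(iO) != 1L || !length(iHs)) next
    accept <- distSeries(cs$coords, iD, iO) < criteria@dMax &
      angleSeries(cs$coords, iD, iH, iO) > criteria@angleMin
    donate <- rep(FALSE, nf)
    dOA <- distSeries(cs$coords, iO, iA)
    for (ih in iHs)
      donate <- donate | (dOA < criteria@dMax &
                            angleSeries(cs$coords, iO, ih, iA) >
                            criteria@angleMin)
    hit <- open & accept & donate
    out[hit] <- w
    open <- open & !hit
    if (!any(open)) break
  }
  out
}

#' Detect a water-mediated hydrogen bond bridge
#'
#' Searches for a water whose oxygen simultaneously (i) accepts a hydrogen
#' bond from the donor triple `partner_a` and (ii) donates, through either of
#' its hydrogens, to the acceptor `acceptorB`, both under `criteria`. When
#' several waters qualify in the same frame the one with the smallest residue
#' number is returned (documented tie-break).
#'
#' @param x an [Ensemble-class] or [StructureFrame-class] containing waters
#'   with hydrogens.
#' @param donor,hydrogen donor heavy atom and its hydrogen (partner A).
#' @param acceptorB acceptor atom on partner B.
#' @param criteria an [HBondCriteria-class].
#' @return a `data.frame` with columns `frame`, `water` (bridging water
#'   residue number, `NA` when no water qualifies) and `bridged`.
#' @export
detectWaterBridge <- function(x, donor, hydrogen, acceptorB,
                              criteria = hbondCriteria()) {
  cs <- asCoordSet(x)
  iD <- resolveAtom(cs$atoms, donor)
  iH <- resolveAtom(cs$atoms, hydrogen)
  iA <- resolveAtom(cs$atoms, acceptorB)
  w <- waterBridgeSeries(cs, iD, iH, iA, criteria)
  data.frame(frame = seq_along(w), water = w, bridged = !is.na(w))
}

ringAtomDefaults <- function(resname) {
  if (resname %in% c("A", "G", "ADE", "GUA", "DA", "DG"))
    c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

glycosidicN <- function(resname) {
  if (resname %in% c("A", "G", "ADE", "GUA", "DA", "DG")) "N9" else "N1"
}

#' Fit a least-squares base plane
#'
#' Fits the plane minimizing the sum of squared perpendicular distances to
#' the base ring atoms (singular-value solution of the centered
#' coordinates). The normal sign is fixed toward the glycosidic N -> C1'
#' direction when both atoms are present, for reproducibility; ring-only
#' atoms are the default (exocyclic atoms can be included by passing
#' `ringAtoms` explicitly).
#'
#' @param x a [StructureFrame-class] (or 1-frame [Ensemble-class]).
#' @param resno residue number of the base.
#' @param ringAtoms atom names defining the plane; defaults to the
#'   six-membered ring for pyrimidines and all nine ring atoms for purines.
#' @return a list of class `"uturnPlane"` with elements `centroid`, `normal`
#'   (unit vector), `residual` (rms perpendicular distance, Angstrom) and
#'   `resno`.
#' @export
fitBasePlane <- function(x, resno, ringAtoms = NULL) {
  cs <- asCoordSet(x)
  if (dim(cs$coords)[3] != 1L)
    stop("fitBasePlane() expects a single frame; see planeAtomDistanceSeries()")
  fitBasePlaneXYZ(cs$atoms, cs$coords[, , 1L, drop = TRUE], resno, ringAtoms)
}

fitBasePlaneXYZ <- function(atoms, xyz, resno, ringAtoms = NULL) {
  rows <- which(atoms$resno == resno)
  if (!length(rows)) stop("no atoms for residue ", resno)
  resname <- atoms$resname[rows[1]]
  if (is.null(ringAtoms)) ringAtoms <- ringAtomDefaults(resname)
  ringAtoms <- normalizeAtomName(ringAtoms)
  sel <- rows[match(ringAtoms, atoms$atom[rows])]
  if (anyNA(sel))
    stop("residue ", resno, " lacks ring atom(s) ",
         paste(ringAtoms[is.na(sel)], collapse = ", "))
  pts <- xyz[sel, , drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 ring atoms")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  if (sv$d[2] < 1e-8)
    stop("ring atoms of residue ", resno, " are collinear")
  normal <- sv$v[, 3L]
  resid <- sqrt(mean((sweep(pts, 2L, ctr) %*% normal)^2))
  iN <- rows[match(glycosidicN(resname), atoms$atom[rows])]
  iC1 <- rows[match("C1'", atoms$atom[rows])]
  if (!is.na(iN) && !is.na(iC1)) {
    ref <- xyz[iC1, ] - xyz[iN, ]
    if (sum(normal * ref) < 0) normal <- -normal
  }
  structure(list(centroid = ctr, normal = normal, residual = resid,
                 resno = resno), class = "uturnPlane")
}

#' @export
print.uturnPlane <- function(x, ...) {
  cat("Base plane of residue", x$resno, "| normal (",
      paste(sprintf("%.3f", x$normal), collapse = ", "),
      ") | rms residual", sprintf("%.4f", x$residual), "A\n")
  invisible(x)
}

#' Perpendicular base-plane to atom distance series
#'
#' For every frame, fits the base plane of `baseResno` and records the
#' unsigned perpendicular distance of `target` from it. This is the quantity
#' used to characterize anion-pi (phosphate oxygen over a base) and
#' lone-pair-pi (ether oxygen over a base) contacts. The summary reports the
#' median (midpoint of the two central values for even frame counts)
#' plus/minus the standard deviation across frames.
#'
#' @param x an [Ensemble-class].
#' @param baseResno residue number whose base plane is fitted.
#' @param target [AtomRef-class] or `"resno:atom"` of the probe atom.
#' @param ringAtoms optional plane-atom override, see [fitBasePlane()].
#' @return a list with `distances` (numeric, per frame), `median` and `sd`
#'   (Angstrom), and the inputs `base` and `target`.
#' @examples
#' e <- genSyntheticNSR(seed = 1)
#' planeAtomDistanceSeries(e, 14, "16:OP2")$median
#' @export
planeAtomDistanceSeries <- function(x, baseResno, target, ringAtoms = NULL) {
  stopifnot(is(x, "Ensemble"))
  iT <- resolveAtom(x@atoms, target)
  nf <- nFrames(x)
  d <- numeric(nf)
  for (i in seq_len(nf)) {
    xyz <- x@coords[, , i, drop = TRUE]
    pl <- fitBasePlaneXYZ(x@atoms, xyz, baseResno, ringAtoms)
    d[i] <- abs(sum((xyz[iT, ] - pl$centroid) * pl$normal))
  }
  list(distances = d, median = median(d), sd = if (nf > 1L) sd(d) else 0,
       base = baseResno, target = formatAtomRef(atomRef(target)))
}
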