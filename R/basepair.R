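## cWW U/U base-pair conformer classification: state schemes, per-frame
## labels, populations and transition counts.

#' Base-pair conformer state definition
#'
#' A state is defined by the direct hydrogen bonds and water bridges it
#' requires. All requirements must hold simultaneously for a frame to carry
#' the label.
#'
#' @slot label character(1), unique within a scheme (e.g. `"2a"`).
#' @slot direct list of direct H-bond triples, each a character vector
#'   `c(donor, hydrogen, acceptor)` of `"resno:atom"` references.
#' @slot bridges list of water-bridge requirements, each a character vector
#'   `c(donor, hydrogen, acceptorB)`: the donor triple hydrogen-bonds to a
#'   water which in turn donates to `acceptorB` (see [detectWaterBridge()]).
#' @name StateDefinition-class
#' @aliases StateDefinition
#' @exportClass StateDefinition
setClass("StateDefinition",
         representation(label = "character", direct = "list",
                        bridges = "list"))

setValidity("StateDefinition", function(object) {
  if (!nzchar(object@label)) return("label must be nonempty")
  if (!length(object@direct) && !length(object@bridges))
    return("a state needs at least one requirement")
  ok <- function(x) is.character(x) && length(x) == 3L
  if (!all(vapply(object@direct, ok, TRUE)) ||
      !all(vapply(object@bridges, ok, TRUE)))
    return("requirements must be character triples c(donor, hydrogen, acceptor)")
  TRUE
})

#' @param label state label.
#' @param direct list of direct-bond triples.
#' @param bridges list of water-bridge triples.
#' @return `stateDefinition()` returns a `StateDefinition`.
#' @rdname StateDefinition-class
#' @export
stateDefinition <- function(label, direct = list(), bridges = list()) {
  if (is.character(direct)) direct <- list(direct)
  if (is.character(bridges)) bridges <- list(bridges)
  new("StateDefinition", label = label, direct = direct, bridges = bridges)
}

#' Base-pair conformer scheme
#'
#' An ordered list of [StateDefinition-class]s. When several states'
#' requirements are met simultaneously, the state with more direct H-bonds
#' wins (the two-bond arrangements are the reference arrangements); among
#' equals, list order decides (so `2a` beats `2b`).
#'
#' @slot name scheme name (e.g. `"U13U18"`).
#' @slot states list of [StateDefinition-class].
#' @name StateScheme-class
#' @aliases StateScheme
#' @exportClass StateScheme
setClass("StateScheme",
         representation(name = "character", states = "list"))

setValidity("StateScheme", function(object) {
  if (!all(vapply(object@states, is, TRUE, "StateDefinition")))
    return("states must be StateDefinition objects")
  labs <- vapply(object@states, function(s) s@label, "")
  if (anyDuplicated(labs)) return("state labels must be unique")
  TRUE
})

#' @param name scheme name.
#' @param states list of [StateDefinition-class].
#' @return `stateScheme()` returns a `StateScheme`.
#' @rdname StateScheme-class
#' @export
stateScheme <- function(name, states) {
  new("StateScheme", name = name, states = states)
}

setMethod("show", "StateScheme", function(object) {
  cat("StateScheme", sQuote(object@name), "with states:",
      paste(schemeLabels(object), collapse = ", "), "\n")
})

#' @rdname builtinSchemes
#' @param scheme a [StateScheme-class].
#' @export
schemeLabels <- function(scheme) vapply(scheme@states, function(s) s@label, "")

## evaluation priority: more direct bonds first, then list order
schemePriority <- function(scheme) {
  nd <- vapply(scheme@states, function(s) length(s@direct), 0L)
  order(-nd, seq_along(scheme@states))
}

#' Built-in U/U base-pair conformer schemes
#'
#' Returns the two cWW U/U schemes of the neomycin-sensing riboswitch.
#'
#' `U13U18` has two states: `2a` with direct U13(N3)H3 -> U18(O4) and
#' U18(N3)H3 -> U13(O2) bonds, and `1a` where the U18(N3)/U13(O2)
#' interaction is water-mediated while the U13(N3) -> U18(O4) bond stays
#' direct. Steric hindrance permits only this one two-bond arrangement and
#' its water-mediated variant for this pair.
#'
#' `U10U21` additionally has the symmetry-related states: `2a` with
#' U21(N3) -> U10(O2) and U10(N3) -> U21(O4) bonds, `2b` with the O2/O4
#' roles swapped (U10(N3) -> U21(O2) and U21(N3) -> U10(O4)), and the
#' single-direct-bond variants `1a`/`1b` in which the H-bond involving the
#' O2 atom is water-mediated.
#'
#' @param resA,resB optional residue-number overrides for applying a scheme
#'   shape to a different U/U pair.
#' @return `builtinSchemes()` returns a named list with elements `U13U18`
#'   and `U10U21`.
#' @examples
#' schemeLabels(builtinSchemes()$U10U21)
#' @export
builtinSchemes <- function() {
  list(U13U18 = uuScheme("U13U18", 13, 18, mirror = FALSE),
       U10U21 = uuScheme("U10U21", 10, 21, mirror = TRUE))
}

## cWW U/U scheme template. "a" arrangement: B(N3)->A(O2) and A(N3)->B(O4);
## "b" mirrors the O2/O4 roles. In 1a/1b the bond involving O2 is the
## water-mediated one.
uuScheme <- function(name, resA, resB, mirror = TRUE) {
  r <- function(res, atom) paste0(res, ":", atom)
  bondBA_O2 <- c(r(resB, "N3"), r(resB, "H3"), r(resA, "O2"))
  bondAB_O4 <- c(r(resA, "N3"), r(resA, "H3"), r(resB, "O4"))
  st2a <- stateDefinition("2a", direct = list(bondBA_O2, bondAB_O4))
  st1a <- stateDefinition("1a", direct = list(bondAB_O4),
                          bridges = list(bondBA_O2))
  if (!mirror) return(stateScheme(name, list(st2a, st1a)))
  bondAB_O2 <- c(r(resA, "N3"), r(resA, "H3"), r(resB, "O2"))
  bondBA_O4 <- c(r(resB, "N3"), r(resB, "H3"), r(resA, "O4"))
  st2b <- stateDefinition("2b", direct = list(bondAB_O2, bondBA_O4))
  st1b <- stateDefinition("1b", direct = list(bondBA_O4),
                          bridges = list(bondAB_O2))
  stateScheme(name, list(st2a, st2b, st1a, st1b))
}

## frames x requirement satisfaction for every distinct requirement of a
## scheme; returns list(directSat, bridgeSat) of named logical matrices.
schemeSatisfaction <- function(cs, scheme, criteria) {
  keyOf <- function(tr) paste(tr, collapse = "|")
  directs <- list(); bridges <- list()
  for (s in scheme@states) {
    for (tr in s@direct) directs[[keyOf(tr)]] <- tr
    for (tr in s@bridges) bridges[[keyOf(tr)]] <- tr
  }
  nf <- dim(cs$coords)[3]
  dSat <- matrix(FALSE, nf, length(directs),
                 dimnames = list(NULL, names(directs)))
  for (k in names(directs)) {
    tr <- directs[[k]]
    iD <- resolveAtom(cs$atoms, tr[1])
    iH <- resolveAtom(cs$atoms, tr[2])
    iA <- resolveAtom(cs$atoms, tr[3])
    dSat[, k] <- distSeries(cs$coords, iD, iA) < criteria@dMax &
      angleSeries(cs$coords, iD, iH, iA) > criteria@angleMin
  }
  bSat <- matrix(FALSE, nf, length(bridges),
                 dimnames = list(NULL, names(bridges)))
  hasWater <- any(isWaterName(cs$atoms$resname))
  for (k in names(bridges)) {
    tr <- bridges[[k]]
    if (!hasWater) next
    iD <- resolveAtom(cs$atoms, tr[1])
    iH <- resolveAtom(cs$atoms, tr[2])
    iA <- resolveAtom(cs$atoms, tr[3])
    bSat[, k] <- !is.na(waterBridgeSeries(cs, iD, iH, iA, criteria))
  }
  list(direct = dSat, bridge = bSat, hasWater = hasWater)
}

classifyAll <- function(cs, scheme, criteria) {
  sat <- schemeSatisfaction(cs, scheme, criteria)
  nf <- dim(cs$coords)[3]
  labels <- rep("unassigned", nf)
  open <- rep(TRUE, nf)
  keyOf <- function(tr) paste(tr, collapse = "|")
  for (si in schemePriority(scheme)) {
    s <- scheme@states[[si]]
    if (length(s@bridges) && !sat$hasWater) next  # state unavailable
    ok <- rep(TRUE, nf)
    for (tr in s@direct) ok <- ok & sat$direct[, keyOf(tr)]
    for (tr in s@bridges) ok <- ok & sat$bridge[, keyOf(tr)]
    hit <- open & ok
    labels[hit] <- s@label
    open <- open & !hit
    if (!any(open)) break
  }
  labels
}

#' Classify one frame into a base-pair conformer state
#'
#' Assigns the first state (by priority: more direct H-bonds first, then
#' scheme list order) whose direct H-bonds are all satisfied and whose water
#' bridges are all found; otherwise `"unassigned"`. A frame meeting a
#' two-direct-bond state's requirements carries that label even if a
#' bridging water is also present (direct beats mediated).
#'
#' @param x a [StructureFrame-class] (or 1-frame [Ensemble-class]).
#' @param scheme a [StateScheme-class].
#' @param criteria an [HBondCriteria-class].
#' @return the state label, a character scalar.
#' @examples
#' e <- genConformerEnsemble(conformerSimSpec(nFrames = 1, seed = 1))
#' classifyFrame(getFrame(e, 1), builtinSchemes()$U13U18)
#' @export
classifyFrame <- function(x, scheme, criteria = hbondCriteria()) {
  cs <- asCoordSet(x)
  if (dim(cs$coords)[3] != 1L)
    stop("classifyFrame() expects a single frame; see tracePopulations()")
  classifyAll(cs, scheme, criteria)[1]
}

#' Trace base-pair conformer populations over an ensemble
#'
#' Classifies every frame (see [classifyFrame()]) and summarizes state
#' populations and transitions. Fractions over all frames (the unassigned
#' fraction reported separately) and percentages renormalized over assigned
#' frames only are both returned. States requiring water bridges are
#' reported as unavailable (`NA` fraction) when the ensemble contains no
#' waters, rather than as zero.
#'
#' @param x an [Ensemble-class].
#' @param scheme a [StateScheme-class].
#' @param criteria an [HBondCriteria-class].
#' @return a list of class `"uturnStateTrace"`: `labels` (per frame),
#'   `fractions` (over all frames, incl. `unassigned`), `assignedPercent`
#'   (renormalized over assigned frames), `transitions` (count matrix over
#'   consecutive frame pairs), `scheme`, `nFrames`.
#' @examples
#' e <- genConformerEnsemble(conformerSimSpec(nFrames = 200, seed = 1))
#' tracePopulations(e, builtinSchemes()$U13U18)$assignedPercent
#' @export
tracePopulations <- function(x, scheme, criteria = hbondCriteria()) {
  stopifnot(is(x, "Ensemble"))
  cs <- asCoordSet(x)
  labels <- classifyAll(cs, scheme, criteria)
  labs <- schemeLabels(scheme)
  hasWater <- any(isWaterName(cs$atoms$resname))
  unavailable <- vapply(scheme@states,
                        function(s) length(s@bridges) > 0 && !hasWater, TRUE)
  names(unavailable) <- labs
  nf <- length(labels)
  counts <- table(factor(labels, levels = c(labs, "unassigned")))
  fractions <- as.numeric(counts) / nf
  names(fractions) <- names(counts)
  fractions[names(which(unavailable))] <- NA_real_
  nAssigned <- sum(labels != "unassigned")
  pct <- if (nAssigned)
    100 * as.numeric(counts[labs]) / nAssigned else rep(NA_real_, length(labs))
  names(pct) <- labs
  pct[unavailable] <- NA_real_
  lv <- c(labs, "unassigned")
  trans <- table(factor(labels[-nf], levels = lv),
                 factor(labels[-1L], levels = lv))
  structure(list(labels = labels, fractions = fractions,
                 assignedPercent = pct, transitions = unclass(trans),
                 scheme = scheme@name, nFrames = nf),
            class = "uturnStateTrace")
}

#' @export
print.uturnStateTrace <- function(x, ...) {
  cat("State trace (", x$scheme, "), ", x$nFrames, " frames\n", sep = "")
  cat("  fractions over all frames:\n")
  print(round(x$fractions, 4))
  cat("  percent over assigned frames:\n")
  print(round(x$assignedPercent, 2))
  invisible(x)
}
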