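## Iterative superposition onto the ensemble average and per-residue RMSD.

## Kabsch: optimal rotation of `mov` onto `ref` over rows `sel`; applies the
## resulting rigid transform to all rows of `mov`.
kabschFit <- function(mov, ref, sel) {
  cm <- colMeans(mov[sel, , drop = FALSE])
  cr <- colMeans(ref[sel, , drop = FALSE])
  A <- sweep(mov[sel, , drop = FALSE], 2L, cm)
  B <- sweep(ref[sel, , drop = FALSE], 2L, cr)
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(mov, 2L, cm) %*% t(R), 2L, cr, `+`)
}

#' Superpose an ensemble on its average structure and compute per-residue RMSD
#'
#' Iterative procedure: all frames are first superposed on frame 1 by the
#' optimal rigid rotation/translation over the fit subset, the coordinate
#' average is computed, all frames are re-superposed on the average and the
#' average recomputed, until the average structure moves by less than `tol`
#' (maximum atom displacement, Angstrom). Per-residue RMSD is then computed
#' over heavy atoms against the final average.
#'
#' @param x an [Ensemble-class] with at least 2 frames.
#' @param subset atoms used for the fit: a character vector of
#'   `"resno:atom"` references, an integer vector of atom-table row indices,
#'   or `NULL` for all heavy atoms.
#' @param tol convergence tolerance on the average structure (Angstrom).
#' @param maxIter iteration cap.
#' @return a list with `ensemble` (the aligned [Ensemble-class], flagged
#'   `aligned`), `average` (natoms x 3 matrix), `perResidue` (`data.frame`
#'   with `resno`, `resname`, `rmsd` over heavy atoms) and `perAtom`
#'   (numeric, per-atom RMSD).
#' @examples
#' e <- genSyntheticNSR(seed = 1)
#' sup <- superposeAndRMSD(e)
#' head(sup$perResidue)
#' @export
superposeAndRMSD <- function(x, subset = NULL, tol = 1e-4, maxIter = 50L) {
  stopifnot(is(x, "Ensemble"))
  nf <- nFrames(x)
  if (nf < 2L) stop("superposition needs at least 2 frames")
  heavy <- which(x@atoms$element != "H")
  sel <- if (is.null(subset)) heavy
  else if (is.numeric(subset)) as.integer(subset)
  else vapply(subset, function(r) resolveAtom(x@atoms, r), 0L)
  if (!length(sel)) stop("fit subset is empty")
  co <- x@coords
  ref <- co[, , 1L, drop = TRUE]
  for (i in seq_len(nf)) co[, , i] <- kabschFit(co[, , i], ref, sel)
  avg <- apply(co, c(1L, 2L), mean)
  for (iter in seq_len(maxIter)) {
    for (i in seq_len(nf)) co[, , i] <- kabschFit(co[, , i], avg, sel)
    newAvg <- apply(co, c(1L, 2L), mean)
    shift <- max(sqrt(rowSums((newAvg - avg)^2)))
    avg <- newAvg
    if (shift < tol) break
  }
  dev2 <- (co - as.vector(avg))^2       # array recycling over frames
  msdAtom <- apply(dev2, 1L, sum) / nf  # per-atom mean squared deviation
  resFac <- factor(x@atoms$resno, levels = unique(x@atoms$resno))
  perRes <- vapply(split(seq_len(nAtoms(x)), resFac), function(rows) {
    rows <- intersect(rows, heavy)
    if (!length(rows)) return(NA_real_)
    sqrt(mean(msdAtom[rows]))
  }, 0)
  aligned <- new("Ensemble", atoms = x@atoms, coords = co, dt = x@dt,
                 provenance = x@provenance, aligned = TRUE)
  list(ensemble = aligned, average = avg,
       perResidue = data.frame(
         resno = as.integer(levels(resFac)),
         resname = x@atoms$resname[match(levels(resFac), x@atoms$resno)],
         rmsd = unname(perRes)),
       perAtom = unname(sqrt(msdAtom)))
}
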