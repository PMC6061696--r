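## Synthetic stand-in for a solution-NMR ensemble of the 27-nt
## neomycin-sensing riboswitch hairpin. This is NOT the deposited
## experimental ensemble: it is toy geometry generated in code whose
## conditions are the experimentally reported NMR-row features -- both cWW
## U/U pairs in the two-direct-H-bond (2a) arrangement, the A16 phosphate
## oxygen 2.93 A above the base-14 plane (anion-pi), the U18 O4' ether
## oxygen 3.01 A above the A16 plane (lone-pair-pi), the U-turn signature
## N3/OP2 H-bond, and a K+ ion in contact with U14(O4).

.NSR_SEQ <- c("G", "G", "C", "U", "G", "C", "U", "U", "G", "U", "C", "C",
              "U", "U", "U", "A", "A", "U", "G", "G", "U", "C", "C", "A",
              "G", "U", "C")

#' Generate a synthetic NSR-style NMR ensemble
#'
#' Builds a 27-residue, multi-model synthetic stand-in for a
#' neomycin-sensing-riboswitch solution ensemble (toy coordinates, see
#' Details), plus two distant waters and one K+ ion at the U14(O4) site.
#' Inter-model variation is isotropic Gaussian coordinate noise.
#'
#' @details The generator realizes, exactly at its declared values: the
#' U13/U18 and U10/U21 pairs posed in their `2a` cWW arrangement (direct
#' H-bonds at ~2.9 Angstrom); `16:OP2` at `planeDistOP2` Angstrom along the
#' base-14 plane normal; `18:O4'` at `planeDistO4p` Angstrom along the A16
#' plane normal; `17:OP2` at 2.86 Angstrom from `14:N3` along the N3-H3
#' direction (the U-turn signature H-bond); a K+ ion 2.75 Angstrom from
#' `14:O4`. All other residues are stacked toy bases far from these
#' features. Coordinates are not chemically consistent between a residue's
#' base and its backbone atoms; the object exists to exercise the
#' measurement chain, not to represent the deposition.
#'
#' @param nModels number of models (frames).
#' @param noise inter-model Gaussian coordinate sigma in Angstrom.
#' @param planeDistOP2 base-14 plane to A16(OP2) distance (Angstrom).
#' @param planeDistO4p A16 plane to U18(O4') distance (Angstrom).
#' @param seed integer seed.
#' @return an [Ensemble-class] with 27 RNA residues, 2 waters and 1 ion.
#' @examples
#' e <- genSyntheticNSR(seed = 1)
#' countRNAResidues(e)
#' @export
genSyntheticNSR <- function(nModels = 20L, noise = 0.05,
                            planeDistOP2 = 2.93, planeDistO4p = 3.01,
                            seed = 1L) {
  resTab <- function(resno, resname, names, xyz) {
    data.frame(resno = resno, resname = resname, atom = names,
               element = guessElement(names),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  shift <- function(tab, off) {
    tab$x <- tab$x + off[1]; tab$y <- tab$y + off[2]; tab$z <- tab$z + off[3]
    tab
  }
  addBackbone <- function(tab) {
    c1 <- which(tab$atom == "C1'")[1]
    base <- as.numeric(tab[c1, c("x", "y", "z")])
    extra <- resTab(tab$resno[1], tab$resname[1], c("O4'", "OP2"),
                    rbind(base + c(1.2, 0, 0.6), base + c(0.5, -1.5, 1.2)))
    rbind(tab, extra)
  }
  special <- c(10L, 13L, 14L, 16L, 18L, 21L)
  parts <- list()
  ## scaffold: stacked toy bases well away from the featured region
  for (i in seq_along(.NSR_SEQ)) {
    if (i %in% special) next
    rn <- .NSR_SEQ[i]
    tpl <- if (rn %in% c("A", "G")) purineTemplate()
    else pyrimidineTemplate(withImino = rn == "U")
    xyz <- rotZ(tpl, (i - 1) * 33 * pi / 180)
    tab <- resTab(i, rn, rownames(tpl), xyz)
    parts[[length(parts) + 1L]] <-
      addBackbone(shift(tab, c(60, 60, 3.4 * i)))
  }
  ## cWW U/U pairs posed in the 2a arrangement
  schemes <- builtinSchemes()
  pose2a <- function(scheme, resA, resB, off) {
    tab <- poseUUPair(scheme@states[[1L]], resA, resB)
    shift(tab, off)
  }
  p1318 <- pose2a(schemes$U13U18, 13L, 18L, c(0, -30, 0))
  p1021 <- pose2a(schemes$U10U21, 10L, 21L, c(30, -30, 0))
  ## U14 and A16 bases flat in z = 0 planes at separated offsets
  tpl14 <- pyrimidineTemplate()
  t14 <- shift(resTab(14L, "U", rownames(tpl14), tpl14), c(-30, 0, 0))
  tpl16 <- purineTemplate()
  t16 <- shift(resTab(16L, "A", rownames(tpl16), tpl16), c(-30, 30, 0))
  ring14 <- t14[t14$atom %in% c("N1", "C2", "N3", "C4", "C5", "C6"), ]
  ctr14 <- colMeans(as.matrix(ring14[, c("x", "y", "z")]))
  ring16 <- t16[t16$atom %in% c("N1", "C2", "N3", "C4", "C5", "C6", "N7",
                                "C8", "N9"), ]
  ctr16 <- colMeans(as.matrix(ring16[, c("x", "y", "z")]))
  asXYZ <- function(tab, at) {
    r <- which(tab$atom == at)
    as.numeric(tab[r, c("x", "y", "z")])
  }
  ## assemble special residues with backbone atoms, then apply the
  ## declared-feature overrides
  s13 <- addBackbone(p1318[p1318$resno == 13L, ])
  s18 <- addBackbone(p1318[p1318$resno == 18L, ])
  s10 <- addBackbone(p1021[p1021$resno == 10L, ])
  s21 <- addBackbone(p1021[p1021$resno == 21L, ])
  s14 <- addBackbone(t14)
  s16 <- addBackbone(t16)
  ## anion-pi: A16 OP2 along the base-14 plane normal (z)
  s16[s16$atom == "OP2", c("x", "y", "z")] <-
    as.list(ctr14 + c(0, 0, planeDistOP2))
  ## lone-pair-pi: U18 O4' along the A16 plane normal (z)
  s18[s18$atom == "O4'", c("x", "y", "z")] <-
    as.list(ctr16 + c(0, 0, planeDistO4p))
  parts <- c(parts, list(s10, s13, s14, s16, s18, s21))
  tab <- do.call(rbind, parts)
  ## U-turn signature H-bond: A17 OP2 placed along U14 N3-H3
  n3 <- asXYZ(s14, "N3"); h3 <- asXYZ(s14, "H3")
  u <- (h3 - n3) / sqrt(sum((h3 - n3)^2))
  tab[tab$resno == 17L & tab$atom == "OP2", c("x", "y", "z")] <-
    as.list(n3 + 2.86 * u)
  ## K+ ion in contact with U14(O4)
  o4 <- asXYZ(s14, "O4")
  uo <- (o4 - ctr14) / sqrt(sum((o4 - ctr14)^2))
  ion <- resTab(501L, "K", "K", matrix(o4 + 2.75 * uo, 1L))
  waters <- rbind(
    resTab(601L, "HOH", c("O", "H1", "H2"),
           rbind(c(80, 0, 0), c(80.98, 0, 0), c(80, 0.98, 0))),
    resTab(602L, "HOH", c("O", "H1", "H2"),
           rbind(c(0, 80, 0), c(0.98, 80, 0), c(0, 80.98, 0))))
  tab <- rbind(tab, ion, waters)
  tab <- tab[order(tab$resno, tab$atom), ]
  xyz0 <- as.matrix(tab[, c("x", "y", "z")])
  set.seed(seed)
  co <- array(rep(xyz0, nModels), c(nrow(tab), 3L, nModels))
  if (noise > 0) co <- co + array(rnorm(length(co), 0, noise), dim(co))
  ensemble(tab[, c("resno", "resname", "atom", "element")], co,
           provenance = sprintf(
             "synthetic NSR-style ensemble (seed %d, %d models)",
             seed, nModels))
}

#' Count RNA residues of an ensemble
#'
#' Number of distinct residue numbers after excluding waters and
#' single-atom ion residues.
#'
#' @param x an [Ensemble-class].
#' @return integer residue count.
#' @export
countRNAResidues <- function(x) {
  stopifnot(is(x, "Ensemble"))
  a <- x@atoms
  keep <- !isWaterName(a$resname) & !isIonName(a$resname)
  length(unique(a$resno[keep]))
}
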