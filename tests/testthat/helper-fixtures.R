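## Shared fixture builders: everything is generated in code at test time.

## minimal ensemble from an atom spec and a list of natoms x 3 matrices
mkEnsemble <- function(atoms, frames, dt = NA_real_, aligned = FALSE) {
  co <- array(NA_real_, c(nrow(atoms), 3L, length(frames)))
  for (i in seq_along(frames)) co[, , i] <- frames[[i]]
  ensemble(atoms, co, dt = dt, aligned = aligned)
}

## simple proton-only atom table for NOE tests
protonAtoms <- function(n) {
  data.frame(resno = seq_len(n), resname = "U", atom = rep("H3", n),
             element = "H")
}

## a random proper rotation matrix and translation
randomRigid <- function() {
  qr0 <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr0)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

## apply one rigid transform to every frame of an ensemble
applyRigid <- function(e, rt) {
  co <- coords(e)
  for (i in seq_len(nFrames(e)))
    co[, , i] <- sweep(co[, , i] %*% t(rt$R), 2L, rt$t, `+`)
  ensemble(atomTable(e), co, dt = frameDt(e), aligned = isAligned(e))
}

## hand-built frame with a donor triple, an acceptor and optional waters;
## waters is a list of 3-vectors (oxygen positions), hydrogens pointed at
## the acceptor
bridgeFrame <- function(waterPos = list(), waterResno = NULL,
                        accPos = c(4.9, 0, 0)) {
  tabs <- list(data.frame(
    resno = c(18L, 18L, 13L),
    resname = c("U", "U", "U"),
    atom = c("N3", "H3", "O2"),
    element = c("N", "H", "O"),
    x = c(0, 1.01, accPos[1]), y = c(0, 0, accPos[2]),
    z = c(0, 0, accPos[3])))
  if (is.null(waterResno)) waterResno <- 100L + seq_along(waterPos)
  for (i in seq_along(waterPos)) {
    ow <- waterPos[[i]]
    u <- accPos - ow; u <- u / sqrt(sum(u^2))
    h1 <- ow + 0.98 * u
    tabs[[length(tabs) + 1L]] <- data.frame(
      resno = waterResno[i], resname = "HOH",
      atom = c("O", "H1", "H2"), element = c("O", "H", "H"),
      x = c(ow[1], h1[1], ow[1]), y = c(ow[2], h1[2], ow[2] + 0.98),
      z = c(ow[3], h1[3], ow[3]))
  }
  tab <- do.call(rbind, tabs)
  mkEnsemble(tab[, 1:4], list(as.matrix(tab[, c("x", "y", "z")])))
}
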