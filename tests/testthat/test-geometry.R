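mkTriple <- function(D, H, A) {
  tab <- data.frame(resno = c(1L, 1L, 2L), resname = c("U", "U", "A"),
                    atom = c("N3", "H3", "OP2"),
                    element = c("N", "H", "O"))
  mkEnsemble(tab, list(rbind(D, H, A)))
}

test_that("hydrogen bonds use strict printed thresholds", {
  ## linear geometry at 2.9 A is satisfied
  hb <- detectHBond(mkTriple(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2.9)),
                    "1:N3", "1:H3", "2:OP2")
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$angle, 180)
  expect_true(hb$satisfied)
  ## a distance exactly at the cutoff fails (strict <): set the cutoff to
  ## the measured distance so the boundary is hit exactly in floating point
  e35 <- mkTriple(c(0, 0, 0), c(0, 0, 1), c(0, 0, 3.5))
  hb <- detectHBond(e35, "1:N3", "1:H3", "2:OP2")
  expect_equal(hb$distance, 3.5)
  expect_false(detectHBond(e35, "1:N3", "1:H3", "2:OP2",
                           hbondCriteria(dMax = hb$distance))$satisfied)
  ## an angle exactly at the cutoff fails (strict >)
  th <- 60 * pi / 180
  A <- c(0, 0, 1) + 1.9 * c(sin(th), 0, cos(th))
  eAng <- mkTriple(c(0, 0, 0), c(0, 0, 1), A)
  hb <- detectHBond(eAng, "1:N3", "1:H3", "2:OP2")
  expect_equal(hb$angle, 120, tolerance = 1e-9)
  expect_false(detectHBond(eAng, "1:N3", "1:H3", "2:OP2",
                           hbondCriteria(angleMin = hb$angle))$satisfied)
  expect_true(detectHBond(eAng, "1:N3", "1:H3", "2:OP2",
                          hbondCriteria(angleMin = hb$angle - 1e-9))$satisfied)
})

test_that("degenerate criteria accept any triple", {
  set.seed(42)
  crit <- hbondCriteria(dMax = Inf, angleMin = 1e-12)
  for (i in 1:20) {
    e <- mkTriple(rnorm(3, sd = 5), rnorm(3, sd = 5), rnorm(3, sd = 5))
    ## random triples are usually covalently implausible; that warning is
    ## not under test here
    hb <- suppressWarnings(detectHBond(e, "1:N3", "1:H3", "2:OP2", crit))
    expect_true(hb$satisfied)
  }
})

test_that("a covalently implausible hydrogen triggers a warning", {
  expect_warning(
    detectHBond(mkTriple(c(0, 0, 0), c(0, 0, 2.0), c(0, 0, 2.9)),
                "1:N3", "1:H3", "2:OP2"),
    "implausible")
})

test_that("water bridges are found, absent, and tie-broken by residue number", {
  ## one water accepting from U18(N3)H3 and donating to U13(O2)
  e <- bridgeFrame(waterPos = list(c(2.6, 0.8, 0)))
  wb <- detectWaterBridge(e, "18:N3", "18:H3", "13:O2")
  expect_true(wb$bridged)
  expect_equal(wb$water, 101L)
  ## no water at all
  wb0 <- detectWaterBridge(bridgeFrame(), "18:N3", "18:H3", "13:O2")
  expect_false(wb0$bridged)
  ## far water does not bridge
  wbFar <- detectWaterBridge(bridgeFrame(waterPos = list(c(30, 0, 0))),
                             "18:N3", "18:H3", "13:O2")
  expect_false(wbFar$bridged)
  ## two qualifying waters, numbers 105 and 88: smallest wins
  e2 <- bridgeFrame(waterPos = list(c(2.6, 0.8, 0), c(2.6, -0.8, 0)),
                    waterResno = c(105L, 88L))
  wb2 <- detectWaterBridge(e2, "18:N3", "18:H3", "13:O2")
  expect_equal(wb2$water, 88L)
})

flatRing <- function(jitterZ = 0) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  tab <- data.frame(resno = 14L, resname = "U",
                    atom = c("N1", "C2", "N3", "C4", "C5", "C6"),
                    element = c("N", "C", "N", "C", "C", "C"))
  xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), jitterZ * rnorm(6))
  list(tab = tab, xyz = xyz)
}

test_that("base-plane fits are exact on flat rings and rigid-invariant", {
  r <- flatRing()
  e <- mkEnsemble(r$tab, list(r$xyz))
  pl <- fitBasePlane(getFrame(e, 1), 14)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$residual, 0, tolerance = 1e-12)
  set.seed(7)
  rt <- randomRigid()
  e2 <- applyRigid(e, rt)
  pl2 <- fitBasePlane(getFrame(e2, 1), 14)
  expect_equal(pl2$residual, pl$residual, tolerance = 1e-9)
  expect_equal(abs(sum(pl2$normal * (rt$R %*% pl$normal))), 1,
               tolerance = 1e-9)
})

test_that("the least-squares plane beats 10^4 random candidate planes", {
  set.seed(11)
  r <- flatRing(jitterZ = 0.05)
  e <- mkEnsemble(r$tab, list(r$xyz))
  pl <- fitBasePlane(getFrame(e, 1), 14)
  ctr <- colMeans(r$xyz)
  X <- sweep(r$xyz, 2, ctr)
  n <- matrix(rnorm(3e4), 1e4, 3)
  n <- n / sqrt(rowSums(n^2))
  proj <- X %*% t(n)                  # 6 x 10^4 projections
  rms <- sqrt(colMeans(sweep(proj, 2, colMeans(proj))^2))
  expect_lte(pl$residual, min(rms) + 1e-12)
})

test_that("degenerate ring inputs fail loudly", {
  tab <- data.frame(resno = 14L, resname = "U",
                    atom = c("N1", "C2", "N3", "C4", "C5", "C6"),
                    element = "C")
  line <- cbind(seq_len(6), 0, 0)
  e <- mkEnsemble(tab, list(line))
  expect_error(fitBasePlane(getFrame(e, 1), 14), "collinear")
  e2 <- genSyntheticNSR(nModels = 1, seed = 1)
  expect_error(fitBasePlane(getFrame(e2, 1), 14, ringAtoms = c("N1", "XX")),
               "XX")
})

test_that("plane-to-atom distances report per frame and summarize medians", {
  r <- flatRing()
  tab <- rbind(r$tab, data.frame(resno = 16L, resname = "A", atom = "OP2",
                                 element = "O"))
  f1 <- rbind(r$xyz, c(0, 0, 3.0))
  e <- mkEnsemble(tab, list(f1, f1))
  ps <- planeAtomDistanceSeries(e, 14, "16:OP2")
  expect_equal(ps$distances, c(3, 3), tolerance = 1e-12)
  expect_equal(ps$sd, 0)
  ## even-count median is the midpoint of the two central values
  f2 <- rbind(r$xyz, c(0, 0, 2.0))
  f3 <- rbind(r$xyz, c(0, 0, 4.0))
  e2 <- mkEnsemble(tab, list(f2, f3))
  expect_equal(planeAtomDistanceSeries(e2, 14, "16:OP2")$median, 3.0)
})

test_that("superposition recovers identical and rigidly rotated frames", {
  e <- genSyntheticNSR(nModels = 1, seed = 3)
  xyz <- coords(e)[, , 1]
  same <- mkEnsemble(atomTable(e), list(xyz, xyz, xyz))
  sup <- superposeAndRMSD(same)
  expect_lt(max(sup$perResidue$rmsd, na.rm = TRUE), 1e-10)
  set.seed(5)
  rots <- lapply(1:3, function(i) {
    rt <- randomRigid()
    sweep(xyz %*% t(rt$R), 2, rt$t, `+`)
  })
  sup2 <- superposeAndRMSD(mkEnsemble(atomTable(e), rots))
  expect_lt(max(sup2$perResidue$rmsd, na.rm = TRUE), 1e-6)
  expect_true(isAligned(sup2$ensemble))
})

test_that("atom RMSD about the average recovers the noise scale", {
  set.seed(13)
  n <- 40
  tab <- data.frame(resno = rep(1:8, each = 5), resname = "U",
                    atom = paste0("C", rep(1:5, 8), rep(1:8, each = 5)),
                    element = "C")
  base <- matrix(rnorm(n * 3, sd = 6), n, 3)
  sigma <- 0.25
  nf <- 10000
  co <- array(rep(base, nf), c(n, 3, nf)) +
    array(rnorm(n * 3 * nf, 0, sigma), c(n, 3, nf))
  a <- atomTable(ensemble(tab, co))
  sup <- superposeAndRMSD(ensemble(tab, co))
  expect_equal(mean(sup$perAtom), sigma * sqrt(3), tolerance = 0.05)
})

test_that("an empty fit subset is rejected", {
  e <- genSyntheticNSR(nModels = 2, seed = 1)
  expect_error(superposeAndRMSD(e, subset = integer(0)), "empty")
})

test_that("geometric outputs are invariant under global rigid motion", {
  set.seed(19)
  e <- genSyntheticNSR(nModels = 4, seed = 19)
  rt <- randomRigid()
  e2 <- applyRigid(e, rt)
  hb1 <- detectHBond(e, "14:N3", "14:H3", "17:OP2")
  hb2 <- detectHBond(e2, "14:N3", "14:H3", "17:OP2")
  expect_equal(hb2$distance, hb1$distance, tolerance = 1e-6)
  expect_equal(hb2$angle, hb1$angle, tolerance = 1e-6)
  p1 <- planeAtomDistanceSeries(e, 14, "16:OP2")
  p2 <- planeAtomDistanceSeries(e2, 14, "16:OP2")
  expect_equal(p2$distances, p1$distances, tolerance = 1e-6)
  r <- noeRestraint("13:H3", "18:H3", 5)
  expect_equal(ensembleNOEDistance(e2, r), ensembleNOEDistance(e, r),
               tolerance = 1e-6)
  s1 <- tracePopulations(e, builtinSchemes()$U13U18)
  s2 <- tracePopulations(e2, builtinSchemes()$U13U18)
  expect_identical(s1$labels, s2$labels)
})
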