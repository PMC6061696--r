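ionFixture <- function(ionPos, sitePos = c(0, 0, 0)) {
  tab <- data.frame(resno = c(14L, 13L, 501L),
                    resname = c("U", "U", "K"),
                    atom = c("O4", "O4", "K"),
                    element = c("O", "O", "K"))
  frames <- lapply(ionPos, function(p) rbind(sitePos, c(10, 0, 0), p))
  mkEnsemble(tab, frames, dt = 10, aligned = TRUE)
}

test_that("occupancy is keyed to the primary atom with shell bookkeeping", {
  site <- ionSite("14:O4", aux = "13:O4")
  e <- ionFixture(list(c(2.7, 0, 0), c(2.7, 0, 0)))
  occ <- siteOccupancy(e, site)
  expect_equal(occ$fraction, 1.0)
  ## ion at 2.7 from primary is 7.3 from the aux atom: outside both shells
  expect_equal(unname(occ$shells[, "13:O4"]), c("none", "none"))
  ## a frame with the ion beyond the inner cutoff is unoccupied
  e2 <- ionFixture(list(c(3.0, 0, 0), c(6.0, 0, 0)))
  occ2 <- siteOccupancy(e2, ionSite("14:O4", aux = "13:O4"))
  expect_equal(unname(occ2$occupied), c(TRUE, FALSE))
})

test_that("aux shells use the inner/outer distance bands", {
  ## place the bound ion 4.0 A from the aux atom directly
  e <- ionFixture(list(c(3.0, 0, 0))) # primary at 0, aux at (10,0,0)
  a <- atomTable(e)
  co <- coords(e)
  co[2, , 1] <- c(7.0, 0, 0)         # aux now 4.0 A from the ion
  occ <- siteOccupancy(ensemble(a, co, dt = 10), ionSite("14:O4", aux = "13:O4"))
  expect_equal(unname(occ$shells[1, "13:O4"]), "outer")
  co[2, , 1] <- c(5.0, 0, 0)         # aux 2.0 A from the ion: inner
  occ <- siteOccupancy(ensemble(a, co, dt = 10), ionSite("14:O4", aux = "13:O4"))
  expect_equal(unname(occ$shells[1, "13:O4"]), "inner")
})

test_that("residence episodes follow the documented absorption rule", {
  r <- residenceStatistics(c(TRUE, TRUE, FALSE, TRUE), dt = 10)
  expect_equal(r$episodes$duration_ps, c(20, 10))
  expect_equal(r$maxDuration, 20)
  r2 <- residenceStatistics(c(TRUE, TRUE, FALSE, TRUE), dt = 10,
                            tolerance = 1)
  expect_equal(nrow(r2$episodes), 1L)
  expect_equal(r2$episodes$duration_ps, 40)
  expect_error(residenceStatistics(c(TRUE), dt = 10, tolerance = -1),
               "tolerance")
  expect_error(residenceStatistics(c(TRUE), dt = NA), "dt")
})

test_that("episode frames conserve occupancy and survive frame reversal", {
  set.seed(3)
  occ <- runif(5000) < 0.3
  r <- residenceStatistics(occ, dt = 10)
  expect_equal(sum(r$episodes$frames) / length(occ), mean(occ))
  rRev <- residenceStatistics(rev(occ), dt = 10)
  expect_equal(rRev$meanDuration, r$meanDuration)
  expect_equal(rRev$maxDuration, r$maxDuration)
})

test_that("two-state generator parameters are recovered from the track", {
  spec <- ionSimSpec(p = 0.8, meanResidence = 250, dt = 10,
                     nFrames = 30000L, seed = 17)
  tr <- genIonTrajectory(spec)
  occ <- siteOccupancy(tr$ensemble, tr$site)
  ## correlated-chain standard error: binomial sigma times the dwell
  ## inflation factor sqrt((1+rho)/(1-rho))
  rho <- 1 - (10 / 250) - (10 / 250) * 0.8 / 0.2
  sig <- sqrt(0.8 * 0.2 / spec$nFrames) * sqrt((1 + rho) / (1 - rho))
  expect_lt(abs(occ$fraction - 0.8), 3 * sig)
  res <- residenceStatistics(occ$occupied, dt = 10)
  expect_lt(abs(res$meanDuration - 250) / 250, 0.10)
})

test_that("the RDF of uniformly placed ions is flat at 1", {
  tab <- data.frame(resno = c(1L, 500L + 1:32),
                    resname = c("U", rep("K", 32)),
                    atom = c("O4", rep("K", 32)),
                    element = c("O", rep("K", 32)))
  set.seed(5)
  nf <- 4000
  co <- array(runif(33 * 3 * nf, -10, 10), c(33, 3, nf))
  co[1, , ] <- 0
  e <- ensemble(tab, co)
  rdf <- computeRDF(e, "K", "1:O4", rMax = 8, binWidth = 0.25)
  sel <- rdf$r >= 3 & rdf$r <= 4
  expect_true(all(abs(rdf$g[sel] - 1) < 0.05))
  ## error shrinks with more frames (~1/sqrt(n))
  e2 <- ensemble(tab, co[, , 1:250, drop = FALSE])
  rdf2 <- computeRDF(e2, "K", "1:O4", rMax = 8, binWidth = 0.25)
  err <- function(r) sqrt(mean((r$g[sel] - 1)^2))
  expect_lt(err(rdf), err(rdf2))
})

test_that("a fixed ion gives a single-bin spike and counts are conserved", {
  e <- ionFixture(list(c(2.8, 0, 0), c(2.8, 0, 0), c(2.8, 0, 0)))
  rdf <- computeRDF(e, "K", "14:O4", rMax = 6, binWidth = 0.1)
  hit <- which(rdf$counts > 0)
  expect_length(hit, 1L)
  expect_true(rdf$r[hit] > 2.7 && rdf$r[hit] < 2.9)
  rdf2 <- computeRDF(e, "K", "14:O4", rMax = 6, binWidth = 0.2)
  expect_equal(sum(rdf2$counts), sum(rdf$counts))
  expect_equal(length(rdf2$counts), length(rdf$counts) / 2)
  expect_error(computeRDF(e, "MG", "14:O4"), "no ions")
})

test_that("density maxima find, rank and merge ion regions", {
  ## single fixed position: one region at that point
  e <- ionFixture(rep(list(c(2.8, 0, 0)), 10))
  dm <- densityMaxima(e, "K", k = 5)
  expect_equal(nrow(dm), 1L)
  expect_equal(unlist(dm[1, c("x", "y", "z")]), c(x = 2.8, y = 0, z = 0),
               tolerance = 1e-9)
  ## two sites occupied 70/30 rank in that order
  pos <- c(rep(list(c(5, 5, 5)), 7), rep(list(c(-5, -5, -5)), 3))
  dm2 <- densityMaxima(ionFixture(pos), "K", k = 2)
  expect_equal(nrow(dm2), 2L)
  expect_gt(dm2$count[1], dm2$count[2])
  expect_equal(unlist(dm2[1, c("x", "y", "z")]), c(x = 5, y = 5, z = 5),
               tolerance = 1e-9)
  ## five distinct sites, k = 5
  pts <- list(c(0, 0, 3), c(8, 0, 0), c(0, 8, 0), c(-8, 0, 0), c(0, -8, 0))
  dm5 <- densityMaxima(ionFixture(rep(pts, 2)), "K", k = 5)
  expect_equal(nrow(dm5), 5L)
  ## unaligned ensembles are rejected with advice
  eUn <- ionFixture(list(c(2.8, 0, 0)))
  eUn@aligned <- FALSE
  expect_error(densityMaxima(eUn, "K"), "superpose")
})
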