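schemes <- builtinSchemes()

test_that("built-in schemes carry the documented states", {
  expect_equal(schemeLabels(schemes$U13U18), c("2a", "1a"))
  expect_equal(schemeLabels(schemes$U10U21), c("2a", "2b", "1a", "1b"))
  expect_false(anyDuplicated(schemeLabels(schemes$U10U21)) > 0)
  ## 2a of U10/U21: U21(N3)->U10(O2) and U10(N3)->U21(O4)
  st2a <- schemes$U10U21@states[[1]]
  expect_setequal(vapply(st2a@direct, function(tr) tr[3], ""),
                  c("10:O2", "21:O4"))
})

test_that("declared-state generation is recovered frame-exactly at zero noise", {
  for (nm in names(schemes)) {
    labs <- schemeLabels(schemes[[nm]])
    P <- matrix(1 / length(labs), length(labs), length(labs),
                dimnames = list(labs, labs))
    e <- genConformerEnsemble(conformerSimSpec(nm, P = P, nFrames = 60,
                                               seed = 5, noise = 0))
    tr <- tracePopulations(e, schemes[[nm]])
    expect_identical(tr$labels, attr(e, "states"))
    expect_equal(sum(tr$fractions, na.rm = TRUE), 1, tolerance = 1e-9)
  }
})

test_that("frames with no interaction are unassigned and singletons are total", {
  tab <- data.frame(resno = c(13L, 13L, 13L, 13L, 18L, 18L, 18L, 18L),
                    resname = "U",
                    atom = rep(c("N3", "H3", "O2", "O4"), 2),
                    element = rep(c("N", "H", "O", "O"), 2))
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(50, 0, 0), c(51, 0, 0), c(50, 1, 0), c(50, -1, 0))
  e <- mkEnsemble(tab, list(far))
  expect_equal(classifyFrame(getFrame(e, 1), schemes$U13U18), "unassigned")

  one <- genConformerEnsemble(conformerSimSpec(
    nFrames = 1, seed = 2, noise = 0,
    P = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("2a", "1a"), c("2a", "1a")))))
  tr <- tracePopulations(one, schemes$U13U18)
  expect_equal(tr$fractions[["2a"]] + tr$fractions[["1a"]], 1)
})

test_that("direct beats water-mediated when both would match", {
  ## a 2a frame still classifies 2a after adding a water that bridges the
  ## same O2 interaction
  e <- genConformerEnsemble(conformerSimSpec(
    nFrames = 1, seed = 3, noise = 0,
    P = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("2a", "1a"), c("2a", "1a")))))
  stopifnot(attr(e, "states") == "2a")
  a <- atomTable(e)
  xyz <- coords(e)[, , 1]
  n3 <- xyz[resolveAtom(a, "18:N3"), ]
  o2 <- xyz[resolveAtom(a, "13:O2"), ]
  mid <- (n3 + o2) / 2 + c(0, 0, 1.2)
  u <- (o2 - mid) / sqrt(sum((o2 - mid)^2))
  wtab <- data.frame(resno = 99L, resname = "HOH",
                     atom = c("O", "H1", "H2"), element = c("O", "H", "H"))
  wxyz <- rbind(mid, mid + 0.98 * u, mid + c(0, 0.98, 0))
  e2 <- mkEnsemble(rbind(a, wtab), list(rbind(xyz, wxyz)))
  expect_equal(classifyFrame(getFrame(e2, 1), schemes$U13U18), "2a")
})

test_that("populations are permutation-invariant, transitions are not", {
  e <- genConformerEnsemble(conformerSimSpec(nFrames = 300, seed = 7))
  tr <- tracePopulations(e, schemes$U13U18)
  set.seed(1)
  perm <- sample(nFrames(e))
  tr2 <- tracePopulations(subsetFrames(e, perm), schemes$U13U18)
  expect_equal(tr2$fractions, tr$fractions)
  expect_equal(sum(tr2$transitions), sum(tr$transitions))
})

test_that("transition counts match the generated label sequence", {
  e <- genConformerEnsemble(conformerSimSpec(nFrames = 50, seed = 9))
  tr <- tracePopulations(e, schemes$U13U18)
  s <- attr(e, "states")
  manual <- table(factor(s[-length(s)], levels = c("2a", "1a", "unassigned")),
                  factor(s[-1], levels = c("2a", "1a", "unassigned")))
  expect_equal(unclass(tr$transitions), unclass(manual),
               ignore_attr = TRUE)
})

test_that("Markov stationary populations are recovered within 3 sigma", {
  ## persistent 2-state chain with stationary (0.6, 0.4); the tolerance is
  ## 3 standard errors of the occupancy estimator for a correlated chain,
  ## i.e. binomial sigma inflated by sqrt((1+rho)/(1-rho)) with rho the
  ## lag-1 autocorrelation 1 - p12 - p21
  P <- matrix(c(0.9, 0.1, 0.15, 0.85), 2, 2, byrow = TRUE,
              dimnames = list(c("2a", "1a"), c("2a", "1a")))
  pi0 <- stationaryDistribution(P)
  expect_equal(unname(pi0), c(0.6, 0.4))
  n <- 20000L
  e <- genConformerEnsemble(conformerSimSpec("U13U18", P = P, nFrames = n,
                                             seed = 23))
  tr <- tracePopulations(e, schemes$U13U18)
  rho <- 1 - P[1, 2] - P[2, 1]
  sig <- sqrt(0.6 * 0.4 / n) * sqrt((1 + rho) / (1 - rho))
  expect_lt(abs(tr$fractions[["2a"]] - 0.6), 3 * sig)
})

test_that("relabeling O2 and O4 in both residues mirrors the 2a/2b states", {
  ## The two-direct-bond arrangements are exact mirror images under the
  ## O2<->O4 relabeling. The single-bond arrangements are not: the
  ## water-mediated bond is defined to involve O2 in both 1a and 1b, so a
  ## relabeled 1a/1b frame (direct bond now on O2, bridge now on O4) matches
  ## no defined arrangement and must come out unassigned.
  P <- matrix(0.25, 4, 4, dimnames = list(c("2a", "2b", "1a", "1b"),
                                          c("2a", "2b", "1a", "1b")))
  e <- genConformerEnsemble(conformerSimSpec("U10U21", P = P, nFrames = 40,
                                             seed = 31, noise = 0))
  a <- atomTable(e)
  swap <- a
  uu <- swap$resno %in% c(10L, 21L)
  o2 <- uu & swap$atom == "O2"
  o4 <- uu & swap$atom == "O4"
  swap$atom[o2] <- "O4"
  swap$atom[o4] <- "O2"
  e2 <- ensemble(swap, coords(e))
  lab1 <- tracePopulations(e, schemes$U10U21)$labels
  lab2 <- tracePopulations(e2, schemes$U10U21)$labels
  map <- c(`2a` = "2b", `2b` = "2a", `1a` = "unassigned",
           `1b` = "unassigned", unassigned = "unassigned")
  expect_identical(unname(map[lab1]), lab2)
  expect_true(all(c("2a", "2b", "1a", "1b") %in% lab1))
})

test_that("water-mediated states are unavailable, not zero, without waters", {
  e <- genConformerEnsemble(conformerSimSpec(
    nFrames = 5, seed = 2, noise = 0,
    P = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("2a", "1a"), c("2a", "1a")))))
  a <- atomTable(e)
  keep <- a$resname != "HOH"
  e2 <- ensemble(a[keep, ], coords(e)[keep, , , drop = FALSE])
  tr <- tracePopulations(e2, schemes$U13U18)
  expect_true(is.na(tr$fractions[["1a"]]))
  expect_equal(tr$fractions[["2a"]], 1)
})

test_that("schemes validate their definitions", {
  expect_error(stateDefinition("x"), "at least one requirement")
  expect_error(stateScheme("s", list(
    stateDefinition("2a", direct = list(c("1:N3", "1:H3", "2:O2"))),
    stateDefinition("2a", direct = list(c("2:N3", "2:H3", "1:O2"))))),
    "unique")
})
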