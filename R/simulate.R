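## Synthetic-data generators. Coordinates are toy geometry, not real RNA:
## the templates only guarantee the logical truth of each state's H-bond
## predicate (bonds satisfied at ~2.9 A / ~165 deg, non-required contacts
## pushed beyond 4.2 A). Every generator is a pure function of its spec and
## seed.

## ---- planar base templates -------------------------------------------------

## idealized planar pyrimidine-like base in local coordinates (z = 0)
pyrimidineTemplate <- function(withImino = TRUE) {
  ang <- c(N1 = 210, C2 = 270, N3 = 330, C4 = 30, C5 = 90, C6 = 150) * pi / 180
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  rownames(ring) <- names(ang)
  ext <- rbind(
    O2 = c(2.61 * cos(ang["C2"]), 2.61 * sin(ang["C2"]), 0),
    O4 = c(2.61 * cos(ang["C4"]), 2.61 * sin(ang["C4"]), 0),
    `C1'` = c(2.86 * cos(ang["N1"]), 2.86 * sin(ang["N1"]), 0))
  if (withImino)
    ext <- rbind(ext, H3 = c(2.40 * cos(ang["N3"]), 2.40 * sin(ang["N3"]), 0))
  rbind(ring, ext)
}

## complete a regular pentagon sharing edge p1-p2, on the side away from
## `awayFrom`; returns the three new vertices in order (next to p1 first)
pentagonOn <- function(p1, p2, awayFrom) {
  mid <- (p1 + p2) / 2
  dir <- mid - awayFrom
  dir <- dir / sqrt(sum(dir^2))
  side <- sqrt(sum((p2 - p1)^2))
  Rp <- side / (2 * sin(pi / 5))
  ctr <- mid + Rp * cos(pi / 5) * dir
  rot <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                           sin(th) * v[1] + cos(th) * v[2], 0)
  v1 <- p1 - ctr
  ## choose rotation sense that walks away from p2
  cand <- ctr + rot(v1, 2 * pi / 5)
  if (sum((cand - p2)^2) < sum((p1 - p2)^2)) {
    step <- -2 * pi / 5
    cand <- ctr + rot(v1, step)
  } else step <- 2 * pi / 5
  v <- v1
  out <- matrix(0, 3L, 3L)
  for (i in 1:3) {
    v <- rot(v, step)
    out[i, ] <- ctr + v
  }
  out
}

purineTemplate <- function() {
  base <- pyrimidineTemplate(withImino = FALSE)
  ring6 <- base[c("N1", "C2", "N3", "C4", "C5", "C6"), ]
  five <- pentagonOn(ring6["C4", ], ring6["C5", ], colMeans(ring6))
  rownames(five) <- c("N9", "C8", "N7")
  n9 <- five["N9", ]
  ctr5 <- colMeans(rbind(ring6[c("C4", "C5"), ], five))
  dirOut <- n9 - ctr5
  dirOut <- dirOut / sqrt(sum(dirOut^2))
  rbind(ring6, five, `C1'` = n9 + 1.47 * dirOut,
        O2 = base["O2", ], O4 = base["O4", ])[
          c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9", "C1'"), ]
}

rotZ <- function(xyz, th) {
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
  xyz %*% t(R)
}

## ---- posing a two-residue U/U pair in a given conformer state --------------

## atoms/coords for one uridine-like residue
uuResidue <- function(resno) {
  tpl <- pyrimidineTemplate()
  data.frame(resno = resno, resname = "U", atom = rownames(tpl),
             element = guessElement(rownames(tpl)),
             x = tpl[, 1], y = tpl[, 2], z = tpl[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

## table-coordinate helpers shared by the posing code
tabXYZ <- function(tab, ref) {
  ref <- atomRef(ref)
  r <- which(tab$resno == ref@resno & tab$atom == ref@atom)
  as.numeric(tab[r, c("x", "y", "z")])
}
tabSetXYZ <- function(tab, ref, p) {
  ref <- atomRef(ref)
  r <- which(tab$resno == ref@resno & tab$atom == ref@atom)
  tab[r, c("x", "y", "z")] <- as.list(p)
  tab
}

## rigid in-plane pose of residue B against fixed residue A so that the
## state's heavy-atom requirements hold; donor imino hydrogens of direct
## bonds are then oriented along the N-H...acceptor axis (bridge donors are
## oriented later, once their water is placed)
poseUUPair <- function(state, resA, resB) {
  A <- uuResidue(resA)
  B0 <- uuResidue(resB)
  Amat <- as.matrix(A[, c("x", "y", "z")])
  B0mat <- as.matrix(B0[, c("x", "y", "z")])
  nA <- nrow(Amat)
  rowOf <- function(ref) {
    ref <- atomRef(ref)
    if (ref@resno == resA) which(A$atom == ref@atom)
    else nA + which(B0$atom == ref@atom)
  }
  ## candidate donor/acceptor combos used for the exclusion penalty
  combos <- list()
  for (rs in list(c(resA, resB), c(resB, resA)))
    for (acc in c("O2", "O4"))
      combos[[length(combos) + 1L]] <-
        c(paste0(rs[1], ":N3"), paste0(rs[1], ":H3"), paste0(rs[2], ":", acc))
  keyOf <- function(tr) paste(tr, collapse = "|")
  required <- vapply(state@direct, keyOf, "")
  bridged <- vapply(state@bridges, keyOf, "")
  excluded <- Filter(function(tr) !(keyOf(tr) %in% c(required, bridged)),
                     combos)
  idx <- function(trs) t(vapply(trs, function(tr)
    c(rowOf(tr[1]), rowOf(tr[3])), c(0L, 0L)))
  iDirect <- idx(state@direct)
  iBridge <- idx(state@bridges)
  iExcl <- idx(excluded)
  applyPose <- function(par) {
    B <- rotZ(B0mat, par[1])
    B[, 1] <- B[, 1] + par[2]
    B[, 2] <- B[, 2] + par[3]
    rbind(Amat, B)
  }
  pairDist <- function(m, ij) {
    if (!nrow(ij)) return(numeric(0))
    sqrt(rowSums((m[ij[, 1], , drop = FALSE] -
                    m[ij[, 2], , drop = FALSE])^2))
  }
  objective <- function(par) {
    m <- applyPose(par)
    sum(4 * (pairDist(m, iDirect) - 2.88)^2) +
      sum((pairDist(m, iBridge) - 4.9)^2) +
      sum(pmax(0, 4.5 - pairDist(m, iExcl))^2)
  }
  starts <- list(c(pi, 7.5 * cos(-pi / 6), 7.5 * sin(-pi / 6)),
                 c(pi / 2, 6, -3), c(3 * pi / 2, 6, 0))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, objective, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  m <- applyPose(best$par)
  tab <- rbind(A, B0)
  tab[, c("x", "y", "z")] <- m
  for (tr in state@direct) {
    n3 <- tabXYZ(tab, tr[1]); acc <- tabXYZ(tab, tr[3])
    u <- (acc - n3) / sqrt(sum((acc - n3)^2))
    tab <- tabSetXYZ(tab, tr[2], n3 + 1.01 * u)
  }
  tab
}

## place a bridging water between the donor triple and the acceptor; returns
## a 3-atom water residue table
placeBridgeWater <- function(tab, tr, waterResno) {
  D <- tabXYZ(tab, tr[1]); A <- tabXYZ(tab, tr[3])
  obj <- function(p)
    (sqrt(sum((p - D)^2)) - 2.85)^2 + (sqrt(sum((p - A)^2)) - 2.85)^2
  fit <- optim((D + A) / 2 + c(0, 0, 0.3), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  Ow <- fit$par
  h1 <- Ow + 0.98 * (A - Ow) / sqrt(sum((A - Ow)^2))
  perp <- c(0, 0, 1)
  if (abs(sum((A - Ow) / sqrt(sum((A - Ow)^2)) * perp)) > 0.9)
    perp <- c(0, 1, 0)
  h2 <- Ow + 0.98 * perp
  data.frame(resno = waterResno, resname = "HOH",
             atom = c("O", "H1", "H2"), element = c("O", "H", "H"),
             x = c(Ow[1], h1[1], h2[1]), y = c(Ow[2], h1[2], h2[2]),
             z = c(Ow[3], h1[3], h2[3]),
             stringsAsFactors = FALSE, row.names = NULL)
}

.templateCache <- new.env(parent = emptyenv())

## full per-state coordinate templates for a U/U scheme; constant atom table
## across states (unused waters parked far away). Poses are deterministic,
## so they are cached per scheme signature.
uuStateTemplates <- function(scheme) {
  sig <- paste(scheme@name,
               paste(vapply(scheme@states, function(s)
                 paste(c(s@label, unlist(s@direct), unlist(s@bridges)),
                       collapse = ","), ""), collapse = ";"))
  hit <- .templateCache[[sig]]
  if (!is.null(hit)) return(hit)
  out <- uuStateTemplatesBuild(scheme)
  .templateCache[[sig]] <- out
  out
}

uuStateTemplatesBuild <- function(scheme) {
  resnos <- sort(unique(unlist(lapply(scheme@states, function(s)
    lapply(c(s@direct, s@bridges), function(tr)
      vapply(tr, function(r) atomRef(r)@resno, 0L))))))
  if (length(resnos) != 2L)
    stop("scheme does not describe a two-residue pair")
  resA <- resnos[1]; resB <- resnos[2]
  keyOf <- function(tr) paste(tr, collapse = "|")
  bridgeKeys <- unique(unlist(lapply(scheme@states, function(s)
    vapply(s@bridges, keyOf, character(1)))))
  waterResno <- setNames(100L + seq_along(bridgeKeys), bridgeKeys)
  templates <- list()
  for (s in scheme@states) {
    tab <- poseUUPair(s, resA, resB)
    for (k in bridgeKeys) {
      if (length(s@bridges) && k %in% vapply(s@bridges, keyOf, "")) {
        tr <- strsplit(k, "|", fixed = TRUE)[[1]]
        w <- placeBridgeWater(tab, tr, waterResno[[k]])
        ## orient the bridge donor's imino hydrogen toward the water oxygen
        n3 <- tabXYZ(tab, tr[1])
        ow <- as.numeric(w[w$atom == "O", c("x", "y", "z")])
        u <- (ow - n3) / sqrt(sum((ow - n3)^2))
        tab <- tabSetXYZ(tab, tr[2], n3 + 1.01 * u)
      } else {
        off <- 60 + 10 * which(bridgeKeys == k)
        w <- data.frame(resno = waterResno[[k]], resname = "HOH",
                        atom = c("O", "H1", "H2"),
                        element = c("O", "H", "H"),
                        x = off + c(0, 0.98, 0), y = off + c(0, 0, 0.98),
                        z = 0, stringsAsFactors = FALSE)
      }
      tab <- rbind(tab, w)
    }
    templates[[s@label]] <- tab
  }
  templates
}

## ---- simulation specs ------------------------------------------------------

#' Conformer-ensemble simulation spec
#'
#' Declares a Markov-switching synthetic ensemble of a cWW U/U pair: a
#' per-frame row-stochastic transition matrix over the scheme's states, the
#' frame count and spacing, isotropic coordinate noise and a seed. The
#' default transition matrix has identical rows `(0.6, 0.4)` over the
#' `2a`/`1a` states, i.e. a rapid-exchange 60/40 equilibrium between the
#' two-H-bond arrangement and its water-mediated variant.
#'
#' @param scheme a [StateScheme-class] or the name of a built-in scheme.
#' @param P row-stochastic transition matrix with one row/column per used
#'   state, dimnames giving the state labels. Default: 60/40 independent
#'   switching between `2a` and `1a`.
#' @param nFrames number of frames.
#' @param dt frame spacing in ps.
#' @param noise isotropic Gaussian coordinate noise sigma in Angstrom.
#' @param seed integer seed.
#' @return a list of class `"ConformerSimSpec"`.
#' @export
conformerSimSpec <- function(scheme = "U13U18", P = NULL, nFrames = 1000L,
                             dt = 10, noise = 0.05, seed = 1L) {
  if (is.character(scheme)) {
    schemes <- builtinSchemes()
    if (!scheme %in% names(schemes)) stop("unknown scheme ", sQuote(scheme))
    scheme <- schemes[[scheme]]
  }
  stopifnot(is(scheme, "StateScheme"))
  if (is.null(P)) {
    P <- matrix(c(0.6, 0.4, 0.6, 0.4), 2L, 2L, byrow = TRUE,
                dimnames = list(c("2a", "1a"), c("2a", "1a")))
  }
  if (is.null(dimnames(P)) ||
      !all(rownames(P) %in% schemeLabels(scheme)))
    stop("P must carry scheme state labels as dimnames")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  if (noise < 0) stop("noise sigma must be >= 0")
  structure(list(scheme = scheme, P = P, nFrames = as.integer(nFrames),
                 dt = dt, noise = noise, seed = as.integer(seed)),
            class = "ConformerSimSpec")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P row-stochastic matrix.
#' @return named stationary probability vector (left eigenvector of `P` for
#'   eigenvalue 1, normalized).
#' @export
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

#' Generate a Markov-switching conformer ensemble
#'
#' Samples a state sequence from the spec's transition matrix (first frame
#' from the stationary distribution), places the two residues in each
#' frame's state template (required H-bonds at ~2.9 Angstrom / ~165 deg,
#' non-required contacts beyond 4.2 Angstrom, bridging waters placed to
#' realize water-mediated states, unused waters parked far away) and adds
#' isotropic Gaussian noise. Bit-reproducible for a fixed spec.
#'
#' @param spec a [conformerSimSpec()].
#' @return an [Ensemble-class] with attribute `"states"` (the generated
#'   label sequence).
#' @examples
#' e <- genConformerEnsemble(conformerSimSpec(nFrames = 10, seed = 7))
#' table(attr(e, "states"))
#' @export
genConformerEnsemble <- function(spec) {
  stopifnot(inherits(spec, "ConformerSimSpec"))
  templates <- uuStateTemplates(spec$scheme)
  used <- rownames(spec$P)
  ## verify realizability: noise-free template must classify as its label
  for (lab in used) {
    tab <- templates[[lab]]
    fr <- ensemble(tab[, c("resno", "resname", "atom", "element")],
                   as.matrix(tab[, c("x", "y", "z")]))
    got <- classifyFrame(getFrame(fr, 1L), spec$scheme)
    if (!identical(got, lab))
      stop("state ", sQuote(lab), " is not geometrically realizable ",
           "(template classifies as ", sQuote(got), ")")
  }
  set.seed(spec$seed)
  n <- spec$nFrames
  cumP <- t(apply(spec$P, 1L, cumsum))
  si <- integer(n)
  si[1] <- sample(length(used), 1L, prob = stationaryDistribution(spec$P))
  if (n > 1L) {
    u <- runif(n - 1L)
    for (i in 2:n)
      si[i] <- 1L + sum(u[i - 1L] > cumP[si[i - 1L], ])
  }
  states <- used[si]
  tab0 <- templates[[used[1]]]
  na <- nrow(tab0)
  tplMat <- lapply(templates, function(t) as.matrix(t[, c("x", "y", "z")]))
  co <- array(NA_real_, c(na, 3L, n))
  for (lab in used) {
    idx <- which(states == lab)
    if (length(idx)) co[, , idx] <- tplMat[[lab]]
  }
  if (spec$noise > 0)
    co <- co + array(rnorm(length(co), 0, spec$noise), dim(co))
  e <- ensemble(tab0[, c("resno", "resname", "atom", "element")], co,
                dt = spec$dt,
                provenance = sprintf("synthetic conformer chain (seed %d)",
                                     spec$seed))
  attr(e, "states") <- states
  e
}

#' Two-state ion trajectory simulation spec
#'
#' Declares a synthetic cation alternating between a binding site and bulk:
#' geometric (discrete-time memoryless) dwell times with the given bound
#' fraction and mean bound residence, emulating a high-occupancy,
#' short-binding-time monovalent site.
#'
#' @param p stationary bound fraction in `[0, 1]`.
#' @param meanResidence mean bound dwell in ps (>= dt).
#' @param dt frame spacing in ps.
#' @param nFrames number of frames.
#' @param boundSigma Gaussian spread (Angstrom) of the bound ion around its
#'   mean contact position 2.8 Angstrom from the primary atom.
#' @param box edge length (Angstrom) of the cubic bulk region centered on
#'   the site.
#' @param species ion species residue name.
#' @param seed integer seed.
#' @return a list of class `"IonSimSpec"`.
#' @export
ionSimSpec <- function(p = 0.8, meanResidence = 250, dt = 10,
                       nFrames = 10000L, boundSigma = 0.15, box = 20,
                       species = "K", seed = 1L) {
  if (p < 0 || p > 1) stop("bound fraction p must be in [0, 1]")
  if (meanResidence < dt) stop("mean residence must be >= dt")
  structure(list(p = p, meanResidence = meanResidence, dt = dt,
                 nFrames = as.integer(nFrames), boundSigma = boundSigma,
                 box = box, species = species, seed = as.integer(seed)),
            class = "IonSimSpec")
}

#' Generate a two-state ion trajectory
#'
#' Alternating bound/unbound dwells with geometric lengths: the bound dwell
#' mean is `meanResidence/dt` frames and the unbound mean is derived from
#' the bound fraction, `meanResidence/dt * (1-p)/p`. Bound frames place the
#' ion Gaussian-distributed around a point at 2.8 Angstrom from the primary
#' atom (random direction per frame); unbound frames place it uniformly in
#' the box but beyond the site's outer cutoff. The returned ensemble is
#' generated in a common frame of reference and is therefore flagged
#' aligned.
#'
#' @param spec an [ionSimSpec()].
#' @param sitePos 3-vector, position of the primary coordinating atom.
#' @return a list with `ensemble` (primary atom `14:O4` plus one ion),
#'   `site` (the matching [IonSite-class]), `bound` (logical per frame) and
#'   `spec`.
#' @examples
#' tr <- genIonTrajectory(ionSimSpec(nFrames = 200, seed = 3))
#' mean(tr$bound)
#' @export
genIonTrajectory <- function(spec, sitePos = c(0, 0, 0)) {
  stopifnot(inherits(spec, "IonSimSpec"))
  set.seed(spec$seed)
  n <- spec$nFrames
  mb <- spec$meanResidence / spec$dt            # mean bound dwell, frames
  site <- ionSite("14:O4", species = spec$species)
  if (spec$p >= 1) {
    warning("p = 1: single infinite bound episode")
    bound <- rep(TRUE, n)
  } else if (spec$p <= 0) {
    bound <- rep(FALSE, n)
  } else {
    mu <- mb * (1 - spec$p) / spec$p            # mean unbound dwell, frames
    bound <- logical(0)
    state <- runif(1) < spec$p
    while (length(bound) < n) {
      m <- if (state) mb else mu
      dwell <- rgeom(1L, prob = min(1, 1 / m)) + 1L
      bound <- c(bound, rep(state, dwell))
      state <- !state
    }
    bound <- bound[seq_len(n)]
  }
  pos <- matrix(NA_real_, n, 3L)
  nb <- sum(bound)
  if (nb) {
    u <- matrix(rnorm(3 * nb), nb, 3L)
    u <- u / sqrt(rowSums(u^2))
    pos[bound, ] <- sweep(2.8 * u +
                            matrix(rnorm(3 * nb, 0, spec$boundSigma),
                                   nb, 3L), 2L, sitePos, `+`)
  }
  nu <- sum(!bound)
  if (nu) {
    draw <- function(k) sweep(matrix(runif(3 * k, -spec$box / 2,
                                           spec$box / 2), k, 3L),
                              2L, sitePos, `+`)
    out <- matrix(NA_real_, 0L, 3L)
    while (nrow(out) < nu) {
      cand <- draw(nu)
      d <- sqrt(rowSums(sweep(cand, 2L, sitePos)^2))
      out <- rbind(out, cand[d > site@outer, , drop = FALSE])
    }
    pos[!bound, ] <- out[seq_len(nu), ]
  }
  atoms <- data.frame(resno = c(14L, 501L), resname = c("U", spec$species),
                      atom = c("O4", spec$species),
                      element = c("O", spec$species))
  co <- array(NA_real_, c(2L, 3L, n))
  co[1L, , ] <- sitePos
  co[2L, , ] <- t(pos)
  list(ensemble = ensemble(atoms, co, dt = spec$dt,
                           provenance = sprintf(
                             "synthetic ion trajectory (seed %d)",
                             spec$seed), aligned = TRUE),
       site = site, bound = bound, spec = spec)
}

#' Generate a synthetic titration series
#'
#' Exact isotherm curve (see [fitBindingIsotherm()]) plus Gaussian shift
#' noise.
#'
#' @param model `"single-site"` or `"cooperative2"`.
#' @param KD dissociation constant (mM).
#' @param ddMax saturating shift change (ppm); the default 0.3 ppm is a
#'   typical saturating imino-proton shift change for mM-scale cation
#'   binding.
#' @param conc concentrations (mM); the default 8-point series spans 0.3 to
#'   100 mM.
#' @param noise Gaussian shift noise sigma (ppm).
#' @param seed integer seed.
#' @return a [TitrationSeries-class].
#' @export
genTitration <- function(model = "single-site", KD = 3, ddMax = 0.3,
                         conc = c(0.3, 1, 2, 5, 10, 20, 50, 100),
                         noise = 0.01, seed = 1L) {
  model <- match.arg(model, c("single-site", "cooperative2"))
  set.seed(seed)
  dd <- isothermCurve(conc, KD, ddMax, model)
  if (noise > 0) dd <- dd + rnorm(length(conc), 0, noise)
  titrationSeries(conc, dd, nucleus = "synthetic", model = model)
}

#' Generate synthetic constant-time intensity series
#'
#' `cos(pi * J * tau)` plus Gaussian noise, per replicate. The defaults
#' mirror the experimental protocol shape: seven constant-time delays,
#' measured twice.
#'
#' @param J coupling in Hz.
#' @param delays constant-time delays in s (default 7 delays, 25-175 ms).
#' @param noise Gaussian noise sigma on the ratios.
#' @param replicates number of replicates.
#' @param seed integer seed.
#' @return a list of [CTIntensitySeries-class], one per replicate.
#' @export
genCTSeries <- function(J = 2.7, delays = seq(0.025, 0.175, by = 0.025),
                        noise = 0.02, replicates = 2L, seed = 1L) {
  if (any(delays <= 0)) stop("delays must be > 0")
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    ratio <- cos(pi * J * delays)
    if (noise > 0) ratio <- ratio + rnorm(length(delays), 0, noise)
    ctIntensitySeries(delays, ratio, replicate = as.character(r),
                      clip = TRUE)
  })
}
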