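## Cation atmosphere: RDFs, site occupancy with shell labels, residence
## episodes, density maxima.

ionRows <- function(atoms, species) {
  which(isIonName(atoms$resname, species))
}

#' Radial distribution function of an ion species around a reference atom
#'
#' g(r) is the observed ion count in each distance shell divided by the
#' count expected for ions distributed uniformly at the ensemble's mean ion
#' number density over the analysis sphere of radius `rMax`; for an
#' ideal-gas ion distribution g(r) converges to 1.
#'
#' @param x an [Ensemble-class] containing at least one ion of `species`.
#' @param species ion residue name (e.g. `"K"`).
#' @param ref reference atom (`AtomRef` or `"resno:atom"`).
#' @param rMax analysis radius in Angstrom.
#' @param binWidth shell width in Angstrom (default 0.1).
#' @return a list of class `"uturnRDF"`: `r` (bin centers), `g`, `counts`,
#'   `binWidth`, `bulkDensity` (ions per cubic Angstrom used for
#'   normalization) and `nFrames`.
#' @export
computeRDF <- function(x, species, ref, rMax = 10, binWidth = 0.1) {
  stopifnot(is(x, "Ensemble"))
  if (binWidth <= 0) stop("binWidth must be > 0")
  ions <- ionRows(x@atoms, species)
  if (!length(ions)) stop("no ions of species ", sQuote(species),
                          " in the ensemble")
  iR <- resolveAtom(x@atoms, ref)
  nf <- nFrames(x)
  dists <- unlist(lapply(ions, function(i) distSeries(x@coords, iR, i)))
  inside <- dists[dists < rMax]
  edges <- seq(0, rMax, by = binWidth)
  if (edges[length(edges)] < rMax) edges <- c(edges, rMax)
  counts <- unname(table(cut(inside, edges, right = FALSE)))
  counts <- as.numeric(counts)
  rho <- (length(inside) / nf) / (4 / 3 * pi * rMax^3)
  shellVol <- 4 / 3 * pi * diff(edges^3)
  expected <- rho * shellVol * nf
  g <- ifelse(expected > 0, counts / expected, 0)
  structure(list(r = (head(edges, -1L) + tail(edges, -1L)) / 2, g = g,
                 counts = counts, binWidth = binWidth, bulkDensity = rho,
                 nFrames = nf, rMax = rMax),
            class = "uturnRDF")
}

#' @export
print.uturnRDF <- function(x, ...) {
  cat("RDF:", length(x$r), "bins of", x$binWidth, "A up to", x$rMax,
      "A | bulk density", signif(x$bulkDensity, 4), "ions/A^3\n")
  invisible(x)
}

#' Per-frame occupancy of a cation binding site
#'
#' A frame is occupied iff any ion of the site's species lies within the
#' inner cutoff of the primary coordinating atom (the site is keyed to the
#' primary atom only). For each auxiliary atom the distance of the
#' nearest-to-primary bound ion is classified as `inner` (below the inner
#' cutoff, a direct contact), `outer` (between the cutoffs, the
#' water-mediated distance range) or `none`.
#'
#' @param x an [Ensemble-class].
#' @param site an [IonSite-class].
#' @return a list of class `"uturnOccupancy"`: `occupied` (logical per
#'   frame), `fraction`, `shells` (character matrix frames x auxiliary
#'   atoms), `shellFractions` (per auxiliary atom, fraction of occupied
#'   frames in each shell class) and `site`.
#' @examples
#' tr <- genIonTrajectory(ionSimSpec(nFrames = 500, seed = 1))
#' occ <- siteOccupancy(tr$ensemble, tr$site)
#' occ$fraction
#' @export
siteOccupancy <- function(x, site) {
  stopifnot(is(x, "Ensemble"), is(site, "IonSite"))
  ions <- ionRows(x@atoms, site@species)
  nf <- nFrames(x)
  iP <- resolveAtom(x@atoms, site@primary)
  if (!length(ions)) {
    occupied <- rep(FALSE, nf)
    dPrim <- matrix(Inf, nf, 0)
  } else {
    dPrim <- vapply(ions, function(i) distSeries(x@coords, iP, i),
                    numeric(nf))
    if (nf == 1L) dPrim <- matrix(dPrim, nrow = 1L)
    occupied <- apply(dPrim, 1L, min) < site@inner
  }
  nearest <- if (length(ions))
    ions[apply(dPrim, 1L, which.min)] else rep(NA_integer_, nf)
  auxNames <- vapply(site@aux, formatAtomRef, "")
  shells <- matrix("none", nf, length(site@aux),
                   dimnames = list(NULL, auxNames))
  for (j in seq_along(site@aux)) {
    iA <- resolveAtom(x@atoms, site@aux[[j]])
    d <- rep(Inf, nf)
    for (i in unique(nearest[occupied])) {
      rows <- occupied & nearest == i
      d[rows] <- distSeries(x@coords, iA, i)[rows]
    }
    shells[d < site@inner, j] <- "inner"
    shells[d >= site@inner & d < site@outer, j] <- "outer"
  }
  shellFractions <- if (length(site@aux) && any(occupied)) {
    t(apply(shells[occupied, , drop = FALSE], 2L, function(s)
      c(inner = mean(s == "inner"), outer = mean(s == "outer"),
        none = mean(s == "none"))))
  } else NULL
  structure(list(occupied = occupied, fraction = mean(occupied),
                 shells = shells, shellFractions = shellFractions,
                 site = site@id),
            class = "uturnOccupancy")
}

#' @export
print.uturnOccupancy <- function(x, ...) {
  cat("Site", sQuote(x$site), "occupancy:",
      sprintf("%.1f%%", 100 * x$fraction), "of",
      length(x$occupied), "frames\n")
  if (!is.null(x$shellFractions)) {
    cat("  auxiliary shell fractions (over occupied frames):\n")
    print(round(x$shellFractions, 3))
  }
  invisible(x)
}

#' Residence-time episodes of a binding site
#'
#' Maximal runs of occupied frames form episodes; unoccupied gaps of length
#' at most `tolerance` frames are absorbed into the surrounding episode.
#' Episode duration is the number of frames times `dt`.
#'
#' @param occupied logical vector of per-frame occupancy (e.g. from
#'   [siteOccupancy()]).
#' @param dt frame time step in ps.
#' @param tolerance gap-absorption length in frames (default 0: strict
#'   episodes).
#' @return a list of class `"uturnResidence"`: `episodes` (`data.frame`
#'   with `start`, `end`, `frames`, `duration_ps`), `meanDuration`,
#'   `maxDuration` (ps; `NA` when there is no episode), `occupancy`,
#'   `tolerance` and `dt`.
#' @examples
#' residenceStatistics(c(TRUE, TRUE, FALSE, TRUE), dt = 10)
#' residenceStatistics(c(TRUE, TRUE, FALSE, TRUE), dt = 10, tolerance = 1)
#' @export
residenceStatistics <- function(occupied, dt, tolerance = 0L) {
  if (is.null(dt) || is.na(dt) || dt <= 0) stop("dt (ps) must be known")
  if (tolerance < 0) stop("tolerance must be >= 0")
  occ <- as.logical(occupied)
  r <- rle(occ)
  if (tolerance > 0 && length(r$lengths) > 2L) {
    ## absorb interior FALSE runs of length <= tolerance
    interior <- which(!r$values & r$lengths <= tolerance &
                        seq_along(r$values) > 1L &
                        seq_along(r$values) < length(r$values))
    if (length(interior)) {
      r$values[interior] <- TRUE
      occ2 <- inverse.rle(r)
      r <- rle(occ2)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  episodes <- data.frame(start = starts[keep], end = ends[keep],
                         frames = r$lengths[keep])
  episodes$duration_ps <- episodes$frames * dt
  structure(list(episodes = episodes,
                 meanDuration = if (nrow(episodes))
                   mean(episodes$duration_ps) else NA_real_,
                 maxDuration = if (nrow(episodes))
                   max(episodes$duration_ps) else NA_real_,
                 occupancy = mean(occ), tolerance = as.integer(tolerance),
                 dt = dt),
            class = "uturnResidence")
}

#' @export
print.uturnResidence <- function(x, ...) {
  cat(nrow(x$episodes), "episode(s); mean",
      round(x$meanDuration, 1), "ps, max", round(x$maxDuration, 1),
      "ps; occupancy", sprintf("%.1f%%", 100 * x$occupancy),
      "(gap tolerance", x$tolerance, "frames)\n")
  invisible(x)
}

#' Top-k ion density regions of an aligned ensemble
#'
#' Bins ion positions on a cubic grid and reports the `k` highest-occupancy
#' regions. Cells are ranked by count and greedily merged into regions: each
#' cell joins the existing region whose (count-weighted) centroid lies
#' within `mergeRadius`, otherwise it seeds a new region.
#'
#' @param x an [Ensemble-class] that has been superposed with
#'   [superposeAndRMSD()] (checked via [isAligned()]).
#' @param species ion residue name.
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @param k number of regions to return.
#' @param mergeRadius merge radius in Angstrom (default 2).
#' @return a `data.frame` with one row per region: `x`, `y`, `z`
#'   (count-weighted centroid), `count` and `occupancy` (count per frame).
#' @export
densityMaxima <- function(x, species, spacing = 0.5, k = 5L,
                          mergeRadius = 2) {
  stopifnot(is(x, "Ensemble"))
  if (!isAligned(x))
    stop("ensemble is not aligned; superpose it first with superposeAndRMSD()")
  ions <- ionRows(x@atoms, species)
  if (!length(ions)) stop("no ions of species ", sQuote(species))
  pos <- do.call(rbind, lapply(ions, function(i) atomTrace(x@coords, i)))
  cell <- floor(sweep(pos, 2L, apply(pos, 2L, min)) / spacing)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  counts <- sort(table(key), decreasing = TRUE)
  centers <- rowsum(pos, key)          # summed coords per cell
  regions <- list()
  for (kk in names(counts)) {
    ctr <- centers[kk, ] / counts[[kk]]
    placed <- FALSE
    for (ri in seq_along(regions)) {
      rg <- regions[[ri]]
      if (sqrt(sum((rg$centroid - ctr)^2)) <= mergeRadius) {
        tot <- rg$count + counts[[kk]]
        rg$centroid <- (rg$centroid * rg$count + ctr * counts[[kk]]) / tot
        rg$count <- tot
        regions[[ri]] <- rg
        placed <- TRUE
        break
      }
    }
    if (!placed) regions[[length(regions) + 1L]] <-
        list(centroid = ctr, count = counts[[kk]])
  }
  ord <- order(-vapply(regions, function(r) r$count, 0))
  regions <- regions[ord][seq_len(min(k, length(regions)))]
  data.frame(x = vapply(regions, function(r) r$centroid[1], 0),
             y = vapply(regions, function(r) r$centroid[2], 0),
             z = vapply(regions, function(r) r$centroid[3], 0),
             count = vapply(regions, function(r) r$count, 0),
             occupancy = vapply(regions, function(r) r$count, 0) / nFrames(x))
}
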