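## Coordinate and table IO. PDB parsing/writing is delegated to bio3d; the
## frame-series TSV is the package's own plain-text trajectory carrier.

#' Read a coordinate ensemble
#'
#' Reads either a standard multi-model PDB file (MODEL/ENDMDL records, as in
#' NMR depositions) or the package's frame-series TSV format (see
#' [writeEnsemble()]). Hydrogens are retained; waters and single-atom ion
#' residues are retained with normalized residue names (`HOH`, `K`, `NA`,
#' `MG`); sugar-atom prime/apostrophe/star spellings are normalized to the
#' apostrophe form.
#'
#' @param path input file.
#' @param format `"pdb-multimodel"` or `"xyz-frames"`; `"auto"` decides by
#'   file extension (`.pdb`/`.ent` versus anything else).
#' @param dt optional frame time step in ps to attach to the ensemble.
#' @return an [Ensemble-class].
#' @seealso [writeEnsemble()], [readNOETable()]
#' @export
readEnsemble <- function(path, format = c("auto", "pdb-multimodel",
                                          "xyz-frames"), dt = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE))
      "pdb-multimodel" else "xyz-frames"
  if (format == "pdb-multimodel") readEnsemblePDB(path, dt)
  else readEnsembleFrames(path, dt)
}

readEnsemblePDB <- function(path, dt = NA_real_) {
  checkModelAtomCounts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(resno = as.integer(at$resno),
                      resname = normalizeResName(at$resid),
                      atom = normalizeAtomName(at$elety),
                      element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                                       guessElement(at$elety),
                                       trimws(at$elesy)),
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz                      # nframes x 3N
  nf <- nrow(xyz)
  na <- nrow(atoms)
  co <- array(NA_real_, c(na, 3L, nf))
  for (i in seq_len(nf))
    co[, , i] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  ensemble(atoms, co, dt = dt, provenance = basename(path))
}

## Pre-scan MODEL blocks so an inconsistent deposition fails with the first
## offending model named, rather than with a parser-internal error.
checkModelAtomCounts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  starts <- which(rec == "MODEL ")
  if (!length(starts)) return(invisible(NULL))
  ends <- which(rec == "ENDMDL")
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  counts <- mapply(function(s, e)
    sum(rec[s:e] %in% c("ATOM  ", "HETATM")), starts, ends)
  bad <- which(counts != counts[1])
  if (length(bad))
    stop("inconsistent atom count across models in ", basename(path),
         ": model ", bad[1], " has ", counts[bad[1]],
         " atoms, model 1 has ", counts[1])
  invisible(NULL)
}

readEnsembleFrames <- function(path, dt = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^# dt_ps:", lines, value = TRUE)
  if (is.na(dt) && length(meta))
    dt <- as.numeric(sub("^# dt_ps:\\s*", "", meta[1]))
  body <- grep("^#", lines, invert = TRUE)
  tab <- tryCatch(
    read.table(text = lines[body], header = TRUE, sep = "\t", quote = "",
               stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("unparsable frame-series file ", path, ": ",
                             conditionMessage(e)))
  need <- c("frame", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("frame-series file must have columns ",
         paste(need, collapse = ", "))
  bad <- which(!complete.cases(tab[, c("x", "y", "z")]) |
                 !is.finite(tab$x) | !is.finite(tab$y) | !is.finite(tab$z))
  if (length(bad))
    stop("non-numeric coordinate in ", basename(path), " at data row ",
         bad[1])
  frames <- sort(unique(tab$frame))
  sp <- split(tab, factor(tab$frame, levels = frames))
  key <- function(d) paste(d$resno, normalizeAtomName(d$atom))
  k1 <- key(sp[[1]])
  ## atom order within a frame block is not significant: blocks are
  ## canonicalized to the first block's order, so shuffling rows in the file
  ## changes nothing downstream
  for (i in seq_along(sp)) {
    ki <- key(sp[[i]])
    ord <- match(k1, ki)
    if (nrow(sp[[i]]) != length(k1) || anyNA(ord))
      stop("inconsistent atom table across frames in ", basename(path),
           ": frame block ", i, " differs from frame block 1")
    sp[[i]] <- sp[[i]][ord, ]
  }
  na <- length(k1)
  co <- array(NA_real_, c(na, 3L, length(sp)))
  for (i in seq_along(sp))
    co[, , i] <- as.matrix(sp[[i]][, c("x", "y", "z")])
  a1 <- sp[[1]]
  atoms <- data.frame(resno = as.integer(a1$resno), resname = a1$resname,
                      atom = a1$atom, element = a1$element,
                      stringsAsFactors = FALSE)
  ensemble(atoms, co, dt = dt, provenance = basename(path))
}

#' Write a coordinate ensemble
#'
#' `"pdb-multimodel"` writes standard MODEL/ENDMDL records via
#' \pkg{bio3d}; `"xyz-frames"` writes the package's frame-series TSV: comment
#' header (with `dt_ps` when known), then one row per atom per frame with
#' columns `frame`, `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`
#' (coordinates to 3 decimals, matching PDB precision).
#'
#' @param x an [Ensemble-class].
#' @param path output file.
#' @param format `"pdb-multimodel"` or `"xyz-frames"`.
#' @return `path`, invisibly.
#' @export
writeEnsemble <- function(x, path, format = c("pdb-multimodel",
                                              "xyz-frames")) {
  stopifnot(is(x, "Ensemble"))
  format <- match.arg(format)
  if (format == "pdb-multimodel") {
    nf <- nFrames(x)
    xyz <- t(apply(x@coords, 3L, function(m) as.vector(t(m))))
    if (nf == 1L) xyz <- matrix(xyz, nrow = 1L)
    a <- x@atoms
    het <- isWaterName(a$resname) | isIonName(a$resname)
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
                     elety = a$atom, chain = rep("A", nrow(a)),
                     elesy = a$element)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# uturn frame-series v1 (coordinates in Angstrom)", con)
    if (!is.na(x@dt)) writeLines(paste0("# dt_ps: ", format(x@dt)), con)
    writeLines(paste(c("frame", "resno", "resname", "atom", "element",
                       "x", "y", "z"), collapse = "\t"), con)
    a <- x@atoms
    for (i in seq_len(nFrames(x))) {
      m <- x@coords[, , i, drop = TRUE]
      writeLines(paste(i, a$resno, a$resname, a$atom, a$element,
                       sprintf("%.3f", m[, 1]), sprintf("%.3f", m[, 2]),
                       sprintf("%.3f", m[, 3]), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read an NOE restraint table
#'
#' Expects tab-separated columns `group_a`, `group_b` (each a
#' semicolon-joined list of `"resno:atom"` proton references) and
#' `upper_bound_A` (Angstrom). This TSV is the package's canonical restraint
#' carrier.
#'
#' @param path input TSV file.
#' @return a list of [NOERestraint-class] objects.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("group_a\tgroup_b\tupper_bound_A",
#'              "14:H3\t17:H8\t3.3",
#'              "14:H5';14:H5''\t16:H8\t5.0"), tf)
#' readNOETable(tf)
#' @export
readNOETable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  need <- c("group_a", "group_b", "upper_bound_A")
  if (!all(need %in% names(tab)))
    stop("NOE table must have columns ", paste(need, collapse = ", "))
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ub <- suppressWarnings(as.numeric(tab$upper_bound_A[i]))
    if (is.na(ub))
      stop("non-numeric upper bound ", sQuote(tab$upper_bound_A[i]),
           " in NOE table row ", i)
    out[[i]] <- tryCatch(
      noeRestraint(tab$group_a[i], tab$group_b[i], ub),
      error = function(e) stop("NOE table row ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}

#' Read a titration table
#'
#' Tab-separated columns `conc_mM` and `dshift_ppm` (optional comment lines
#' starting with `#`).
#'
#' @param path input TSV file.
#' @param nucleus,model passed to [titrationSeries()].
#' @return a [TitrationSeries-class].
#' @export
readTitrationTable <- function(path, nucleus = "", model = "single-site") {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#")
  if (!all(c("conc_mM", "dshift_ppm") %in% names(tab)))
    stop("titration table must have columns conc_mM, dshift_ppm")
  titrationSeries(tab$conc_mM, tab$dshift_ppm, nucleus = nucleus,
                  model = model)
}

#' Read a constant-time intensity-ratio table
#'
#' Tab-separated columns `tau_s`, `ratio` and `replicate`; returns one
#' [CTIntensitySeries-class] per replicate.
#'
#' @param path input TSV file.
#' @param clip clip ratios marginally outside `[-1, 1]`.
#' @return a list of [CTIntensitySeries-class] objects.
#' @export
readCTTable <- function(path, clip = FALSE) {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#")
  if (!all(c("tau_s", "ratio", "replicate") %in% names(tab)))
    stop("constant-time table must have columns tau_s, ratio, replicate")
  lapply(split(tab, tab$replicate), function(d)
    ctIntensitySeries(d$tau_s, d$ratio, replicate = d$replicate[1],
                      clip = clip))
}
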