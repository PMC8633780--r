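#' Read a macromolecular structure
#'
#' Parses a PDB (v3.x) or mmCIF coordinate file into a \code{PDBStructure}.
#' Waters are dropped unless requested, alternate locations are resolved per
#' atom group according to \code{altlocPolicy}, and SEQRES records are
#' captured when present. Parsing is delegated to \pkg{bio3d}.
#'
#' @param path path to a PDB or mmCIF file (mmCIF detected by extension).
#' @param keepWaters keep water residues (HOH etc.)? Default \code{FALSE}.
#' @param altlocPolicy one of \code{"highest_occupancy"} (keep the highest-
#'   occupancy conformer per atom, ties broken by altLoc identifier order),
#'   \code{"first_listed"}, or \code{"keep_all"}.
#' @return A \code{PDBStructure}.
#' @export
readStructure <- function(path, keepWaters = FALSE,
                          altlocPolicy = c("highest_occupancy", "first_listed",
                                           "keep_all")) {
  altlocPolicy <- match.arg(altlocPolicy)
  if (!file.exists(path)) stop("file not found: ", path)
  isCif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (isCif) bio3d::read.cif(path)
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || !nrow(a)) stop("empty model in ", path)
  blank <- function(v) { v <- as.character(v); v[is.na(v)] <- ""; v }
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    element = {
      e <- toupper(blank(a$elesy))
      e[!nzchar(e)] <- .elementFromName(a$elety[!nzchar(e)])
      e
    },
    altLoc = blank(a$alt),
    resName = as.character(a$resid),
    chainId = { ch <- blank(a$chain); ch[!nzchar(ch)] <- "A"; ch },
    resNo = as.integer(a$resno),
    insert = blank(a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = { o <- a$o; o[is.na(o)] <- 1; pmin(pmax(o, 0), 1) },
    b = { b <- a$b; b[is.na(b)] <- 0; pmax(b, 0) },
    isHetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!keepWaters) atoms <- atoms[!atoms$resName %in% .waterNames, , drop = FALSE]
  if (!nrow(atoms)) stop("empty model (no non-water atoms) in ", path)
  atoms <- .resolveAltloc(atoms, altlocPolicy)
  seqres <- list()
  if (!is.null(pdb$seqres) && length(pdb$seqres))
    seqres <- split(unname(pdb$seqres), names(pdb$seqres))
  ttl <- path
  new("PDBStructure", title = ttl, atoms = atoms, seqres = seqres)
}

.resolveAltloc <- function(atoms, policy) {
  if (policy == "keep_all" || all(!nzchar(atoms$altLoc))) {
    rownames(atoms) <- NULL
    return(atoms)
  }
  key <- paste(atoms$chainId, atoms$resNo, atoms$insert, atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    sel <- if (policy == "highest_occupancy")
      idx[order(-atoms$occupancy[idx], atoms$altLoc[idx])][1]
    else idx[1]
    keep[setdiff(idx, sel)] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altLoc <- ""
  rownames(atoms) <- NULL
  atoms
}

#' Construct a structure from an atom table
#'
#' @param atoms atom data.frame (see \code{\linkS4class{PDBStructure}}).
#' @param title title string.
#' @param seqres optional named list of 3-letter code vectors per chain.
#' @return A \code{PDBStructure}.
#' @export
structureFromAtoms <- function(atoms, title = "", seqres = list()) {
  rownames(atoms) <- NULL
  new("PDBStructure", title = title, atoms = atoms, seqres = seqres)
}

#' Replace the coordinates of a structure
#'
#' @param s a \code{PDBStructure}.
#' @param coords n x 3 coordinate matrix in atom-table order.
#' @return A \code{PDBStructure} with updated coordinates.
#' @export
setCoords <- function(s, coords) {
  stopifnot(nrow(coords) == nrow(s@atoms), ncol(coords) == 3)
  s@atoms$x <- coords[, 1]; s@atoms$y <- coords[, 2]; s@atoms$z <- coords[, 3]
  s
}

#' Extract atom coordinates
#'
#' @param s a \code{PDBStructure}.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(s) .coordMatrix(s@atoms)

#' Write a structure to a PDB file
#'
#' Round-trips through \code{readStructure} preserving atom count, names,
#' coordinates to 3 decimals and B-factors to 2 decimals.
#'
#' @param s a \code{PDBStructure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(s, path) {
  a <- s@atoms
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, ": no such directory")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(.coordMatrix(a))),
                   type = ifelse(a$isHetero, "HETATM", "ATOM"),
                   resno = a$resNo, resid = a$resName, eleno = a$serial,
                   elety = a$name, chain = a$chainId,
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   alt = ifelse(nzchar(a$altLoc), a$altLoc, NA),
                   o = a$occupancy, b = a$b, elesy = a$element,
                   verbose = FALSE)
  invisible(path)
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' Frames are written as MODEL/ENDMDL blocks, e.g. the frames saved by
#' \code{\link{runGeoSim}} (at the default 500 steps with every 50th saved,
#' at most 11 frames including frame 0).
#'
#' @param frames a list of \code{PDBStructure} frames, or an
#'   \code{\linkS4class{Ensemble}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEnsemble <- function(frames, path) {
  if (is(frames, "Ensemble")) frames <- ensembleStructures(frames)
  if (!length(frames)) stop("empty frame list")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(frames)) {
    writeStructure(frames[[i]], tmp)
    lines <- readLines(tmp)
    lines <- lines[!grepl("^END", lines)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Materialize ensemble frames as structures
#'
#' @param e an \code{\linkS4class{Ensemble}}.
#' @return list of \code{PDBStructure}, one per frame.
#' @export
ensembleStructures <- function(e) {
  base <- structureFromAtoms(e@atoms, title = "ensemble frame")
  lapply(e@frames, function(f) setCoords(base, f))
}

# ---- internal selection helpers ----

.regionRows <- function(atoms, region) {
  which(atoms$chainId == region@chainId &
        atoms$resNo >= region@firstResidue &
        atoms$resNo <= region@lastResidue)
}

# Calpha rows of protein residues, one per residue (first altloc kept)
.calphaRows <- function(atoms) {
  idx <- which(atoms$name == "CA" & !atoms$isHetero &
               atoms$element != "H")
  key <- paste(atoms$chainId[idx], atoms$resNo[idx], atoms$insert[idx])
  idx[!duplicated(key)]
}

# residues in file order: data.frame(chainId, resNo, insert, resName, rows)
.residueTable <- function(atoms) {
  key <- paste(atoms$chainId, atoms$resNo, atoms$insert, sep = "\r")
  first <- which(!duplicated(key))
  data.frame(chainId = atoms$chainId[first], resNo = atoms$resNo[first],
             insert = atoms$insert[first], resName = atoms$resName[first],
             key = key[first], stringsAsFactors = FALSE)
}

.residueRowIndex <- function(atoms) {
  key <- paste(atoms$chainId, atoms$resNo, atoms$insert, sep = "\r")
  split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
}
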